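#' Pit aperture fraction
#'
#' Computes the aperture fraction `F_AP = A_Pit_Ap / A_Pit` for every pit and
#' aggregates as the mean of the per-pit ratios (not the ratio of the mean
#' areas -- the two differ whenever pit sizes vary).
#'
#' @param pits Data frame with columns `A_Pit` (bordered pit area, > 0) and
#'   `A_Pit_Ap` (pit aperture area, `0 <= A_Pit_Ap <= A_Pit`), in any common
#'   area unit.
#' @return A list: `per_pit` (tibble with an added `f_ap` column), `mean`,
#'   `sd` of the per-pit fractions.
#' @export
aperture_fraction <- function(pits) {
  stopifnot(is.data.frame(pits), all(c("A_Pit", "A_Pit_Ap") %in% names(pits)))
  if (any(pits$A_Pit <= 0)) abort("every bordered pit area must be positive")
  if (any(pits$A_Pit_Ap < 0 | pits$A_Pit_Ap > pits$A_Pit)) {
    abort("pit aperture area must lie in [0, A_Pit] for every pit")
  }
  out <- tibble::as_tibble(pits)
  out$f_ap <- out$A_Pit_Ap / out$A_Pit
  list(per_pit = out, mean = mean(out$f_ap),
       sd = if (nrow(out) > 1) sd(out$f_ap) else NA_real_)
}

#' Pit membrane thickness from measurement triplets
#'
#' Each membrane's thickness is the mean of exactly three measurements taken
#' along the membrane; the group summary is the mean and SD over membranes.
#'
#' @param triplets A numeric matrix or data frame with 3 columns (one row per
#'   membrane), or a list of length-3 numeric vectors. All measurements in
#'   nm, > 0.
#' @return A list: `per_pit` (numeric vector of per-membrane means), `mean`,
#'   `sd`.
#' @export
membrane_thickness <- function(triplets) {
  if (is.list(triplets) && !is.data.frame(triplets)) {
    if (any(lengths(triplets) != 3L)) {
      abort("each membrane needs exactly 3 thickness measurements")
    }
    triplets <- do.call(rbind, triplets)
  }
  m <- as.matrix(triplets)
  if (ncol(m) != 3L) abort("each membrane needs exactly 3 thickness measurements")
  if (!is.numeric(m) || any(m <= 0)) abort("thickness measurements must be positive")
  per_pit <- rowMeans(m)
  list(per_pit = unname(per_pit), mean = mean(per_pit),
       sd = if (length(per_pit) > 1) sd(per_pit) else NA_real_)
}

#' Two-group trait comparison with normality and variance pretests
#'
#' Runs Shapiro--Wilk on each group and Levene's test (centred on the group
#' means) for homogeneity of variance, then a two-sided Student's t-test:
#' pooled-variance when Levene's p > alpha, Welch's otherwise. The branch
#' taken is always reported.
#'
#' @param group_a,group_b Numeric vectors (each n >= 3, with spread in at
#'   least one group).
#' @param alpha Significance level for the pretest and the flag.
#' @return A one-row tibble: `n_a`, `n_b`, `normality_p_a`, `normality_p_b`,
#'   `variance_homogeneity_p`, `method` (`"pooled"`/`"welch"`),
#'   `t_statistic`, `df`, `p_value`, `significant`.
#' @export
compare_trait <- function(group_a, group_b, alpha = 0.05) {
  group_a <- as.numeric(group_a); group_b <- as.numeric(group_b)
  if (length(group_a) < 3L || length(group_b) < 3L) {
    abort("each group needs at least 3 observations")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    abort("both groups have zero variance: the tests are undefined")
  }
  sw_a <- if (sd(group_a) > 0) shapiro.test(group_a)$p.value else NA_real_
  sw_b <- if (sd(group_b) > 0) shapiro.test(group_b)$p.value else NA_real_
  values <- c(group_a, group_b)
  grp <- factor(rep(c("a", "b"), c(length(group_a), length(group_b))))
  lev_p <- car::leveneTest(values, grp, center = mean)[1, "Pr(>F)"]
  pooled <- is.finite(lev_p) && lev_p > alpha
  tt <- t.test(group_a, group_b, var.equal = pooled)
  tibble::tibble(
    n_a = length(group_a), n_b = length(group_b),
    normality_p_a = sw_a, normality_p_b = sw_b,
    variance_homogeneity_p = lev_p,
    method = if (pooled) "pooled" else "welch",
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value,
    significant = tt$p.value < alpha
  )
}

#' Spearman rank correlation with a permutation p-value
#'
#' Spearman's rho with average ranks for ties. The two-sided p-value is
#' exact (full enumeration of permutations) for n <= 8 and Monte-Carlo
#' (seeded, `n_perm` draws) otherwise; the asymptotic p-value from the
#' t-approximation is reported alongside.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, non-constant.
#' @param n_perm Monte-Carlo permutations when n > 8.
#' @param seed Optional integer seed for the Monte-Carlo case.
#' @return A one-row tibble: `rho`, `p_value` (permutation), `p_asymptotic`,
#'   `n`, `method`.
#' @export
rank_correlation <- function(x, y, n_perm = 10000L, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (n < 4L) abort("at least 4 pairs are required")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vectors have no rank correlation")

  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p_asym <- if (is.finite(tstat)) 2 * pt(-abs(tstat), n - 2) else 0

  if (n <= 8L) {
    perms <- all_permutations(n)
    rho_perm <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p_perm <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    p_perm <- with_seed(seed, {
      hits <- sum(vapply(seq_len(n_perm), function(i) {
        abs(cor(rx, ry[sample.int(n)])) >= abs(rho) - 1e-12
      }, logical(1)))
      (hits + 1) / (n_perm + 1)
    })
    method <- "Monte-Carlo permutation"
  }
  tibble::tibble(rho = rho, p_value = p_perm, p_asymptotic = p_asym,
                 n = n, method = method)
}

# All permutations of 1..n as a matrix (n! rows); n <= 8 keeps this small.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Compare every trait between organs of each species
#'
#' Applies [compare_trait()] to each species x trait cell of a long anatomy
#' table, comparing leaf midrib against branch -- the trait-table analysis in
#' tidy form.
#'
#' @param table Long tibble from [generate_anatomy_table()] (columns
#'   `species`, `organ` in `{leaf_midrib, branch}`, `trait`, `value`).
#' @param alpha Significance level.
#' @return A tibble with one row per species x trait, the [compare_trait()]
#'   columns, and group means/SDs.
#' @export
compare_anatomy_table <- function(table, alpha = 0.05) {
  stopifnot(is.data.frame(table),
            all(c("species", "organ", "trait", "value") %in% names(table)))
  cells <- dplyr::distinct(table[c("species", "trait")])
  purrr::pmap_dfr(cells, function(species, trait) {
    a <- table$value[table$species == species & table$trait == trait &
                       table$organ == "leaf_midrib"]
    b <- table$value[table$species == species & table$trait == trait &
                       table$organ == "branch"]
    res <- compare_trait(a, b, alpha = alpha)
    dplyr::bind_cols(
      tibble::tibble(species = species, trait = trait,
                     mean_midrib = mean(a), sd_midrib = sd(a),
                     mean_branch = mean(b), sd_branch = sd(b)),
      res
    )
  })
}
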