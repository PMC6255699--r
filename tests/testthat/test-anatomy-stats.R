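test_that("aperture fraction is the mean of per-pit ratios", {
  pits <- tibble::tibble(A_Pit = c(10, 20), A_Pit_Ap = c(1, 1))
  out <- aperture_fraction(pits)
  expect_equal(out$per_pit$f_ap, c(0.10, 0.05))
  expect_equal(out$mean, 0.075)          # not 2/30 = 0.0667
  expect_false(isTRUE(all.equal(out$mean, 2 / 30)))

  full <- aperture_fraction(tibble::tibble(A_Pit = c(3, 8), A_Pit_Ap = c(3, 8)))
  expect_equal(full$mean, 1)
  none <- aperture_fraction(tibble::tibble(A_Pit = c(3, 8), A_Pit_Ap = c(0, 0)))
  expect_equal(none$mean, 0)
  expect_error(aperture_fraction(tibble::tibble(A_Pit = 5, A_Pit_Ap = 6)),
               "\\[0, A_Pit\\]")
})

test_that("aperture fraction is invariant to order and area rescaling", {
  set.seed(12)
  pits <- tibble::tibble(A_Pit = runif(30, 2, 30))
  pits$A_Pit_Ap <- pits$A_Pit * runif(30, 0, 1)
  base <- aperture_fraction(pits)
  shuffled <- aperture_fraction(pits[sample(30), ])
  expect_equal(base$mean, shuffled$mean)
  expect_equal(base$sd, shuffled$sd)
  scaled <- aperture_fraction(dplyr::mutate(pits, A_Pit = A_Pit * 7.3,
                                            A_Pit_Ap = A_Pit_Ap * 7.3))
  expect_equal(base$mean, scaled$mean)
})

test_that("membrane thickness averages triplets and summarises over pits", {
  expect_equal(membrane_thickness(rbind(c(200, 200, 200)))$per_pit, 200)
  expect_equal(membrane_thickness(rbind(c(150, 240, 210)))$per_pit, 200)
  two <- membrane_thickness(rbind(c(200, 200, 200), c(300, 300, 300)))
  expect_equal(two$mean, 250)
  expect_equal(two$sd, 70.71, tolerance = 1e-3)
  expect_error(membrane_thickness(rbind(c(200, 210))), "exactly 3")
  expect_error(membrane_thickness(list(c(1, 2, 3, 4))), "exactly 3")
  expect_error(membrane_thickness(rbind(c(-5, 200, 210))), "positive")
})

test_that("identical groups give t = 0, p = 1", {
  g <- c(1, 2, 3, 4, 5)
  res <- compare_trait(g, g)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("pooled t matches the closed-form two-sample statistic", {
  res <- compare_trait(c(1, 2, 3, 4, 5), c(3, 4, 5, 6, 7))
  expect_equal(res$method, "pooled")
  expect_equal(res$t_statistic, -2)
  expect_equal(res$df, 8)
  # closed-form oracle on random inputs
  pooled_t <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1))
    res <- compare_trait(a, b)
    if (res$method == "pooled") {
      expect_equal(res$t_statistic, pooled_t(a, b), tolerance = 1e-12)
    } else {
      expect_equal(res$t_statistic, unname(t.test(a, b)$statistic),
                   tolerance = 1e-12)
    }
  }
})

test_that("Welch branch engages when variances differ", {
  set.seed(42)
  a <- rnorm(40, 0, 1)
  b <- rnorm(40, 0, 6)
  res <- compare_trait(a, b)
  expect_lt(res$variance_homogeneity_p, 0.05)
  expect_equal(res$method, "welch")
  expect_error(compare_trait(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(compare_trait(1:2, 1:5), "at least 3")
})

test_that("wall-thickness contrast detects branch > leaf at large n", {
  set.seed(8)
  leaf <- rnorm(50, 2.01, 0.32)
  branch <- rnorm(50, 2.27, 0.46)
  res <- compare_trait(leaf, branch)
  expect_true(res$significant)
  expect_lt(res$t_statistic, 0)  # branch thicker than leaf
})

test_that("full pretest-then-t procedure keeps its type-I error near alpha", {
  rejections <- vapply(1:2000, function(s) {
    set.seed(s)
    compare_trait(rnorm(30), rnorm(30))$significant
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Spearman rho matches the closed rank formula and catches monotone", {
  expect_equal(rank_correlation(1:6, c(2, 4, 9, 11, 30, 31))$rho, 1)
  expect_equal(rank_correlation(1:6, -c(2, 4, 9, 11, 30, 31))$rho, -1)
  res <- rank_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$rho, 0.6)
  expect_equal(res$method, "exact permutation")
  # brute-force 1 - 6*sum(d^2)/(n(n^2-1)) on 100 tie-free random vectors
  for (s in 1:100) {
    set.seed(s)
    n <- sample(4:12, 1)
    x <- sample(1000, n); y <- sample(1000, n)
    d <- rank(x) - rank(y)
    expect_equal(rank_correlation(x, y, n_perm = 10, seed = 1)$rho,
                 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  }
  expect_error(rank_correlation(rep(1, 5), 1:5), "constant")
  expect_error(rank_correlation(1:3, 1:3), "at least 4")
})

test_that("exact permutation p-value equals full-enumeration oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 5, 1, 4, 3)
  res <- rank_correlation(x, y)
  # oracle: enumerate all 120 permutations directly
  perms <- expand.grid(rep(list(1:5), 5))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y[unlist(p)])))
  obs <- cor(rank(x), rank(y))
  expect_equal(res$p_value, mean(abs(rhos) >= abs(obs) - 1e-12))
  # Monte-Carlo branch is deterministic under seed
  xx <- 1:12; yy <- c(3, 1, 5, 2, 8, 6, 12, 7, 9, 4, 11, 10)
  a <- rank_correlation(xx, yy, n_perm = 500, seed = 9)
  b <- rank_correlation(xx, yy, n_perm = 500, seed = 9)
  expect_identical(a, b)
  expect_equal(a$method, "Monte-Carlo permutation")
})

test_that("printed membrane-vs-P50 correlation is not reproducible from table means", {
  # six (T_PM, P50) pairs as printed for midribs and branches of the three
  # species; neither Spearman nor Pearson on these rounded means gives -0.92,
  # which is why that value is not asserted anywhere else in this package.
  t_pm <- c(240, 165, 498, 492, 305, 268)
  p50 <- c(-2.87, -1.80, -6.46, -9.21, -2.01, -2.10)
  rho <- rank_correlation(t_pm, p50)$rho
  pear <- cor(t_pm, p50)
  expect_lt(rho, 0)           # direction agrees: thicker membranes, lower P50
  expect_lt(pear, 0)
  expect_gt(abs(rho - (-0.92)), 0.02)
  expect_gt(abs(pear - (-0.92)), 0.02)
})

test_that("anatomy-table comparison runs per species x trait", {
  spec0 <- dplyr::filter(anatomy_presets(), species == "betula",
                         trait %in% c("T_PM", "T_CW"))
  tab <- generate_anatomy_table(spec0, seed = 77)
  res <- compare_anatomy_table(tab)
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$significant, res$p_value < 0.05)
})
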