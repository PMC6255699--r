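#' Sample a synthetic conduit population for one vein cross-section
#'
#' Draws conduit lumen areas from a lognormal distribution parameterised so
#' that the population mean and standard deviation equal the requested
#' moments, and places the corresponding non-overlapping disks in a square
#' field by rejection sampling. The lognormal is used because conduit areas
#' are strictly positive and right-skewed.
#'
#' @param n_conduits Number of conduits to place (may be 0).
#' @param area_mean_um2,area_sd_um2 Target population mean and SD of lumen
#'   area (um^2).
#' @param field_um Side length of the square placement field (um).
#' @param seed Optional integer seed; the call is deterministic under a fixed
#'   seed and leaves the caller's RNG state untouched.
#' @param vein One of `"midrib"`, `"order23"`, `"branch"`; recorded in the
#'   `vein` column.
#' @param species Free-text species label.
#' @param margin_um Clearance kept between a lumen edge and the field border
#'   (room for the rendered cell wall).
#' @param min_gap_um Minimum edge-to-edge clearance between neighbouring
#'   lumina (um); emulates the shared cell walls that separate real conduit
#'   lumina and keeps rasterised disks from fusing into one dark component.
#' @param max_attempts Rejection-sampling attempts allowed per conduit before
#'   the configuration is declared over-dense.
#'
#' @return A tibble with one row per conduit: `center_x_um`, `center_y_um`,
#'   `area_um2`, `embolism_threshold_MPa` (`NA` until
#'   [assign_embolism_thresholds()] is called), `vein`, `species`.
#' @seealso [assign_embolism_thresholds()], [render_scan_pair()]
#' @export
sample_conduit_population <- function(n_conduits,
                                      area_mean_um2 = 96,
                                      area_sd_um2 = 66,
                                      field_um = 180,
                                      seed = NULL,
                                      vein = c("midrib", "order23", "branch"),
                                      species = "synthetic",
                                      margin_um = 2,
                                      min_gap_um = 2,
                                      max_attempts = 5000L) {
  vein <- match.arg(vein)
  stopifnot(n_conduits >= 0, area_mean_um2 > 0, area_sd_um2 >= 0, field_um > 0)
  n_conduits <- as.integer(n_conduits)

  empty <- tibble::tibble(
    center_x_um = numeric(0), center_y_um = numeric(0), area_um2 = numeric(0),
    embolism_threshold_MPa = numeric(0), vein = character(0),
    species = character(0)
  )
  if (n_conduits == 0L) return(empty)

  with_seed(seed, {
    areas <- rlnorm_moments(n_conduits, area_mean_um2, area_sd_um2)
    radii <- sqrt(areas / pi)
    # largest disks first: markedly better packing for the same field
    ord <- order(radii, decreasing = TRUE)
    radii_s <- radii[ord]
    if (2 * max(radii_s) + 2 * margin_um > field_um) {
      abort(paste0(
        "placement field (", field_um, " um) cannot fit a conduit of radius ",
        round(max(radii_s), 1), " um"
      ))
    }
    cx <- cy <- numeric(n_conduits)
    for (i in seq_len(n_conduits)) {
      r <- radii_s[i]
      lo <- r + margin_um
      hi <- field_um - r - margin_um
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        x <- stats::runif(1, lo, hi)
        y <- stats::runif(1, lo, hi)
        if (i == 1L ||
            all((x - cx[seq_len(i - 1L)])^2 + (y - cy[seq_len(i - 1L)])^2 >
                (r + radii_s[seq_len(i - 1L)] + min_gap_um)^2)) {
          cx[i] <- x; cy[i] <- y
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        abort(paste0(
          "failed to place conduit ", i, " of ", n_conduits, " after ",
          max_attempts, " attempts: field too dense for the requested areas"
        ))
      }
    }
    inv <- order(ord)
    tibble::tibble(
      center_x_um = cx[inv], center_y_um = cy[inv], area_um2 = areas,
      embolism_threshold_MPa = NA_real_, vein = vein, species = species
    )
  })
}

# Lognormal draws with *arithmetic* mean m and SD s.
rlnorm_moments <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  sig2 <- log(1 + (s / m)^2)
  rlnorm(n, meanlog = log(m) - sig2 / 2, sdlog = sqrt(sig2))
}

#' Assign per-conduit embolism thresholds realising a target sigmoid
#'
#' Each conduit receives an air-seeding threshold drawn from a logistic
#' distribution with location `b_MPa` (the P50) and scale `25 / S`. A conduit
#' is embolized at xylem water potential psi iff psi <= threshold, so the
#' probability a conduit is gas-filled at psi equals
#' `1 / (1 + exp((S/25) * (psi - b)))` -- the vulnerability sigmoid as a
#' fraction. Thresholds are drawn independently of conduit area, which makes
#' the *expected conductance-weighted* percent loss of conductance equal the
#' same sigmoid.
#'
#' @param pop Conduit population tibble from [sample_conduit_population()].
#' @param b_MPa P50 of the target vulnerability curve (MPa, negative).
#' @param S Slope of the curve at P50 (percent per MPa, positive).
#' @param seed Optional integer seed.
#' @return `pop` with `embolism_threshold_MPa` filled in.
#' @export
assign_embolism_thresholds <- function(pop, b_MPa, S, seed = NULL) {
  stopifnot(is.data.frame(pop))
  if (!is.numeric(S) || length(S) != 1L || S <= 0) {
    abort("`S` must be a single positive slope (percent per MPa)")
  }
  if (!is.numeric(b_MPa) || length(b_MPa) != 1L || b_MPa >= 0) {
    abort("`b_MPa` must be a single negative water potential (MPa)")
  }
  with_seed(seed, {
    pop$embolism_threshold_MPa <- rlogis(nrow(pop), location = b_MPa,
                                         scale = 25 / S)
    pop
  })
}

#' Which conduits are embolized at a given water potential?
#'
#' @param pop Conduit population with thresholds assigned.
#' @param psi_MPa Xylem water potential (MPa, <= 0).
#' @return Logical vector, one element per conduit.
#' @export
is_embolized <- function(pop, psi_MPa) {
  if (anyNA(pop$embolism_threshold_MPa)) {
    abort("population has no embolism thresholds; call assign_embolism_thresholds() first")
  }
  psi_MPa <= pop$embolism_threshold_MPa
}

#' The vulnerability sigmoid
#'
#' Percent loss of conductance as a function of xylem water potential:
#' `PLC(psi) = 100 / (1 + exp((S/25) * (psi - b)))`, so `PLC(b) = 50` and the
#' slope of the curve at `b` is `-S` percent per MPa.
#'
#' @param psi_MPa Water potential (MPa), vectorised.
#' @param b_MPa P50 (MPa).
#' @param S Slope parameter (percent per MPa).
#' @return PLC in percent, same length as `psi_MPa`.
#' @export
plc_sigmoid <- function(psi_MPa, b_MPa, S) {
  100 / (1 + exp((S / 25) * (psi_MPa - b_MPa)))
}
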