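#' Generate a synthetic centrifuge (cavitron) vulnerability run
#'
#' Emulates the flow-centrifuge protocol: the imposed pressure starts at
#' `start_MPa` (default -0.58 MPa) and is stepwise decreased until the
#' noiseless percent loss of conductivity reaches at least 90%. Observed PLC
#' is the vulnerability sigmoid plus Gaussian measurement noise, clamped to
#' [0, 100].
#'
#' @param b_MPa,S True curve parameters (P50 in MPa, slope in percent/MPa).
#' @param start_MPa First imposed pressure (MPa, negative).
#' @param step_MPa Pressure step (MPa, negative).
#' @param noise_sd SD of Gaussian PLC noise (percent).
#' @param seed Optional integer seed.
#' @param max_steps Safety bound on the number of pressure steps.
#' @return A tibble (`pressure_MPa`, `plc_percent`) with attributes
#'   `true_b_MPa` and `true_S`; the last row is the first grid point whose
#'   noiseless PLC is >= 90.
#' @export
generate_centrifuge_run <- function(b_MPa, S, start_MPa = -0.58,
                                    step_MPa = -0.25, noise_sd = 2,
                                    seed = NULL, max_steps = 500L) {
  stopifnot(start_MPa < 0, step_MPa < 0, S > 0, b_MPa < 0, noise_sd >= 0)
  pressures <- seq(start_MPa, by = step_MPa, length.out = max_steps)
  clean <- plc_sigmoid(pressures, b_MPa, S)
  stop_at <- which(clean >= 90)[1]
  if (is.na(stop_at)) {
    abort("sigmoid never reaches 90% PLC within `max_steps` pressure steps")
  }
  pressures <- pressures[seq_len(stop_at)]
  clean <- clean[seq_len(stop_at)]
  with_seed(seed, {
    obs <- clean + rnorm(length(clean), 0, noise_sd)
    out <- tibble::tibble(
      pressure_MPa = pressures,
      plc_percent = pmin(100, pmax(0, obs))
    )
    attr(out, "true_b_MPa") <- b_MPa
    attr(out, "true_S") <- S
    out
  })
}

#' Generate a synthetic anatomical trait table
#'
#' Draws per-replicate trait values as Gaussian around the requested cell
#' means, truncated at zero for non-negative traits (and to [0, 1] for the
#' pit aperture fraction) by redrawing out-of-range values.
#'
#' @param spec A data frame with columns `species`, `organ`, `trait`, `mean`,
#'   `sd`, `n` (one row per table cell; `n >= 2`, `sd >= 0`).
#' @param seed Optional integer seed.
#' @return A long tibble: `species`, `organ`, `trait`, `value`, `unit`.
#' @export
generate_anatomy_table <- function(spec, seed = NULL) {
  stopifnot(is.data.frame(spec),
            all(c("species", "organ", "trait", "mean", "sd", "n") %in%
                  names(spec)))
  if (any(spec$sd < 0)) abort("`sd` must be non-negative")
  if (any(spec$n < 2)) abort("every cell needs n >= 2 replicates")
  with_seed(seed, {
    purrr::pmap_dfr(
      spec[c("species", "organ", "trait", "mean", "sd", "n")],
      function(species, organ, trait, mean, sd, n) {
        upper <- if (trait == "F_AP") 1 else Inf
        unit <- trait_unit(trait)
        tibble::tibble(
          species = species, organ = organ, trait = trait,
          value = rnorm_trunc(n, mean, sd, lower = 0, upper = upper),
          unit = unit
        )
      }
    )
  })
}

# Gaussian draws truncated to [lower, upper] by redrawing.
rnorm_trunc <- function(n, mean, sd, lower = 0, upper = Inf) {
  x <- rnorm(n, mean, sd)
  for (it in 1:1000) {
    bad <- x < lower | x > upper
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmin(upper, pmax(lower, x))
}

trait_unit <- function(trait) {
  switch(trait,
    A_C = "um2", A_Pit = "um2", A_Pit_Ap = "um2",
    F_AP = "fraction", T_PM = "nm", D_PC = "nm", T_CW = "um",
    "unknown"
  )
}

#' Species presets for the three-species embolism study
#'
#' One row per species x organ with the vulnerability-curve parameters
#' (P50 `b_MPa` and slope `S`), the number of scans or branches, and the
#' conduit-area moments used by the conduit generator. P50 values follow the
#' published estimates for *Betula pendula*, *Laurus nobilis* and
#' *Liriodendron tulipifera*; slopes are published only for the *L. nobilis*
#' leaf curves, so the remaining slopes are package defaults (see the
#' methods vignette).
#'
#' Each microCT organ also carries its campaign design: the number of
#' conduits per simulated cross-section (`n_conduits`, fewer for the
#' larger-conduit species), the rendered frame side (`field_um`), and the
#' water-potential floor of the scan campaign (`psi_min_MPa`): scans are
#' spread evenly from -0.5 MPa down to the potential where the expected
#' curve reaches about 97% PLC (capped at the -9.5 MPa drying limit),
#' mirroring the stop-at-saturation practice of the centrifuge protocol.
#'
#' @return A tibble with columns `species`, `organ`, `source`, `b_MPa`,
#'   `b_se`, `S`, `n_samples`, `area_mean_um2`, `area_sd_um2`, `n_conduits`,
#'   `field_um`, `psi_min_MPa`.
#' @export
species_presets <- function() {
  out <- tibble::tribble(
    ~species,        ~organ,        ~source,             ~b_MPa, ~b_se, ~S,    ~n_samples, ~area_mean_um2, ~area_sd_um2, ~n_conduits, ~field_um,
    "betula",        "leaf_midrib", "microct_midrib",    -2.87,  0.14,  40,    16L,        96,             66,           50L,         190,
    "betula",        "order23",     "microct_order23",   -3.28,  0.31,  40,    13L,        96,             66,           50L,         190,
    "betula",        "branch",      "centrifuge_branch", -1.80,  0.01,  60,    6L,         219,            115,          NA_integer_, NA,
    "laurus",        "leaf_midrib", "microct_midrib",    -6.46,  0.24,  14.76, 26L,        231,            87,           35L,         220,
    "laurus",        "order23",     "microct_order23",   -7.83,  0.74,  7.75,  21L,        231,            87,           35L,         220,
    "laurus",        "branch",      "centrifuge_branch", -9.21,  0.23,  30,    4L,         278,            114,          NA_integer_, NA,
    "liriodendron",  "leaf_midrib", "microct_midrib",    -2.01,  0.09,  40,    24L,        171,            33,           40L,         210,
    "liriodendron",  "order23",     "microct_order23",   -2.14,  0.17,  40,    20L,        171,            33,           40L,         210,
    "liriodendron",  "branch",      "centrifuge_branch", -2.10,  0.02,  60,    4L,         409,            158,          NA_integer_, NA
  )
  out$psi_min_MPa <- ifelse(out$organ == "branch", NA,
                            pmax(-9.5, out$b_MPa - 3.5 * 25 / out$S))
  out
}

#' Anatomical trait presets (mean +/- SD per species x organ)
#'
#' Cell means and SDs for conduit area (A_C, um^2), bordered pit area
#' (A_Pit, um^2), pit aperture area (A_Pit_Ap, um^2), pit aperture fraction
#' (F_AP), pit membrane thickness (T_PM, nm), pit chamber depth (D_PC, nm)
#' and interconduit wall thickness (T_CW, um) for the three study species,
#' with replicate counts reflecting the measurement protocols (>= 50 conduits
#' for areas, >= 100 pits for SEM pit geometry, 15--25 pits for TEM
#' thicknesses).
#'
#' @return A tibble usable as the `spec` of [generate_anatomy_table()].
#' @export
anatomy_presets <- function() {
  cells <- tibble::tribble(
    ~species, ~organ,        ~trait,     ~mean,  ~sd,
    "betula", "leaf_midrib", "A_C",      96,     66,
    "betula", "branch",      "A_C",      219,    115,
    "betula", "leaf_midrib", "A_Pit",    4.54,   0.91,
    "betula", "branch",      "A_Pit",    3.01,   0.86,
    "betula", "leaf_midrib", "A_Pit_Ap", 1.28,   0.65,
    "betula", "branch",      "A_Pit_Ap", 0.63,   0.13,
    "betula", "leaf_midrib", "F_AP",     0.35,   0.25,
    "betula", "branch",      "F_AP",     0.24,   0.08,
    "betula", "leaf_midrib", "T_PM",     240,    60,
    "betula", "branch",      "T_PM",     165,    27,
    "betula", "leaf_midrib", "D_PC",     405,    110,
    "betula", "branch",      "D_PC",     560,    131,
    "betula", "leaf_midrib", "T_CW",     2.01,   0.32,
    "betula", "branch",      "T_CW",     2.27,   0.46,
    "laurus", "leaf_midrib", "A_C",      231,    87,
    "laurus", "branch",      "A_C",      278,    114,
    "laurus", "leaf_midrib", "A_Pit",    18.02,  2.81,
    "laurus", "branch",      "A_Pit",    13.77,  3.81,
    "laurus", "leaf_midrib", "A_Pit_Ap", 1.23,   0.18,
    "laurus", "branch",      "A_Pit_Ap", 2.14,   1.24,
    "laurus", "leaf_midrib", "F_AP",     0.08,   0.03,
    "laurus", "branch",      "F_AP",     0.13,   0.09,
    "laurus", "leaf_midrib", "T_PM",     498,    68,
    "laurus", "branch",      "T_PM",     492,    125,
    "laurus", "leaf_midrib", "D_PC",     410,    125,
    "laurus", "branch",      "D_PC",     411,    111,
    "laurus", "leaf_midrib", "T_CW",     3.62,   0.49,
    "laurus", "branch",      "T_CW",     4.48,   0.64,
    "liriodendron", "leaf_midrib", "A_C",      171,   33,
    "liriodendron", "branch",      "A_C",      409,   158,
    "liriodendron", "leaf_midrib", "A_Pit",    22.61, 7.06,
    "liriodendron", "branch",      "A_Pit",    34.61, 8.82,
    "liriodendron", "leaf_midrib", "A_Pit_Ap", 6.66,  3.01,
    "liriodendron", "branch",      "A_Pit_Ap", 5.22,  2.24,
    "liriodendron", "leaf_midrib", "F_AP",     0.29,  0.07,
    "liriodendron", "branch",      "F_AP",     0.27,  0.07,
    "liriodendron", "leaf_midrib", "T_PM",     305,   88,
    "liriodendron", "branch",      "T_PM",     268,   91,
    "liriodendron", "leaf_midrib", "D_PC",     698,   248,
    "liriodendron", "branch",      "D_PC",     805,   87,
    "liriodendron", "leaf_midrib", "T_CW",     3.54,  1.15,
    "liriodendron", "branch",      "T_CW",     2.99,  0.38
  )
  cells$n <- dplyr::case_when(
    cells$trait == "A_C" ~ 50L,
    cells$trait %in% c("A_Pit", "A_Pit_Ap", "F_AP", "D_PC") ~ 100L,
    TRUE ~ 20L
  )
  cells
}
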