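#' Measure one scan pair: segment both images and compute theoretical PLC
#'
#' Segments the pre-cut and post-cut images, pools the detected areas, and
#' converts them to the theoretical percent loss of conductance.
#'
#' @param pair A `scan_pair` from [render_scan_pair()].
#' @param min_area_um2 Minimum component area retained (um^2).
#' @param threshold Grey-level threshold passed to [segment_dark_lumina()];
#'   the default 80 sits between the gas-lumen and background grey levels of
#'   the default render and is robust to the default image noise. Use
#'   `"auto"` for Otsu.
#' @param constants A [hydraulic_constants()] object.
#' @return A one-row tibble: `psi_MPa`, `n_embolized`, `n_total`, `k_init`,
#'   `k_max`, `plc_percent`.
#' @export
measure_scan_pair <- function(pair, min_area_um2 = 4, threshold = 80,
                              constants = hydraulic_constants()) {
  stopifnot(inherits(pair, "scan_pair"))
  px <- pair$params$pixel_size_um
  pre <- segment_dark_lumina(pair$image_pre, px, min_area_um2, threshold,
                             role = "pre_cut")
  post <- segment_dark_lumina(pair$image_post, px, min_area_um2, threshold,
                              role = "post_cut")
  areas <- summarize_scan_pair(pre, post)
  k_init <- sum(theoretical_conductance(
    conduit_diameter(areas$embolized_areas), constants))
  k_max <- sum(theoretical_conductance(
    conduit_diameter(areas$all_areas), constants))
  tibble::tibble(
    psi_MPa = pair$psi_MPa,
    n_embolized = length(areas$embolized_areas),
    n_total = length(areas$all_areas),
    k_init = k_init, k_max = k_max,
    plc_percent = theoretical_plc(areas$embolized_areas, areas$all_areas,
                                  constants)
  )
}

#' Simulate a full microCT vein campaign
#'
#' Generates one scan pair per target water potential (conduit population,
#' per-conduit embolism thresholds, pre-/post-cut renders), segments each
#' pair and computes its theoretical PLC -- the complete in-silico version of
#' a beamline campaign, ready for curve fitting.
#'
#' @param n_scans Number of scan pairs (leaves).
#' @param b_MPa,S True vulnerability-curve parameters.
#' @param psi_range Water-potential range sampled (MPa); scans are evenly
#'   spaced over it.
#' @param n_conduits Conduits per vein cross-section.
#' @param area_mean_um2,area_sd_um2 Conduit-area moments.
#' @param field_um Placement field / rendered frame side (um).
#' @param params Optional [render_params()]; defaults to a frame matching
#'   `field_um` at 0.65 um/px.
#' @param threshold Segmentation threshold (see [measure_scan_pair()]).
#' @param seed Master seed; each scan derives its own child seed.
#' @return A tibble with one row per scan: the [measure_scan_pair()] columns
#'   plus `scan`, `true_plc` (noiseless sigmoid at psi) and
#'   `true_frac_embolized` (ground-truth conductance-weighted PLC).
#' @export
simulate_vein_campaign <- function(n_scans, b_MPa, S,
                                   psi_range = c(-0.5, -9.5),
                                   n_conduits = 50,
                                   area_mean_um2 = 96, area_sd_um2 = 66,
                                   field_um = 180,
                                   params = NULL,
                                   threshold = 80,
                                   seed = NULL) {
  stopifnot(n_scans >= 1)
  if (is.null(params)) params <- field_render_params(field_um)
  psis <- seq(max(psi_range), min(psi_range), length.out = n_scans)
  purrr::map_dfr(seq_len(n_scans), function(i) {
    s <- child_seed(seed, i)
    pop <- sample_conduit_population(
      n_conduits, area_mean_um2, area_sd_um2, field_um = field_um, seed = s
    )
    pop <- assign_embolism_thresholds(pop, b_MPa, S, seed = child_seed(seed, i + n_scans))
    pair <- render_scan_pair(pop, psis[i], params,
                             seed = child_seed(seed, i + 2L * n_scans))
    row <- measure_scan_pair(pair, threshold = threshold)
    k <- theoretical_conductance(conduit_diameter(pop$area_um2))
    row$scan <- i
    row$true_plc <- plc_sigmoid(psis[i], b_MPa, S)
    row$true_frac_embolized <- 100 * sum(k[pair$truth$embolized]) / sum(k)
    row
  })
}

#' Write a rendered scan pair to image files with a JSON sidecar
#'
#' @param pair A `scan_pair`.
#' @param path_prefix Output prefix; writes `<prefix>_pre.<ext>`,
#'   `<prefix>_post.<ext>` and `<prefix>.json` (water potential, pixel size,
#'   ground truth).
#' @param format `"tiff"` or `"png"`.
#' @return The sidecar path, invisibly.
#' @export
write_scan_pair <- function(pair, path_prefix, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(pair, "scan_pair"))
  ext <- if (format == "tiff") ".tif" else ".png"
  writer <- function(img, path) {
    m <- img / 255
    if (format == "tiff") tiff::writeTIFF(m, path, bits.per.sample = 8L)
    else png::writePNG(m, path)
  }
  writer(pair$image_pre, paste0(path_prefix, "_pre", ext))
  writer(pair$image_post, paste0(path_prefix, "_post", ext))
  sidecar <- paste0(path_prefix, ".json")
  jsonlite::write_json(list(
    psi_MPa = pair$psi_MPa,
    pixel_size_um = pair$params$pixel_size_um,
    truth = pair$truth
  ), sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a grayscale cross-section image
#'
#' Reads a TIFF or PNG into a numeric matrix of 8-bit grey levels (0--255).
#' RGB images with identical channels are collapsed; true colour images are
#' rejected.
#'
#' @param path Image path (`.tif`, `.tiff`, `.png`).
#' @return A numeric matrix, rows = image rows.
#' @export
read_scan_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    abort(paste0("unsupported image format: .", ext))
  )
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    flat <- matrix(img, ncol = ch)
    if (any(abs(flat[, 1] - flat) > 1e-9)) {
      abort("image has distinct colour channels; a grayscale image is required")
    }
    img <- img[, , 1]
  }
  round(img * 255)
}

#' Read a (water potential, PLC) observation table
#'
#' @param path CSV with header columns `psi_MPa` and `plc_percent`.
#' @return A tibble with those columns.
#' @export
read_vulnerability_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("psi_MPa", "plc_percent") %in% names(d))) {
    abort("CSV must have columns `psi_MPa` and `plc_percent`")
  }
  tibble::as_tibble(d)
}

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end analysis. Species presets come from
#' [species_presets()]; any subset of species can be run.
#'
#' @param out_dir Output directory (created if missing).
#' @param species Character vector of preset species.
#' @param seed Master seed for the whole run.
#' @param n_conduits Conduits per simulated vein cross-section; `NULL` uses
#'   the per-organ preset value.
#' @param field_um Simulated frame side (um); `NULL` uses the preset.
#' @param psi_range Water-potential range of the microCT campaign (MPa);
#'   `NULL` spans -0.5 MPa to the preset per-organ `psi_min_MPa`.
#' @param threshold Segmentation threshold (grey level or `"auto"`).
#' @param min_area_um2 Minimum detection area (um^2).
#' @param centrifuge_noise_sd PLC noise SD of centrifuge runs (percent).
#' @param centrifuge_step_MPa Pressure step of centrifuge runs (MPa, < 0).
#' @param anatomy_n Override replicate count per anatomy cell (NULL = preset).
#' @param write_plots Write vulnerability-curve PNGs?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            species = c("betula", "laurus", "liriodendron"),
                            seed = 1L,
                            n_conduits = NULL,
                            field_um = NULL,
                            psi_range = NULL,
                            threshold = 80,
                            min_area_um2 = 4,
                            centrifuge_noise_sd = 2,
                            centrifuge_step_MPa = -0.25,
                            anatomy_n = NULL,
                            write_plots = TRUE) {
  species <- match.arg(species, several.ok = TRUE)
  structure(list(
    out_dir = out_dir, species = species, seed = as.integer(seed),
    n_conduits = n_conduits, field_um = field_um, psi_range = psi_range,
    threshold = threshold, min_area_um2 = min_area_um2,
    centrifuge_noise_sd = centrifuge_noise_sd,
    centrifuge_step_MPa = centrifuge_step_MPa,
    anatomy_n = anatomy_n, write_plots = write_plots
  ), class = "pipeline_config")
}

#' Run the end-to-end embolism analysis
#'
#' For each requested species: simulates the microCT campaign for the leaf
#' midrib and the second/third-order veins (generate, render, segment,
#' theoretical PLC), fits both vulnerability curves, simulates and fits
#' per-branch centrifuge runs, performs the three pairwise P50 comparisons by
#' 95%-CI overlap, and runs the organ-contrast statistics on a synthetic
#' anatomy table. Writes per-dataset observation CSVs, fit JSONs, a
#' P50-summary CSV, a comparisons CSV, an anatomy statistics CSV, optional
#' curve plots, the fully-resolved configuration, and a run log.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: `p50_table`, `comparisons`, `anatomy_stats`,
#'   `fits` (named list of `vc_fit`/branch summaries), `log` (character).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", sprintf(...))
    logf <<- c(logf, msg)
  }
  presets <- species_presets()
  presets <- presets[presets$species %in% config$species, ]
  say("run started: species = %s, seed = %d",
      paste(config$species, collapse = ", "), config$seed)

  # resolved config next to the outputs, seed included
  cfg_plain <- unclass(config)
  jsonlite::write_json(cfg_plain, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  fits <- list()
  rows <- list()
  comparisons <- list()

  for (sp in config$species) {
    pre_sp <- presets[presets$species == sp, ]
    sp_seed <- child_seed(config$seed, match(sp, c("betula", "laurus",
                                                   "liriodendron")))
    stage <- function(organ) paste0(sp, "/", organ)

    # --- microCT organs: midrib and order-2/3 veins --------------------
    microct_fits <- list()
    for (organ in c("leaf_midrib", "order23")) {
      p <- pre_sp[pre_sp$organ == organ, ]
      obs <- with_stage(stage(organ), say, simulate_vein_campaign(
        n_scans = p$n_samples, b_MPa = p$b_MPa, S = p$S,
        psi_range = config$psi_range %||% c(-0.5, p$psi_min_MPa),
        n_conduits = config$n_conduits %||% p$n_conduits,
        area_mean_um2 = p$area_mean_um2, area_sd_um2 = p$area_sd_um2,
        field_um = config$field_um %||% p$field_um,
        threshold = config$threshold,
        seed = child_seed(sp_seed, match(organ, c("leaf_midrib", "order23")))
      ))
      say("%s: %d scans, %d-%d conduits detected per scan",
          stage(organ), nrow(obs), min(obs$n_total), max(obs$n_total))
      write.csv(obs, file.path(config$out_dir,
                               paste0(sp, "_", organ, "_observations.csv")),
                row.names = FALSE)
      fit <- with_stage(stage(organ), say,
                        fit_vulnerability_curve(obs, source = p$source,
                                                label = stage(organ)))
      if (!fit$converged) {
        abort(paste0("stage ", stage(organ), ": vulnerability fit failed (",
                     fit$message, "); observations at ",
                     file.path(config$out_dir,
                               paste0(sp, "_", organ, "_observations.csv"))))
      }
      write_fit_json(fit, file.path(config$out_dir,
                                    paste0(sp, "_", organ, "_fit.json")))
      if (isTRUE(config$write_plots)) {
        save_fit_plot(fit, file.path(config$out_dir,
                                     paste0(sp, "_", organ, "_curve.png")))
      }
      microct_fits[[organ]] <- fit
      fits[[stage(organ)]] <- fit
      rows[[stage(organ)]] <- tibble::tibble(
        species = sp, organ = organ, method = "microCT",
        p50_MPa = fit$b_MPa, p50_se = fit$b_se,
        ci95_lo = fit$ci95_b[1], ci95_hi = fit$ci95_b[2],
        slope = fit$S, n = fit$n_obs
      )
    }

    # --- centrifuge branches ------------------------------------------
    p <- pre_sp[pre_sp$organ == "branch", ]
    branch_obs <- purrr::map_dfr(seq_len(p$n_samples), function(j) {
      run <- generate_centrifuge_run(
        b_MPa = p$b_MPa, S = p$S, step_MPa = config$centrifuge_step_MPa,
        noise_sd = config$centrifuge_noise_sd,
        seed = child_seed(sp_seed, 100L + j)
      )
      run$branch <- j
      run
    })
    names(branch_obs)[names(branch_obs) == "pressure_MPa"] <- "psi_MPa"
    write.csv(branch_obs, file.path(config$out_dir,
                                    paste0(sp, "_branch_observations.csv")),
              row.names = FALSE)
    branch <- with_stage(stage("branch"), say, p50_by_branch(branch_obs))
    say("%s: %d branches, mean P50 = %.2f MPa", stage("branch"),
        branch$n_branches, branch$b_MPa)
    fits[[stage("branch")]] <- branch
    rows[[stage("branch")]] <- tibble::tibble(
      species = sp, organ = "branch", method = "centrifuge",
      p50_MPa = branch$b_MPa, p50_se = branch$b_se,
      ci95_lo = branch$ci95_lo, ci95_hi = branch$ci95_hi,
      slope = NA_real_, n = branch$n_branches
    )

    # --- pairwise P50 comparisons (95%-CI overlap) --------------------
    ci_branch <- c(branch$ci95_lo, branch$ci95_hi)
    cmp <- tibble::tribble(
      ~species, ~contrast, ~decision, ~p50_difference,
      sp, "leaf_midrib vs order23",
      compare_by_ci_overlap(microct_fits$leaf_midrib, microct_fits$order23),
      p50_difference(microct_fits$leaf_midrib, microct_fits$order23),
      sp, "leaf_midrib vs branch",
      compare_by_ci_overlap(microct_fits$leaf_midrib, ci_branch),
      p50_difference(microct_fits$leaf_midrib, branch$b_MPa),
      sp, "order23 vs branch",
      compare_by_ci_overlap(microct_fits$order23, ci_branch),
      p50_difference(microct_fits$order23, branch$b_MPa)
    )
    comparisons[[sp]] <- cmp
  }

  # --- anatomy statistics ---------------------------------------------
  aspec <- anatomy_presets()
  aspec <- aspec[aspec$species %in% config$species, ]
  if (!is.null(config$anatomy_n)) aspec$n <- as.integer(config$anatomy_n)
  atab <- generate_anatomy_table(aspec, seed = child_seed(config$seed, 999L))
  write.csv(atab, file.path(config$out_dir, "anatomy_table.csv"),
            row.names = FALSE)
  astats <- with_stage("anatomy_stats", say, compare_anatomy_table(atab))
  say("anatomy_stats: %d trait contrasts, %d significant at 0.05",
      nrow(astats), sum(astats$significant))

  p50_table <- dplyr::bind_rows(rows)
  comparisons <- dplyr::bind_rows(comparisons)
  write.csv(p50_table, file.path(config$out_dir, "p50_table.csv"),
            row.names = FALSE)
  write.csv(comparisons, file.path(config$out_dir, "p50_comparisons.csv"),
            row.names = FALSE)
  write.csv(astats, file.path(config$out_dir, "anatomy_stats.csv"),
            row.names = FALSE)
  say("run finished")
  writeLines(logf, file.path(config$out_dir, "run.log"))

  invisible(list(p50_table = p50_table, comparisons = comparisons,
                 anatomy_stats = astats, fits = fits, log = logf))
}

# Run `expr`; on error, re-raise naming the failed stage.
with_stage <- function(stage, say, expr) {
  tryCatch(expr, error = function(e) {
    say("STAGE FAILED: %s (%s)", stage, conditionMessage(e))
    abort(paste0("stage ", stage, " failed: ", conditionMessage(e)))
  })
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    b_MPa = fit$b_MPa, b_se = fit$b_se, ci95_b = fit$ci95_b,
    S = fit$S, S_se = fit$S_se, ci95_S = fit$ci95_S,
    residual_sd = fit$residual_sd, n_obs = fit$n_obs,
    converged = fit$converged, source = fit$source, label = fit$label,
    residuals = fit$data$plc_percent - plc_sigmoid(fit$data$psi_MPa,
                                                   fit$b_MPa, fit$S)
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

save_fit_plot <- function(fit, path, width = 5, height = 4) {
  p <- autoplot(fit)
  suppressMessages(ggplot2::ggsave(path, p, width = width, height = height,
                                   dpi = 150))
  invisible(path)
}
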