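#' Rendering parameters for synthetic microCT cross-sections
#'
#' Defaults emulate a phase-contrast reconstruction at 0.65 um voxel size
#' with a 1.7 mm field of view (2615 px): water-filled lumina render grey,
#' gas-filled lumina considerably dark, cell walls bright. Smaller frames
#' are routinely used in simulations and tests.
#'
#' @param pixel_size_um Physical pixel size (um).
#' @param image_width_px,image_height_px Frame size in pixels.
#' @param intensity_background,intensity_water_lumen,intensity_gas_lumen,intensity_wall
#'   8-bit grey levels (0--255). Gas must be darker than water.
#' @param gaussian_noise_sd SD of additive Gaussian image noise (grey levels).
#' @param wall_thickness_um Rendered conduit wall thickness (um).
#' @return A list of class `render_params`.
#' @export
render_params <- function(pixel_size_um = 0.65,
                          image_width_px = 2615L,
                          image_height_px = image_width_px,
                          intensity_background = 120,
                          intensity_water_lumen = 140,
                          intensity_gas_lumen = 40,
                          intensity_wall = 170,
                          gaussian_noise_sd = 5,
                          wall_thickness_um = 1.3) {
  stopifnot(
    pixel_size_um > 0, image_width_px >= 1, image_height_px >= 1,
    gaussian_noise_sd >= 0, wall_thickness_um >= 0
  )
  ints <- c(intensity_background, intensity_water_lumen, intensity_gas_lumen,
            intensity_wall)
  if (any(ints < 0 | ints > 255)) abort("intensities must be 8-bit (0-255)")
  if (intensity_gas_lumen >= intensity_water_lumen) {
    abort("gas-filled lumina must be darker than water-filled lumina")
  }
  structure(list(
    pixel_size_um = pixel_size_um,
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    intensity_background = intensity_background,
    intensity_water_lumen = intensity_water_lumen,
    intensity_gas_lumen = intensity_gas_lumen,
    intensity_wall = intensity_wall,
    gaussian_noise_sd = gaussian_noise_sd,
    wall_thickness_um = wall_thickness_um
  ), class = "render_params")
}

#' Frame-sized render parameters for a square field
#'
#' Convenience wrapper around [render_params()] producing a frame that just
#' covers a square field of `field_um` at the given pixel size -- the
#' simulation-scale default used by [simulate_vein_campaign()] and the tests.
#'
#' @param field_um Field side length (um).
#' @param pixel_size_um Physical pixel size (um).
#' @param ... Passed to [render_params()].
#' @return A `render_params` object.
#' @export
field_render_params <- function(field_um, pixel_size_um = 0.65, ...) {
  px <- as.integer(ceiling(field_um / pixel_size_um))
  render_params(pixel_size_um = pixel_size_um, image_width_px = px,
                image_height_px = px, ...)
}

#' Render a pre-cut/post-cut microCT-like scan pair
#'
#' The pre-cut image shows conduits embolized at `psi_MPa` as dark disks and
#' still-functional (water-filled) conduits as grey disks; the post-cut image
#' shows every lumen dark, emulating the cut that embolizes 100% of the
#' water-conducting conduits and provides the maximal-conductance reference.
#' Ground truth is carried along for validation.
#'
#' @param pop Conduit population with embolism thresholds assigned.
#' @param psi_MPa Xylem water potential of the scan (MPa, <= 0).
#' @param params A [render_params()] object; every lumen disk must fit in the
#'   frame.
#' @param seed Optional integer seed (image noise only).
#' @return A list of class `scan_pair`: `psi_MPa`, `image_pre`, `image_post`
#'   (integer matrices, rows = image rows), `truth` (the population tibble
#'   with an `embolized` flag), `params`.
#' @export
render_scan_pair <- function(pop, psi_MPa, params = render_params(),
                             seed = NULL) {
  stopifnot(inherits(params, "render_params"), psi_MPa <= 0)
  emb <- is_embolized(pop, psi_MPa)
  radii <- sqrt(pop$area_um2 / pi)
  w_um <- params$image_width_px * params$pixel_size_um
  h_um <- params$image_height_px * params$pixel_size_um
  if (any(pop$center_x_um - radii < 0 | pop$center_x_um + radii > w_um |
          pop$center_y_um - radii < 0 | pop$center_y_um + radii > h_um)) {
    abort("conduit disk extends outside the image frame: enlarge the frame or regenerate the population")
  }
  with_seed(seed, {
    pre <- draw_cross_section(pop, ifelse(emb, params$intensity_gas_lumen,
                                          params$intensity_water_lumen), params)
    post <- draw_cross_section(pop, rep(params$intensity_gas_lumen, nrow(pop)),
                               params)
    truth <- pop
    truth$embolized <- emb
    structure(list(
      psi_MPa = psi_MPa,
      image_pre = add_image_noise(pre, params$gaussian_noise_sd),
      image_post = add_image_noise(post, params$gaussian_noise_sd),
      truth = truth,
      params = params
    ), class = "scan_pair")
  })
}

# Rasterise lumina (with a bright wall annulus) onto the background.
# A pixel belongs to a disk iff its centre lies within the disk radius;
# pixel (row i, col j), 0-based, has physical centre ((j+0.5), (i+0.5)) * px.
draw_cross_section <- function(pop, lumen_intensity, params) {
  px <- params$pixel_size_um
  img <- matrix(params$intensity_background,
                nrow = params$image_height_px, ncol = params$image_width_px)
  if (nrow(pop) == 0L) return(img)
  radii <- sqrt(pop$area_um2 / pi)
  wall <- params$wall_thickness_um
  for (i in seq_len(nrow(pop))) {
    r <- radii[i]
    rw <- r + wall
    # candidate pixel block (1-based matrix indices)
    c0 <- max(1L, floor((pop$center_x_um[i] - rw) / px) + 1L)
    c1 <- min(params$image_width_px, ceiling((pop$center_x_um[i] + rw) / px))
    r0 <- max(1L, floor((pop$center_y_um[i] - rw) / px) + 1L)
    r1 <- min(params$image_height_px, ceiling((pop$center_y_um[i] + rw) / px))
    cols <- c0:c1; rows <- r0:r1
    dx <- (cols - 0.5) * px - pop$center_x_um[i]
    dy <- (rows - 0.5) * px - pop$center_y_um[i]
    d2 <- outer(dy^2, dx^2, `+`)
    block <- img[rows, cols, drop = FALSE]
    block[d2 <= rw^2] <- params$intensity_wall
    block[d2 <= r^2] <- lumen_intensity[i]
    img[rows, cols] <- block
  }
  img
}

add_image_noise <- function(img, sd) {
  if (sd > 0) img <- img + rnorm(length(img), 0, sd)
  m <- matrix(as.integer(pmin(255, pmax(0, round(img)))),
              nrow = nrow(img), ncol = ncol(img))
  m
}

#' @export
print.scan_pair <- function(x, ...) {
  cat("<scan_pair>  psi =", x$psi_MPa, "MPa;",
      nrow(x$truth), "conduits (", sum(x$truth$embolized), "embolized );",
      nrow(x$image_pre), "x", ncol(x$image_pre), "px @",
      x$params$pixel_size_um, "um/px\n")
  invisible(x)
}
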