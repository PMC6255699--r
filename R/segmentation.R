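#' Segment gas-filled (dark) conduit lumina in a cross-section image
#'
#' Pixels darker than the threshold are foreground; 8-connected components
#' with area at least `min_area_um2` are reported with physical centroid and
#' area. This is the computational analogue of thresholding the image and
#' measuring particle areas by hand.
#'
#' @param image Single-channel numeric matrix of grey levels (0--255), rows =
#'   image rows.
#' @param pixel_size_um Physical pixel size (um).
#' @param min_area_um2 Minimum component area retained (um^2); the default
#'   4 um^2 (~9 px at 0.65 um) rejects speckle while keeping any plausible
#'   tracheid lumen.
#' @param threshold `"auto"` for Otsu's method on the intensity histogram, or
#'   a fixed grey level; pixels strictly below it are foreground.
#' @param role Which scan the image comes from (`"pre_cut"` or `"post_cut"`);
#'   recorded on the result.
#' @return A tibble of class `conduit_map` with one detection per row
#'   (`centroid_x_um`, `centroid_y_um`, `area_um2`), ordered row-major by
#'   centroid, and attributes `pixel_size_um`, `threshold_used`,
#'   `source_role`. An image with no dark components yields zero rows.
#' @export
segment_dark_lumina <- function(image, pixel_size_um = 0.65,
                                min_area_um2 = 4, threshold = "auto",
                                role = c("pre_cut", "post_cut")) {
  role <- match.arg(role)
  if (is.array(image) && length(dim(image)) > 2) {
    abort("`image` must be a single-channel (grayscale) matrix")
  }
  if (!is.matrix(image) || !is.numeric(image)) {
    abort("`image` must be a numeric matrix of grey levels")
  }
  stopifnot(pixel_size_um > 0, min_area_um2 >= 0)

  empty_map <- function(thr) {
    out <- tibble::tibble(centroid_x_um = numeric(0),
                          centroid_y_um = numeric(0),
                          area_um2 = numeric(0))
    new_conduit_map(out, pixel_size_um, thr, role)
  }
  if (length(image) == 0L) return(empty_map(NA_real_))

  if (identical(threshold, "auto")) {
    if (diff(range(image)) == 0) return(empty_map(NA_real_))
    threshold <- 255 * EBImage::otsu(EBImage::Image(t(image) / 255),
                                     range = c(0, 1), levels = 256L)
  }
  stopifnot(is.numeric(threshold), length(threshold) == 1L)

  fg <- image < threshold
  if (!any(fg)) return(empty_map(threshold))

  # EBImage::bwlabel is 4-connected; merge labels touching diagonally to get
  # the 8-connected components the measurement contract requires. Labeling
  # is orientation-neutral, so the matrix is passed without transposition.
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1)))
  lab <- merge_diagonal_labels(lab)

  px_area <- pixel_size_um^2
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * px_area >= min_area_um2)
  if (length(keep) == 0L) return(empty_map(threshold))

  idx <- which(lab > 0L)
  labs <- lab[idx]
  rows0 <- (idx - 1L) %% nrow(lab)        # 0-based row index
  cols0 <- (idx - 1L) %/% nrow(lab)       # 0-based col index
  cx <- unname(rowsum(cols0, labs)[, 1] / sizes + 0.5) * pixel_size_um
  cy <- unname(rowsum(rows0, labs)[, 1] / sizes + 0.5) * pixel_size_um

  out <- tibble::tibble(
    centroid_x_um = cx[keep],
    centroid_y_um = cy[keep],
    area_um2 = sizes[keep] * px_area
  )
  out <- out[order(out$centroid_y_um, out$centroid_x_um), ]
  new_conduit_map(out, pixel_size_um, threshold, role)
}

new_conduit_map <- function(tbl, pixel_size_um, threshold, role) {
  attr(tbl, "pixel_size_um") <- pixel_size_um
  attr(tbl, "threshold_used") <- threshold
  attr(tbl, "source_role") <- role
  class(tbl) <- c("conduit_map", class(tbl))
  tbl
}

# Union labels of 4-connected components that touch only diagonally, then
# relabel 1..k. Vectorised: collect diagonal label pairs, union-find on the
# (small) label set.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L || max(lab) <= 1L) return(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right neighbours
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # down-left neighbours
  m1 <- a1 > 0L & b1 > 0L & a1 != b1
  m2 <- a2 > 0L & b2 > 0L & a2 != b2
  p <- cbind(c(a1[m1], a2[m2]), c(b1[m1], b2[m2]))
  k <- max(lab)
  if (nrow(p) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in seq_len(nrow(p))) {
    ra <- find(p[r, 1]); rb <- find(p[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(k), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

#' Collect embolized and total conduit areas from a segmented scan pair
#'
#' The pre-cut map supplies the areas of conduits already gas-filled in the
#' intact leaf; the post-cut map (all functional conduits cut open, hence
#' 100% embolized) supplies the areas of all conduits. No conduit-by-conduit
#' matching is attempted -- the downstream percent loss of conductance uses
#' totals only.
#'
#' @param pre,post `conduit_map` tibbles from the pre-cut and post-cut images.
#' @return A list with `embolized_areas` and `all_areas` (numeric vectors of
#'   um^2). A pre-cut count exceeding the post-cut count is physically
#'   impossible under the model and raises a warning.
#' @export
summarize_scan_pair <- function(pre, post) {
  stopifnot(is.data.frame(pre), is.data.frame(post))
  pre_px <- attr(pre, "pixel_size_um"); post_px <- attr(post, "pixel_size_um")
  if (!is.null(pre_px) && !is.null(post_px) && !isTRUE(all.equal(pre_px, post_px))) {
    abort("pre-cut and post-cut maps have different pixel sizes")
  }
  if (nrow(pre) > nrow(post)) {
    warn(paste0(
      "pre-cut scan has more detections (", nrow(pre), ") than the post-cut scan (",
      nrow(post), "): physically impossible; check the segmentation"
    ))
  }
  list(embolized_areas = pre$area_um2, all_areas = post$area_um2)
}

#' Write a conduit map to CSV (with a JSON summary sidecar)
#'
#' @param map A `conduit_map`.
#' @param path Output CSV path; a `.json` summary (count, total area, pixel
#'   size, threshold) is written next to it.
#' @return `path`, invisibly.
#' @export
write_conduit_map <- function(map, path) {
  write.csv(as.data.frame(map)[c("centroid_x_um", "centroid_y_um", "area_um2")],
            path, row.names = FALSE)
  summary <- list(
    n_conduits = nrow(map),
    total_area_um2 = sum(map$area_um2),
    pixel_size_um = attr(map, "pixel_size_um"),
    threshold_used = attr(map, "threshold_used"),
    source_role = attr(map, "source_role")
  )
  jsonlite::write_json(summary, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
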