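#' Segment bright cells from a single channel by Otsu thresholding
#'
#' Intended for synthetic or otherwise well-separated, high-contrast images
#' (e.g. a uniform cytoplasmic channel): global Otsu threshold, connected
#' components (8-connectivity), then an area filter. Components are
#' relabeled 1..K in raster (row-major) order of their first pixel.
#'
#' @param image 2D numeric matrix.
#' @param min_area,max_area Component area bounds in px.
#' @return Integer label matrix (0 = background).
#' @export
segment_simple <- function(image, min_area = 50, max_area = Inf) {
  stopifnot(is.matrix(image))
  rng <- range(image, finite = TRUE)
  if (!is.finite(rng[2]) || rng[2] <= rng[1]) {
    warn("image is constant; returning empty mask")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  sc <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(sc))
  lab <- as.matrix(EBImage::bwlabel(sc > thr))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area & sizes <= max_area)
  if (length(keep) == 0L) {
    warn("no components survived the area filter; returning empty mask")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  # raster order of first pixel: row-major scan
  first_px <- vapply(keep, function(k) {
    idx <- which(lab == k)
    pr <- ((idx - 1L) %% nrow(lab)) + 1L
    pc <- ((idx - 1L) %/% nrow(lab)) + 1L
    min((pr - 1L) * ncol(lab) + pc)
  }, numeric(1))
  keep <- keep[order(first_px)]
  out <- matrix(0L, nrow(image), ncol(image))
  for (k in seq_along(keep)) out[lab == keep[k]] <- k
  out
}

#' Extract per-cell geometry from a label mask
#'
#' Fits a straight axis to each labeled component (principal direction of
#' its pixel coordinates); the poles are the extreme pixel-center
#' projections along that axis and the cell length is their separation in
#' µm. Pole ordering is deterministic: `pole_a` is the pole with the
#' smaller row (ties broken by smaller column), so that axial coordinates
#' are reproducible before any intensity-based orientation is applied.
#'
#' Near-isotropic components (principal-axis eigenvalue ratio < 2) are kept
#' but flagged `low_anisotropy`; components under `min_px` pixels are
#' skipped with a warning.
#'
#' @param mask Integer label matrix (0 = background).
#' @param pixel_size Pixel size in µm/px.
#' @param min_px Minimum component size in px.
#' @return A tibble, one row per cell: `cell_id`, `area_px`, pole
#'   coordinates, unit axis vector, centroid, `length_um`,
#'   `low_anisotropy`.
#' @export
extract_geometry <- function(mask, pixel_size, min_px = 5L) {
  stopifnot(is.matrix(mask), pixel_size > 0)
  labs <- sort(unique(mask[mask > 0]))
  rows <- vector("list", length(labs))
  skipped <- 0L
  for (k in seq_along(labs)) {
    idx <- which(mask == labs[k])
    if (length(idx) < min_px) { skipped <- skipped + 1L; next }
    pr <- ((idx - 1L) %% nrow(mask)) + 1L
    pc <- ((idx - 1L) %/% nrow(mask)) + 1L
    ctr <- c(mean(pr), mean(pc))
    cm <- cbind(pr - ctr[1], pc - ctr[2])
    cv <- crossprod(cm) / length(idx)
    eg <- eigen(cv, symmetric = TRUE)
    ax <- eg$vectors[, 1]
    proj <- cm %*% ax
    pa <- ctr + min(proj) * ax
    pb <- ctr + max(proj) * ax
    if (pb[1] < pa[1] || (pb[1] == pa[1] && pb[2] < pa[2])) {
      tmp <- pa; pa <- pb; pb <- tmp; ax <- -ax
    }
    rows[[k]] <- tibble(
      cell_id = labs[k], area_px = length(idx),
      centroid_row = ctr[1], centroid_col = ctr[2],
      axis_row = ax[1], axis_col = ax[2],
      pole_a_row = pa[1], pole_a_col = pa[2],
      pole_b_row = pb[1], pole_b_col = pb[2],
      length_um = (max(proj) - min(proj)) * pixel_size,
      pixel_size = pixel_size,
      low_anisotropy = eg$values[1] < 2 * eg$values[2]
    )
  }
  if (skipped > 0L)
    warn(sprintf("%d component(s) under %d px skipped", skipped, min_px))
  out <- bind_rows(rows)
  if (nrow(out) == 0L)
    out <- tibble(cell_id = integer(), area_px = integer(),
                  centroid_row = double(), centroid_col = double(),
                  axis_row = double(), axis_col = double(),
                  pole_a_row = double(), pole_a_col = double(),
                  pole_b_row = double(), pole_b_col = double(),
                  length_um = double(), pixel_size = double(),
                  low_anisotropy = logical())
  out
}

#' Axial coordinate of points within a cell
#'
#' Projects points onto the cell axis and expresses the position as a
#' fraction `s` of cell length from `pole_a` (clamped to \[0, 1\]) and as
#' `x_um = s * length_um`. Off-axis (perpendicular) offsets do not change
#' `s`.
#'
#' @param row,col Point coordinates in px (vectors of equal length).
#' @param geometry A single-row geometry tibble (one cell) from
#'   [extract_geometry()] or [truth_geometry()].
#' @return A tibble with columns `s` and `x_um`.
#' @export
axial_coordinate <- function(row, col, geometry) {
  stopifnot(nrow(geometry) == 1L, geometry$length_um > 0)
  ab <- c(geometry$pole_b_row - geometry$pole_a_row,
          geometry$pole_b_col - geometry$pole_a_col)
  len_px2 <- sum(ab^2)
  s <- pmin(1, pmax(0, ((row - geometry$pole_a_row) * ab[1] +
                        (col - geometry$pole_a_col) * ab[2]) / len_px2))
  tibble(s = s, x_um = s * geometry$length_um)
}

#' Geometry tibble from ground truth
#'
#' Converts the exact generator truth into the same frame produced by
#' [extract_geometry()], for pipeline runs that bypass mask-based geometry
#' estimation.
#'
#' @param truths A `ground_truth` object (with `$config`).
#' @return A geometry tibble (see [extract_geometry()]).
#' @export
truth_geometry <- function(truths) {
  stopifnot(inherits(truths, "ground_truth"), !is.null(truths$config))
  px <- truths$config$pixel_size
  cells <- truths$cells
  dr <- cells$pole_b_row - cells$pole_a_row
  dc <- cells$pole_b_col - cells$pole_a_col
  n <- sqrt(dr^2 + dc^2)
  tibble(cell_id = cells$cell_id,
         area_px = NA_integer_,
         centroid_row = (cells$pole_a_row + cells$pole_b_row) / 2,
         centroid_col = (cells$pole_a_col + cells$pole_b_col) / 2,
         axis_row = dr / n, axis_col = dc / n,
         pole_a_row = cells$pole_a_row, pole_a_col = cells$pole_a_col,
         pole_b_row = cells$pole_b_row, pole_b_col = cells$pole_b_col,
         length_um = cells$length_um, pixel_size = px,
         low_anisotropy = FALSE)
}
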