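#' Pearson colocalization within one cell mask
#'
#' The Pearson correlation coefficient between two channels over the
#' pixels of a single cell mask — the per-cell analogue of an ROI-based
#' Coloc-2 measurement. Zero variance in either channel yields an
#' undefined (NA) PCC with `flag = "zero_variance"`.
#'
#' @param channel_a,channel_b Channel matrices of identical shape.
#' @param mask Logical matrix, or an integer label matrix with `cell_id`.
#' @param cell_id Cell label to select when `mask` is a label matrix.
#' @param min_px Minimum mask size (default 10 px).
#' @return A one-row tibble: `cell_id`, `pcc`, `n_pixels`, `flag`.
#' @export
pcc_within_mask <- function(channel_a, channel_b, mask, cell_id = NA_integer_,
                            min_px = 10L) {
  if (!all(dim(channel_a) == dim(channel_b)) ||
      !all(dim(channel_a) == dim(mask)))
    abort("channel and mask shapes differ")
  sel <- if (is.logical(mask)) mask else mask == cell_id
  n <- sum(sel)
  if (n < min_px) abort(sprintf("mask has %d px; need >= %d", n, min_px))
  a <- channel_a[sel]; b <- channel_b[sel]
  if (stats::var(a) == 0 || stats::var(b) == 0)
    return(tibble(cell_id = cell_id, pcc = NA_real_, n_pixels = n,
                  flag = "zero_variance"))
  tibble(cell_id = cell_id, pcc = cor(a, b), n_pixels = n,
         flag = NA_character_)
}

#' Per-cell PCC over a whole field
#'
#' @param channels Named list of channel matrices.
#' @param mask Integer label matrix.
#' @param pair Character vector of two channel names.
#' @param min_px Minimum cell size in px; smaller cells are skipped.
#' @return A tibble, one row per cell: `cell_id`, `channel_a`,
#'   `channel_b`, `pcc`, `n_pixels`, `flag`.
#' @export
coloc_cells <- function(channels, mask, pair, min_px = 10L) {
  stopifnot(length(pair) == 2L, all(pair %in% names(channels)))
  labs <- sort(unique(mask[mask > 0L]))
  out <- lapply(labs, function(l) {
    if (sum(mask == l) < min_px) return(NULL)
    pcc_within_mask(channels[[pair[1]]], channels[[pair[2]]], mask, l,
                    min_px = min_px)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L)
    return(tibble(cell_id = integer(), channel_a = character(),
                  channel_b = character(), pcc = double(),
                  n_pixels = integer(), flag = character()))
  mutate(res, channel_a = pair[1], channel_b = pair[2], .after = "cell_id")
}

#' Summarize per-cell PCCs as mean +/- SD
#'
#' Undefined (NA) PCCs are excluded and counted; the SD uses the n - 1
#' denominator and is NA for a single cell.
#'
#' @param results Tibble from [coloc_cells()] (or any tibble with `pcc`).
#' @return A one-row tibble: `mean_pcc`, `sd_pcc`, `n_cells`,
#'   `n_undefined`.
#' @export
summarize_pcc <- function(results) {
  p <- results$pcc
  und <- sum(is.na(p)); p <- p[!is.na(p)]
  if (length(p) == 0L) abort("no defined PCC values")
  tibble(mean_pcc = mean(p),
         sd_pcc = if (length(p) > 1L) stats::sd(p) else NA_real_,
         n_cells = length(p), n_undefined = und)
}
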