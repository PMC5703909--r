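#' Per-cell ParB segregation metrics S and D_min
#'
#' For a cell of length `L` containing two foci, `D1'` is the distance of
#' the left focus (smaller `s`) from `pole_a`, `D2'` the distance of the
#' right focus from `pole_b`, and `D = L - D1' - D2'` the inter-focus
#' distance. After relabeling so that `D1 = min(D1', D2')` and
#' `D2 = max(D1', D2')`, the segregation symmetry coefficient is
#'
#'   `S = D / (D + D2 - D1) x 100%`
#'
#' (100% when the foci sit symmetrically, i.e. D1 = D2) and the normalized
#' pole distance is `D_min = D1 / L x 100%`. By definition S = 0% for a
#' cell with a single focus, whose D_min is its own pole distance
#' normalized to L. Cells with no foci have both metrics undefined; cells
#' with three or more foci have S undefined (they are excluded from
#' symmetry analyses) and D_min taken from the focus nearest a pole.
#' Coincident foci (inter-focus distance D = 0) give S = NA with `flag =
#' "coincident_foci"`, so S lies in (0, 100\] whenever it is defined.
#'
#' Both metrics are invariant under mirror reflection (s -> 1 - s) and
#' under rescaling of the cell.
#'
#' @param foci Focus tibble ([detect_foci()]) with columns `cell_id`, `s`.
#' @param geometry Geometry tibble with `cell_id`, `length_um` (cells with
#'   no detected foci are reported with `n_foci = 0`).
#' @return A tibble, one row per cell: `cell_id`, `n_foci`, `d1_um`,
#'   `d2_um`, `d_um`, `S`, `D_min` (percent), `length_um`, `flag`.
#' @export
compute_segregation_metrics <- function(foci, geometry) {
  stopifnot(all(c("cell_id", "length_um") %in% names(geometry)))
  if (nrow(foci) > 0 && !all(foci$cell_id %in% geometry$cell_id))
    abort("foci reference cells absent from `geometry`")
  rows <- lapply(seq_len(nrow(geometry)), function(i) {
    cid <- geometry$cell_id[i]; L <- geometry$length_um[i]
    s <- sort(foci$s[foci$cell_id == cid])
    x <- s * L
    n <- length(s)
    flag <- NA_character_
    d1 <- d2 <- d <- S <- dmin <- NA_real_
    if (n == 1L) {
      S <- 0
      dmin <- 100 * min(x, L - x) / L
    } else if (n == 2L) {
      d1p <- x[1]               # left focus to pole_a
      d2p <- L - x[2]           # right focus to pole_b
      d <- L - d1p - d2p        # inter-focus distance, >= 0 by ordering
      d1 <- min(d1p, d2p); d2 <- max(d1p, d2p)
      # d = 0 means coincident foci (and is the only way S could reach 0):
      # S is undefined there, keeping S in (0, 100] whenever defined
      if (d > 0) S <- 100 * d / (d + d2 - d1) else flag <- "coincident_foci"
      dmin <- 100 * d1 / L
    } else if (n >= 3L) {
      flag <- "multi_focus"
      dmin <- 100 * min(pmin(x, L - x)) / L
    }
    tibble(cell_id = cid, n_foci = n, d1_um = d1, d2_um = d2, d_um = d,
           S = S, D_min = dmin, length_um = L, flag = flag)
  })
  bind_rows(rows)
}

#' Population summary of segregation metrics
#'
#' Tallies cells by focus count (0, 1, 2, >2, as counts and percentages)
#' and, on request, restricts the S table to two-focus cells — the
#' convention used for symmetry analyses, which consider only cells
#' containing two ParB foci.
#'
#' @param metrics Tibble from [compute_segregation_metrics()].
#' @param s_two_focus_only Restrict `$s_values` to cells with exactly two
#'   foci (default `TRUE`).
#' @return A list: `$cells` (the per-cell metrics), `$tally`
#'   (`focus_class`, `n`, `pct`), `$s_values` (tibble of `cell_id`, `S`;
#'   empty with a warning if no qualifying cells).
#' @export
population_metrics <- function(metrics, s_two_focus_only = TRUE) {
  if (nrow(metrics) == 0L) abort("empty metrics table")
  cls <- cut(metrics$n_foci, c(-0.5, 0.5, 1.5, 2.5, Inf),
             labels = c("0", "1", "2", ">2"))
  tally <- tibble(focus_class = levels(cls),
                  n = as.integer(table(cls))) |>
    mutate(pct = 100 * .data$n / sum(.data$n))
  sv <- if (s_two_focus_only)
    dplyr::filter(metrics, .data$n_foci == 2L, !is.na(.data$S)) else
    dplyr::filter(metrics, !is.na(.data$S))
  if (nrow(sv) == 0L)
    warn("no cells qualify for the S table")
  list(cells = metrics, tally = tally,
       s_values = select(sv, "cell_id", "S"))
}
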