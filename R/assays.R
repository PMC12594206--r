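## The three quantitative assay statistics: reporter splicing index,
## chemotaxis index and colocalization quantification.

#' Reporter splicing index per worm, with group summaries
#'
#' The splicing index is the ratio of green (inclusion reporter, GFP) to
#' red (skipping reporter, mCherry) fluorescence per worm; it correlates
#' inversely with the frequency of exon skipping. Group summaries are
#' mean +/- SEM, with SEM the sample standard deviation (n - 1 denominator)
#' over sqrt(n).
#'
#' @param measurements Data frame with columns `gfp`, `mcherry` and the
#'   grouping column.
#' @param group_by Name of the grouping column (default `"group"`).
#' @return List with `per_worm` (input rows plus `index`, mCherry-zero
#'   worms dropped with a warning) and `summary` (data frame `group, n,
#'   mean, sem`).
#' @export
splicing_index <- function(measurements, group_by = "group") {
  stopifnot(all(c("gfp", "mcherry", group_by) %in% names(measurements)))
  bad <- measurements$mcherry <= 0
  if (any(bad)) {
    warning(sum(bad), " worm(s) with nonpositive mCherry excluded")
    measurements <- measurements[!bad, , drop = FALSE]
  }
  measurements$index <- measurements$gfp / measurements$mcherry
  groups <- split(measurements$index, measurements[[group_by]])
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, 0L),
    mean = vapply(groups, mean, 0),
    sem = vapply(groups, function(x)
      if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_, 0),
    row.names = NULL)
  list(per_worm = measurements, summary = summary)
}

#' Chemotaxis index from region counts
#'
#' `(#IA - #T) / (#IA + #T + #S)` over worm counts in the gradient (IA),
#' trap (T) and start (S) regions; always in `[-1, 1]`. Lower values
#' indicate higher memory capacity under the assay's convention.
#'
#' @param counts A `ChemotaxisCounts` (list with `IA`, `T`, `S`) or the
#'   three counts as separate arguments.
#' @param T,S Trap and start counts when `counts` is given as `#IA`.
#' @return The chemotaxis index.
#' @export
chemotaxis_index <- function(counts, T = NULL, S = NULL) {
  if (is.list(counts)) {
    ia <- counts$IA; tt <- counts$T; ss <- counts$S
  } else {
    ia <- counts; tt <- T; ss <- S
  }
  if (any(c(ia, tt, ss) < 0)) stop("counts must be nonnegative")
  total <- ia + tt + ss
  if (total == 0) stop("no worms counted: index undefined")
  (ia - tt) / total
}

#' Manders colocalization coefficients
#'
#' Intensity-weighted Manders coefficients with explicit per-channel
#' thresholds: `M1` is the red intensity summed over pixels where green
#' exceeds its threshold, divided by the red intensity summed over pixels
#' where red exceeds its threshold; `M2` is the same with channels
#' swapped. Both range from 0 (no colocalization) to 1 (perfect
#' colocalization). With a channel entirely at or below threshold the
#' corresponding coefficient is undefined and returned as `NA` with a
#' warning.
#'
#' @param images A `ChannelImagePair` (list with `red`, `green`,
#'   `thresholds`), or the red matrix when `green` is supplied.
#' @param green Green-channel matrix (optional alternative interface).
#' @param thresholds Named numeric `c(red =, green =)`; defaults to the
#'   pair's thresholds, else 0.
#' @return Named numeric `c(M1 =, M2 =)`.
#' @export
manders_coefficients <- function(images, green = NULL, thresholds = NULL) {
  if (is.null(green)) {
    red <- images$red; grn <- images$green
    if (is.null(thresholds)) thresholds <- images$thresholds
  } else {
    red <- as.matrix(images); grn <- as.matrix(green)
  }
  if (is.null(thresholds)) thresholds <- c(red = 0, green = 0)
  if (!all(dim(red) == dim(grn))) stop("channel shapes differ")
  if (any(red < 0) || any(grn < 0)) stop("intensities must be nonnegative")
  red_on <- red > thresholds[["red"]]
  grn_on <- grn > thresholds[["green"]]
  denom1 <- sum(red[red_on]); denom2 <- sum(grn[grn_on])
  M1 <- if (denom1 > 0) sum(red[grn_on]) / denom1 else NA_real_
  M2 <- if (denom2 > 0) sum(grn[red_on]) / denom2 else NA_real_
  if (is.na(M1) || is.na(M2))
    warning("a channel is entirely below threshold; coefficient undefined")
  c(M1 = M1, M2 = M2)
}

#' ROI colocalization percentages
#'
#' Given per-ROI labels (white = colocalized, red = query protein only,
#' green = partner only), returns each class as a percentage of the total
#' white + red + green ROI count; the three percentages sum to 100.
#'
#' @param roi_labels Character vector of labels in
#'   `c("white", "red", "green")`.
#' @return Named numeric percentages `c(white =, red =, green =)`.
#' @export
roi_colocalization_summary <- function(roi_labels) {
  if (length(roi_labels) < 1L) stop("need at least one ROI")
  bad <- setdiff(unique(roi_labels), c("white", "red", "green"))
  if (length(bad)) stop("unknown ROI label(s): ", paste(bad, collapse = ", "))
  n <- c(white = sum(roi_labels == "white"),
         red = sum(roi_labels == "red"),
         green = sum(roi_labels == "green"))
  100 * n / sum(n)
}

#' Auto-label ROIs from thresholded channel overlap (synthetic helper)
#'
#' Tiles the image into square ROIs and labels each tile containing any
#' above-threshold signal as white (both channels), red or green. ROI
#' drawing was a manual step in real slides; this helper exists so the
#' percentage summary can be exercised on synthetic images.
#'
#' @param images A `ChannelImagePair`.
#' @param tile ROI side length in pixels.
#' @return Character label vector (tiles without signal are dropped).
#' @export
label_rois <- function(images, tile = 8L) {
  red_on <- images$red > images$thresholds[["red"]]
  grn_on <- images$green > images$thresholds[["green"]]
  n <- nrow(red_on)
  starts <- seq(1L, n, by = tile)
  labs <- character(0)
  for (i in starts) for (j in starts) {
    ri <- i:min(i + tile - 1L, n); rj <- j:min(j + tile - 1L, n)
    has_r <- any(red_on[ri, rj]); has_g <- any(grn_on[ri, rj])
    if (has_r && has_g) labs <- c(labs, "white")
    else if (has_r) labs <- c(labs, "red")
    else if (has_g) labs <- c(labs, "green")
  }
  labs
}
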