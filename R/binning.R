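#' Average a daily stress series onto the 100 degree-day bin grid
#'
#' Bin `b` holds the unweighted mean of the daily index over days whose
#' cumulative thermal time from emergence falls in
#' `((b - 1) * bin_width, b * bin_width]`. The output is truncated, or
#' right-padded with the final observed bin's value, to exactly `n_bins`
#' entries so that every environment yields an equal-length vector for
#' clustering. An interior bin that no day lands in (possible only with
#' unusually coarse series) inherits the previous bin's value.
#'
#' @param daily_index Daily stress index in `[0, 1]`.
#' @param daily_tt Daily thermal time aligned with `daily_index`
#'   (degree-days).
#' @param bin_width Bin width (degree-days, default 100).
#' @param n_bins Number of bins; conventionally
#'   `floor(tt_maturity / bin_width)` of the reference cultivar.
#' @return Numeric vector of length `n_bins`.
#' @export
bin_trajectory <- function(daily_index, daily_tt, bin_width = 100, n_bins) {
  if (length(daily_index) == 0) stop("empty daily series")
  stopifnot(length(daily_index) == length(daily_tt))
  if (n_bins <= 0) stop("n_bins must be positive")
  cum_tt <- cumsum(daily_tt)
  if (max(cum_tt) <= 0) stop("cumulative thermal time must be positive")
  bin <- ceiling(cum_tt / bin_width)
  bin[bin < 1] <- 1           # zero-tt leading days count in the first bin
  means <- tapply(daily_index, factor(bin, levels = seq_len(max(bin))), mean)
  out <- as.numeric(means)[seq_len(min(max(bin), n_bins))]
  # fill interior gaps, then right-pad with the last observed value
  for (b in seq_along(out))
    if (is.na(out[b])) out[b] <- if (b > 1) out[b - 1] else daily_index[1]
  if (length(out) < n_bins) out <- c(out, rep(out[length(out)],
                                              n_bins - length(out)))
  out
}

#' Assemble a trajectory matrix from simulated seasons
#'
#' @param seasons List of `season_result` objects.
#' @param index `"rt"` (water) or `"gt"` (heat) daily series.
#' @param n_bins Number of 100 degree-day bins.
#' @param meta Optional data frame of per-season labels (site, year, sowing,
#'   management, cultivar), one row per season.
#' @return A list of class `trajectory_matrix` with `x` (seasons x bins
#'   matrix, columns `bin_01` ...) and `meta`.
#' @export
build_trajectory_matrix <- function(seasons, index = c("rt", "gt"),
                                    n_bins = 14, meta = NULL) {
  index <- match.arg(index)
  x <- t(vapply(seasons, function(s)
    bin_trajectory(s$daily[[index]], s$daily$tt, 100, n_bins),
    numeric(n_bins)))
  colnames(x) <- sprintf("bin_%02d", seq_len(n_bins))
  if (!is.null(meta)) stopifnot(nrow(meta) == nrow(x))
  structure(list(x = x, meta = meta, index = index),
            class = "trajectory_matrix")
}
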