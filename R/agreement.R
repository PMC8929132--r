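#' Agreement metrics between observed and simulated series
#'
#' Computes the standard model-evaluation quartet: root mean square error
#' `rmse = sqrt(mean((sim - obs)^2))`; normalized RMSE as a percentage of
#' the observed mean, `nrmse = 100 * rmse / mean(obs)`; the Nash-Sutcliffe
#' efficiency `nse = 1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2)`
#' (1 is a perfect model, 0 matches predicting the observed mean); and the
#' Pearson correlation. NRMSE is undefined for a zero observed mean and NSE
#' for a zero-variance observed series; both are returned as `NA` with a
#' flag.
#'
#' @param observed,simulated Equal-length numeric vectors (length >= 2, no
#'   missing pairs).
#' @return A list of class `agreement_report`: `rmse`, `nrmse`, `nse`,
#'   `pearson_r`, `n`, `flags` (character, possibly empty).
#' @export
agreement <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must have equal length")
  if (length(observed) < 2) stop("need at least two pairs")
  if (anyNA(observed) || anyNA(simulated)) stop("missing pairs not allowed")
  err <- simulated - observed
  rmse <- sqrt(mean(err^2))
  flags <- character()
  mo <- mean(observed)
  if (mo == 0) {
    nrmse <- NA_real_
    flags <- c(flags, "nrmse undefined: observed mean is zero")
  } else nrmse <- 100 * rmse / mo
  ss_obs <- sum((observed - mo)^2)
  if (ss_obs == 0) {
    nse <- NA_real_
    pearson_r <- NA_real_
    flags <- c(flags, "nse/r undefined: observed series has zero variance")
  } else {
    nse <- 1 - sum(err^2) / ss_obs
    pearson_r <- if (stats::sd(simulated) == 0) NA_real_ else
      stats::cor(observed, simulated)
    if (is.na(pearson_r))
      flags <- c(flags, "r undefined: simulated series has zero variance")
  }
  structure(list(rmse = rmse, nrmse = nrmse, nse = nse,
                 pearson_r = pearson_r, n = length(observed), flags = flags),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement over n = %d: RMSE %.4g, NRMSE %.3f%%, NSE %.4f, r %.4f\n",
              x$n, x$rmse, x$nrmse, x$nse, x$pearson_r))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
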