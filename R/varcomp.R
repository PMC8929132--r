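#' Random-effects variance components of trial yields
#'
#' Fits the mixed model `yield ~ 1 + (1 | site) + (1 | site:ecg)` by REML
#' (through \pkg{lme4}), i.e. site and the environment classification nested
#' in site as random effects, and reports each variance component and its
#' percentage of the total. REML estimates are non-negative by construction;
#' boundary fits (a component estimated at zero) are reported as zero. A
#' hybrid random intercept can be added with `include_hybrid = TRUE`.
#'
#' @param table Data frame with columns `site`, `ecg`, `yield_kg_ha` (and
#'   `hybrid` when `include_hybrid`).
#' @param include_hybrid Add `(1 | hybrid)` to the model (default `FALSE`).
#' @return A list of class `variance_decomposition`: `components` (named
#'   variances), `percentages` (summing to 100), `method`, `flags`.
#' @export
variance_components <- function(table, include_hybrid = FALSE) {
  stopifnot(all(c("site", "ecg", "yield_kg_ha") %in% names(table)))
  table <- as.data.frame(table)
  table$site <- factor(table$site)
  table$ecg <- factor(table$ecg)
  flags <- character()
  if (nlevels(table$site) < 2) stop("need at least 2 sites")
  per_site_levels <- tapply(table$ecg, table$site,
                            function(e) length(unique(e)))
  if (all(per_site_levels < 2))
    flags <- c(flags,
               "every site carries a single category: nested component confounded with site")
  if (stats::var(table$yield_kg_ha) == 0) {
    comp <- c(site = 0, `ecg:site` = 0, residual = 0)
    if (include_hybrid) comp <- c(comp[1:2], hybrid = 0, residual = 0)
    return(structure(list(components = comp,
                          percentages = c(comp[-length(comp)] * 0,
                                          residual = 100),
                          method = "degenerate (zero total variance)",
                          flags = c(flags, "zero total variance")),
                     class = "variance_decomposition"))
  }
  f <- yield_kg_ha ~ 1 + (1 | site) + (1 | site:ecg)
  if (include_hybrid)
    f <- yield_kg_ha ~ 1 + (1 | site) + (1 | site:ecg) + (1 | hybrid)
  fit <- lme4::lmer(f, data = table, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- stats::setNames(vc$vcov, vc$grp)
  names(comp)[names(comp) == "Residual"] <- "residual"
  names(comp)[names(comp) == "site:ecg"] <- "ecg_in_site"
  comp <- pmax(comp, 0)
  pct <- 100 * comp / sum(comp)
  structure(list(components = comp, percentages = pct, method = "REML (lme4)",
                 flags = flags, fit = fit),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("variance components (", x$method, ")\n", sep = "")
  for (nm in names(x$components))
    cat(sprintf("  %-12s %12.2f  (%5.1f%%)\n", nm, x$components[nm],
                x$percentages[nm]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
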