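#' Fit a log-logistic dose-response curve and estimate the IC50
#'
#' Fits `y = bottom + (top - bottom) / (1 + (ic50/I)^hill)` to percent
#' inhibition versus inhibitor concentration. By default the plateaus are
#' fixed at 0 and 100 because the data are normalized to an uninhibited
#' control; set `free_plateaus = TRUE` to estimate them.
#'
#' When the largest observed mean inhibition stays below 50% the IC50 is
#' not bracketed: the result is flagged `"ic50_above_max_tested"` and the
#' point estimate is withheld (`NA`).
#'
#' @param table Data frame with columns `inhibitor_um` and `inhibition_pct`
#'   (replicate rows welcome). Rows with `inhibitor_um == 0` are excluded
#'   from the nonlinear fit (the model value there is the plateau).
#' @param top,bottom Plateau values used when plateaus are fixed.
#' @param free_plateaus Estimate `top` and `bottom` as well.
#' @return A [fit_result()] over `ic50`, `hill` (and plateaus when free).
#' @examples
#' p <- dose_response_params(ic50 = 39.7)
#' I <- c(6.2, 12.5, 25, 50, 100)
#' fit_ic50(data.frame(inhibitor_um = I, inhibition_pct = dose_response(I, p)))
#' @export
fit_ic50 <- function(table, top = 100, bottom = 0, free_plateaus = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("inhibitor_um", "inhibition_pct") %in% names(table)))
  d <- table[table$inhibitor_um > 0, ]
  if (length(unique(d$inhibitor_um)) < 4)
    stop("need at least 4 nonzero inhibitor concentrations", call. = FALSE)
  n <- nrow(d)
  means <- tapply(d$inhibition_pct, d$inhibitor_um, mean)
  if (max(means) < 50) {
    return(fit_result(params = c(ic50 = NA_real_, hill = NA_real_),
                      n = n, converged = FALSE,
                      model_label = "log_logistic_dose_response",
                      flags = "ic50_above_max_tested",
                      extra = list(max_mean_inhibition = max(means),
                                   max_tested_um = max(d$inhibitor_um))))
  }
  # start: concentration whose mean response is closest to the midpoint
  conc <- as.numeric(names(means))
  mid <- (top + bottom) / 2
  ic50_0 <- conc[which.min(abs(means - mid))]
  if (free_plateaus) {
    fml <- inhibition_pct ~ bottom + (top - bottom) /
      (1 + (ic50 / inhibitor_um)^hill)
    start <- list(ic50 = ic50_0, hill = 1, top = max(means), bottom = min(means, 0))
    lower <- c(ic50 = 1e-9, hill = 0.1, top = 1, bottom = -50)
  } else {
    fml <- stats::as.formula(sprintf(
      "inhibition_pct ~ %g + (%g - %g) / (1 + (ic50 / inhibitor_um)^hill)",
      bottom, top, bottom))
    start <- list(ic50 = ic50_0, hill = 1)
    lower <- c(ic50 = 1e-9, hill = 0.1)
  }
  fit <- multistart_nls(fml, data = d, start = start, lower = lower)
  if (is.null(fit)) {
    return(fit_result(params = setNames(rep(NA_real_, length(start)),
                                        names(start)),
                      n = n, converged = FALSE,
                      model_label = "log_logistic_dose_response",
                      flags = "non_convergence"))
  }
  fit_result(params = coef(fit), se = nls_se(fit),
             rss = sum(residuals(fit)^2), n = n, converged = TRUE,
             model_label = "log_logistic_dose_response",
             extra = list(concentration_units = "um"))
}
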