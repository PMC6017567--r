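#' @importFrom stats coef lm nls residuals vcov predict sd quantile median
NULL

# small-sample corrected AIC for a least-squares fit with k mean parameters
# (the error variance adds one); Inf when the correction is undefined.
aicc_ls <- function(rss, n, k_mean) {
  k <- k_mean + 1
  if (n - k - 1 <= 0) return(Inf)
  rss <- max(rss, .Machine$double.xmin)  # guard log(0) on perfect fits
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# ICs for competing least-squares models on the same n points; all models
# must share one criterion, so when the AICc correction is undefined for
# the largest model the whole comparison falls back to plain AIC.
ic_compare <- function(rss, k_mean, n) {
  stopifnot(length(rss) == length(k_mean))
  rss <- pmax(rss, .Machine$double.xmin)
  if (n - (max(k_mean) + 1) - 1 <= 0)
    return(n * log(rss / n) + 2 * (k_mean + 1))
  vapply(seq_along(rss), function(i) aicc_ls(rss[i], n, k_mean[i]), 0)
}

#' Construct a fit result
#'
#' Uniform container returned by all fitters: point estimates, standard
#' errors (present only when the optimizer converged), residual sum of
#' squares, sample size, an AICc value comparable across models fit to the
#' same data, and any quality flags.
#'
#' @param params Named numeric vector of estimates.
#' @param se Named numeric vector of standard errors, or `NULL`.
#' @param rss Residual sum of squares.
#' @param n Number of data points.
#' @param converged Logical.
#' @param model_label Text label of the fitted model.
#' @param flags Character vector of quality flags (empty when clean).
#' @param extra Optional named list of model-specific extras.
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(params, se = NULL, rss = NA_real_, n = NA_integer_,
                       converged = FALSE, model_label = "", flags = character(0),
                       extra = list()) {
  stopifnot(is.character(flags))
  if (!converged) se <- NULL
  structure(list(params = params, se = se, rss = rss, n = as.integer(n),
                 converged = converged, model_label = model_label,
                 flags = flags,
                 aicc = if (is.finite(rss) && !is.na(n))
                   aicc_ls(rss, n, length(params)) else NA_real_,
                 extra = extra),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result: %s>  converged: %s\n", x$model_label, x$converged))
  if (length(x$params)) {
    tab <- data.frame(estimate = x$params,
                      se = if (is.null(x$se)) NA_real_ else x$se[names(x$params)])
    print(tab)
  }
  cat(sprintf("rss = %.4g on n = %d points, AICc = %.4g\n", x$rss, x$n, x$aicc))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# Levenberg-Marquardt least squares with a deterministic multi-start:
# the data-driven start plus perturbed copies (each parameter scaled by a
# cycled factor from {0.3, 3, 0.1, 10}); best converged fit by RSS wins.
# Returns the nls object or NULL when every start fails.
multistart_nls <- function(formula, data, start, lower = NULL, upper = NULL,
                           weights = NULL, n_starts = 5) {
  np <- length(start)
  lo <- if (is.null(lower)) rep(-Inf, np) else rep_len(lower, np)
  hi <- if (is.null(upper)) rep(Inf, np) else rep_len(upper, np)
  factors <- c(0.3, 3, 0.1, 10)
  starts <- list(start)
  for (i in seq_len(n_starts - 1)) {
    s <- unlist(start)
    for (j in seq_along(s)) {
      f <- factors[((i + j - 2) %% length(factors)) + 1]
      s[[j]] <- s[[j]] * f
    }
    s <- pmin(pmax(s, ifelse(is.finite(lo), lo + abs(lo) * 1e-7 + 1e-12, -Inf)),
              ifelse(is.finite(hi), hi - abs(hi) * 1e-7, Inf))
    starts[[i + 1]] <- as.list(s)
  }
  best <- NULL; best_rss <- Inf
  for (s in starts) {
    fit <- tryCatch(
      suppressWarnings(do.call(minpack.lm::nlsLM, c(
        list(formula, data = data, start = s, lower = lo, upper = hi,
             control = minpack.lm::nls.lm.control(maxiter = 200)),
        if (!is.null(weights)) list(weights = weights)))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  best
}

# standard errors from an nls fit, NA-safe for singular information
nls_se <- function(fit) {
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  if (is.null(se)) se <- rep(NA_real_, length(coef(fit)))
  names(se) <- names(coef(fit))
  se
}
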