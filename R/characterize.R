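#' Extract a kobs series from progress curves
#'
#' Fits the slow-binding model to every curve (each inhibitor concentration
#' and replicate) via [fit_progress_curve()] and summarizes the observed
#' rate per inhibitor concentration: the replicate mean of `kobs` and its
#' standard error (the across-replicate SEM when replicated, otherwise the
#' regression SE). Curves at zero inhibitor and curves flagged
#' time-independent or non-convergent are excluded from the series but
#' counted in the attached bookkeeping.
#'
#' @param curves Progress-curve data frame (columns `time_s`, `signal_au`,
#'   `inhibitor_um`, `substrate_um`, `replicate`).
#' @param weights Passed to [fit_progress_curve()].
#' @return Data frame with columns `inhibitor_um`, `kobs`, `se`, `n_curves`;
#'   per-curve fits in `attr(, "fits")` and the fraction of inhibited
#'   curves showing time dependence in `attr(, "time_dependent_fraction")`.
#' @export
kobs_series <- function(curves, weights = NULL) {
  stopifnot(is.data.frame(curves),
            all(c("time_s", "signal_au", "inhibitor_um", "replicate")
                %in% names(curves)))
  parts <- split(curves, list(curves$inhibitor_um, curves$replicate),
                 drop = TRUE)
  fits <- lapply(parts, function(g) {
    f <- fit_progress_curve(g[, c("time_s", "signal_au")], weights = weights)
    f$extra$inhibitor_um <- g$inhibitor_um[1]
    f$extra$replicate <- g$replicate[1]
    f
  })
  inhibited <- vapply(fits, function(f) f$extra$inhibitor_um > 0, TRUE)
  usable <- vapply(fits, function(f) {
    f$converged && !("no_time_dependence" %in% f$flags) &&
      f$extra$inhibitor_um > 0
  }, TRUE)
  td_frac <- if (any(inhibited)) mean(usable[inhibited]) else 0
  rows <- lapply(split(fits[usable], vapply(fits[usable], function(f)
    f$extra$inhibitor_um, 0)), function(fl) {
      ks <- vapply(fl, function(f) f$params[["kobs"]], 0)
      se <- if (length(ks) > 1) stats::sd(ks) / sqrt(length(ks))
            else fl[[1]]$se[["kobs"]]
      data.frame(inhibitor_um = fl[[1]]$extra$inhibitor_um,
                 kobs = mean(ks), se = se, n_curves = length(ks))
    })
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(inhibitor_um = numeric(0), kobs = numeric(0),
                         se = numeric(0), n_curves = integer(0))
  out <- out[order(out$inhibitor_um), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "time_dependent_fraction") <- td_frac
  out
}

#' Full kinetic characterization of one compound
#'
#' Orchestrates the analysis stages over whatever assay data are supplied:
#' per-curve slow-binding fits and the kobs-versus-inhibitor analysis
#' (mechanism class and two-step rate constants) from progress curves,
#' inhibition-mode classification and Dixon Ki from a steady-state velocity
#' grid, and IC50 estimation from dose-response tables with and without
#' enzyme preincubation.
#'
#' The mechanism class is `"no_time_dependence"` when fewer than half of
#' the inhibited progress curves beat a straight line (AICc), otherwise
#' `"one_step"` or `"two_step"` as called by [classify_mechanism()];
#' two-step parameters are reported only for the `"two_step"` class.
#'
#' @param progress_curves Optional progress-curve data frame (see
#'   [simulate_progress_closed_form()] for the column contract).
#' @param steady_state Optional velocity grid (`substrate_um`,
#'   `inhibitor_um`, `v_au_per_s`, `replicate`).
#' @param dose_response Optional table (`inhibitor_um`, `inhibition_pct`,
#'   `replicate`).
#' @param dose_response_preincubated Optional table in the same format,
#'   measured after preincubating enzyme with inhibitor.
#' @param compound_id Identifier echoed in the report.
#' @return An object of class `inhibition_result` with fields `compound_id`,
#'   `ic50` / `ic50_preincubated` ([fit_result()]s or `NULL`), `mode_call`,
#'   `dixon`, `mechanism_class`, `two_step` ([fit_result()] or `NULL`) and
#'   `kobs_series`.
#' @export
characterize_compound <- function(progress_curves = NULL,
                                  steady_state = NULL,
                                  dose_response = NULL,
                                  dose_response_preincubated = NULL,
                                  compound_id = "compound") {
  if (is.null(progress_curves) && is.null(steady_state) &&
      is.null(dose_response) && is.null(dose_response_preincubated))
    stop("at least one input dataset is required", call. = FALSE)
  check_cols <- function(df, cols, what) {
    if (is.null(df)) return(invisible(NULL))
    missing <- setdiff(cols, names(df))
    if (length(missing))
      stop(sprintf("%s: missing column(s) %s; concentration columns must be in uM (_um suffix)",
                   what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_cols(progress_curves,
             c("time_s", "signal_au", "inhibitor_um", "replicate"),
             "progress_curves")
  check_cols(steady_state,
             c("substrate_um", "inhibitor_um", "v_au_per_s"), "steady_state")
  check_cols(dose_response, c("inhibitor_um", "inhibition_pct"),
             "dose_response")
  check_cols(dose_response_preincubated, c("inhibitor_um", "inhibition_pct"),
             "dose_response_preincubated")

  mechanism_class <- NA_character_
  series <- NULL; two_step <- NULL
  if (!is.null(progress_curves)) {
    series <- kobs_series(progress_curves)
    td <- attr(series, "time_dependent_fraction")
    if (td < 0.5 || nrow(series) < 4) {
      mechanism_class <- "no_time_dependence"
    } else {
      mechanism_class <- as.character(classify_mechanism(series))
      if (mechanism_class == "two_step")
        two_step <- fit_kobs_hyperbola(series)
    }
  }
  mode_call <- if (!is.null(steady_state)) classify_mode(steady_state) else NULL
  dixon <- if (!is.null(mode_call)) mode_call$dixon else NULL
  ic50 <- if (!is.null(dose_response)) fit_ic50(dose_response) else NULL
  ic50_pre <- if (!is.null(dose_response_preincubated))
    fit_ic50(dose_response_preincubated) else NULL

  structure(list(compound_id = compound_id,
                 ic50 = ic50,
                 ic50_preincubated = ic50_pre,
                 mode_call = mode_call,
                 dixon = dixon,
                 mechanism_class = mechanism_class,
                 two_step = two_step,
                 kobs_series = series),
            class = "inhibition_result")
}

#' @export
print.inhibition_result <- function(x, ...) {
  cat(sprintf("Compound %s\n", x$compound_id))
  if (!is.null(x$ic50)) {
    if (x$ic50$converged)
      cat(sprintf("  IC50 = %.4g uM (hill %.3g)\n",
                  x$ic50$params[["ic50"]], x$ic50$params[["hill"]]))
    else cat(sprintf("  IC50: %s\n", paste(x$ic50$flags, collapse = ", ")))
  }
  if (!is.null(x$ic50_preincubated) && x$ic50_preincubated$converged)
    cat(sprintf("  IC50 (preincubated) = %.4g uM\n",
                x$ic50_preincubated$params[["ic50"]]))
  if (!is.null(x$mode_call))
    cat(sprintf("  Mode: %s (Ki = %.4g uM global; Dixon %.4g uM)\n",
                x$mode_call$mode, x$mode_call$Ki,
                if (!is.null(x$dixon)) x$dixon$Ki else NA_real_))
  if (!is.na(x$mechanism_class))
    cat(sprintf("  Binding kinetics: %s\n", x$mechanism_class))
  if (!is.null(x$two_step) && x$two_step$converged)
    cat(sprintf("  Two-step: k3 = %.3g /s, k4 = %.3g /s, Kiapp = %.4g uM (Ki* = %.4g uM)\n",
                x$two_step$params[["k3"]], x$two_step$params[["k4"]],
                x$two_step$params[["Kiapp"]],
                overall_ki_star(two_step_params(x$two_step$params[["k3"]],
                                                x$two_step$params[["k4"]],
                                                x$two_step$params[["Kiapp"]]))))
  invisible(x)
}
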