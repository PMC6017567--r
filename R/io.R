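#' @importFrom utils read.csv write.csv combn
NULL

progress_cols <- c("time_s", "signal_au", "inhibitor_um", "substrate_um",
                   "replicate")
velocity_cols <- c("substrate_um", "inhibitor_um", "v_au_per_s", "replicate")
dose_cols <- c("inhibitor_um", "inhibition_pct", "replicate")

check_schema <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in cols) {
    if (col == "replicate") next
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      stop(sprintf("%s: non-numeric or non-finite value in column '%s' (data row %d)",
                   path, col, bad[1]), call. = FALSE)
  }
  if (!nrow(df)) stop(sprintf("%s: no data rows", path), call. = FALSE)
  df
}

# strip generator classes so jsonlite serializes parameter objects plainly
plain <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, plain)
  } else x
}

#' Write a tidy assay CSV with a JSON parameter sidecar
#'
#' Writes the dataset to `path` and, when the data carry generator
#' metadata, a sidecar `<path>.json` recording the seed, design and
#' generating parameters so the run can be reproduced exactly.
#'
#' @param df Data frame from one of the `simulate_*` generators (or any
#'   data frame following the column contracts).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  meta <- attr(df, "metadata")
  if (!is.null(meta)) {
    jsonlite::write_json(plain(meta), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read tidy assay CSVs
#'
#' Readers for the three tidy formats the package exchanges, with schema
#' validation that names the offending column: progress curves
#' (`time_s, signal_au, inhibitor_um, substrate_um, replicate`), velocity
#' grids (`substrate_um, inhibitor_um, v_au_per_s, replicate`) and
#' dose-response tables (`inhibitor_um, inhibition_pct, replicate`).
#'
#' @param path CSV path.
#' @return A validated data frame.
#' @export
read_progress_csv <- function(path) {
  check_schema(read.csv(path), progress_cols, path)
}

#' @rdname read_progress_csv
#' @export
read_velocity_csv <- function(path) {
  check_schema(read.csv(path), velocity_cols, path)
}

#' @rdname read_progress_csv
#' @export
read_dose_csv <- function(path) {
  check_schema(read.csv(path), dose_cols, path)
}

fit_result_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(model = f$model_label, converged = f$converged,
       estimates = as.list(f$params),
       se = if (is.null(f$se)) NULL else as.list(f$se),
       rss = f$rss, n = f$n, aicc = f$aicc,
       flags = as.list(f$flags))
}

#' Serialize an inhibition result to a JSON report
#'
#' Writes every field of the per-compound report (IC50 fits, mode call with
#' its AICc evidence table, Dixon estimate, mechanism class, two-step
#' parameters, kobs series) to JSON. All numeric field names carry explicit
#' units.
#'
#' @param result An `inhibition_result` from [characterize_compound()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path) {
  stopifnot(inherits(result, "inhibition_result"))
  rep <- list(
    compound_id = result$compound_id,
    ic50_um = fit_result_to_list(result$ic50),
    ic50_preincubated_um = fit_result_to_list(result$ic50_preincubated),
    mode = if (!is.null(result$mode_call)) list(
      call = result$mode_call$mode,
      ki_um = result$mode_call$Ki,
      ki_se_um = result$mode_call$Ki_se,
      evidence_aicc = result$mode_call$evidence,
      lineweaver_burk_common_intercept_p =
        result$mode_call$lineweaver_burk$common_intercept_p
    ) else NULL,
    dixon = if (!is.null(result$dixon)) list(
      ki_um = result$dixon$Ki,
      ki_se_um = result$dixon$se,
      global_fit_ki_um = result$dixon$global_Ki
    ) else NULL,
    mechanism_class = result$mechanism_class,
    two_step = fit_result_to_list(result$two_step),
    kobs_series = if (!is.null(result$kobs_series) &&
                      nrow(result$kobs_series))
      result$kobs_series[, c("inhibitor_um", "kobs", "se", "n_curves")]
    else NULL
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Flat summary row of an inhibition result
#'
#' One-row data frame mirroring a results-table layout: IC50 with and
#' without preincubation, binding mode with Ki, mechanism class, and the
#' two-step rate constants.
#'
#' @param result An `inhibition_result`.
#' @return A one-row data frame.
#' @export
summary_row <- function(result) {
  stopifnot(inherits(result, "inhibition_result"))
  g <- function(f, p) if (!is.null(f) && f$converged) f$params[[p]] else NA_real_
  data.frame(
    compound_id = result$compound_id,
    ic50_um = g(result$ic50, "ic50"),
    ic50_preincubated_um = g(result$ic50_preincubated, "ic50"),
    mode = if (!is.null(result$mode_call)) result$mode_call$mode else NA_character_,
    ki_um = if (!is.null(result$mode_call)) result$mode_call$Ki else NA_real_,
    dixon_ki_um = if (!is.null(result$dixon)) result$dixon$Ki else NA_real_,
    mechanism_class = result$mechanism_class,
    k3_per_s = g(result$two_step, "k3"),
    k4_per_s = g(result$two_step, "k4"),
    kiapp_um = g(result$two_step, "Kiapp"))
}
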