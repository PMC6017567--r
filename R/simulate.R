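#' @importFrom stats rnorm
NULL

# attach generator metadata so every dataset carries its provenance
with_metadata <- function(df, metadata) {
  attr(df, "metadata") <- metadata
  df
}

set_design_seed <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  invisible(NULL)
}

#' Simulate progress curves from the closed-form slow-binding model
#'
#' Evaluates the slow-binding progress curve [progress_value()] on the
#' design's time grid for each inhibitor concentration, with one parameter
#' set per concentration, and adds Gaussian noise with standard deviation
#' `noise_sd * max(clean signal)`. Deterministic given `design$seed`.
#'
#' @param design [assay_design()] object. Only the first substrate
#'   concentration is used (the closed form is conditional on one S).
#' @param params List of [slow_binding_params()], one per entry of
#'   `design$inhibitor_concs` (same order).
#' @return A data frame with columns `time_s`, `signal_au`, `inhibitor_um`,
#'   `substrate_um`, `replicate`, carrying the generating parameters in
#'   `attr(, "metadata")`.
#' @examples
#' d <- assay_design(inhibitor_concs = 50, replicates = 1, seed = 1)
#' curves <- simulate_progress_closed_form(
#'   d, list(slow_binding_params(1e-4, 5e-5, 0.002)))
#' head(curves)
#' @export
simulate_progress_closed_form <- function(design, params) {
  stopifnot(inherits(design, "assay_design"), is.list(params))
  if (length(params) != length(design$inhibitor_concs))
    stop("need one slow_binding_params per inhibitor concentration",
         call. = FALSE)
  ok <- vapply(params, inherits, logical(1), what = "slow_binding_params")
  if (!all(ok)) stop("params must be slow_binding_params objects", call. = FALSE)
  S <- design$substrate_concs[1]
  set_design_seed(design)
  clean <- lapply(params, function(p) progress_value(design$t_grid, p))
  sd_abs <- design$noise_sd * max(unlist(clean), 0)
  rows <- list()
  for (i in seq_along(design$inhibitor_concs)) {
    for (r in seq_len(design$replicates)) {
      sig <- clean[[i]]
      if (sd_abs > 0) sig <- sig + rnorm(length(sig), 0, sd_abs)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = design$t_grid, signal_au = sig,
        inhibitor_um = design$inhibitor_concs[i], substrate_um = S,
        replicate = r)
    }
  }
  out <- do.call(rbind, rows)
  with_metadata(out, list(generator = "closed_form", seed = design$seed,
                          design = design, params = params))
}

# mass-action ODE of the two-step competitive scheme; enzyme pool
# normalized to 1.  x1 = EI fraction, x2 = E*I fraction, P = signal (AU).
two_step_ode <- function(t, y, parms) {
  u <- 1 - y[1] - y[2]                     # uninhibited enzyme fraction
  fE <- u * parms$Km / (parms$Km + parms$S) # free E among uninhibited pool
  kon <- parms$kon
  d1 <- kon * parms$I * fE - kon * parms$Ki * y[1] -
    parms$k3 * y[1] + parms$k4 * y[2]
  d2 <- parms$k3 * y[1] - parms$k4 * y[2]
  dP <- parms$v0 * u
  list(c(d1, d2, dP))
}

#' Simulate progress curves by mass-action integration
#'
#' Numerically integrates the two-step competitive binding scheme
#' E + I <-> E.I <-> E*.I alongside Michaelis-Menten turnover: the rapid
#' first step uses rate constants (`kon`, `koff = kon * Ki`), the slow
#' isomerization uses `k3`/`k4`, substrate binding is treated as rapidly
#' equilibrating, and the product rate is the uninhibited velocity scaled
#' by the instantaneous free-enzyme fraction. Enzyme is trace: substrate is
#' held constant, and a depletion estimate above `depletion_cap` is
#' recorded as a warning in the metadata.
#'
#' @param design [assay_design()] object.
#' @param mech [mechanism_spec()] object with `inh$mode == "competitive"`.
#'   When `mech$two_step` is `NULL` the curves are linear with the
#'   rapid-equilibrium competitive slope.
#' @return A data frame in the same format as
#'   [simulate_progress_closed_form()].
#' @export
simulate_progress_mechanistic <- function(design, mech) {
  stopifnot(inherits(design, "assay_design"), inherits(mech, "mechanism_spec"))
  if (mech$inh$mode != "competitive")
    stop("mechanistic simulator implements competitive binding only",
         call. = FALSE)
  check_fast_step(mech, design)
  set_design_seed(design)
  warnings <- character(0)
  clean <- list(); key <- list()
  for (S in design$substrate_concs) {
    v0 <- velocity(S, 0, mech$mm)
    for (I in design$inhibitor_concs) {
      if (is.null(mech$two_step)) {
        sig <- velocity(S, I, mech$mm, mech$inh) * design$t_grid
      } else {
        parms <- list(S = S, I = I, Km = mech$mm$Km, Ki = mech$inh$Ki,
                      kon = mech$fast_step_kon, k3 = mech$two_step$k3,
                      k4 = mech$two_step$k4, v0 = v0)
        sol <- deSolve::lsoda(c(0, 0, 0), design$t_grid, two_step_ode, parms,
                              rtol = 1e-8, atol = 1e-12)
        sig <- sol[, 4]
      }
      depl <- max(sig) / mech$signal_per_um / max(S, .Machine$double.eps)
      if (S > 0 && depl > mech$depletion_cap)
        warnings <- c(warnings, sprintf(
          "substrate depletion %.1f%% exceeds cap %.1f%% at S=%g, I=%g",
          100 * depl, 100 * mech$depletion_cap, S, I))
      clean[[length(clean) + 1L]] <- sig
      key[[length(key) + 1L]] <- c(S = S, I = I)
    }
  }
  sd_abs <- design$noise_sd * max(unlist(clean), 0)
  rows <- list()
  for (j in seq_along(clean)) {
    for (r in seq_len(design$replicates)) {
      sig <- clean[[j]]
      if (sd_abs > 0) sig <- sig + rnorm(length(sig), 0, sd_abs)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = design$t_grid, signal_au = sig,
        inhibitor_um = key[[j]]["I"], substrate_um = key[[j]]["S"],
        replicate = r, row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  if (length(warnings)) warning(paste(warnings, collapse = "; "), call. = FALSE)
  with_metadata(out, list(generator = "mechanistic", seed = design$seed,
                          design = design, mechanism = mech,
                          warnings = warnings))
}

#' Simulate a steady-state velocity grid
#'
#' Evaluates the rate law [velocity()] over the full substrate-by-inhibitor
#' design and perturbs each replicate with multiplicative Gaussian noise
#' `v * (1 + N(0, noise_sd))`, truncated at zero. Deterministic given
#' `design$seed`.
#'
#' @param design [assay_design()] object; `noise_sd` is the multiplicative
#'   fraction here (0.02 is typical of triplicate initial-velocity reads).
#' @param mech [mechanism_spec()] object (only `mm` and `inh` are used).
#' @return A data frame with columns `substrate_um`, `inhibitor_um`,
#'   `v_au_per_s`, `replicate`, with metadata attached.
#' @export
simulate_steady_state <- function(design, mech) {
  stopifnot(inherits(design, "assay_design"), inherits(mech, "mechanism_spec"))
  set_design_seed(design)
  grid <- expand.grid(substrate_um = design$substrate_concs,
                      inhibitor_um = design$inhibitor_concs,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v <- velocity(grid$substrate_um, grid$inhibitor_um, mech$mm, mech$inh)
  if (design$noise_sd > 0)
    v <- v * (1 + rnorm(length(v), 0, design$noise_sd))
  grid$v_au_per_s <- pmax(v, 0)
  out <- grid[, c("substrate_um", "inhibitor_um", "v_au_per_s", "replicate")]
  with_metadata(out, list(generator = "steady_state", seed = design$seed,
                          design = design, mechanism = mech))
}

#' Simulate a percent-inhibition dose-response table
#'
#' Evaluates the log-logistic model [dose_response()] at the design's
#' inhibitor concentrations and adds Gaussian noise in percentage points.
#' Deterministic given `design$seed`.
#'
#' @param design [assay_design()] object (inhibitor concentrations and
#'   replicates are used).
#' @param p [dose_response_params()] object.
#' @param noise_pp Additive noise sigma in percentage points; default 2,
#'   the replicate scatter typical of endpoint inhibition assays.
#' @return A data frame with columns `inhibitor_um`, `inhibition_pct`,
#'   `replicate`, with metadata attached.
#' @examples
#' d <- assay_design(inhibitor_concs = c(6.2, 12.5, 25, 50, 100), seed = 1)
#' simulate_dose_response(d, dose_response_params(ic50 = 39.7))
#' @export
simulate_dose_response <- function(design, p, noise_pp = 2) {
  stopifnot(inherits(design, "assay_design"),
            inherits(p, "dose_response_params"))
  if (!length(design$inhibitor_concs))
    stop("inhibitor_concs must be nonempty", call. = FALSE)
  if (noise_pp < 0) stop("noise_pp must be nonnegative", call. = FALSE)
  set_design_seed(design)
  grid <- expand.grid(inhibitor_um = design$inhibitor_concs,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  y <- dose_response(grid$inhibitor_um, p)
  if (noise_pp > 0) y <- y + rnorm(length(y), 0, noise_pp)
  grid$inhibition_pct <- y
  out <- grid[, c("inhibitor_um", "inhibition_pct", "replicate")]
  with_metadata(out, list(generator = "dose_response", seed = design$seed,
                          design = design, params = p, noise_pp = noise_pp))
}
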