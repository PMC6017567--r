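#' Assay design for synthetic data generation
#'
#' Describes a plate-reader kinetic assay: which inhibitor and substrate
#' concentrations are run, when the signal is sampled, how many replicates,
#' and how noisy the read is. Defaults mirror a mushroom-tyrosinase /
#' L-tyrosine dopachrome assay read at 475 nm: a 20-minute window sampled
#' every 10 s, substrate 375 uM final (50 uL of 1.5 mM into 200 uL total),
#' and a two-fold inhibitor dilution series from 100 down to 6.2 uM.
#'
#' @param inhibitor_concs Inhibitor concentrations (uM), nonnegative.
#' @param substrate_concs Substrate concentrations (uM), nonnegative.
#' @param t_grid Sampling times (s), strictly increasing from 0.
#' @param replicates Number of replicate wells per condition (>= 1).
#' @param noise_sd Gaussian noise sigma. For progress curves it is a
#'   fraction of the maximal clean signal (additive); for steady-state
#'   velocities it is a multiplicative fraction. Defaults: 0.01 for curves;
#'   pass 0.02 for velocity grids (the triplicate-level scatter typical of
#'   this assay).
#' @param seed RNG seed (integer) or `NULL` to leave the RNG stream alone.
#' @return An object of class `assay_design`.
#' @examples
#' assay_design()
#' @export
assay_design <- function(inhibitor_concs = c(0, 6.2, 12.5, 25, 50, 100),
                         substrate_concs = 375,
                         t_grid = seq(0, 1200, by = 10),
                         replicates = 3,
                         noise_sd = 0.01,
                         seed = NULL) {
  stopifnot(is.numeric(inhibitor_concs), is.numeric(substrate_concs),
            is.numeric(t_grid), length(t_grid) >= 2)
  if (any(inhibitor_concs < 0) || any(substrate_concs < 0))
    stop("concentrations must be nonnegative", call. = FALSE)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing from 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(list(inhibitor_concs = inhibitor_concs,
                 substrate_concs = substrate_concs,
                 t_grid = t_grid,
                 replicates = as.integer(replicates),
                 noise_sd = noise_sd,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "assay_design")
}

#' Mechanism specification for the mass-action simulator
#'
#' Bundles the turnover and inhibition parameters that generate synthetic
#' data. When `two_step` is supplied the inhibitor binds in two steps:
#' a rapid association with rate `fast_step_kon` and dissociation
#' `fast_step_kon * Ki` (so the first-step dissociation constant is
#' `inh$Ki`), followed by slow isomerization with the `two_step` rates.
#' The apparent first-step constant at assay substrate concentration S is
#' then `Ki * (1 + S/Km)`; the `Kiapp` field of `two_step` is not read by
#' the ODE integrator.
#'
#' @param mm [mm_params()] object.
#' @param inh [inhibition_model()] object.
#' @param two_step Optional [two_step_params()] object; `NULL` for a
#'   rapid-equilibrium (time-independent) inhibitor.
#' @param fast_step_kon Association rate of the rapid first step
#'   (1/(uM*s)); default 10, fast enough that the first step equilibrates
#'   well inside one sampling interval.
#' @param signal_per_um Conversion from product concentration to signal
#'   (AU/uM); default 0.0037 (dopachrome at 475 nm, 1 cm path). Used only
#'   to check substrate depletion.
#' @param depletion_cap Maximal tolerated fractional substrate depletion
#'   before a warning is recorded in the output metadata; default 0.1.
#' @return An object of class `mechanism_spec`.
#' @export
mechanism_spec <- function(mm, inh, two_step = NULL, fast_step_kon = 10,
                           signal_per_um = 0.0037, depletion_cap = 0.1) {
  stopifnot(inherits(mm, "mm_params"), inherits(inh, "inhibition_model"))
  if (!is.null(two_step)) stopifnot(inherits(two_step, "two_step_params"))
  if (fast_step_kon <= 0) stop("fast_step_kon must be positive", call. = FALSE)
  if (signal_per_um <= 0) stop("signal_per_um must be positive", call. = FALSE)
  structure(list(mm = mm, inh = inh, two_step = two_step,
                 fast_step_kon = fast_step_kon,
                 signal_per_um = signal_per_um,
                 depletion_cap = depletion_cap),
            class = "mechanism_spec")
}

# EI equilibration must be fast relative to the first sampling interval:
# half-time of the rapid step  <  t_grid[2] - t_grid[1].
check_fast_step <- function(mech, design) {
  dt <- min(diff(design$t_grid))
  Imax <- max(design$inhibitor_concs)
  # relaxation rate of E + I <-> EI at the least favourable concentration
  rate <- mech$fast_step_kon * (mech$inh$Ki + Imax)
  half_time <- log(2) / rate
  if (half_time >= dt)
    stop(sprintf(paste0("rapid first step too slow: EI equilibration ",
                        "half-time %.3g s >= sampling interval %.3g s; ",
                        "increase fast_step_kon"), half_time, dt),
         call. = FALSE)
  invisible(TRUE)
}
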