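#' Steady-state velocity under reversible inhibition
#'
#' Evaluates the rapid-equilibrium rate law for the given inhibition mode.
#' For competitive inhibition the rate is
#' `Vmax * S / (Km * (1 + I/Ki) + S)`: Vmax is unchanged and the apparent Km
#' is scaled by `(1 + I/Ki)`. Uncompetitive inhibition scales the `S` term
#' instead, noncompetitive scales both equally, and mixed scales them with
#' constants `Ki` and `alpha*Ki`.
#'
#' @param S Substrate concentration (uM), nonnegative. Vectorized.
#' @param I Inhibitor concentration (uM), nonnegative. Vectorized (recycled
#'   against `S`).
#' @param mm [mm_params()] object.
#' @param inh [inhibition_model()] object, or `NULL` for the uninhibited
#'   Michaelis-Menten rate.
#' @return Velocity in AU/s.
#' @examples
#' mm <- mm_params(Vmax = 1, Km = 100)
#' velocity(100, 0, mm)                                   # Vmax/2
#' velocity(100, 10.3, mm, inhibition_model("competitive", 10.3))  # Vmax/3
#' @export
velocity <- function(S, I = 0, mm, inh = NULL) {
  stopifnot(inherits(mm, "mm_params"))
  if (any(S < 0)) stop("S must be nonnegative", call. = FALSE)
  if (any(I < 0)) stop("I must be nonnegative", call. = FALSE)
  if (is.null(inh)) return(mm$Vmax * S / (mm$Km + S))
  stopifnot(inherits(inh, "inhibition_model"))
  a <- switch(inh$mode,   # factor on Km
    competitive    = 1 + I / inh$Ki,
    uncompetitive  = 1,
    noncompetitive = 1 + I / inh$Ki,
    mixed          = 1 + I / inh$Ki
  )
  b <- switch(inh$mode,   # factor on S
    competitive    = 1,
    uncompetitive  = 1 + I / inh$Ki,
    noncompetitive = 1 + I / inh$Ki,
    mixed          = 1 + I / (inh$alpha * inh$Ki)
  )
  mm$Vmax * S / (mm$Km * a + S * b)
}

#' Slow-binding progress-curve value
#'
#' Closed-form product signal of a slow-binding inhibition progress curve,
#' `P(t) = vs*t + (vi - vs)/kobs * (1 - exp(-kobs*t))`. The curve starts at
#' zero with slope `vi` and relaxes with rate `kobs` to a straight line of
#' slope `vs`.
#'
#' @param t Time (s), nonnegative. Vectorized.
#' @param p [slow_binding_params()] object.
#' @return Product signal (AU).
#' @examples
#' p <- slow_binding_params(vi = 1, vs = 0.5, kobs = 0.01)
#' progress_value(100, p)   # 50 + 50 * (1 - exp(-1)) = 81.606
#' @export
progress_value <- function(t, p) {
  stopifnot(inherits(p, "slow_binding_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  p$vs * t + (p$vi - p$vs) / p$kobs * (1 - exp(-p$kobs * t))
}

#' Observed rate constant versus inhibitor concentration
#'
#' The hyperbolic dependence of the slow-binding approach rate on inhibitor
#' concentration under the two-step mechanism:
#' `kobs(I) = k4 + k3 * I / (Kiapp + I)`. It equals `k4` at `I = 0`,
#' increases monotonically, and saturates at `k3 + k4`.
#'
#' @param I Inhibitor concentration (uM), nonnegative. Vectorized.
#' @param p [two_step_params()] object.
#' @return kobs (1/s).
#' @examples
#' p <- two_step_params(k3 = 0.0041, k4 = 0.0004, Kiapp = 35.8)
#' kobs_of_I(35.8, p)   # k4 + k3/2 = 0.00245
#' @export
kobs_of_I <- function(I, p) {
  stopifnot(inherits(p, "two_step_params"))
  if (any(I < 0)) stop("I must be nonnegative", call. = FALSE)
  p$k4 + p$k3 * I / (p$Kiapp + I)
}

#' Percent inhibition from endpoint signal changes
#'
#' `100 * (delta_control - delta_inhibitor) / delta_control`, the standard
#' normalization of an endpoint inhibition assay to its uninhibited control.
#'
#' @param d [assay_deltas()] object, or the control signal change when
#'   `delta_inhibitor` is supplied.
#' @param delta_inhibitor Optional; signal change with inhibitor, when `d`
#'   is given as a bare number.
#' @return Percent inhibition.
#' @examples
#' percent_inhibition(assay_deltas(0.5, 0.2))   # 60
#' percent_inhibition(0.5, 0.2)                 # same
#' @export
percent_inhibition <- function(d, delta_inhibitor = NULL) {
  if (!inherits(d, "assay_deltas")) d <- assay_deltas(d, delta_inhibitor)
  (d$delta_control - d$delta_inhibitor) / d$delta_control * 100
}

#' Log-logistic dose-response value
#'
#' Percent inhibition predicted by the four-parameter log-logistic model,
#' `bottom + (top - bottom) / (1 + (ic50/I)^hill)`. At `I = 0` the model
#' returns `bottom` by convention (the limit for positive `hill`).
#'
#' @param I Inhibitor concentration (uM), nonnegative. Vectorized.
#' @param p [dose_response_params()] object.
#' @return Percent inhibition.
#' @examples
#' dose_response(39.7, dose_response_params(ic50 = 39.7))   # 50
#' @export
dose_response <- function(I, p) {
  stopifnot(inherits(p, "dose_response_params"))
  if (any(I < 0)) stop("I must be nonnegative", call. = FALSE)
  out <- ifelse(I == 0, p$bottom,
                p$bottom + (p$top - p$bottom) / (1 + (p$ic50 / I)^p$hill))
  out
}

#' Overall steady-state inhibition constant of the two-step mechanism
#'
#' The apparent dissociation constant of the fully equilibrated two-step
#' scheme, `Ki* = Kiapp * k4 / (k3 + k4)`: isomerization to the tighter
#' complex deepens net binding by the factor `k4/(k3+k4)`.
#'
#' @param p [two_step_params()] object.
#' @return Ki* (uM).
#' @examples
#' overall_ki_star(two_step_params(0.0041, 0.0004, 35.8))   # ~3.18
#' @export
overall_ki_star <- function(p) {
  stopifnot(inherits(p, "two_step_params"))
  if (p$k3 + p$k4 <= 0) stop("k3 + k4 must be positive", call. = FALSE)
  p$Kiapp * p$k4 / (p$k3 + p$k4)
}

#' Apparent inhibition constant of a competitive inhibitor
#'
#' For competitive binding the apparent constant measured at substrate
#' concentration `S` is `Kiapp = Ki * (1 + S/Km)`: substrate competes for
#' the same site and shields the enzyme. Exposed as a convenience for
#' interpreting fitted `Kiapp` values; none of the fitters assume it.
#'
#' @param Ki True inhibition constant (uM).
#' @param S Substrate concentration (uM).
#' @param Km Michaelis constant (uM).
#' @return Apparent Ki (uM).
#' @export
kiapp_from_ki <- function(Ki, S, Km) {
  stopifnot(Ki > 0, S >= 0, Km > 0)
  Ki * (1 + S / Km)
}

#' Slow-binding curve parameters implied by a two-step mechanism
#'
#' Maps a mechanism (Michaelis-Menten turnover, rapid competitive first
#' binding step with apparent constant `Kiapp` at the assay substrate
#' concentration, slow isomerization `k3`/`k4`) to the three progress-curve
#' parameters at inhibitor concentration `I`:
#' \describe{
#'   \item{vi}{`v0 / (1 + I/Kiapp)` — only the rapid step has equilibrated;}
#'   \item{vs}{`v0 / (1 + I/Ki*)` with `Ki* = Kiapp*k4/(k3+k4)` — both steps
#'     equilibrated;}
#'   \item{kobs}{[kobs_of_I()] evaluated at `I`.}
#' }
#' where `v0` is the uninhibited velocity at the assay substrate
#' concentration.
#'
#' @param I Inhibitor concentration (uM), scalar.
#' @param S Substrate concentration (uM), scalar.
#' @param mm [mm_params()] object.
#' @param ts [two_step_params()] object with `Kiapp` expressed at this `S`.
#' @return A [slow_binding_params()] object.
#' @export
slow_binding_params_for <- function(I, S, mm, ts) {
  stopifnot(inherits(mm, "mm_params"), inherits(ts, "two_step_params"),
            length(I) == 1L, I >= 0, length(S) == 1L, S >= 0)
  v0 <- mm$Vmax * S / (mm$Km + S)
  vi <- v0 / (1 + I / ts$Kiapp)
  vs <- v0 / (1 + I / overall_ki_star(ts))
  kobs <- kobs_of_I(I, ts)
  if (kobs <= 0) stop("kobs is zero at this I; curve is linear", call. = FALSE)
  slow_binding_params(vi = vi, vs = vs, kobs = kobs)
}
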