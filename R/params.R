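#' Michaelis-Menten parameters
#'
#' Container for the substrate-saturation parameters of an enzyme assay.
#' Units are fixed package-wide: time in seconds, concentrations in uM and
#' signal in absorbance units (AU), so velocities are AU/s.
#'
#' @param Vmax Maximal velocity (AU/s). Must be positive.
#' @param Km Michaelis constant (uM). Must be positive.
#' @return An object of class `mm_params`.
#' @examples
#' mm_params(Vmax = 1, Km = 100)
#' @export
mm_params <- function(Vmax, Km) {
  stopifnot(is.numeric(Vmax), is.numeric(Km), length(Vmax) == 1L, length(Km) == 1L)
  if (!is.finite(Vmax) || Vmax <= 0) stop("Vmax must be positive", call. = FALSE)
  if (!is.finite(Km) || Km <= 0) stop("Km must be positive", call. = FALSE)
  structure(list(Vmax = Vmax, Km = Km), class = "mm_params")
}

#' Reversible inhibition model
#'
#' Mode and inhibition constant of a rapid-equilibrium reversible inhibitor.
#' `alpha` is the mixed-mode factor scaling the inhibitor's affinity for the
#' enzyme-substrate complex; it is ignored unless `mode = "mixed"`.
#'
#' @param mode One of `"competitive"`, `"uncompetitive"`, `"noncompetitive"`,
#'   `"mixed"`.
#' @param Ki Inhibition constant (uM), positive.
#' @param alpha Mixed-mode factor (dimensionless), positive; default 1.
#' @return An object of class `inhibition_model`.
#' @examples
#' inhibition_model("competitive", Ki = 10.3)
#' @export
inhibition_model <- function(mode = c("competitive", "uncompetitive",
                                      "noncompetitive", "mixed"),
                             Ki, alpha = 1) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(Ki), length(Ki) == 1L)
  if (!is.finite(Ki) || Ki <= 0) stop("Ki must be positive", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be positive", call. = FALSE)
  structure(list(mode = mode, Ki = Ki, alpha = alpha),
            class = "inhibition_model")
}

#' Slow-binding progress-curve parameters
#'
#' The three parameters of the standard slow-binding progress curve
#' P(t) = vs*t + (vi - vs)/kobs * (1 - exp(-kobs*t)): the initial velocity
#' `vi`, the final steady-state velocity `vs`, and the first-order rate
#' `kobs` of the transition between them.
#'
#' @param vi Initial velocity (AU/s), nonnegative.
#' @param vs Steady-state velocity (AU/s), nonnegative. For an inhibitor
#'   `vs <= vi`; `vs > vi` is permitted (activation) but flagged downstream.
#' @param kobs Observed approach rate (1/s), positive.
#' @return An object of class `slow_binding_params`.
#' @examples
#' slow_binding_params(vi = 1, vs = 0.5, kobs = 0.01)
#' @export
slow_binding_params <- function(vi, vs, kobs) {
  stopifnot(is.numeric(vi), is.numeric(vs), is.numeric(kobs))
  if (!is.finite(kobs) || kobs <= 0) stop("kobs must be positive", call. = FALSE)
  if (!is.finite(vi) || vi < 0) stop("vi must be nonnegative", call. = FALSE)
  if (!is.finite(vs) || vs < 0) stop("vs must be nonnegative", call. = FALSE)
  structure(list(vi = vi, vs = vs, kobs = kobs), class = "slow_binding_params")
}

#' Two-step (induced-fit) binding parameters
#'
#' Parameters of the isomerization mechanism E + I <-> E.I <-> E*.I in which
#' the initial complex forms rapidly (apparent dissociation constant
#' `Kiapp` under assay conditions) and then isomerizes slowly to a tighter
#' complex with forward rate `k3` and reverse rate `k4`.
#'
#' @param k3 Forward isomerization rate (1/s), positive.
#' @param k4 Reverse isomerization rate (1/s), nonnegative.
#' @param Kiapp Apparent inhibition constant of the rapid first step (uM),
#'   positive.
#' @return An object of class `two_step_params`.
#' @examples
#' two_step_params(k3 = 0.0041, k4 = 0.0004, Kiapp = 35.8)
#' @export
two_step_params <- function(k3, k4, Kiapp) {
  stopifnot(is.numeric(k3), is.numeric(k4), is.numeric(Kiapp))
  if (!is.finite(k3) || k3 <= 0) stop("k3 must be positive", call. = FALSE)
  if (!is.finite(k4) || k4 < 0) stop("k4 must be nonnegative", call. = FALSE)
  if (!is.finite(Kiapp) || Kiapp <= 0) stop("Kiapp must be positive", call. = FALSE)
  structure(list(k3 = k3, k4 = k4, Kiapp = Kiapp), class = "two_step_params")
}

#' Endpoint assay signal changes
#'
#' Signal change of the uninhibited control and of the inhibited reaction
#' over the assay window, the inputs of the percent-inhibition calculation.
#'
#' @param delta_control Signal change of the uninhibited reaction (AU),
#'   positive.
#' @param delta_inhibitor Signal change with inhibitor present (AU).
#' @return An object of class `assay_deltas`.
#' @export
assay_deltas <- function(delta_control, delta_inhibitor) {
  stopifnot(is.numeric(delta_control), is.numeric(delta_inhibitor))
  if (!is.finite(delta_control) || delta_control <= 0)
    stop("delta_control must be positive", call. = FALSE)
  structure(list(delta_control = delta_control,
                 delta_inhibitor = delta_inhibitor),
            class = "assay_deltas")
}

#' Log-logistic dose-response parameters
#'
#' Four-parameter log-logistic description of percent inhibition versus
#' inhibitor concentration, used for IC50 estimation.
#'
#' @param ic50 Half-maximal inhibitory concentration (uM), positive.
#' @param hill Hill slope (dimensionless); default 1.
#' @param top Upper plateau (percent); default 100.
#' @param bottom Lower plateau (percent); default 0. Must satisfy
#'   `top > bottom`.
#' @return An object of class `dose_response_params`.
#' @examples
#' dose_response_params(ic50 = 39.7)
#' @export
dose_response_params <- function(ic50, hill = 1, top = 100, bottom = 0) {
  stopifnot(is.numeric(ic50), is.numeric(hill), is.numeric(top), is.numeric(bottom))
  if (!is.finite(ic50) || ic50 <= 0) stop("ic50 must be positive", call. = FALSE)
  if (!(top > bottom)) stop("top must exceed bottom", call. = FALSE)
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom),
            class = "dose_response_params")
}

#' @export
print.mm_params <- function(x, ...) {
  cat(sprintf("Michaelis-Menten: Vmax = %g AU/s, Km = %g uM\n", x$Vmax, x$Km))
  invisible(x)
}

#' @export
print.inhibition_model <- function(x, ...) {
  cat(sprintf("Inhibition model: %s, Ki = %g uM%s\n", x$mode, x$Ki,
              if (x$mode == "mixed") sprintf(", alpha = %g", x$alpha) else ""))
  invisible(x)
}

#' @export
print.two_step_params <- function(x, ...) {
  cat(sprintf("Two-step binding: k3 = %g /s, k4 = %g /s, Kiapp = %g uM\n",
              x$k3, x$k4, x$Kiapp))
  invisible(x)
}

#' @export
print.slow_binding_params <- function(x, ...) {
  cat(sprintf("Slow-binding curve: vi = %g, vs = %g AU/s, kobs = %g /s\n",
              x$vi, x$vs, x$kobs))
  invisible(x)
}
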