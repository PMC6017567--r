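rate_law_formulas <- list(
  competitive    = v_au_per_s ~ Vmax * substrate_um /
    (Km * (1 + inhibitor_um / Ki) + substrate_um),
  uncompetitive  = v_au_per_s ~ Vmax * substrate_um /
    (Km + substrate_um * (1 + inhibitor_um / Ki)),
  noncompetitive = v_au_per_s ~ Vmax * substrate_um /
    ((Km + substrate_um) * (1 + inhibitor_um / Ki)),
  mixed          = v_au_per_s ~ Vmax * substrate_um /
    (Km * (1 + inhibitor_um / Ki) +
       substrate_um * (1 + inhibitor_um / (alpha * Ki)))
)

fit_rate_law <- function(grid, mode) {
  Vmax0 <- max(grid$v_au_per_s) * 1.2
  Km0 <- stats::median(grid$substrate_um)
  Ipos <- grid$inhibitor_um[grid$inhibitor_um > 0]
  Ki0 <- if (length(Ipos)) stats::median(Ipos) else Km0
  start <- list(Vmax = Vmax0, Km = Km0, Ki = Ki0)
  lower <- c(Vmax = 1e-12, Km = 1e-9, Ki = 1e-9)
  if (mode == "mixed") {
    start$alpha <- 1
    lower <- c(lower, alpha = 1e-3)
  }
  fit <- multistart_nls(rate_law_formulas[[mode]], data = grid,
                        start = start, lower = lower)
  if (is.null(fit)) {
    return(fit_result(params = setNames(rep(NA_real_, length(start)),
                                        names(start)),
                      n = nrow(grid), converged = FALSE,
                      model_label = mode, flags = "non_convergence"))
  }
  fit_result(params = coef(fit), se = nls_se(fit),
             rss = sum(residuals(fit)^2), n = nrow(grid), converged = TRUE,
             model_label = mode)
}

# per-inhibitor Lineweaver-Burk regressions (1/v vs 1/S) and an F-test of
# a common 1/Vmax intercept across inhibitor concentrations
lineweaver_burk_diagnostics <- function(grid) {
  d <- grid[grid$v_au_per_s > 0 & grid$substrate_um > 0, ]
  d$inv_v <- 1 / d$v_au_per_s
  d$inv_S <- 1 / d$substrate_um
  d$If <- factor(d$inhibitor_um)
  per_I <- do.call(rbind, lapply(split(d, d$If), function(g) {
    cf <- coef(lm(inv_v ~ inv_S, g))
    data.frame(inhibitor_um = g$inhibitor_um[1],
               intercept = cf[["(Intercept)"]], slope = cf[["inv_S"]])
  }))
  rownames(per_I) <- NULL
  p <- NA_real_
  if (nlevels(d$If) >= 2) {
    full <- lm(inv_v ~ If / inv_S - 1, d)           # free intercepts + slopes
    common <- lm(inv_v ~ If:inv_S, d)               # one shared intercept
    p <- tryCatch(stats::anova(common, full)[2, "Pr(>F)"],
                  error = function(e) NA_real_)
  }
  list(per_inhibitor = per_I, common_intercept_p = p)
}

#' Classify the inhibition mode from a steady-state velocity grid
#'
#' Fits the competitive, uncompetitive, noncompetitive and mixed
#' rapid-equilibrium rate laws globally to velocities measured over a
#' substrate-by-inhibitor design and selects the mode by AICc, with a
#' parsimony rule: when a model with fewer parameters sits within 2 AICc
#' units of the minimum, the simplest such model is chosen. Per-inhibitor
#' Lineweaver-Burk regressions and an F-test of a common 1/Vmax intercept
#' (the visual signature of competitive inhibition) are attached as
#' diagnostics, along with the Dixon-plot intersection estimate of Ki when
#' the design supports it.
#'
#' @param grid Data frame with columns `substrate_um`, `inhibitor_um`,
#'   `v_au_per_s` (and optionally `replicate`); must contain at least two
#'   distinct substrate and two distinct inhibitor concentrations.
#' @return An object of class `mode_call`: `mode`, `Ki` (with `Ki_se`),
#'   the per-mode `evidence` AICc table, all `fits`, `lineweaver_burk`
#'   diagnostics and the `dixon` estimate (or `NULL`).
#' @examples
#' mech <- mechanism_spec(mm_params(1, 100),
#'                        inhibition_model("competitive", 10.3))
#' g <- simulate_steady_state(
#'   assay_design(inhibitor_concs = c(0, 5, 10, 20),
#'                substrate_concs = c(50, 100, 200, 400),
#'                noise_sd = 0, replicates = 1), mech)
#' classify_mode(g)$mode
#' @export
classify_mode <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("substrate_um", "inhibitor_um", "v_au_per_s") %in% names(grid)))
  if (length(unique(grid$substrate_um)) < 2)
    stop("singular design: need at least 2 distinct substrate concentrations",
         call. = FALSE)
  if (length(unique(grid$inhibitor_um)) < 2)
    stop("need at least 2 distinct inhibitor concentrations", call. = FALSE)
  modes <- names(rate_law_formulas)
  fits <- lapply(modes, function(m) fit_rate_law(grid, m))
  names(fits) <- modes
  aicc <- vapply(fits, function(f) if (f$converged) f$aicc else Inf, 0)
  k <- vapply(fits, function(f) length(f$params), 0L)
  best <- min(aicc)
  # simplest model within 2 AICc units of the minimum
  in_band <- which(aicc - best < 2)
  chosen <- in_band[order(k[in_band], aicc[in_band])][1]
  mode <- modes[chosen]
  f <- fits[[chosen]]
  dixon <- tryCatch(dixon_ki(grid), error = function(e) NULL)
  structure(list(
    mode = mode,
    Ki = f$params[["Ki"]],
    Ki_se = if (!is.null(f$se)) f$se[["Ki"]] else NA_real_,
    alpha = if (mode == "mixed") f$params[["alpha"]] else NA_real_,
    evidence = data.frame(mode = modes, k = k, aicc = aicc,
                          delta_aicc = aicc - best, row.names = NULL),
    fits = fits,
    lineweaver_burk = lineweaver_burk_diagnostics(grid),
    dixon = dixon
  ), class = "mode_call")
}

#' @export
print.mode_call <- function(x, ...) {
  cat(sprintf("Inhibition mode: %s  (Ki = %.4g +/- %.2g uM, global fit)\n",
              x$mode, x$Ki, x$Ki_se))
  if (!is.null(x$dixon))
    cat(sprintf("Dixon-plot Ki: %.4g uM\n", x$dixon$Ki))
  print(x$evidence)
  invisible(x)
}

#' Dixon-plot estimate of the inhibition constant
#'
#' Regresses `1/v` on inhibitor concentration at each substrate
#' concentration and locates the abscissa of every pairwise intersection of
#' those lines; for a competitive inhibitor the lines cross at `I = -Ki`,
#' so the estimate is minus the mean intersection abscissa. The spread of
#' the pairwise abscissae provides the standard error. The global
#' competitive-fit Ki on the same grid is reported alongside for
#' comparison.
#'
#' @param grid As in [classify_mode()]; needs at least two distinct
#'   substrate concentrations and three distinct inhibitor concentrations.
#' @return An object of class `dixon_ki`: `Ki`, `se`, the pairwise
#'   `intersections`, the per-substrate `lines`, and `global_Ki`.
#' @examples
#' mech <- mechanism_spec(mm_params(1, 100),
#'                        inhibition_model("competitive", 10.3))
#' g <- simulate_steady_state(
#'   assay_design(inhibitor_concs = c(0, 5, 10, 20),
#'                substrate_concs = c(100, 200, 400),
#'                noise_sd = 0, replicates = 1), mech)
#' dixon_ki(g)$Ki
#' @export
dixon_ki <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("substrate_um", "inhibitor_um", "v_au_per_s") %in% names(grid)))
  d <- grid[grid$v_au_per_s > 0, ]
  S_levels <- sort(unique(d$substrate_um))
  if (length(S_levels) < 2)
    stop("need at least 2 distinct substrate concentrations", call. = FALSE)
  per_S_nI <- tapply(d$inhibitor_um, d$substrate_um,
                     function(x) length(unique(x)))
  if (any(per_S_nI < 3))
    stop("need at least 3 distinct inhibitor concentrations per substrate",
         call. = FALSE)
  d$inv_v <- 1 / d$v_au_per_s
  lines <- do.call(rbind, lapply(S_levels, function(S) {
    g <- d[d$substrate_um == S, ]
    cf <- coef(lm(inv_v ~ inhibitor_um, g))
    data.frame(substrate_um = S, intercept = cf[["(Intercept)"]],
               slope = cf[["inhibitor_um"]])
  }))
  pairs <- utils::combn(nrow(lines), 2)
  xs <- apply(pairs, 2, function(idx) {
    b <- lines$slope[idx]; a <- lines$intercept[idx]
    if (abs(b[1] - b[2]) < 1e-9 * max(abs(b)))
      return(NA_real_)
    (a[2] - a[1]) / (b[1] - b[2])
  })
  if (all(is.na(xs)))
    stop("Dixon intersection undefined: lines are parallel (uncompetitive pattern)",
         call. = FALSE)
  xs <- xs[!is.na(xs)]
  Ki <- -mean(xs)
  if (Ki <= 0)
    stop("Dixon intersection lies at positive inhibitor concentration; ",
         "grid is not consistent with competitive inhibition", call. = FALSE)
  se <- if (length(xs) > 1) stats::sd(xs) / sqrt(length(xs)) else NA_real_
  gfit <- fit_rate_law(d, "competitive")
  structure(list(Ki = Ki, se = se,
                 intersections = -xs, lines = lines,
                 global_Ki = if (gfit$converged) gfit$params[["Ki"]] else NA_real_),
            class = "dixon_ki")
}

#' @export
print.dixon_ki <- function(x, ...) {
  cat(sprintf("Dixon-plot Ki = %.4g uM (se %.2g, %d line pairs); global fit Ki = %.4g uM\n",
              x$Ki, x$se, length(x$intersections), x$global_Ki))
  invisible(x)
}
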