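#' Kinetic parameters of the six-state roadblock transit model
#'
#' Bundles the rates and probabilities governing transit of an elongation
#' complex (EC) through a DNA-bound protein roadblock: the backtrack rate
#' `k1`, the backtrack recovery rate `k2`, the spontaneous roadblock
#' dissociation rate `k3`, and the probability `p1` of dislodging the
#' roadblock at each ramming encounter. Dynamics are simulated in discrete
#' time with step `dt` and capped at `t_max`; trajectories still at the
#' roadblock at `t_max` are right-censored ("indefinitely stalled").
#'
#' @param k1 backtrack rate, 1/s (>= 0)
#' @param k2 recovery rate from the backtracked state, 1/s (>= 0)
#' @param k3 spontaneous roadblock dissociation rate, 1/s (>= 0)
#' @param p1 probability of dislodging the roadblock per encounter, between 0 and 1
#' @param dt simulation time step, s (default 1)
#' @param t_max simulation cap, s (default 5000); must be >= 2 * dt
#' @return an object of class `kinetic_params`
#' @examples
#' kinetic_params(k1 = 0.02, k2 = 0.002, k3 = 0.02, p1 = 0.05)
#' @export
kinetic_params <- function(k1, k2, k3, p1, dt = 1, t_max = 5000) {
  stopifnot(is.numeric(k1), is.numeric(k2), is.numeric(k3), is.numeric(p1),
            length(k1) == 1L, length(k2) == 1L, length(k3) == 1L,
            length(p1) == 1L, length(dt) == 1L, length(t_max) == 1L)
  if (k1 < 0 || k2 < 0 || k3 < 0)
    stop("rates k1, k2, k3 must be non-negative")
  if (p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]")
  if (dt <= 0) stop("dt must be positive")
  if (t_max < 2 * dt) stop("t_max must be at least 2 * dt")
  structure(list(k1 = k1, k2 = k2, k3 = k3, p1 = p1, dt = dt, t_max = t_max),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Six-state transit model parameters\n")
  cat(sprintf("  k1 (backtrack)    : %g /s\n", x$k1))
  cat(sprintf("  k2 (recovery)     : %g /s\n", x$k2))
  cat(sprintf("  k3 (dissociation) : %g /s\n", x$k3))
  cat(sprintf("  P1 (dislodging)   : %g\n", x$p1))
  cat(sprintf("  dt = %g s, t_max = %g s\n", x$dt, x$t_max))
  invisible(x)
}

#' Transit rate of the passive pathway
#'
#' The passive route is transit upon spontaneous roadblock dissociation, so
#' its effective rate is simply the dissociation rate: `k_passive = k3`.
#'
#' @param params a [kinetic_params()] object
#' @return the passive transit rate, 1/s
#' @export
k_passive <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$k3
}

#' Effective cycling rate of the active (reciprocating) pathway
#'
#' A backtrack-recovery cycle takes on average `1/k1 + 1/k2`, giving the
#' cycling rate `k_active = k1 / (1 + k1/k2) = 1 / (1/k1 + 1/k2)`. If
#' `k1 = 0` the active pathway never starts and the rate is 0. If `k1 > 0`
#' but `k2 = 0` recovery never completes; the rate is defined as 0 and the
#' result carries the attribute `recovery_blocked = TRUE`.
#'
#' @param params a [kinetic_params()] object
#' @return the active pathway cycling rate, 1/s
#' @export
k_active <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  if (params$k1 == 0) return(0)
  if (params$k2 == 0) return(structure(0, recovery_blocked = TRUE))
  params$k1 / (1 + params$k1 / params$k2)
}

#' Michaelis-Menten model of GreA-stimulated backtrack recovery
#'
#' GreA rescues backtracked ECs by stimulating cleavage of the extruded RNA.
#' The recovery rate is modelled as a basal rate plus a saturable
#' GreA-dependent increment: `k2(G) = k2_basal + k2_cat * G / (Km + G)`.
#'
#' @param k2_basal intrinsic recovery rate, 1/s (>= 0)
#' @param k2_cat maximal GreA-stimulated increment, 1/s (>= 0)
#' @param km half-saturation GreA concentration, uM (>= 0)
#' @return an object of class `grea_model`
#' @export
grea_model <- function(k2_basal, k2_cat, km) {
  stopifnot(is.numeric(k2_basal), is.numeric(k2_cat), is.numeric(km))
  if (k2_basal < 0 || k2_cat < 0 || km < 0)
    stop("all grea_model parameters must be non-negative")
  structure(list(k2_basal = k2_basal, k2_cat = k2_cat, km = km),
            class = "grea_model")
}

#' Recovery rate at a given GreA concentration
#'
#' @param model a [grea_model()] object
#' @param grea_uM GreA concentration, uM (>= 0)
#' @return the adjusted recovery rate `k2`, 1/s
#' @export
grea_adjusted_k2 <- function(model, grea_uM) {
  stopifnot(inherits(model, "grea_model"), is.numeric(grea_uM))
  if (any(grea_uM < 0)) stop("GreA concentration must be non-negative")
  if (model$km == 0) {
    # degenerate MM: saturated for any positive concentration
    return(model$k2_basal + ifelse(grea_uM > 0, model$k2_cat, 0))
  }
  model$k2_basal + model$k2_cat * grea_uM / (model$km + grea_uM)
}

#' Classify the transit regime from the pathway rate ratio
#'
#' The ratio `k_active / k_passive` separates three regimes: passive
#' (backtrack-recovery cycling much slower than roadblock dissociation),
#' active (cycling much faster), and hybrid (comparable rates).
#'
#' @param params a [kinetic_params()] object
#' @param lo ratio at or below which the regime is `passive` (default 0.1)
#' @param hi ratio at or above which the regime is `active` (default 10)
#' @return an object of class `regime_class` with fields `label` and `ratio`
#' @export
classify_regime <- function(params, lo = 0.1, hi = 10) {
  stopifnot(inherits(params, "kinetic_params"), lo > 0, lo < hi)
  ka <- as.numeric(k_active(params))
  kp <- k_passive(params)
  if (ka == 0 && kp == 0)
    stop("both pathway rates are zero: no transit possible")
  if (kp == 0) {
    ratio <- Inf
    label <- "active"
  } else {
    ratio <- ka / kp
    label <- if (ratio <= lo) "passive" else if (ratio >= hi) "active" else "hybrid"
  }
  structure(list(label = label, ratio = ratio, lo = lo, hi = hi),
            class = "regime_class")
}

#' @export
print.regime_class <- function(x, ...) {
  cat(sprintf("Transit regime: %s (k_active/k_passive = %g)\n",
              x$label, x$ratio))
  invisible(x)
}

#' Closed-form mean pause time in the passive limit
#'
#' In the limit `k1 = 0`, `p1 = 0` the discrete-time walk reduces to two
#' mandatory steps plus a geometric wait for roadblock dissociation with
#' per-step probability `p = 1 - exp(-k3 * dt)`, giving mean duration
#' `2 dt + dt (1 - p)^2 / p`. Used as an analytic oracle for the simulator.
#'
#' @param k3 roadblock dissociation rate, 1/s (> 0)
#' @param dt time step, s
#' @return the expected pause duration, s
#' @export
passive_limit_mean <- function(k3, dt = 1) {
  stopifnot(is.numeric(k3), is.numeric(dt), dt > 0)
  if (k3 <= 0) stop("k3 must be positive")
  p <- 1 - exp(-k3 * dt)
  2 * dt + dt * (1 - p)^2 / p
}
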