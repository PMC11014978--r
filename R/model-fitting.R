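#' Map experimental conditions to kinetic parameter sets
#'
#' Encodes the parameter-sharing structure used for global fitting:
#' per roadblock there is one backtrack rate `k1`, dissociation rate `k3`
#' and dislodging probability `p1`; assisting force prevents backtracking
#' (`k1 = 0`); GreA enters only through the recovery rate `k2` via a
#' Michaelis-Menten [grea_model()]; and the force magnitude has no effect
#' (only its direction matters).
#'
#' @param roadblocks a named list; each element is a list with fields `k1`,
#'   `k3`, `p1`, `grea` (a [grea_model()]), and optionally `dt`, `t_max`
#' @return an object of class `condition_map`
#' @export
condition_map <- function(roadblocks) {
  stopifnot(is.list(roadblocks), length(names(roadblocks)) ==
              length(roadblocks))
  for (nm in names(roadblocks)) {
    r <- roadblocks[[nm]]
    if (!all(c("k1", "k3", "p1", "grea") %in% names(r)))
      stop("each roadblock entry needs k1, k3, p1, grea")
    if (!inherits(r$grea, "grea_model"))
      stop("grea must be a grea_model")
  }
  structure(roadblocks, class = "condition_map")
}

#' Resolve a condition to its kinetic parameters
#'
#' @param map a [condition_map()]
#' @param cond a [condition()]
#' @return a [kinetic_params()] object
#' @export
resolve_condition <- function(map, cond) {
  stopifnot(inherits(map, "condition_map"), inherits(cond, "expt_condition"))
  r <- map[[cond$roadblock]]
  if (is.null(r)) stop("condition's roadblock is not covered by the map: ",
                       cond$roadblock)
  k1 <- if (cond$force_direction == "assisting") 0 else r$k1
  k2 <- grea_adjusted_k2(r$grea, cond$grea_uM)
  kinetic_params(k1 = k1, k2 = k2, k3 = r$k3, p1 = r$p1,
                 dt = if (is.null(r$dt)) 1 else r$dt,
                 t_max = if (is.null(r$t_max)) 5000 else r$t_max)
}

# two-sample Kolmogorov-Smirnov statistic (ties allowed)
.ks_stat <- function(a, b) {
  v <- sort(unique(c(a, b)))
  Fa <- vapply(v, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(v, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

#' Distance between simulated and observed pause-time distributions
#'
#' Two-sample Kolmogorov-Smirnov statistic on the uncensored durations
#' (after applying the experimental 20 s pause threshold to the simulated
#' durations, for like-with-like comparison), plus a weighted squared
#' difference between the censored ("indefinitely stalled") fractions.
#'
#' @param sim,obs [pause_sample()] objects
#' @param min_pause_s pause threshold applied to simulated durations
#'   (default 20 s)
#' @param w_cens weight of the censored-fraction term (default 1)
#' @return a non-negative scalar; 0 for identical samples
#' @export
distribution_distance <- function(sim, obs, min_pause_s = 20, w_cens = 1) {
  stopifnot(inherits(sim, "pause_sample"), inherits(obs, "pause_sample"))
  keep <- sim$censored | sim$durations >= min_pause_s
  sd_ <- sim$durations[keep]; sc <- sim$censored[keep]
  od <- obs$durations; oc <- obs$censored
  if (length(sd_) == 0 || length(od) == 0)
    stop("empty sample after applying the pause threshold")
  a <- sd_[!sc]; b <- od[!oc]
  ks <- if (length(a) > 0 && length(b) > 0) .ks_stat(a, b)
        else if (length(a) == length(b)) 0 else 1
  ks + w_cens * (mean(sc) - mean(oc))^2
}

#' Search configuration for global model fitting
#'
#' @param n_sim simulated trajectories per condition per objective
#'   evaluation
#' @param seed master seed; the same trajectory streams are reused across
#'   objective evaluations (common random numbers)
#' @param grid_k named list of coarse log-grids for `k1`, `k2`, `k3`;
#'   `grid_p1` for the dislodging probability; `grid_gre` multipliers for
#'   the GreA-boosted recovery rate
#' @param maxit Nelder-Mead refinement budget
#' @param min_pause_s,w_cens passed to [distribution_distance()]
#' @return a list of class `fit_search_config`
#' @export
fit_search_config <- function(n_sim = 1000, seed = 1,
                              grid_k = NULL, grid_p1 = c(0.05, 0.3),
                              grid_gre = c(3, 10), maxit = 150,
                              min_pause_s = 20, w_cens = 1) {
  if (is.null(grid_k))
    grid_k <- list(k1 = c(0.002, 0.01, 0.05),
                   k2 = c(0.002, 0.01, 0.05),
                   k3 = c(0.001, 0.005, 0.02))
  structure(list(n_sim = n_sim, seed = seed, grid_k = grid_k,
                 grid_p1 = grid_p1, grid_gre = grid_gre, maxit = maxit,
                 min_pause_s = min_pause_s, w_cens = w_cens),
            class = "fit_search_config")
}

#' Fit the transit model to condition-grouped pause samples
#'
#' Simulation-based fit: for each roadblock, searches for the parameter set
#' (`k1`, basal `k2`, GreA-boosted `k2`, `k3`, `p1`) that minimises the sum
#' of [distribution_distance()] values over that roadblock's conditions,
#' simulating `n_sim` pauses per condition per evaluation with common
#' random numbers. A coarse log-grid scan is refined by Nelder-Mead on
#' transformed coordinates. Conditions must follow the sharing rules of
#' [condition_map()]: assisting force zeroes `k1`, GreA acts only on `k2`.
#'
#' @param obs named list of [pause_sample()] objects, each carrying its
#'   [condition()] (in `$condition`)
#' @param search a [fit_search_config()]
#' @return an object of class `fit_result`: `params_by_roadblock` (fitted
#'   `k1`, `k2_basal`, `k2_plus`, `k3`, `p1` per roadblock), `distance`,
#'   `p_values` (per-condition adequacy t-tests at the fitted parameters),
#'   `regimes` (per-roadblock [classify_regime()] labels), `n_sim`, `seed`,
#'   `convergence`
#' @export
fit_global <- function(obs, search = fit_search_config()) {
  stopifnot(is.list(obs), length(obs) >= 2)
  conds <- lapply(obs, `[[`, "condition")
  if (any(vapply(conds, is.null, logical(1))))
    stop("every observed sample must carry its condition")
  rbs <- unique(vapply(conds, `[[`, character(1), "roadblock"))

  fit_one_roadblock <- function(rb) {
    idx <- which(vapply(conds, `[[`, character(1), "roadblock") == rb)
    # canonical condition order, so the objective (and its common random
    # number streams) does not depend on how the caller ordered the input
    key <- vapply(conds[idx], function(cc)
      paste(cc$force_direction, cc$grea_uM, cc$salt_mM), character(1))
    idx <- idx[order(key)]
    samples <- obs[idx]
    cc <- conds[idx]
    windows <- vapply(samples, function(s)
      if (is.finite(s$censor_time)) s$censor_time else 5000, numeric(1))

    sim_condition <- function(theta, i, n_sim) {
      # theta: log k1, log k2m, log(k2p - k2m), log k3, qlogis p1
      k1 <- exp(theta[1]); k2m <- exp(theta[2])
      k2p <- k2m + exp(theta[3]); k3 <- exp(theta[4])
      p1 <- stats::plogis(theta[5])
      k1c <- if (cc[[i]]$force_direction == "assisting") 0 else k1
      k2c <- if (cc[[i]]$grea_uM > 0) k2p else k2m
      pars <- kinetic_params(k1c, k2c, k3, p1)
      generate_pause_sample(pars, n_sim, min(windows[i], pars$t_max),
                            seed = search$seed, stream_offset = (i - 1) *
                              search$n_sim)
    }
    objective <- function(theta) {
      tot <- 0
      for (i in seq_along(samples)) {
        sim <- sim_condition(theta, i, search$n_sim)
        tot <- tot + distribution_distance(sim, samples[[i]],
                                           search$min_pause_s,
                                           search$w_cens)
      }
      tot
    }

    # coarse grid scan
    g <- expand.grid(k1 = search$grid_k$k1, k2 = search$grid_k$k2,
                     k3 = search$grid_k$k3, p1 = search$grid_p1,
                     gre = search$grid_gre)
    best <- NULL
    for (r in seq_len(nrow(g))) {
      th <- c(log(g$k1[r]), log(g$k2[r]), log(g$k2[r] * (g$gre[r] - 1)),
              log(g$k3[r]), stats::qlogis(g$p1[r]))
      v <- objective(th)
      if (is.null(best) || v < best$value) best <- list(par = th, value = v)
    }
    # local refinement
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = search$maxit))
    if (opt$value > best$value) opt <- best else opt <- opt[c("par", "value")]

    th <- opt$par
    pars <- list(k1 = exp(th[1]), k2_basal = exp(th[2]),
                 k2_plus = exp(th[2]) + exp(th[3]), k3 = exp(th[4]),
                 p1 = stats::plogis(th[5]))
    # adequacy at the optimum, with a fresh stream
    pv <- numeric(length(samples))
    for (i in seq_along(samples)) {
      sim <- sim_condition(th, i, search$n_sim)
      pv[i] <- tryCatch(adequacy_ttest(sim, samples[[i]]),
                        error = function(e) NA_real_)
    }
    names(pv) <- names(samples)
    regime <- classify_regime(kinetic_params(pars$k1, pars$k2_basal,
                                             pars$k3, pars$p1))
    list(params = pars, distance = opt$value, p_values = pv,
         regime = regime)
  }

  fits <- lapply(rbs, fit_one_roadblock)
  names(fits) <- rbs
  structure(list(
    params_by_roadblock = lapply(fits, `[[`, "params"),
    distance = sum(vapply(fits, `[[`, numeric(1), "distance")),
    p_values = lapply(fits, `[[`, "p_values"),
    regimes = lapply(fits, `[[`, "regime"),
    n_sim = search$n_sim, seed = search$seed,
    convergence = TRUE),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Global transit-model fit\n")
  for (rb in names(x$params_by_roadblock)) {
    p <- x$params_by_roadblock[[rb]]
    cat(sprintf("  %s: k1=%.4g k2=%.4g (GreA+: %.4g) k3=%.4g P1=%.3f -> %s regime (ratio %.3g)\n",
                rb, p$k1, p$k2_basal, p$k2_plus, p$k3, p$p1,
                x$regimes[[rb]]$label, x$regimes[[rb]]$ratio))
  }
  cat(sprintf("  total distance %.4g (n_sim %d, seed %d)\n",
              x$distance, x$n_sim, x$seed))
  invisible(x)
}

#' Canonical parameter sets for the three transit regimes
#'
#' Illustrative parameter sets placing the model firmly in the passive
#' (`k_active/k_passive` about 0.09), hybrid (about 1) and active (about
#' 50) regimes, with a GreA-boosted recovery rate for the GreA+ conditions.
#' Used throughout the tests, the vignette and the acceptance suite as the
#' stated synthetic world.
#'
#' @param regime one of `"passive"`, `"hybrid"`, `"active"`
#' @return a list with `k1`, `k2_basal`, `k2_plus`, `k3`, `p1`
#' @export
regime_example_params <- function(regime = c("passive", "hybrid",
                                             "active")) {
  regime <- match.arg(regime)
  switch(regime,
    passive = list(k1 = 0.02, k2_basal = 0.002, k2_plus = 0.05,
                   k3 = 0.02, p1 = 0.05),
    hybrid  = list(k1 = 0.02, k2_basal = 0.02, k2_plus = 0.1,
                   k3 = 0.01, p1 = 0.15),
    active  = list(k1 = 0.05, k2_basal = 0.05, k2_plus = 0.25,
                   k3 = 5e-4, p1 = 0.3))
}

#' Welch two-sample t-test of simulated against observed pauses
#'
#' Two-sided Welch test on the uncensored pause durations; the paper-style
#' adequacy check for the fitted model (p > 0.05 indicates no detectable
#' mean discrepancy).
#'
#' @param sim,obs [pause_sample()] objects (>= 2 uncensored values each)
#' @return the two-sided p-value
#' @export
adequacy_ttest <- function(sim, obs) {
  a <- sim$durations[!sim$censored]
  b <- obs$durations[!obs$censored]
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 uncensored values per sample")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(1)
    stop("degenerate variance with unequal means")
  }
  stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Qualitative regime predictions per condition
#'
#' For each roadblock in a fit (or for explicit parameters), simulates the
#' four canonical conditions -- assisting/GreA-, assisting/GreA+,
#' opposing/GreA-, opposing/GreA+ -- and reports mean pause times (censored
#' durations truncated at the observation window), the implied ordering,
#' and whether the opposing/GreA- distribution prefers a double
#' exponential.
#'
#' @param fit a [fit_global()] result, or a named list of per-roadblock
#'   parameter lists (`k1`, `k2_basal`, `k2_plus`, `k3`, `p1`)
#' @param n_sim pauses per condition (default 5000)
#' @param obs_window observation window for censoring, s (default 3600)
#' @param seed master seed
#' @return a named list; per roadblock a list with `means` (named numeric,
#'   the four conditions), `ordering` (condition names sorted by decreasing
#'   mean), `double_exp_opposing_gre_minus` (logical), `regime`
#' @export
regime_report <- function(fit, n_sim = 5000, obs_window = 3600, seed = 1) {
  pb <- if (inherits(fit, "fit_result")) fit$params_by_roadblock else fit
  out <- list()
  cond_names <- c("assisting/Gre-", "assisting/Gre+",
                  "opposing/Gre-", "opposing/Gre+")
  for (rb in names(pb)) {
    p <- pb[[rb]]
    sets <- list(
      kinetic_params(0,     p$k2_basal, p$k3, p$p1),
      kinetic_params(0,     p$k2_plus,  p$k3, p$p1),
      kinetic_params(p$k1,  p$k2_basal, p$k3, p$p1),
      kinetic_params(p$k1,  p$k2_plus,  p$k3, p$p1))
    samples <- lapply(seq_along(sets), function(i)
      generate_pause_sample(sets[[i]], n_sim,
                            min(obs_window, sets[[i]]$t_max),
                            seed = .derive_seed(seed, i)))
    means <- vapply(samples, function(s) mean(s$durations), numeric(1))
    names(means) <- cond_names
    og <- samples[[3]]
    dbl <- tryCatch({
      sel <- select_model(fit_exp_single(og, n_boot = 200, seed = seed),
                          fit_exp_double(og, seed = seed))
      sel$choice == "double"
    }, error = function(e) NA)
    out[[rb]] <- list(
      means = means,
      ordering = cond_names[order(means, decreasing = TRUE)],
      double_exp_opposing_gre_minus = dbl,
      regime = classify_regime(kinetic_params(p$k1, p$k2_basal, p$k3,
                                              p$p1))$label)
  }
  out
}
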