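#' Simulate a single roadblock pause
#'
#' Runs one trajectory of the discrete-time six-state transit walk. Per time
#' step `dt`: the roadblock, while bound, dissociates with probability
#' `1 - exp(-k3 dt)`; the EC then updates its state (pre-encounter ->
#' ramming; at-roadblock -> backtracked with probability `1 - exp(-k1 dt)`
#' while the roadblock is bound, else transit; backtracked -> ramming with
#' probability `1 - exp(-k2 dt)`; ramming -> transit with probability `p1`
#' while the roadblock is bound, returning to the at-roadblock state on
#' failure, or transit unconditionally once the roadblock is gone); time is
#' incremented after the state update. The walk is capped at `t_max`.
#'
#' @param params a [kinetic_params()] object
#' @param seed integer seed for the trajectory's random stream
#' @return a list of class `pause_outcome` with fields `duration` (s),
#'   `outcome` (`"transited"` or `"stalled_censored"`), `n_cycles` (completed
#'   backtrack-recovery cycles) and `dislodged` (`TRUE` if transit occurred
#'   by actively dislodging the roadblock rather than after spontaneous
#'   dissociation)
#' @seealso [simulate_ensemble()], [simulate_single_reference()]
#' @export
simulate_single <- function(params, seed) {
  stopifnot(inherits(params, "kinetic_params"))
  r <- .simulate_transit_cpp(1L, params$k1, params$k2, params$k3, params$p1,
                             params$dt, params$t_max, as.numeric(seed))
  structure(list(duration = r$duration[1],
                 outcome = if (r$transited[1]) "transited" else "stalled_censored",
                 n_cycles = r$n_cycles[1],
                 dislodged = r$dislodged[1]),
            class = "pause_outcome")
}

#' Simulate an ensemble of roadblock pauses
#'
#' Runs `n` independent trajectories of the six-state walk. Trajectory
#' streams are derived from `seed` by a counter-based scheme, so the
#' ensemble is reproducible and order-independent, and re-using the same
#' seed across calls yields common random numbers.
#'
#' @param params a [kinetic_params()] object
#' @param n number of trajectories (>= 1)
#' @param seed integer master seed
#' @param stream_offset advance the trajectory counter (used to generate
#'   non-overlapping ensembles under one master seed)
#' @return a list of class `transit_ensemble` with a data frame `outcomes`
#'   (columns `duration`, `transited`, `n_cycles`, `dislodged`) and a
#'   `summary` list (mean duration, censored fraction, transit fraction,
#'   dislodged fraction, mean number of cycles)
#' @export
simulate_ensemble <- function(params, n, seed, stream_offset = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  r <- .simulate_transit_cpp(n, params$k1, params$k2, params$k3, params$p1,
                             params$dt, params$t_max, as.numeric(seed),
                             as.numeric(stream_offset))
  outcomes <- data.frame(duration = r$duration, transited = r$transited,
                         n_cycles = r$n_cycles, dislodged = r$dislodged)
  structure(list(
    outcomes = outcomes,
    params = params,
    seed = seed,
    summary = list(
      mean_duration = mean(outcomes$duration),
      censored_fraction = mean(!outcomes$transited),
      transit_fraction = mean(outcomes$transited),
      dislodged_fraction = mean(outcomes$dislodged),
      mean_n_cycles = mean(outcomes$n_cycles))),
    class = "transit_ensemble")
}

#' @export
print.transit_ensemble <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Transit ensemble: %d trajectories\n", nrow(x$outcomes)))
  cat(sprintf("  mean pause %.1f s | transit %.1f%% | censored %.1f%% | dislodged %.1f%% | mean cycles %.2f\n",
              s$mean_duration, 100 * s$transit_fraction,
              100 * s$censored_fraction, 100 * s$dislodged_fraction,
              s$mean_n_cycles))
  invisible(x)
}

#' Literal reference implementation of the transit walk
#'
#' A line-by-line transcription of the discrete-time update rules using R's
#' own random number generator. It is deliberately naive and slow; it exists
#' as an independent oracle against which the optimized simulator is
#' validated (two-sample distributional equivalence).
#'
#' @inheritParams simulate_single
#' @return as [simulate_single()]
#' @export
simulate_single_reference <- function(params, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  if (!is.null(seed)) set.seed(seed)
  k1 <- params$k1; k2 <- params$k2; k3 <- params$k3; p1 <- params$p1
  dt <- params$dt; t_max <- params$t_max
  state <- 1L
  rb_on <- TRUE
  t_c <- 0
  n_cycles <- 0L
  dislodged <- FALSE
  while (state != 6L && t_c < t_max) {
    if (rb_on) {
      if (stats::runif(1) < 1 - exp(-k3 * dt)) rb_on <- FALSE
    }
    if (state == 1L) {
      state <- 5L
    } else if (state == 2L) {
      if (rb_on) {
        if (stats::runif(1) < 1 - exp(-k1 * dt)) state <- 3L
      } else {
        state <- 6L
      }
    } else if (state == 3L) {
      if (stats::runif(1) < 1 - exp(-k2 * dt)) {
        state <- 5L
        n_cycles <- n_cycles + 1L
      }
    } else if (state == 5L) {
      if (rb_on) {
        if (stats::runif(1) < p1) {
          state <- 6L
          dislodged <- TRUE
        } else {
          state <- 2L
        }
      } else {
        state <- 6L
      }
    }
    t_c <- t_c + dt
  }
  structure(list(duration = t_c,
                 outcome = if (state == 6L) "transited" else "stalled_censored",
                 n_cycles = n_cycles,
                 dislodged = dislodged),
            class = "pause_outcome")
}

#' Reference ensemble via the literal implementation
#'
#' @inheritParams simulate_ensemble
#' @return a data frame with columns `duration`, `transited`, `n_cycles`,
#'   `dislodged`
#' @export
simulate_ensemble_reference <- function(params, n, seed) {
  set.seed(seed)
  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- simulate_single_reference(params)
  data.frame(duration = vapply(out, `[[`, numeric(1), "duration"),
             transited = vapply(out, function(o) o$outcome == "transited",
                                logical(1)),
             n_cycles = vapply(out, `[[`, integer(1), "n_cycles"),
             dislodged = vapply(out, `[[`, logical(1), "dislodged"))
}

#' Draw a pause sample with observation-window censoring
#'
#' Simulates `n` pauses from the six-state walk and applies the finite
#' observation window of the experiment: pauses reaching `obs_window` are
#' flagged as censored ("indefinitely stalled") and truncated to
#' `obs_window`.
#'
#' @param params a [kinetic_params()] object
#' @param n number of pauses (>= 1)
#' @param obs_window observation window, s (0 < obs_window <= `params$t_max`)
#' @param seed integer master seed
#' @param stream_offset see [simulate_ensemble()]
#' @return a [pause_sample()] object
#' @export
generate_pause_sample <- function(params, n, obs_window, seed,
                                  stream_offset = 0) {
  stopifnot(inherits(params, "kinetic_params"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be a positive integer")
  if (obs_window <= 0) stop("obs_window must be positive")
  if (obs_window > params$t_max)
    stop("obs_window must not exceed params$t_max")
  ens <- simulate_ensemble(params, n, seed, stream_offset)
  d <- ens$outcomes$duration
  cens <- !ens$outcomes$transited | d >= obs_window
  d[d >= obs_window] <- obs_window
  pause_sample(durations = d, censored = cens, censor_time = obs_window,
               extra = list(dislodged = ens$outcomes$dislodged & !cens,
                            n_cycles = ens$outcomes$n_cycles,
                            seed = seed))
}
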