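#' Transcription template geometry
#'
#' Positions along the template in bp from the transcription start
#' (promoter, position 0). Defaults follow the layout
#' promoter - 709 bp - lac operator - 612 bp - terminator, with the
#' surface anchor 1021 bp from the start site for opposing-force templates
#' and 2014 bp for assisting-force templates.
#'
#' @param operator_pos roadblock binding site, bp (default 709)
#' @param terminator_pos terminator, bp (default 1321)
#' @param anchor_offset anchor-to-start distance, bp (default per direction)
#' @param direction `"opposing"` or `"assisting"` force geometry
#' @return an object of class `template_geometry`
#' @export
template_geometry <- function(operator_pos = 709, terminator_pos = 709 + 612,
                              anchor_offset = NULL,
                              direction = c("opposing", "assisting")) {
  direction <- match.arg(direction)
  if (is.null(anchor_offset))
    anchor_offset <- if (direction == "opposing") 1021 else 2014
  if (!(0 < operator_pos && operator_pos < terminator_pos))
    stop("need 0 < operator_pos < terminator_pos")
  if (anchor_offset <= 0) stop("anchor_offset must be positive")
  structure(list(promoter_pos = 0, operator_pos = operator_pos,
                 terminator_pos = terminator_pos,
                 anchor_offset = anchor_offset, direction = direction),
            class = "template_geometry")
}

#' Experimental condition descriptor
#'
#' @param roadblock one of `"LacI-Os"`, `"LacI-O1"`, `"LacI-O2"`,
#'   `"EcoRI-Q111"`
#' @param force_direction `"opposing"`, `"assisting"` or `"zero"`
#' @param force_pN force magnitude in pN, one of 0, 0.2, 0.7, 2.0, 5.0;
#'   must be 0 exactly when `force_direction = "zero"`
#' @param grea_uM GreA concentration, uM (>= 0; experiments used 10 uM
#'   unless stated otherwise)
#' @param salt_mM monovalent cation concentration, 50 or 150 mM
#' @return an object of class `expt_condition` (named to avoid colliding
#'   with R's own condition system)
#' @export
condition <- function(roadblock = c("LacI-O1", "LacI-O2", "LacI-Os",
                                    "EcoRI-Q111"),
                      force_direction = c("opposing", "assisting", "zero"),
                      force_pN = 0.2, grea_uM = 0, salt_mM = 50) {
  roadblock <- match.arg(roadblock)
  force_direction <- match.arg(force_direction)
  if (!force_pN %in% c(0, 0.2, 0.7, 2.0, 5.0))
    stop("force_pN must be one of 0, 0.2, 0.7, 2.0, 5.0")
  if ((force_pN == 0) != (force_direction == "zero"))
    stop("force_pN must be 0 exactly when force_direction is 'zero'")
  if (grea_uM < 0) stop("grea_uM must be non-negative")
  if (!salt_mM %in% c(50, 150)) stop("salt_mM must be 50 or 150")
  structure(list(roadblock = roadblock, force_direction = force_direction,
                 force_pN = force_pN, grea_uM = grea_uM, salt_mM = salt_mM),
            class = "expt_condition")
}

#' @export
format.expt_condition <- function(x, ...) {
  sprintf("%s, %s force %g pN, GreA %g uM, %g mM salt",
          x$roadblock, x$force_direction, x$force_pN, x$grea_uM, x$salt_mM)
}

#' @export
print.expt_condition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Synthetic trace generator configuration
#'
#' Defaults state the conditions the generated records emulate: steady
#' elongation at 10 bp/s; Gaussian tracking noise of 4 nm SD; per-bead
#' expansion factors (`a_true`); ubiquitous short pauses at 1 per 200 bp
#' with 3 s exponential mean; 1/3 nm per bp (so +/- 20 nm equals 60 bp); a
#' 180 s pre-NTP dwell at the promoter; and per-roadblock observation
#' windows (1800 s for LacI-O1/O2, 3600 s otherwise) when `obs_window` is
#' left `NULL`.
#'
#' @param velocity elongation velocity, bp/s (> 0)
#' @param noise_sd Gaussian measurement noise SD, nm (>= 0)
#' @param a_true per-bead position scale factor (0 < a_true <= 1.2)
#' @param ubiquitous_pause_rate short-pause rate, events/bp
#' @param ubiquitous_pause_mean short-pause exponential mean, s
#' @param nm_per_bp conversion, nm per bp (default 1/3; the B-DNA rise
#'   0.34 is the physical alternative)
#' @param obs_window observation window, s (`NULL`: per-roadblock default)
#' @param seed integer seed for this trace
#' @param promoter_dwell pre-NTP dwell at position 0, s
#' @param gap_len if > 0, a NaN gap of this many samples is inserted at the
#'   NTP-addition time to emulate buffer-exchange tracking loss
#' @param rb_exclusion_bp half-width of the zone around the operator in
#'   which no ubiquitous pause is placed (default 30 bp = 10 nm). A short
#'   pause immediately adjacent to the roadblock pause is physically
#'   indistinguishable from it in the record, so the generator keeps the
#'   injected roadblock pause identifiable; set to 0 to disable
#' @return an object of class `trace_gen_config`
#' @export
trace_gen_config <- function(velocity = 10, noise_sd = 4, a_true = 1,
                             ubiquitous_pause_rate = 1 / 200,
                             ubiquitous_pause_mean = 3,
                             nm_per_bp = 1 / 3, obs_window = NULL,
                             seed = 1, promoter_dwell = 180, gap_len = 0,
                             rb_exclusion_bp = 30) {
  if (velocity <= 0) stop("velocity must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!(a_true > 0 && a_true <= 1.2)) stop("a_true must lie in (0, 1.2]")
  if (nm_per_bp <= 0) stop("nm_per_bp must be positive")
  structure(list(velocity = velocity, noise_sd = noise_sd, a_true = a_true,
                 ubiquitous_pause_rate = ubiquitous_pause_rate,
                 ubiquitous_pause_mean = ubiquitous_pause_mean,
                 nm_per_bp = nm_per_bp, obs_window = obs_window,
                 seed = seed, promoter_dwell = promoter_dwell,
                 gap_len = gap_len, rb_exclusion_bp = rb_exclusion_bp),
            class = "trace_gen_config")
}

.default_obs_window <- function(roadblock) {
  if (roadblock %in% c("LacI-O1", "LacI-O2")) 1800 else 3600
}

# deterministic 31-bit seed derivation for sub-streams
.derive_seed <- function(master, a = 0, b = 0) {
  x <- (as.numeric(master) %% 2147483647) + 1
  x <- (x * 48271 + 1013904223 * (a + 1)) %% 2147483647
  x <- (x * 69621 + 2654435761 * (b + 1)) %% 2147483647
  as.integer(x %% 2147483647)
}

# run R code under a local RNG seed, restoring the global stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(code)
}

#' Generate a synthetic tether-extension trace
#'
#' Emulates a single-molecule record of transcription through a roadblock:
#' monotonic progress at `gen$velocity` from the promoter to the terminator,
#' interrupted by short ubiquitous pauses (Poisson-placed along the
#' template, exponential durations) and by one roadblock pause at the
#' operator drawn from the six-state kinetic model, with the pause censored
#' if the observation window ends first. The latent position (bp) is mapped
#' to extension as `extension = s * a_true * nm_per_bp * position` plus
#' i.i.d. Gaussian noise, where `s` is +1 for assisting-force geometry and
#' -1 for opposing (extension decreases as transcription proceeds). The
#' record is sampled at 1 s and truncated at the observation window;
#' ground-truth annotations are stored in `meta`.
#'
#' @param geometry a [template_geometry()]
#' @param cond a [condition()]
#' @param gen a [trace_gen_config()]
#' @param params a [kinetic_params()] for the roadblock pause
#' @return an object of class `raw_trace`: list with `time_s`,
#'   `extension_nm` (NA at gaps) and `meta` (condition, generator config,
#'   geometry, and `truth`: per-sample latent positions, roadblock pause
#'   start/duration/outcome, ubiquitous pause table)
#' @export
generate_trace <- function(geometry, cond, gen, params) {
  stopifnot(inherits(geometry, "template_geometry"),
            inherits(cond, "expt_condition"),
            inherits(gen, "trace_gen_config"),
            inherits(params, "kinetic_params"))
  obs_window <- if (is.null(gen$obs_window))
    .default_obs_window(cond$roadblock) else gen$obs_window
  dt <- 1

  .with_seed(.derive_seed(gen$seed, 1), {
    # ubiquitous pauses: Poisson number, uniform positions, exponential dwell
    L <- geometry$terminator_pos
    n_ub <- stats::rpois(1, gen$ubiquitous_pause_rate * L)
    excl <- if (is.null(gen$rb_exclusion_bp)) 30 else gen$rb_exclusion_bp
    up <- stats::runif(n_ub, 0, L)
    keep_ub <- abs(up - geometry$operator_pos) > excl
    ub <- data.frame(position = sort(up[keep_ub]),
                     duration = stats::rexp(sum(keep_ub),
                                            1 / gen$ubiquitous_pause_mean))

    # build the latent position path as (position, hold time) waypoints
    pos_path <- numeric(0)   # latent position per 1 s sample
    t_now <- 0
    emit <- function(pos, n_samples) {
      k <- min(n_samples, max(0, obs_window - length(pos_path)))
      if (k > 0) pos_path <<- c(pos_path, rep(pos, k))
    }
    advance <- function(from, to) {
      # march at gen$velocity, dropping ubiquitous pauses on the way
      stops <- ub[ub$position > from & ub$position <= to, , drop = FALSE]
      cur <- from
      for (j in seq_len(nrow(stops))) {
        n_mv <- round((stops$position[j] - cur) / (gen$velocity * dt))
        if (n_mv > 0)
          emit_ramp(cur, stops$position[j], n_mv)
        cur <- stops$position[j]
        emit(cur, round(stops$duration[j] / dt))
      }
      n_mv <- round((to - cur) / (gen$velocity * dt))
      if (n_mv > 0) emit_ramp(cur, to, n_mv)
    }
    emit_ramp <- function(from, to, n_mv) {
      # interior samples only: the arrival sample belongs to the dwell at
      # the destination, so a pause of p samples shows a p-sample plateau
      k <- min(n_mv - 1, max(0, obs_window - length(pos_path)))
      if (k > 0)
        pos_path <<- c(pos_path, from + (to - from) * seq_len(k) / n_mv)
    }

    emit(0, round(gen$promoter_dwell / dt))
    advance(0, geometry$operator_pos)

    # roadblock pause at the operator, censored by the remaining window
    t_arrival <- length(pos_path) * dt
    remaining <- obs_window - t_arrival
    truth_pause <- NULL
    if (remaining >= 2 * params$dt) {
      ps <- generate_pause_sample(params, 1, min(remaining, params$t_max),
                                  seed = .derive_seed(gen$seed, 2))
      pdur <- ps$durations[1]
      pcens <- ps$censored[1]
      emit(geometry$operator_pos, round(pdur / dt))
      truth_pause <- list(start_s = t_arrival, duration_s = pdur,
                          censored = pcens,
                          outcome = if (pcens) "stalled_censored"
                                    else "transited")
      if (!pcens) {
        advance(geometry$operator_pos, geometry$terminator_pos)
        emit(geometry$terminator_pos, obs_window)  # hold to window end
      }
    } else {
      # the EC barely reaches the roadblock before the window closes
      emit(geometry$operator_pos, obs_window)
      truth_pause <- list(start_s = t_arrival,
                          duration_s = max(obs_window - t_arrival, 0),
                          censored = TRUE, outcome = "stalled_censored")
    }

    n <- length(pos_path)
    sgn <- if (geometry$direction == "opposing") -1 else 1
    ext <- sgn * gen$a_true * gen$nm_per_bp * pos_path +
      stats::rnorm(n, 0, gen$noise_sd)
    if (gen$gap_len > 0) {
      g0 <- round(gen$promoter_dwell / dt)
      gi <- seq(g0 + 1, min(g0 + gen$gap_len, n))
      ext[gi] <- NA_real_
    }

    structure(list(
      time_s = seq(0, by = dt, length.out = n),
      extension_nm = ext,
      meta = list(condition = cond, gen = gen, geometry = geometry,
                  params = params, obs_window = obs_window,
                  truth = list(position_bp = pos_path,
                               roadblock_pause = truth_pause,
                               ubiquitous = ub))),
      class = "raw_trace")
  })
}

#' @export
print.raw_trace <- function(x, ...) {
  tp <- x$meta$truth$roadblock_pause
  cat(sprintf("Synthetic trace: %d samples at 1 s | %s\n",
              length(x$time_s), format(x$meta$condition)))
  cat(sprintf("  roadblock pause: %.0f s at %.0f s (%s)\n",
              tp$duration_s, tp$start_s, tp$outcome))
  invisible(x)
}

#' Generate a cohort of synthetic traces
#'
#' @param rows a list of rows, each a list with fields `label` (unique
#'   condition label), `condition`, `n_traces`, `params`, and optionally
#'   `geometry` and `gen` (defaults applied otherwise)
#' @param master_seed integer; per-trace seeds are derived deterministically
#'   from it, so the same master seed reproduces the cohort bit for bit
#' @return a list of `raw_trace` objects; each carries its `label` in
#'   `meta$label`
#' @export
generate_cohort <- function(rows, master_seed = 1) {
  labels <- vapply(rows, function(r) r$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  out <- list()
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    geometry <- if (!is.null(r$geometry)) r$geometry
      else template_geometry(direction = if (r$condition$force_direction ==
                                             "assisting") "assisting"
                             else "opposing")
    gen0 <- if (!is.null(r$gen)) r$gen else trace_gen_config()
    for (j in seq_len(r$n_traces)) {
      gen <- gen0
      gen$seed <- .derive_seed(master_seed, i, j)
      tr <- generate_trace(geometry, r$condition, gen, r$params)
      tr$meta$label <- r$label
      tr$meta$trace_id <- sprintf("%s_%03d", r$label, j)
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}
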