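#' Dwell-time histogram of a stepped trace
#'
#' Converts a piecewise-constant trace into the total time spent per
#' position bin: each finite sample contributes its sampling interval
#' `dt_sample` to the bin containing its fitted level. Gap samples
#' contribute nothing, so the total dwell equals the non-gap duration of the
#' source trace. Because the stepped trace changes level only at sparse
#' jumps, the histogram consists of sharp peaks at pause positions.
#'
#' @param stepped a [fit_steps()] result, or a numeric vector of levels
#' @param bin_width bin width in the level units (default 1 nm)
#' @param dt_sample sampling interval, s (default 1)
#' @return an object of class `dwell_histogram` with fields `bin_edges`,
#'   `mid` (bin centres), `dwell` (s per bin), `units`, `total_dwell`
#' @export
dwell_histogram <- function(stepped, bin_width = 1, dt_sample = 1,
                            units = "nm") {
  if (bin_width <= 0) stop("bin_width must be positive")
  levels <- if (inherits(stepped, "stepped_trace")) stepped$levels else stepped
  levels <- levels[is.finite(levels)]
  if (length(levels) == 0) stop("empty stepped trace")
  bin <- floor(levels / bin_width)
  lo <- min(bin); hi <- max(bin)
  dwell <- numeric(hi - lo + 1L)
  tb <- table(bin)
  dwell[as.integer(names(tb)) - lo + 1L] <- as.numeric(tb) * dt_sample
  # dwell-weighted mean level per occupied bin: sharper than the bin centre
  # for alignment (plateaus sit at one level, not at the bin midpoint)
  lv <- tapply(levels, bin, mean)
  edges <- (lo:(hi + 1L)) * bin_width
  mid <- edges[-length(edges)] + bin_width / 2
  level_mean <- mid
  level_mean[as.integer(names(lv)) - lo + 1L] <- as.numeric(lv)
  structure(list(bin_edges = edges,
                 mid = mid,
                 level_mean = level_mean,
                 dwell = dwell,
                 units = units,
                 bin_width = bin_width,
                 total_dwell = sum(dwell)),
            class = "dwell_histogram")
}

#' @export
print.dwell_histogram <- function(x, ...) {
  cat(sprintf("Dwell histogram: %d bins of %g %s, total dwell %.0f s\n",
              length(x$dwell), x$bin_width, x$units, x$total_dwell))
  top <- order(x$dwell, decreasing = TRUE)[seq_len(min(3, length(x$dwell)))]
  for (i in top)
    if (x$dwell[i] > 0)
      cat(sprintf("  peak at %.1f %s: %.0f s\n", x$mid[i], x$units, x$dwell[i]))
  invisible(x)
}

#' Plot a dwell-time histogram
#'
#' @param x a `dwell_histogram`
#' @param ... passed to [graphics::plot()]
#' @export
plot.dwell_histogram <- function(x, ...) {
  graphics::plot(x$mid, x$dwell, type = "h",
                 xlab = sprintf("position (%s)", x$units),
                 ylab = "dwell (s)", ...)
  invisible(x)
}

#' Optimise the per-trace expansion factor
#'
#' Bead-to-bead variation in size and magnetisation rescales each record by
#' an unknown factor. A grid search over the expansion factor `a` (shift `b`
#' fixed at 0 by default, since the transcription start pins the origin)
#' maximises the dwell captured within `+/- window` of the landmark
#' positions (promoter, roadblock, terminator), weighting each dwell
#' contribution by a triangular kernel `1 - |pos - landmark| / window` so
#' that the optimum centres the dwell peaks on the landmarks (a hard window
#' leaves the objective flat over a range of `a`). Ties are broken toward
#' `a = 1`.
#'
#' @param hist a [dwell_histogram()]
#' @param landmarks numeric vector (>= 2) of landmark positions in the
#'   histogram's units after rescaling (i.e. true positions)
#' @param window half-width of the landmark capture window (default 20 nm)
#' @param a_range search interval for `a` (default `c(0.70, 1.40)`)
#' @param a_step grid step (default 0.001)
#' @param fit_b if `TRUE`, jointly search a small grid of shifts `b`
#'   (default `FALSE`, `b = 0`)
#' @param b_range,b_step shift grid, used only when `fit_b = TRUE`
#' @return an object of class `alignment_result` with fields `a`, `b`,
#'   `objective` (landmark dwell captured, s), `landmarks_used`, and
#'   `failed` (`TRUE` if no grid point captured any dwell)
#' @export
optimize_scale <- function(hist, landmarks, window = 20,
                           a_range = c(0.70, 1.40), a_step = 0.001,
                           fit_b = FALSE, b_range = c(-30, 30), b_step = 1) {
  stopifnot(inherits(hist, "dwell_histogram"))
  if (length(landmarks) < 2) stop("need at least 2 landmarks")
  if (a_range[1] <= 0 || a_range[2] > 2 || a_range[1] >= a_range[2])
    stop("a_range must lie within (0, 2]")
  a_grid <- seq(a_range[1], a_range[2], by = a_step)
  b_grid <- if (fit_b) seq(b_range[1], b_range[2], by = b_step) else 0
  nz <- which(hist$dwell > 0)
  mids <- if (!is.null(hist$level_mean)) hist$level_mean[nz]
          else hist$mid[nz]
  dwell <- hist$dwell[nz]

  objective <- function(a, b) {
    pos <- a * mids + b
    w <- rep(0, length(pos))
    for (lm in landmarks)
      w <- pmax(w, 1 - abs(pos - lm) / window)
    sum(dwell * w)
  }

  best <- list(a = NA_real_, b = NA_real_, obj = -Inf)
  for (b in b_grid) {
    objs <- vapply(a_grid, objective, numeric(1), b = b)
    m <- max(objs)
    if (m > best$obj ||
        (m == best$obj && !is.na(best$a) &&
         min(abs(a_grid[objs == m] - 1)) < abs(best$a - 1))) {
      cand <- a_grid[objs == m]
      best <- list(a = cand[which.min(abs(cand - 1))], b = b, obj = m)
    }
  }
  failed <- !is.finite(best$obj) || best$obj <= 0
  structure(list(a = best$a, b = best$b, objective = best$obj,
                 landmarks_used = landmarks, window = window,
                 failed = failed),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Alignment: a = %.3f, b = %g, landmark dwell %.0f s%s\n",
              x$a, x$b, x$objective,
              if (x$failed) " [FAILED: no landmark dwell captured]" else ""))
  invisible(x)
}

#' Apply a linear rescaling and convert to template coordinates
#'
#' Maps fitted extension levels to positions along the template in base
#' pairs: `position = sign * (a * level + b) / nm_per_bp`, with the origin
#' at the transcription start (position 0). For traces recorded under
#' opposing force the extension decreases as transcription proceeds;
#' `direction = "opposing"` flips the sign so positions always increase in
#' the direction of transcription.
#'
#' @param stepped a [fit_steps()] result (or numeric level vector, nm)
#' @param r an [optimize_scale()] result (or a list with `a` and `b`)
#' @param nm_per_bp nm per base pair (default 1/3, making 20 nm = 60 bp)
#' @param direction `"assisting"` (default) or `"opposing"`
#' @return numeric vector of positions in bp, `NA` at gaps
#' @export
apply_scale <- function(stepped, r, nm_per_bp = 1 / 3,
                        direction = c("assisting", "opposing")) {
  direction <- match.arg(direction)
  levels <- if (inherits(stepped, "stepped_trace")) stepped$levels else stepped
  sgn <- if (direction == "opposing") -1 else 1
  sgn * (r$a * levels + r$b) / nm_per_bp
}
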