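#' Condition-grouped collection of pause durations
#'
#' Container for roadblock pause durations with right-censoring flags, the
#' experimental condition they were collected under, and the number of
#' source traces. Censored entries are "indefinitely stalled" complexes whose
#' pause outlasted the observation window; their recorded duration is the
#' censoring time.
#'
#' @param durations numeric vector of pause durations, s (> 0)
#' @param censored logical vector, same length; `TRUE` marks right-censored
#'   durations
#' @param condition optional [condition()] describing the experiment
#' @param n_traces optional count of source traces
#' @param censor_time observation window used for censoring, s (used by the
#'   parametric bootstrap); `NA` if unknown
#' @param extra optional list of auxiliary per-pause columns
#' @return an object of class `pause_sample`
#' @export
pause_sample <- function(durations, censored = rep(FALSE, length(durations)),
                         condition = NULL, n_traces = NA_integer_,
                         censor_time = NA_real_, extra = NULL) {
  stopifnot(is.numeric(durations), is.logical(censored),
            length(durations) == length(censored))
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("durations must be positive and finite")
  structure(list(durations = as.numeric(durations),
                 censored = censored,
                 condition = condition,
                 n_traces = n_traces,
                 censor_time = censor_time,
                 extra = extra),
            class = "pause_sample")
}

#' @export
print.pause_sample <- function(x, ...) {
  cat(sprintf("Pause sample: %d pauses (%d censored)",
              length(x$durations), sum(x$censored)))
  if (!is.null(x$condition))
    cat(" |", format(x$condition))
  cat(sprintf("\n  mean %.1f s, median %.1f s", mean(x$durations),
              stats::median(x$durations)))
  if (!is.na(x$censor_time))
    cat(sprintf(", observation window %g s", x$censor_time))
  cat("\n")
  invisible(x)
}

#' @export
length.pause_sample <- function(x) length(x$durations)

#' Plot the Kaplan-Meier CCDF of a pause sample
#'
#' @param x a `pause_sample`
#' @param log_y log-scale the survival axis (default `TRUE`, which turns
#'   an exponential CCDF into a straight line)
#' @param ... passed to [graphics::plot()]
#' @export
plot.pause_sample <- function(x, log_y = TRUE, ...) {
  cc <- ccdf(x)
  keep <- cc$ccdf > 0
  graphics::plot(cc$t[keep], cc$ccdf[keep], type = "s",
                 log = if (log_y) "y" else "",
                 xlab = "pause time (s)", ylab = "fraction > t", ...)
  invisible(x)
}

#' Drop censored records from a pause sample
#'
#' Reproduces the "excluding indefinite stalls" analyses: censored records
#' are removed entirely rather than treated as censored observations.
#'
#' @param sample a [pause_sample()]
#' @return a [pause_sample()] containing only uncensored records
#' @export
drop_censored <- function(sample) {
  stopifnot(inherits(sample, "pause_sample"))
  keep <- !sample$censored
  pause_sample(sample$durations[keep], sample$censored[keep],
               condition = sample$condition, n_traces = sample$n_traces,
               censor_time = sample$censor_time,
               extra = if (!is.null(sample$extra))
                 lapply(sample$extra, function(v)
                   if (length(v) == length(keep)) v[keep] else v))
}
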