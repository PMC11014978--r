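#' Write a trace as TSV (with JSON sidecar)
#'
#' Columns `time_s`, `extension_nm`; gap samples are written as empty
#' fields. When the trace carries metadata (a synthetic `raw_trace`), a
#' sidecar `<path>.json` records the condition, generator settings and
#' ground truth.
#'
#' @param trace a `raw_trace`, or a data frame / list with `time_s` and
#'   `extension_nm`
#' @param path output TSV path
#' @param sidecar write the JSON sidecar when metadata is present
#'   (default `TRUE`)
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path, sidecar = TRUE) {
  df <- data.frame(time_s = trace$time_s,
                   extension_nm = trace$extension_nm)
  ext <- ifelse(is.finite(df$extension_nm),
                formatC(df$extension_nm, format = "g", digits = 10), "")
  lines <- c("time_s\textension_nm",
             paste(formatC(df$time_s, format = "g", digits = 10), ext,
                   sep = "\t"))
  writeLines(lines, path)
  if (sidecar && !is.null(trace$meta)) {
    meta <- trace$meta
    meta$truth$position_bp <- NULL  # bulky; regenerable from the seed
    jsonlite::write_json(.unclass_rec(meta), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

.unclass_rec <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_rec) else x
}

#' Read a trace TSV
#'
#' Validates the header and the uniform 1-column time grid; empty or
#' non-finite extension fields become gaps (`NA`).
#'
#' @param path TSV with header `time_s`, `extension_nm`
#' @return a list of class `raw_trace` with `time_s`, `extension_nm`, and
#'   `meta` (from the JSON sidecar if present, else `NULL`)
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("numeric", "numeric"),
                          na.strings = c("", "NA", "NaN"))
  if (!identical(names(df), c("time_s", "extension_nm")))
    stop("expected columns time_s, extension_nm")
  t <- df$time_s
  if (length(t) > 1) {
    dt <- diff(t)
    if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-9 * max(dt[1], 1))
      stop("time grid must be strictly increasing and uniform")
  }
  meta <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc))
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  structure(list(time_s = t, extension_nm = df$extension_nm, meta = meta),
            class = "raw_trace")
}

#' Write / read pause records
#'
#' @param records a `pause_records` data frame
#' @param path TSV path
#' @return `path` (write) or the records (read)
#' @export
write_pause_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pause_records
#' @export
read_pause_records <- function(path) {
  out <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(out) <- c("pause_records", "data.frame")
  out
}

#' End-to-end pipeline configuration
#'
#' @param cohort list of cohort rows as for [generate_cohort()]
#' @param master_seed master seed; all stage randomness derives from it
#' @param out_dir output directory (`NULL`: nothing written to disk)
#' @param lambda step-fit penalty (`"auto"` for [default_lambda()])
#' @param fit_model run [fit_global()] on the extracted pauses
#' @param search a [fit_search_config()] for the model-fitting stage
#' @param min_pause_s,window_bp pause-extraction settings
#' @return a list of class `run_config` with a deterministic `hash`
#' @export
run_config <- function(cohort, master_seed = 1, out_dir = NULL,
                       lambda = "auto", fit_model = FALSE,
                       search = fit_search_config(seed = master_seed),
                       min_pause_s = 20, window_bp = 60) {
  cfg <- list(cohort = cohort, master_seed = master_seed,
              out_dir = out_dir, lambda = lambda, fit_model = fit_model,
              search = search, min_pause_s = min_pause_s,
              window_bp = window_bp)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Deterministic hash of a configuration
#'
#' Canonical-JSON MD5, used to stamp every stage output so results can be
#' traced back to the exact configuration that produced them.
#'
#' @param cfg any JSON-serialisable list (a `hash` field is ignored)
#' @return a 32-character hex string
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(.unclass_rec(cfg), f, auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Chains all stages: synthesis, total-variation step fitting, dwell
#' histogram + alignment, roadblock pause extraction, censored exponential
#' fitting with single/double model selection and, optionally, global
#' kinetic-model fitting. Re-running with the same configuration is
#' bit-identical.
#'
#' @param config a [run_config()]
#' @return a list of class `pipeline_report` with per-stage summaries: the
#'   cohort size, per-trace alignment factors, the pause records, per-label
#'   [pause_sample()]s and exponential fits, the model fit (if requested),
#'   and the seeds and config hash used
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- list()
  traces <- generate_cohort(config$cohort, config$master_seed)
  log$n_traces <- length(traces)

  records <- NULL
  aligns <- list()
  for (tr in traces) {
    y <- tr$extension_nm
    lam <- if (identical(config$lambda, "auto")) default_lambda(y)
           else config$lambda
    st <- fit_steps(y, lam)
    geom <- tr$meta$geometry
    gen <- tr$meta$gen
    sgn <- if (geom$direction == "opposing") -1 else 1
    lm_nm <- sgn * gen$nm_per_bp *
      c(geom$promoter_pos, geom$operator_pos, geom$terminator_pos)
    hist <- dwell_histogram(st, bin_width = 1)
    al <- optimize_scale(hist, landmarks = lm_nm, window = 20)
    aligns[[tr$meta$trace_id]] <- al
    pos <- apply_scale(st, al, nm_per_bp = gen$nm_per_bp,
                       direction = geom$direction)
    recs <- extract_pauses(pos, geom, window_bp = config$window_bp,
                           min_pause_s = config$min_pause_s,
                           trace_id = tr$meta$trace_id,
                           condition = tr$meta$condition)
    if (nrow(recs) > 0) {
      recs$label <- tr$meta$label
      records <- rbind(records, recs)
    }
  }
  log$n_pauses <- if (is.null(records)) 0L else nrow(records)

  samples <- list()
  fits <- list()
  if (!is.null(records)) {
    for (lab in unique(records$label)) {
      rr <- records[records$label == lab, , drop = FALSE]
      row <- Filter(function(r) r$label == lab, config$cohort)[[1]]
      ow <- if (!is.null(row$gen) && !is.null(row$gen$obs_window))
        row$gen$obs_window else .default_obs_window(row$condition$roadblock)
      smp <- pause_sample(rr$duration_s, rr$outcome != "transited",
                          condition = row$condition,
                          n_traces = length(unique(rr$trace_id)),
                          censor_time = ow)
      samples[[lab]] <- smp
      if (sum(!smp$censored) >= 5) {
        single <- fit_exp_single(smp, seed = config$master_seed)
        dbl <- if (sum(!smp$censored) >= 20)
          fit_exp_double(smp, seed = config$master_seed) else NULL
        fits[[lab]] <- list(
          single = single, double = dbl,
          selected = if (!is.null(dbl)) select_model(single, dbl)$choice
                     else "single")
      }
    }
  }

  model_fit <- NULL
  if (isTRUE(config$fit_model) && length(samples) >= 2)
    model_fit <- fit_global(samples, config$search)

  report <- structure(list(
    config_hash = config$hash, master_seed = config$master_seed,
    log = log, alignments = aligns, records = records,
    samples = samples, exp_fits = fits, model_fit = model_fit),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(records))
      write_pause_records(records,
                          file.path(config$out_dir, "pause_records.tsv"))
    summ <- list(config_hash = config$hash,
                 master_seed = config$master_seed, log = log,
                 a_factors = vapply(aligns, `[[`, numeric(1), "a"),
                 exp_fits = lapply(fits, function(f) list(
                   tau_single = f$single$tau, ci90 = f$single$ci90,
                   selected = f$selected)))
    if (!is.null(model_fit))
      summ$model_fit <- list(params = model_fit$params_by_roadblock,
                             distance = model_fit$distance,
                             regimes = lapply(model_fit$regimes, `[[`,
                                              "label"))
    if (length(samples) > 0) {
      grDevices::pdf(file.path(config$out_dir, "ccdf.pdf"), width = 5,
                     height = 4)
      for (lab in names(samples))
        plot(samples[[lab]], main = lab)
      grDevices::dev.off()
    }
    jsonlite::write_json(.unclass_rec(summ),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("Pipeline report (config %s)\n", substr(x$config_hash, 1, 8)))
  cat(sprintf("  %d traces -> %d roadblock pauses\n",
              x$log$n_traces, x$log$n_pauses))
  for (lab in names(x$exp_fits)) {
    f <- x$exp_fits[[lab]]
    cat(sprintf("  %s: tau = %.1f s [%.1f, %.1f], model: %s\n", lab,
                f$single$tau, f$single$ci90[1], f$single$ci90[2],
                f$selected))
  }
  if (!is.null(x$model_fit)) print(x$model_fit)
  invisible(x)
}
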