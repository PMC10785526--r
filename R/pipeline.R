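# End-to-end pipeline: annotation -> coverage -> matrix -> clustering ->
# outputs, with per-stage logging and a machine-readable run report.

#' Build and validate a run configuration
#'
#' Collects every tunable of the pipeline with its documented default.
#' Paths are checked at validation time; numeric ranges are enforced.
#'
#' @param alignment path to the treatment SAM file.
#' @param annotation path to the GFF3/GTF annotation.
#' @param out_dir output directory.
#' @param feature_type annotation feature type to analyze; default `"CDS"`.
#' @param control_alignment optional control SAM enabling log2-ratio mode.
#' @param bins number of bins L each feature is normalized to; default 100.
#' @param threshold relative-improvement stopping threshold; default 0.20.
#' @param seed RNG seed; default 1337.
#' @param k_max largest k tried by the selection loop; default 10.
#' @param restarts random initializations per k; default 5.
#' @param fixed_k optional fixed number of clusters (skips selection).
#' @param distance `"squared"` (default) or `"absolute"` pointwise distance.
#' @param reverse_minus reverse minus-strand features? Default `TRUE`.
#' @param scale_rows divide each row by its mean before clustering?
#'   Default `FALSE`.
#' @param pseudocount pseudocount for log2-ratio mode; default 1.
#' @param keep_duplicates count duplicate-flagged reads? Default `TRUE`.
#' @param min_mapq minimum MAPQ; default 0.
#' @param log_level `"warn"`, `"info"` (default) or `"debug"`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(alignment, annotation, out_dir,
                       feature_type = "CDS", control_alignment = NULL,
                       bins = 100L, threshold = 0.20, seed = 1337L,
                       k_max = 10L, restarts = 5L, fixed_k = NULL,
                       distance = c("squared", "absolute"),
                       reverse_minus = TRUE, scale_rows = FALSE,
                       pseudocount = 1, keep_duplicates = TRUE,
                       min_mapq = 0L, log_level = "info") {
  distance <- match.arg(distance)
  if (!file.exists(alignment)) {
    stop("alignment stage: file not found: ", alignment)
  }
  if (!file.exists(annotation)) {
    stop("annotation stage: file not found: ", annotation)
  }
  if (!is.null(control_alignment) && !file.exists(control_alignment)) {
    stop("alignment stage: control file not found: ", control_alignment)
  }
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (bins < 1L) stop("bins must be >= 1")
  if (k_max < 1L) stop("k_max must be >= 1")
  if (!is.null(fixed_k) && fixed_k < 1L) stop("fixed_k must be >= 1")
  structure(
    list(alignment = alignment, annotation = annotation, out_dir = out_dir,
         feature_type = feature_type, control_alignment = control_alignment,
         bins = as.integer(bins), threshold = threshold,
         seed = as.integer(seed), k_max = as.integer(k_max),
         restarts = as.integer(restarts), fixed_k = fixed_k,
         distance = distance, reverse_minus = reverse_minus,
         scale_rows = scale_rows, pseudocount = pseudocount,
         keep_duplicates = keep_duplicates, min_mapq = as.integer(min_mapq),
         log_level = log_level),
    class = "run_config")
}

#' Run the full clustering pipeline
#'
#' Executes the five stages in order — read annotation, read alignment(s),
#' build the length-normalized feature matrix, cluster (automatic k
#' selection unless `fixed_k` is set), write outputs — logging per-stage
#' timing and counts to stderr. All text outputs are deterministic given
#' the configuration (including the seed).
#'
#' @param config a `run_config`.
#' @return the `cluster_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old <- options(clustagene.log_level = config$log_level)
  on.exit(options(old))
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(code), error = function(e) {
      stop(name, " stage: ", conditionMessage(e), call. = FALSE)
    })
    log_msg("info", sprintf("%s stage done in %.2fs", name,
                            proc.time()[["elapsed"]] - t0))
    out
  }

  features <- stage("annotation", parse_annotation(config$annotation,
                                                   config$feature_type))
  log_msg("info", nrow(features), " feature(s) of type ",
          config$feature_type, " parsed")

  track <- stage("alignment", build_coverage(
    config$alignment, keep_duplicates = config$keep_duplicates,
    min_mapq = config$min_mapq))
  log_msg("info", track$n_counted, " record(s) counted, ",
          track$n_skipped, " skipped")
  control <- NULL
  if (!is.null(config$control_alignment)) {
    control <- stage("alignment", build_coverage(
      config$control_alignment, keep_duplicates = config$keep_duplicates,
      min_mapq = config$min_mapq))
  }

  mat <- stage("matrix", build_matrix(
    track, features, L = config$bins, control = control,
    reverse_minus = config$reverse_minus, scale_rows = config$scale_rows,
    pseudocount = config$pseudocount))
  log_msg("info", nrow(mat), " feature vector(s) of length ", config$bins)

  fit <- stage("clustering", {
    if (!is.null(config$fixed_k)) {
      list(model = best_kmeans(mat, config$fixed_k, seed = config$seed,
                               restarts = config$restarts,
                               distance = config$distance),
           trace = NULL)
    } else {
      select_k(mat, threshold = config$threshold, seed = config$seed,
               k_max = config$k_max, restarts = config$restarts,
               distance = config$distance)
    }
  })
  model <- fit$model
  trace <- fit$trace
  log_msg("info", "selected k = ", model$k)

  report <- cluster_report(model, mat, trace = trace,
                           params = config_params(config),
                           skipped = attr(mat, "skipped"))
  stage("outputs", {
    write_membership(report, config$out_dir)
    render_plots(report, config$out_dir)
    write_run_report(report, config$out_dir)
  })
  invisible(report)
}

# parameters recorded in run_report.json (paths normalized to basenames so
# reports are comparable across working directories)
config_params <- function(config) {
  p <- unclass(config)
  p$alignment <- basename(p$alignment)
  p$annotation <- basename(p$annotation)
  if (!is.null(p$control_alignment)) {
    p$control_alignment <- basename(p$control_alignment)
  }
  p$out_dir <- NULL
  p
}
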