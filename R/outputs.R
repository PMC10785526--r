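# Run outputs: per-cluster metagene plots, the conventional unclustered
# plot, membership text files, and a machine-readable run report. Every
# plotted series is also written as TSV so numeric content is testable
# (and reusable) without parsing images.

#' Assemble a cluster report from a fitted model
#'
#' Collects everything the output writers need: per-cluster member id
#' lists (in original annotation order), member counts, center vectors,
#' the positionwise mean over all rows (the unclustered metagene curve),
#' the k-selection trace and run parameters. Validates the partition
#' invariant: the member lists partition the matrix ids exactly.
#'
#' @param model a `cluster_model`.
#' @param matrix the `feature_matrix` the model was fitted to.
#' @param trace optional k-selection trace data frame.
#' @param params named list of run parameters to record.
#' @param skipped number of features skipped upstream.
#' @return an object of class `cluster_report`.
#' @export
cluster_report <- function(model, matrix, trace = NULL, params = list(),
                           skipped = 0L) {
  ids <- rownames(matrix)
  members <- lapply(seq_len(model$k), function(j) ids[model$assignments == j])
  counts <- lengths(members)
  got <- unlist(members, use.names = FALSE)
  if (anyDuplicated(got) || length(got) != length(ids) ||
      !setequal(got, ids)) {
    stop("internal error: cluster membership does not partition the ids")
  }
  structure(
    list(k = model$k, members = members, counts = counts,
         centers = model$centers, unclustered = colMeans(matrix),
         assignments = model$assignments, ids = ids,
         total_distance = model$total_distance, trace = trace,
         params = params, skipped = as.integer(skipped)),
    class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("cluster_report: %d feature(s) in %d cluster(s)\n",
              length(x$ids), x$k))
  cat(sprintf("  sizes: %s\n", paste(x$counts, collapse = ", ")))
  cat(sprintf("  total distance: %.6g\n", x$total_distance))
  if (x$skipped > 0L) cat(sprintf("  skipped upstream: %d\n", x$skipped))
  invisible(x)
}

#' Write per-cluster membership files
#'
#' Writes one plain-text file per cluster (`cluster_<i>.txt`, one feature
#' id per line, in original annotation order) and a `summary.tsv` with
#' columns `feature_id`, `cluster_index`. Clusters are numbered from 1.
#'
#' @param report a `cluster_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
write_membership <- function(report, out_dir) {
  ensure_dir(out_dir)
  paths <- character(0)
  for (j in seq_len(report$k)) {
    p <- file.path(out_dir, sprintf("cluster_%d.txt", j))
    writeLines(report$members[[j]], p)
    paths <- c(paths, p)
  }
  sp <- file.path(out_dir, "summary.tsv")
  utils::write.table(
    data.frame(feature_id = report$ids, cluster_index = report$assignments),
    sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sp))
}

#' Render metagene plots and their numeric series
#'
#' Writes one image per cluster plotting its center vector (y = mean
#' signal, x = normalized position) plus one "unclustered" image plotting
#' the positionwise mean over all rows — the conventional single metagene
#' curve that clustering is meant to improve on. Each series is also
#' written as `plot_<i>.tsv` / `plot_unclustered.tsv` (columns `position`,
#' `value`). If no graphics device is available the TSVs are still
#' written and a warning is raised.
#'
#' @param report a `cluster_report`.
#' @param out_dir output directory (created if needed).
#' @return character vector of image paths (possibly empty), invisibly.
#' @export
render_plots <- function(report, out_dir) {
  ensure_dir(out_dir)
  series <- c(list(unclustered = report$unclustered),
              stats::setNames(
                lapply(seq_len(report$k), function(j) report$centers[j, ]),
                seq_len(report$k)))
  titles <- c(sprintf("Unclustered metagene (n = %d)", length(report$ids)),
              sprintf("Cluster %d (n = %d)", seq_len(report$k),
                      report$counts))
  images <- character(0)
  for (i in seq_along(series)) {
    tag <- names(series)[i]
    y <- series[[i]]
    utils::write.table(
      data.frame(position = seq_along(y) - 1L, value = y),
      file.path(out_dir, sprintf("plot_%s.tsv", tag)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    img <- file.path(out_dir, sprintf("plot_%s.png", tag))
    ok <- tryCatch({
      ndev <- length(grDevices::dev.list())
      grDevices::png(img, width = 900, height = 600, res = 120)
      graphics::plot(seq_along(y) - 1L, y, type = "l", lwd = 2,
                     col = "steelblue4", xlab = "Normalized position (bin)",
                     ylab = "Mean signal", main = titles[i])
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      # close the device if it was opened before the failure
      if (length(grDevices::dev.list()) > ndev) {
        try(grDevices::dev.off(), silent = TRUE)
      }
      FALSE
    })
    if (ok) images <- c(images, img)
  }
  if (length(images) == 0L) {
    warning("no graphics device available; numeric series written as TSV only")
  }
  invisible(images)
}

#' Write the machine-readable run report
#'
#' Serializes parameters, selected k, cluster sizes, the k-selection trace
#' and skipped-feature counts to `run_report.json`.
#'
#' @param report a `cluster_report`.
#' @param out_dir output directory (created if needed).
#' @return the JSON path, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  ensure_dir(out_dir)
  p <- file.path(out_dir, "run_report.json")
  payload <- list(
    selected_k = report$k,
    cluster_sizes = as.integer(report$counts),
    n_features = length(report$ids),
    total_distance = report$total_distance,
    skipped_features = report$skipped,
    parameters = report$params,
    trace = report$trace)
  jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(p)
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(path)) stop("cannot create directory: ", path)
  }
  invisible(path)
}
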