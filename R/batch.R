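#' Process a folder of images
#'
#' The batch workflow: every TIFF in \code{input_dir} is processed
#' independently with one shared parameter set (thresholds themselves are
#' recomputed per image), counts are written to a timestamped CSV, review
#' overlays are rendered per image, and a log records per-image thresholds
#' and solver diagnostics. One failing image is logged and skipped, never
#' fatal to the batch; the batch result is independent of processing order.
#'
#' @param input_dir Directory containing \code{.tif}/\code{.tiff} images.
#' @param output_dir Directory for the CSV, overlays and log (created if
#'   needed).
#' @param mapping A [channel_mapping()] shared by all images.
#' @param params A [fins_params()].
#' @param floors Marker floor(s), as in [fins()].
#' @param overlay Render a PNG overlay per image? Default TRUE.
#' @param timestamp Timestamp used in the CSV filename; defaults to now.
#' @return Object of class \code{"fins_batch"}: \code{csv} (path),
#'   \code{statuses} (named character, \code{"ok"} or the error message),
#'   \code{records} (data frame of counts), \code{log} (path).
#' @export
run_batch <- function(input_dir, output_dir, mapping,
                      params = fins_params(), floors = 0.1, overlay = TRUE,
                      timestamp = Sys.time()) {
  stopifnot(dir.exists(input_dir), inherits(mapping, "fins_mapping"))
  files <- list.files(input_dir, pattern = "\\.tiff?$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- sort(files)
  if (!length(files))
    stop("no TIFF images found in ", input_dir)
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  statuses <- character(length(files))
  names(statuses) <- basename(files)
  results <- list()
  log_lines <- character()
  for (k in seq_along(files)) {
    res <- tryCatch(
      withCallingHandlers(
        fins(files[k], mapping = mapping, params = params, floors = floors),
        warning = function(w) {
          log_lines <<- c(log_lines, paste0("WARN ", basename(files[k]), ": ",
                                            conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      statuses[k] <- conditionMessage(res)
      log_lines <- c(log_lines,
                     paste0("SKIP ", basename(files[k]), ": ",
                            conditionMessage(res)))
      next
    }
    statuses[k] <- "ok"
    results[[length(results) + 1]] <- res
    s <- summary(res)
    mk <- paste(vapply(s$markers, function(m)
      sprintf("%s: t=%.4f%s count=%d", m$name, m$t,
              if (m$floored) " (floored)" else "", m$count), ""),
      collapse = "; ")
    log_lines <- c(log_lines, sprintf(
      "OK %s: t_delta=%.4f n=%d; %s; iterations=%d converged=%s",
      basename(files[k]), s$t_delta, s$n, mk, s$iterations, s$converged))
    if (overlay) {
      positives <- stats::setNames(
        lapply(res$markers, function(m) m$positive_ids),
        vapply(res$markers, function(m) m$name, ""))
      render_overlay(list(), res$labels, positives,
                     file.path(output_dir,
                               paste0(tools::file_path_sans_ext(basename(files[k])),
                                      "_overlay.png")))
    }
  }
  if (!length(results))
    stop("no image in ", input_dir, " could be processed")
  records <- do.call(rbind, lapply(results, as.data.frame))
  csv <- write_counts_csv(records, output_dir, timestamp = timestamp)
  log_path <- file.path(output_dir, "fins_batch.log")
  writeLines(log_lines, log_path)
  structure(list(csv = csv, statuses = statuses, records = records,
                 log = log_path),
            class = "fins_batch")
}

#' @export
print.fins_batch <- function(x, ...) {
  ok <- sum(x$statuses == "ok")
  cat("FINS batch:", ok, "of", length(x$statuses), "images processed\n")
  cat("  counts:", x$csv, "\n  log:   ", x$log, "\n")
  invisible(x)
}
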