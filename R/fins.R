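#' Count stained nuclei in a multi-channel fluorescence image
#'
#' The main entry point. Segments nuclear regions from the counterstain
#' channel by convex TV-regularised segmentation (see [minimize_energy()]),
#' labels disconnected nuclei, and scores each marker channel for
#' per-nucleus positivity with a floored global Otsu threshold. The result
#' carries the counts, the segmentation, the thresholds used and solver
#' diagnostics, and has \code{print}, \code{summary}, \code{plot} and
#' \code{as.data.frame} methods.
#'
#' A constant (degenerate) counterstain channel yields an all-zero record
#' flagged \code{degenerate = TRUE} with a warning, rather than an error,
#' so that one blank image does not abort a batch.
#'
#' @param x A path to a multi-plane TIFF, or a list of [channel_image()]s
#'   whose first element (or the one with role \code{"counterstain"}) is
#'   the counterstain.
#' @param mapping A [channel_mapping()]; required when \code{x} is a path,
#'   ignored otherwise.
#' @param params A [fins_params()].
#' @param floors Marker threshold floor(s): a single value applied to every
#'   marker, or a named vector per channel name. Default 0.1.
#' @param image_name Label used in records; defaults to the file name, or
#'   \code{"image"}.
#' @param ... Unused.
#' @return An object of class \code{"fins"}.
#' @export
#' @examples
#' fx <- generate_fixture(fixture_spec(n_nuclei = 6, seed = 1))
#' res <- fins(fx$channels)
#' res
#' as.data.frame(res)
fins <- function(x, mapping = NULL, params = fins_params(), floors = 0.1,
                 image_name = NULL, ...) {
  if (is.character(x)) {
    if (is.null(mapping))
      stop("a channel_mapping() is required when reading from a file")
    if (is.null(image_name)) image_name <- basename(x)
    channels <- read_multichannel(x, mapping)
  } else if (is.list(x)) {
    channels <- x
    if (is.null(image_name)) image_name <- "image"
  } else stop("x must be a file path or a list of channel images")

  roles <- vapply(channels, function(ch) attr(ch, "role") %||% "marker", "")
  ci <- which(roles == "counterstain")
  if (length(ci) != 1)
    stop("exactly one counterstain channel is required")
  counter <- channels[[ci]]
  markers <- channels[-ci]
  shp <- dim(counter)
  for (ch in markers)
    if (!identical(dim(ch), shp)) stop("channel shapes differ")

  marker_names <- vapply(markers, function(ch) attr(ch, "name") %||% "", "")
  marker_names[!nzchar(marker_names)] <-
    paste0("marker", which(!nzchar(marker_names)))
  floor_of <- function(nm) {
    if (length(floors) == 1 && is.null(names(floors))) return(unname(floors))
    if (!is.null(names(floors)) && nm %in% names(floors))
      return(unname(floors[nm]))
    0.1
  }

  seg <- tryCatch(segment_nuclei(counter, params),
                  fins_degenerate_histogram = function(e) NULL)
  if (is.null(seg)) {
    warning("degenerate counterstain channel in '", image_name,
            "': recording zero counts", call. = FALSE)
    empty <- label_nuclei(matrix(FALSE, shp[1], shp[2]))
    mk <- lapply(seq_along(markers), function(k)
      list(name = marker_names[k],
           threshold = marker_threshold(markers[[k]], floor_of(marker_names[k])),
           count = 0L, positive_ids = integer()))
    return(structure(list(image_name = image_name, n = 0L, labels = empty,
                          t_delta = NA_real_, field = NULL, markers = mk,
                          params = params, degenerate = TRUE),
                     class = "fins"))
  }

  mk <- lapply(seq_along(markers), function(k) {
    th <- marker_threshold(markers[[k]], floor_of(marker_names[k]))
    pos <- count_positive_nuclei(markers[[k]], seg$labels, th)
    list(name = marker_names[k], threshold = th,
         count = pos$count, positive_ids = pos$positive_ids)
  })
  structure(list(image_name = image_name, n = seg$labels$n,
                 labels = seg$labels, t_delta = seg$t_delta,
                 field = seg$field, markers = mk, params = params,
                 degenerate = FALSE),
            class = "fins")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fins <- function(x, ...) {
  cat("FINS counts for '", x$image_name, "'\n", sep = "")
  cat("  nuclei (counterstain):", x$n, "\n")
  for (m in x$markers)
    cat(sprintf("  %s positive: %d / %d\n", m$name, m$count, x$n))
  if (x$degenerate)
    cat("  [degenerate counterstain channel: counts are zero]\n")
  invisible(x)
}

#' @export
summary.fins <- function(object, ...) {
  s <- list(image_name = object$image_name, n = object$n,
            t_delta = object$t_delta,
            markers = lapply(object$markers, function(m)
              list(name = m$name, count = m$count, t = m$threshold$t,
                   floored = m$threshold$floored)),
            iterations = object$field$iterations %||% NA_integer_,
            converged = object$field$converged %||% NA,
            final_energy = object$field$final_energy %||% NA_real_,
            nonbinary_fraction = object$field$nonbinary_fraction %||% NA_real_,
            degenerate = object$degenerate)
  class(s) <- "summary.fins"
  s
}

#' @export
print.summary.fins <- function(x, ...) {
  cat("FINS analysis of '", x$image_name, "'\n", sep = "")
  cat(sprintf("  counterstain threshold t = %.4f; %d nuclei\n",
              x$t_delta, x$n))
  for (m in x$markers)
    cat(sprintf("  %s: %d positive (t = %.4f%s)\n", m$name, m$count, m$t,
                if (m$floored) ", floored" else ""))
  cat(sprintf("  solver: %d iterations, %s; energy %.4f; %.2f%% non-binary pixels\n",
              x$iterations,
              if (isTRUE(x$converged)) "converged" else "iteration cap reached",
              x$final_energy, 100 * x$nonbinary_fraction))
  invisible(x)
}

#' @export
as.data.frame.fins <- function(x, ...) {
  counts <- stats::setNames(lapply(x$markers, function(m) m$count),
                            vapply(x$markers, function(m) m$name, ""))
  do.call(data.frame,
          c(list(image_name = x$image_name, DAPI = x$n), counts,
            list(stringsAsFactors = FALSE, check.names = FALSE)))
}

#' Plot a FINS result as a review overlay
#'
#' Shows the segmented nuclear regions (white) with coloured contours
#' around nuclei positive for each marker.
#'
#' @param x A \code{fins} object.
#' @param ... Passed to \code{plot}.
#' @export
plot.fins <- function(x, ...) {
  positives <- stats::setNames(lapply(x$markers, function(m) m$positive_ids),
                               vapply(x$markers, function(m) m$name, ""))
  arr <- overlay_array(x$labels, positives)
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(grDevices::as.raster(arr), main = x$image_name, ...)
  invisible(x)
}
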