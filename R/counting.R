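#' Marker threshold with floor
#'
#' A single global Otsu threshold is computed on the whole marker channel
#' and floored at \code{floor} (default 0.1): \code{t = max(otsu, floor)}.
#' The floor guards against images where the histogram gives no adequate
#' split — near-blank channels, or channels whose Otsu value collapses into
#' the background mode — and makes an all-background channel count zero
#' positives (positivity requires intensity strictly above \code{t}).
#' A constant channel, where Otsu is undefined, falls back to the floor.
#'
#' @param z Marker [channel_image()].
#' @param floor Minimum admissible threshold (default 0.1). Applies to
#'   marker channels only; the counterstain threshold is never floored.
#' @return Object of class \code{"fins_marker_threshold"}: \code{t},
#'   \code{floored} (TRUE when the floor binds), \code{channel_name}.
#' @export
marker_threshold <- function(z, floor = 0.1) {
  stopifnot(is.numeric(floor), length(floor) == 1, floor >= 0, floor < 1)
  otsu <- tryCatch(otsu_threshold(z),
                   fins_degenerate_histogram = function(e) -Inf)
  t <- max(otsu, floor)
  structure(list(t = t, floored = otsu < floor,
                 channel_name = if (is.null(attr(z, "name"))) "" else attr(z, "name")),
            class = "fins_marker_threshold")
}

#' Count nuclei positive for a marker
#'
#' A nucleus is positive when any pixel of its region has marker intensity
#' strictly above the threshold; signal outside every nuclear region is
#' ignored. The count is binary per nucleus: foci multiplicity is not
#' quantified.
#'
#' @param z Marker [channel_image()], same shape as the labelling.
#' @param labels A [label_nuclei()] result.
#' @param t A [marker_threshold()] result or a numeric threshold.
#' @return List with \code{count} and the sorted \code{positive_ids}
#'   (nucleus labels scored positive).
#' @export
count_positive_nuclei <- function(z, labels, t) {
  if (inherits(t, "fins_marker_threshold")) t <- t$t
  stopifnot(inherits(labels, "fins_labels"), is.numeric(t), length(t) == 1)
  z <- unclass(z)
  if (!identical(dim(z), dim(labels$label_map)))
    stop("marker channel and labelling have different shapes")
  supra <- labels$label_map[z > t]
  ids <- sort(unique(supra[supra > 0L]))
  list(count = length(ids), positive_ids = as.integer(ids))
}
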