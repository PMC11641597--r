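#' Distance of a count pair from the centroid of rater count pairs
#'
#' Counts are treated as points (counterstain count, marker count) in the
#' plane; the centroid is the arithmetic mean of the rater points and the
#' distance is unweighted Euclidean on the raw integer counts.
#'
#' @param pairs Numeric matrix (or data frame) with one row per rater and
#'   two columns (counterstain count, marker count); at least one row.
#' @param query Length-2 numeric vector, the evaluated count pair.
#' @return Euclidean distance from \code{query} to the centroid.
#' @export
#' @examples
#' centroid_distance(rbind(c(0, 0), c(2, 0)), c(1, 1))  # centroid (1,0) -> 1
centroid_distance <- function(pairs, query) {
  pairs <- as.matrix(pairs)
  stopifnot(nrow(pairs) >= 1, ncol(pairs) == 2, length(query) == 2)
  centroid <- colMeans(pairs)
  sqrt(sum((as.numeric(query) - centroid)^2))
}

#' Bundle rater and algorithm counts for one image
#'
#' @param image_name Image label.
#' @param raters Data frame with columns \code{rater_id}, \code{dapi},
#'   \code{marker} (non-negative integer counts), one row per rater.
#' @param algorithm Length-2 vector: the algorithm's (dapi, marker) counts,
#'   or \code{NULL} when only raters are compared.
#' @return Object of class \code{"fins_rater_set"}.
#' @export
rater_count_set <- function(image_name, raters, algorithm = NULL) {
  stopifnot(is.data.frame(raters),
            all(c("rater_id", "dapi", "marker") %in% names(raters)),
            nrow(raters) >= 2,
            all(raters$dapi >= 0), all(raters$marker >= 0))
  if (!is.null(algorithm)) stopifnot(length(algorithm) == 2, all(algorithm >= 0))
  structure(list(image_name = image_name, raters = raters,
                 algorithm = algorithm),
            class = "fins_rater_set")
}

#' Percentage concordance of a counter with the other raters
#'
#' For each image, the evaluated counter's (counterstain, marker) point is
#' compared against the centroid of the \emph{other} raters' points: the
#' counter is concordant on that image when its distance to the centroid is
#' strictly below the maximum of those raters' distances to the same
#' centroid. The percentage of concordant images is returned.
#'
#' By default the algorithm's counts are evaluated against all raters.
#' With \code{leave_out}, the named rater is evaluated instead against the
#' remaining raters (the algorithm counts are then ignored), giving each
#' human counter the analogous score. Note the deliberate asymmetry: the
#' algorithm is compared against all raters while a left-out rater is
#' compared against one fewer, which tends to flatter the algorithm
#' slightly since the maximum distance grows with more raters.
#'
#' Ties (distance exactly equal to the maximum — e.g. when all counts are
#' identical, so both are zero) count as non-concordant under the strict
#' inequality.
#'
#' @param sets List of [rater_count_set()] objects (one per image).
#' @param leave_out Optional rater id to evaluate instead of the algorithm.
#' @return Object of class \code{"fins_concordance"}: \code{per_image}
#'   data frame (image, distance, max_rater_distance, within) and
#'   \code{percentage} in \[0, 100\].
#' @export
percentage_concordance <- function(sets, leave_out = NULL) {
  if (inherits(sets, "fins_rater_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    stopifnot(inherits(s, "fins_rater_set"))
    r <- s$raters
    if (!is.null(leave_out)) {
      if (!leave_out %in% r$rater_id)
        stop("rater '", leave_out, "' absent for image ", s$image_name)
      query <- as.numeric(r[r$rater_id == leave_out, c("dapi", "marker")][1, ])
      r <- r[r$rater_id != leave_out, , drop = FALSE]
    } else {
      if (is.null(s$algorithm))
        stop("no algorithm counts for image ", s$image_name)
      query <- as.numeric(s$algorithm)
    }
    if (nrow(r) < 2)
      stop("fewer than 2 remaining raters for image ", s$image_name)
    pts <- as.matrix(r[, c("dapi", "marker")])
    centroid <- colMeans(pts)
    d_raters <- sqrt(rowSums(sweep(pts, 2, centroid)^2))
    d <- sqrt(sum((query - centroid)^2))
    data.frame(image = s$image_name, distance = d,
               max_rater_distance = max(d_raters),
               within = d < max(d_raters), stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 percentage = 100 * mean(per_image$within),
                 counter = leave_out %||% "algorithm"),
            class = "fins_concordance")
}

#' @export
print.fins_concordance <- function(x, ...) {
  cat(sprintf("Percentage concordance (%s vs other raters): %.1f%% over %d images\n",
              x$counter, x$percentage, nrow(x$per_image)))
  invisible(x)
}

#' Percent over (or under) the rater count range
#'
#' Signed percentage by which the algorithm's count falls outside the
#' range of the rater counts: positive above the range, relative to the
#' rater maximum; negative below it, relative to the rater minimum; zero
#' when inside the range (inclusive).
#'
#' @param algorithm_count Integer count from the algorithm.
#' @param rater_counts Non-empty integer vector of rater counts with a
#'   positive maximum.
#' @return Signed percentage.
#' @export
#' @examples
#' percent_over_range(62, c(55, 51, 54, 51, 39))  # 12.7 (% over the max)
percent_over_range <- function(algorithm_count, rater_counts) {
  stopifnot(length(rater_counts) >= 1, max(rater_counts) > 0,
            length(algorithm_count) == 1, algorithm_count >= 0)
  hi <- max(rater_counts); lo <- min(rater_counts)
  if (algorithm_count > hi) return(100 * (algorithm_count - hi) / hi)
  if (algorithm_count < lo) {
    if (lo == 0) stop("below an all-zero rater range: percentage undefined")
    return(100 * (algorithm_count - lo) / lo)
  }
  0
}

#' Read rater counts from CSV
#'
#' Expects a long-format CSV with columns \code{image_name},
#' \code{rater_id}, \code{channel}, \code{count}. Rows whose
#' \code{rater_id} equals \code{algorithm_id} supply the algorithm's
#' counts; the rest are raters.
#'
#' @param path CSV path.
#' @param dapi_channel Channel name holding the counterstain count
#'   (default \code{"DAPI"}).
#' @param marker_channel Channel name of the marker being analysed.
#' @param algorithm_id Rater id identifying the algorithm rows (default
#'   \code{"FINS"}); may be absent.
#' @return List of [rater_count_set()] objects, one per image, in file
#'   order of first appearance.
#' @export
read_rater_counts <- function(path, marker_channel, dapi_channel = "DAPI",
                              algorithm_id = "FINS") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_name", "rater_id", "channel", "count")
  if (!all(need %in% names(df)))
    stop("rater CSV must have columns: ", paste(need, collapse = ", "))
  images <- unique(df$image_name)
  lapply(images, function(img) {
    sub <- df[df$image_name == img, ]
    wide <- merge(
      stats::setNames(sub[sub$channel == dapi_channel, c("rater_id", "count")],
                      c("rater_id", "dapi")),
      stats::setNames(sub[sub$channel == marker_channel, c("rater_id", "count")],
                      c("rater_id", "marker")),
      by = "rater_id")
    alg <- wide[wide$rater_id == algorithm_id, , drop = FALSE]
    raters <- wide[wide$rater_id != algorithm_id, , drop = FALSE]
    rater_count_set(img, raters,
                    algorithm = if (nrow(alg)) as.numeric(alg[1, c("dapi", "marker")]) else NULL)
  })
}

#' Write a concordance result to CSV
#'
#' One row per image (distance, maximum rater distance, within flag),
#' followed by a summary row carrying the percentage.
#'
#' @param result A [percentage_concordance()] result.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_concordance_csv <- function(result, path) {
  stopifnot(inherits(result, "fins_concordance"))
  out <- result$per_image
  out$percentage <- ""
  out$percentage[1] <- format(result$percentage)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
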