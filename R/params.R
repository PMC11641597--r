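#' Solver and counting parameters
#'
#' Collects the tunable parameters of the nuclear-segmentation solver and the
#' downstream labelling step. The defaults are the ones the method was
#' developed with and are intended to work across cell types without
#' per-image adjustment.
#'
#' @param lambda Fidelity weight of the data term in the segmentation energy.
#'   Larger values make the solution follow the thresholded image more
#'   closely; smaller values smooth interfaces more aggressively. Default 20.
#' @param beta Binarization level applied to the relaxed solution
#'   \code{u*}; the nuclear foreground is \code{u* > beta}. Must lie in
#'   (0, 1). Because \code{u*} is approximately binary, the result is
#'   insensitive to the exact level. Default 0.5.
#' @param mu Split Bregman penalty weight coupling the auxiliary gradient
#'   field to the gradient of \code{u}. Solver-internal; default 1.
#' @param tol Relative-change stopping tolerance
#'   \code{||u_k+1 - u_k|| / ||u_k||}. Default 1e-4.
#' @param max_iter Iteration cap for the outer Bregman loop. Reaching it is
#'   reported (\code{converged = FALSE}), not an error. Default 200.
#' @param edge_weight_enabled Hook for a non-constant edge weight in the TV
#'   term. Edges are not well defined for this image class, so the weight is
#'   fixed to 1 and this flag must currently remain \code{FALSE}.
#' @param min_area Minimum component area in pixels; smaller components are
#'   discarded after labelling. Default 0 (off): small debris is tolerated
#'   and left to review rather than silently filtered.
#' @param connectivity Pixel connectivity for labelling disconnected nuclei,
#'   4 or 8. Default 8, which merges corner-touching fragments of one
#'   nucleus.
#'
#' @return An object of class \code{"fins_params"} (a validated list).
#' @export
#' @examples
#' fins_params(lambda = 20, beta = 0.5)
fins_params <- function(lambda = 20, beta = 0.5, mu = 1, tol = 1e-4,
                        max_iter = 200, edge_weight_enabled = FALSE,
                        min_area = 0, connectivity = 8) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, lambda > 0,
            is.numeric(beta), length(beta) == 1, beta > 0, beta < 1,
            is.numeric(mu), length(mu) == 1, mu > 0,
            is.numeric(tol), length(tol) == 1, tol > 0,
            is.numeric(max_iter), length(max_iter) == 1, max_iter >= 1,
            is.logical(edge_weight_enabled), length(edge_weight_enabled) == 1,
            is.numeric(min_area), min_area >= 0,
            connectivity %in% c(4, 8))
  if (edge_weight_enabled)
    stop("a non-constant edge weight g(x) is not supported; the weight is fixed to 1")
  structure(list(lambda = lambda, beta = beta, mu = mu, tol = tol,
                 max_iter = as.integer(max_iter),
                 edge_weight_enabled = edge_weight_enabled,
                 min_area = as.integer(min_area),
                 connectivity = as.integer(connectivity)),
            class = "fins_params")
}

#' Map image planes to channel roles
#'
#' Declares which plane of a multi-plane image is the nuclear counterstain
#' (e.g. DAPI) and which planes are nuclear-marker channels (e.g. Ki67,
#' gamma-H2AX). Plane indices are 1-based.
#'
#' @param counterstain 1-based plane index of the counterstain channel.
#' @param markers Named integer vector of marker plane indices, e.g.
#'   \code{c(Ki67 = 1, gH2AX = 2)}. May be empty (counterstain-only
#'   counting).
#' @return An object of class \code{"fins_mapping"}.
#' @export
#' @examples
#' channel_mapping(counterstain = 3, markers = c(Ki67 = 1, gH2AX = 2))
channel_mapping <- function(counterstain, markers = integer()) {
  counterstain <- as.integer(counterstain)
  stopifnot(length(counterstain) == 1, counterstain >= 1)
  markers <- stats::setNames(as.integer(markers), names(markers))
  if (length(markers)) {
    if (is.null(names(markers)) || any(!nzchar(names(markers))))
      stop("every marker channel must be named")
    stopifnot(all(markers >= 1))
  }
  idx <- c(counterstain, markers)
  if (anyDuplicated(idx))
    stop("channel indices must be distinct")
  structure(list(counterstain = counterstain, markers = markers),
            class = "fins_mapping")
}
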