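#' Otsu threshold of a normalized channel
#'
#' Histogram-based automatic threshold over 256 bins on \[0, 1\],
#' minimizing the intra-class intensity variance (equivalently, maximizing
#' the between-class variance).
#'
#' @param z A [channel_image()] or numeric matrix with values in \[0, 1\].
#' @return Threshold in (min(z), max(z)).
#' @section Degenerate images: a constant image admits no two-class split;
#'   a classed error (condition class \code{"fins_degenerate_histogram"}) is
#'   signalled so that callers can decide (the marker floor falls back to
#'   its fixed value; the batch driver flags the image and records zero
#'   counts).
#' @export
otsu_threshold <- function(z) {
  z <- unclass(z)
  stopifnot(is.matrix(z), min(z) >= 0, max(z) <= 1)
  if (diff(range(z)) == 0)
    stop(structure(class = c("fins_degenerate_histogram", "error", "condition"),
                   list(message = "constant image: histogram has a single class",
                        call = sys.call(-1))))
  EBImage::otsu(z, range = c(0, 1), levels = 256)
}

#' Build the intensity fitting term
#'
#' The data term of the segmentation energy is \code{f(x) = t - z(x)}:
#' negative where the counterstain exceeds the threshold (evidence for
#' foreground), positive below it.
#'
#' @param z Counterstain [channel_image()] (or matrix in \[0, 1\]).
#' @param t Threshold in (0, 1), normally from [otsu_threshold()].
#' @return Object of class \code{"fins_fitting"}: list with the matrix
#'   \code{f} and \code{threshold}.
#' @export
build_fitting_term <- function(z, t) {
  stopifnot(is.numeric(t), length(t) == 1, t > 0, t < 1)
  z <- unclass(z)
  stopifnot(is.matrix(z))
  structure(list(f = t - z, threshold = t), class = "fins_fitting")
}

#' Initial labelling from the sign of the fitting term
#'
#' The solver is started at the binary indicator of \code{f < 0}, i.e. the
#' raw thresholded image, which lies close to the global minimiser. (For a
#' fixed fitting term the converged segmentation does not depend on the
#' initialization; this start merely saves iterations.)
#'
#' @param f A [build_fitting_term()] result.
#' @return An indicator field (class \code{"fins_indicator"}) with
#'   \code{iterations = 0}.
#' @export
initialize_indicator <- function(f) {
  stopifnot(inherits(f, "fins_fitting"))
  u0 <- (f$f < 0) * 1
  indicator_field(u0, converged = NA, iterations = 0L, f = f)
}

indicator_field <- function(u, converged, iterations, f = NULL, lambda = NULL,
                            rel_change = NA_real_) {
  stopifnot(is.matrix(u), min(u) >= 0, max(u) <= 1)
  e <- if (!is.null(f) && !is.null(lambda)) tv_energy(u, f, lambda) else NA_real_
  structure(list(u = u, converged = converged,
                 iterations = as.integer(iterations), final_energy = e,
                 nonbinary_fraction = mean(u > 0.05 & u < 0.95),
                 rel_change = rel_change),
            class = "fins_indicator")
}

#' Discrete segmentation energy
#'
#' Evaluates \code{sum |grad u| + lambda * sum f * u} with isotropic TV on
#' forward differences and replicate (Neumann) boundary, the discrete form
#' of the relaxed two-phase segmentation energy.
#'
#' @param u Labelling matrix in \[0, 1\] (or a \code{"fins_indicator"}).
#' @param f A \code{"fins_fitting"} object or matrix.
#' @param lambda Fidelity weight.
#' @return The energy (a scalar).
#' @export
tv_energy <- function(u, f, lambda) {
  if (inherits(u, "fins_indicator")) u <- u$u
  if (inherits(f, "fins_fitting")) f <- f$f
  nr <- nrow(u); nc <- ncol(u)
  ux <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], rep(0, nr))
  uy <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], rep(0, nc))
  sum(sqrt(ux^2 + uy^2)) + lambda * sum(f * u)
}

#' Minimize the relaxed segmentation energy
#'
#' Computes the global minimiser of the convex relaxation
#' \deqn{\min_{u \in [0,1]} \int |\nabla u| \, dx + \lambda \int f(x)\,u(x)\, dx}
#' by Split Bregman iteration: per outer iteration one Gauss-Seidel sweep
#' for the \code{u}-subproblem (with clipping to \[0, 1\]), vector
#' shrinkage for the auxiliary gradient field, and a Bregman update.
#' The converged solution is approximately binary, so any threshold of it
#' in (0, 1) yields (the indicator of) a minimiser of the original binary
#' problem.
#'
#' @param f A [build_fitting_term()] result (finite everywhere).
#' @param params A [fins_params()] object (\code{lambda}, \code{mu},
#'   \code{tol}, \code{max_iter}).
#' @param init Starting point: \code{"threshold"} (the indicator of
#'   \code{f < 0}), \code{"zero"}, or a matrix in \[0, 1\].
#' @return A \code{"fins_indicator"}: the relaxed solution \code{u} plus
#'   \code{converged}, \code{iterations}, \code{final_energy} and the
#'   fraction of non-binary pixels (\code{u} in (0.05, 0.95)). Hitting
#'   \code{max_iter} is reported via \code{converged = FALSE}, not an
#'   error.
#' @export
minimize_energy <- function(f, params = fins_params(), init = "threshold") {
  stopifnot(inherits(f, "fins_fitting"), inherits(params, "fins_params"))
  if (any(!is.finite(f$f)))
    stop("fitting term contains non-finite values")
  u0 <- if (is.matrix(init)) {
    stopifnot(identical(dim(init), dim(f$f)), min(init) >= 0, max(init) <= 1)
    init
  } else if (identical(init, "zero")) {
    matrix(0, nrow(f$f), ncol(f$f))
  } else {
    (f$f < 0) * 1
  }
  fit <- sb_segment(f$f, u0, params$lambda, params$mu, params$tol,
                    params$max_iter)
  indicator_field(fit$u, converged = fit$converged,
                  iterations = fit$iterations, f = f,
                  lambda = params$lambda, rel_change = fit$rel_change)
}

#' Binarize the relaxed solution
#'
#' The nuclear foreground is the superlevel set \code{u* > beta}. Since the
#' relaxed solution is approximately binary, any \code{beta} in (0, 1)
#' gives essentially the same region; 0.5 is the default.
#'
#' @param u A \code{"fins_indicator"} or matrix in \[0, 1\].
#' @param beta Level in (0, 1).
#' @return Logical matrix (the foreground mask).
#' @export
binarize_solution <- function(u, beta = 0.5) {
  stopifnot(beta > 0, beta < 1)
  if (inherits(u, "fins_indicator")) u <- u$u
  u > beta
}

#' Label disconnected nuclei
#'
#' Connected-component labelling of the foreground mask. Components are
#' numbered 1..n in raster-scan order (row by row) of their first pixel;
#' an optional minimum-area filter discards small components (off by
#' default: small debris is tolerated and left to review).
#'
#' @param mask Logical matrix, the segmented foreground.
#' @param connectivity 4 or 8 (default 8).
#' @param min_area Minimum component size in pixels (default 0 = keep all).
#' @return Object of class \code{"fins_labels"}: \code{label_map} (integer
#'   matrix, 0 = background), \code{n}, and per-nucleus pixel counts
#'   \code{sizes}.
#' @export
label_nuclei <- function(mask, connectivity = 8, min_area = 0) {
  stopifnot(is.matrix(mask), is.logical(mask), connectivity %in% c(4, 8))
  lab <- label_components(mask, as.integer(connectivity))
  n <- attr(lab, "n")
  sizes <- if (n > 0) tabulate(lab[lab > 0], nbins = n) else integer()
  if (min_area > 0 && n > 0) {
    keep <- which(sizes >= min_area)
    remap <- integer(n)
    remap[keep] <- seq_along(keep)   # ascending old ids keep raster order
    fg <- lab > 0
    lab[fg] <- remap[lab[fg]]
    n <- length(keep)
    sizes <- sizes[keep]
  }
  attr(lab, "n") <- NULL
  structure(list(label_map = lab, n = n, sizes = sizes),
            class = "fins_labels")
}

#' Pixel indices of one nucleus
#'
#' @param labels A [label_nuclei()] result.
#' @param i Nucleus id in 1..n.
#' @return Integer vector of linear pixel indices of region i.
#' @export
region_pixels <- function(labels, i) {
  stopifnot(inherits(labels, "fins_labels"), i >= 1, i <= labels$n)
  which(labels$label_map == i)
}

#' Segment the counterstain channel
#'
#' Full nuclear-region pipeline on one counterstain image: Otsu threshold,
#' fitting term, TV energy minimization, binarization at \code{beta}, and
#' labelling of disconnected nuclei.
#'
#' @param z Counterstain [channel_image()].
#' @param params A [fins_params()].
#' @return List with \code{labels} ([label_nuclei()] result), the
#'   threshold \code{t_delta}, the relaxed solution \code{field}, and the
#'   binary \code{mask}.
#' @export
segment_nuclei <- function(z, params = fins_params()) {
  t_delta <- otsu_threshold(z)
  f <- build_fitting_term(z, t_delta)
  field <- minimize_energy(f, params)
  mask <- binarize_solution(field, params$beta)
  labels <- label_nuclei(mask, params$connectivity, params$min_area)
  list(labels = labels, t_delta = t_delta, field = field, mask = mask)
}
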