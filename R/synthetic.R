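#' Specify a synthetic multi-channel fluorescence field
#'
#' Describes a field of non-overlapping elliptical nuclei of heterogeneous
#' size on a dim autofluorescent background, with additive Gaussian noise,
#' optional moderate-contrast impulse speckle on the counterstain, optional
#' sub-threshold cell detritus, optionally border-cropped nuclei, and
#' per-marker punctate foci planted strictly inside a known subset of
#' nuclei. The rendered channels come with a ground truth (nucleus count,
#' label image, per-marker positive ids), so every pipeline stage can be
#' verified without external data.
#'
#' Default levels: nuclear foreground 0.75 over background 0.05 (so the
#' foreground-background separation far exceeds 3 standard deviations of
#' the default noise and an Otsu split is well posed); focus intensity 0.85
#' with enough focus area per positive nucleus (broad Ki67 regions, many
#' gamma-H2AX foci) that the marker Otsu threshold sits between the focus
#' and background modes — well above the 0.1 floor — across the whole
#' modelled noise range, rather than collapsing into the background mode
#' as it would for vanishingly sparse foreground. Speckle
#' impulses are drawn 0.35-0.45 above background: bright enough that plain
#' thresholding picks them up as spurious components, while a single-pixel
#' component's fidelity gain stays below its interface cost in the TV
#' energy, so the regularised segmentation removes them. Impulse speckle is
#' applied to the counterstain only, where it stresses segmentation; marker
#' channels carry Gaussian noise but no supra-threshold artefacts, so
#' ground-truth positivity stays well defined.
#'
#' @param height,width Field size in pixels.
#' @param n_nuclei Number of nuclei.
#' @param radius_range Min/max nuclear semi-major axis, pixels. The minor
#'   axis is 0.7-1.0 of the major axis, at random orientation.
#' @param intensity_nucleus Mean counterstain foreground level in (0, 1\];
#'   per-nucleus brightness varies by +/- 8\%.
#' @param background Mean background level (all channels).
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param speckle_rate Per-pixel probability of an impulse on the
#'   counterstain channel.
#' @param n_detritus Number of small dim debris objects (intensity
#'   0.12-0.25, below any sensible nuclear threshold).
#' @param border_fraction Fraction of nuclei centred within one radius of
#'   the image border (cropped by it).
#' @param marker_specs List of per-marker specs, each a list with
#'   \code{name}, \code{positive_fraction}, \code{n_foci},
#'   \code{focus_intensity}, \code{focus_radius}.
#' @param profile Radial intensity profile of a nucleus:
#'   \code{"cosine"} (default; flat core with a cosine taper to background,
#'   giving the solver realistic soft edges) or \code{"hard"} (piecewise
#'   constant).
#' @param seed RNG seed; identical specs give bit-identical fixtures.
#' @return An object of class \code{"fins_fixture_spec"}.
#' @export
fixture_spec <- function(height = 256, width = 256, n_nuclei = 12,
                         radius_range = c(7, 14), intensity_nucleus = 0.75,
                         background = 0.05, noise_sigma = 0.02,
                         speckle_rate = 5e-4, n_detritus = 2,
                         border_fraction = 0.1,
                         marker_specs = list(
                           list(name = "Ki67", positive_fraction = 0.4,
                                n_foci = 3, focus_intensity = 0.85,
                                focus_radius = 6),
                           list(name = "gH2AX", positive_fraction = 0.6,
                                n_foci = 8, focus_intensity = 0.85,
                                focus_radius = 3)),
                         profile = c("cosine", "hard"), seed = 1) {
  profile <- match.arg(profile)
  stopifnot(height >= 16, width >= 16, n_nuclei >= 0,
            length(radius_range) == 2, radius_range[1] > 2,
            radius_range[2] >= radius_range[1],
            intensity_nucleus > 0, intensity_nucleus <= 1,
            background >= 0, background < intensity_nucleus,
            noise_sigma >= 0, speckle_rate >= 0, speckle_rate <= 1,
            n_detritus >= 0, border_fraction >= 0, border_fraction <= 1)
  if (n_nuclei * pi * radius_range[2]^2 > 0.4 * height * width)
    stop("placement infeasible: total nucleus area exceeds 40% of the field")
  for (m in marker_specs)
    stopifnot(is.character(m$name), m$positive_fraction >= 0,
              m$positive_fraction <= 1, m$n_foci >= 1,
              m$focus_intensity > 0, m$focus_intensity <= 1,
              m$focus_radius > 0)
  structure(list(height = height, width = width, n_nuclei = n_nuclei,
                 radius_range = radius_range,
                 intensity_nucleus = intensity_nucleus,
                 background = background, noise_sigma = noise_sigma,
                 speckle_rate = speckle_rate, n_detritus = n_detritus,
                 border_fraction = border_fraction,
                 marker_specs = marker_specs, profile = profile,
                 seed = as.integer(seed)),
            class = "fins_fixture_spec")
}

# Radial profile on the normalized ellipse coordinate rho (1 = boundary).
radial_profile <- function(rho, profile, core = 0.7) {
  if (profile == "hard") return((rho <= 1) * 1)
  p <- numeric(length(rho))
  p[rho <= core] <- 1
  taper <- rho > core & rho <= 1
  p[taper] <- 0.5 * (1 + cos(pi * (rho[taper] - core) / (1 - core)))
  p
}

# Normalized squared ellipse coordinate of grid points around a center.
ellipse_rho2 <- function(rows, cols, cy, cx, a, b, theta) {
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2
}

#' Generate a synthetic fixture with ground truth
#'
#' Renders the channels described by a [fixture_spec()]: a counterstain
#' channel of non-overlapping elliptical nuclei plus background, noise,
#' speckle and detritus, and one channel per marker with punctate foci
#' strictly inside the nuclei chosen positive. Nucleus ids (and hence the
#' truth's positive-id sets) are numbered in raster-scan order of the first
#' nucleus pixel, matching the labelling convention of [label_nuclei()].
#'
#' @param spec A [fixture_spec()].
#' @return An object of class \code{"fins_fixture"}: \code{channels} (a
#'   named list of [channel_image()]s, counterstain \code{"DAPI"} first),
#'   \code{truth} (\code{n_nuclei}, \code{centers}, \code{axes},
#'   \code{angles}, \code{border_ids}, \code{positive_ids} per marker,
#'   noiseless \code{label_map}), \code{mapping} (a [channel_mapping()]
#'   matching the channel order), and the \code{spec}.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fins_fixture_spec"))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width; n <- spec$n_nuclei
  bg <- spec$background

  # --- placement: border nuclei first, then interior; rejection sampling
  n_border <- round(spec$border_fraction * n)
  cy <- cx <- aa <- bb <- th <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in seq_len(5000)) {
      a <- runif(1, spec$radius_range[1], spec$radius_range[2])
      b <- a * runif(1, 0.7, 1)
      ang <- runif(1, 0, pi)
      if (i <= n_border) {
        side <- sample.int(4, 1)
        d <- runif(1, 0.15 * a, 0.85 * a)   # centre within one radius of edge
        if (side == 1) { y <- d; x <- runif(1, a + 2, w - a - 2) }
        else if (side == 2) { y <- h - d; x <- runif(1, a + 2, w - a - 2) }
        else if (side == 3) { x <- d; y <- runif(1, a + 2, h - a - 2) }
        else { x <- w - d; y <- runif(1, a + 2, h - a - 2) }
      } else {
        y <- runif(1, a + 3, h - a - 3)
        x <- runif(1, a + 3, w - a - 3)
      }
      prev <- seq_len(i - 1)
      if (!length(prev) ||
          all(sqrt((cy[prev] - y)^2 + (cx[prev] - x)^2) > aa[prev] + a + 3)) {
        cy[i] <- y; cx[i] <- x; aa[i] <- a; bb[i] <- b; th[i] <- ang
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n, " non-overlapping nuclei; enlarge the field")
  }

  # --- relabel nuclei in raster-scan order of their first (noiseless) pixel
  label_map <- matrix(0L, h, w)
  rho2_of <- function(i) {
    rows <- max(1, floor(cy[i] - aa[i] - 1)):min(h, ceiling(cy[i] + aa[i] + 1))
    cols <- max(1, floor(cx[i] - aa[i] - 1)):min(w, ceiling(cx[i] + aa[i] + 1))
    list(rows = rows, cols = cols,
         rho2 = ellipse_rho2(rows, cols, cy[i], cx[i], aa[i], bb[i], th[i]))
  }
  geom <- lapply(seq_len(n), rho2_of)
  for (i in seq_len(n)) {
    g <- geom[[i]]
    inside <- g$rho2 <= 1
    label_map[g$rows, g$cols][inside] <- i
  }
  first_px <- vapply(seq_len(n), function(i) {
    hit <- which(t(label_map) == i)   # t(): row-major raster order
    if (length(hit)) min(hit) else .Machine$integer.max
  }, numeric(1))
  ord <- order(first_px)
  relab <- integer(n); relab[ord] <- seq_len(n)
  fg <- label_map > 0
  label_map[fg] <- relab[label_map[fg]]
  inv <- ord  # new id k corresponds to original nucleus inv[k]
  cy <- cy[inv]; cx <- cx[inv]; aa <- aa[inv]; bb <- bb[inv]; th <- th[inv]
  geom <- geom[inv]
  border_ids <- if (n_border > 0) sort(relab[seq_len(n_border)]) else integer()

  # --- counterstain channel
  dapi <- matrix(bg, h, w)
  brightness <- runif(n, 0.92, 1.08)
  for (i in seq_len(n)) {
    g <- geom[[i]]
    prof <- radial_profile(sqrt(g$rho2), spec$profile)
    lvl <- min(1, spec$intensity_nucleus * brightness[i])
    patch <- bg + (lvl - bg) * prof
    dapi[g$rows, g$cols] <- pmax(dapi[g$rows, g$cols], patch)
  }
  for (j in seq_len(spec$n_detritus)) {     # dim sub-threshold debris
    for (attempt in seq_len(200)) {
      r <- runif(1, 1.5, 3)
      y <- runif(1, r + 1, h - r - 1); x <- runif(1, r + 1, w - r - 1)
      d <- sqrt((cy - y)^2 + (cx - x)^2)
      if (!n || all(d > aa + r + 3)) break
    }
    rows <- max(1, floor(y - r - 1)):min(h, ceiling(y + r + 1))
    cols <- max(1, floor(x - r - 1)):min(w, ceiling(x + r + 1))
    rho2 <- ellipse_rho2(rows, cols, y, x, r, r, 0)
    lvl <- runif(1, 0.12, 0.25)
    dapi[rows, cols] <- pmax(dapi[rows, cols], bg + (lvl - bg) * (rho2 <= 1))
  }
  if (spec$noise_sigma > 0)
    dapi <- dapi + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
  if (spec$speckle_rate > 0) {
    hit <- which(runif(h * w) < spec$speckle_rate)
    dapi[hit] <- pmax(dapi[hit], bg + runif(length(hit), 0.35, 0.45))
  }
  dapi <- pmin(pmax(dapi, 0), 1)

  # --- marker channels
  positive_ids <- list()
  channels <- list(DAPI = channel_image(dapi, "counterstain", "DAPI"))
  for (m in spec$marker_specs) {
    n_pos <- round(m$positive_fraction * n)
    pos <- if (n_pos > 0) sort(sample.int(n, n_pos)) else integer()
    zm <- matrix(bg, h, w)
    for (i in pos) {
      fr0 <- min(m$focus_radius, 0.5 * bb[i])
      rho_max <- max(0.1, 1 - fr0 / bb[i] - 0.05)
      for (k in seq_len(m$n_foci)) {
        # keep the focus strictly inside the nucleus AND inside the image
        # (border-cropped nuclei get foci in their visible part, shrunk
        # near the image edge if needed)
        fy <- cy[i]; fx <- cx[i]; fr <- fr0
        for (attempt in seq_len(50)) {
          rho <- rho_max * sqrt(runif(1)); phi <- runif(1, 0, 2 * pi)
          ox <- rho * aa[i] * cos(phi); oy <- rho * bb[i] * sin(phi)
          y <- cy[i] + ox * sin(th[i]) + oy * cos(th[i])
          x <- cx[i] + ox * cos(th[i]) - oy * sin(th[i])
          r_eff <- min(fr0, y - 1, x - 1, h - y, w - x)
          if (r_eff >= 1) { fy <- y; fx <- x; fr <- r_eff; break }
        }
        fr <- max(1, min(fr, fy - 1, fx - 1, h - fy, w - fx))
        rows <- max(1, floor(fy - fr - 1)):min(h, ceiling(fy + fr + 1))
        cols <- max(1, floor(fx - fr - 1)):min(w, ceiling(fx + fr + 1))
        rho2 <- ellipse_rho2(rows, cols, fy, fx, fr, fr, 0)
        prof <- radial_profile(sqrt(rho2), "cosine", core = 0.5)
        zm[rows, cols] <- pmax(zm[rows, cols],
                               bg + (m$focus_intensity - bg) * prof)
      }
    }
    if (spec$noise_sigma > 0)
      zm <- zm + matrix(rnorm(h * w, 0, spec$noise_sigma), h, w)
    zm <- pmin(pmax(zm, 0), 1)
    channels[[m$name]] <- channel_image(zm, "marker", m$name)
    positive_ids[[m$name]] <- pos
  }

  mapping <- channel_mapping(
    counterstain = 1,
    markers = stats::setNames(seq_along(spec$marker_specs) + 1,
                              vapply(spec$marker_specs, `[[`, "", "name")))
  truth <- structure(list(n_nuclei = n, centers = cbind(y = cy, x = cx),
                          axes = cbind(a = aa, b = bb), angles = th,
                          border_ids = border_ids,
                          positive_ids = positive_ids,
                          label_map = label_map),
                     class = "fins_fixture_truth")
  structure(list(channels = channels, truth = truth, mapping = mapping,
                 spec = spec),
            class = "fins_fixture")
}

#' Generate a sweep of fixtures over noise levels
#'
#' Produces \code{reps} fixtures at each noise level, with seeds derived
#' from the base seed (\code{base$seed + index}, all distinct).
#'
#' @param base A [fixture_spec()] used as template.
#' @param noise_levels Numeric vector of \code{noise_sigma} values.
#' @param reps Replicates per level (>= 1).
#' @return List of \code{"fins_fixture"} objects of length
#'   \code{length(noise_levels) * reps}, each with \code{noise_sigma} and
#'   \code{seed} fields set.
#' @export
sweep_fixtures <- function(base, noise_levels, reps = 1) {
  stopifnot(inherits(base, "fins_fixture_spec"), reps >= 1,
            length(noise_levels) >= 1)
  idx <- 0
  out <- list()
  for (sigma in noise_levels) {
    for (r in seq_len(reps)) {
      idx <- idx + 1
      sp <- base
      sp$noise_sigma <- sigma
      sp$seed <- base$seed + idx
      out[[idx]] <- generate_fixture(sp)
    }
  }
  out
}

#' Write a fixture as TIFF plus truth sidecar
#'
#' Writes the channels as one multi-plane 16-bit grayscale TIFF (plane
#' order equals channel order: counterstain first, then markers) and the
#' ground truth as a JSON sidecar, for round-trip tests through the real
#' reader. 16-bit quantization bounds the round-trip error by 1/65535.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @param name Basename (without extension); files are
#'   \code{<name>.ome.tiff} and \code{<name>.truth.json}.
#' @return Named character vector with the \code{image} and \code{truth}
#'   paths.
#' @export
write_fixture <- function(fixture, dir, name = "fixture") {
  stopifnot(inherits(fixture, "fins_fixture"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  img_path <- file.path(dir, paste0(name, ".ome.tiff"))
  planes <- lapply(fixture$channels, function(ch) {
    m <- unclass(ch); attributes(m) <- list(dim = dim(m)); m
  })
  tiff::writeTIFF(planes, img_path, bits.per.sample = 16)
  truth_path <- file.path(dir, paste0(name, ".truth.json"))
  tr <- fixture$truth
  jsonlite::write_json(
    list(n_nuclei = tr$n_nuclei,
         centers = unname(apply(tr$centers, 1, as.numeric, simplify = FALSE)),
         positive_ids = tr$positive_ids,
         border_ids = tr$border_ids,
         channel_names = names(fixture$channels),
         counterstain_channel = fixture$mapping$counterstain,
         marker_channels = as.list(fixture$mapping$markers)),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(image = img_path, truth = truth_path)
}
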