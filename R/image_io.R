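#' Construct a normalized channel image
#'
#' A channel image is a 2D intensity field with every value in \[0, 1\],
#' carrying a role: either the nuclear counterstain used to delineate
#' nuclei, or a marker channel scored for per-nucleus positivity.
#'
#' @param z Numeric matrix with all values in \[0, 1\].
#' @param role \code{"counterstain"} or \code{"marker"}.
#' @param name Channel label, e.g. \code{"DAPI"}, \code{"Ki67"}.
#' @return An object of class \code{"fins_channel"}: the matrix \code{z}
#'   with \code{role} and \code{name} attributes.
#' @export
channel_image <- function(z, role = c("counterstain", "marker"), name = "") {
  role <- match.arg(role)
  stopifnot(is.matrix(z), is.numeric(z))
  if (anyNA(z) || min(z) < 0 || max(z) > 1)
    stop("channel intensities must be finite and within [0, 1]; use normalize_intensities()")
  structure(z, role = role, name = name, class = c("fins_channel", "matrix", "array"))
}

#' Normalize raw intensities to \[0, 1\]
#'
#' Integer data of bit depth \code{b} is divided by \code{2^b - 1} (full
#' dtype scale), so that a fixed absolute threshold such as the marker floor
#' keeps its meaning across images regardless of how much of the dynamic
#' range an individual image uses. Real-valued data already inside \[0, 1\]
#' passes through unchanged; real data outside \[0, 1\] is min-max rescaled.
#' The map is idempotent and monotone.
#'
#' @param raw Numeric matrix of non-negative intensities.
#' @param bit_depth Integer bit depth (8, 12, 16, ...) for integer-valued
#'   input. If \code{NULL} and \code{raw} is stored as integer, 8/16/32 is
#'   inferred from the maximum; real-valued input needs no bit depth.
#' @param role,name Passed to [channel_image()].
#' @return A [channel_image()].
#' @export
#' @examples
#' normalize_intensities(matrix(c(0L, 128L, 255L, 255L), 2), bit_depth = 8)
normalize_intensities <- function(raw, bit_depth = NULL,
                                  role = "counterstain", name = "") {
  stopifnot(is.matrix(raw), is.numeric(raw))
  if (anyNA(raw) || any(!is.finite(raw)))
    stop("raw image contains missing or non-finite intensities")
  if (min(raw) < 0)
    stop("negative intensities are not a valid fluorescence signal")
  integral <- is.integer(raw) || !is.null(bit_depth)
  if (integral) {
    if (is.null(bit_depth)) {
      mx <- max(raw)
      bit_depth <- if (mx <= 255) 8L else if (mx <= 65535) 16L else 32L
    }
    full <- 2^bit_depth - 1
    if (max(raw) > full)
      stop("intensities exceed the declared bit depth")
    z <- unclass(raw) / full
    storage.mode(z) <- "double"
  } else if (max(raw) <= 1) {
    z <- raw                       # already normalized; identity
  } else {
    rng <- range(raw)
    z <- (raw - rng[1]) / (rng[2] - rng[1])
  }
  channel_image(z, role = role, name = name)
}

#' Read a multi-channel TIFF and map planes to channels
#'
#' Reads a multi-plane (grayscale) TIFF or OME-TIFF, checks that all mapped
#' planes exist and share one shape, and returns normalized channel images:
#' the counterstain first, then the marker channels in mapping order.
#' Integer pixel data is scaled by dtype full range (see
#' [normalize_intensities()]).
#'
#' @param path Path to a \code{.tif}/\code{.tiff} file.
#' @param mapping A [channel_mapping()].
#' @return List of [channel_image()] objects, counterstain first.
#' @export
read_multichannel <- function(path, mapping) {
  stopifnot(inherits(mapping, "fins_mapping"))
  if (!file.exists(path))
    stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "lif")
    stop("LIF container not supported (", path,
         "); export the acquisition to TIFF first")
  if (!ext %in% c("tif", "tiff"))
    stop("unsupported image container '", ext, "': ", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  planes <- lapply(planes, function(p) {
    if (length(dim(p)) == 3) {
      if (dim(p)[3] == 1) p <- p[, , 1]
      else stop("expected grayscale planes, got a ", dim(p)[3],
                "-sample plane: ", path)
    }
    p
  })
  idx <- c(mapping$counterstain, mapping$markers)
  if (max(idx) > length(planes))
    stop("channel index out of range: requested plane ", max(idx),
         " but ", path, " has ", length(planes))
  shp <- dim(planes[[idx[1]]])
  if (!all(vapply(planes[idx], function(p) identical(dim(p), shp), logical(1))))
    stop("planes of unequal shape in ", path)
  out <- vector("list", length(idx))
  out[[1]] <- channel_image(planes[[mapping$counterstain]],
                            role = "counterstain", name = "DAPI")
  for (k in seq_along(mapping$markers))
    out[[k + 1]] <- channel_image(planes[[mapping$markers[k]]],
                                  role = "marker",
                                  name = names(mapping$markers)[k])
  names(out) <- vapply(out, attr, "", "name")
  out
}

#' Write the batch counts CSV
#'
#' Writes one row per image with the DAPI nucleus count and each marker's
#' positive count, to a file named \code{fins_counts_<timestamp>.csv} with
#' an ISO-8601 (basic format) timestamp.
#'
#' @param records A data frame of counts (as returned by
#'   \code{as.data.frame} on [fins()] results, row-bound), or a list of
#'   \code{fins} objects.
#' @param out_dir Output directory (created if needed).
#' @param timestamp A \code{POSIXct} used in the filename; defaults to now.
#' @return The path of the written file, invisibly a character scalar.
#' @export
write_counts_csv <- function(records, out_dir, timestamp = Sys.time()) {
  if (is.list(records) && !is.data.frame(records))
    records <- do.call(rbind, lapply(records, as.data.frame))
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stamp <- format(timestamp, "%Y%m%dT%H%M%S")
  path <- file.path(out_dir, paste0("fins_counts_", stamp, ".csv"))
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  path
}

# Boundary pixels of the given label ids: region pixels with a 4-neighbour
# outside the region. Returns a logical matrix.
region_boundary <- function(label_map, ids) {
  inr <- matrix(label_map %in% ids, nrow(label_map), ncol(label_map))
  nr <- nrow(inr); nc <- ncol(inr)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, nr, nc)
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  }
  interior <- pad(inr, 1, 0) & pad(inr, -1, 0) & pad(inr, 0, 1) & pad(inr, 0, -1)
  inr & !interior
}

# Compose the review overlay as an RGB array: white nuclear regions on
# black, one contour colour per marker around positive nuclei.
overlay_array <- function(labels, positives = list()) {
  lm <- labels$label_map
  base <- (lm > 0) * 1
  arr <- array(base, dim = c(nrow(lm), ncol(lm), 3))
  cols <- grDevices::col2rgb(c("red", "green", "blue", "magenta", "cyan")) / 255
  for (k in seq_along(positives)) {
    ids <- positives[[k]]
    if (!length(ids)) next
    b <- region_boundary(lm, ids)
    col <- cols[, ((k - 1) %% ncol(cols)) + 1]
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[b] <- col[ch]
      arr[, , ch] <- plane
    }
  }
  arr
}

#' Render a review overlay image
#'
#' Writes a PNG showing the segmented nuclear regions as white-on-black,
#' with a coloured contour drawn around every nucleus scored positive for
#' each marker (red for the first marker, green for the second, then blue,
#' magenta, cyan). This is the static equivalent of reviewing counts in an
#' interactive viewer.
#'
#' @param channels List of channel images of the acquisition (used for the
#'   shape check; the overlay itself shows the segmentation).
#' @param labels A [label_nuclei()] result.
#' @param positives Named list (one element per marker) of positive nucleus
#'   label ids.
#' @param out_path Output PNG path.
#' @return \code{out_path}, invisibly.
#' @export
render_overlay <- function(channels, labels, positives, out_path) {
  shp <- dim(labels$label_map)
  for (ch in channels)
    if (!identical(dim(ch)[1:2], shp))
      stop("channel and label shapes differ")
  arr <- overlay_array(labels, positives)
  png::writePNG(arr, out_path)
  invisible(out_path)
}
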