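# Background subtraction and per-channel thresholding. The segmentation
# contract mirrors the standard ImageJ-style workflow: Gaussian-blur
# background estimate, Otsu threshold per channel, then a monomer floor so
# diffuse non-pathological signal is excluded, then a small-object filter.

# cache of boundary-reflecting blur matrices keyed by (n, sigma, radius)
.blur_cache <- new.env(parent = emptyenv())

gaussian_kernel_1d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

blur_matrix <- function(n, sigma) {
  key <- sprintf("%d_%.8g", n, sigma)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  B <- matrix(0, n, n)
  i <- seq_len(n)
  for (d in (-r):r) {
    j <- reflect_index(i + d, n)
    idx <- cbind(i, j)
    B[idx] <- B[idx] + k[d + r + 1L]
  }
  .blur_cache[[key]] <- B
  B
}

#' Separable Gaussian blur with symmetric boundary reflection
#'
#' Truncated discrete Gaussian (radius `ceiling(4*sigma)`), applied along
#' rows then columns via cached convolution matrices.
#'
#' @param x numeric matrix.
#' @param sigma standard deviation in pixels (> 0).
#' @return blurred matrix, same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  check_matrix(x, "x")
  check_scalar_num(sigma, "sigma", positive = TRUE)
  Br <- blur_matrix(nrow(x), sigma)
  Bc <- blur_matrix(ncol(x), sigma)
  Br %*% x %*% t(Bc)
}

#' Gaussian-blur background subtraction
#'
#' Returns `x - GaussianBlur(x, sigma)` clipped below at zero; the blur is
#' the background estimate, so `sigma` must be large relative to the
#' objects to preserve.
#'
#' @param channel numeric matrix of intensities (finite).
#' @param sigma blur sigma in pixels.
#' @return background-subtracted matrix, same shape, non-negative.
#' @export
subtract_background <- function(channel, sigma) {
  check_matrix(channel, "channel")
  if (!all(is.finite(channel))) stop_lq("non-finite pixels in channel")
  pmax(channel - gaussian_blur(channel, sigma), 0)
}

#' Otsu threshold of an intensity image
#'
#' Histogram of `n_bins` equal-width bins over the observed range; returns
#' the bin edge maximising between-class variance. Foreground is defined as
#' pixels strictly greater than the threshold; ties resolve to the smallest
#' qualifying threshold.
#'
#' @param channel numeric matrix or vector with at least two distinct
#'   values (a constant image has no defined threshold and errors).
#' @param n_bins number of histogram bins.
#' @return threshold intensity (scalar).
#' @export
otsu_threshold <- function(channel, n_bins = 256L) {
  v <- as.numeric(channel)
  if (!all(is.finite(v))) stop_lq("non-finite pixels in channel")
  rng <- range(v)
  if (rng[1L] == rng[2L]) stop_lq("constant image: Otsu threshold undefined")
  n_bins <- as.integer(n_bins)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  # between-class variance via cumulative first moments over bin centers
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  W <- cumsum(counts)
  M <- cumsum(counts * centers)
  tot_w <- W[n_bins]; tot_m <- M[n_bins]
  t_idx <- seq_len(n_bins - 1L)
  w0 <- W[t_idx]; w1 <- tot_w - w0
  bcv <- ifelse(w0 > 0 & w1 > 0,
                (M[t_idx] * tot_w - tot_m * w0)^2 / (w0 * w1),
                -Inf)
  edges[which.max(bcv) + 1L]   # which.max takes the first (smallest) maximiser
}

#' Segment one epitope channel
#'
#' Pipeline: [subtract_background()] -> [otsu_threshold()] -> raise the
#' threshold to the monomer floor -> binarise (strictly greater) -> drop
#' connected components smaller than `min_object_px`. In
#' `"quantile_of_background"` mode the floor is the configured quantile
#' (default 0.999) of background-subtracted intensities outside the Otsu
#' foreground. A channel that is constant after background subtraction
#' (e.g. pure monomer background, noise-free) yields an empty mask rather
#' than an error.
#'
#' @param channel numeric intensity matrix.
#' @param config an [analysis_config()].
#' @param epitope label recorded on the mask.
#' @param region_mask optional logical matrix; thresholds are computed and
#'   applied within the region only.
#' @return object of class `channel_mask` with fields `epitope`, `mask`,
#'   `otsu_threshold`, `floor_applied`, `threshold` (the effective maximum
#'   of the two), `n_foreground_px`, and `n_removed_objects`.
#' @export
segment_channel <- function(channel, config = analysis_config(),
                            epitope = NA_character_, region_mask = NULL) {
  check_matrix(channel, "channel")
  bg <- subtract_background(channel, config$blur_sigma_px)
  sel <- if (is.null(region_mask)) rep(TRUE, length(bg)) else as.vector(region_mask)
  vals <- bg[sel]
  # effectively constant after background subtraction (e.g. pure monomer
  # background): nothing to segment; 1e-8 absorbs blur round-off
  if (diff(range(vals)) <= 1e-8) {
    mask <- matrix(FALSE, nrow(channel), ncol(channel))
    return(new_channel_mask(epitope, mask, otsu = NA_real_, floor = NA_real_,
                            removed = 0L))
  }
  otsu <- otsu_threshold(vals, config$n_bins)
  floor_val <- if (config$monomer_floor_mode == "absolute") {
    config$monomer_floor_value
  } else {
    bgpx <- vals[vals <= otsu]
    if (length(bgpx)) stats::quantile(bgpx, config$monomer_floor_value, names = FALSE)
    else otsu
  }
  thr <- max(otsu, floor_val)
  mask <- bg > thr
  if (!is.null(region_mask)) mask <- mask & region_mask
  removed <- 0L
  if (config$min_object_px > 1L && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    drop <- which(sizes < config$min_object_px)
    if (length(drop)) {
      mask[lab %in% drop] <- FALSE
      removed <- length(drop)
    }
  }
  new_channel_mask(epitope, mask, otsu = otsu, floor = floor_val,
                   removed = removed)
}

new_channel_mask <- function(epitope, mask, otsu, floor, removed) {
  structure(list(epitope = epitope, mask = mask,
                 otsu_threshold = otsu, floor_applied = floor,
                 threshold = suppressWarnings(max(otsu, floor, na.rm = TRUE)),
                 n_foreground_px = sum(mask),
                 n_removed_objects = removed),
            class = "channel_mask")
}

#' @export
print.channel_mask <- function(x, ...) {
  cat(sprintf("<channel_mask> %s: %d foreground px (otsu=%.4g, floor=%.4g, removed=%d)\n",
              x$epitope, x$n_foreground_px, x$otsu_threshold, x$floor_applied,
              x$n_removed_objects))
  invisible(x)
}

#' Segment every epitope channel of a multiplex image
#'
#' @param image a [multiplex_image()].
#' @param config an [analysis_config()].
#' @return named list of `channel_mask`, one per epitope.
#' @export
segment_image <- function(image, config = analysis_config()) {
  stopifnot(inherits(image, "multiplex_image"))
  stats::setNames(lapply(names(image$channels), function(ep) {
    segment_channel(image$channels[[ep]], config, epitope = ep,
                    region_mask = image$region_mask)
  }), names(image$channels))
}
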