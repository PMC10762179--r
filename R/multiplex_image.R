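# MultiplexImage: the package's central container. One co-registered 2-D
# intensity array per epitope antibody, plus pixel size and an optional
# region-of-interest mask delimiting the area quantified.

#' Construct a multiplex image
#'
#' @param channels named list of numeric matrices (one per epitope label),
#'   all of identical dimensions, finite and non-negative, in arbitrary
#'   fluorescence units.
#' @param pixel_size_um pixel edge length in micrometres (> 0). Areas in
#'   um^2 are derived as `px * pixel_size_um^2`.
#' @param region_mask optional logical matrix of the same shape marking the
#'   region quantified (pathology load denominator); `NULL` means the whole
#'   image.
#' @param case_id,region_label free-text identifiers carried into reports.
#' @return object of class `multiplex_image`.
#' @export
multiplex_image <- function(channels, pixel_size_um, region_mask = NULL,
                            case_id = NA_character_, region_label = NA_character_) {
  if (!is.list(channels) || !length(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_lq("`channels` must be a non-empty named list of matrices")
  dims <- lapply(channels, function(ch) {
    check_matrix(ch, "channel")
    if (!all(is.finite(ch))) stop_lq("channel intensities must be finite")
    if (any(ch < 0)) stop_lq("channel intensities must be >= 0")
    dim(ch)
  })
  d0 <- dims[[1L]]
  if (!all(vapply(dims, function(d) identical(d, d0), TRUE)))
    stop_lq("all channels must share one shape")
  check_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  if (!is.null(region_mask)) {
    check_matrix(region_mask, "region_mask")
    if (!identical(dim(region_mask), d0))
      stop_lq("`region_mask` must share the channel shape")
    region_mask <- region_mask & TRUE
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um,
                 region_mask = region_mask, case_id = case_id,
                 region_label = region_label),
            class = "multiplex_image")
}

#' @export
print.multiplex_image <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<multiplex_image> %d x %d px (%.3g um/px), channels: %s\n",
              d[1L], d[2L], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  if (!is.na(x$case_id)) cat("  case:", x$case_id, " region:", x$region_label, "\n")
  invisible(x)
}

#' @export
dim.multiplex_image <- function(x) dim(x$channels[[1L]])

#' Epitope labels of a multiplex image
#' @param image a `multiplex_image`.
#' @return character vector.
#' @export
epitopes <- function(image) names(image$channels)
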