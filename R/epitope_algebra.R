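# Epitope-unique / overlap area algebra: the core decomposition of total
# aggregate immunolabelling. Definitions follow the subtraction form used
# in the source workflow -- unique(e) = total - area(union of the others);
# overlap = total - sum of uniques -- which are provably equivalent to the
# per-pixel set definitions (unique = labelled by e only; overlap =
# coverage >= 2). Both forms are exposed so tests can assert the identity.

mask_list <- function(masks) {
  if (inherits(masks, "channel_mask")) masks <- list(masks)
  out <- lapply(masks, as_mask_matrix)
  if (!length(out)) stop_lq("need at least one mask")
  d0 <- dim(out[[1L]])
  for (m in out) if (!identical(dim(m), d0)) stop_lq("masks are not co-registered")
  out
}

mask_union <- function(ms) Reduce(`|`, ms)

#' Total immunolabelling area (union of all epitope masks)
#'
#' @param masks named list of `channel_mask` objects or logical matrices,
#'   co-registered.
#' @return pixel count of the union.
#' @export
total_area <- function(masks) sum(mask_union(mask_list(masks)))

#' Epitope-unique immunolabelling area
#'
#' `total - area(union of the other masks)`: pixels labelled by this
#' epitope and no other.
#'
#' @param masks named list of masks.
#' @param epitope label to isolate (must name an element of `masks`).
#' @return pixel count.
#' @export
unique_area <- function(masks, epitope) {
  ms <- mask_list(masks)
  if (!epitope %in% names(masks)) stop_lq("unknown epitope label: ", epitope)
  others <- ms[names(masks) != epitope]
  tot <- sum(mask_union(ms))
  if (!length(others)) return(tot)
  tot - sum(mask_union(others))
}

#' Net overlapping immunolabelling area
#'
#' `total - sum of unique areas`: pixels covered by at least two masks.
#'
#' @param masks named list of masks.
#' @return pixel count.
#' @export
overlap_area <- function(masks) {
  ms <- mask_list(masks)
  labs <- names(masks)
  if (is.null(labs)) stop_lq("masks must be named by epitope")
  tot <- sum(mask_union(ms))
  uniq <- vapply(labs, function(e) {
    others <- ms[labs != e]
    if (!length(others)) tot else tot - sum(mask_union(others))
  }, 0L)
  tot - sum(uniq)
}

#' Assemble the full epitope-area report
#'
#' Areas in pixels and um^2, percentages of the total immunolabelling
#' area, and pathology load (total immunolabelling area as a percentage of
#' the region quantified). When the total area is zero the percentages are
#' undefined (`NA`, flagged via `percent_defined = FALSE`) and the load
#' is 0.
#'
#' @param masks named list of masks (one per epitope).
#' @param region_mask logical matrix delimiting the region quantified;
#'   `NULL` means the whole image. Mask foreground outside the region is
#'   clipped (with a message).
#' @param pixel_size_um pixel size for um^2 conversion.
#' @param case_id,region_label identifiers carried into the report.
#' @return object of class `epitope_area_report`.
#' @export
epitope_report <- function(masks, region_mask = NULL, pixel_size_um = 1,
                           case_id = NA_character_, region_label = NA_character_) {
  ms <- mask_list(masks)
  labs <- names(masks)
  if (is.null(labs) || any(!nzchar(labs))) stop_lq("masks must be named by epitope")
  check_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  d <- dim(ms[[1L]])
  if (is.null(region_mask)) {
    region_mask <- matrix(TRUE, d[1L], d[2L])
  } else {
    check_matrix(region_mask, "region_mask")
    if (!identical(dim(region_mask), d)) stop_lq("region_mask shape mismatch")
  }
  region_area <- sum(region_mask)
  if (region_area == 0L) stop_lq("zero region area")
  clipped <- vapply(ms, function(m) sum(m & !region_mask), 0L)
  if (any(clipped > 0L)) {
    message("clipping ", sum(clipped), " foreground px outside the region mask")
    ms <- lapply(ms, function(m) m & region_mask)
  }
  tot <- sum(mask_union(ms))
  uniq <- vapply(labs, function(e) {
    others <- ms[labs != e]
    if (!length(others)) tot else tot - sum(mask_union(others))
  }, 0L)
  ovl <- tot - sum(uniq)
  px2 <- pixel_size_um^2
  defined <- tot > 0L
  pct <- function(a) if (defined) 100 * a / tot else NA_real_
  structure(list(
    case_id = case_id, region_label = region_label,
    epitopes = labs,
    total_area_px = tot, total_area_um2 = tot * px2,
    unique_area_px = uniq, unique_area_um2 = uniq * px2,
    overlap_area_px = ovl, overlap_area_um2 = ovl * px2,
    unique_pct = vapply(uniq, pct, 0), overlap_pct = pct(ovl),
    region_area_px = region_area,
    pathology_load_pct = 100 * tot / region_area,
    percent_defined = defined,
    pixel_size_um = pixel_size_um
  ), class = "epitope_area_report")
}

#' Per-aggregate epitope composition
#'
#' [epitope_report()] restricted to one aggregate's pixel footprint: the
#' per-aggregate percentage decomposition (e.g. an object covered only by
#' the pS129 mask reports unique_pS129 = 100%).
#'
#' @param obj an `aggregate_object` from [label_aggregates()], or an
#'   integer vector of pixel indices.
#' @param masks named list of masks.
#' @param pixel_size_um pixel size.
#' @return `epitope_area_report` whose region is the object footprint.
#' @export
aggregate_composition <- function(obj, masks, pixel_size_um = 1) {
  px <- if (inherits(obj, "aggregate_object")) obj$pixel_idx else as.integer(obj)
  ms <- mask_list(masks)
  d <- dim(ms[[1L]])
  foot <- matrix(FALSE, d[1L], d[2L])
  foot[px] <- TRUE
  clipped <- lapply(ms, function(m) m & foot)
  names(clipped) <- names(masks)
  epitope_report(clipped, region_mask = foot, pixel_size_um = pixel_size_um)
}

#' @export
print.epitope_area_report <- function(x, ...) {
  cat(sprintf("<epitope_area_report> total %d px (%.4g um2), load %.3g%%\n",
              x$total_area_px, x$total_area_um2, x$pathology_load_pct))
  if (x$percent_defined) {
    for (e in x$epitopes)
      cat(sprintf("  unique %-6s %6.2f%%\n", e, x$unique_pct[[e]]))
    cat(sprintf("  overlap       %6.2f%%\n", x$overlap_pct))
  } else cat("  percentages undefined (empty total)\n")
  invisible(x)
}

#' @export
as.data.frame.epitope_area_report <- function(x, ...) {
  row <- data.frame(case_id = x$case_id, region = x$region_label,
                    region_area_px = x$region_area_px,
                    total_area_px = x$total_area_px,
                    total_area_um2 = x$total_area_um2,
                    stringsAsFactors = FALSE)
  for (e in x$epitopes) row[[paste0("unique_", e, "_pct")]] <- x$unique_pct[[e]]
  row$overlap_pct <- x$overlap_pct
  row$pathology_load_pct <- x$pathology_load_pct
  row
}
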