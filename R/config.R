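# Analysis configuration: every tunable of the segmentation, algebra,
# morphometry and statistics stages lives here so whole runs are
# reproducible from a single JSON file.

#' Default epitope panel
#'
#' Canonical channel labels for the three-antibody alpha-synuclein panel:
#' N-terminus (residues 34-45), pS129, and C-terminus (residues 118-123).
#' The pipeline generalises to any k >= 2 labels; these are the defaults.
#'
#' @return character vector of epitope labels.
#' @export
default_epitopes <- function() c("Nterm", "pS129", "Cterm")

#' Build a validated analysis configuration
#'
#' @param channel_map named integer vector mapping epitope label -> 1-based
#'   channel index in the image file. Default maps the canonical panel to
#'   channels 1:3.
#' @param blur_sigma_px Gaussian background-blur sigma in pixels. The
#'   operation is stated by the source workflow without a value; 20 px is
#'   the package default and must exceed the radius of the largest object
#'   to be preserved.
#' @param monomer_floor_mode `"quantile_of_background"` (default) raises the
#'   Otsu threshold to a high quantile of the non-foreground background so
#'   diffuse monomeric alpha-synuclein is excluded; `"absolute"` uses
#'   `monomer_floor_value` as an intensity floor directly.
#' @param monomer_floor_value quantile (in (0,1), default 0.999) or absolute
#'   intensity depending on `monomer_floor_mode`.
#' @param min_object_px connected components smaller than this are removed
#'   (automated substitute for manual segmentation confirmation).
#' @param n_bins histogram bins for Otsu thresholding.
#' @param morphology list of classification thresholds, see
#'   [classify_morphology()].
#' @param alpha significance level for the statistics layer.
#' @param pixel_size_um fallback pixel size when image metadata carries none.
#' @param pk_mode PK time-course quantity: `"intensity"` (integrated
#'   background-subtracted intensity in the pre-treatment footprint) or
#'   `"area"` (thresholded area).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(channel_map = stats::setNames(1:3, default_epitopes()),
                            blur_sigma_px = 20,
                            monomer_floor_mode = c("quantile_of_background", "absolute"),
                            monomer_floor_value = 0.999,
                            min_object_px = 5L,
                            n_bins = 256L,
                            morphology = morphology_rules(),
                            alpha = 0.05,
                            pixel_size_um = NULL,
                            pk_mode = c("intensity", "area")) {
  monomer_floor_mode <- match.arg(monomer_floor_mode)
  pk_mode <- match.arg(pk_mode)
  if (is.null(names(channel_map)) || anyDuplicated(names(channel_map)) ||
      anyDuplicated(channel_map))
    stop_lq("`channel_map` must map exactly one channel per epitope label")
  check_scalar_num(blur_sigma_px, "blur_sigma_px", positive = TRUE)
  check_scalar_num(monomer_floor_value, "monomer_floor_value", nonneg = TRUE)
  if (monomer_floor_mode == "quantile_of_background" &&
      (monomer_floor_value <= 0 || monomer_floor_value >= 1))
    stop_lq("quantile `monomer_floor_value` must lie in (0,1)")
  check_scalar_num(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_lq("`alpha` must lie in (0,1)")
  check_scalar_num(min_object_px, "min_object_px", nonneg = TRUE)
  check_scalar_num(n_bins, "n_bins", positive = TRUE)
  if (!is.null(pixel_size_um)) check_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  structure(list(
    channel_map = channel_map,
    blur_sigma_px = blur_sigma_px,
    monomer_floor_mode = monomer_floor_mode,
    monomer_floor_value = monomer_floor_value,
    min_object_px = as.integer(min_object_px),
    n_bins = as.integer(n_bins),
    morphology = morphology,
    alpha = alpha,
    pixel_size_um = pixel_size_um,
    pk_mode = pk_mode
  ), class = "analysis_config")
}

#' Morphology classification thresholds
#'
#' Numeric rules for assigning aggregate classes; the source workflow gives
#' no numeric criteria (assignment was confirmed manually) so these are
#' declared package defaults, all configurable.
#'
#' @param c_min minimum circularity for a Lewy body.
#' @param a_max maximum moment aspect ratio for a Lewy body.
#' @param a_min_ln minimum aspect ratio for a Lewy neurite.
#' @param s_min minimum elongation (Feret^2 / area) for a Lewy neurite; a
#'   skeleton length/width proxy that catches strongly curved neurites.
#' @param punctate_max_um puncta upper equivalent-diameter bound in um.
#' @param punctate_a_max maximum aspect ratio for a punctum.
#' @return named list of rules.
#' @export
morphology_rules <- function(c_min = 0.6, a_max = 2.0, a_min_ln = 3.0,
                             s_min = 6.0, punctate_max_um = 2.5,
                             punctate_a_max = 2.0) {
  list(c_min = c_min, a_max = a_max, a_min_ln = a_min_ln, s_min = s_min,
       punctate_max_um = punctate_max_um, punctate_a_max = punctate_a_max)
}

#' Read an analysis configuration from JSON
#'
#' Unknown keys are rejected; missing keys take package defaults. The
#' `channel_map` entry may be either a named list of indices or a compact
#' string `"1=Nterm,2=pS129,3=Cterm"`.
#'
#' @param path JSON file.
#' @return `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop_lq("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), c(known, "morphology"))
  if (length(bad)) stop_lq("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$channel_map) && is.character(raw$channel_map) &&
      length(raw$channel_map) == 1L)
    raw$channel_map <- parse_channel_map(raw$channel_map)
  if (!is.null(raw$channel_map) && is.list(raw$channel_map))
    raw$channel_map <- unlist(raw$channel_map)
  if (!is.null(raw$morphology)) raw$morphology <- do.call(morphology_rules, as.list(raw$morphology))
  do.call(analysis_config, raw)
}

#' Parse a compact channel-map string
#'
#' @param s string like `"1=Nterm,2=pS129,3=Cterm"` (1-based indices).
#' @return named integer vector, epitope label -> channel index.
#' @export
parse_channel_map <- function(s) {
  parts <- strsplit(trimws(strsplit(s, ",")[[1]]), "=", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop_lq("malformed channel map string: ", s)
  idx <- as.integer(vapply(parts, `[`, "", 1L))
  lab <- vapply(parts, `[`, "", 2L)
  if (anyNA(idx)) stop_lq("malformed channel map string: ", s)
  stats::setNames(idx, lab)
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat("  channels:", paste(sprintf("%s=%d", names(x$channel_map), x$channel_map),
                           collapse = ", "), "\n")
  cat(sprintf("  blur_sigma_px=%g  floor=%s(%g)  min_object_px=%d  n_bins=%d\n",
              x$blur_sigma_px, x$monomer_floor_mode, x$monomer_floor_value,
              x$min_object_px, x$n_bins))
  cat(sprintf("  alpha=%g  pk_mode=%s\n", x$alpha, x$pk_mode))
  invisible(x)
}
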