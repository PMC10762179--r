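# High-level image and report IO: OME-TIFF in/out for multiplex images,
# CSV reports, scene export with ground-truth label images.

#' Read a multi-channel OME-TIFF / TIFF as a multiplex image
#'
#' Channel naming precedence: an explicit `channel_map` wins; otherwise
#' OME-XML channel names are used. Pixel size precedence: OME-XML
#' `PhysicalSizeX`, then `pixel_size_um`, then `config$pixel_size_um`; if
#' all are missing the read fails.
#'
#' @param path TIFF or OME-TIFF file (one grayscale page per channel).
#' @param channel_map named integer vector (epitope label -> 1-based page
#'   index) or a compact string `"1=Nterm,2=pS129,3=Cterm"`; `NULL` to rely
#'   on OME metadata.
#' @param pixel_size_um fallback pixel size in um.
#' @param config optional [analysis_config()] supplying fallbacks.
#' @param case_id,region_label identifiers attached to the image.
#' @return a [multiplex_image()].
#' @export
read_multiplex <- function(path, channel_map = NULL, pixel_size_um = NULL,
                           config = NULL, case_id = NA_character_,
                           region_label = NA_character_) {
  tf <- read_tiff(path)
  ome <- parse_ome_xml(tf$description)
  n <- length(tf$pages)
  if (is.character(channel_map) && length(channel_map) == 1L)
    channel_map <- parse_channel_map(channel_map)
  if (is.null(channel_map)) {
    if (is.null(ome$channel_names))
      stop_lq("no channel_map given and no OME channel names in ", path)
    if (length(ome$channel_names) != n)
      stop_lq("OME metadata names ", length(ome$channel_names),
              " channels but file has ", n, " pages")
    channel_map <- stats::setNames(seq_len(n), ome$channel_names)
  }
  if (any(channel_map < 1L) || any(channel_map > n))
    stop_lq("channel_map references channel ", max(channel_map),
            " of a ", n, "-channel file")
  px <- ome$pixel_size_um %||% pixel_size_um %||% config$pixel_size_um
  if (is.null(px))
    stop_lq("pixel size missing from metadata and no fallback configured")
  channels <- stats::setNames(lapply(channel_map, function(i) tf$pages[[i]]),
                              names(channel_map))
  multiplex_image(channels, pixel_size_um = px, case_id = case_id,
                  region_label = region_label)
}

#' Write a multiplex image as OME-TIFF
#'
#' One 16-bit page per channel (intensities quantised on export), channel
#' names and physical pixel size recorded in OME-XML.
#'
#' @param image a [multiplex_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(image, path) {
  stopifnot(inherits(image, "multiplex_image"))
  d <- dim(image)
  xml <- build_ome_xml(names(image$channels), d[1L], d[2L], image$pixel_size_um)
  write_tiff(path, image$channels, description = xml)
}

#' Write epitope-area reports to CSV
#'
#' One row per (case, region). Stable column set: `case_id`, `region`,
#' `region_area_px`, `total_area_px`, `total_area_um2`, one
#' `unique_<epitope>_pct` per epitope, `overlap_pct`, `pathology_load_pct`.
#' Percentages are rounded to 2 decimals in the file; areas keep full
#' precision.
#'
#' @param reports a single `epitope_area_report` or a list of them; an
#'   empty list yields a header-only CSV for the default panel.
#' @param path output CSV.
#' @return the written data frame, invisibly.
#' @export
write_report <- function(reports, path) {
  if (inherits(reports, "epitope_area_report")) reports <- list(reports)
  if (length(reports)) {
    df <- do.call(rbind, lapply(reports, as.data.frame))
  } else {
    labs <- default_epitopes()
    cols <- c("case_id", "region", "region_area_px", "total_area_px",
              "total_area_um2", paste0("unique_", labs, "_pct"),
              "overlap_pct", "pathology_load_pct")
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  pct <- grep("_pct$", names(df))
  df[pct] <- lapply(df[pct], function(v) round(as.numeric(v), 2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a rendered scene with its ground truth
#'
#' Writes the multiplex image as OME-TIFF, one ground-truth label TIFF per
#' epitope (pixel value = aggregate id, 0 = background), and a CSV manifest
#' of per-aggregate kind, size and epitope composition.
#'
#' @param scene list with `image` and `ground_truth` as returned by
#'   [render_scene()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return named list of written paths, invisibly.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(prefix, ".ome.tiff"))
  write_multiplex(scene$image, img_path)
  gt <- scene$ground_truth
  d <- gt$dim
  paths <- list(image = img_path)
  for (ep in gt$epitopes) {
    lab <- matrix(0, d[1L], d[2L])
    for (a in gt$aggregates) {
      px <- a$epitope_px[[ep]]
      if (length(px)) lab[px] <- a$id
    }
    p <- file.path(dir, sprintf("%s_gt_%s.tiff", prefix, ep))
    write_tiff(p, lab)
    paths[[paste0("gt_", ep)]] <- p
  }
  man <- do.call(rbind, lapply(gt$aggregates, function(a) {
    data.frame(id = a$id, kind = a$kind, size_um = a$size_um,
               footprint_px = length(a$footprint_px),
               composition = paste(names(Filter(length, a$epitope_px)),
                                   collapse = "+"))
  }))
  man_path <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(man, man_path, row.names = FALSE)
  paths$manifest <- man_path
  invisible(paths)
}
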