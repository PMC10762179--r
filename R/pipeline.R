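# End-to-end orchestration: simulate -> segment -> quantify -> stats, with
# per-stage logging, a run manifest, and deterministic outputs under fixed
# seeds. A CLI wrapper lives in inst/cli/lewyquant.R.

read_input_image <- function(x, config) {
  if (inherits(x, "multiplex_image")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_multiplex(x, channel_map = config$channel_map, config = config,
                          case_id = sub("\\.(ome\\.)?tiff?$", "", basename(x))))
  stop_lq("inputs must be multiplex_image objects or file paths")
}

#' Per-region / per-case analysis across a set of images
#'
#' For each image: segment every epitope channel, build the epitope-area
#' report, label and classify aggregates, and compute the morphology
#' distribution. Across cases (when at least 3 succeed): one-way ANOVA with
#' Tukey HSD on epitope-unique percentages by epitope, and Pearson
#' correlation between unique N-terminus and unique pS129 percentages. A
#' failing image is logged and skipped; the run fails only if every image
#' fails.
#'
#' @param inputs list of [multiplex_image()]s and/or TIFF paths.
#' @param config an [analysis_config()].
#' @param out_dir optional output directory for CSVs and the run manifest.
#' @return list with `reports` (per-case data frame), `morphology`
#'   (per-case class shares), `objects` (per-object descriptors and epitope
#'   composition), `stats` (list of test results), `stats_table`, `log`,
#'   and `manifest`.
#' @export
run_region_analysis <- function(inputs, config = analysis_config(),
                                out_dir = NULL) {
  if (!length(inputs)) stop_lq("need at least one input image")
  report_rows <- list(); morph_rows <- list(); object_rows <- list()
  log_lines <- character(0)
  failures <- 0L
  for (i in seq_along(inputs)) {
    res <- tryCatch({
      img <- read_input_image(inputs[[i]], config)
      masks <- segment_image(img, config)
      rep_i <- epitope_report(masks, region_mask = img$region_mask,
                              pixel_size_um = img$pixel_size_um,
                              case_id = img$case_id %||% sprintf("case%02d", i),
                              region_label = img$region_label)
      union_mask <- mask_union(lapply(masks, as_mask_matrix))
      objs <- label_aggregates(union_mask, pixel_size_um = img$pixel_size_um,
                               min_object_px = config$min_object_px)
      objs <- lapply(objs, classify_morphology, rules = config$morphology)
      dist_i <- morphology_distribution(objs)
      obj_df <- do.call(rbind, lapply(objs, function(o) {
        comp <- aggregate_composition(o, masks, pixel_size_um = img$pixel_size_um)
        row <- data.frame(case_id = rep_i$case_id, object_id = o$id,
                          morph_class = o$morph_class, area_px = o$area_px,
                          area_um2 = o$area_um2,
                          equivalent_diameter_um = o$equivalent_diameter_um,
                          feret_diameter_um = o$feret_diameter_um,
                          circularity = o$circularity,
                          aspect_ratio = o$aspect_ratio,
                          stringsAsFactors = FALSE)
        for (e in comp$epitopes) row[[paste0("unique_", e, "_pct")]] <- comp$unique_pct[[e]]
        row$overlap_pct <- comp$overlap_pct
        row
      }))
      thr <- vapply(masks, function(m) m$threshold, 0)
      log_lines <- c(log_lines, sprintf(
        "[%s] thresholds: %s; removed objects: %s; aggregates: %d",
        rep_i$case_id,
        paste(sprintf("%s=%.4g", names(thr), thr), collapse = " "),
        paste(vapply(masks, function(m) m$n_removed_objects, 0L), collapse = "/"),
        length(objs)))
      list(report = rep_i, dist = dist_i, objects = obj_df)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- failures + 1L
      log_lines <- c(log_lines, sprintf("[input %d] FAILED: %s", i,
                                        conditionMessage(res)))
      next
    }
    report_rows[[length(report_rows) + 1L]] <- res$report
    md <- data.frame(case_id = res$report$case_id, t(res$dist$area_share_pct),
                     stringsAsFactors = FALSE)
    names(md)[-1L] <- paste0(names(res$dist$area_share_pct), "_area_pct")
    morph_rows[[length(morph_rows) + 1L]] <- md
    if (!is.null(res$objects)) object_rows[[length(object_rows) + 1L]] <- res$objects
  }
  if (failures == length(inputs)) stop_lq("all input images failed")
  reports_df <- do.call(rbind, lapply(report_rows, as.data.frame))
  morph_df <- do.call(rbind, morph_rows)
  objects_df <- if (length(object_rows)) do.call(rbind, object_rows) else NULL
  stats_res <- list()
  uniq_cols <- grep("^unique_.*_pct$", names(reports_df), value = TRUE)
  if (nrow(reports_df) >= 3L && length(uniq_cols) >= 2L) {
    groups <- stats::setNames(lapply(uniq_cols, function(cn) reports_df[[cn]]),
                              sub("^unique_(.*)_pct$", "\\1", uniq_cols))
    stats_res$unique_pct_anova <- tryCatch(one_way_anova(groups),
                                           error = function(e) NULL)
    stats_res$unique_pct_tukey <- tryCatch(tukey_hsd(groups),
                                           error = function(e) NULL)
    if (all(c("unique_Nterm_pct", "unique_pS129_pct") %in% uniq_cols)) {
      stats_res$nterm_ps129_pearson <- tryCatch(
        pearson_cor(reports_df$unique_Nterm_pct, reports_df$unique_pS129_pct),
        error = function(e) NULL)
    }
  }
  stats_res <- Filter(Negate(is.null), stats_res)
  out <- list(reports = reports_df, morphology = morph_df, objects = objects_df,
              stats = stats_res, stats_table = stats_summary(stats_res),
              log = log_lines,
              manifest = list(n_inputs = length(inputs), n_failed = failures,
                              config = unclass(config)[setdiff(names(config), "morphology")],
                              version = as.character(utils::packageVersion("lewyquant")),
                              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report_rows, file.path(out_dir, "epitope_reports.csv"))
    utils::write.csv(morph_df, file.path(out_dir, "morphology_distribution.csv"),
                     row.names = FALSE)
    if (!is.null(objects_df))
      utils::write.csv(objects_df, file.path(out_dir, "aggregates.csv"),
                       row.names = FALSE)
    if (nrow(out$stats_table))
      utils::write.csv(out$stats_table, file.path(out_dir, "stats_summary.csv"),
                       row.names = FALSE)
    writeLines(log_lines, file.path(out_dir, "segmentation.log"))
    out$manifest$outputs <- list.files(out_dir)
    jsonlite::write_json(out$manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(out)
}

#' Proteinase-K time-course analysis across subjects
#'
#' For each subject: segment the pre-treatment image to fix the union
#' footprint, measure every timepoint ([measure_timepoint()]), normalise
#' to t = 0 and estimate retention. Across subjects: repeated-measures
#' one-way ANOVA (with Tukey comparisons) per epitope on the
#' subjects-by-timepoints table of normalised percentages.
#'
#' @param series list of subjects, each a list with `timepoints_min`
#'   (first must be 0, identical across subjects) and `images` (list of
#'   [multiplex_image()], one per timepoint).
#' @param config an [analysis_config()]; `config$pk_mode` selects the
#'   measured quantity (intensity by default at pipeline level).
#' @param out_dir optional output directory.
#' @return list with `series` (long-format data frame incl. retention),
#'   `stats` (per-epitope rm-ANOVA and Tukey), `stats_table`.
#' @export
run_pk_analysis <- function(series, config = analysis_config(), out_dir = NULL) {
  if (!length(series)) stop_lq("need at least one subject")
  tp0 <- series[[1L]]$timepoints_min
  if (is.null(tp0) || tp0[1L] != 0)
    stop_lq("timepoints must start at 0 (pre-treatment image required)")
  rows <- list()
  for (s in seq_along(series)) {
    sub <- series[[s]]
    if (!identical(sub$timepoints_min, tp0))
      stop_lq("inconsistent timepoints across subjects")
    if (length(sub$images) != length(tp0))
      stop_lq("subject ", s, ": one image per timepoint required")
    masks0 <- segment_image(sub$images[[1L]], config)
    foot <- mask_union(lapply(masks0, as_mask_matrix))
    for (i in seq_along(tp0)) {
      q <- measure_timepoint(sub$images[[i]], config, mode = config$pk_mode,
                             footprint = foot)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = sprintf("S%02d", s), epitope = names(q),
        timepoint_min = tp0[i], raw = unname(q), stringsAsFactors = FALSE)
    }
  }
  raw <- do.call(rbind, rows)
  norm <- normalize_series(raw)
  fitted <- fit_retention(norm)
  stats_res <- list()
  for (e in unique(norm$epitope)) {
    d <- norm[norm$epitope == e, ]
    tab <- stats::xtabs(normalized_pct ~ subject + timepoint_min, data = d)
    tab <- matrix(tab, nrow = nrow(tab), dimnames = dimnames(tab))
    res <- tryCatch(rm_one_way_anova(tab), error = function(err) NULL)
    if (!is.null(res)) {
      stats_res[[paste0(e, "_rm_anova")]] <- res
      stats_res[[paste0(e, "_tukey")]] <- tryCatch(tukey_hsd_rm(tab),
                                                   error = function(err) NULL)
    }
  }
  stats_res <- Filter(Negate(is.null), stats_res)
  out <- list(series = fitted, stats = stats_res,
              stats_table = stats_summary(stats_res))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(fitted, file.path(out_dir, "pk_series.csv"), row.names = FALSE)
    if (nrow(out$stats_table))
      utils::write.csv(out$stats_table, file.path(out_dir, "pk_stats.csv"),
                       row.names = FALSE)
  }
  invisible(out)
}

# ---- cohort simulators -----------------------------------------------------

#' Simulate a TMA-style cohort with complementary unique fractions
#'
#' Builds `n_cases` single-core scenes in which the N-terminus-exclusive
#' and pS129-exclusive area fractions are complementary across cases
#' (case-level fraction f drawn uniformly, N-only ~ f, pS129-only ~
#' 0.88 - f, the remainder triple-labelled plus a small C-terminus-only
#' population), emulating the strong negative N-terminus/pS129 correlation
#' seen across such cohorts. Aggregate-to-population assignment is
#' area-proportional (largest-remainder) so realised fractions track their
#' targets closely.
#'
#' @param n_cases number of cases (cores).
#' @param seed base RNG seed; case i uses a derived child seed.
#' @param shape,pixel_size_um scene geometry.
#' @param n_aggregates aggregates per core.
#' @param noise_sigma detector noise.
#' @return list with `images` (list of [multiplex_image()]), `specs`, and
#'   `target_fractions` (data frame of per-case population targets).
#' @export
simulate_tma_cohort <- function(n_cases = 23L, seed = 1L,
                                shape = c(224L, 224L), pixel_size_um = 0.5,
                                n_aggregates = 26L, noise_sigma = 2) {
  images <- vector("list", n_cases)
  specs <- vector("list", n_cases)
  targets <- data.frame(case = seq_len(n_cases), f_n = NA_real_)
  for (ci in seq_len(n_cases)) {
    cs <- child_seed(seed, ci)
    spec <- with_seed(cs, {
      f <- stats::runif(1, 0.15, 0.73)
      targets$f_n[ci] <- f
      placed <- list()
      place <- function(reach_px) {
        for (try in 1:500) {
          ctr <- c(stats::runif(1, 1 + reach_px + 4, shape[1L] - reach_px - 4),
                   stats::runif(1, 1 + reach_px + 4, shape[2L] - reach_px - 4))
          ok <- TRUE
          for (p in placed)
            if (sqrt(sum((ctr - p[1:2])^2)) < reach_px + p[3L] + 3) { ok <- FALSE; break }
          if (ok || try == 500L) {  # overlap is legal once separation attempts run out
            placed[[length(placed) + 1L]] <<- c(ctr, reach_px)
            return(ctr)
          }
        }
      }
      # draw sizes first, then assign populations area-proportionally
      lens <- stats::runif(n_aggregates, 8, 14)
      thick <- stats::runif(n_aggregates, 1, 1.8)
      area_w <- lens * thick
      share <- c(n_only = f, p_only = max(0.88 - f, 0.02), triple = 0.10,
                 c_only = 0.02)
      share <- share / sum(share)
      pop <- character(n_aggregates)
      alloc <- stats::setNames(numeric(4), names(share))
      ord <- order(area_w, decreasing = TRUE)
      tot_w <- sum(area_w)
      for (j in ord) {
        deficit <- share - alloc / tot_w
        k <- names(which.max(deficit))
        pop[j] <- k
        alloc[k] <- alloc[k] + area_w[j]
      }
      pk <- function() stats::runif(1, 150, 210)
      aggs <- lapply(seq_len(n_aggregates), function(j) {
        prof <- switch(pop[j],
          n_only = list(Nterm = list(pattern = "uniform", peak = pk())),
          p_only = list(pS129 = list(pattern = "uniform", peak = pk())),
          c_only = list(Cterm = list(pattern = "uniform", peak = pk())),
          triple = list(Nterm = list(pattern = "uniform", peak = pk()),
                        pS129 = list(pattern = "uniform", peak = pk()),
                        Cterm = list(pattern = "uniform", peak = pk())))
        ctr <- place(lens[j] / 2 / pixel_size_um + 2)
        aggregate_spec("lewy_neurite", ctr, lens[j], epitope_profile = prof,
                       thickness_um = thick[j],
                       orientation = stats::runif(1, 0, 2 * pi),
                       curvature = stats::runif(1, -0.8, 0.8) / (lens[j] / pixel_size_um))
      })
      scene_spec(aggs, shape = shape, pixel_size_um = pixel_size_um,
                 noise_sigma = noise_sigma, seed = cs)
    })
    specs[[ci]] <- spec
    sc <- render_scene(spec)
    sc$image$case_id <- sprintf("TMA%02d", ci)
    sc$image$region_label <- "MTG_core"
    images[[ci]] <- sc$image
  }
  list(images = images, specs = specs, target_fractions = targets)
}

#' Simulate a proteinase-K digestion cohort
#'
#' `n_subjects` scenes of protease-susceptible N-terminus-exclusive
#' pathology (glial threads and lysosomal puncta) plus one unaffected
#' triple-labelled Lewy body control, digested under a shared retention
#' schedule.
#'
#' @param n_subjects number of subjects (tissue sections).
#' @param seed base seed; subject i uses a derived child seed.
#' @param timepoints_min digestion schedule, starting at 0.
#' @param retention_nterm N-terminus retention factors, one per timepoint
#'   (default mirrors early unmasking then progressive digestion).
#' @param shape,pixel_size_um,noise_sigma scene parameters.
#' @param affected_kinds aggregate kinds subject to digestion. The cohort
#'   default is all kinds: the whole measured footprint degrades
#'   N-terminally while pS129/C-terminus retain, so the pooled per-subject
#'   signal tracks the retention schedule directly (an unaffected
#'   population would dilute it).
#' @return list of subjects, each with `timepoints_min`, `images`,
#'   `ground_truths`, and `spec`; suitable for [run_pk_analysis()].
#' @export
simulate_pk_cohort <- function(n_subjects = 8L, seed = 1L,
                               timepoints_min = c(0, 15, 30, 60),
                               retention_nterm = c(1, 1.1, 0.7, 0.45),
                               shape = c(128L, 128L), pixel_size_um = 0.5,
                               noise_sigma = 2,
                               affected_kinds = AGGREGATE_KINDS) {
  model <- pk_model(timepoints_min,
                    retention = list(Nterm = retention_nterm),
                    affected_kinds = affected_kinds)
  lapply(seq_len(n_subjects), function(s) {
    cs <- child_seed(seed, 1000L + s)
    spec <- random_scene_spec(cs, shape = shape, pixel_size_um = pixel_size_um,
                              n_lb = 1L, n_ln = 0L, n_punctate = 4L,
                              n_glial = 2L, lb_diameter_um = c(8, 14),
                              noise_sigma = noise_sigma)
    ser <- simulate_pk_series(spec, model)
    list(timepoints_min = ser$timepoints_min, images = ser$images,
         ground_truths = ser$ground_truths, spec = spec)
  })
}
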