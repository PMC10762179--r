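# Property-based benchmark harness. Each benchmark recomputes one of the
# package's verification properties from scratch -- generating inputs,
# running the implementation, and comparing against an independent
# brute-force route -- and returns the measured metric(s). The acceptance
# script and the acceptance tests both consume these.

# brute-force per-pixel algebra (independent route: coverage counting)
bf_algebra <- function(masks) {
  cov <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  list(total = sum(cov >= 1L),
       unique = vapply(names(masks), function(e) sum(masks[[e]] & cov == 1L), 0L),
       overlap = sum(cov >= 2L))
}

# brute-force Otsu (independent route: explicit per-threshold class means)
bf_otsu <- function(v, n_bins = 256L) {
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(bin, n_bins)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  best_t <- NA_real_; best_v <- -Inf
  for (t in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[seq_len(t)]); n1 <- sum(counts) - n0
    if (n0 == 0L || n1 == 0L) next
    mu0 <- sum(counts[seq_len(t)] * centers[seq_len(t)]) / n0
    mu1 <- sum(counts[(t + 1L):n_bins] * centers[(t + 1L):n_bins]) / n1
    bcv <- (n0 / (n0 + n1)) * (n1 / (n0 + n1)) * (mu0 - mu1)^2
    if (bcv > best_v) { best_v <- bcv; best_t <- edges[t + 1L] }
  }
  best_t
}

#' Benchmark: mask-algebra conservation on random mask triples
#'
#' Draws random mask triples, checks `total = sum(unique) + overlap`
#' exactly and that unique/overlap equal an independent per-pixel
#' enumeration.
#'
#' @param n number of random triples.
#' @param seed RNG seed.
#' @param shape mask shape in pixels.
#' @return list with `n`, `exact_fraction` (fraction of triples where every
#'   identity held exactly) and `max_abs_error`.
#' @export
benchmark_mask_algebra <- function(n = 1000L, seed = 1L, shape = c(64L, 64L)) {
  with_seed(seed, {
    ok <- 0L; max_err <- 0
    for (i in seq_len(n)) {
      masks <- stats::setNames(lapply(1:3, function(j)
        matrix(stats::runif(prod(shape)) < stats::runif(1, 0.05, 0.6),
               shape[1L], shape[2L])), c("Nterm", "pS129", "Cterm"))
      ref <- bf_algebra(masks)
      tot <- total_area(masks)
      uniq <- vapply(names(masks), unique_area, 0L, masks = masks)
      ovl <- overlap_area(masks)
      errs <- c(abs(tot - ref$total), abs(uniq - ref$unique),
                abs(ovl - ref$overlap), abs(tot - sum(uniq) - ovl))
      max_err <- max(max_err, errs)
      if (all(errs == 0)) ok <- ok + 1L
    }
    list(n = n, exact_fraction = ok / n, max_abs_error = max_err)
  })
}

#' Benchmark: Otsu oracle equivalence on random 8-bit images
#'
#' @param n number of random images.
#' @param seed RNG seed.
#' @param n_px pixels per image.
#' @return list with `n` and `agreement_fraction` (exact threshold matches
#'   against the exhaustive maximiser).
#' @export
benchmark_otsu <- function(n = 500L, seed = 1L, n_px = 1024L) {
  with_seed(seed, {
    ok <- 0L
    for (i in seq_len(n)) {
      # varied histogram shapes: flat, skewed, bimodal
      kind <- i %% 3L
      v <- if (kind == 0L) sample(0:255, n_px, replace = TRUE)
      else if (kind == 1L) pmin(255, pmax(0, round(stats::rnorm(n_px, 80, 40))))
      else pmin(255, pmax(0, round(c(stats::rnorm(n_px / 2, 60, 25),
                                     stats::rnorm(n_px / 2, 190, 20)))))
      if (length(unique(v)) < 2L) next
      if (identical(otsu_threshold(v), bf_otsu(v))) ok <- ok + 1L
    }
    list(n = n, agreement_fraction = ok / n)
  })
}

#' Benchmark: ground-truth recovery on randomised synthetic scenes
#'
#' Renders seeded mixed-pathology scenes twice (noise-free and at the
#' simulator's default noise), runs the segmentation + epitope-algebra
#' pipeline, and compares recovered unique/overlap percentages against the
#' exact [expected_report()] oracle, plus per-channel Jaccard overlap of
#' the noise-free masks.
#'
#' @param n_scenes number of scenes.
#' @param seed base seed.
#' @return list with per-condition maximum absolute percentage errors and
#'   the minimum noise-free Jaccard index.
#' @export
benchmark_scene_recovery <- function(n_scenes = 20L, seed = 1L) {
  cfg <- analysis_config()
  err_noisefree <- 0; err_noisy <- 0; jaccard_min <- 1
  for (i in seq_len(n_scenes)) {
    cs <- child_seed(seed, 100L + i)
    for (sigma in c(0, 2)) {
      spec <- random_scene_spec(cs, noise_sigma = sigma)
      sc <- render_scene(spec)
      ref <- expected_report(sc$ground_truth)
      masks <- segment_image(sc$image, cfg)
      got <- epitope_report(masks, pixel_size_um = spec$pixel_size_um)
      errs <- c(abs(got$unique_pct - ref$unique_pct),
                abs(got$overlap_pct - ref$overlap_pct))
      if (sigma == 0) {
        err_noisefree <- max(err_noisefree, errs)
        for (e in names(masks)) {
          gtm <- gt_epitope_mask(sc$ground_truth, e)
          if (!any(gtm)) next
          jac <- sum(gtm & masks[[e]]$mask) / sum(gtm | masks[[e]]$mask)
          jaccard_min <- min(jaccard_min, jac)
        }
      } else err_noisy <- max(err_noisy, errs)
    }
  }
  list(n_scenes = n_scenes, max_abs_err_pct_noisefree = err_noisefree,
       max_abs_err_pct_noisy = err_noisy, jaccard_min_noisefree = jaccard_min)
}

#' Benchmark: morphology classification recovery on noise-free scenes
#'
#' Segments noise-free scenes, matches each labelled object to the
#' ground-truth aggregate with maximal footprint overlap, and scores
#' classification against [expected_morph_class()]; also compares the
#' recovered class area shares against the ground-truth composition.
#'
#' @param n_scenes number of scenes.
#' @param seed base seed.
#' @return list with `accuracy` (fraction of objects recovering their
#'   ground-truth class) and `max_share_err_pct`.
#' @export
benchmark_morphology <- function(n_scenes = 20L, seed = 1L) {
  cfg <- analysis_config()
  hits <- 0L; total <- 0L; share_err <- 0
  for (i in seq_len(n_scenes)) {
    cs <- child_seed(seed, 200L + i)
    sc <- render_scene(random_scene_spec(cs, noise_sigma = 0))
    gt <- sc$ground_truth
    masks <- segment_image(sc$image, cfg)
    um <- Reduce(`|`, lapply(masks, function(m) m$mask))
    objs <- lapply(label_aggregates(um, gt$pixel_size_um, cfg$min_object_px),
                   classify_morphology, rules = cfg$morphology)
    for (o in objs) {
      ov <- vapply(gt$aggregates,
                   function(a) length(intersect(o$pixel_idx, a$footprint_px)), 0L)
      kind <- gt$aggregates[[which.max(ov)]]$kind
      total <- total + 1L
      if (identical(o$morph_class, expected_morph_class(kind))) hits <- hits + 1L
    }
    got <- morphology_distribution(objs)$area_share_pct
    gt_area <- vapply(gt$aggregates, function(a) length(a$footprint_px), 0L)
    gt_cls <- expected_morph_class(vapply(gt$aggregates, function(a) a$kind, ""))
    ref <- vapply(names(got), function(k) 100 * sum(gt_area[gt_cls == k]) / sum(gt_area), 0)
    share_err <- max(share_err, abs(got - ref))
  }
  list(n_objects = total, accuracy = hits / total, max_share_err_pct = share_err)
}

#' Benchmark: proteinase-K retention recovery and time-effect detection
#'
#' Simulates digestion cohorts (8 subjects, schedule 0/15/30/60 min,
#' N-terminus retention 1/1.1/0.7/0.45, other epitopes at 1), runs the PK
#' pipeline, and reports (i) the maximum absolute error of the mean
#' estimated N-terminus retention, (ii) the fraction of replicate cohorts
#' in which the repeated-measures ANOVA detects the N-terminus time effect
#' at `alpha`, and (iii) the rejection fraction under the all-ones null.
#'
#' @param n_replicates replicate cohorts per condition.
#' @param seed base seed.
#' @param alpha significance level.
#' @param shape scene size (scaled down for runtime; the effect operates
#'   at aggregate scale, not image scale).
#' @return list of metrics.
#' @export
benchmark_pk <- function(n_replicates = 100L, seed = 1L, alpha = 0.05,
                         shape = c(112L, 112L)) {
  cfg <- analysis_config()
  truth <- c(1, 1.1, 0.7, 0.45)
  detect <- 0L; null_reject <- 0L; ret_err <- 0
  for (r in seq_len(n_replicates)) {
    coh <- simulate_pk_cohort(n_subjects = 8L, seed = child_seed(seed, 300L + r),
                              shape = shape)
    res <- run_pk_analysis(coh, cfg)
    if (res$stats$Nterm_rm_anova$p_value < alpha) detect <- detect + 1L
    if (r == 1L) {
      mean_ret <- vapply(c(0, 15, 30, 60), function(t)
        mean(res$series$retention[res$series$epitope == "Nterm" &
                                    res$series$timepoint_min == t]), 0)
      ret_err <- max(abs(mean_ret - truth))
    }
    coh0 <- simulate_pk_cohort(n_subjects = 8L,
                               seed = child_seed(seed, 700L + r),
                               retention_nterm = c(1, 1, 1, 1), shape = shape)
    res0 <- run_pk_analysis(coh0, cfg)
    if (res0$stats$Nterm_rm_anova$p_value < alpha) null_reject <- null_reject + 1L
  }
  list(n_replicates = n_replicates,
       retention_max_abs_err = ret_err,
       detection_fraction = detect / n_replicates,
       null_rejection_fraction = null_reject / n_replicates)
}

#' Benchmark: one-way ANOVA type-I error calibration
#'
#' Simulates equal-mean normal groups and reports the rejection fraction
#' at `alpha`.
#'
#' @param n_sims number of simulated experiments.
#' @param seed RNG seed.
#' @param k groups, `n_per` observations each.
#' @param alpha level.
#' @return list with `rejection_fraction`.
#' @export
benchmark_anova_type1 <- function(n_sims = 10000L, seed = 1L, k = 3L,
                                  n_per = 10L, alpha = 0.05) {
  with_seed(seed, {
    rej <- 0L
    for (i in seq_len(n_sims)) {
      groups <- lapply(seq_len(k), function(j) stats::rnorm(n_per))
      if (one_way_anova(groups)$p_value < alpha) rej <- rej + 1L
    }
    list(n_sims = n_sims, rejection_fraction = rej / n_sims)
  })
}

#' Benchmark: TMA-style cohort correlation
#'
#' Simulates the complementary-fraction cohort, runs the full region
#' pipeline, and returns the estimated Pearson correlation between unique
#' N-terminus and unique pS129 percentages across cases.
#'
#' @param n_cases cohort size.
#' @param seed RNG seed.
#' @return list with `pearson_r`, `p_value`, and cohort means of the four
#'   composition percentages.
#' @export
benchmark_tma_correlation <- function(n_cases = 23L, seed = 1L) {
  cohort <- simulate_tma_cohort(n_cases = n_cases, seed = seed)
  res <- suppressMessages(run_region_analysis(cohort$images, analysis_config()))
  pear <- res$stats$nterm_ps129_pearson
  list(n_cases = n_cases, pearson_r = pear$statistic, p_value = pear$p_value,
       mean_unique_nterm_pct = mean(res$reports$unique_Nterm_pct),
       mean_unique_ps129_pct = mean(res$reports$unique_pS129_pct),
       mean_unique_cterm_pct = mean(res$reports$unique_Cterm_pct),
       mean_overlap_pct = mean(res$reports$overlap_pct))
}
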