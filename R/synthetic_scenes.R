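# Synthetic multiplex-scene simulator. Stands in for human-brain multiplex
# immunofluorescence: Lewy bodies with uniform N-terminus fill and
# peripherally concentrated pS129/C-terminus rings, thread/club Lewy
# neurites (including epitope-exclusive populations), punctate lysosomal
# and thin glial aggregates labelled only in the N-terminus channel,
# diffuse C-terminus-dominant monomeric background, detector noise, and
# multiplicative epitope-specific decay across proteinase-K timepoints.
# Every render carries exact per-aggregate ground truth.

AGGREGATE_KINDS <- c("lewy_body", "lewy_neurite", "punctate_lysosomal", "glial")
EPITOPE_PATTERNS <- c("absent", "uniform", "peripheral_ring", "punctate")

#' Specify one simulated aggregate
#'
#' @param kind one of `"lewy_body"`, `"lewy_neurite"`,
#'   `"punctate_lysosomal"`, `"glial"`.
#' @param centroid numeric `c(row, col)` in pixels.
#' @param size_um characteristic size in um: LB/punctum diameter, or
#'   neurite/glial thread length. Lewy bodies are drawable over the
#'   observed ~5-55 um range, neurites over ~3-25 um.
#' @param epitope_profile named list, one entry per labelled epitope:
#'   `list(pattern = <"uniform"|"peripheral_ring"|"punctate"|"absent">,
#'   peak = <intensity>)`. At least one pattern must differ from absent.
#' @param thickness_um thread thickness (neurite/glial kinds).
#' @param orientation initial heading in radians (neurite/glial).
#' @param curvature heading change per pixel of arclength (constant-
#'   curvature arc; neurite/glial).
#' @param club logical; inflate one end of a neurite (club morphology).
#' @return object of class `aggregate_spec`.
#' @export
aggregate_spec <- function(kind, centroid, size_um, epitope_profile,
                           thickness_um = 1.5, orientation = 0,
                           curvature = 0, club = FALSE) {
  kind <- match.arg(kind, AGGREGATE_KINDS)
  check_scalar_num(size_um, "size_um", positive = TRUE)
  check_scalar_num(thickness_um, "thickness_um", positive = TRUE)
  if (length(centroid) != 2L || !all(is.finite(centroid)))
    stop_lq("`centroid` must be c(row, col)")
  if (!is.list(epitope_profile) || !length(epitope_profile) ||
      is.null(names(epitope_profile)))
    stop_lq("`epitope_profile` must be a named list")
  active <- 0L
  for (e in names(epitope_profile)) {
    pr <- epitope_profile[[e]]
    pr$pattern <- match.arg(pr$pattern, EPITOPE_PATTERNS)
    if (pr$pattern != "absent") {
      check_scalar_num(pr$peak, paste0("peak[", e, "]"), positive = TRUE)
      active <- active + 1L
    }
    epitope_profile[[e]] <- pr
  }
  if (active == 0L) stop_lq("at least one epitope pattern must differ from 'absent'")
  structure(list(kind = kind, centroid = as.numeric(centroid),
                 size_um = size_um, thickness_um = thickness_um,
                 epitope_profile = epitope_profile,
                 orientation = orientation, curvature = curvature,
                 club = club),
            class = "aggregate_spec")
}

#' Specify a synthetic multiplex scene
#'
#' @param aggregates list of [aggregate_spec()]s.
#' @param shape image shape `c(rows, cols)` in pixels.
#' @param pixel_size_um pixel size (> 0); default 0.5 um/px.
#' @param monomer_background named per-epitope constant low-intensity level
#'   emulating diffuse monomeric alpha-synuclein; C-terminus-dominant by
#'   default (the C-terminus antibody also labels non-pathological
#'   monomer).
#' @param noise_sigma additive Gaussian detector noise sd (>= 0).
#' @param poisson_scale optional signal-dependent component: noise sd grows
#'   as `poisson_scale * sqrt(intensity)` (0 disables).
#' @param seed integer; fixes the rendered output bit-exactly.
#' @param epitopes channel order; defaults to the union of profile and
#'   background labels ordered as [default_epitopes()].
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(aggregates, shape = c(256L, 256L), pixel_size_um = 0.5,
                       monomer_background = c(Nterm = 1, pS129 = 1, Cterm = 12),
                       noise_sigma = 2, poisson_scale = 0, seed = 1L,
                       epitopes = NULL) {
  check_scalar_num(pixel_size_um, "pixel_size_um", positive = TRUE)
  check_scalar_num(noise_sigma, "noise_sigma", nonneg = TRUE)
  check_scalar_num(poisson_scale, "poisson_scale", nonneg = TRUE)
  check_scalar_num(seed, "seed")
  if (length(shape) != 2L || any(shape < 1L)) stop_lq("`shape` must be c(rows, cols)")
  if (inherits(aggregates, "aggregate_spec")) aggregates <- list(aggregates)
  for (a in aggregates) stopifnot(inherits(a, "aggregate_spec"))
  prof_labs <- unique(unlist(lapply(aggregates, function(a) names(a$epitope_profile))))
  labs <- epitopes %||% {
    all_labs <- union(prof_labs, names(monomer_background))
    canonical <- default_epitopes()
    c(intersect(canonical, all_labs), setdiff(all_labs, canonical))
  }
  if (!length(labs)) stop_lq("no epitope labels in scene")
  bg <- stats::setNames(rep(0, length(labs)), labs)
  common <- intersect(names(monomer_background), labs)
  bg[common] <- monomer_background[common]
  structure(list(aggregates = aggregates, shape = as.integer(shape),
                 pixel_size_um = pixel_size_um, monomer_background = bg,
                 noise_sigma = noise_sigma, poisson_scale = poisson_scale,
                 seed = as.integer(seed), epitopes = labs),
            class = "scene_spec")
}

# ---- rasterisation ---------------------------------------------------------

disc_pixels <- function(centroid, radius_px, shape) {
  r0 <- max(1L, floor(centroid[1L] - radius_px)); r1 <- min(shape[1L], ceiling(centroid[1L] + radius_px))
  c0 <- max(1L, floor(centroid[2L] - radius_px)); c1 <- min(shape[2L], ceiling(centroid[2L] + radius_px))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  g <- expand.grid(row = rr, col = cc)
  d2 <- (g$row - centroid[1L])^2 + (g$col - centroid[2L])^2
  keep <- d2 <= radius_px^2
  as.integer((g$col[keep] - 1L) * shape[1L] + g$row[keep])
}

arc_path <- function(centroid, length_px, orientation, curvature, step = 0.5) {
  n <- max(2L, ceiling(length_px / step) + 1L)
  s <- (seq_len(n) - 1L) * step
  theta <- orientation + curvature * s
  drow <- c(0, step * sin(theta[-n]))
  dcol <- c(0, step * cos(theta[-n]))
  rows <- cumsum(drow); cols <- cumsum(dcol)
  rows <- rows - mean(range(rows)) + centroid[1L]
  cols <- cols - mean(range(cols)) + centroid[2L]
  cbind(rows, cols)
}

tube_pixels <- function(path, radius_px, shape) {
  r0 <- max(1L, floor(min(path[, 1L]) - radius_px))
  r1 <- min(shape[1L], ceiling(max(path[, 1L]) + radius_px))
  c0 <- max(1L, floor(min(path[, 2L]) - radius_px))
  c1 <- min(shape[2L], ceiling(max(path[, 2L]) + radius_px))
  if (r0 > r1 || c0 > c1) return(integer(0))
  g <- expand.grid(row = r0:r1, col = c0:c1)
  d2 <- outer(g$row, path[, 1L], `-`)^2 + outer(g$col, path[, 2L], `-`)^2
  keep <- matrixStats_rowMins(d2) <= radius_px^2
  as.integer((g$col[keep] - 1L) * shape[1L] + g$row[keep])
}

# rowMins without a matrixStats dependency
matrixStats_rowMins <- function(m) do.call(pmin, as.data.frame(m))

# Iterative 8-neighbour erosion used for peripheral rings on non-disc
# footprints.
erode_mask <- function(mask, iterations) {
  for (i in seq_len(iterations)) {
    nr <- nrow(mask); nc <- ncol(mask)
    shift <- function(dr, dc) {
      out <- matrix(FALSE, nr, nc)
      rs <- max(1L, 1L + dr):min(nr, nr + dr)
      cs <- max(1L, 1L + dc):min(nc, nc + dc)
      out[rs, cs] <- mask[rs - dr, cs - dc]
      out
    }
    mask <- mask & shift(1L, 0L) & shift(-1L, 0L) & shift(0L, 1L) & shift(0L, -1L) &
      shift(1L, 1L) & shift(1L, -1L) & shift(-1L, 1L) & shift(-1L, -1L)
  }
  mask
}

# Rasterise one aggregate. Returns footprint pixel indices plus per-epitope
# pattern pixel indices. Consumes RNG only for the "punctate" intra-
# aggregate pattern.
rasterise_aggregate <- function(agg, shape, pixel_size_um, ring_fraction = 0.25) {
  R_px <- (agg$size_um / 2) / pixel_size_um
  half_w <- max(1, (agg$thickness_um / 2) / pixel_size_um)
  if (agg$kind %in% c("lewy_body", "punctate_lysosomal")) {
    R_px <- max(R_px, 1)
    foot <- disc_pixels(agg$centroid, R_px, shape)
  } else {
    L_px <- agg$size_um / pixel_size_um
    path <- arc_path(agg$centroid, L_px, agg$orientation, agg$curvature)
    foot <- tube_pixels(path, half_w, shape)
    if (agg$club) {
      club_r <- max(1.5 * half_w, half_w + 1.5)
      foot <- union(foot, disc_pixels(path[nrow(path), ], club_r, shape))
    }
  }
  if (!length(foot)) stop_lq("aggregate footprint lies entirely outside the image")
  ep_px <- list()
  for (e in names(agg$epitope_profile)) {
    pr <- agg$epitope_profile[[e]]
    ep_px[[e]] <- switch(pr$pattern,
      absent = integer(0),
      uniform = foot,
      peripheral_ring = {
        if (agg$kind %in% c("lewy_body", "punctate_lysosomal")) {
          rows <- ((foot - 1L) %% shape[1L]) + 1L
          cols <- ((foot - 1L) %/% shape[1L]) + 1L
          d2 <- (rows - agg$centroid[1L])^2 + (cols - agg$centroid[2L])^2
          ring <- foot[d2 >= ((1 - ring_fraction) * R_px)^2]
          if (length(ring)) ring else foot
        } else {
          m <- matrix(FALSE, shape[1L], shape[2L]); m[foot] <- TRUE
          core <- erode_mask(m, max(1L, round(ring_fraction * half_w * 2)))
          ring <- foot[!core[foot]]
          if (length(ring)) ring else foot
        }
      },
      punctate = {
        n_dots <- max(3L, round(length(foot) / 40))
        seeds <- foot[sample.int(length(foot), min(n_dots, length(foot)))]
        px <- integer(0)
        for (s in seeds) {
          ctr <- c(((s - 1L) %% shape[1L]) + 1L, ((s - 1L) %/% shape[1L]) + 1L)
          px <- union(px, disc_pixels(ctr, 1.5, shape))
        }
        intersect(px, foot)
      })
  }
  list(footprint_px = foot, epitope_px = ep_px)
}

# ---- rendering -------------------------------------------------------------

render_core <- function(spec, retention = NULL, noise_seed = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  shape <- spec$shape
  rast <- with_seed(spec$seed, lapply(spec$aggregates, rasterise_aggregate,
                                      shape = shape,
                                      pixel_size_um = spec$pixel_size_um))
  labs <- spec$epitopes
  channels <- stats::setNames(lapply(labs, function(e) matrix(0, shape[1L], shape[2L])), labs)
  gt_aggs <- vector("list", length(spec$aggregates))
  for (i in seq_along(spec$aggregates)) {
    agg <- spec$aggregates[[i]]
    rz <- rast[[i]]
    sums <- stats::setNames(numeric(length(labs)), labs)
    peaks <- stats::setNames(numeric(length(labs)), labs)
    for (e in names(agg$epitope_profile)) {
      pr <- agg$epitope_profile[[e]]
      if (pr$pattern == "absent" || !e %in% labs) next
      fac <- 1
      if (!is.null(retention) && agg$kind %in% retention$kinds)
        fac <- retention$factors[[e]] %||% 1
      px <- rz$epitope_px[[e]]
      if (length(px)) channels[[e]][px] <- channels[[e]][px] + pr$peak * fac
      sums[e] <- pr$peak * fac * length(px)
      peaks[e] <- pr$peak * fac
    }
    gt_aggs[[i]] <- list(id = i, kind = agg$kind, size_um = agg$size_um,
                         footprint_px = rz$footprint_px,
                         epitope_px = rz$epitope_px[intersect(names(rz$epitope_px), labs)],
                         epitope_peak = peaks, intensity_sum = sums)
  }
  for (e in labs) channels[[e]] <- channels[[e]] + spec$monomer_background[[e]]
  if (spec$noise_sigma > 0 || spec$poisson_scale > 0) {
    ns <- noise_seed %||% spec$seed
    channels <- with_seed(ns, {
      for (e in labs) {
        ch <- channels[[e]]
        n <- length(ch)
        ch <- ch + stats::rnorm(n, 0, max(spec$noise_sigma, 1e-12))
        if (spec$poisson_scale > 0)
          ch <- ch + spec$poisson_scale * sqrt(pmax(ch, 0)) * stats::rnorm(n)
        channels[[e]] <- pmax(ch, 0)
      }
      channels
    })
  }
  gt <- structure(list(dim = shape, pixel_size_um = spec$pixel_size_um,
                       epitopes = labs, region_mask = NULL,
                       aggregates = gt_aggs, seed = spec$seed),
                  class = "scene_ground_truth")
  img <- multiplex_image(channels, pixel_size_um = spec$pixel_size_um,
                         case_id = sprintf("sim_seed%d", spec$seed),
                         region_label = "synthetic")
  list(image = img, ground_truth = gt)
}

#' Render a synthetic multiplex scene
#'
#' Rasterises every aggregate per its epitope patterns (uniform fill;
#' peripheral ring = annulus over the outer 25% of the radius; punctate =
#' scattered small discs inside the footprint), adds monomer background and
#' detector noise last. Identical specs (including seed) render
#' bit-identically.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (a [multiplex_image()]) and `ground_truth`
#'   (class `scene_ground_truth`: per-aggregate noiseless per-epitope pixel
#'   sets, kinds, peaks and integrated intensities).
#' @export
render_scene <- function(spec) render_core(spec)

#' Ground-truth epitope mask
#'
#' Union of the noiseless per-aggregate masks for one epitope.
#'
#' @param gt a `scene_ground_truth`.
#' @param epitope label.
#' @return logical matrix.
#' @export
gt_epitope_mask <- function(gt, epitope) {
  m <- matrix(FALSE, gt$dim[1L], gt$dim[2L])
  for (a in gt$aggregates) {
    px <- a$epitope_px[[epitope]]
    if (length(px)) m[px] <- TRUE
  }
  m
}

#' Exact expected epitope-area report from ground truth
#'
#' Computes total/unique/overlap areas by exact per-pixel set enumeration
#' over the noiseless ground-truth masks -- the oracle the mask-algebra and
#' recovery tests compare against. An empty ground truth yields all-zero
#' areas with percentages flagged undefined.
#'
#' @param gt a `scene_ground_truth`.
#' @return `epitope_area_report`.
#' @export
expected_report <- function(gt) {
  stopifnot(inherits(gt, "scene_ground_truth"))
  labs <- gt$epitopes
  npx <- prod(gt$dim)
  member <- matrix(FALSE, npx, length(labs), dimnames = list(NULL, labs))
  for (a in gt$aggregates) {
    for (e in labs) {
      px <- a$epitope_px[[e]]
      if (length(px)) member[px, e] <- TRUE
    }
  }
  coverage <- rowSums(member)
  tot <- sum(coverage >= 1L)
  uniq <- vapply(labs, function(e) sum(member[, e] & coverage == 1L), 0L)
  ovl <- sum(coverage >= 2L)
  region_area <- if (is.null(gt$region_mask)) npx else sum(gt$region_mask)
  px2 <- gt$pixel_size_um^2
  defined <- tot > 0L
  pct <- function(a) if (defined) 100 * a / tot else NA_real_
  structure(list(
    case_id = sprintf("gt_seed%d", gt$seed), region_label = "ground_truth",
    epitopes = labs,
    total_area_px = tot, total_area_um2 = tot * px2,
    unique_area_px = uniq, unique_area_um2 = uniq * px2,
    overlap_area_px = ovl, overlap_area_um2 = ovl * px2,
    unique_pct = vapply(uniq, pct, 0), overlap_pct = pct(ovl),
    region_area_px = region_area,
    pathology_load_pct = 100 * tot / region_area,
    percent_defined = defined,
    pixel_size_um = gt$pixel_size_um
  ), class = "epitope_area_report")
}

# ---- proteinase-K series ---------------------------------------------------

#' Specify a proteinase-K digestion model
#'
#' Multiplicative retention of each epitope's aggregate signal at each
#' cumulative digestion timepoint. Factors above 1 model epitope unmasking
#' (observed at 15 min); retention at the pre-treatment timepoint must be
#' exactly 1.
#'
#' @param timepoints_min ordered numeric timepoints starting at 0. The
#'   reference cumulative schedule is `c(0, 15, 30, 40, 50, 60)` minutes.
#' @param retention named list: epitope -> numeric vector of factors, one
#'   per timepoint (all >= 0, first == 1). Epitopes not listed retain 1.
#' @param affected_kinds aggregate kinds subject to digestion; defaults to
#'   the protease-susceptible N-terminus-exclusive populations.
#' @return object of class `pk_model`.
#' @export
pk_model <- function(timepoints_min = c(0, 15, 30, 40, 50, 60),
                     retention = list(),
                     affected_kinds = c("punctate_lysosomal", "glial")) {
  if (timepoints_min[1L] != 0) stop_lq("timepoints must start at 0 (pre-treatment)")
  if (is.unsorted(timepoints_min, strictly = TRUE))
    stop_lq("timepoints must be strictly increasing")
  for (e in names(retention)) {
    r <- retention[[e]]
    if (length(r) != length(timepoints_min))
      stop_lq("retention[", e, "] must have one factor per timepoint")
    if (any(r < 0)) stop_lq("retention factors must be >= 0")
    if (r[1L] != 1) stop_lq("retention at timepoint 0 must equal 1")
  }
  affected_kinds <- match.arg(affected_kinds, AGGREGATE_KINDS, several.ok = TRUE)
  structure(list(timepoints_min = timepoints_min, retention = retention,
                 affected_kinds = affected_kinds),
            class = "pk_model")
}

#' Simulate a proteinase-K digestion image series
#'
#' One image per timepoint. For aggregates of the affected kinds each
#' epitope's rasterised intensity is multiplied by its retention factor
#' before background and noise are added; timepoint 0 reproduces
#' [render_scene()] bit-exactly. Per-timepoint noise uses
#' `seed XOR timepoint-index` so series are reproducible yet independent
#' across timepoints while geometry stays registered.
#'
#' @param spec a [scene_spec()].
#' @param model a [pk_model()].
#' @return list with `timepoints_min`, `images` (list of
#'   [multiplex_image()]) and `ground_truths` (list of
#'   `scene_ground_truth`, carrying retention-scaled integrated
#'   intensities).
#' @export
simulate_pk_series <- function(spec, model) {
  stopifnot(inherits(spec, "scene_spec"), inherits(model, "pk_model"))
  tp <- model$timepoints_min
  images <- vector("list", length(tp))
  gts <- vector("list", length(tp))
  for (i in seq_along(tp)) {
    factors <- stats::setNames(rep(1, length(spec$epitopes)), spec$epitopes)
    for (e in names(model$retention)) {
      if (e %in% names(factors)) factors[[e]] <- model$retention[[e]][i]
    }
    out <- render_core(spec,
                       retention = list(factors = as.list(factors),
                                        kinds = model$affected_kinds),
                       noise_seed = bitwXor(spec$seed, i - 1L))
    images[[i]] <- out$image
    gts[[i]] <- out$ground_truth
  }
  list(timepoints_min = tp, images = images, ground_truths = gts)
}

# ---- random scene generation -----------------------------------------------

#' Draw a randomised mixed-pathology scene specification
#'
#' The default composition emulates a mixed region: Lewy bodies with
#' uniform N-terminus fill and pS129/C-terminus peripheral rings;
#' neurites split between triple-labelled, N-terminus-exclusive and
#' pS129-exclusive populations; punctate lysosomal and thin glial
#' aggregates labelled only in the N-terminus channel. Aggregates are
#' placed with rejection sampling so footprints stay inside the image and
#' do not touch.
#'
#' @param seed integer RNG seed (also becomes the scene seed).
#' @param shape image shape in pixels.
#' @param pixel_size_um pixel size; default 0.5 um/px.
#' @param n_lb,n_ln,n_punctate,n_glial aggregate counts per kind.
#' @param lb_diameter_um range of LB diameters (typical intracellular
#'   7-21 um; extracellular 40-55 um bodies can be requested explicitly).
#' @param ln_length_um,ln_thickness_um neurite length and thickness ranges.
#' @param punctate_diameter_um,glial_length_um size ranges for the
#'   N-terminus-exclusive populations.
#' @param noise_sigma,poisson_scale noise parameters passed to
#'   [scene_spec()].
#' @param monomer_background per-epitope background levels.
#' @return a [scene_spec()].
#' @export
random_scene_spec <- function(seed, shape = c(256L, 256L), pixel_size_um = 0.5,
                              n_lb = 3L, n_ln = 6L, n_punctate = 5L, n_glial = 2L,
                              lb_diameter_um = c(7, 21),
                              ln_length_um = c(8, 25),
                              ln_thickness_um = c(1, 2),
                              punctate_diameter_um = c(1, 2),
                              glial_length_um = c(8, 15),
                              noise_sigma = 2, poisson_scale = 0,
                              monomer_background = c(Nterm = 1, pS129 = 1, Cterm = 12)) {
  with_seed(seed, {
    placed <- list()   # list of c(row, col, reach_px)
    margin_px <- 4
    place <- function(reach_px) {
      lo_r <- 1 + reach_px + margin_px; hi_r <- shape[1L] - reach_px - margin_px
      lo_c <- 1 + reach_px + margin_px; hi_c <- shape[2L] - reach_px - margin_px
      if (lo_r >= hi_r || lo_c >= hi_c)
        stop_lq("aggregate too large for the image; increase shape")
      for (try in 1:400) {
        ctr <- c(stats::runif(1, lo_r, hi_r), stats::runif(1, lo_c, hi_c))
        ok <- TRUE
        for (p in placed) {
          if (sqrt(sum((ctr - p[1:2])^2)) < reach_px + p[3L] + 3) { ok <- FALSE; break }
        }
        if (ok || try == 400L) {
          # overlapping aggregates are legal; after exhausting separation
          # attempts fall back to any in-bounds position
          placed[[length(placed) + 1L]] <<- c(ctr, reach_px)
          return(ctr)
        }
      }
    }
    aggs <- list()
    for (i in seq_len(n_lb)) {
      d <- stats::runif(1, lb_diameter_um[1L], lb_diameter_um[2L])
      ctr <- place(d / 2 / pixel_size_um)
      aggs[[length(aggs) + 1L]] <- aggregate_spec(
        "lewy_body", ctr, d,
        epitope_profile = list(
          Nterm = list(pattern = "uniform", peak = stats::runif(1, 150, 200)),
          pS129 = list(pattern = "peripheral_ring", peak = stats::runif(1, 180, 230)),
          Cterm = list(pattern = "peripheral_ring", peak = stats::runif(1, 130, 180))))
    }
    ln_profiles <- function() {
      u <- stats::runif(1)
      pk <- function() stats::runif(1, 140, 210)
      if (u < 0.40) list(Nterm = list(pattern = "uniform", peak = pk()),
                         pS129 = list(pattern = "uniform", peak = pk()),
                         Cterm = list(pattern = "uniform", peak = pk()))
      else if (u < 0.65) list(Nterm = list(pattern = "uniform", peak = pk()))
      else if (u < 0.90) list(pS129 = list(pattern = "uniform", peak = pk()))
      else list(Nterm = list(pattern = "uniform", peak = pk()),
                pS129 = list(pattern = "uniform", peak = pk()))
    }
    for (i in seq_len(n_ln)) {
      len <- stats::runif(1, ln_length_um[1L], ln_length_um[2L])
      ctr <- place(len / 2 / pixel_size_um + 2)
      turn <- stats::runif(1, -1, 1)
      aggs[[length(aggs) + 1L]] <- aggregate_spec(
        "lewy_neurite", ctr, len, epitope_profile = ln_profiles(),
        thickness_um = stats::runif(1, ln_thickness_um[1L], ln_thickness_um[2L]),
        orientation = stats::runif(1, 0, 2 * pi),
        curvature = turn / (len / pixel_size_um),
        club = stats::runif(1) < 0.3)
    }
    for (i in seq_len(n_punctate)) {
      d <- stats::runif(1, punctate_diameter_um[1L], punctate_diameter_um[2L])
      ctr <- place(d / 2 / pixel_size_um + 1)
      aggs[[length(aggs) + 1L]] <- aggregate_spec(
        "punctate_lysosomal", ctr, d,
        epitope_profile = list(Nterm = list(pattern = "uniform",
                                            peak = stats::runif(1, 150, 210))))
    }
    for (i in seq_len(n_glial)) {
      len <- stats::runif(1, glial_length_um[1L], glial_length_um[2L])
      ctr <- place(len / 2 / pixel_size_um + 2)
      turn <- stats::runif(1, -0.8, 0.8)
      aggs[[length(aggs) + 1L]] <- aggregate_spec(
        "glial", ctr, len,
        epitope_profile = list(Nterm = list(pattern = "uniform",
                                            peak = stats::runif(1, 150, 210))),
        thickness_um = 1.2,
        orientation = stats::runif(1, 0, 2 * pi),
        curvature = turn / (len / pixel_size_um))
    }
    scene_spec(aggs, shape = shape, pixel_size_um = pixel_size_um,
               monomer_background = monomer_background,
               noise_sigma = noise_sigma, poisson_scale = poisson_scale,
               seed = seed)
  })
}

#' Expected morphology class for a simulated aggregate kind
#'
#' Mapping used by recovery tests: Lewy bodies map to `lewy_body`,
#' neuritic kinds (including glial threads) to `lewy_neurite`, lysosomal
#' puncta to `punctate`.
#'
#' @param kind aggregate kind string(s).
#' @return morphology class string(s).
#' @export
expected_morph_class <- function(kind) {
  unname(c(lewy_body = "lewy_body", lewy_neurite = "lewy_neurite",
           glial = "lewy_neurite", punctate_lysosomal = "punctate")[kind])
}
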