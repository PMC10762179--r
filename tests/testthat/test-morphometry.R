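test_that("connected-component labelling matches a flood-fill oracle", {
  # two disjoint discs -> 2 objects; touching discs merge under 8-connectivity
  m <- disc_mask(40, 60, 15, 15, 6) | disc_mask(40, 60, 15, 45, 6)
  expect_identical(max(label_components(m)), 2L)
  touching <- disc_mask(40, 60, 20, 20, 6) | disc_mask(40, 60, 20, 32, 6.5)
  expect_identical(max(label_components(touching)),
                   oracle_component_count(touching))
  set.seed(55)
  for (i in 1:15) {
    sp <- random_mask(18, 18, runif(1, 0.15, 0.5))
    lab <- label_components(sp)
    expect_identical(max(lab), oracle_component_count(sp))
    # labelling conserves foreground pixels
    expect_identical(sum(lab > 0L), sum(sp))
  }
  expect_identical(max(label_components(matrix(FALSE, 5, 5))), 0L)
})

test_that("descriptors: disc and bar have the expected shape statistics", {
  disc <- disc_mask(60, 60, 30, 30, 20)
  objs <- label_aggregates(disc, pixel_size_um = 0.5)
  expect_length(objs, 1)
  o <- classify_morphology(objs[[1]])
  expect_identical(o$morph_class, "lewy_body")
  expect_gt(o$circularity, 0.95)
  expect_lt(o$aspect_ratio, 1.1)
  # disc radius 10 px at 0.5 um/px -> equivalent diameter ~10 um
  d10 <- label_aggregates(disc_mask(40, 40, 20, 20, 10), pixel_size_um = 0.5)[[1]]
  expect_equal(unname(diameter_um(d10)["equivalent"]), 10, tolerance = 0.05)

  bar <- matrix(FALSE, 20, 80); bar[9:11, 11:70] <- TRUE  # 3 x 60 bar
  b <- classify_morphology(label_aggregates(bar)[[1]])
  expect_identical(b$morph_class, "lewy_neurite")
  expect_equal(b$aspect_ratio, 20, tolerance = 0.01)

  line <- matrix(FALSE, 10, 120); line[5, 11:110] <- TRUE  # 1 x 100 px line
  l <- label_aggregates(line, pixel_size_um = 1)[[1]]
  expect_equal(unname(diameter_um(l)["feret"]), 100, tolerance = 0.01)
  expect_equal(unname(diameter_um(l)["equivalent"]), 2 * sqrt(100 / pi),
               tolerance = 1e-6)
})

test_that("object areas conserve the union-mask foreground", {
  set.seed(8)
  sc <- render_scene(random_scene_spec(12, shape = c(128L, 128L), n_lb = 2L,
                                       n_ln = 3L, n_punctate = 2L, n_glial = 1L,
                                       noise_sigma = 0))
  um <- Reduce(`|`, lapply(sc$ground_truth$epitopes, gt_epitope_mask,
                           gt = sc$ground_truth))
  objs <- label_aggregates(um, pixel_size_um = 0.5, min_object_px = 1L)
  expect_identical(sum(vapply(objs, function(o) o$area_px, 0L)), sum(um))
  all_px <- sort(unlist(lapply(objs, function(o) o$pixel_idx)))
  expect_identical(all_px, sort(which(um)))  # no pixel lost or double-counted
})

test_that("descriptors are scale-equivariant in pixel size", {
  m <- disc_mask(50, 50, 25, 25, 12)
  o1 <- label_aggregates(m, pixel_size_um = 0.5)[[1]]
  o2 <- label_aggregates(m, pixel_size_um = 1.0)[[1]]
  expect_equal(o2$equivalent_diameter_um, 2 * o1$equivalent_diameter_um)
  expect_equal(o2$feret_diameter_um, 2 * o1$feret_diameter_um)
  expect_equal(o2$area_um2, 4 * o1$area_um2)
  expect_equal(o2$circularity, o1$circularity)
  expect_equal(o2$aspect_ratio, o1$aspect_ratio)
})

test_that("simulator fixtures classify to their ground-truth kinds", {
  hits <- 0L; total <- 0L
  for (seed in c(41, 42)) {
    spec <- random_scene_spec(seed, noise_sigma = 0)
    sc <- render_scene(spec)
    gt <- sc$ground_truth
    masks <- segment_image(sc$image, analysis_config())
    um <- Reduce(`|`, lapply(masks, function(m) m$mask))
    objs <- lapply(label_aggregates(um, 0.5, 5L), classify_morphology)
    for (o in objs) {
      ov <- vapply(gt$aggregates,
                   function(a) length(intersect(o$pixel_idx, a$footprint_px)), 0L)
      kind <- gt$aggregates[[which.max(ov)]]$kind
      total <- total + 1L
      if (identical(o$morph_class, expected_morph_class(kind))) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("morphology distribution shares are exact arithmetic", {
  mk <- function(cls, area) {
    structure(list(id = 1L, pixel_idx = seq_len(area), area_px = area,
                   morph_class = cls), class = "aggregate_object")
  }
  d <- morphology_distribution(list(mk("lewy_body", 100L), mk("lewy_neurite", 300L)))
  expect_equal(d$area_share_pct[["lewy_neurite"]], 75)
  expect_equal(d$area_share_pct[["lewy_body"]], 25)
  expect_equal(sum(d$area_share_pct), 100, tolerance = 1e-9)
  d2 <- morphology_distribution(list(mk("lewy_body", 50L), mk("lewy_body", 70L)))
  expect_equal(d2$area_share_pct[["lewy_body"]], 100)
  d0 <- morphology_distribution(list())
  expect_false(d0$defined)
  expect_true(all(is.na(d0$area_share_pct)))
})
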