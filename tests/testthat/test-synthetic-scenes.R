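test_that("aggregate and scene specs validate their invariants", {
  prof <- list(Nterm = list(pattern = "uniform", peak = 100))
  expect_error(aggregate_spec("lewy_body", c(10, 10), -3, prof), "size_um")
  expect_error(aggregate_spec("lewy_body", c(10, 10), 5,
                              list(Nterm = list(pattern = "absent"))),
               "at least one epitope")
  expect_error(aggregate_spec("lewy_body", c(10, 10), 5,
                              list(Nterm = list(pattern = "uniform", peak = 0))),
               "peak")
  a <- aggregate_spec("lewy_body", c(10, 10), 50, prof)  # extracellular range drawable
  expect_s3_class(a, "aggregate_spec")
  expect_error(scene_spec(a, pixel_size_um = 0), "pixel_size_um")
  expect_error(scene_spec(a, noise_sigma = -1), "noise_sigma")
  # footprint entirely outside the image is rejected at render time
  far <- aggregate_spec("lewy_body", c(500, 500), 10, prof)
  expect_error(render_scene(scene_spec(far, shape = c(64L, 64L))), "outside")
})

test_that("uniform patterns render identically across channels; absent stays background", {
  prof3 <- list(Nterm = list(pattern = "uniform", peak = 150),
                pS129 = list(pattern = "uniform", peak = 150),
                Cterm = list(pattern = "uniform", peak = 150))
  spec <- scene_spec(aggregate_spec("lewy_body", c(24, 24), 10, prof3),
                     shape = c(48L, 48L), noise_sigma = 0,
                     monomer_background = c(Nterm = 0, pS129 = 0, Cterm = 0),
                     seed = 2)
  sc <- render_scene(spec)
  foot <- sc$ground_truth$aggregates[[1]]$footprint_px
  for (e in c("Nterm", "pS129", "Cterm")) {
    ch <- sc$image$channels[[e]]
    expect_true(all(ch[foot] == 150))
    expect_true(all(ch[-foot] == 0))
  }
  # neurite labelled only N-terminus: other channels are pure background
  spec2 <- scene_spec(aggregate_spec("lewy_neurite", c(24, 24), 10,
                                     list(Nterm = list(pattern = "uniform", peak = 120)),
                                     thickness_um = 1.5),
                      shape = c(48L, 48L), noise_sigma = 0, seed = 3)
  sc2 <- render_scene(spec2)
  expect_true(all(sc2$image$channels$pS129 == spec2$monomer_background[["pS129"]]))
  expect_true(all(sc2$image$channels$Cterm == spec2$monomer_background[["Cterm"]]))
  expect_gt(max(sc2$image$channels$Nterm), 100)
})

test_that("rendering is bit-identical under a fixed seed", {
  spec <- random_scene_spec(99, shape = c(96L, 96L), n_lb = 1L, n_ln = 2L,
                            n_punctate = 2L, n_glial = 1L, poisson_scale = 0.5)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$ground_truth$aggregates, b$ground_truth$aggregates)
  # and a different seed changes the noise
  spec2 <- random_scene_spec(100, shape = c(96L, 96L), n_lb = 1L, n_ln = 2L,
                             n_punctate = 2L, n_glial = 1L)
  expect_false(identical(render_scene(spec2)$image$channels, a$image$channels))
})

test_that("peripheral ring pixels concentrate in the outer annulus", {
  spec <- scene_spec(aggregate_spec(
    "lewy_body", c(40, 40), 20,
    epitope_profile = list(Nterm = list(pattern = "uniform", peak = 150),
                           pS129 = list(pattern = "peripheral_ring", peak = 200))),
    shape = c(80L, 80L), pixel_size_um = 0.5, noise_sigma = 0, seed = 4)
  sc <- render_scene(spec)
  gt <- sc$ground_truth$aggregates[[1]]
  ring <- gt$epitope_px$pS129
  expect_gt(length(ring), 0)
  nr <- 80
  r <- ((ring - 1) %% nr) + 1; c <- ((ring - 1) %/% nr) + 1
  d <- sqrt((r - 40)^2 + (c - 40)^2)
  R_px <- 20 / 2 / 0.5
  expect_gte(mean(d >= 0.75 * R_px), 0.9)   # >= 90% in the outer 25% annulus
  expect_true(all(ring %in% gt$footprint_px))
})

test_that("expected_report is an exact per-pixel oracle and satisfies additivity", {
  # toy composition: one N-only aggregate -> unique_N = 100%
  sc1 <- render_scene(scene_spec(
    aggregate_spec("punctate_lysosomal", c(20, 20), 3,
                   list(Nterm = list(pattern = "uniform", peak = 150))),
    shape = c(40L, 40L), noise_sigma = 0, seed = 1,
    epitopes = c("Nterm", "pS129", "Cterm")))
  r1 <- expected_report(sc1$ground_truth)
  expect_equal(r1$unique_pct[["Nterm"]], 100)
  expect_equal(r1$overlap_pct, 0)
  # identical labelling in all channels -> overlap = 100%
  prof3 <- list(Nterm = list(pattern = "uniform", peak = 100),
                pS129 = list(pattern = "uniform", peak = 100),
                Cterm = list(pattern = "uniform", peak = 100))
  sc2 <- render_scene(scene_spec(aggregate_spec("lewy_body", c(20, 20), 8, prof3),
                                 shape = c(40L, 40L), noise_sigma = 0, seed = 1))
  r2 <- expected_report(sc2$ground_truth)
  expect_equal(r2$overlap_pct, 100)
  expect_true(all(r2$unique_pct == 0))
  # randomised scenes: additivity exact, matches epitope_algebra on gt masks
  for (seed in c(6, 16)) {
    sc <- render_scene(random_scene_spec(seed, shape = c(128L, 128L), n_lb = 2L,
                                         n_ln = 3L, n_punctate = 2L, n_glial = 1L))
    er <- expected_report(sc$ground_truth)
    expect_identical(er$total_area_px, sum(er$unique_area_px) + er$overlap_area_px)
    gt_masks <- stats::setNames(
      lapply(sc$ground_truth$epitopes, gt_epitope_mask, gt = sc$ground_truth),
      sc$ground_truth$epitopes)
    ar <- epitope_report(gt_masks, pixel_size_um = sc$ground_truth$pixel_size_um)
    expect_identical(er$total_area_px, ar$total_area_px)
    expect_equal(unname(er$unique_area_px), unname(ar$unique_area_px))
    expect_identical(er$overlap_area_px, ar$overlap_area_px)
    # every ground-truth pixel lies inside the image
    npx <- prod(sc$ground_truth$dim)
    for (a in sc$ground_truth$aggregates)
      expect_true(all(a$footprint_px >= 1 & a$footprint_px <= npx))
  }
  # empty ground truth -> zero areas, flagged undefined
  gt0 <- structure(list(dim = c(10L, 10L), pixel_size_um = 1,
                        epitopes = "Nterm", region_mask = NULL,
                        aggregates = list(), seed = 0L),
                   class = "scene_ground_truth")
  r0 <- expected_report(gt0)
  expect_identical(r0$total_area_px, 0L)
  expect_false(r0$percent_defined)
})

test_that("PK series: retention scaling, unmasking, t0 identity and monotone decay", {
  spec <- scene_spec(
    aggregate_spec("glial", c(24, 24), 10,
                   list(Nterm = list(pattern = "uniform", peak = 160)),
                   thickness_um = 1.5),
    shape = c(48L, 48L), noise_sigma = 0,
    monomer_background = c(Nterm = 0, pS129 = 0, Cterm = 0), seed = 8,
    epitopes = c("Nterm", "pS129", "Cterm"))
  model <- pk_model(c(0, 15, 30), retention = list(Nterm = c(1, 1.2, 0.5)),
                    affected_kinds = "glial")
  ser <- simulate_pk_series(spec, model)
  base <- render_scene(spec)
  expect_identical(ser$images[[1]]$channels, base$image$channels)   # t0 identity
  foot <- base$ground_truth$aggregates[[1]]$footprint_px
  expect_equal(max(ser$images[[2]]$channels$Nterm[foot]), 160 * 1.2) # unmasking
  expect_equal(max(ser$images[[3]]$channels$Nterm[foot]), 160 * 0.5) # halving
  expect_true(all(ser$images[[3]]$channels$pS129 == 0))              # others untouched
  # monotone ground-truth intensity under non-increasing retention
  model2 <- pk_model(c(0, 15, 30, 60), retention = list(Nterm = c(1, 0.9, 0.6, 0.3)),
                     affected_kinds = "glial")
  ser2 <- simulate_pk_series(spec, model2)
  sums <- vapply(ser2$ground_truths,
                 function(g) g$aggregates[[1]]$intensity_sum[["Nterm"]], 0)
  expect_true(all(diff(sums) <= 0))
  # invalid models rejected
  expect_error(pk_model(c(5, 15), list()), "start at 0")
  expect_error(pk_model(c(0, 15), retention = list(Nterm = c(0.9, 1))), "equal 1")
  expect_error(pk_model(c(0, 15), retention = list(Nterm = c(1, -0.1))), ">= 0")
  # all-ones retention: same per-timepoint seed policy gives a reproducible series
  model3 <- pk_model(c(0, 15), retention = list(), affected_kinds = "glial")
  s1 <- simulate_pk_series(spec, model3)
  s2 <- simulate_pk_series(spec, model3)
  expect_identical(s1$images[[2]]$channels, s2$images[[2]]$channels)
})
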