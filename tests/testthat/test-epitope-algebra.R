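test_that("toy interval masks decompose exactly (per-pixel oracle fixture)", {
  m <- toy_interval_masks()
  # brute-force enumeration: total 20, unique A/B/C = 5/0/5, overlap 10
  orc <- oracle_algebra(m)
  expect_identical(orc$total, 20L)
  expect_identical(unname(orc$unique), c(5L, 0L, 5L))
  expect_identical(orc$overlap, 10L)
  expect_identical(total_area(m), 20L)
  expect_identical(unique_area(m, "A"), 5L)
  expect_identical(unique_area(m, "B"), 0L)
  expect_identical(unique_area(m, "C"), 5L)
  expect_identical(overlap_area(m), 10L)
  expect_error(unique_area(m, "D"), "unknown epitope")
})

test_that("degenerate mask combinations behave per definition", {
  full <- matrix(TRUE, 7, 10)
  empty <- matrix(FALSE, 7, 10)
  ident <- list(N = full, P = full, C = full)
  expect_identical(total_area(list(N = full)), 70L)
  expect_identical(overlap_area(ident), 70L)
  expect_true(all(vapply(names(ident), unique_area, 0L, masks = ident) == 0L))
  expect_identical(unique_area(list(N = empty, P = full), "N"), 0L)
  disjoint <- list(A = rbind(matrix(TRUE, 3, 10), matrix(FALSE, 4, 10)),
                   B = rbind(matrix(FALSE, 3, 10), matrix(TRUE, 4, 10)))
  expect_identical(total_area(disjoint), 70L)
  expect_identical(overlap_area(disjoint), 0L)
  expect_error(total_area(list(a = matrix(TRUE, 2, 2), b = matrix(TRUE, 3, 3))),
               "co-registered")
})

test_that("algebra invariants hold on random masks (property sweep)", {
  set.seed(404)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    masks <- stats::setNames(replicate(k, random_mask(12, 12, runif(1, 0.1, 0.6)),
                                       simplify = FALSE), LETTERS[1:k])
    orc <- oracle_algebra(masks)
    tot <- total_area(masks)
    uniq <- vapply(names(masks), unique_area, 0L, masks = masks)
    ovl <- overlap_area(masks)
    # additivity + oracle identity
    expect_identical(tot, orc$total)
    expect_identical(unname(uniq), unname(orc$unique))
    expect_identical(ovl, orc$overlap)
    expect_identical(tot, sum(uniq) + ovl)
    # permutation symmetry
    perm <- sample(names(masks))
    expect_identical(total_area(masks[perm]), tot)
    expect_identical(overlap_area(masks[perm]), ovl)
    expect_identical(unname(vapply(perm, unique_area, 0L, masks = masks[perm])),
                     unname(uniq[perm]))
    # monotonicity: growing one mask never decreases the total
    grown <- masks
    add <- random_mask(12, 12, 0.2)
    grown[[1L]] <- grown[[1L]] | add
    expect_gte(total_area(grown), tot)
  }
})

test_that("epitope_report assembles percentages, units and pathology load", {
  nr <- 100; nc <- 100
  m <- matrix(FALSE, nr, nc); m[1:10, 1:20] <- TRUE   # 200 px
  rep1 <- epitope_report(list(Nterm = m,
                              pS129 = matrix(FALSE, nr, nc),
                              Cterm = matrix(FALSE, nr, nc)),
                         pixel_size_um = 1)
  expect_equal(rep1$unique_pct[["Nterm"]], 100)
  expect_equal(rep1$overlap_pct, 0)
  expect_equal(rep1$pathology_load_pct, 2.0)
  # unit conversion: 100 px at 0.1 um/px -> 1.0 um2
  m2 <- matrix(FALSE, 50, 50); m2[1:10, 1:10] <- TRUE
  rep2 <- epitope_report(list(N = m2), pixel_size_um = 0.1)
  expect_equal(rep2$total_area_um2, 1.0)
  # zero total -> flagged undefined, load 0
  rep0 <- epitope_report(list(N = matrix(FALSE, 5, 5)), pixel_size_um = 1)
  expect_false(rep0$percent_defined)
  expect_true(is.na(rep0$overlap_pct))
  expect_equal(rep0$pathology_load_pct, 0)
  expect_error(epitope_report(list(N = m2), region_mask = matrix(FALSE, 50, 50)),
               "zero region")
  # percentage closure
  set.seed(5)
  masks <- list(N = random_mask(20, 20), P = random_mask(20, 20),
                C = random_mask(20, 20))
  r <- epitope_report(masks)
  expect_equal(sum(r$unique_pct) + r$overlap_pct, 100, tolerance = 1e-9)
})

test_that("aggregate_composition equals the oracle on object footprints", {
  set.seed(31)
  masks <- list(N = random_mask(15, 15, 0.5), P = random_mask(15, 15, 0.5),
                C = random_mask(15, 15, 0.5))
  for (i in 1:20) {
    px <- sample(225, sample(5:40, 1))
    comp <- aggregate_composition(px, masks)
    clipped <- lapply(masks, function(m) { f <- matrix(FALSE, 15, 15); f[px] <- TRUE; m & f })
    orc <- oracle_algebra(clipped)
    expect_identical(comp$total_area_px, orc$total)
    expect_identical(unname(comp$unique_area_px), unname(orc$unique))
    expect_identical(comp$overlap_area_px, orc$overlap)
  }
  # object fully inside all masks -> overlap 100%; single-mask object -> unique 100%
  full <- matrix(TRUE, 15, 15)
  none <- matrix(FALSE, 15, 15)
  c1 <- aggregate_composition(1:30, list(N = full, P = full, C = full))
  expect_equal(c1$overlap_pct, 100)
  c2 <- aggregate_composition(1:30, list(N = none, P = full, C = none))
  expect_equal(c2$unique_pct[["P"]], 100)
})
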