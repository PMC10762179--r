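test_that("OME-TIFF round trip is the identity up to 16-bit quantisation", {
  set.seed(14)
  img <- multiplex_image(
    list(Nterm = matrix(runif(18 * 25, 0, 300), 18, 25),
         pS129 = matrix(runif(18 * 25, 0, 300), 18, 25),
         Cterm = matrix(runif(18 * 25, 0, 300), 18, 25)),
    pixel_size_um = 0.1)
  tf <- withr::local_tempfile(fileext = ".ome.tiff")
  write_multiplex(img, tf)
  back <- read_multiplex(tf)
  expect_identical(names(back$channels), names(img$channels))
  expect_equal(back$pixel_size_um, 0.1)   # pixel size from metadata
  for (e in names(img$channels)) {
    expect_lte(max(abs(back$channels[[e]] - img$channels[[e]])), 0.5)
    expect_identical(back$channels[[e]], round(img$channels[[e]]))
  }
})

test_that("channel maps are validated against the file", {
  img <- multiplex_image(list(A = matrix(1, 6, 6), B = matrix(2, 6, 6),
                              C = matrix(3, 6, 6)), 1)
  tf <- withr::local_tempfile(fileext = ".tiff")
  write_multiplex(img, tf)
  expect_error(read_multiplex(tf, channel_map = c(Nterm = 5L)),
               "channel 5 of a 3-channel")
  remapped <- read_multiplex(tf, channel_map = c(x = 2L, y = 1L))
  expect_equal(remapped$channels$x[1, 1], 2)
  expect_error(read_multiplex(withr::local_tempfile(fileext = ".tiff")),
               "not found")
  # pixel size absent from both metadata and config -> error
  write_tiff(tf, list(matrix(1, 6, 6)))
  expect_error(read_multiplex(tf, channel_map = c(N = 1L)), "pixel size")
  expect_equal(read_multiplex(tf, channel_map = c(N = 1L),
                              pixel_size_um = 0.25)$pixel_size_um, 0.25)
})

test_that("python tifffile reads our OME-TIFF identically (external oracle)", {
  img <- multiplex_image(list(Nterm = matrix(seq_len(60) * 3, 6, 10),
                              pS129 = matrix(seq_len(60) * 5, 6, 10)), 0.5)
  tf <- withr::local_tempfile(fileext = ".ome.tiff")
  write_multiplex(img, tf)
  out <- withr::local_tempfile(fileext = ".txt")
  script <- sprintf(paste0(
    "import tifffile, numpy as np\n",
    "a = tifffile.imread('%s')\n",
    "print(a.shape[0], a.shape[1], a.shape[2], int(a.sum()), int(a[0,3,4]), int(a[1,5,9]))\n"),
    tf)
  status <- suppressWarnings(system2("python", "-", stdout = out, input = script))
  skip_if(status != 0L, "python/tifffile unavailable")
  vals <- scan(out, what = numeric(), quiet = TRUE)
  expect_equal(vals[1:3], c(2, 6, 10))
  expect_equal(vals[4], sum(img$channels$Nterm) + sum(img$channels$pS129))
  expect_equal(vals[5], img$channels$Nterm[4, 5])   # row-major [3,4] == R [4,5]
  expect_equal(vals[6], img$channels$pS129[6, 10])
})

test_that("report CSVs are stable and round-trip numerically", {
  m <- matrix(FALSE, 50, 50); m[1:10, 1:10] <- TRUE
  rep1 <- epitope_report(list(Nterm = m, pS129 = matrix(FALSE, 50, 50),
                              Cterm = matrix(FALSE, 50, 50)),
                         pixel_size_um = 0.5, case_id = "caseA",
                         region_label = "SN")
  tf <- withr::local_tempfile(fileext = ".csv")
  write_report(rep1, tf)
  back <- utils::read.csv(tf)
  expect_equal(back$unique_Nterm_pct, 100)
  expect_equal(back$total_area_px, 100)
  expect_equal(back$total_area_um2, 25)
  expect_equal(back$pathology_load_pct, 4)
  expect_identical(back$case_id, "caseA")
  # empty report list -> header-only CSV
  write_report(list(), tf)
  empty <- utils::read.csv(tf)
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("case_id", "unique_Nterm_pct", "overlap_pct",
                    "pathology_load_pct") %in% names(empty)))
})

test_that("scene export writes image, labels and manifest", {
  sc <- render_scene(random_scene_spec(3, shape = c(96L, 96L), n_lb = 1L,
                                       n_ln = 2L, n_punctate = 1L, n_glial = 0L))
  dir <- withr::local_tempdir()
  paths <- write_scene(sc, dir, prefix = "s3")
  expect_true(all(file.exists(unlist(paths))))
  man <- utils::read.csv(paths$manifest)
  expect_identical(nrow(man), length(sc$ground_truth$aggregates))
  lab <- read_tiff(paths$gt_Nterm)$pages[[1]]
  ids <- sort(unique(lab[lab > 0]))
  gt_ids <- vapply(sc$ground_truth$aggregates, function(a)
    if (length(a$epitope_px$Nterm)) a$id else NA_integer_, 0L)
  expect_identical(as.integer(ids), sort(gt_ids[!is.na(gt_ids)]))
})

test_that("JSON configs load with validation", {
  tf <- withr::local_tempfile(fileext = ".json")
  writeLines('{"blur_sigma_px": 10, "channel_map": "1=Nterm,2=pS129,3=Cterm",
              "min_object_px": 8}', tf)
  cfg <- read_analysis_config(tf)
  expect_equal(cfg$blur_sigma_px, 10)
  expect_identical(cfg$min_object_px, 8L)
  expect_identical(cfg$channel_map, c(Nterm = 1L, pS129 = 2L, Cterm = 3L))
  writeLines('{"alpha": 2}', tf)
  expect_error(read_analysis_config(tf), "alpha")
  writeLines('{"bogus_key": 1}', tf)
  expect_error(read_analysis_config(tf), "unknown config keys")
})
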