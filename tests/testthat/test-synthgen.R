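# Synthetic scene and cohort generation: determinism, containment,
# parameter fidelity, placement failure.

test_that("empty scene has all-zero masks and empty truth", {
  s <- generate_scene(morphology_distribution(), 0, c(64, 64), seed = 1)
  expect_true(all(s$masks$cell == 0L) && all(s$masks$nucleus == 0L))
  expect_equal(nrow(s$truth), 0L)
  expect_true(s$is_benign)
})

test_that("scenes are bit-identical under the same seed", {
  d <- morphology_distribution()
  s1 <- generate_scene(d, 15, c(450, 450), seed = 7)
  s2 <- generate_scene(d, 15, c(450, 450), seed = 7)
  expect_identical(s1$masks$cell, s2$masks$cell)
  expect_identical(s1$masks$nucleus, s2$masks$nucleus)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_scene(d, 15, c(450, 450), seed = 8)
  expect_false(identical(s1$masks$cell, s3$masks$cell))
})

test_that("every nucleus is contained in its cell and shares its label", {
  d <- morphology_distribution()
  for (seed in c(3, 14, 15)) {
    s <- generate_scene(d, 20, c(512, 512), seed = seed)
    nid <- s$masks$nucleus[s$masks$nucleus > 0L]
    cid <- s$masks$cell[s$masks$nucleus > 0L]
    expect_true(all(nid == cid))  # containment + label sharing at once
    expect_true(all(s$truth$sn >= 1))
    # disjoint cells: every positive pixel carries exactly one label
    expect_equal(sum(tabulate(s$masks$cell[s$masks$cell > 0])),
                 sum(s$truth$sc))
  }
})

test_that("degenerate distributions produce the configured morphology", {
  # fixed-area cells: every measured SC within 3% of 2000
  d <- morphology_distribution(cell_area_mean = 2000, cell_area_sd = 0)
  s <- generate_scene(d, 50, c(1500, 1500), seed = 21)
  f <- extract_features(s$masks)
  expect_true(all(abs(f$SC - 2000) / 2000 < 0.03))
  # near-circular single cell: measured EP within 0.05 of 1
  dc <- morphology_distribution(aspect_ratio_mean = 1, aspect_ratio_sd = 0)
  sc <- generate_scene(dc, 1, c(200, 200), seed = 22)
  expect_lt(abs(ellipticity(sc$masks$cell) - 1), 0.05)
})

test_that("impossible placement fails with the achieved count", {
  d <- morphology_distribution(cell_area_mean = 500, cell_area_sd = 0)
  expect_error(
    generate_scene(d, 50, c(60, 60), seed = 5, max_rejections = 30),
    "placed \\d+ of 50")
  expect_error(morphology_distribution(cell_area_mean = -5), "positive")
  expect_error(morphology_distribution(ncr_mean = 1.2), "ncr_mean")
})

test_that("cohorts are reproducible and carry one covariate row per slide", {
  gs <- list(A = morphology_distribution(), B = morphology_distribution())
  co <- generate_cohort(gs, slides_per_group = 2, cells_per_slide = 30,
                        seed = 9, image_shape = c(512, 512))
  expect_equal(nrow(co$covariates), 4L)
  expect_equal(co$covariates$ln_status, c(0L, 0L, 1L, 1L))
  co2 <- generate_cohort(gs, slides_per_group = 2, cells_per_slide = 30,
                         seed = 9, image_shape = c(512, 512))
  expect_identical(co$truth, co2$truth)
  expect_identical(co$scenes[["B_s02"]]$masks, co2$scenes[["B_s02"]]$masks)
  # single group, single slide -> exactly one covariate row
  co1 <- generate_cohort(list(G = morphology_distribution()), 1, 30,
                         seed = 2, image_shape = c(512, 512))
  expect_equal(nrow(co1$covariates), 1L)
  expect_error(generate_cohort(list(morphology_distribution()), 1, 5),
               "names")
  expect_error(
    generate_cohort(list(A = morphology_distribution(),
                         A = morphology_distribution()), 1, 5, seed = 1,
                    image_shape = c(256, 256)),
    "distinct|duplicate")
})

test_that("truth-level effect sizes equal the configured values", {
  gs <- list(A = morphology_distribution(cell_area_mean = 2000),
             B = morphology_distribution(cell_area_mean = 3000))
  co <- generate_cohort(gs, slides_per_group = 6, cells_per_slide = 2000,
                        seed = 13, render = FALSE)
  m <- tapply(co$truth$area_param, co$truth$group, mean)
  expect_equal(unname(m["B"] / m["A"]), 1.5, tolerance = 0.03)
  expect_null(co$scenes)
})

test_that("slide_jitter perturbs per-slide parameters around the group value", {
  gs <- list(A = morphology_distribution(aspect_ratio_sd = 0.08))
  co <- generate_cohort(gs, slides_per_group = 12, cells_per_slide = 10,
                        seed = 31, render = FALSE,
                        slide_jitter = c(aspect_ratio_sd = 0.03))
  sds <- co$slide_params$aspect_ratio_sd
  expect_gt(stats::sd(sds), 0.005)      # jitter present
  expect_lt(abs(mean(sds) - 0.08), 0.03)  # centered on the group value
  co0 <- generate_cohort(gs, slides_per_group = 12, cells_per_slide = 10,
                         seed = 31, render = FALSE)
  expect_true(all(co0$slide_params$aspect_ratio_sd == 0.08))
})

test_that("cohort artifacts are written to disk when out_dir is given", {
  tdir <- withr::local_tempdir()
  generate_cohort(list(A = morphology_distribution()), 1, 20, seed = 4,
                  image_shape = c(400, 400), out_dir = tdir)
  expect_true(all(file.exists(file.path(
    tdir, c("covariates.csv", "truth.csv", "slide_params.csv", "config.yaml",
            "A_s01_cell.tif", "A_s01_nucleus.tif")))))
  rt <- read_masks(file.path(tdir, "A_s01_cell.tif"),
                   file.path(tdir, "A_s01_nucleus.tif"))
  expect_equal(length(unique(rt$cell[rt$cell > 0])), 20L)
})
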