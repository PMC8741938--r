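# Per-cell feature extraction: areas, min-area rectangle, ellipticity,
# nucleus assignment.

block_mask <- function(nr, nc, r, cc) {
  m <- matrix(0L, nr, nc)
  m[r, cc] <- 1L
  m
}

test_that("cell_area counts pixels exactly and rejects empty masks", {
  expect_equal(cell_area(block_mask(30, 40, 10:19, 5:24)), 200L)
  expect_equal(cell_area(block_mask(5, 5, 3, 3)), 1L)
  expect_error(cell_area(matrix(0L, 4, 4)), "empty")
  # rasterized disk, radius 20: pixel count within 2% of pi r^2
  disk <- raster_ellipse_oracle(20, 20, 0)
  expect_lt(abs(cell_area(disk) - pi * 400) / (pi * 400), 0.02)
})

test_that("min_area_rect matches the pixel-extent convention on axis-aligned shapes", {
  r <- min_area_rect(block_mask(30, 40, 10:19, 5:24))  # 10 x 20 block
  expect_equal(unname(r$size), c(20, 10))
  expect_equal(min(r$size), 10)
  # never exceeds the axis-aligned bounding box area
  expect_lte(r$area, 20 * 10 + 1e-9)
  expect_equal(unname(min_area_rect(block_mask(7, 7, 4, 4))$size), c(1, 1))
  # collinear mask: short side 1 by convention
  lin <- block_mask(10, 10, 5, 2:9)
  expect_equal(unname(min_area_rect(lin)$size), c(8, 1))
  expect_error(min_area_rect(matrix(0L, 3, 3)), "empty")
})

test_that("rotated rectangle recovers area and angle after rasterization", {
  # 10 x 20 rectangle rotated 30 degrees, rasterized on pixel centers
  # (half-extents 9.5 / 4.5: a w-px-wide block spans w - 1 pixel centers)
  phi <- 30 * pi / 180
  n <- 61; cy <- cx <- 31
  m <- matrix(0L, n, n)
  for (r in 1:n) for (cc in 1:n) {
    u <- (cc - cx) * cos(phi) + (r - cy) * sin(phi)
    v <- (r - cy) * cos(phi) - (cc - cx) * sin(phi)
    if (abs(u) <= 9.5 && abs(v) <= 4.5) m[r, cc] <- 1L
  }
  rect <- min_area_rect(m)
  expect_lt(abs(rect$area - 200) / 200, 0.05)
  expect_lt(min(abs(rect$angle - 30), abs(rect$angle - 150)), 3)
})

test_that("ellipticity is short/long, 1 for round shapes, rotation invariant", {
  expect_equal(ellipticity(block_mask(30, 40, 10:19, 5:24)), 0.5)
  expect_equal(ellipticity(block_mask(5, 5, 3, 3)), 1.0)
  disk <- raster_ellipse_oracle(15, 15, 0)
  expect_lt(abs(ellipticity(disk) - 1), 0.05)
  set.seed(61)
  for (k in 1:10) {
    m <- random_blob_mask()
    ep <- ellipticity(m)
    expect_gt(ep, 0); expect_lte(ep, 1)
    expect_equal(ellipticity(t(m)[ncol(m):1, , drop = FALSE]), ep,
                 tolerance = 1e-12)  # 90-degree rotation
    # translation: embed in a larger canvas with an offset
    big <- matrix(0L, nrow(m) + 13, ncol(m) + 7)
    big[13 + seq_len(nrow(m)), 7 + seq_len(ncol(m))] <- m
    expect_equal(ellipticity(big), ep, tolerance = 1e-12)
    expect_equal(cell_area(big), cell_area(m))
  }
})

test_that("calipers rectangle agrees with the brute-force angle sweep", {
  set.seed(71)
  for (k in 1:40) {
    pts <- random_convex_polygon(sample(8:30, 1))
    ours <- min_area_rect_points(pts)$area
    orc <- oracle_min_rect(pts)
    expect_lte(ours, orc$coarse_min + 1e-9)
    expect_lt(abs(ours - orc$refined_min) / orc$refined_min, 1e-6)
  }
})

test_that("min-area rectangle never exceeds the axis-aligned bbox on random blobs", {
  set.seed(81)
  for (k in 1:50) {
    m <- random_blob_mask()
    pts <- which(m != 0, arr.ind = TRUE)
    aabb <- (diff(range(pts[, 1])) + 1) * (diff(range(pts[, 2])) + 1)
    expect_lte(min_area_rect(m)$area, aabb + 1e-9)
  }
})

test_that("nucleus assignment picks the largest intersection, ties to smallest id", {
  cellm <- matrix(0L, 20, 30)
  cellm[3:14, 3:22] <- 1L
  nucm <- matrix(0L, 20, 30)
  nucm[5:10, 4:8] <- 1L    # n1: 30 px inside the cell
  nucm[5:14, 12:16] <- 2L  # n2: 50 px inside the cell
  a <- assign_nuclei(instance_masks(cellm, nucm))
  expect_equal(a$nucleus_id, 2L)
  expect_equal(a$overlap, 50L)
  # tie: equal intersections -> smaller id
  nucm2 <- matrix(0L, 20, 30)
  nucm2[5:9, 4:9] <- 3L
  nucm2[5:9, 12:17] <- 1L
  a2 <- assign_nuclei(instance_masks(cellm, nucm2))
  expect_equal(a2$nucleus_id, 1L)
  # no overlapping nucleus -> NA
  far <- matrix(0L, 20, 30); far[17:19, 25:29] <- 1L
  a3 <- assign_nuclei(instance_masks(cellm, far))
  expect_true(is.na(a3$nucleus_id))
})

test_that("extract_features reproduces the hand-enumerated fixture", {
  cellm <- matrix(0L, 15, 15); cellm[4:12, 4:12] <- 1L
  nucm <- matrix(0L, 15, 15); nucm[6:8, 6:8] <- 1L
  f <- extract_features(instance_masks(cellm, nucm))
  expect_equal(f$SC, 81L)
  expect_equal(f$SN, 9L)
  expect_equal(f$NCR, 1 / 9)
  expect_equal(f$row, 8); expect_equal(f$col, 8)
  expect_equal(f$EP, 1.0)
  # empty masks -> empty record list
  e <- extract_features(instance_masks(matrix(0L, 5, 5), matrix(0L, 5, 5)))
  expect_equal(nrow(e), 0L)
  # cell without nucleus keeps SC/EP, nulls SN/NCR
  f2 <- extract_features(instance_masks(cellm, matrix(0L, 15, 15)))
  expect_equal(f2$SC, 81L)
  expect_true(is.na(f2$SN) && is.na(f2$NCR))
})

test_that("NCR lies in (0, 1] whenever the nucleus is contained in the cell", {
  set.seed(91)
  d <- morphology_distribution()
  s <- generate_scene(d, 12, c(450, 450))
  f <- extract_features(s$masks)
  expect_equal(nrow(f), 12L)
  expect_true(all(!is.na(f$NCR)))
  expect_true(all(f$NCR > 0 & f$NCR <= 1))
})

test_that("pixel areas convert to square micrometers", {
  expect_equal(pixels_to_um2(1000), 1000 * 0.238^2)
  expect_equal(pixels_to_um2(100, pixel_size = 1), 100)
})
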