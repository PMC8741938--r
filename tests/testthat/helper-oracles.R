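# Independent oracles and fixture builders. Everything here is deliberately
# brute-force / enumeration code that shares no logic with the package
# internals it checks.

# ---- minimum-area rectangle: angle-sweep oracle -----------------------------

# enclosing-rectangle area of a point set at each rotation angle (radians)
rect_area_at_angles <- function(pts, th) {
  x <- pts[, 2]; y <- pts[, 1]
  vapply(th, function(t) {
    u <- x * cos(t) + y * sin(t)
    v <- y * cos(t) - x * sin(t)
    (max(u) - min(u)) * (max(v) - min(v))
  }, numeric(1))
}

# coarse 0.1-degree sweep over [0, 90) plus local refinement around the
# coarse argmin (the area-angle function has kinks, so the refinement is
# what pins the minimum to ~1e-7 relative)
oracle_min_rect <- function(pts, coarse_deg = 0.1) {
  coarse <- seq(0, 90 - coarse_deg, by = coarse_deg) * pi / 180
  a_coarse <- rect_area_at_angles(pts, coarse)
  i <- which.min(a_coarse)
  lo <- coarse[i] - coarse_deg * pi / 180
  hi <- coarse[i] + coarse_deg * pi / 180
  fine <- seq(lo, hi, length.out = 4001)
  a_fine <- rect_area_at_angles(pts, fine)
  for (pass in 1:2) {  # second refinement pass: ~1e-8 deg resolution
    j <- which.min(a_fine)
    lo <- fine[max(1, j - 1)]; hi <- fine[min(length(fine), j + 1)]
    fine <- seq(lo, hi, length.out = 4001)
    a_fine <- rect_area_at_angles(pts, fine)
  }
  list(coarse_min = min(a_coarse), refined_min = min(a_fine))
}

# random convex polygon: convex hull vertices of n random points in a box
random_convex_polygon <- function(n = 20, span = 50) {
  x <- stats::runif(n, 0, span); y <- stats::runif(n, 0, span)
  h <- grDevices::chull(x, y)
  cbind(row = y[h], col = x[h])
}

# ---- rasterization oracle ---------------------------------------------------

# pixel-center-in-ellipse rasterizer, written independently of the
# generator's internals
raster_ellipse_oracle <- function(a, b, phi, pad = 4) {
  half <- ceiling(max(a, b)) + pad
  n <- 2 * half + 1
  cy <- cx <- half + 1
  m <- matrix(0L, n, n)
  for (r in 1:n) for (cc in 1:n) {
    dy <- r - cy; dx <- cc - cx
    u <- dx * cos(phi) + dy * sin(phi)
    v <- dy * cos(phi) - dx * sin(phi)
    if ((u / a)^2 + (v / b)^2 <= 1) m[r, cc] <- 1L
  }
  m
}

# random compact blob mask: union of a few overlapping disks
random_blob_mask <- function(size = 60, n_disks = 3) {
  m <- matrix(0L, size, size)
  cx0 <- stats::runif(1, size * 0.35, size * 0.65)
  cy0 <- stats::runif(1, size * 0.35, size * 0.65)
  for (k in seq_len(n_disks)) {
    r <- stats::runif(1, 4, 10)
    cy <- cy0 + stats::runif(1, -6, 6); cx <- cx0 + stats::runif(1, -6, 6)
    for (rr in max(1, floor(cy - r)):min(size, ceiling(cy + r)))
      for (cc in max(1, floor(cx - r)):min(size, ceiling(cx + r)))
        if ((rr - cy)^2 + (cc - cx)^2 <= r^2) m[rr, cc] <- 1L
  }
  m
}

# ---- Youden: exhaustive threshold search ------------------------------------

oracle_youden <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  cand <- sort(unique(scores))
  cand <- sort(unique(c(cand, cand - 1e-9, min(cand) - 1, max(cand) + 1,
                        (cand[-1] + cand[-length(cand)]) / 2)))
  J <- vapply(cand, function(cth) {
    pred <- scores >= cth
    mean(pred[labels == 1]) + mean(!pred[labels == 0]) - 1
  }, numeric(1))
  list(J = max(J), cutoffs = cand, Js = J)
}

# ---- FROC: from-scratch threshold sweep -------------------------------------

# greedy matcher, re-implemented as a plain loop
oracle_match <- function(gt, det) {
  det <- det[order(-det$confidence, det$row, det$col), , drop = FALSE]
  claimed <- integer(0)
  tp <- 0L
  for (i in seq_len(nrow(det))) {
    lab <- gt[round(det$row[i]), round(det$col[i])]
    if (lab > 0 && !(lab %in% claimed)) {
      claimed <- c(claimed, lab)
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = nrow(det) - tp)
}

oracle_froc <- function(gt_masks, detections, benign,
                        fp_targets = c(1, 2, 4, 8, 16, 32)) {
  total_gt <- sum(vapply(gt_masks, function(m)
    if (is.null(m)) 0L else length(unique(m[m > 0])), integer(1)))
  ths <- c(Inf, sort(unique(detections$confidence), decreasing = TRUE))
  recall <- fps <- numeric(length(ths))
  for (k in seq_along(ths)) {
    t <- ths[k]
    tp_tot <- 0L; fp_ben <- 0L
    for (id in names(gt_masks)) {
      d <- detections[detections$image_id == id &
                        detections$confidence >= t, , drop = FALSE]
      if (!nrow(d)) next
      m <- oracle_match(gt_masks[[id]], d)
      tp_tot <- tp_tot + m$tp
      if (id %in% benign) fp_ben <- fp_ben + m$fp
    }
    recall[k] <- tp_tot / total_gt
    fps[k] <- fp_ben / length(benign)
  }
  rec <- vapply(fp_targets, function(f) max(recall[fps <= f]), numeric(1))
  list(recalls = rec, froc = mean(rec))
}

# ---- misc -------------------------------------------------------------------

# two-group truth-level cohort, slide-mean t-test p-value (for type-I /
# power replicates)
replicate_cohort_pvalue <- function(mean_b, seed, slides = 10, cells = 500) {
  co <- generate_cohort(
    list(A = morphology_distribution(cell_area_mean = 2000, cell_area_sd = 400),
         B = morphology_distribution(cell_area_mean = mean_b, cell_area_sd = 400)),
    slides_per_group = slides, cells_per_slide = cells,
    seed = seed, render = FALSE)
  sm <- tapply(co$truth$area_param, co$truth$slide_id, mean)
  grp <- co$covariates$group[match(names(sm), co$covariates$slide_id)]
  two_group_test(sm[grp == "A"], sm[grp == "B"])$p
}

# ---- toy detection fixtures -------------------------------------------------

toy_gt <- function(labels_at) {
  m <- matrix(0L, 40, 40)
  for (i in seq_along(labels_at)) {
    p <- labels_at[[i]]
    m[p[1]:(p[1] + 4), p[2]:(p[2] + 4)] <- i
  }
  m
}

make_eval <- function(seed = 241, hit_rate = 0.7, n_img = 5, n_benign = 3,
                      fp_lambda = 4) {
  set.seed(seed)
  gt <- list(); det <- list(); benign <- character(0)
  for (i in seq_len(n_img)) {
    id <- sprintf("t%d", i)
    pos <- expand.grid(r = seq(2, 32, by = 7), c = seq(2, 32, by = 7))
    pos <- pos[sample(nrow(pos), 12), ]
    gt[[id]] <- toy_gt(lapply(seq_len(12), function(j) c(pos$r[j], pos$c[j])))
    hit <- runif(12) < hit_rate
    if (any(hit))
      det[[id]] <- data.frame(image_id = id, row = pos$r[hit] + 2,
                              col = pos$c[hit] + 2,
                              confidence = round(rbeta(sum(hit), 4, 2), 3))
  }
  for (i in seq_len(n_benign)) {
    id <- sprintf("b%d", i)
    gt[[id]] <- matrix(0L, 40, 40)
    benign <- c(benign, id)
    nfp <- rpois(1, fp_lambda)
    if (nfp > 0)
      det[[id]] <- data.frame(image_id = id, row = sample(40, nfp, TRUE),
                              col = sample(40, nfp, TRUE),
                              confidence = round(rbeta(nfp, 2, 4), 3))
  }
  list(gt = gt, det = do.call(rbind, det), benign = benign)
}
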