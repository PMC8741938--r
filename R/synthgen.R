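#' Synthetic signet-ring-cell scenes
#'
#' Scenes of non-overlapping, roughly elliptical cells, each containing one
#' peripherally displaced nucleus, rasterized into paired instance label
#' masks with exact per-cell ground truth. They give every downstream stage
#' (morphometry, aggregation, cohort statistics, detection evaluation) a
#' parameter-recovery test surface: the generative cell area, aspect ratio
#' and nuclear/cytoplasmic ratio are known exactly, so measured features can
#' be compared against truth.
#'
#' @name synthgen
NULL

# run code under a temporary RNG state seeded with `seed`; NULL = use the
# current stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Per-slide morphology distribution
#'
#' Sampling law for the generator: cell areas are lognormal (positive,
#' right-skewed, as histologic areas are), parameterized by their natural
#' mean and SD in pixels; aspect ratio (short/long of the cell ellipse) and
#' nuclear/cytoplasmic ratio are Gaussian with clipping into their valid
#' ranges ((0.1, 1] and (0.01, 0.9)). `nucleus_eccentricity` in [0, 1)
#' displaces the nucleus along the cell's major axis as a fraction of the
#' free margin, so the nucleus always stays inside the cell.
#'
#' Defaults describe a plausible x40 signet-ring field: 2000 px mean cell
#' area (~113 um^2 at 0.238 um/px), moderately elongated cells
#' (aspect 0.75 +- 0.08), NCR 0.15 +- 0.04, strongly eccentric nuclei.
#'
#' @param cell_area_mean,cell_area_sd lognormal cell area, pixels.
#' @param aspect_ratio_mean,aspect_ratio_sd clipped-Gaussian aspect ratio,
#'   short/long in (0, 1].
#' @param ncr_mean,ncr_sd clipped-Gaussian nucleus/cell area ratio in (0, 1).
#' @param nucleus_eccentricity nucleus offset fraction in [0, 1).
#' @param crescent subtract a central mucin-vacuole ellipse from the nucleus
#'   so it rasterizes as a crescent.
#' @return object of class `morphology_distribution`.
#' @export
morphology_distribution <- function(cell_area_mean = 2000, cell_area_sd = 400,
                                    aspect_ratio_mean = 0.75,
                                    aspect_ratio_sd = 0.08,
                                    ncr_mean = 0.15, ncr_sd = 0.04,
                                    nucleus_eccentricity = 0.7,
                                    crescent = FALSE) {
  d <- list(cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
            aspect_ratio_mean = aspect_ratio_mean,
            aspect_ratio_sd = aspect_ratio_sd,
            ncr_mean = ncr_mean, ncr_sd = ncr_sd,
            nucleus_eccentricity = nucleus_eccentricity,
            crescent = isTRUE(crescent))
  validate_distribution(d)
  structure(d, class = "morphology_distribution")
}

validate_distribution <- function(d) {
  num <- vapply(d[setdiff(names(d), "crescent")], is.numeric, logical(1))
  if (!all(num)) stop("morphology_distribution: non-numeric parameter")
  if (d$cell_area_mean <= 0) stop("cell_area_mean must be positive")
  if (d$cell_area_sd < 0) stop("cell_area_sd must be non-negative")
  if (d$aspect_ratio_mean <= 0 || d$aspect_ratio_mean > 1)
    stop("aspect_ratio_mean must be in (0, 1]")
  if (d$aspect_ratio_sd < 0) stop("aspect_ratio_sd must be non-negative")
  if (d$ncr_mean <= 0 || d$ncr_mean >= 1) stop("ncr_mean must be in (0, 1)")
  if (d$ncr_sd < 0) stop("ncr_sd must be non-negative")
  if (d$nucleus_eccentricity < 0 || d$nucleus_eccentricity >= 1)
    stop("nucleus_eccentricity must be in [0, 1)")
  invisible(d)
}

# lognormal with given natural-scale mean and sd
rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

rnorm_clip <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Sample per-cell generative parameters
#'
#' Draws the (area, aspect ratio, NCR, orientation) tuples that
#' [generate_scene()] rasterizes; exposed so truth-level simulations can use
#' exactly the same sampling law without paying for rasterization.
#'
#' @param dist a [morphology_distribution].
#' @param n number of cells.
#' @return data.frame with columns `area`, `aspect`, `ncr`, `phi` (major
#'   axis angle, radians), `a`, `b` (ellipse semi-axes, pixels).
#' @export
sample_cell_params <- function(dist, n) {
  stopifnot(inherits(dist, "morphology_distribution"), n >= 0)
  area <- rlnorm_ms(n, dist$cell_area_mean, dist$cell_area_sd)
  aspect <- rnorm_clip(n, dist$aspect_ratio_mean, dist$aspect_ratio_sd, 0.1, 1)
  ncr <- rnorm_clip(n, dist$ncr_mean, dist$ncr_sd, 0.01, 0.9)
  phi <- stats::runif(n, 0, pi)
  a <- sqrt(area / (pi * aspect))
  data.frame(area = area, aspect = aspect, ncr = ncr, phi = phi,
             a = a, b = aspect * a)
}

# linear indices of pixel centers inside a rotated ellipse
raster_ellipse <- function(cy, cx, a, b, phi, nr, nc) {
  hr <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
  hc <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
  r0 <- max(1L, floor(cy - hr)); r1 <- min(nr, ceiling(cy + hr))
  c0 <- max(1L, floor(cx - hc)); c1 <- min(nc, ceiling(cx + hc))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dy <- rr - cy; dx <- cc - cx
  nrr <- length(rr); ncc <- length(cc)
  U <- rep(dy * sin(phi), times = ncc) + rep(dx * cos(phi), each = nrr)
  V <- rep(dy * cos(phi), times = ncc) - rep(dx * sin(phi), each = nrr)
  inside <- (U / a)^2 + (V / b)^2 <= 1
  lin <- rep(rr, times = ncc) + (rep(cc, each = nrr) - 1L) * nr
  lin[inside]
}

#' Generate one synthetic scene
#'
#' Cells are placed by rejection sampling (a candidate position is rejected
#' if any pixel is already occupied; after `max_rejections` failed draws for
#' one cell the generator stops with an error naming the achieved count).
#' Each cell is a rasterized rotated ellipse; its nucleus is a scaled copy
#' (area ratio = sampled NCR) displaced along the major axis and sharing the
#' cell's label in the nucleus mask. `n_cells = 0` produces a benign scene
#' with all-zero masks.
#'
#' @param dist a [morphology_distribution].
#' @param n_cells number of cells (>= 0).
#' @param image_shape c(rows, cols) in pixels.
#' @param seed integer seed; identical (dist, n_cells, image_shape, seed)
#'   give bit-identical masks. NULL uses the current RNG stream.
#' @param max_rejections placement attempts per cell before failing.
#' @return object of class `scene`: list with `masks` ([instance_masks]),
#'   `truth` (per-cell data.frame: sampled parameters plus rasterized `sc`,
#'   `sn` pixel counts), `image_shape`, `is_benign`, `seed`.
#' @export
generate_scene <- function(dist, n_cells, image_shape = c(512, 512),
                           seed = NULL, max_rejections = 1000) {
  stopifnot(inherits(dist, "morphology_distribution"),
            length(image_shape) == 2, all(image_shape >= 8),
            n_cells >= 0, max_rejections >= 1)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  with_seed(seed, {
    cellm <- matrix(0L, nr, nc)
    nucm <- matrix(0L, nr, nc)
    pars <- sample_cell_params(dist, n_cells)
    truth <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      a <- pars$a[i]; b <- pars$b[i]; phi <- pars$phi[i]
      hr <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
      hc <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
      if (2 * hr + 2 >= nr || 2 * hc + 2 >= nc)
        stop(sprintf(paste0("generate_scene: image %dx%d too small for a ",
                            "sampled cell of area %.0f px"), nr, nc,
                     pars$area[i]))
      placed <- FALSE
      for (att in seq_len(max_rejections)) {
        cy <- stats::runif(1, hr + 1, nr - hr)
        cx <- stats::runif(1, hc + 1, nc - hc)
        px <- raster_ellipse(cy, cx, a, b, phi, nr, nc)
        if (!length(px) || any(cellm[px] != 0L)) next
        s <- sqrt(pars$ncr[i])
        off <- dist$nucleus_eccentricity * max(0, a * (1 - s) - 1)
        sgn <- if (stats::runif(1) < 0.5) -1 else 1
        ncy <- cy + sgn * off * sin(phi)
        ncx <- cx + sgn * off * cos(phi)
        npx <- raster_ellipse(ncy, ncx, s * a, s * b, phi, nr, nc)
        if (dist$crescent) {
          # carve the mucin vacuole (an ellipse at the cell center) out
          vpx <- raster_ellipse(cy, cx, 0.8 * a, 0.8 * b, phi, nr, nc)
          npx <- setdiff(npx, vpx)
        }
        npx <- intersect(npx, px)  # guard against 1-px rasterization overhang
        cellm[px] <- i
        nucm[npx] <- i
        truth[[i]] <- data.frame(
          cell_id = i, row = cy, col = cx, a = a, b = b, phi = phi,
          area_param = pars$area[i], aspect_param = pars$aspect[i],
          ncr_param = pars$ncr[i], sc = length(px), sn = length(npx),
          nucleus_row = ncy, nucleus_col = ncx)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf(paste0("generate_scene: placement failed after %d ",
                            "rejections; placed %d of %d cells (increase ",
                            "image_shape or max_rejections)"),
                     max_rejections, i - 1L, n_cells))
    }
    truth <- if (n_cells > 0) do.call(rbind, truth) else
      data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                 a = numeric(0), b = numeric(0), phi = numeric(0),
                 area_param = numeric(0), aspect_param = numeric(0),
                 ncr_param = numeric(0), sc = integer(0), sn = integer(0),
                 nucleus_row = numeric(0), nucleus_col = numeric(0))
    structure(list(masks = instance_masks(cellm, nucm),
                   truth = truth, image_shape = c(nr, nc),
                   is_benign = n_cells == 0L, seed = seed),
              class = "scene")
  })
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("scene: %d x %d px, %d cells%s\n", x$image_shape[1],
              x$image_shape[2], nrow(x$truth),
              if (x$is_benign) " (benign)" else ""))
  invisible(x)
}

# image side so that n cells of the largest group mean fill ~`fill` of it
auto_shape <- function(groups, cells_per_slide, fill = 0.1) {
  amax <- max(vapply(groups, function(g) g$cell_area_mean + 2 * g$cell_area_sd,
                     numeric(1)))
  side <- ceiling(sqrt(cells_per_slide * amax / fill))
  c(side, side)
}

clip_dist <- function(d) {
  d$cell_area_mean <- max(d$cell_area_mean, 50)
  d$cell_area_sd <- max(d$cell_area_sd, 0)
  d$aspect_ratio_mean <- min(max(d$aspect_ratio_mean, 0.1), 1)
  d$aspect_ratio_sd <- max(d$aspect_ratio_sd, 0.005)
  d$ncr_mean <- min(max(d$ncr_mean, 0.02), 0.9)
  d$ncr_sd <- max(d$ncr_sd, 0)
  d$nucleus_eccentricity <- min(max(d$nucleus_eccentricity, 0), 0.99)
  d
}

#' Generate a synthetic cohort of slides
#'
#' One scene per slide, `slides_per_group` slides for each named group, with
#' a covariate table joining each slide to its group's clinical labels. Each
#' slide draws from its own RNG stream derived from the master seed and the
#' slide index, so cohorts are reproducible slide by slide. With
#' `slide_jitter`, named distribution parameters get an additive per-slide
#' Gaussian perturbation (then re-clipped to validity), emulating
#' between-patient heterogeneity; realized per-slide parameters are recorded
#' in `slide_params`. `render = FALSE` skips rasterization and returns
#' truth-level samples only (same sampling law), for cheap replicate
#' simulations.
#'
#' @param groups named list of [morphology_distribution] objects; names are
#'   the group labels and must be distinct.
#' @param slides_per_group,cells_per_slide cohort dimensions.
#' @param seed master integer seed.
#' @param image_shape c(rows, cols); NULL = sized automatically so cells
#'   fill about `fill` of the image.
#' @param fill target cell pixel fraction for automatic sizing.
#' @param slide_jitter named numeric vector of per-slide Gaussian SDs added
#'   to distribution parameters (e.g. `c(aspect_ratio_sd = 0.03)`).
#' @param covariates optional data.frame with one row per group and columns
#'   among site, lesion_type, ln_status, t_stage; defaults assign
#'   `ln_status` 0, 1, ... in group order.
#' @param render rasterize scenes (TRUE) or sample truth tables only.
#' @param max_rejections per-cell placement budget.
#' @param out_dir optional directory: writes covariates.csv, truth.csv,
#'   slide_params.csv, config.yaml and (when rendering) per-slide mask TIFFs.
#' @return list with `covariates`, `truth` (per-cell rows with slide_id),
#'   `slide_params`, `scenes` (named list, NULL when `render = FALSE`) and
#'   `config`.
#' @export
generate_cohort <- function(groups, slides_per_group, cells_per_slide,
                            seed = NULL, image_shape = NULL, fill = 0.1,
                            slide_jitter = NULL, covariates = NULL,
                            render = TRUE, max_rejections = 1000,
                            out_dir = NULL) {
  stopifnot(length(groups) >= 1, slides_per_group >= 1, cells_per_slide >= 0)
  if (is.null(names(groups)) || any(names(groups) == "") ||
      anyDuplicated(names(groups)))
    stop("generate_cohort: groups must have distinct non-empty names")
  for (g in groups) stopifnot(inherits(g, "morphology_distribution"))
  ng <- length(groups)
  if (is.null(covariates)) {
    covariates <- data.frame(group = names(groups),
                             site = "stomach", lesion_type = "primary",
                             ln_status = seq_len(ng) - 1L, t_stage = NA_integer_)
  } else {
    covariates <- as.data.frame(covariates)
    covariates$group <- names(groups)
    for (col in c("site", "lesion_type", "ln_status", "t_stage"))
      if (is.null(covariates[[col]])) covariates[[col]] <- NA
  }
  if (is.null(image_shape) && render)
    image_shape <- auto_shape(groups, cells_per_slide, fill)
  n_slides <- ng * slides_per_group
  slide_seeds <- if (is.null(seed)) {
    sample.int(.Machine$integer.max, n_slides)
  } else {
    (as.numeric(seed) + 104729 * seq_len(n_slides)) %% 2147483647
  }
  slide_ids <- as.vector(vapply(names(groups), function(g)
    sprintf("%s_s%02d", g, seq_len(slides_per_group)),
    character(slides_per_group)))
  if (anyDuplicated(slide_ids)) stop("generate_cohort: duplicate slide ids")
  scenes <- if (render) stats::setNames(vector("list", n_slides), slide_ids)
  truth_list <- vector("list", n_slides)
  par_list <- vector("list", n_slides)
  cov_rows <- vector("list", n_slides)
  k <- 0L
  for (gi in seq_len(ng)) {
    gname <- names(groups)[gi]
    for (si in seq_len(slides_per_group)) {
      k <- k + 1L
      sid <- slide_ids[k]
      res <- with_seed(slide_seeds[k], {
        d <- unclass(groups[[gi]])
        if (!is.null(slide_jitter)) {
          for (nm in names(slide_jitter)) {
            if (!nm %in% names(d)) stop("slide_jitter: unknown parameter ", nm)
            d[[nm]] <- d[[nm]] + stats::rnorm(1, 0, slide_jitter[[nm]])
          }
          d <- clip_dist(d)
        }
        dd <- structure(d, class = "morphology_distribution")
        if (render) {
          sc <- generate_scene(dd, cells_per_slide, image_shape,
                               seed = NULL, max_rejections = max_rejections)
          list(dist = d, truth = sc$truth, scene = sc)
        } else {
          p <- sample_cell_params(dd, cells_per_slide)
          tr <- data.frame(cell_id = seq_len(nrow(p)),
                           area_param = p$area, aspect_param = p$aspect,
                           ncr_param = p$ncr)
          list(dist = d, truth = tr, scene = NULL)
        }
      })
      if (render) scenes[[sid]] <- res$scene
      tr <- res$truth
      if (nrow(tr)) tr <- cbind(slide_id = sid, group = gname, tr)
      truth_list[[k]] <- tr
      par_list[[k]] <- data.frame(slide_id = sid, group = gname,
                                  as.data.frame(res$dist[setdiff(names(res$dist),
                                                                 "crescent")]))
      cov_rows[[k]] <- data.frame(slide_id = sid,
                                  covariates[gi, , drop = FALSE],
                                  n_cells = nrow(res$truth))
    }
  }
  cov <- do.call(rbind, cov_rows)
  rownames(cov) <- NULL
  out <- list(covariates = cov,
              truth = do.call(rbind, truth_list[lengths(truth_list) > 0]),
              slide_params = do.call(rbind, par_list),
              scenes = scenes,
              config = list(groups = lapply(groups, unclass),
                            slides_per_group = slides_per_group,
                            cells_per_slide = cells_per_slide, seed = seed,
                            image_shape = image_shape,
                            slide_jitter = as.list(slide_jitter),
                            render = render))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$covariates, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(out$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(out$slide_params, file.path(out_dir, "slide_params.csv"),
                     row.names = FALSE)
    yaml::write_yaml(out$config, file.path(out_dir, "config.yaml"))
    if (render) {
      for (sid in slide_ids) {
        write_masks(scenes[[sid]]$masks,
                    file.path(out_dir, paste0(sid, "_cell.tif")),
                    file.path(out_dir, paste0(sid, "_nucleus.tif")))
      }
    }
  }
  out
}
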