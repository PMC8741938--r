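#' Demo pipeline configuration
#'
#' A self-contained two-group synthetic cohort: 10 slides per group, 500
#' cells per slide, groups differing only in ellipticity atypia
#' (aspect-ratio SD 0.06 vs 0.12) with per-slide heterogeneity (SD 0.03) so
#' group distributions overlap the way patients do, group B labeled
#' lymph-node positive. Also carries the heatmap and detector-simulation
#' settings used by the `heatmap` and `froc` steps.
#'
#' @param seed master seed.
#' @return nested configuration list (YAML-serializable).
#' @export
default_demo_config <- function(seed = 42) {
  list(
    seed = seed,
    cohort = list(
      slides_per_group = 10, cells_per_slide = 500, fill = 0.1,
      slide_jitter = list(aspect_ratio_sd = 0.03),
      groups = list(
        A = list(cell_area_mean = 2000, cell_area_sd = 400,
                 aspect_ratio_mean = 0.75, aspect_ratio_sd = 0.06,
                 ncr_mean = 0.15, ncr_sd = 0.04, nucleus_eccentricity = 0.7,
                 ln_status = 0, site = "colorectum", lesion_type = "primary"),
        B = list(cell_area_mean = 2000, cell_area_sd = 400,
                 aspect_ratio_mean = 0.75, aspect_ratio_sd = 0.12,
                 ncr_mean = 0.15, ncr_sd = 0.04, nucleus_eccentricity = 0.7,
                 ln_status = 1, site = "colorectum", lesion_type = "primary"))),
    min_cells = 500,
    stats = list(test = "t", dichotomize = TRUE, alpha = 0.05,
                 outcome = "ln_status",
                 variables = c("sc_mean", "sn_mean", "ep_mean", "ncr_mean",
                               "sc_sd", "sn_sd", "ep_sd", "ncr_sd")),
    heatmap = list(scale_factor = 8, sigma = 2, blend_alpha = 0.5),
    froc = list(n_tumor = 6, n_benign = 6, cells_per_image = 25,
                image_side = 420, hit_rate = 0.8, fp_per_benign = 3),
    write_masks = FALSE)
}

config_groups <- function(cfg) {
  dist_fields <- names(formals(morphology_distribution))
  groups <- lapply(cfg$cohort$groups, function(g)
    do.call(morphology_distribution, g[intersect(names(g), dist_fields)]))
  cov <- do.call(rbind, lapply(cfg$cohort$groups, function(g)
    data.frame(site = g$site %||% NA, lesion_type = g$lesion_type %||% NA,
               ln_status = g$ln_status %||% NA, t_stage = g$t_stage %||% NA)))
  list(groups = groups, covariates = cov)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_manifest <- function(out_dir, step, cfg, counts) {
  jsonlite::write_json(
    list(step = step, seed = cfg$seed,
         package = as.character(utils::packageVersion("srcmorph")),
         config = cfg, counts = counts),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null", pretty = TRUE)
}

#' Run the pipeline end-to-end or step by step
#'
#' Steps: `simulate` (synthetic cohort with ground truth), `extract`
#' (per-cell morphometry on every slide), `aggregate` (slide summaries +
#' covariate join, inclusion filter), `compare` (two-group tests on each
#' summary statistic and the Youden + logistic forest table), `heatmap`
#' (Gaussian density map and overlay for the first tumor slide), `froc`
#' (simulated point detector evaluated against the masks), and `all`, which
#' chains simulate, extract, aggregate and compare. Every step writes CSV /
#' JSON / image artifacts plus a `manifest.json` (config echo, seed,
#' package version, row counts) into `out_dir`; reruns with the same seed
#' produce byte-identical CSV outputs. All randomness flows from the master
#' seed in the config (overridable with `seed`).
#'
#' @param step one of "all", "simulate", "extract", "aggregate", "compare",
#'   "heatmap", "froc".
#' @param config configuration list (see [default_demo_config()]) or path
#'   to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @param seed optional master-seed override.
#' @return invisibly, a list of the step's in-memory results.
#' @export
run_pipeline <- function(step = c("all", "simulate", "extract", "aggregate",
                                  "compare", "heatmap", "froc"),
                         config = default_demo_config(), out_dir, seed = NULL) {
  step <- match.arg(step)
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.null(seed)) cfg$seed <- seed
  if (missing(out_dir)) stop("run_pipeline: out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  simulate_fn <- function() {
    gg <- config_groups(cfg)
    cohort <- generate_cohort(
      gg$groups,
      slides_per_group = cfg$cohort$slides_per_group,
      cells_per_slide = cfg$cohort$cells_per_slide,
      seed = cfg$seed, fill = cfg$cohort$fill %||% 0.1,
      slide_jitter = unlist(cfg$cohort$slide_jitter),
      covariates = gg$covariates, render = TRUE)
    utils::write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$slide_params,
                     file.path(out_dir, "slide_params.csv"), row.names = FALSE)
    if (isTRUE(cfg$write_masks)) {
      for (sid in names(cohort$scenes)) {
        write_masks(cohort$scenes[[sid]]$masks,
                    file.path(out_dir, paste0(sid, "_cell.tif")),
                    file.path(out_dir, paste0(sid, "_nucleus.tif")))
      }
    }
    cohort
  }

  extract_fn <- function(cohort) {
    feats <- do.call(rbind, lapply(names(cohort$scenes), function(sid)
      extract_features(cohort$scenes[[sid]]$masks, slide_id = sid)))
    write_features(feats, file.path(out_dir, "features.csv"))
    feats
  }

  aggregate_fn <- function(feats, cohort) {
    summ <- summarize_cohort(feats, min_cells = cfg$min_cells %||% 500)
    tab <- merge(summ, cohort$covariates, by = "slide_id", sort = TRUE)
    tab <- tab[order(tab$slide_id), ]
    utils::write.csv(tab, file.path(out_dir, "cohort_table.csv"),
                     row.names = FALSE)
    tab
  }

  compare_fn <- function(tab) {
    st <- cfg$stats
    outcome <- st$outcome %||% "ln_status"
    vars <- st$variables %||% c("sc_mean", "sn_mean", "ep_mean", "ncr_mean",
                                "sc_sd", "sn_sd", "ep_sd", "ncr_sd")
    tab <- tab[tab$included, , drop = FALSE]
    y <- tab[[outcome]]
    tests <- do.call(rbind, lapply(vars, function(v) {
      tt <- two_group_test(tab[[v]][y == 0], tab[[v]][y == 1],
                           method = st$test %||% "t")
      data.frame(variable = v, statistic = tt$statistic, p = tt$p,
                 method = tt$method)
    }))
    utils::write.csv(tests, file.path(out_dir, "group_tests.csv"),
                     row.names = FALSE)
    ft <- forest_table(tab, outcome, vars,
                       dichotomize = isTRUE(st$dichotomize %||% TRUE))
    utils::write.csv(ft, file.path(out_dir, "forest.csv"), row.names = FALSE)
    list(tests = tests, forest = ft)
  }

  heatmap_fn <- function(cohort) {
    hm <- cfg$heatmap
    sid <- names(cohort$scenes)[1]
    scene <- cohort$scenes[[sid]]
    sf <- hm$scale_factor %||% 8
    shp <- ceiling(scene$image_shape / sf)
    spec <- heatmap_spec(shp, sf, sigma = hm$sigma %||% 2,
                         blend_alpha = hm$blend_alpha %||% 0.5)
    map <- gaussian_map(scene$truth[, c("row", "col")], spec)
    # quick gray thumbnail from the cell mask occupancy
    thumb <- 1 - 0.7 * (map$counts > 0)
    ov <- overlay_heatmap(thumb, map, blend_alpha = spec$blend_alpha)
    write_heatmap(map, file.path(out_dir, "heatmap_intensity.tif"),
                  overlay = ov, png_path = file.path(out_dir, "heatmap_overlay.png"))
    map
  }

  froc_fn <- function() {
    fc <- cfg$froc
    with_seed(cfg$seed + 1L, {
      dist <- morphology_distribution(cell_area_mean = 600, cell_area_sd = 150)
      side <- fc$image_side %||% 420
      gt <- list(); det <- list(); benign <- character(0)
      for (i in seq_len(fc$n_tumor %||% 6)) {
        id <- sprintf("tumor_%02d", i)
        sc <- generate_scene(dist, fc$cells_per_image %||% 25, c(side, side))
        gt[[id]] <- sc$masks$cell
        hit <- stats::runif(nrow(sc$truth)) < (fc$hit_rate %||% 0.8)
        if (any(hit)) {
          det[[id]] <- data.frame(
            image_id = id,
            row = round(sc$truth$row[hit]), col = round(sc$truth$col[hit]),
            confidence = stats::rbeta(sum(hit), 4, 2))
        }
      }
      for (i in seq_len(fc$n_benign %||% 6)) {
        id <- sprintf("benign_%02d", i)
        gt[[id]] <- matrix(0L, side, side)
        benign <- c(benign, id)
        nfp <- stats::rpois(1, fc$fp_per_benign %||% 3)
        if (nfp > 0) {
          det[[id]] <- data.frame(
            image_id = id,
            row = sample.int(side, nfp, replace = TRUE),
            col = sample.int(side, nfp, replace = TRUE),
            confidence = stats::rbeta(nfp, 2, 4))
        }
      }
      detections <- do.call(rbind, det)
      ds <- eval_dataset(gt, detections, benign)
      fr <- froc_curve(ds)
      write_froc(fr, file.path(out_dir, "froc.csv"),
                 file.path(out_dir, "froc.json"))
      write_detections(detections, file.path(out_dir, "detections.csv"))
      fr
    })
  }

  if (step %in% c("all", "simulate", "extract", "aggregate", "compare",
                  "heatmap")) {
    res$cohort <- simulate_fn()
  }
  if (step %in% c("all", "extract", "aggregate", "compare")) {
    res$features <- extract_fn(res$cohort)
  }
  if (step %in% c("all", "aggregate", "compare")) {
    res$cohort_table <- aggregate_fn(res$features, res$cohort)
  }
  if (step %in% c("all", "compare")) {
    res$compare <- compare_fn(res$cohort_table)
  }
  if (step == "heatmap") {
    res$heatmap <- heatmap_fn(res$cohort)
  }
  if (step == "froc") {
    res$froc <- froc_fn()
  }
  counts <- list(
    slides = if (!is.null(res$cohort)) nrow(res$cohort$covariates) else NULL,
    cells = if (!is.null(res$features)) nrow(res$features) else NULL,
    slides_included = if (!is.null(res$cohort_table))
      sum(res$cohort_table$included) else NULL)
  write_manifest(out_dir, step, cfg, counts)
  invisible(res)
}
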