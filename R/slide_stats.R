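#' Per-slide aggregation of cell features
#'
#' A slide is summarized by the mean and sample standard deviation of each
#' of the four per-cell properties; the SD is the slide's atypia measure
#' (within-slide heterogeneity of the feature). Nucleus-dependent statistics
#' (`SN`, `NCR`) are computed over nucleus-assigned cells only; `SC` and
#' `EP` use all cells. A slide is flagged `included` when it carries at
#' least `min_cells` cells (default 500, the stability rule for selecting
#' sections).
#'
#' @param records data.frame of per-cell records (from [extract_features()]).
#' @param min_cells inclusion threshold on the number of cells.
#' @param slide_id optional identifier copied into the output.
#' @return one-row data.frame: `slide_id`, `n_cells`, `n_with_nucleus`,
#'   `sc_mean`, `sc_sd`, `sn_mean`, `sn_sd`, `ep_mean`, `ep_sd`, `ncr_mean`,
#'   `ncr_sd`, `included`.
#' @export
summarize_slide <- function(records, min_cells = 500, slide_id = NA_character_) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("summarize_slide: empty record list")
  stopifnot(all(c("SC", "EP", "SN", "NCR") %in% names(records)))
  n <- nrow(records)
  nn <- sum(!is.na(records$NCR))
  ms <- function(x, what) {
    x <- x[!is.na(x)]
    if (!length(x)) {
      warning("summarize_slide: no values for ", what, "; statistics are NA")
      return(c(NA_real_, NA_real_))
    }
    s <- if (length(x) >= 2L) stats::sd(x) else {
      warning("summarize_slide: single value for ", what,
              "; sample SD undefined (NA)")
      NA_real_
    }
    c(mean(x), s)
  }
  sc <- ms(records$SC, "SC"); sn <- ms(records$SN, "SN")
  ep <- ms(records$EP, "EP"); ncr <- ms(records$NCR, "NCR")
  data.frame(slide_id = slide_id, n_cells = n, n_with_nucleus = nn,
             sc_mean = sc[1], sc_sd = sc[2], sn_mean = sn[1], sn_sd = sn[2],
             ep_mean = ep[1], ep_sd = ep[2], ncr_mean = ncr[1],
             ncr_sd = ncr[2], included = n >= min_cells)
}

#' Summarize every slide of a cohort feature table
#'
#' @param features per-cell records carrying a `slide_id` column.
#' @param min_cells inclusion threshold per slide.
#' @return data.frame, one [summarize_slide()] row per slide, in order of
#'   first appearance.
#' @export
summarize_cohort <- function(features, min_cells = 500) {
  stopifnot("slide_id" %in% names(features))
  ids <- unique(features$slide_id)
  out <- do.call(rbind, lapply(ids, function(s)
    summarize_slide(features[features$slide_id == s, , drop = FALSE],
                    min_cells = min_cells, slide_id = s)))
  rownames(out) <- NULL
  out
}

#' Histogram bins for one feature
#'
#' Equal-width bins over the observed range of the non-missing values;
#' counts always sum to the number of non-missing values. A degenerate range
#' (all values equal) is widened by +-0.5 so the single value falls into one
#' interior bin.
#'
#' @param records per-cell records.
#' @param feature one of "SC", "SN", "EP", "NCR".
#' @param n_bins number of bins.
#' @return list with `edges` (length `n_bins + 1`), `counts`, `feature`, `n`.
#' @export
histogram_data <- function(records, feature, n_bins = 30) {
  if (!feature %in% c("SC", "SN", "EP", "NCR"))
    stop("histogram_data: unknown feature '", feature, "'")
  x <- records[[feature]]
  x <- x[!is.na(x)]
  if (!length(x)) stop("histogram_data: no non-missing values for ", feature)
  lo <- min(x); hi <- max(x)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  edges <- seq(lo, hi, length.out = n_bins + 1)
  counts <- graphics::hist(x, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = TRUE)$counts
  list(edges = edges, counts = counts, feature = feature, n = sum(counts))
}

#' Per-cell triples for the 3-D property scatter
#'
#' One row per nucleus-assigned cell: `SC`, the chosen nucleus measure
#' (`SN` or `NCR`) and `EP`, copied from the records.
#'
#' @param records per-cell records.
#' @param z nucleus axis: "SN" or "NCR".
#' @return data.frame with columns SC, SN or NCR, EP.
#' @export
scatter3d_data <- function(records, z = c("SN", "NCR")) {
  z <- match.arg(z)
  sel <- !is.na(records$NCR) & !is.na(records$SN)
  out <- records[sel, c("SC", z, "EP"), drop = FALSE]
  rownames(out) <- NULL
  out
}
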