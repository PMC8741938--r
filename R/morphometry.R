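#' Per-cell morphometry from instance masks
#'
#' The four inherent cell properties are computed directly from instance
#' label masks: cell area `SC` (pixel count of the cell mask), nucleus area
#' `SN` (pixel count of the assigned nucleus mask), ellipticity `EP` (aspect
#' ratio short/long of the minimum-area rotated bounding box of the cell
#' mask, in (0, 1] with 1 = most round) and nuclear/cytoplasmic ratio
#' `NCR = SN / SC`. All areas stay in pixels; [pixels_to_um2()] converts for
#' reporting.
#'
#' @name morphometry
NULL

#' Pixel area of a single instance mask
#'
#' Area is the total number of pixels in the mask, i.e. `sum(mask != 0)`.
#'
#' @param mask binary or label matrix of one instance (non-zero = foreground).
#' @return integer pixel count.
#' @export
cell_area <- function(mask) {
  stopifnot(is.matrix(mask))
  n <- sum(mask != 0)
  if (n == 0L) stop("cell_area: empty mask")
  as.integer(n)
}

#' Minimum-area rotated bounding rectangle of a point set
#'
#' Convex hull followed by rotating calipers: the minimal rectangle has a
#' side collinear with a hull edge, so each hull edge direction is tried and
#' the smallest enclosing rectangle kept. Degenerate (collinear or single)
#' point sets return a zero-width rectangle along the extent direction.
#'
#' @param pts n x 2 matrix of (row, col) coordinates.
#' @return list with `center` (row, col), `size` c(long, short) -- extents of
#'   the point set along the rectangle axes, `angle` of the long axis in
#'   degrees in `[0, 180)` measured from the column axis, and `area`
#'   (`long * short`).
#' @export
min_area_rect_points <- function(pts) {
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2, nrow(pts) >= 1)
  y <- pts[, 1]  # row
  x <- pts[, 2]  # col
  finish <- function(ux, uy, hx, hy) {
    pu <- hx * ux + hy * uy
    pv <- -hx * uy + hy * ux
    w <- max(pu) - min(pu)
    h <- max(pv) - min(pv)
    cu <- (max(pu) + min(pu)) / 2
    cv <- (max(pv) + min(pv)) / 2
    cx <- cu * ux - cv * uy
    cy <- cu * uy + cv * ux
    if (w >= h) {
      ang <- atan2(uy, ux)
      size <- c(long = w, short = h)
    } else {
      ang <- atan2(ux, -uy)
      size <- c(long = h, short = w)
    }
    list(center = c(row = cy, col = cx), size = size,
         angle = (ang * 180 / pi) %% 180, area = w * h)
  }
  ux <- unique(x); uy_ <- unique(y)
  if (length(ux) == 1L && length(uy_) == 1L) {
    return(list(center = c(row = y[1], col = x[1]),
                size = c(long = 0, short = 0), angle = 0, area = 0))
  }
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  if (nh <= 2L) {
    # collinear: orient along the two hull extremes
    ex <- hx[min(2L, nh)] - hx[1L]; ey <- hy[min(2L, nh)] - hy[1L]
    if (nh == 1L) { # chull collapsed; use overall extent
      ex <- max(x) - min(x); ey <- max(y) - min(y)
    }
    L <- sqrt(ex^2 + ey^2)
    return(finish(ex / L, ey / L, x, y))
  }
  best <- NULL
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    L <- sqrt(ex^2 + ey^2)
    if (L == 0) next
    ex <- ex / L; ey <- ey / L
    pu <- hx * ex + hy * ey
    pv <- -hx * ey + hy * ex
    area <- (max(pu) - min(pu)) * (max(pv) - min(pv))
    if (is.null(best) || area < best$area - 1e-12) {
      best <- list(area = area, ux = ex, uy = ey)
    }
  }
  finish(best$ux, best$uy, hx, hy)
}

#' Minimum-area rotated bounding rectangle of an instance mask
#'
#' The rectangle is fitted to pixel centers, then each reported side length
#' is increased by 1 px to account for the +-0.5 px pixel extent. With this
#' convention an axis-aligned w x h pixel block reports sides (max(w,h),
#' min(w,h)) exactly, a single pixel reports (1, 1), and collinear masks
#' report a short side of 1.
#'
#' @param mask binary or label matrix of one instance.
#' @return list with `center` (row, col), `size` c(long, short) in pixels
#'   (pixel-extent padded), and `angle` of the long side in degrees.
#' @export
min_area_rect <- function(mask) {
  stopifnot(is.matrix(mask))
  pts <- which(mask != 0, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("min_area_rect: empty mask")
  r <- min_area_rect_points(pts)
  r$size <- r$size + 1
  r$area <- r$size[["long"]] * r$size[["short"]]
  r
}

#' Ellipticity (aspect ratio) of an instance mask
#'
#' Short side divided by long side of [min_area_rect()], in (0, 1]; 1 for
#' squares and disks. Invariant to translation and 90-degree rotation.
#'
#' @inheritParams min_area_rect
#' @return numeric in (0, 1].
#' @export
ellipticity <- function(mask) {
  r <- min_area_rect(mask)
  unname(r$size[["short"]] / r$size[["long"]])
}

#' Assign each cell the nucleus with the largest mask intersection
#'
#' For every cell instance, the nucleus instance maximizing the pixel
#' intersection with that cell is assigned; ties go to the smallest nucleus
#' id. Cells intersecting no nucleus get `NA`. The rule is applied per cell,
#' so one nucleus may be assigned to several cells. Intersections are
#' computed on the raw label images, without dilation.
#'
#' @param masks an [instance_masks] object.
#' @return data.frame with columns `cell_id`, `nucleus_id` (NA when no
#'   overlap) and `overlap` (pixels).
#' @export
assign_nuclei <- function(masks) {
  stopifnot(inherits(masks, "instance_masks"))
  cellm <- masks$cell; nucm <- masks$nucleus
  cells <- sort(unique(cellm[cellm > 0L]))
  out <- data.frame(cell_id = as.integer(cells),
                    nucleus_id = NA_integer_, overlap = 0L)
  both <- which(cellm > 0L & nucm > 0L)
  if (length(both)) {
    cl <- cellm[both]; nl <- nucm[both]
    key <- paste(cl, nl)
    cnt <- rowsum(rep(1L, length(key)), group = key)
    parts <- strsplit(rownames(cnt), " ", fixed = TRUE)
    d <- data.frame(cell = as.integer(vapply(parts, `[`, "", 1L)),
                    nuc  = as.integer(vapply(parts, `[`, "", 2L)),
                    ov   = as.integer(cnt[, 1L]))
    d <- d[order(d$cell, -d$ov, d$nuc), ]
    best <- d[!duplicated(d$cell), ]
    m <- match(out$cell_id, best$cell)
    hit <- !is.na(m)
    out$nucleus_id[hit] <- best$nuc[m[hit]]
    out$overlap[hit] <- best$ov[m[hit]]
  }
  out
}

#' Extract per-cell feature records from instance masks
#'
#' One record per cell instance, ordered by cell id: centroid (mean pixel
#' coordinate), `SC`, `EP`, the assigned nucleus (largest intersection),
#' `SN` and `NCR`. Cells with no assigned nucleus keep `SC`/`EP` but have
#' `NA` for `nucleus_id`, `SN` and `NCR`.
#'
#' @param masks an [instance_masks] object.
#' @param slide_id optional slide identifier stored in a `slide_id` column.
#' @return data.frame with columns `slide_id` (if given), `cell_id`, `row`,
#'   `col`, `SC`, `EP`, `nucleus_id`, `SN`, `NCR`.
#' @export
extract_features <- function(masks, slide_id = NULL) {
  stopifnot(inherits(masks, "instance_masks"))
  cellm <- masks$cell
  nr <- nrow(cellm)
  pix <- which(cellm > 0L)
  if (length(pix) == 0L) {
    out <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      SC = integer(0), EP = numeric(0), nucleus_id = integer(0),
                      SN = integer(0), NCR = numeric(0))
    if (!is.null(slide_id)) out <- cbind(slide_id = character(0), out)
    return(out)
  }
  labs <- cellm[pix]
  rows <- (pix - 1L) %% nr + 1L
  cols <- (pix - 1L) %/% nr + 1L
  sc_tab <- tabulate(labs)
  ids <- which(sc_tab > 0L)
  cy <- rowsum(as.numeric(rows), labs)[, 1L] / sc_tab[ids]
  cx <- rowsum(as.numeric(cols), labs)[, 1L] / sc_tab[ids]
  sp <- split(seq_along(labs), labs)
  ep <- vapply(sp, function(ii) {
    r <- min_area_rect_points(cbind(rows[ii], cols[ii]))
    (r$size[["short"]] + 1) / (r$size[["long"]] + 1)
  }, numeric(1))
  nucm <- masks$nucleus
  sn_tab <- tabulate(nucm[nucm > 0L])
  amap <- assign_nuclei(masks)
  stopifnot(identical(amap$cell_id, as.integer(ids)))
  sn <- ifelse(is.na(amap$nucleus_id), NA_integer_, sn_tab[amap$nucleus_id])
  out <- data.frame(cell_id = as.integer(ids),
                    row = unname(cy), col = unname(cx),
                    SC = as.integer(sc_tab[ids]), EP = unname(ep),
                    nucleus_id = amap$nucleus_id, SN = as.integer(sn),
                    NCR = as.numeric(sn) / as.numeric(sc_tab[ids]))
  if (!is.null(slide_id)) out <- cbind(slide_id = slide_id, out)
  rownames(out) <- NULL
  out
}

#' Convert pixel areas to square micrometers
#'
#' Reporting convenience: `area_px * pixel_size^2`, with the default pixel
#' size 0.238 um/px of a x40 scan.
#'
#' @param area_px numeric pixel areas.
#' @param pixel_size pixel edge length in micrometers.
#' @return areas in um^2.
#' @export
pixels_to_um2 <- function(area_px, pixel_size = 0.238) {
  stopifnot(pixel_size > 0)
  area_px * pixel_size^2
}
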