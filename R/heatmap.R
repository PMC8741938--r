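#' Heatmap rendering spec
#'
#' Geometry and rendering parameters for the cell-density heatmap: the
#' thumbnail shape, the full-resolution-to-thumbnail downscale factor, the
#' Gaussian kernel SD in thumbnail pixels (default 2) and the overlay blend
#' weight.
#'
#' @param thumbnail_shape c(rows, cols) of the thumbnail.
#' @param scale_factor full-res pixels per thumbnail pixel (>= 1).
#' @param sigma Gaussian SD in thumbnail pixels (> 0).
#' @param blend_alpha overlay weight in [0, 1].
#' @return object of class `heatmap_spec`.
#' @export
heatmap_spec <- function(thumbnail_shape, scale_factor, sigma = 2,
                         blend_alpha = 0.5) {
  stopifnot(length(thumbnail_shape) == 2, all(thumbnail_shape >= 1),
            scale_factor >= 1, sigma > 0,
            blend_alpha >= 0, blend_alpha <= 1)
  structure(list(thumbnail_shape = as.integer(thumbnail_shape),
                 scale_factor = scale_factor, sigma = sigma,
                 blend_alpha = blend_alpha), class = "heatmap_spec")
}

# separable zero-padded convolution with a 1-D kernel along rows
conv_rows <- function(m, k, rad) {
  nr <- nrow(m)
  mp <- rbind(matrix(0, rad, ncol(m)), m, matrix(0, rad, ncol(m)))
  out <- matrix(0, nr, ncol(m))
  for (d in -rad:rad) {
    out <- out + k[d + rad + 1] * mp[(1:nr) + rad + d, , drop = FALSE]
  }
  out
}

#' Gaussian density map of cell centers at thumbnail scale
#'
#' Each full-resolution center is downscaled by `scale_factor` (floor onto
#' the thumbnail grid); impulses accumulate (several cells may land in one
#' thumbnail pixel) and the impulse image is convolved with an isotropic
#' Gaussian of SD `sigma`, truncated at 4 sigma and normalized to unit mass,
#' with zero padding at the borders. The returned `intensity` is the
#' max-normalized map in [0, 1] (an all-zero map stays zero); `raw` is the
#' unnormalized density whose interior mass equals the number of cells, for
#' quantitative use.
#'
#' @param centers n x 2 matrix (or data.frame) of full-resolution (row, col)
#'   coordinates, 1-based.
#' @param spec a [heatmap_spec].
#' @return object of class `gaussian_map`: list with `intensity`, `raw`,
#'   `counts` (the impulse accumulator) and `spec`.
#' @export
gaussian_map <- function(centers, spec) {
  stopifnot(inherits(spec, "heatmap_spec"))
  centers <- as.matrix(as.data.frame(centers)[, 1:2])
  nrt <- spec$thumbnail_shape[1]; nct <- spec$thumbnail_shape[2]
  sf <- spec$scale_factor
  if (nrow(centers)) {
    bad <- centers[, 1] < 1 | centers[, 1] > nrt * sf |
      centers[, 2] < 1 | centers[, 2] > nct * sf
    if (any(bad))
      stop("gaussian_map: centers out of bounds at rows ",
           paste(utils::head(which(bad), 10), collapse = ", "))
  }
  acc <- matrix(0, nrt, nct)
  if (nrow(centers)) {
    tr <- pmin(nrt, floor((centers[, 1] - 1) / sf) + 1)
    tc <- pmin(nct, floor((centers[, 2] - 1) / sf) + 1)
    tab <- tabulate((tc - 1) * nrt + tr, nbins = nrt * nct)
    acc <- matrix(tab, nrt, nct)
  }
  rad <- ceiling(4 * spec$sigma)
  k <- stats::dnorm(-rad:rad, sd = spec$sigma)
  k <- k / sum(k)
  raw <- t(conv_rows(t(conv_rows(acc, k, rad)), k, rad))
  mx <- max(raw)
  intensity <- if (mx > 0) raw / mx else raw
  structure(list(intensity = intensity, raw = raw, counts = acc, spec = spec),
            class = "gaussian_map")
}

#' @export
print.gaussian_map <- function(x, ...) {
  cat(sprintf("gaussian_map: %d x %d thumbnail px, %d cells, sigma %.1f\n",
              nrow(x$intensity), ncol(x$intensity), sum(x$counts),
              x$spec$sigma))
  invisible(x)
}

#' Blend a colormapped intensity map over a thumbnail
#'
#' Pixel-wise convex combination `(1 - alpha) * thumbnail + alpha *
#' colormap(intensity)`: `alpha = 0` returns the thumbnail unchanged and
#' every output channel lies between the two inputs.
#'
#' @param thumbnail numeric array h x w x 3 in [0, 1], or an h x w gray
#'   matrix (replicated to 3 channels).
#' @param intensity matrix in [0, 1] (or a [gaussian_map]).
#' @param blend_alpha weight of the heatmap layer in [0, 1].
#' @param colormap palette name passed to [grDevices::hcl.colors()].
#' @return h x w x 3 numeric array in [0, 1].
#' @export
overlay_heatmap <- function(thumbnail, intensity, blend_alpha = 0.5,
                            colormap = "Inferno") {
  if (inherits(intensity, "gaussian_map")) intensity <- intensity$intensity
  if (is.matrix(thumbnail))
    thumbnail <- array(rep(thumbnail, 3), c(dim(thumbnail), 3))
  stopifnot(length(dim(thumbnail)) == 3, dim(thumbnail)[3] == 3,
            blend_alpha >= 0, blend_alpha <= 1)
  if (!identical(dim(thumbnail)[1:2], dim(intensity)))
    stop("overlay_heatmap: thumbnail and intensity shapes differ (",
         paste(dim(thumbnail)[1:2], collapse = "x"), " vs ",
         paste(dim(intensity), collapse = "x"), ")")
  pal <- grDevices::hcl.colors(256, colormap)
  ramp <- t(grDevices::col2rgb(pal)) / 255
  idx <- pmin(255L, pmax(0L, as.integer(floor(intensity * 255)))) + 1L
  col_img <- array(0, dim(thumbnail))
  for (ch in 1:3) col_img[, , ch] <- matrix(ramp[idx, ch], nrow(intensity))
  (1 - blend_alpha) * thumbnail + blend_alpha * col_img
}

#' Write a gaussian map (float TIFF) and overlay (PNG)
#'
#' @param map a [gaussian_map].
#' @param tiff_path destination for the float32 intensity TIFF.
#' @param overlay optional h x w x 3 overlay array; written as PNG to
#'   `png_path` when both are given.
#' @param png_path destination for the overlay PNG.
#' @export
write_heatmap <- function(map, tiff_path, overlay = NULL, png_path = NULL) {
  stopifnot(inherits(map, "gaussian_map"))
  tiff::writeTIFF(map$intensity, tiff_path, bits.per.sample = 32)
  if (!is.null(overlay) && !is.null(png_path)) {
    png::writePNG(overlay, png_path)
  }
  invisible(tiff_path)
}
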