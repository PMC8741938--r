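#' Paired cell / nucleus instance label masks
#'
#' Container for a pair of 2-D integer label images of identical shape:
#' `cell` and `nucleus`, with 0 = background and positive integers as
#' instance labels, plus the scan's pixel size as metadata. All coordinates
#' in this package are 1-based (row, col) matrix indices.
#'
#' @param cell,nucleus integer matrices of identical dimensions,
#'   non-negative values.
#' @param pixel_size pixel edge length in micrometers (metadata only;
#'   default 0.238, a x40 scan).
#' @return object of class `instance_masks`.
#' @export
instance_masks <- function(cell, nucleus, pixel_size = 0.238) {
  stopifnot(is.matrix(cell), is.matrix(nucleus))
  if (!identical(dim(cell), dim(nucleus)))
    stop("instance_masks: cell and nucleus masks have different shapes (",
         paste(dim(cell), collapse = "x"), " vs ",
         paste(dim(nucleus), collapse = "x"), ")")
  if (anyNA(cell) || anyNA(nucleus)) stop("instance_masks: NA labels")
  if (any(cell != floor(cell)) || any(nucleus != floor(nucleus)))
    stop("instance_masks: labels must be integers (got float values)")
  if (min(cell) < 0 || min(nucleus) < 0)
    stop("instance_masks: negative labels")
  storage.mode(cell) <- "integer"
  storage.mode(nucleus) <- "integer"
  structure(list(cell = cell, nucleus = nucleus, pixel_size = pixel_size),
            class = "instance_masks")
}

#' @export
print.instance_masks <- function(x, ...) {
  cat(sprintf("instance_masks: %d x %d px, %d cells, %d nuclei, %.3f um/px\n",
              nrow(x$cell), ncol(x$cell),
              length(unique(x$cell[x$cell > 0L])),
              length(unique(x$nucleus[x$nucleus > 0L])), x$pixel_size))
  invisible(x)
}

#' Label connected components of a binary image
#'
#' 8-connectivity (default) or 4-connectivity. Base labeling is
#' `EBImage::bwlabel()` (4-connected); for 8-connectivity, labels that touch
#' diagonally are merged by union-find. Labels are renumbered 1..k in
#' row-major order of each component's first pixel, so the assignment is a
#' pure function of the input.
#'
#' @param binary logical or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer label matrix, 0 = background.
#' @export
label_components <- function(binary, connectivity = 8) {
  stopifnot(is.matrix(binary), connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(matrix(as.numeric(binary != 0), nrow(binary)))
  lab <- matrix(as.integer(round(lab)), nrow(binary))
  nlab <- max(lab)
  if (connectivity == 8 && nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
      cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
      cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # / diagonal
    pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      fg <- lab > 0L
      lab[fg] <- root[lab[fg]]
    }
  }
  relabel_rowmajor(lab)
}

# renumber positive labels 1..k ordered by each label's first pixel in a
# row-major scan
relabel_rowmajor <- function(lab) {
  pix <- which(lab > 0L)
  if (!length(pix)) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  l <- lab[pix]
  r <- (pix - 1L) %% nr + 1L
  cc <- (pix - 1L) %/% nr + 1L
  rm_idx <- (as.numeric(r) - 1) * nc + cc
  first <- tapply(rm_idx, l, min)
  ord <- order(first)
  map <- integer(max(l))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[pix] <- map[l]
  lab
}

#' Convert a 4-class semantic mask into instance masks
#'
#' The semantic convention encodes each pixel as 0 = background, 1 = cell,
#' 2 = nuclei, 3 = instance boundary. Cell instances are the connected
#' components of the cell-or-nuclei pixels with boundary pixels removed (the
#' boundary class is what separates touching cells); the nuclei pixels of a
#' component form that component's nucleus instance, sharing its label.
#' Boundary pixels are then reattributed to the geodesically nearest
#' instance (breadth-first search through the boundary region, ties to the
#' smallest label), so cell areas are not biased downward; set
#' `assign_boundary = FALSE` to leave them unassigned.
#'
#' @param semantic integer matrix with values in {0, 1, 2, 3}.
#' @param connectivity component connectivity, 8 (default) or 4.
#' @param assign_boundary reattribute boundary pixels (default TRUE).
#' @param pixel_size metadata, um/px.
#' @return an [instance_masks] object.
#' @export
semantic_to_instances <- function(semantic, connectivity = 8,
                                  assign_boundary = TRUE,
                                  pixel_size = 0.238) {
  stopifnot(is.matrix(semantic))
  if (!all(semantic %in% 0:3))
    stop("semantic_to_instances: values outside {0,1,2,3}: ",
         paste(utils::head(setdiff(unique(as.vector(semantic)), 0:3), 5),
               collapse = ", "))
  interior <- semantic == 1L | semantic == 2L
  lab <- label_components(interior, connectivity)
  if (assign_boundary && any(semantic == 3L) && max(lab) > 0L) {
    lab <- grow_into(lab, semantic == 3L, connectivity)
  }
  nuc <- lab
  nuc[semantic != 2L] <- 0L
  instance_masks(lab, nuc, pixel_size)
}

# multi-source BFS: propagate labels into `region` pixels, one geodesic
# step per round; ties within a round resolve to the smallest label
grow_into <- function(lab, region, connectivity = 8) {
  nr <- nrow(lab); nc <- ncol(lab)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  }
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  active <- region & lab == 0L
  while (any(active)) {
    nbmin <- matrix(Inf, nr, nc)
    for (o in offs) {
      s <- shift(lab, o[1], o[2])
      s[s == 0L] <- NA_integer_
      nbmin <- pmin(nbmin, s, na.rm = TRUE)
    }
    newly <- active & is.finite(nbmin)
    if (!any(newly)) break  # unreachable boundary pixels stay unassigned
    lab[newly] <- as.integer(nbmin[newly])
    active <- active & !newly
  }
  lab
}

read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, payload = FALSE)
    if (info$bits.per.sample[1] > 16L)
      stop("float (32-bit) TIFF not supported for label masks in ", path,
           "; write 8/16-bit integer labels")
    img <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    img <- round(png::readPNG(path) * 255)
  } else stop("unsupported mask format '", ext, "' (use TIFF or PNG)")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3] == 1L) img <- img[, , 1L]
    else stop("expected a single-channel label image: ", path)
  }
  if (any(img != floor(img)))
    stop("float pixel values in ", path, "; label masks must be integer")
  matrix(as.integer(img), nrow(img))
}

write_label_image <- function(mat, path) {
  stopifnot(is.matrix(mat))
  ext <- tolower(tools::file_ext(path))
  mx <- max(mat, 0L)
  if (ext %in% c("tif", "tiff")) {
    if (mx > 65535L) stop("more than 65535 labels; 16-bit TIFF cannot hold them")
    tiff::writeTIFF(mat / 65535, path, bits.per.sample = 16,
                    compression = "none")
  } else if (ext == "png") {
    if (mx > 255L)
      stop("mask has ", mx, " labels; 8-bit PNG holds at most 255 (use TIFF)")
    png::writePNG(mat / 255, path)
  } else stop("unsupported mask format '", ext, "' (use TIFF or PNG)")
  invisible(path)
}

#' Read / write paired instance masks
#'
#' Masks round-trip losslessly: 16-bit labeled TIFF for up to 65535 labels,
#' or 8-bit PNG for up to 255. Writing a PNG with more than 255 labels is
#' refused. Float-valued images are rejected on read.
#'
#' @param cell_path,nucleus_path image file paths (.tif/.tiff/.png).
#' @param pixel_size metadata, um/px.
#' @return `read_masks()` returns an [instance_masks]; `write_masks()`
#'   returns the paths invisibly.
#' @export
read_masks <- function(cell_path, nucleus_path, pixel_size = 0.238) {
  instance_masks(read_label_image(cell_path), read_label_image(nucleus_path),
                 pixel_size)
}

#' @param masks an [instance_masks] object.
#' @rdname read_masks
#' @export
write_masks <- function(masks, cell_path, nucleus_path) {
  stopifnot(inherits(masks, "instance_masks"))
  write_label_image(masks$cell, cell_path)
  write_label_image(masks$nucleus, nucleus_path)
  invisible(c(cell_path, nucleus_path))
}

#' Read / write detection tables
#'
#' CSV with header `image_id,row,col,confidence`; coordinates are 1-based
#' pixel indices at full resolution, confidences in [0, 1].
#'
#' @param path CSV file path.
#' @return data.frame with the four columns.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col", "confidence")
  if (!all(need %in% names(d)))
    stop("detection table must have columns: ", paste(need, collapse = ", "))
  d <- d[, need]
  if (any(d$confidence < 0 | d$confidence > 1))
    stop("confidences outside [0, 1]")
  d
}

#' @param detections data.frame with columns image_id, row, col, confidence.
#' @rdname read_detections
#' @export
write_detections <- function(detections, path) {
  need <- c("image_id", "row", "col", "confidence")
  stopifnot(all(need %in% names(detections)))
  if (any(detections$confidence < 0 | detections$confidence > 1))
    stop("confidences outside [0, 1]")
  utils::write.csv(detections[, need], path, row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell feature tables
#'
#' Plain CSV serialization of [extract_features()] output.
#'
#' @param features data.frame of per-cell records.
#' @param path CSV file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
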