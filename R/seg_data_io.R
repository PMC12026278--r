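# Reading and writing images, label masks, class palettes and dataset
# manifests, plus the resize/scale/flip preprocessing.
#
# Mask dialect: 8-bit single-channel PNG whose pixel value IS the class id
# (the PASCAL-VOC indexed convention). RGB masks are accepted on read by
# looking colors up in the palette; unknown colors are an error. Label maps
# in memory are integer matrices (H x W, row-major top-left origin, 0-based
# ids, 0 = background).

#' Class palette
#'
#' An ordered id-name-color table. Ids must be 0..K-1 with no gaps, colors
#' pairwise distinct, and id 0 is the background.
#'
#' @param names character vector of class names; `names[1]` must be
#'   "background".
#' @param colors K x 3 integer matrix of RGB triples in 0..255, or NULL to
#'   generate distinct colors (black background, evenly spaced hues).
#' @return data.frame of class `class_palette` with columns class_id, name,
#'   r, g, b.
#' @export
class_palette <- function(names, colors = NULL) {
  K <- length(names)
  if (K < 2L) stop("a palette needs at least background plus one class")
  if (names[1L] != "background") stop("class id 0 must be named 'background'")
  if (is.null(colors)) {
    hues <- grDevices::hsv(((seq_len(K - 1L) - 1L) * 0.61803) %% 1, 0.85, 0.95)
    colors <- rbind(c(0L, 0L, 0L), t(grDevices::col2rgb(hues)))
  }
  colors <- matrix(as.integer(colors), ncol = 3L)
  if (nrow(colors) != K) stop("colors must have one row per class")
  pal <- data.frame(class_id = 0:(K - 1L), name = names,
                    r = colors[, 1L], g = colors[, 2L], b = colors[, 3L],
                    stringsAsFactors = FALSE)
  validate_palette(pal)
  class(pal) <- c("class_palette", "data.frame")
  pal
}

validate_palette <- function(pal) {
  K <- nrow(pal)
  if (!identical(as.integer(pal$class_id), 0:(K - 1L)))
    stop("class ids must be 0..K-1 with no gaps")
  if (pal$name[1L] != "background") stop("class id 0 must be 'background'")
  key <- paste(pal$r, pal$g, pal$b)
  if (anyDuplicated(key)) stop("palette colors must be pairwise distinct")
  if (any(pal$r < 0 | pal$r > 255 | pal$g < 0 | pal$g > 255 |
          pal$b < 0 | pal$b > 255)) stop("colors must be 8-bit")
  invisible(pal)
}

#' Read / write a palette as JSON
#' @param path file path.
#' @export
read_palette <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  ord <- order(vapply(j, function(e) e$id, 1))
  j <- j[ord]
  class_palette(vapply(j, function(e) e$name, ""),
                t(vapply(j, function(e) as.integer(e$color), integer(3L))))
}

#' @rdname read_palette
#' @param palette a [class_palette()].
#' @export
write_palette <- function(palette, path) {
  entries <- lapply(seq_len(nrow(palette)), function(i) {
    list(id = palette$class_id[i], name = palette$name[i],
         color = c(palette$r[i], palette$g[i], palette$b[i]))
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE)
  invisible(path)
}

#' Segmentation sample
#'
#' Pairs an 8-bit RGB image with an integer label map of the same height
#' and width.
#'
#' @param image H x W x 3 array of intensities in 0..255.
#' @param labels H x W integer matrix of class ids.
#' @param source_id character identifier.
#' @param num_classes K; every label must be `< K`.
#' @return list of class `seg_sample`.
#' @export
seg_sample <- function(image, labels, source_id = "", num_classes) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("image must be H x W x 3")
  if (!identical(dim(image)[1:2], dim(labels)))
    stop("image and labels must share height and width")
  storage.mode(labels) <- "integer"
  if (min(labels) < 0L || max(labels) >= num_classes)
    stop("labels must lie in 0..K-1")
  structure(list(image = image, labels = labels, source_id = source_id,
                 num_classes = as.integer(num_classes)),
            class = "seg_sample")
}

#' Read an RGB image
#'
#' @param path PNG file.
#' @return H x W x 3 array of intensities in 0..255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  a <- switch(as.character(dim(a)[3L]),
              "1" = a[, , c(1L, 1L, 1L), drop = FALSE],
              "2" = a[, , c(1L, 1L, 1L), drop = FALSE],   # gray + alpha
              a[, , 1:3, drop = FALSE])
  round(a * 255)
}

#' Write an RGB image
#' @param image H x W x 3 array in 0..255.
#' @param path output PNG path.
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' Read a label mask
#'
#' Accepts a single-channel indexed mask (pixel value = class id) or an RGB
#' mask whose colors all appear in the palette.
#'
#' @param path mask PNG.
#' @param palette a [class_palette()].
#' @return H x W integer label matrix.
#' @export
read_mask <- function(path, palette) {
  if (!file.exists(path)) stop("no such file: ", path)
  a <- png::readPNG(path)
  K <- nrow(palette)
  if (length(dim(a)) == 2L) {
    ids <- round(a * 255)
    if (max(ids) >= K)
      stop("mask contains id ", max(ids), " but palette has K = ", K)
    storage.mode(ids) <- "integer"
    return(ids)
  }
  if (dim(a)[3L] >= 3L) {
    rgb <- round(a[, , 1:3] * 255)
    key <- rgb[, , 1L] * 65536 + rgb[, , 2L] * 256 + rgb[, , 3L]
    palkey <- palette$r * 65536 + palette$g * 256 + palette$b
    idx <- match(as.vector(key), palkey)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1L]
      stop(sprintf("mask color (%d,%d,%d) is not in the palette",
                   as.vector(rgb[, , 1L])[bad], as.vector(rgb[, , 2L])[bad],
                   as.vector(rgb[, , 3L])[bad]))
    }
    ids <- matrix(palette$class_id[idx], dim(a)[1L], dim(a)[2L])
    storage.mode(ids) <- "integer"
    return(ids)
  }
  stop("unsupported mask format: ", path)
}

#' Write a label mask
#'
#' Writes the indexed single-channel form (pixel value = class id), so
#' `read_mask(write_mask(x))` is pixel-exact.
#'
#' @param labels H x W integer label matrix, values `< nrow(palette)`.
#' @param palette a [class_palette()].
#' @param path output path.
#' @param rgb also write the color-rendered mask next to `path` (suffix
#'   `_rgb.png`), for inspection.
#' @export
write_mask <- function(labels, palette, path, rgb = FALSE) {
  K <- nrow(palette)
  if (max(labels) >= K || min(labels) < 0L)
    stop("labels contain ids outside 0..K-1 (K = ", K, ")")
  png::writePNG(labels / 255, path)
  if (rgb) {
    h <- dim(labels)[1L]; w <- dim(labels)[2L]
    img <- array(0, c(h, w, 3L))
    img[, , 1L] <- palette$r[labels + 1L] / 255
    img[, , 2L] <- palette$g[labels + 1L] / 255
    img[, , 3L] <- palette$b[labels + 1L] / 255
    png::writePNG(img, sub("\\.png$", "_rgb.png", path))
  }
  invisible(path)
}

#' Preprocess a sample for the network
#'
#' Resizes the image bilinearly to `side` x `side`, scales intensities to
#' `[0, 1]` (0 -> 0, 255 -> 1 exactly), and resizes labels with
#' nearest-neighbour interpolation (which never invents a class id). With
#' `training = TRUE`, image and labels are flipped horizontally together
#' with probability 1/2 under the current RNG state.
#'
#' @param sample a [seg_sample()].
#' @param side output side in pixels (> 0).
#' @param training apply the random flip.
#' @return list with `image` (array dim `c(3, side, side, 1)`) and `labels`
#'   (side x side integer matrix).
#' @export
preprocess <- function(sample, side = 512L, training = FALSE) {
  stopifnot(inherits(sample, "seg_sample"))
  side <- as.integer(side)
  if (side <= 0L) stop("side must be positive")
  d <- dim(sample$image)
  x <- aperm(sample$image, c(3L, 1L, 2L)) / 255     # (3,H,W)
  dim(x) <- c(3L, d[1L], d[2L], 1L)
  x <- resize_bilinear_fwd(x, 3L, d[1L], d[2L], 1L, side, side)
  dim(x) <- c(3L, side, side, 1L)
  lab <- resize_nearest_labels(sample$labels, side, side)
  if (training && stats::runif(1) < 0.5) {
    x <- x[, , rev(seq_len(side)), , drop = FALSE]
    lab <- lab[, rev(seq_len(side))]
  }
  list(image = x, labels = lab)
}

#' Dataset manifest
#'
#' @param items data.frame with columns `image`, `mask` (file paths).
#' @param split "train" or "test".
#' @param num_classes K.
#' @param check verify that all listed files exist.
#' @return list of class `dataset_manifest`.
#' @export
dataset_manifest <- function(items, split = c("train", "test"), num_classes,
                             check = TRUE) {
  split <- match.arg(split)
  stopifnot(is.data.frame(items), all(c("image", "mask") %in% names(items)))
  if (check && nrow(items)) {
    missing <- !file.exists(items$image) | !file.exists(items$mask)
    if (any(missing))
      stop("missing files in manifest: ",
           paste(items$image[missing], collapse = ", "))
  }
  structure(list(split = split, items = items,
                 num_classes = as.integer(num_classes)),
            class = "dataset_manifest")
}

#' Read / write a manifest CSV (columns image, mask)
#' @param path CSV path.
#' @param split,num_classes see [dataset_manifest()].
#' @export
read_manifest <- function(path, split = "train", num_classes) {
  items <- utils::read.csv(path, stringsAsFactors = FALSE)
  base <- dirname(path)
  items$image <- file.path(base, items$image)
  items$mask <- file.path(base, items$mask)
  dataset_manifest(items, split, num_classes)
}

#' @rdname read_manifest
#' @param manifest a [dataset_manifest()]; paths are stored relative to the
#'   CSV's directory.
#' @export
write_manifest <- function(manifest, path) {
  base <- dirname(path)
  items <- manifest$items
  rel <- function(p) {
    ifelse(startsWith(p, paste0(base, "/")),
           substring(p, nchar(base) + 2L), p)
  }
  utils::write.csv(data.frame(image = rel(items$image),
                              mask = rel(items$mask)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every sample a manifest lists
#' @param manifest a [dataset_manifest()].
#' @param palette matching [class_palette()].
#' @return list of `seg_sample` objects.
#' @export
load_samples <- function(manifest, palette) {
  lapply(seq_len(nrow(manifest$items)), function(i) {
    seg_sample(read_image(manifest$items$image[i]),
               read_mask(manifest$items$mask[i], palette),
               source_id = basename(manifest$items$image[i]),
               num_classes = manifest$num_classes)
  })
}
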