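# Deterministic synthetic plate scenes.
#
# Each scene is a dark tabletop, a bright circular plate, and 0..n textured
# elliptical food blobs drawn inside the plate. Blob classes are sampled
# from a long-tailed weight vector (weights proportional to 1/rank by
# default, mirroring the class imbalance of real food-segmentation sets);
# later blobs occlude earlier ones, emulating stacked/overlapping items.
# Every scene is a pure function of (seed, index), so datasets are
# bit-reproducible, and a JSON sidecar records the visible per-class pixel
# areas and the plate geometry for downstream ground-truth checks.

#' Scene specification for the synthetic generator
#'
#' @param num_classes K including background (K >= 2).
#' @param seed integer master seed.
#' @param items_per_scene length-2 integer range (min, max) of blobs.
#' @param class_weights sampling weights for the K-1 food classes;
#'   default long tail `1/rank`. Non-negative, sum > 0.
#' @param canvas_side square image side in pixels.
#' @param plate_radius_fraction plate radius as a fraction of the side.
#' @param noise_sd per-pixel intensity noise (8-bit units).
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(num_classes = 4L, seed = 0L,
                       items_per_scene = c(1L, 3L), class_weights = NULL,
                       canvas_side = 128L, plate_radius_fraction = 0.42,
                       noise_sd = 14) {
  K <- as.integer(num_classes)
  if (K < 2L) stop("num_classes must be >= 2")
  if (is.null(class_weights)) class_weights <- 1 / seq_len(K - 1L)
  if (length(class_weights) != K - 1L)
    stop("class_weights must have K-1 entries")
  if (any(class_weights < 0) || sum(class_weights) <= 0)
    stop("class_weights must be non-negative with positive sum")
  if (length(items_per_scene) != 2L || any(items_per_scene < 0) ||
      items_per_scene[1L] > items_per_scene[2L])
    stop("items_per_scene must be a non-decreasing (min, max) pair")
  structure(list(num_classes = K, seed = as.integer(seed),
                 items_per_scene = as.integer(items_per_scene),
                 class_weights = class_weights,
                 canvas_side = as.integer(canvas_side),
                 plate_radius_fraction = plate_radius_fraction,
                 noise_sd = noise_sd),
            class = "scene_spec")
}

#' Palette for a scene specification
#'
#' Background plus K-1 generic food classes with distinct saturated colors.
#' @param spec a [scene_spec()].
#' @return a [class_palette()].
#' @export
scene_palette <- function(spec) {
  foods <- c("rice", "beans", "chicken", "salad", "potato", "stew", "fish",
             "pasta", "bread", "egg", "beef", "soup", "fruit", "cheese")
  K <- spec$num_classes
  nm <- foods[((seq_len(K - 1L) - 1L) %% length(foods)) + 1L]
  dup <- duplicated(nm)
  nm[dup] <- paste0(nm[dup], "_", cumsum(dup)[dup] + 1L)
  class_palette(c("background", nm))
}

#' Generate one synthetic plate scene
#'
#' Fully reproducible from `(spec$seed, index)`.
#'
#' @param spec a [scene_spec()].
#' @param index non-negative scene index.
#' @return a [seg_sample()] with attributes `areas` (named visible pixel
#'   count per food class recomputed from the final mask), `plate`
#'   (center/radius/area of the drawn plate) and `palette`.
#' @export
generate_scene <- function(spec, index = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed((spec$seed * 99991L + as.integer(index)) %% .Machine$integer.max)
  S <- spec$canvas_side
  pal <- scene_palette(spec)
  rows <- matrix(seq_len(S), S, S)
  cols <- matrix(seq_len(S), S, S, byrow = TRUE)
  img <- array(0, c(S, S, 3L))
  for (ch in 1:3) img[, , ch] <- 38 + 6 * ch           # dark tabletop
  labels <- matrix(0L, S, S)
  cx <- S / 2 + stats::runif(1, -0.03, 0.03) * S
  cy <- S / 2 + stats::runif(1, -0.03, 0.03) * S
  pr <- spec$plate_radius_fraction * S
  plate <- (rows - cy)^2 + (cols - cx)^2 <= pr^2
  for (ch in 1:3) {
    m <- img[, , ch]
    m[plate] <- 228 - 4 * ch
    img[, , ch] <- m
  }
  n_items <- if (spec$items_per_scene[2L] == 0L) 0L else
    sample(spec$items_per_scene[1L]:spec$items_per_scene[2L], 1L)
  for (i in seq_len(n_items)) {
    cls <- sample.int(spec$num_classes - 1L, 1L, prob = spec$class_weights)
    a <- stats::runif(1, 0.30, 0.62) * pr
    b <- stats::runif(1, 0.30, 0.62) * pr
    th <- stats::runif(1, 0, pi)
    rmax <- max(pr - max(a, b) - 1, 1)
    ang <- stats::runif(1, 0, 2 * pi)
    rr <- stats::runif(1, 0, rmax)
    bx <- cx + rr * cos(ang); by <- cy + rr * sin(ang)
    u <- (rows - bx) * cos(th) + (cols - by) * sin(th)
    v <- -(rows - bx) * sin(th) + (cols - by) * cos(th)
    inside <- (u / a)^2 + (v / b)^2 <= 1
    labels[inside] <- cls
    base <- c(pal$r[cls + 1L], pal$g[cls + 1L], pal$b[cls + 1L])
    for (ch in 1:3) {
      m <- img[, , ch]
      m[inside] <- base[ch]
      img[, , ch] <- m
    }
  }
  img <- img + array(stats::rnorm(S * S * 3, 0, spec$noise_sd), dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  areas <- tabulate(labels[labels > 0L], nbins = spec$num_classes - 1L)
  names(areas) <- pal$name[-1L]
  smp <- seg_sample(img, labels, source_id = sprintf("scene_%05d", index),
                    num_classes = spec$num_classes)
  attr(smp, "areas") <- areas
  attr(smp, "plate") <- list(center = c(cy, cx), radius = pr,
                             area = sum(plate))
  attr(smp, "palette") <- pal
  smp
}

#' Generate a dataset tree on disk
#'
#' Writes images, indexed masks, the palette JSON, train/test manifest CSVs,
#' per-scene area sidecars, and a toy composition table. Train scenes use
#' indices `0..n_train-1` and test scenes `n_train..n_train+n_test-1`, so
#' the splits are disjoint by construction.
#'
#' @param spec a [scene_spec()].
#' @param n_train,n_test split sizes (>= 0).
#' @param out_dir output directory (created if needed).
#' @return list with `train` and `test` [dataset_manifest()]s, `palette`,
#'   and `composition` (a [composition_table()]).
#' @export
generate_dataset <- function(spec, n_train, n_test, out_dir) {
  stopifnot(n_train >= 0L, n_test >= 0L)
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "scenes"), showWarnings = FALSE)
  pal <- scene_palette(spec)
  write_palette(pal, file.path(out_dir, "palette.json"))
  comp <- toy_composition(pal)
  write_composition(comp, file.path(out_dir, "composition.csv"))
  emit <- function(indices, split) {
    items <- data.frame(image = character(0), mask = character(0))
    for (i in indices) {
      smp <- generate_scene(spec, i)
      ipath <- file.path(out_dir, "images", sprintf("scene_%05d.png", i))
      mpath <- file.path(out_dir, "masks", sprintf("scene_%05d.png", i))
      write_image(smp$image, ipath)
      write_mask(smp$labels, pal, mpath)
      jsonlite::write_json(
        list(index = i, areas = as.list(attr(smp, "areas")),
             plate = attr(smp, "plate")),
        file.path(out_dir, "scenes", sprintf("scene_%05d.json", i)),
        auto_unbox = TRUE)
      items <- rbind(items, data.frame(image = ipath, mask = mpath))
    }
    man <- dataset_manifest(items, split, spec$num_classes)
    write_manifest(man, file.path(out_dir, paste0("manifest_", split, ".csv")))
    man
  }
  train <- emit(seq_len(n_train) - 1L, "train")
  test <- emit(n_train + seq_len(n_test) - 1L, "test")
  list(train = train, test = test, palette = pal, composition = comp)
}

## deterministic toy composition values per food class
toy_composition <- function(palette) {
  foods <- palette[-1L, ]
  k <- nrow(foods)
  composition_table(data.frame(
    class_id = foods$class_id,
    name = foods$name,
    reference_serving_grams = 150 + 25 * (foods$class_id %% 7L),
    kcal_100g = 80 + 30 * (foods$class_id %% 5L),
    protein_100g = 2 + 4 * (foods$class_id %% 4L),
    carb_100g = 5 + 10 * (foods$class_id %% 3L),
    stringsAsFactors = FALSE
  ))
}
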