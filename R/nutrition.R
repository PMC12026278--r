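# Nutrient estimation from a segmentation mask.
#
# The plate is located as the minimum enclosing circle of all non-background
# pixels (radius inflated by a small margin); each food's plate-area
# fraction is converted to grams by linear scaling of a reference
# full-plate serving weight, and grams to energy/protein/carbohydrate via
# per-100 g composition values. Volume, stacking and occlusion are
# deliberately not modelled: estimates are area-proportional by design.

#' Food composition table
#'
#' @param df data.frame with columns `class_id`, `name`,
#'   `reference_serving_grams` (grams corresponding to a full-plate
#'   portion), `kcal_100g`, `protein_100g`, `carb_100g`. All values must be
#'   non-negative.
#' @return data.frame of class `composition_table`.
#' @export
composition_table <- function(df) {
  need <- c("class_id", "name", "reference_serving_grams", "kcal_100g",
            "protein_100g", "carb_100g")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)), collapse = ", "))
  num <- df[, need[-(1:2)]]
  if (any(as.matrix(num) < 0)) stop("composition values must be >= 0")
  df <- df[, need]
  class(df) <- c("composition_table", "data.frame")
  df
}

#' Read / write a composition table CSV
#' @param path CSV path.
#' @export
read_composition <- function(path) composition_table(utils::read.csv(path,
  stringsAsFactors = FALSE))

#' @rdname read_composition
#' @param table a [composition_table()].
#' @export
write_composition <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit the plate circle to a label map
#'
#' Minimum enclosing circle of all non-background pixels (exact, via the
#' convex hull and Welzl's algorithm), with the radius inflated by
#' `margin`. The plate area is the count of pixel centres inside the
#' inflated circle.
#'
#' @param labels H x W integer label map with at least one non-zero pixel.
#' @param margin relative radius inflation (default 5%).
#' @return list of class `plate_region`: `center` (row, col), `radius`,
#'   `total_area`.
#' @export
fit_plate_circle <- function(labels, margin = 0.05) {
  pts <- which(labels != 0L, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("all-background mask: no plate to fit")
  hull <- pts[grDevices::chull(pts[, 1L], pts[, 2L]), , drop = FALSE]
  mec <- welzl_mec(hull)
  radius <- mec$r * (1 + margin)
  h <- dim(labels)[1L]; w <- dim(labels)[2L]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- (rows - mec$c[1L])^2 + (cols - mec$c[2L])^2 <= radius^2
  structure(list(center = mec$c, radius = radius, total_area = sum(inside),
                 inside = inside),
            class = "plate_region")
}

## exact minimum enclosing circle of a small point set (Welzl, move-to-front)
welzl_mec <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(c = as.numeric(pts[1L, ]), r = 0))
  circ2 <- function(p, q) {
    c0 <- (p + q) / 2
    list(c = c0, r = sqrt(sum((p - c0)^2)))
  }
  circ3 <- function(p, q, r) {
    ax <- p[1L]; ay <- p[2L]; bx <- q[1L]; by <- q[2L]; cx <- r[1L]; cy <- r[2L]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-12) {
      cands <- list(circ2(p, q), circ2(p, r), circ2(q, r))
      rs <- vapply(cands, function(cc) cc$r, 1)
      best <- cands[[which.max(rs)]]
      return(best)
    }
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
    c0 <- c(ux, uy)
    list(c = c0, r = sqrt(sum((p - c0)^2)))
  }
  inc <- function(circle, p, eps = 1e-7)
    sqrt(sum((p - circle$c)^2)) <= circle$r + eps
  trivial <- function(boundary) {
    nb <- length(boundary)
    if (nb == 0L) return(list(c = c(0, 0), r = -1))
    if (nb == 1L) return(list(c = boundary[[1L]], r = 0))
    if (nb == 2L) return(circ2(boundary[[1L]], boundary[[2L]]))
    circ3(boundary[[1L]], boundary[[2L]], boundary[[3L]])
  }
  ord <- sample.int(n)   # randomized order; expected linear time
  pl <- lapply(ord, function(i) as.numeric(pts[i, ]))
  mec_rec <- function(i, boundary) {
    if (i > n || length(boundary) == 3L) return(trivial(boundary))
    circle <- mec_rec(i + 1L, boundary)
    p <- pl[[i]]
    if (circle$r >= 0 && inc(circle, p)) return(circle)
    mec_rec(i + 1L, c(boundary, list(p)))
  }
  old <- options(expressions = 500000L)
  on.exit(options(old))
  mec_rec(1L, list())
}

#' Plate-area fractions per food class
#'
#' For every food class (id >= 1), the fraction of plate pixels the class
#' occupies: pixels of that class inside the plate circle divided by the
#' plate's total pixel count.
#'
#' @param labels H x W integer label map.
#' @param plate a [fit_plate_circle()] result.
#' @param num_classes K (labels must be < K); defaults to `max(labels)+1`.
#' @return named numeric vector of length K-1 (class ids 1..K-1), in [0, 1].
#' @export
area_fractions <- function(labels, plate, num_classes = max(labels) + 1L) {
  K <- as.integer(num_classes)
  lab_in <- labels[plate$inside]
  counts <- tabulate(lab_in[lab_in > 0L], nbins = K - 1L)
  fr <- counts / plate$total_area
  names(fr) <- as.character(seq_len(K - 1L))
  fr
}

#' Estimate grams and nutrients from area fractions
#'
#' `grams_c = fraction_c * reference_serving_grams_c`; each nutrient is
#' `grams_c * per100g_c / 100`. Foods occupying area but missing from the
#' composition table are flagged `unknown` and excluded from the totals
#' (with a warning).
#'
#' @param fractions named fractions from [area_fractions()] (names are
#'   class ids).
#' @param table a [composition_table()].
#' @param palette optional [class_palette()] used to attach food names.
#' @return object of class `nutrient_estimate`: data.frame `per_food`
#'   (class_id, name, area_fraction, grams, kcal, protein_g, carb_g,
#'   unknown) plus a `totals` attribute.
#' @export
estimate_nutrients <- function(fractions, table, palette = NULL) {
  ids <- as.integer(names(fractions))
  m <- match(ids, table$class_id)
  unknown <- is.na(m) & fractions > 0
  if (any(unknown))
    warning("no composition entry for class id(s) ",
            paste(ids[unknown], collapse = ", "), "; excluded from totals")
  ref <- ifelse(is.na(m), NA_real_, table$reference_serving_grams[m])
  grams <- fractions * ref
  per <- data.frame(
    class_id = ids,
    name = if (!is.null(palette)) palette$name[ids + 1L]
           else ifelse(is.na(m), NA_character_, table$name[m]),
    area_fraction = as.numeric(fractions),
    grams = as.numeric(grams),
    kcal = as.numeric(grams * ifelse(is.na(m), NA_real_, table$kcal_100g[m]) / 100),
    protein_g = as.numeric(grams * ifelse(is.na(m), NA_real_, table$protein_100g[m]) / 100),
    carb_g = as.numeric(grams * ifelse(is.na(m), NA_real_, table$carb_100g[m]) / 100),
    unknown = unknown,
    stringsAsFactors = FALSE
  )
  keep <- !per$unknown & !is.na(per$grams)
  totals <- c(grams = sum(per$grams[keep]), kcal = sum(per$kcal[keep]),
              protein_g = sum(per$protein_g[keep]),
              carb_g = sum(per$carb_g[keep]))
  structure(per, totals = totals, class = c("nutrient_estimate", "data.frame"))
}

#' Full mask-to-nutrients chain
#'
#' @param labels label map with at least one food pixel.
#' @param table a [composition_table()].
#' @param num_classes K.
#' @param margin plate-circle margin.
#' @param palette optional palette for names.
#' @return a `nutrient_estimate` (with the fitted `plate` as an attribute).
#' @export
nutrients_from_mask <- function(labels, table, num_classes = max(labels) + 1L,
                                margin = 0.05, palette = NULL) {
  plate <- fit_plate_circle(labels, margin)
  fr <- area_fractions(labels, plate, num_classes)
  est <- estimate_nutrients(fr, table, palette)
  attr(est, "plate") <- plate
  est
}
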