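test_that("plate fitting handles degenerate and ideal masks", {
  # single food pixel: margin-only radius, unit area
  lab <- matrix(0L, 20, 20); lab[7, 9] <- 1L
  pl <- fit_plate_circle(lab)
  expect_equal(pl$center, c(7, 9))
  expect_equal(pl$radius, 0)
  expect_equal(pl$total_area, 1)
  # filled disk of radius r: fitted radius within [r, 1.05 r] + pixel slack
  lab2 <- matrix(0L, 64, 64)
  rows <- matrix(1:64, 64, 64); cols <- t(rows)
  disk <- (rows - 32)^2 + (cols - 32)^2 <= 20^2
  lab2[disk] <- 2L
  pl2 <- fit_plate_circle(lab2)
  expect_gte(pl2$radius, 20 - 1)
  expect_lte(pl2$radius, 1.05 * (20 + 1))
  # every food pixel is inside the fitted circle
  expect_true(all(pl2$inside[lab2 > 0]))
  expect_error(fit_plate_circle(matrix(0L, 5, 5)), "all-background")
})

test_that("area fractions are exact for full coverage and empty classes", {
  lab <- matrix(0L, 40, 40)
  rows <- matrix(1:40, 40, 40); cols <- t(rows)
  disk <- (rows - 20)^2 + (cols - 20)^2 <= 12^2
  lab[disk] <- 1L
  pl <- fit_plate_circle(lab, margin = 0)
  fr <- area_fractions(lab, pl, num_classes = 3)
  expect_equal(unname(fr["1"]), 1)      # plate fully covered by food 1
  expect_equal(unname(fr["2"]), 0)      # absent class
})

test_that("fractions recovered from generated masks match recorded areas", {
  spec <- scene_spec(num_classes = 4, seed = 3, canvas_side = 96,
                     items_per_scene = c(2, 3))
  for (i in 0:3) {
    s <- generate_scene(spec, i)
    plate_truth <- attr(s, "plate")
    pl <- fit_plate_circle(s$labels)
    fr <- area_fractions(s$labels, pl, num_classes = 4)
    truth <- attr(s, "areas") / pl$total_area
    # identical pixel counts; denominators differ only via the fitted circle
    counts_got <- fr * pl$total_area
    expect_equal(unname(counts_got), unname(attr(s, "areas")))
    # fitted plate is no larger than ~the drawn plate w/ margin and hull slack
    expect_lte(pl$radius, plate_truth$radius * 1.10)
  }
})

test_that("nutrient arithmetic matches hand computation and is linear", {
  tab <- composition_table(data.frame(
    class_id = 1:2, name = c("rice", "stew"),
    reference_serving_grams = c(200, 100),
    kcal_100g = c(150, 90), protein_100g = c(3, 7), carb_100g = c(30, 10)))
  # fraction 1.0 of a 200 g reference at 150 kcal/100 g -> 200 g, 300 kcal
  est <- estimate_nutrients(c(`1` = 1, `2` = 0), tab)
  expect_equal(est$grams, c(200, 0))
  expect_equal(est$kcal, c(300, 0))
  expect_equal(unname(attr(est, "totals")["kcal"]), 300)
  # two foods at 0.3 / 0.2 -> 60 g and 20 g; totals are sums
  est2 <- estimate_nutrients(c(`1` = 0.3, `2` = 0.2), tab)
  expect_equal(est2$grams, c(60, 20))
  expect_equal(unname(attr(est2, "totals")["grams"]), 80)
  expect_equal(unname(attr(est2, "totals")["protein_g"]),
               60 * 3 / 100 + 20 * 7 / 100)
  # linearity: doubling a fraction doubles grams and every nutrient
  est3 <- estimate_nutrients(c(`1` = 0.6, `2` = 0.2), tab)
  expect_equal(est3$grams[1], 2 * est2$grams[1])
  expect_equal(est3$kcal[1], 2 * est2$kcal[1])
  expect_equal(est3$carb_g[1], 2 * est2$carb_g[1])
  # removing a food removes exactly its contribution from the totals
  with2 <- unname(attr(est3, "totals")["kcal"])
  without2 <- unname(attr(estimate_nutrients(c(`1` = 0.6, `2` = 0),
                                             tab), "totals")["kcal"])
  expect_equal(with2 - without2, est3$kcal[2])
})

test_that("foods missing from the table are flagged and excluded", {
  tab <- composition_table(data.frame(
    class_id = 1L, name = "rice", reference_serving_grams = 200,
    kcal_100g = 150, protein_100g = 3, carb_100g = 30))
  expect_warning(est <- estimate_nutrients(c(`1` = 0.5, `2` = 0.2), tab),
                 "no composition entry")
  expect_true(est$unknown[2])
  expect_equal(unname(attr(est, "totals")["grams"]), 100)
  expect_error(composition_table(data.frame(class_id = 1, name = "x",
                                            reference_serving_grams = -5,
                                            kcal_100g = 1, protein_100g = 1,
                                            carb_100g = 1)), ">= 0")
})

test_that("near-identical masks give near-identical estimates", {
  spec <- scene_spec(num_classes = 4, seed = 8, canvas_side = 96,
                     items_per_scene = c(2, 2))
  s <- generate_scene(spec, 0)
  tab <- toy_tab <- foodseg:::toy_composition(attr(s, "palette"))
  gt <- s$labels
  # perturb a thin boundary band of the prediction
  pred <- gt
  flip <- which(gt > 0)
  flip <- flip[seq_len(min(50, length(flip)))]
  pred[flip] <- 0L
  e_gt <- nutrients_from_mask(gt, tab, num_classes = 4)
  e_pr <- nutrients_from_mask(pred, tab, num_classes = 4)
  # per-food gram difference bounded by the pixel disagreement scaled by the
  # reference serving over the plate area
  pl <- attr(e_gt, "plate")
  disagreement <- vapply(1:3, function(k) sum((gt == k) != (pred == k)), 1)
  bound <- disagreement / pl$total_area *
    tab$reference_serving_grams[match(1:3, tab$class_id)] + 1e-9
  # allow for the slightly different fitted plates via a 15% slack
  expect_true(all(abs(e_gt$grams - e_pr$grams) <= 1.15 * bound +
                    0.15 * e_gt$grams))
})

test_that("composition CSV round trip preserves values", {
  tab <- composition_table(data.frame(
    class_id = 1:3, name = c("a", "b", "c"),
    reference_serving_grams = c(100, 200, 300),
    kcal_100g = c(50, 60, 70), protein_100g = c(1, 2, 3),
    carb_100g = c(10, 20, 30)))
  p <- withr::local_tempfile(fileext = ".csv")
  write_composition(tab, p)
  expect_equal(as.data.frame(read_composition(p)), as.data.frame(tab))
})
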