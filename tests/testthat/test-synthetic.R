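test_that("scene generation is bit-reproducible and validates its spec", {
  spec <- scene_spec(num_classes = 4, seed = 7, canvas_side = 64)
  a <- generate_scene(spec, 3)
  b <- generate_scene(spec, 3)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- generate_scene(spec, 4)
  expect_false(identical(a$labels, c$labels))
  expect_error(scene_spec(num_classes = 1), ">= 2")
  expect_error(scene_spec(num_classes = 3, class_weights = c(-1, 1)),
               "non-negative")
  expect_error(scene_spec(items_per_scene = c(3, 1)), "non-decreasing")
})

test_that("degenerate scene specs behave as contracted", {
  empty <- scene_spec(num_classes = 3, seed = 0, canvas_side = 48,
                      items_per_scene = c(0, 0))
  s <- generate_scene(empty, 0)
  expect_true(all(s$labels == 0L))
  onecls <- scene_spec(num_classes = 4, seed = 0, canvas_side = 48,
                       class_weights = c(1, 0, 0), items_per_scene = c(2, 3))
  for (i in 0:5) {
    lab <- generate_scene(onecls, i)$labels
    expect_true(all(lab %in% c(0L, 1L)))
  }
})

test_that("recorded blob areas equal areas recomputed from the mask", {
  spec <- scene_spec(num_classes = 4, seed = 2, canvas_side = 64)
  for (i in 0:4) {
    s <- generate_scene(spec, i)
    recomputed <- tabulate(s$labels[s$labels > 0], nbins = 3)
    expect_equal(unname(attr(s, "areas")), recomputed)
  }
})

test_that("long-tailed class weights shape empirical frequencies", {
  spec <- scene_spec(num_classes = 5, seed = 0, canvas_side = 32,
                     items_per_scene = c(1, 2))
  counts <- integer(4)
  for (i in 0:499) {
    lab <- generate_scene(spec, i)$labels
    present <- unique(lab[lab > 0])
    counts[present] <- counts[present] + 1L
  }
  # image counts ordered like the 1/rank weights
  expect_identical(order(counts, decreasing = TRUE), 1:4)
})

test_that("generated dataset trees are valid, disjoint and reloadable", {
  td <- withr::local_tempdir()
  spec <- scene_spec(num_classes = 3, seed = 5, canvas_side = 48)
  ds <- generate_dataset(spec, 8, 2, td)
  expect_equal(nrow(ds$train$items), 8)
  expect_equal(nrow(ds$test$items), 2)
  expect_length(intersect(ds$train$items$image, ds$test$items$image), 0)
  pal <- read_palette(file.path(td, "palette.json"))
  samples <- load_samples(ds$test, pal)
  expect_true(all(vapply(samples, function(s) max(s$labels) < 3, TRUE)))
  # empty split remains valid
  td2 <- withr::local_tempdir()
  ds2 <- generate_dataset(spec, 0, 2, td2)
  expect_equal(nrow(ds2$train$items), 0)
})
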