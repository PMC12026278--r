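test_that("palette invariants are enforced", {
  pal <- class_palette(c("background", "rice", "beans"))
  expect_s3_class(pal, "class_palette")
  expect_identical(pal$class_id, 0:2)
  expect_error(class_palette(c("rice", "beans")), "background")
  expect_error(class_palette(c("background", "a", "b"),
                             colors = rbind(c(0, 0, 0), c(1, 2, 3), c(1, 2, 3))),
               "distinct")
})

test_that("palette JSON round trip preserves ids, names and colors", {
  pal <- class_palette(c("background", "rice", "beans", "stew"))
  p <- withr::local_tempfile(fileext = ".json")
  write_palette(pal, p)
  pal2 <- read_palette(p)
  expect_equal(as.data.frame(pal2), as.data.frame(pal))
})

test_that("mask write/read round trip is pixel-exact", {
  pal <- class_palette(c("background", "a", "b", "c", "d"))
  p <- withr::local_tempfile(fileext = ".png")
  # all-background identity case
  z <- matrix(0L, 7, 9)
  write_mask(z, pal, p)
  expect_identical(read_mask(p, pal), z)
  # map using a subset of ids {0,3}
  m <- matrix(0L, 12, 10); m[3:6, 2:5] <- 3L
  write_mask(m, pal, p)
  got <- read_mask(p, pal)
  expect_identical(got, m)
  expect_setequal(unique(as.vector(got)), c(0L, 3L))
  # random valid map under a fixed seed
  set.seed(0)
  r <- rand_labels(16, 11, 5)
  write_mask(r, pal, p)
  expect_identical(read_mask(p, pal), r)
})

test_that("mask contract violations raise", {
  pal <- class_palette(c("background", "a", "b"))
  p <- withr::local_tempfile(fileext = ".png")
  expect_error(write_mask(matrix(3L, 4, 4), pal, p), "0..K-1")
  # RGB mask with a color missing from the palette
  img <- array(0, c(4, 4, 3)); img[1, 1, ] <- c(10, 20, 30) / 255
  png::writePNG(img, p)
  expect_error(read_mask(p, pal), "not in the palette")
  expect_error(read_mask(file.path(tempdir(), "nope.png"), pal), "no such file")
})

test_that("RGB masks are decoded through the palette", {
  pal <- class_palette(c("background", "a", "b"))
  m <- matrix(0L, 6, 6); m[2:4, 2:4] <- 2L
  p <- withr::local_tempfile(fileext = ".png")
  write_mask(m, pal, p, rgb = TRUE)
  rgb_path <- sub("\\.png$", "_rgb.png", p)
  expect_identical(read_mask(rgb_path, pal), m)
})

test_that("preprocess scales exactly and preserves size-512-free contracts", {
  K <- 3L
  img <- array(255, c(64, 64, 3))
  img[1:32, , ] <- 0
  s <- seg_sample(img, matrix(0L, 64, 64), num_classes = K)
  pr <- preprocess(s, side = 64)
  expect_equal(dim(pr$image), c(3, 64, 64, 1))
  expect_equal(max(pr$image), 1)   # 255 -> 1.0 exactly
  expect_equal(min(pr$image), 0)   # 0 -> 0.0 exactly
  # constant image upsamples to the same constant
  s2 <- seg_sample(array(100, c(16, 16, 3)), matrix(1L, 16, 16),
                   num_classes = K)
  pr2 <- preprocess(s2, side = 64)
  expect_true(all(abs(pr2$image - 100 / 255) < 1e-12))
  expect_true(all(pr2$labels == 1L))
  expect_error(preprocess(s2, side = 0), "positive")
})

test_that("flip mirrors labels and conserves per-class pixel counts", {
  smp <- tiny_samples(1, side = 64)[[1]]
  base <- preprocess(smp, side = 64, training = FALSE)
  set.seed(1)
  flip_expected <- {
    set.seed(1)
    stats::runif(1) < 0.5
  }
  set.seed(1)
  pr <- preprocess(smp, side = 64, training = TRUE)
  if (flip_expected) {
    expect_identical(pr$labels, base$labels[, 64:1])
  } else {
    expect_identical(pr$labels, base$labels)
  }
  expect_identical(tabulate(pr$labels + 1L, 3), tabulate(base$labels + 1L, 3))
  # nearest-neighbour resize never invents a class id
  small <- preprocess(smp, side = 48)
  expect_true(all(unique(as.vector(small$labels)) %in%
                    unique(as.vector(smp$labels))))
})

test_that("manifest round trip validates file existence", {
  td <- withr::local_tempdir()
  ds <- generate_dataset(scene_spec(num_classes = 3, seed = 1,
                                    canvas_side = 48), 3, 1, td)
  man <- read_manifest(file.path(td, "manifest_train.csv"), "train", 3)
  expect_equal(nrow(man$items), 3)
  expect_true(all(file.exists(man$items$image)))
  bad <- man$items
  bad$image[1] <- file.path(td, "missing.png")
  expect_error(dataset_manifest(bad, "train", 3), "missing")
})
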