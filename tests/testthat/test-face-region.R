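test_that("landmark sets enforce the 68-point contract", {
  expect_s3_class(landmark_set(runif(68, 1, 50), runif(68, 1, 50)), "landmark_set")
  expect_error(landmark_set(runif(67), runif(67)), class = "exprfeat_invalid_landmarks")
  expect_error(landmark_set(c(NA, runif(67)), runif(68)),
               class = "exprfeat_invalid_landmarks")
})

test_that("landmark sidecars round-trip", {
  lm <- landmark_set(runif(68, 1, 99.5), runif(68, 1, 99.5))
  f <- withr::local_tempfile(fileext = ".pts")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(back$x, lm$x, tolerance = 1e-8)
  expect_equal(back$y, lm$y, tolerance = 1e-8)
})

test_that("grayscale conversion uses BT.601 weights and is identity on gray input", {
  g <- matrix(sample(0:255, 100, TRUE), 10, 10)
  expect_identical(to_grayscale(g), g)
  rgb <- array(0, c(4, 4, 3))
  rgb[, , 1] <- 200; rgb[, , 2] <- 100; rgb[, , 3] <- 50
  expect_true(all(to_grayscale(rgb) == round(0.299 * 200 + 0.587 * 100 + 0.114 * 50)))
})

test_that("PGM images round-trip through the plain-text writer", {
  img <- matrix(sample(0:255, 30 * 20, TRUE), 20, 30)
  f <- withr::local_tempfile(fileext = ".pgm")
  write_image(img, f)
  expect_identical(read_image(f), img)
})

test_that("PNG images round-trip at 8-bit precision", {
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(img, f)
  expect_identical(read_image(f), img)
})

test_that("crop output is always 130x130 and full-span landmarks reduce crop to a resize", {
  for (n in c(150, 260, 333)) {
    img <- rand_face(n, n = n)
    lm <- landmark_set(runif(68, 5, n - 5), runif(68, 5, n - 5))
    expect_identical(dim(crop_face(img, lm)), c(130L, 130L))
  }
  ## points 1-27 spanning the whole image: crop is the identity, only resize acts
  img <- rand_face(99, n = 260)
  x <- c(1, runif(25, 2, 259), 260, runif(41, 2, 259))
  y <- c(1, runif(25, 2, 259), 260, runif(41, 2, 259))
  out <- crop_face(img, landmark_set(x, y))
  expect_identical(unclass(out)[, ], resize_bilinear(img, 130, 130)[, ])
})

test_that("cropping is invariant to a common integer translation", {
  base <- rand_face(5, n = 80)
  lx <- runif(68, 8, 72); ly <- runif(68, 8, 72)
  canvas1 <- matrix(0L, 200, 200); canvas1[1:80, 1:80] <- base
  canvas2 <- matrix(0L, 200, 200); canvas2[101:180, 61:140] <- base
  out1 <- crop_face(canvas1, landmark_set(lx, ly))
  out2 <- crop_face(canvas2, landmark_set(lx + 60, ly + 100))
  expect_identical(unclass(out1)[, ], unclass(out2)[, ])
})

test_that("degenerate and invalid landmark geometry is rejected", {
  img <- rand_face(1, n = 60)
  same <- landmark_set(rep(30, 68), rep(30, 68))
  expect_error(crop_face(img, same), class = "exprfeat_degenerate_region")
})

test_that("crop of a synthetic face matches the generator's stored ground-truth patch", {
  g <- generate_face(synthetic_spec(seed = 3), 2, 1, 1)
  out <- crop_face(g$image, g$landmarks)
  expect_identical(attr(out, "face_box"), g$truth$crop_box)
  expect_identical(unclass(out)[, ],
                   resize_bilinear(g$truth$face_patch, 130, 130)[, ])
})
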