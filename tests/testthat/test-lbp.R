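test_that("lbp_code follows the thresholding definition bit by bit", {
  expect_identical(lbp_code(matrix(5, 3, 3)), 255L)   # ties count as 1
  hi <- matrix(1, 3, 3); hi[2, 2] <- 9
  expect_identical(lbp_code(hi), 0L)
  ## worked example: center 5, neighbors (n = 0..7) = 6,2,7,9,1,5,3,8 -> 173
  p <- matrix(0, 3, 3); p[2, 2] <- 5
  nb <- c(6, 2, 7, 9, 1, 5, 3, 8)
  for (k in 1:8) p[2 + ORACLE_OFFSETS[k, 1], 2 + ORACLE_OFFSETS[k, 2]] <- nb[k]
  expect_identical(lbp_code(p), 173L)
  expect_identical(lbp_code(p), oracle_lbp_code(p))
  expect_error(lbp_code(matrix(1, 2, 2)), class = "exprfeat_shape_error")
  ## random patches agree with the direct evaluation
  set.seed(42)
  for (i in 1:50) {
    q <- matrix(sample(0:255, 9, TRUE), 3, 3)
    expect_identical(lbp_code(q), oracle_lbp_code(q))
  }
})

test_that("uniform mapping has 58 uniform codes ranked ascending, rest pooled in bin 58", {
  bins <- uniform_bin_map()
  oracle <- oracle_uniform_bins()
  expect_identical(bins, oracle)
  expect_identical(sum(bins != 58L), 58L)
  expect_identical(uniform_bin(0), 0L)
  expect_identical(uniform_bin(255), 57L)   # largest uniform code
  expect_identical(uniform_bin(173), 58L)   # 6 circular transitions
  expect_error(uniform_bin(256))
})

test_that("lbp_face computes the code at every interior pixel", {
  expect_true(all(lbp_face(matrix(7, 130, 130)) == 255L))
  expect_identical(dim(lbp_face(matrix(7, 130, 130))), c(128L, 128L))
  ## single bright pixel: code 0 there; its 8 neighbors see only ties and the
  ## brighter pixel, so (ties counting as 1) they all code 255 -- pinned by
  ## the brute-force oracle
  f <- matrix(10, 130, 130); f[60, 60] <- 200
  cm <- lbp_face(f)
  expect_identical(cm[59, 59], 0L)
  neigh_at <- cbind(59 + ORACLE_OFFSETS[, 1], 59 + ORACLE_OFFSETS[, 2])
  expect_true(all(cm[neigh_at] == 255L))
  expect_identical(cm, oracle_lbp_face(f))
  ## dual case: single dark pixel -> each neighbor has exactly one zero bit
  f2 <- matrix(10, 130, 130); f2[60, 60] <- 0
  cm2 <- lbp_face(f2)
  expect_identical(cm2[59, 59], 255L)
  zero_bits <- vapply(cm2[neigh_at],
                      function(k) sum((k %/% 2^(0:7)) %% 2 == 0), numeric(1))
  expect_true(all(zero_bits == 1))
  expect_error(lbp_face(matrix(1, 2, 5)), class = "exprfeat_shape_error")
})

test_that("lbp_face equals the per-pixel brute-force oracle on random faces", {
  for (s in 1:5) {
    face <- rand_face(s)
    expect_identical(lbp_face(face), oracle_lbp_face(face))
  }
})

test_that("lbp_face is invariant to brightness shifts and positive scaling", {
  face <- rand_face(8)
  ref <- lbp_face(face)
  expect_identical(lbp_face(face + 31), ref)
  expect_identical(lbp_face(face * 2.5), ref)
})

test_that("patch histograms conserve counts and concatenate row-major", {
  cm <- lbp_face(matrix(7, 130, 130))       # all codes 255 -> bin 57
  f <- lbp_features(cm, 16)
  expect_length(f, 64 * 59)
  blocks <- matrix(f, nrow = 59)
  expect_true(all(blocks[58, ] == 256))     # bin 57 is row 58 (1-based)
  expect_true(all(blocks[-58, ] == 0))
  ## conservation on a random map, both patch sizes
  cm2 <- lbp_face(rand_face(12))
  for (ps in c(16, 8)) {
    f2 <- lbp_features(cm2, ps)
    expect_true(all(colSums(matrix(f2, nrow = 59)) == ps^2))
  }
  expect_length(lbp_features(cm2, 8), 256 * 59)
  expect_error(lbp_features(cm2, 17), class = "exprfeat_config_error")
})
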