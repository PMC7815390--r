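test_that("segment test and score match the explicit circular-run oracle", {
  expect_false(fast_is_corner(matrix(50, 20, 20), 10, 10, 10))
  expect_identical(fast_score(matrix(50, 20, 20), 10, 10, 10), 0)
  expect_error(fast_is_corner(matrix(50, 20, 20), 2, 10, 10),
               class = "exprfeat_border_error")
  ## disk of 255 on black: decided purely by circle membership
  img <- matrix(0, 21, 21)
  d2 <- (row(img) - 11)^2 + (col(img) - 11)^2
  img[d2 <= 9] <- 255
  expect_identical(fast_is_corner(img, 11, 11, 50),
                   oracle_fast_corner(img, 11, 11, 50))
  ## corner region of a bright square on dark background: the circular-scan
  ## oracle decides each pixel (a 90-degree corner subtends only ~5 of the 16
  ## circle pixels, so the exact corner pixel itself is borderline for n=12)
  sq <- matrix(0, 30, 30); sq[10:25, 10:25] <- 200
  for (r in 8:13) for (c in 8:13) {
    expect_identical(fast_is_corner(sq, r, c, 30), oracle_fast_corner(sq, r, c, 30))
  }
  ## a structure sharper than 90 degrees (small blob) does fire
  blob <- matrix(0, 30, 30); blob[14:16, 14:16] <- 200
  expect_true(fast_is_corner(blob, 15, 15, 30))
  expect_true(oracle_fast_corner(blob, 15, 15, 30))
  ## random images: per-pixel agreement of decision and score
  for (s in 1:3) {
    set.seed(s)
    im <- matrix(sample(0:255, 32 * 32, TRUE), 32, 32)
    for (t in c(10, 30)) {
      band <- expand.grid(row = 4:29, col = 4:29)
      ev <- exprfeat:::fast_eval(im, band$row, band$col, t)
      orc <- vapply(seq_len(nrow(band)), function(i) {
        oracle_fast_corner(im, band$row[i], band$col[i], t)
      }, logical(1))
      osc <- vapply(seq_len(nrow(band)), function(i) {
        oracle_fast_score(im, band$row[i], band$col[i], t)
      }, numeric(1))
      expect_identical(ev$corner, orc)
      expect_equal(ev$score, osc)
    }
  }
})

test_that("score follows the per-pixel exceedance reading and is monotone in contrast", {
  img <- matrix(100, 20, 20)
  img[10 - 3, 10] <- 100 + 30 + 5    # one circle pixel just past the band
  expect_identical(fast_score(img, 10, 10, 30), 5)
  ## halving the contrast of a strong corner strictly lowers the score
  sq <- matrix(0, 30, 30); sq[10:25, 10:25] <- 200
  weak <- matrix(0, 30, 30); weak[10:25, 10:25] <- 100
  expect_gt(fast_score(sq, 10, 10, 30), fast_score(weak, 10, 10, 30))
})

test_that("region-balanced detection fills the budget with the per-region quota", {
  pl <- planted_lattice(1)
  kp <- detect_region_balanced(pl$image, n = 160, grid_m = 4, grid_n = 4, t0 = 30)
  expect_identical(nrow(kp), 160L)
  counts <- as.numeric(table(factor(kp$region, levels = 0:15)))
  expect_true(all(counts == 10))    # T = 160 / 16 exactly
  ## every selected keypoint within 1 pixel (Chebyshev) of a planted blob
  d <- vapply(seq_len(nrow(kp)), function(i) {
    min(pmax(abs(kp$row[i] - pl$centers$row), abs(kp$col[i] - pl$centers$col)))
  }, numeric(1))
  expect_true(all(d <= 1))
  ## remainder rule: n = 166 -> T = 10 plus one extra for 6 regions
  kp2 <- detect_region_balanced(pl$image, n = 166, grid_m = 4, grid_n = 4, t0 = 30)
  counts2 <- as.numeric(table(factor(kp2$region, levels = 0:15)))
  expect_identical(sum(counts2), 166)
  expect_true(all(counts2 %in% c(10, 11)))
  expect_identical(sum(counts2 == 11), 6L)
})

test_that("single-region detection degenerates to global FAST with top-n selection", {
  pl <- planted_lattice(2)
  bal <- detect_region_balanced(pl$image, n = 40, grid_m = 1, grid_n = 1,
                                t0 = 30, margin = 17)
  glo <- detect_fast(pl$image, n = 40, t = 30, margin = 17)
  expect_setequal(paste(bal$row, bal$col), paste(glo$row, glo$col))
})

test_that("no two kept corners are 3x3 neighbors within a region, and flat images warn", {
  set.seed(3)
  img <- matrix(sample(0:255, 130 * 130, TRUE), 130, 130)
  kp <- detect_region_balanced(img, n = 160, t0 = 30)
  for (reg in unique(kp$region)) {
    sub <- kp[kp$region == reg, ]
    if (nrow(sub) > 1) {
      dmat <- pmax(abs(outer(sub$row, sub$row, "-")),
                   abs(outer(sub$col, sub$col, "-")))
      expect_true(all(dmat[upper.tri(dmat)] > 1))
    }
  }
  expect_lte(nrow(kp), 160)
  expect_warning(flat <- detect_region_balanced(matrix(77, 130, 130), n = 16),
                 "keypoints")
  expect_identical(nrow(flat), 0L)
  expect_error(detect_region_balanced(img, n = 8, grid_m = 4, grid_n = 4),
               class = "exprfeat_config_error")
})

test_that("region balance spreads keypoints more evenly than global top-n", {
  ## corners everywhere, but far stronger in one quadrant
  for (s in 1:3) {
    set.seed(s)
    img <- matrix(100, 130, 130)
    for (r in seq(22, 112, by = 7)) for (c in seq(22, 112, by = 7)) {
      amp <- if (r < 66 && c < 66) 150 else 40
      img[r + (-1:1), c + (-1:1)] <- 100 + amp * sample(c(1, -1), 1)
    }
    img <- img + matrix(rnorm(130 * 130, 0, 3), 130, 130)
    bal <- detect_region_balanced(img, n = 160, t0 = 30)
    glo <- detect_fast(img, n = 160, t = 30, margin = 17)
    v_bal <- var(as.numeric(table(factor(bal$region, levels = 0:15))))
    v_glo <- var(as.numeric(table(factor(region_index(glo), levels = 0:15))))
    expect_lt(v_bal, v_glo)
  }
})

test_that("intensity-centroid orientation points at the bright side", {
  flat <- matrix(77, 41, 41)
  expect_identical(orientation(flat, 21, 21, 15), 0)      # zero moments tie-break
  right <- matrix(0, 41, 41); right[, 22:41] <- 200        # bright +x half
  expect_equal(orientation(right, 21, 21, 15), 0)
  down <- matrix(0, 41, 41); down[22:41, ] <- 200          # bright +y half
  expect_equal(orientation(down, 21, 21, 15), pi / 2)
  ## rotating the half-plane by 90 degrees shifts theta by pi/2
  expect_equal(orientation(down, 21, 21, 15) - orientation(right, 21, 21, 15),
               pi / 2, tolerance = 0.1)
  expect_error(orientation(flat, 3, 21, 15), class = "exprfeat_border_error")
})

test_that("the sampling pattern is Gaussian-placed, in-window and seed-pinned", {
  p1 <- brief_pattern(256, 31, seed = 1234)
  p2 <- brief_pattern(256, 31, seed = 1234)
  expect_identical(p1, p2)
  expect_identical(nrow(p1), 256L)
  expect_true(all(p1 >= -15 & p1 <= 15))
  expect_false(identical(p1, brief_pattern(256, 31, seed = 99)))
})

test_that("BRIEF bits follow the comparison rule and its invariances", {
  pat <- brief_pattern()
  flat_sm <- box_smooth(matrix(120, 81, 81), 5)
  expect_true(all(brief_descriptor(flat_sm, 41, 41, pat) == 0))  # equality -> 0
  ## oracle equality on a fixed gradient patch (unsteered)
  grad <- outer(1:81, 1:81, function(r, c) r + 2 * c)
  sm <- box_smooth(grad, 5)
  expect_identical(brief_descriptor(sm, 41, 41, pat, steered = FALSE),
                   oracle_brief(sm, 41, 41, pat))
  ## invariance to positive affine intensity change, 20 seeded patches
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(sample(0:255, 81 * 81, TRUE), 81, 81)
    th <- orientation(img, 41, 41, 15)
    d1 <- brief_descriptor(box_smooth(img, 5), 41, 41, pat, th)
    d2 <- brief_descriptor(box_smooth(2 * img + 7, 5), 41, 41, pat, th)
    expect_identical(d1, d2)
  }
  expect_error(brief_descriptor(flat_sm, 5, 41, pat),
               class = "exprfeat_border_error")
})

test_that("steering reduces descriptor drift under image rotation", {
  pat <- brief_pattern()
  theta_rot <- 15 * pi / 180
  d_steer <- numeric(20); d_plain <- numeric(20)
  for (s in 1:20) {
    set.seed(s)
    img <- box_smooth(matrix(runif(81 * 81, 0, 255), 81, 81), 7)
    rot <- rotate_image(img, theta_rot)
    sm1 <- box_smooth(img, 5); sm2 <- box_smooth(rot, 5)
    th1 <- orientation(img, 41, 41, 15); th2 <- orientation(rot, 41, 41, 15)
    d_steer[s] <- hamming(brief_descriptor(sm1, 41, 41, pat, th1, TRUE),
                          brief_descriptor(sm2, 41, 41, pat, th2, TRUE))
    d_plain[s] <- hamming(brief_descriptor(sm1, 41, 41, pat, 0, FALSE),
                          brief_descriptor(sm2, 41, 41, pat, 0, FALSE))
  }
  expect_lt(mean(d_steer), mean(d_plain))
})

test_that("orb_feature assembles a fixed-length deterministic bit vector", {
  cfg <- pipeline_config(n_keypoints = 32L, grid_m = 4L, grid_n = 4L)
  g <- generate_face(synthetic_spec(seed = 5), 1, 2, 1)
  face <- crop_face(g$image, g$landmarks)
  f1 <- orb_feature(face, cfg)
  f2 <- orb_feature(face, cfg)
  expect_identical(f1, f2)
  expect_length(f1, 32 * 256)
  expect_true(all(f1 %in% c(0, 1)))
  ## flat image: zero padding and all-false validity mask
  expect_warning(f0 <- orb_feature(matrix(55, 130, 130), cfg))
  expect_true(all(f0 == 0))
  expect_false(any(attr(f0, "valid")))
})
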