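#' Region-balanced FAST keypoint detection
#'
#' Divides the image evenly into `grid_m` x `grid_n` regions and shares the
#' total keypoint budget `n` among them: each region receives a quota
#' `T = floor(n / (grid_m * grid_n))`, with the remainder granted one-each to
#' the regions with the strongest corners. Within a region, FAST corners are
#' detected at the initial threshold `t0`; when a region yields fewer than its
#' quota, the threshold is halved (`t <- max(1, floor(t/2))`) and detection
#' repeated, stopping at `t = 1`. Non-maximal suppression (strict 3x3 local
#' score maximum, row-major tie-break) is applied within each region, then the
#' top-quota corners by score are kept. If some regions remain short at the
#' minimum threshold, their unused slots are refilled from the highest-scoring
#' surplus candidates elsewhere, so the total equals `n` whenever enough
#' corners exist anywhere; flat images yield fewer (with a warning).
#'
#' @param image Intensity matrix.
#' @param n Total keypoint budget.
#' @param grid_m,grid_n Rows and columns of the region division.
#' @param t0 Initial FAST threshold.
#' @param fast_n Contiguous run length of the segment test.
#' @param margin Border exclusion margin; defaults to 17 so that the 35x35
#'   descriptor window of every retained corner fits inside the image.
#' @return Tibble with columns `row`, `col`, `score`, `region` (0-based,
#'   row-major region index), ordered region-major then by descending score.
#' @export
#' @examples
#' img <- matrix(0, 130, 130)
#' img[seq(30, 100, by = 14), seq(30, 100, by = 14)] <- 255
#' detect_region_balanced(img, n = 16, grid_m = 2, grid_n = 2)
detect_region_balanced <- function(image, n = 160L, grid_m = 4L, grid_n = 4L,
                                   t0 = 30, fast_n = 12L, margin = 17L) {
  if (grid_m * grid_n > n) {
    abort("region grid has more cells than the keypoint budget `n`",
          class = "exprfeat_config_error")
  }
  h <- nrow(image); w <- ncol(image)
  region_h <- floor(seq(0, h, length.out = grid_m + 1))
  region_w <- floor(seq(0, w, length.out = grid_n + 1))
  band <- candidate_band(image, margin)

  quota_base <- n %/% (grid_m * grid_n)
  remainder <- n - quota_base * grid_m * grid_n

  ## Detect per region with per-region threshold relaxation.
  regions <- vector("list", grid_m * grid_n)
  for (ri in seq_len(grid_m)) {
    for (ci in seq_len(grid_n)) {
      idx <- (ri - 1L) * grid_n + (ci - 1L)          # 0-based row-major
      sel <- band$row > region_h[ri] & band$row <= region_h[ri + 1] &
             band$col > region_w[ci] & band$col <= region_w[ci + 1]
      rows <- band$row[sel]; cols <- band$col[sel]
      det <- tibble::tibble(row = integer(), col = integer(), score = numeric())
      if (length(rows) > 0) {
        t <- t0
        repeat {
          ev <- fast_eval(image, rows, cols, t, fast_n)
          det <- tibble::tibble(row = rows[ev$corner], col = cols[ev$corner],
                                score = ev$score[ev$corner])
          det <- nms_3x3(det)
          if (nrow(det) >= quota_base || t <= 1) break
          t <- max(1, t %/% 2)
        }
      }
      det <- det[order(-det$score, det$row, det$col), , drop = FALSE]
      det$region <- rep(idx, nrow(det))
      regions[[idx + 1L]] <- det
    }
  }

  ## Remainder goes one-each to the regions with the strongest top corner.
  top_score <- vapply(regions, function(d) if (nrow(d)) d$score[1] else -Inf,
                      numeric(1))
  quota <- rep(quota_base, grid_m * grid_n)
  if (remainder > 0) {
    extra <- order(-top_score)[seq_len(remainder)]
    quota[extra] <- quota[extra] + 1L
  }
  take <- pmin(quota, vapply(regions, nrow, integer(1)))

  ## Refill any deficit from the best unused candidates anywhere.
  deficit <- n - sum(take)
  avail <- vapply(regions, nrow, integer(1))
  while (deficit > 0) {
    next_score <- vapply(seq_along(regions), function(i) {
      if (avail[i] > take[i]) regions[[i]]$score[take[i] + 1L] else -Inf
    }, numeric(1))
    best <- which.max(next_score)
    if (!is.finite(next_score[best])) break
    take[best] <- take[best] + 1L
    deficit <- deficit - 1L
  }
  if (deficit > 0) {
    warn(sprintf("only %d of %d requested keypoints found at minimum threshold",
                 n - deficit, n))
  }

  out <- dplyr::bind_rows(lapply(seq_along(regions), function(i) {
    head(regions[[i]], take[i])
  }))
  if (nrow(out) == 0) {
    out <- tibble::tibble(row = integer(), col = integer(),
                          score = numeric(), region = integer())
  }
  out
}

#' Intensity-centroid orientation of a keypoint patch
#'
#' The orientation is the angle of the vector from the patch center to the
#' intensity centroid: `theta = atan2(m01, m10)` with image moments
#' `m_pq = sum x^p y^q I(x, y)` over the disk of the given radius (`x` =
#' column offset, `y` = row offset, image rows increasing downward). A
#' radially symmetric patch has both moments zero and gets angle 0 by the
#' `atan2(0, 0)` convention.
#'
#' @param image Intensity matrix.
#' @param row,col Keypoint position; the disk must fit inside the image.
#' @param radius Disk radius in pixels.
#' @return Angle in radians in `(-pi, pi]`.
#' @export
orientation <- function(image, row, col, radius = 15L) {
  h <- nrow(image); w <- ncol(image)
  if (row - radius < 1 || col - radius < 1 || row + radius > h || col + radius > w) {
    abort("orientation patch does not fit inside the image",
          class = "exprfeat_border_error")
  }
  off <- disk_offsets(radius)
  inten <- image[cbind(row + off[, "dr"], col + off[, "dc"])]
  m10 <- sum(off[, "dc"] * inten)
  m01 <- sum(off[, "dr"] * inten)
  atan2(m01, m10)
}

disk_offsets <- function(radius) {
  d <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d <- d[d$dr^2 + d$dc^2 <= radius^2, ]
  as.matrix(d)
}

#' Gaussian BRIEF sampling pattern
#'
#' Draws the 256 patch-pair coordinates of the BRIEF descriptor i.i.d. from an
#' isotropic Gaussian with standard deviation `S/5` (variance `S^2/25`, with
#' `S = 31` the effective patch size), rounded to integer offsets and clipped
#' to the 31x31 window. The pattern is generated from a pinned seed so the
#' descriptor layout is reproducible across sessions and machines.
#'
#' @param n_pairs Number of comparison pairs (bits).
#' @param patch Effective window side `S` (odd).
#' @param seed Integer seed pinning the realized pattern.
#' @return Integer matrix `n_pairs` x 4 with columns `r1, c1, r2, c2`
#'   (offsets relative to the keypoint), plus attributes `patch` and `seed`.
#' @export
brief_pattern <- function(n_pairs = 256L, patch = 31L, seed = 1234L) {
  stopifnot(patch %% 2 == 1, n_pairs >= 1)
  half <- (patch - 1L) %/% 2L
  coords <- withr::with_seed(seed, {
    round(matrix(rnorm(n_pairs * 4, mean = 0, sd = patch / 5), n_pairs, 4))
  })
  coords <- pmin(pmax(coords, -half), half)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("r1", "c1", "r2", "c2")
  attr(coords, "patch") <- as.integer(patch)
  attr(coords, "seed") <- as.integer(seed)
  coords
}

#' Box smoothing of an intensity image
#'
#' Mean filter over a `window` x `window` box via an integral image; at the
#' borders the box is truncated to the in-image part. BRIEF compares smoothed
#' intensities to reduce noise sensitivity.
#'
#' @param image Intensity matrix.
#' @param window Odd box side.
#' @return Numeric matrix of the same size.
#' @export
box_smooth <- function(image, window = 5L) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  ## integral image with a zero row/col prefix
  S <- matrix(0, h + 1, w + 1)
  S[2:(h + 1), 2:(w + 1)] <- t(apply(apply(image, 2, cumsum), 1, cumsum))
  rv <- as.vector(row(image)); cv <- as.vector(col(image))
  r0 <- pmax(rv - half, 1); r1 <- pmin(rv + half, h)
  c0 <- pmax(cv - half, 1); c1 <- pmin(cv + half, w)
  sums <- S[cbind(r1 + 1, c1 + 1)] - S[cbind(r0, c1 + 1)] -
          S[cbind(r1 + 1, c0)] + S[cbind(r0, c0)]
  matrix(sums / ((r1 - r0 + 1) * (c1 - c0 + 1)), h, w)
}

#' Steered BRIEF descriptor of one keypoint
#'
#' For each sampling pair, compares box-smoothed intensities at the two
#' offsets (optionally rotated by the keypoint orientation `theta`, nearest
#' pixel): the bit is 1 iff the first location is strictly darker than the
#' second (`I(r1,c1) < I(r2,c2)`; equality gives 0). Comparisons are
#' invariant to positive affine intensity changes because smoothing is linear.
#'
#' @param smoothed Box-smoothed intensity matrix (see [box_smooth()]).
#' @param row,col Keypoint position; the sampling window (rotated offsets are
#'   clipped to the window) must fit inside the image.
#' @param pattern Sampling pattern from [brief_pattern()].
#' @param theta Orientation in radians; used only when `steered = TRUE`.
#' @param steered Rotate the sampling pattern by `theta`?
#' @return Integer vector of 0/1 bits, length `nrow(pattern)`.
#' @export
brief_descriptor <- function(smoothed, row, col, pattern, theta = 0,
                             steered = TRUE) {
  half <- (attr(pattern, "patch") - 1L) %/% 2L
  if (row - half < 1 || col - half < 1 ||
      row + half > nrow(smoothed) || col + half > ncol(smoothed)) {
    abort("descriptor window does not fit inside the image",
          class = "exprfeat_border_error")
  }
  p <- pattern
  if (steered && theta != 0) {
    cs <- cos(theta); sn <- sin(theta)
    rot <- function(dr, dc) {
      ## rotate (x=dc, y=dr) by theta, nearest pixel, clip to the window
      list(dr = pmin(pmax(round(dc * sn + dr * cs), -half), half),
           dc = pmin(pmax(round(dc * cs - dr * sn), -half), half))
    }
    a <- rot(p[, "r1"], p[, "c1"]); b <- rot(p[, "r2"], p[, "c2"])
    i1 <- smoothed[cbind(row + a$dr, col + a$dc)]
    i2 <- smoothed[cbind(row + b$dr, col + b$dc)]
  } else {
    i1 <- smoothed[cbind(row + p[, "r1"], col + p[, "c1"])]
    i2 <- smoothed[cbind(row + p[, "r2"], col + p[, "c2"])]
  }
  as.integer(i1 < i2)
}

#' Fixed-length region-balanced ORB feature of a face image
#'
#' Runs the full keypoint pipeline on one face region: region-balanced FAST
#' detection, intensity-centroid orientation, and steered BRIEF description
#' of every corner. Descriptors are concatenated in region-scan order (region
#' row-major; within a region by descending corner score), giving a fixed
#' `n * 256`-bit vector suitable as a classifier input; missing keypoint
#' slots (flat images) are zero-padded and flagged in the validity mask.
#'
#' @param face Intensity matrix (the 130x130 face region).
#' @param config A [pipeline_config()] supplying the detector and descriptor
#'   constants.
#' @param pattern Optional precomputed [brief_pattern()]; generated from
#'   `config` when `NULL`.
#' @return Numeric 0/1 vector of length `n_keypoints * brief_bits`, with
#'   attributes `valid` (logical mask per keypoint slot) and `keypoints`
#'   (the detection tibble).
#' @export
orb_feature <- function(face, config = pipeline_config(), pattern = NULL) {
  if (is.null(pattern)) {
    pattern <- brief_pattern(config$brief_bits, config$brief_window,
                             config$pattern_seed)
  }
  kp <- detect_region_balanced(face, n = config$n_keypoints,
                               grid_m = config$grid_m, grid_n = config$grid_n,
                               t0 = config$fast_t0, fast_n = config$fast_n,
                               margin = config$descriptor_margin)
  bits <- matrix(0L, config$n_keypoints, config$brief_bits)
  valid <- rep(FALSE, config$n_keypoints)
  if (nrow(kp) > 0) {
    smoothed <- box_smooth(face, config$smooth_window)
    kp$theta <- vapply(seq_len(nrow(kp)), function(i) {
      orientation(face, kp$row[i], kp$col[i], config$orientation_radius)
    }, numeric(1))
    for (i in seq_len(nrow(kp))) {
      bits[i, ] <- brief_descriptor(smoothed, kp$row[i], kp$col[i],
                                    pattern, theta = kp$theta[i], steered = TRUE)
      valid[i] <- TRUE
    }
  }
  out <- as.numeric(t(bits))
  attr(out, "valid") <- valid
  attr(out, "keypoints") <- kp
  out
}
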