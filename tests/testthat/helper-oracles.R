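# Independent brute-force oracles used to pin expected values. These follow
# the definitions directly and share no code path with the package internals.

# neighbor offsets, bit n = 0..7, clockwise from top-left (the pinned convention)
ORACLE_OFFSETS <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                         ncol = 2, byrow = TRUE)

oracle_lbp_code <- function(patch) {
  ic <- patch[2, 2]
  code <- 0
  for (k in 1:8) {
    u <- patch[2 + ORACLE_OFFSETS[k, 1], 2 + ORACLE_OFFSETS[k, 2]] - ic
    if (u >= 0) code <- code + 2^(k - 1)
  }
  as.integer(code)
}

oracle_lbp_face <- function(face) {
  h <- nrow(face); w <- ncol(face)
  out <- matrix(0L, h - 2, w - 2)
  for (r in 2:(h - 1)) {
    for (c in 2:(w - 1)) {
      vals <- face[cbind(r + ORACLE_OFFSETS[, 1], c + ORACLE_OFFSETS[, 2])]
      out[r - 1, c - 1] <- as.integer(sum(2^(0:7) * (vals >= face[r, c])))
    }
  }
  out
}

# circular transition count via integer division (independent of intToBits)
oracle_transitions <- function(code) {
  bits <- (code %/% 2^(0:7)) %% 2
  sum(bits != bits[c(2:8, 1)])
}

# full enumeration: bin index of each code 0..255 under the uniform mapping
oracle_uniform_bins <- function() {
  trans <- vapply(0:255, oracle_transitions, numeric(1))
  uniform_codes <- (0:255)[trans <= 2]
  bins <- rep(58L, 256)
  bins[uniform_codes + 1] <- seq_along(uniform_codes) - 1L
  bins
}

# 16-pixel Bresenham circle offsets, clockwise from 12 o'clock
ORACLE_CIRCLE <- matrix(c(-3, 0, -3, 1, -2, 2, -1, 3, 0, 3, 1, 3, 2, 2, 3, 1,
                          3, 0, 3, -1, 2, -2, 1, -3, 0, -3, -1, -3, -2, -2, -3, -1),
                        ncol = 2, byrow = TRUE)

# explicit circular-run scan: a corner iff some run of >= n contiguous circle
# pixels is entirely brighter than ip + t or entirely darker than ip - t
oracle_fast_corner <- function(image, r, c, t, n = 12) {
  vals <- image[cbind(r + ORACLE_CIRCLE[, 1], c + ORACLE_CIRCLE[, 2])]
  ip <- image[r, c]
  bright <- vals >= ip + t
  dark <- vals <= ip - t
  for (s in 1:16) {
    idx <- ((s - 1 + 0:(n - 1)) %% 16) + 1
    if (all(bright[idx]) || all(dark[idx])) return(TRUE)
  }
  FALSE
}

oracle_fast_score <- function(image, r, c, t) {
  vals <- image[cbind(r + ORACLE_CIRCLE[, 1], c + ORACLE_CIRCLE[, 2])]
  ip <- image[r, c]
  bright <- vals[vals >= ip + t]
  dark <- vals[vals <= ip - t]
  max(sum(bright - ip - t), sum(ip - dark - t), 0)
}

# literal loop over the sampling pairs (unsteered)
oracle_brief <- function(smoothed, r, c, pattern) {
  bits <- integer(nrow(pattern))
  for (i in seq_len(nrow(pattern))) {
    i1 <- smoothed[r + pattern[i, "r1"], c + pattern[i, "c1"]]
    i2 <- smoothed[r + pattern[i, "r2"], c + pattern[i, "c2"]]
    bits[i] <- if (i1 < i2) 1L else 0L
  }
  bits
}

hamming <- function(a, b) sum(a != b)

# inverse-mapping bilinear rotation about the image center (fixture transform)
rotate_image <- function(img, theta) {
  h <- nrow(img); w <- ncol(img)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  out <- matrix(0, h, w)
  cs <- cos(-theta); sn <- sin(-theta)
  for (r in 1:h) {
    for (c in 1:w) {
      dy <- r - cr; dx <- c - cc
      sr <- cr + sn * dx + cs * dy
      sc <- cc + cs * dx - sn * dy
      r0 <- floor(sr); c0 <- floor(sc)
      if (r0 >= 1 && c0 >= 1 && r0 + 1 <= h && c0 + 1 <= w) {
        fr <- sr - r0; fc <- sc - c0
        out[r, c] <- (1 - fr) * (1 - fc) * img[r0, c0] +
                     (1 - fr) * fc * img[r0, c0 + 1] +
                     fr * (1 - fc) * img[r0 + 1, c0] +
                     fr * fc * img[r0 + 1, c0 + 1]
      }
    }
  }
  out
}
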