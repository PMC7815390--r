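## The 16-pixel Bresenham circle of radius 3 around a candidate corner,
## (row, col) offsets listed clockwise starting at 12 o'clock.
FAST_CIRCLE <- matrix(c(-3L,  0L, -3L,  1L, -2L,  2L, -1L,  3L,
                         0L,  3L,  1L,  3L,  2L,  2L,  3L,  1L,
                         3L,  0L,  3L, -1L,  2L, -2L,  1L, -3L,
                         0L, -3L, -1L, -3L, -2L, -2L, -3L, -1L),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("dr", "dc")))

## Intensities on the 16-pixel circle for a set of centers (matrix n x 16).
circle_intensities <- function(image, rows, cols) {
  n <- length(rows)
  out <- matrix(0, n, 16)
  for (k in 1:16) {
    out[, k] <- image[cbind(rows + FAST_CIRCLE[k, "dr"],
                            cols + FAST_CIRCLE[k, "dc"])]
  }
  out
}

## TRUE where a circular run of >= fast_n TRUEs exists in each row of a
## logical n x 16 matrix. Checks all 16 starting positions on the doubled
## sequence with vectorized ANDs.
has_circular_run <- function(flags, fast_n) {
  doubled <- cbind(flags, flags[, seq_len(fast_n - 1), drop = FALSE])
  hit <- rep(FALSE, nrow(flags))
  for (s in 1:16) {
    run <- doubled[, s]
    for (j in seq_len(fast_n - 1)) run <- run & doubled[, s + j]
    hit <- hit | run
    if (all(hit)) break
  }
  hit
}

#' FAST segment test at a single pixel
#'
#' A pixel `p` is a corner when at least `fast_n` (12 by default) contiguous
#' pixels on the 16-pixel Bresenham circle around it are all brighter than
#' `I_p + t` or all darker than `I_p - t` (both bounds inclusive; contiguity
#' wraps around the circle).
#'
#' @param image Numeric intensity matrix.
#' @param row,col Pixel position (1-based); must be at least 3 pixels away
#'   from every border so the circle fits.
#' @param t Positive intensity threshold.
#' @param fast_n Required contiguous run length.
#' @return Logical scalar.
#' @export
fast_is_corner <- function(image, row, col, t, fast_n = 12L) {
  check_circle_fits(image, row, col)
  stopifnot(t > 0)
  circ <- circle_intensities(image, row, col)
  ip <- image[row, col]
  has_circular_run(circ >= ip + t, fast_n) ||
    has_circular_run(circ <= ip - t, fast_n)
}

#' FAST corner score
#'
#' Score used for non-maximal suppression: the larger of the summed exceedances
#' over the bright and dark circle sets,
#' `max(sum over bright of (I_x - I_p - t), sum over dark of (I_p - I_x - t))`,
#' where bright/dark are the circle pixels at or beyond `I_p + t` / `I_p - t`.
#' Zero when both sets are empty; monotone in contrast.
#'
#' @inheritParams fast_is_corner
#' @return Nonnegative numeric score.
#' @export
fast_score <- function(image, row, col, t, fast_n = 12L) {
  check_circle_fits(image, row, col)
  stopifnot(t > 0)
  circ <- drop(circle_intensities(image, row, col))
  d <- circ - image[row, col]
  max(sum(pmax(d - t, 0)), sum(pmax(-d - t, 0)), 0)
}

check_circle_fits <- function(image, row, col) {
  if (row < 4 || col < 4 || row > nrow(image) - 3 || col > ncol(image) - 3) {
    abort("pixel is closer than 3 pixels to the image border; the FAST circle does not fit",
          class = "exprfeat_border_error")
  }
  invisible(TRUE)
}

## Vectorized corner mask + score map over a candidate band.
## rows/cols: vectors of candidate positions (parallel). Returns list of
## logical `corner` and numeric `score` vectors.
fast_eval <- function(image, rows, cols, t, fast_n = 12L) {
  circ <- circle_intensities(image, rows, cols)
  ip <- image[cbind(rows, cols)]
  d <- circ - ip
  corner <- has_circular_run(d >= t, fast_n) | has_circular_run(d <= -t, fast_n)
  score <- pmax(rowSums(pmax(d - t, 0)), rowSums(pmax(-d - t, 0)))
  list(corner = corner, score = score)
}

## Strict 3x3 non-maximal suppression on a set of scored detections within a
## bounded window. `det` is a tibble/data.frame with row, col, score. A
## detection is kept when its score strictly exceeds every 8-neighbor
## detection's score, ties broken by row-major position (the earlier pixel
## wins).
nms_3x3 <- function(det) {
  if (nrow(det) == 0) return(det)
  ## dense local score lookup over the detection bounding box (+1 halo)
  r_off <- min(det$row) - 2L; c_off <- min(det$col) - 2L
  h <- max(det$row) - r_off + 2L; w <- max(det$col) - c_off + 2L
  S <- matrix(-Inf, h, w)
  S[cbind(det$row - r_off, det$col - c_off)] <- det$score
  keep <- rep(TRUE, nrow(det))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- S[cbind(det$row - r_off + dr, det$col - c_off + dc)]
    present <- is.finite(nb)
    ## the neighbor comes later in row-major order iff dr > 0 | (dr == 0 & dc > 0)
    later <- dr > 0 || (dr == 0 && dc > 0)
    lose <- present & (det$score < nb | (det$score == nb & !later))
    keep <- keep & !lose
  }
  det[keep, , drop = FALSE]
}

#' Global FAST detection with non-maximal suppression and top-n selection
#'
#' The unbalanced baseline: detect all FAST corners in the candidate band at a
#' single threshold, suppress non-maxima in 3x3 neighborhoods, and keep the
#' `n` highest-scoring corners image-wide. Used as the comparison point for
#' the region-balanced detector, whose motivation is that global selection
#' concentrates keypoints in high-contrast areas.
#'
#' @param image Intensity matrix.
#' @param n Number of corners to return (at most).
#' @param t Threshold.
#' @param fast_n Contiguous run length of the segment test.
#' @param margin Exclusion margin at the image border (defaults to 3, the
#'   circle radius; use the descriptor margin when corners will be described).
#' @return Tibble with columns `row`, `col`, `score`, ordered by descending
#'   score (ties row-major).
#' @export
detect_fast <- function(image, n = 160L, t = 30, fast_n = 12L, margin = 3L) {
  band <- candidate_band(image, margin)
  ev <- fast_eval(image, band$row, band$col, t, fast_n)
  det <- tibble::tibble(row = band$row[ev$corner], col = band$col[ev$corner],
                        score = ev$score[ev$corner])
  det <- nms_3x3(det)
  det <- det[order(-det$score, det$row, det$col), , drop = FALSE]
  head(det, n)
}

candidate_band <- function(image, margin) {
  margin <- max(margin, 3L)
  h <- nrow(image); w <- ncol(image)
  if (h < 2 * margin + 1 || w < 2 * margin + 1) {
    abort("image too small for the requested border margin",
          class = "exprfeat_shape_error")
  }
  rows <- (margin + 1L):(h - margin)
  cols <- (margin + 1L):(w - margin)
  expand.grid(row = rows, col = cols)
}
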