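## Neighbor offsets (row, col) for bits n = 0..7: clockwise from the
## top-left corner of the 3x3 neighborhood. Any fixed ordering permutes the
## code bits without changing uniform-pattern membership; this one is pinned
## so codes are reproducible and oracle-checkable.
LBP_OFFSETS <- matrix(c(-1L, -1L,
                        -1L,  0L,
                        -1L,  1L,
                         0L,  1L,
                         1L,  1L,
                         1L,  0L,
                         1L, -1L,
                         0L, -1L),
                      ncol = 2, byrow = TRUE,
                      dimnames = list(NULL, c("dr", "dc")))

#' LBP code of a single 3x3 neighborhood
#'
#' The local binary pattern operator thresholds the 8 neighbors of the center
#' pixel at the center intensity: bit `n` is 1 when `i_n - i_c >= 0` (ties
#' count as 1), and the code is `sum(2^n * bit_n)` for `n = 0..7`. Neighbors
#' are ordered clockwise from the top-left of the neighborhood.
#'
#' @param patch A 3x3 numeric matrix of intensities.
#' @return Integer code in \[0, 255\].
#' @export
#' @examples
#' lbp_code(matrix(5, 3, 3))  # constant patch: all ties -> 255
lbp_code <- function(patch) {
  if (!is.matrix(patch) || any(dim(patch) != c(3, 3)) || !all(is.finite(patch))) {
    abort("`patch` must be a finite 3x3 matrix", class = "exprfeat_shape_error")
  }
  center <- patch[2, 2]
  bits <- patch[cbind(2 + LBP_OFFSETS[, "dr"], 2 + LBP_OFFSETS[, "dc"])] >= center
  as.integer(sum(2^(0:7) * bits))
}

#' Number of circular 0/1 transitions of an 8-bit code
#'
#' @param code Integer vector of codes in \[0, 255\].
#' @return Integer vector of transition counts (0, 2, 4, 6 or 8).
#' @export
lbp_transitions <- function(code) {
  stopifnot(all(code >= 0 & code <= 255))
  vapply(as.integer(code), function(k) {
    bits <- as.integer(intToBits(k))[1:8]
    sum(bits != bits[c(2:8, 1)])
  }, integer(1))
}

#' Uniform-pattern bin map for 8-bit LBP codes
#'
#' A code is *uniform* when its circular bit string has at most one 0-1 and
#' one 1-0 transition (at most 2 transitions in total); exactly 58 of the 256
#' codes qualify. Uniform codes are assigned bins 0..57 in ascending code
#' order; every non-uniform code shares bin 58, giving 59 histogram bins.
#'
#' @return Integer vector of length 256: `uniform_bin_map()[code + 1]` is the
#'   bin (0-based) of `code`.
#' @export
#' @examples
#' table(uniform_bin_map())["58"]  # 198 non-uniform codes pooled in bin 58
uniform_bin_map <- function() {
  trans <- lbp_transitions(0:255)
  uniform <- which(trans <= 2) - 1L   # codes, ascending
  bins <- rep(58L, 256)
  bins[uniform + 1L] <- seq_along(uniform) - 1L
  bins
}

#' @rdname uniform_bin_map
#' @param code Integer vector of codes in \[0, 255\].
#' @return `uniform_bin()` returns the bin index (0..58) of each code.
#' @export
uniform_bin <- function(code) {
  if (any(code < 0 | code > 255 | code != round(code))) {
    abort("`code` must be integers in [0, 255]")
  }
  uniform_bin_map()[as.integer(code) + 1L]
}

#' LBP code map of a face region
#'
#' Applies [lbp_code()] at every interior pixel of the face region; for a
#' 130x130 face the resulting code map is 128x128 (border pixels only serve
#' as neighbors). Fully vectorized via shifted copies of the image.
#'
#' @param face Numeric intensity matrix (the 130x130 face region by default;
#'   any size >= 3x3 is accepted and shrinks by the 1-pixel border).
#' @return Integer matrix of codes in \[0, 255\], `(nrow-2) x (ncol-2)`.
#' @export
lbp_face <- function(face) {
  if (!is.matrix(face) || nrow(face) < 3 || ncol(face) < 3) {
    abort("`face` must be a matrix of at least 3x3", class = "exprfeat_shape_error")
  }
  h <- nrow(face); w <- ncol(face)
  center <- face[2:(h - 1), 2:(w - 1), drop = FALSE]
  codes <- matrix(0L, h - 2, w - 2)
  for (n in 1:8) {
    dr <- LBP_OFFSETS[n, "dr"]; dc <- LBP_OFFSETS[n, "dc"]
    nb <- face[(2 + dr):(h - 1 + dr), (2 + dc):(w - 1 + dc), drop = FALSE]
    codes <- codes + as.integer(2^(n - 1)) * (nb >= center)
  }
  storage.mode(codes) <- "integer"
  codes
}

#' Patch-wise uniform-LBP histogram feature
#'
#' Tiles the code map into `patch_size` x `patch_size` patches (row-major
#' order), maps codes to uniform bins, and concatenates the per-patch 59-bin
#' histograms of raw counts. With 16x16 patches on a 128x128 map this yields
#' 64 patches and a 3776-dimensional feature.
#'
#' @param code_map Integer code matrix from [lbp_face()].
#' @param patch_size Patch side; must divide both dimensions of `code_map`.
#' @return Numeric vector of length `n_patches * 59` with attributes
#'   `patch_grid` (rows, cols of the patch tiling) and `n_bins`.
#' @export
#' @examples
#' f <- lbp_features(lbp_face(matrix(7, 130, 130)))
#' length(f)  # 64 * 59
lbp_features <- function(code_map, patch_size = 16L) {
  h <- nrow(code_map); w <- ncol(code_map)
  if (h %% patch_size != 0 || w %% patch_size != 0) {
    abort(sprintf("`patch_size` (%d) must divide the code map dimensions (%dx%d)",
                  patch_size, h, w),
          class = "exprfeat_config_error")
  }
  bins <- matrix(uniform_bin(code_map), h, w)
  pr <- h %/% patch_size; pc <- w %/% patch_size
  ## patch id in row-major order, then tabulate bins within patch
  prow <- (row(bins) - 1L) %/% patch_size
  pcol <- (col(bins) - 1L) %/% patch_size
  patch_id <- prow * pc + pcol            # 0-based, row-major
  counts <- table(factor(patch_id, levels = 0:(pr * pc - 1)),
                  factor(bins, levels = 0:58))
  out <- as.numeric(t(unclass(counts)))   # per patch: 59 contiguous bins
  attr(out, "patch_grid") <- c(rows = pr, cols = pc)
  attr(out, "n_bins") <- 59L
  out
}
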