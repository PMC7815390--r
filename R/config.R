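#' SVM model-selection configuration
#'
#' Settings for the RBF-kernel support vector machine and its nested grid
#' search. The cost grid is absolute; the kernel width grid is expressed as
#' multipliers of a data-driven scale `gamma0 = 1/median(D)`, where `D` are the
#' squared Euclidean distances between training vectors (the median heuristic).
#' A relative grid keeps the search meaningful whatever the feature scaling:
#' fused vectors standardized to spread `K = 100` have squared distances many
#' orders of magnitude larger than raw binary descriptors, so any fixed
#' absolute width would degenerate for one of them.
#'
#' @param cost Numeric vector of soft-margin cost values `C` to search.
#' @param gamma_mult Numeric vector of multipliers applied to the median
#'   heuristic width `gamma0`.
#' @param inner_k Folds of the inner cross-validation used for grid search
#'   within each outer training fold.
#' @return An object of class `svm_config` (a validated list).
#' @export
#' @examples
#' svm_config(cost = c(1, 10), gamma_mult = 1)
svm_config <- function(cost = 2^c(-1, 3, 7),
                       gamma_mult = 2^c(-2, 0, 2),
                       inner_k = 5) {
  stopifnot(is.numeric(cost), length(cost) >= 1, all(is.finite(cost)), all(cost > 0))
  stopifnot(is.numeric(gamma_mult), length(gamma_mult) >= 1, all(gamma_mult > 0))
  stopifnot(is.numeric(inner_k), length(inner_k) == 1, inner_k >= 2)
  structure(
    list(cost = as.numeric(cost), gamma_mult = as.numeric(gamma_mult),
         inner_k = as.integer(inner_k)),
    class = "svm_config"
  )
}

#' Pipeline configuration: the single source of constants
#'
#' Every numeric constant used by the pipeline stages lives here, validated at
#' construction time: the face-region size (130, giving a 128x128 LBP code
#' map), the LBP patch size, the FAST segment test (16-pixel circle, 12
#' contiguous, initial threshold), the region grid and keypoint budget of the
#' region-balanced detector, the BRIEF geometry (256 bits, 5x5 smoothing,
#' 31x31 effective window) and its pinned sampling-pattern seed, the Z-score
#' fusion constants `K` and `C`, and the cross-validation protocol (k folds,
#' repeats).
#'
#' @param face_size Side of the square face region in pixels.
#' @param patch_size Side of the square LBP histogram patches; must divide
#'   `face_size - 2`.
#' @param fast_t0 Initial FAST intensity threshold.
#' @param fast_n Required contiguous circle pixels in the segment test.
#' @param grid_m,grid_n Rows and columns of the region division.
#' @param n_keypoints Total keypoint budget `n` shared across regions.
#' @param brief_bits Descriptor length in bits.
#' @param smooth_window Side of the box smoothing window.
#' @param brief_window Effective BRIEF sampling window side after the
#'   smoothing margin is removed.
#' @param orientation_radius Radius of the intensity-centroid patch.
#' @param pattern_seed Seed pinning the Gaussian BRIEF sampling pattern.
#' @param K,C Z-score fusion spread and offset constants.
#' @param cv_k Outer cross-validation folds.
#' @param cv_repeats Repetitions of the whole cross-validation.
#' @param svm An [svm_config()] object.
#' @param seed Base seed for fold assignment and any other randomness.
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(n_keypoints = 80, grid_m = 4, grid_n = 4)
#' cfg$n_keypoints
pipeline_config <- function(face_size = 130L,
                            patch_size = 16L,
                            fast_t0 = 30L,
                            fast_n = 12L,
                            grid_m = 4L,
                            grid_n = 4L,
                            n_keypoints = 160L,
                            brief_bits = 256L,
                            smooth_window = 5L,
                            brief_window = 31L,
                            orientation_radius = 15L,
                            pattern_seed = 1234L,
                            K = 100,
                            C = 0,
                            cv_k = 10L,
                            cv_repeats = 10L,
                            svm = svm_config(),
                            seed = 0L) {
  as_int1 <- function(x, nm, lo, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x != round(x) ||
        x < lo || x > hi) {
      abort(sprintf("`%s` must be a single integer in [%s, %s]", nm, lo, hi))
    }
    as.integer(x)
  }
  face_size <- as_int1(face_size, "face_size", 16)
  lbp_map_size <- face_size - 2L
  patch_size <- as_int1(patch_size, "patch_size", 1, lbp_map_size)
  if (lbp_map_size %% patch_size != 0) {
    abort(sprintf("`patch_size` (%d) must divide the LBP map size (%d)",
                  patch_size, lbp_map_size))
  }
  fast_t0 <- as_int1(fast_t0, "fast_t0", 1, 255)
  fast_n <- as_int1(fast_n, "fast_n", 9, 16)
  grid_m <- as_int1(grid_m, "grid_m", 1)
  grid_n <- as_int1(grid_n, "grid_n", 1)
  n_keypoints <- as_int1(n_keypoints, "n_keypoints", 1)
  if (grid_m * grid_n > n_keypoints) {
    abort("region grid has more cells than the keypoint budget `n_keypoints`")
  }
  brief_bits <- as_int1(brief_bits, "brief_bits", 1)
  smooth_window <- as_int1(smooth_window, "smooth_window", 1)
  if (smooth_window %% 2 != 1) abort("`smooth_window` must be odd")
  brief_window <- as_int1(brief_window, "brief_window", 3)
  if (brief_window %% 2 != 1) abort("`brief_window` must be odd")
  orientation_radius <- as_int1(orientation_radius, "orientation_radius", 1)
  pattern_seed <- as_int1(pattern_seed, "pattern_seed", 0, 2^31 - 1)
  stopifnot(is.numeric(K), length(K) == 1, is.finite(K), K > 0)
  stopifnot(is.numeric(C), length(C) == 1, is.finite(C))
  cv_k <- as_int1(cv_k, "cv_k", 2)
  cv_repeats <- as_int1(cv_repeats, "cv_repeats", 1)
  if (!inherits(svm, "svm_config")) abort("`svm` must be an svm_config()")
  seed <- as_int1(seed, "seed", 0, 2^31 - 1)
  ## margin inside which a keypoint's descriptor window fits entirely:
  ## (brief_window + smooth_window - 2) / 2 pixels on every side
  margin <- (brief_window + smooth_window - 2L) %/% 2L
  structure(
    list(face_size = face_size, lbp_map_size = lbp_map_size,
         patch_size = patch_size,
         fast_t0 = fast_t0, fast_n = fast_n, circle_size = 16L,
         grid_m = grid_m, grid_n = grid_n, n_keypoints = n_keypoints,
         brief_bits = brief_bits, smooth_window = smooth_window,
         brief_window = brief_window, orientation_radius = orientation_radius,
         descriptor_margin = margin,
         pattern_seed = pattern_seed, K = as.numeric(K), C = as.numeric(C),
         cv_k = cv_k, cv_repeats = cv_repeats, svm = svm, seed = seed,
         config_version = 1L),
    class = "pipeline_config"
  )
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config v", x$config_version, ">\n", sep = "")
  cat(sprintf("  face %dx%d -> LBP map %dx%d, patches %dx%d (%d bins each)\n",
              x$face_size, x$face_size, x$lbp_map_size, x$lbp_map_size,
              x$patch_size, x$patch_size, 59L))
  cat(sprintf("  FAST: circle 16, n=%d contiguous, t0=%d; regions %dx%d, budget n=%d\n",
              x$fast_n, x$fast_t0, x$grid_m, x$grid_n, x$n_keypoints))
  cat(sprintf("  BRIEF: %d bits, %dx%d smoothing, %dx%d window, pattern seed %d\n",
              x$brief_bits, x$smooth_window, x$smooth_window,
              x$brief_window, x$brief_window, x$pattern_seed))
  cat(sprintf("  fusion: K=%g, C=%g;  CV: %d-fold x %d repeats, seed %d\n",
              x$K, x$C, x$cv_k, x$cv_repeats, x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' The serialized form round-trips exactly: `read_config(write_config(cfg, f))`
#' reconstructs a configuration identical to `cfg`.
#'
#' @param config A [pipeline_config()].
#' @param path File path of the JSON document.
#' @return `write_config()` returns `path` invisibly; `read_config()` returns a
#'   `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$svm <- unclass(x$svm)
  x$lbp_map_size <- NULL          # derived
  x$descriptor_margin <- NULL     # derived
  x$circle_size <- NULL           # fixed
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$config_version <- NULL
  svm <- x$svm
  x$svm <- NULL
  args <- x
  args$svm <- do.call(svm_config, svm %||% list())
  do.call(pipeline_config, args)
}
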