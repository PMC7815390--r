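# Programmatic fixtures shared across test files.

rand_face <- function(seed, n = 130) {
  set.seed(seed)
  matrix(sample(0:255, n * n, replace = TRUE), n, n)
}

# lattice of 3x3 blobs (alternating bright/dark) on a mid-gray background:
# every 4x4 region of a 130x130 image holds well over 10 strong corners
planted_lattice <- function(seed = 1, size = 130, step = 5, amp = 150) {
  set.seed(seed)
  img <- matrix(100, size, size)
  centers <- expand.grid(row = seq(20, size - 20, by = step),
                         col = seq(20, size - 20, by = step))
  sign <- rep_len(c(1, -1), nrow(centers))
  for (i in seq_len(nrow(centers))) {
    r <- centers$row[i]; c <- centers$col[i]
    img[r + (-1:1), c + (-1:1)] <- 100 + amp * sign[i]
  }
  list(image = img, centers = centers)
}

# per-region index (0-based, row-major) of keypoint positions
region_index <- function(kp, m = 4, n = 4, h = 130, w = 130) {
  rh <- floor(seq(0, h, length.out = m + 1))
  rw <- floor(seq(0, w, length.out = n + 1))
  ri <- findInterval(kp$row, rh, left.open = TRUE, all.inside = TRUE)
  ci <- findInterval(kp$col, rw, left.open = TRUE, all.inside = TRUE)
  (ri - 1) * n + ci - 1
}

balanced_manifest <- function(n_subjects, n_classes = 7, reps = 1) {
  labs <- exprfeat:::EXPRESSION_LABELS[seq_len(n_classes)]
  grid <- expand.grid(rep = seq_len(reps), label = labs,
                      subject = sprintf("S%02d", seq_len(n_subjects)),
                      stringsAsFactors = FALSE)
  tibble::tibble(path = sprintf("img%04d", seq_len(nrow(grid))),
                 label = grid$label, subject = grid$subject)
}

# tiny extracted feature set, cached across test files within a run
tiny_feature_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(n_subjects = 6, n_classes = 3, reps = 2, seed = 11)
      cfg <- pipeline_config(cv_repeats = 1, cv_k = 5, seed = 11,
                             svm = svm_config(cost = 8, gamma_mult = 1))
      cache <<- extract_features(generate_dataset(spec), cfg)
    }
    cache
  }
})
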