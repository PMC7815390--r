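test_that("generation is a pure function of (seed, subject, class, replicate)", {
  spec <- synthetic_spec(seed = 13)
  a <- generate_face(spec, 3, 2, 1)
  b <- generate_face(spec, 3, 2, 1)
  expect_identical(a$image, b$image)
  expect_identical(a$landmarks, b$landmarks)
  ## different replicate, subject or class changes the image
  expect_false(identical(a$image, generate_face(spec, 3, 2, 2)$image))
  expect_false(identical(a$image, generate_face(spec, 4, 2, 1)$image))
  expect_false(identical(a$image, generate_face(spec, 3, 3, 1)$image))
  expect_error(generate_face(spec, 99, 1, 1))
})

test_that("class parameter sets are pairwise distinct", {
  spec <- synthetic_spec()
  cps <- lapply(1:7, function(cl) exprfeat:::class_params(spec, cl))
  sig <- vapply(cps, function(p) paste(p$orientation, p$freq,
                                       paste(round(p$blobs, 6), collapse = ","),
                                       sep = "|"), character(1))
  expect_identical(anyDuplicated(sig), 0L)
})

test_that("a dataset is the full factorial with a valid manifest", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 10, n_classes = 7, reps = 3))
  expect_identical(nrow(ds$manifest), 210L)
  expect_identical(length(ds$images), 210L)
  expect_identical(sort(unique(ds$manifest$label)),
                   sort(exprfeat:::EXPRESSION_LABELS))
  expect_identical(length(unique(ds$manifest$subject)), 10L)
  expect_true(all(table(ds$manifest$subject, ds$manifest$label) == 3))
})

test_that("classes with orthogonal gratings have different mean LBP features", {
  ## classes 1 and 3 carry gratings at 0 and 90 degrees
  spec <- synthetic_spec(n_subjects = 2, n_classes = 3, reps = 2, seed = 21)
  feats <- function(cl) {
    rowsum <- NULL
    for (s in 1:2) for (r in 1:2) {
      g <- generate_face(spec, s, cl, r)
      f <- lbp_features(lbp_face(crop_face(g$image, g$landmarks)))
      rowsum <- if (is.null(rowsum)) f else rowsum + f
    }
    rowsum / 4
  }
  expect_gt(mean(abs(feats(1) - feats(3))), 0)
})

test_that("planted corner blobs are recovered by region-balanced detection", {
  spec <- synthetic_spec(seed = 17)
  rates <- vapply(1:4, function(s) {
    g <- generate_face(spec, s, ((s - 1) %% 7) + 1, 1)
    kp <- detect_region_balanced(g$image)
    bi <- g$truth$blobs_image
    d <- vapply(seq_len(nrow(bi)), function(i) {
      min(sqrt((kp$row - bi[i, "row"])^2 + (kp$col - bi[i, "col"])^2))
    }, numeric(1))
    mean(d <= 2)
  }, numeric(1))
  expect_true(all(rates >= 0.8))
})

test_that("harder texture contrast settings do not score above easier ones", {
  acc_at <- function(contrast) {
    spec <- synthetic_spec(n_subjects = 6, n_classes = 3, reps = 2,
                           texture_contrast = contrast, seed = 11)
    cfg <- pipeline_config(cv_repeats = 1, cv_k = 5, seed = 11,
                           svm = svm_config(cost = 8, gamma_mult = 1))
    fs <- extract_features(generate_dataset(spec), cfg)
    run_cv(feature_matrix(fs, "fused"), fs$manifest, "SD", k = 5,
           repeats = 1, svm = cfg$svm, seed = 11)$mean_accuracy
  }
  expect_gte(acc_at(30), acc_at(8) - 0.02)
})

test_that("datasets write to disk and read back losslessly", {
  ds <- generate_dataset(synthetic_spec(n_subjects = 2, n_classes = 2, reps = 1,
                                        seed = 31))
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(man$path, ds$manifest$path)
  id <- man$path[1]
  expect_identical(read_image(file.path(dir, id)), ds$images[[id]])
  lm <- read_landmarks(file.path(dir, paste0(tools::file_path_sans_ext(id), ".pts")))
  expect_equal(lm$x, ds$landmarks[[id]]$x, tolerance = 1e-8)
})
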