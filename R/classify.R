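#' Build cross-validation folds under the SD or SI protocol
#'
#' Subject-dependent (SD) folds are a label-stratified random partition of the
#' *images*: the same subject may appear in both the training and the test
#' side of a fold. Subject-independent (SI) folds partition the *subjects*
#' into `k` groups, so no subject identifier ever appears on both sides —
#' the protocol that models recognizing expressions of unseen people. Folds
#' are computed on records sorted by `(path, subject, label)`, so the
#' partition is invariant to the row order of the manifest and reproducible
#' from the seed.
#'
#' @param manifest Data frame with columns `path`, `label`, `subject`.
#' @param protocol `"SD"` or `"SI"`.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of `k` integer vectors of test-set row indices into
#'   `manifest` (disjoint, covering all rows).
#' @export
#' @examples
#' m <- tibble::tibble(path = sprintf("i%02d", 1:20),
#'                     label = rep(c("happy", "sad"), 10),
#'                     subject = rep(sprintf("S%d", 1:5), each = 4))
#' folds <- make_folds(m, "SI", k = 5, seed = 1)
make_folds <- function(manifest, protocol = c("SD", "SI"), k = 10L, seed = 0L) {
  protocol <- match.arg(protocol)
  stopifnot(all(c("path", "label", "subject") %in% names(manifest)))
  if (any(!nzchar(manifest$subject))) abort("every record needs a nonempty subject")
  n <- nrow(manifest)
  ord <- order(manifest$path, manifest$subject, manifest$label)

  withr::with_seed(as.integer(seed), {
    if (protocol == "SD") {
      fold_of <- integer(n)
      start <- 0L
      for (lab in sort(unique(manifest$label))) {
        idx <- ord[manifest$label[ord] == lab]
        idx <- sample(idx)
        ## rotate the dealing start so fold sizes stay balanced across labels
        fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
        start <- (start + length(idx)) %% k
      }
    } else {
      subjects <- sort(unique(manifest$subject))
      if (length(subjects) < k) {
        abort(sprintf("SI protocol needs at least k=%d distinct subjects, got %d",
                      k, length(subjects)),
              class = "exprfeat_protocol_error")
      }
      subjects <- sample(subjects)
      group <- ((seq_along(subjects) - 1L) %% k) + 1L
      fold_of <- group[match(manifest$subject, subjects)]
    }
  })
  lapply(seq_len(k), function(f) which(fold_of == f))
}

## Stratified inner folds on a training label vector (for grid search).
inner_folds <- function(labels, k, seed) {
  withr::with_seed(as.integer(seed), {
    fold_of <- integer(length(labels))
    start <- 0L
    for (lab in sort(unique(labels))) {
      idx <- sample(which(labels == lab))
      fold_of[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- (start + length(idx)) %% k
    }
    fold_of
  })
}

## Squared Euclidean distance matrix via the Gram matrix.
squared_distances <- function(X) {
  G <- tcrossprod(X)
  nrm <- diag(G)
  D <- outer(nrm, nrm, "+") - 2 * G
  D[D < 0] <- 0
  D
}

## Exact distance-preserving embedding (classical multidimensional scaling).
## The RBF kernel depends on the feature vectors only through their pairwise
## squared distances, so embedding the n images into at most n-1 coordinates
## with identical distances leaves every kernel value unchanged while letting
## libsvm work on short vectors instead of the ~40k-dimensional originals.
mds_embed <- function(D) {
  n <- nrow(D)
  rm_ <- rowMeans(D); gm <- mean(D)
  B <- -0.5 * (D - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + gm)
  e <- eigen(B, symmetric = TRUE)
  keep <- e$values > max(e$values, 0) * 1e-12
  if (!any(keep)) return(matrix(0, n, 1))
  e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]),
                                           nrow = sum(keep))
}

## Fit a C-SVC (libsvm, RBF kernel, one-vs-one multiclass) on the embedded
## coordinates and predict test labels.
svm_fit_predict <- function(Z, labels, train, test, cost, gamma) {
  fit <- e1071::svm(Z[train, , drop = FALSE], factor(labels[train]),
                    kernel = "radial", gamma = gamma, cost = cost,
                    scale = FALSE)
  as.character(predict(fit, Z[test, , drop = FALSE]))
}

## Nested grid search: pick (cost, gamma) maximizing inner-CV accuracy on the
## training rows; gamma = mult / median(squared training distances).
grid_search <- function(Z, D, labels, train, svm_cfg, seed) {
  Dtr <- D[train, train, drop = FALSE]
  med <- median(Dtr[upper.tri(Dtr)])
  if (!is.finite(med) || med <= 0) med <- 1
  gamma0 <- 1 / med
  fold_of <- inner_folds(labels[train], svm_cfg$inner_k, seed)
  grid <- expand.grid(cost = svm_cfg$cost, gamma_mult = svm_cfg$gamma_mult)
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    correct <- 0L; total <- 0L
    for (f in seq_len(svm_cfg$inner_k)) {
      itr <- train[fold_of != f]; ite <- train[fold_of == f]
      if (length(ite) == 0 || length(unique(labels[itr])) < 2) next
      pred <- svm_fit_predict(Z, labels, itr, ite,
                              grid$cost[g], grid$gamma_mult[g] * gamma0)
      correct <- correct + sum(pred == labels[ite])
      total <- total + length(ite)
    }
    if (total == 0) 0 else correct / total
  }, numeric(1))
  best <- which.max(acc)   # ties: first grid entry wins (deterministic)
  list(cost = grid$cost[best], gamma = grid$gamma_mult[best] * gamma0,
       inner_accuracy = acc[best])
}

#' Repeated cross-validated SVM evaluation
#'
#' Evaluates an RBF-kernel SVM (libsvm C-classification, one-vs-one
#' multiclass) on a feature matrix under the SD or SI protocol: for each of `repeats`
#' repetitions, fresh `k` folds are drawn, and within each outer training
#' fold the cost and kernel width are chosen by an inner `inner_k`-fold grid
#' search (see [svm_config()]) before refitting on the whole training fold
#' and scoring the held-out fold. Accuracies are pooled over repeats x folds
#' and predictions accumulated into a confusion matrix.
#'
#' In SD mode a fold whose training side lost a class is redrawn with a
#' shifted seed; in SI mode (where class absence can be forced by the subject
#' partition) it is accepted with a warning.
#'
#' Internally the feature rows are re-expressed in an exact
#' distance-preserving coordinate system (classical multidimensional
#' scaling of the full squared-distance matrix) before the SVM sees them;
#' every RBF kernel value is unchanged by this, and libsvm runs on vectors
#' of length at most n instead of the full feature dimension.
#'
#' @param features Numeric matrix, one row per manifest record.
#' @param manifest Data frame with columns `path`, `label`, `subject`,
#'   rows aligned with `features`.
#' @param protocol `"SD"` or `"SI"`.
#' @param k Outer folds.
#' @param repeats Repetitions of the whole CV.
#' @param svm An [svm_config()].
#' @param seed Integer seed; fold draws use `seed + 101 * repeat`.
#' @return An object of class `cv_result`: list with `protocol`, `k`,
#'   `repeats`, `labels`, `folds` (tibble of per-fold accuracies),
#'   `mean_accuracy`, `sd_accuracy` (SD of per-repeat means), `confusion`
#'   (true x predicted counts), and `params` (chosen hyperparameters per
#'   fold).
#' @export
run_cv <- function(features, manifest, protocol = c("SD", "SI"), k = 10L,
                   repeats = 10L, svm = svm_config(), seed = 0L) {
  protocol <- match.arg(protocol)
  features <- as.matrix(features)
  stopifnot(nrow(features) == nrow(manifest))
  labels <- as.character(manifest$label)
  lev <- sort(unique(labels))
  D <- squared_distances(features)
  Z <- mds_embed(D)

  fold_rows <- list(); param_rows <- list()
  confusion <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  for (rep_i in seq_len(repeats)) {
    fold_seed <- as.integer(seed) + 101L * rep_i
    folds <- make_folds(manifest, protocol, k, fold_seed)
    if (protocol == "SD") {
      ## reroll folds (bounded) until every training side has every class
      for (try in 1:20) {
        ok <- all(vapply(folds, function(te) {
          length(setdiff(lev, labels[-te])) == 0
        }, logical(1)))
        if (ok) break
        fold_seed <- fold_seed + 7919L
        folds <- make_folds(manifest, protocol, k, fold_seed)
      }
    }
    for (f in seq_len(k)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(nrow(manifest)), test)
      if (length(test) == 0) next
      missing <- setdiff(lev, labels[train])
      if (length(missing) > 0) {
        warn(sprintf("repeat %d fold %d: class(es) %s absent from training side",
                     rep_i, f, paste(missing, collapse = ", ")))
      }
      gs <- grid_search(Z, D, labels, train, svm, seed = fold_seed + f)
      pred <- svm_fit_predict(Z, labels, train, test, gs$cost, gs$gamma)
      acc <- mean(pred == labels[test])
      fold_rows[[length(fold_rows) + 1L]] <-
        tibble::tibble(rep = rep_i, fold = f, n_test = length(test),
                       accuracy = acc)
      param_rows[[length(param_rows) + 1L]] <-
        tibble::tibble(rep = rep_i, fold = f, cost = gs$cost, gamma = gs$gamma,
                       inner_accuracy = gs$inner_accuracy)
      tab <- table(factor(labels[test], lev), factor(pred, lev))
      confusion <- confusion + unclass(tab)
    }
  }
  fold_tbl <- dplyr::bind_rows(fold_rows)
  rep_means <- dplyr::summarise(dplyr::group_by(fold_tbl, .data$rep),
                                acc = sum(.data$accuracy * .data$n_test) /
                                      sum(.data$n_test))$acc
  structure(
    list(protocol = protocol, k = k, repeats = repeats, labels = lev,
         folds = fold_tbl,
         mean_accuracy = sum(fold_tbl$accuracy * fold_tbl$n_test) /
                         sum(fold_tbl$n_test),
         sd_accuracy = if (repeats > 1) sd(rep_means) else NA_real_,
         confusion = confusion,
         params = dplyr::bind_rows(param_rows),
         seed = as.integer(seed)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s protocol, %d-fold x %d repeats>\n",
              x$protocol, x$k, x$repeats))
  cat(sprintf("  mean accuracy %.3f", x$mean_accuracy))
  if (!is.na(x$sd_accuracy)) cat(sprintf(" (SD over repeats %.3f)", x$sd_accuracy))
  cat("\n  confusion matrix (true x predicted):\n")
  print(x$confusion)
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' `tidy()` returns the per-fold accuracies; `glance()` a one-row summary.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::mutate(x$folds, protocol = x$protocol, .before = 1)
}

#' @rdname tidy.cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, k = x$k, repeats = x$repeats,
                 n = sum(x$folds$n_test[x$folds$rep == 1]),
                 mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd_accuracy)
}

#' Plot a cross-validation confusion matrix
#'
#' Heatmap of the pooled confusion matrix (row-normalized), with the mean
#' accuracy in the title.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  cm <- object$confusion
  df <- as.data.frame.table(cm / pmax(rowSums(cm), 1), responseName = "rate")
  names(df)[1:2] <- c("true", "predicted")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rate)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(title = sprintf("%s protocol, mean accuracy %.3f",
                                  object$protocol, object$mean_accuracy),
                  x = "predicted", y = "true", fill = "rate") +
    ggplot2::theme_minimal()
}
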