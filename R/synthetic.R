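## Deterministic sub-seed derivation (kept below 2^31).
seed_for <- function(seed, a = 0L, b = 0L, c = 0L, salt = 0L) {
  (as.double(seed) * 48271 + a * 7919 + b * 911 + c * 101 + salt * 17) %% 2147483647
}

#' Specification of a synthetic expression dataset
#'
#' Describes a deterministic generator of face-like images with known 68-point
#' landmarks, class-dependent texture and corner structure, and
#' subject-specific nuisance variation. Each class carries two signals: an
#' oriented sinusoidal grating inside the face oval (read by the LBP texture
#' histograms) and a class-specific constellation of small high-contrast
#' blobs (read by the corner detector and BRIEF descriptors). Subjects differ
#' by a global brightness offset and a mild similarity warp (scale, rotation,
#' translation) of the whole face, which is what makes the subject-dependent
#' and subject-independent protocols genuinely different. Replicates differ
#' by the grating phase and pixel noise.
#'
#' The default scale (10 subjects x 7 classes x 3 replicates = 210 images)
#' mirrors the size of a small laboratory expression database.
#'
#' @param n_subjects Number of subjects.
#' @param n_classes Number of expression classes (at most 7; labels are taken
#'   from the canonical 7-expression set in order).
#' @param reps Images per subject per class.
#' @param image_size Side of the square canvas in pixels.
#' @param texture_contrast Amplitude of the class grating (intensity levels).
#' @param subject_contrast Amplitude of the subject identity grating
#'   (intensity levels): a secondary oriented texture fixed per subject
#'   across all classes and replicates, emulating identity-specific skin and
#'   facial structure. It is what makes recognizing expressions of unseen
#'   subjects harder than held-out images of known subjects.
#' @param noise_sd Additive Gaussian pixel noise SD (intensity levels).
#' @param n_blobs Blobs per class constellation.
#' @param seed Master seed; every image is a pure function of
#'   (seed, subject, class, replicate).
#' @return An object of class `synthetic_spec`.
#' @export
#' @examples
#' spec <- synthetic_spec(n_subjects = 3, n_classes = 3, reps = 2)
synthetic_spec <- function(n_subjects = 10L, n_classes = 7L, reps = 3L,
                           image_size = 160L, texture_contrast = 30,
                           subject_contrast = 18, noise_sd = 12,
                           n_blobs = 12L, seed = 0L) {
  stopifnot(n_subjects >= 1, n_classes >= 1, n_classes <= 7, reps >= 1,
            image_size >= 120, texture_contrast >= 0, subject_contrast >= 0,
            noise_sd >= 0, n_blobs >= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), n_classes = as.integer(n_classes),
         reps = as.integer(reps), image_size = as.integer(image_size),
         texture_contrast = as.numeric(texture_contrast),
         subject_contrast = as.numeric(subject_contrast),
         noise_sd = as.numeric(noise_sd), n_blobs = as.integer(n_blobs),
         seed = as.integer(seed),
         labels = EXPRESSION_LABELS[seq_len(n_classes)],
         base_intensity = 150, background = 60),
    class = "synthetic_spec"
  )
}

## Canonical 68-point layout in unit face coordinates (x right, y down).
landmark_template <- function() {
  pts <- matrix(NA_real_, 68, 2)
  ang <- pi * (1 + (0:16) / 16)                       # jaw 1-17
  pts[1:17, ] <- cbind(0.5 + 0.42 * cos(ang), 0.35 - 0.60 * sin(ang))
  t5 <- (0:4) / 4
  pts[18:22, ] <- cbind(0.18 + 0.24 * t5, 0.27 - 0.04 * sin(pi * t5))  # brows
  pts[23:27, ] <- cbind(0.58 + 0.24 * t5, 0.27 - 0.04 * sin(pi * t5))
  pts[28:31, ] <- cbind(rep(0.5, 4), 0.36 + 0.06 * (0:3))              # nose bridge
  pts[32:36, ] <- cbind(0.42 + 0.04 * (0:4), rep(0.60, 5))             # nostril row
  hex <- pi / 180 * c(180, 120, 60, 0, 300, 240)                       # eyes
  pts[37:42, ] <- cbind(0.30 + 0.06 * cos(hex), 0.38 - 0.025 * sin(hex))
  pts[43:48, ] <- cbind(0.70 + 0.06 * cos(hex), 0.38 - 0.025 * sin(hex))
  a12 <- pi / 180 * (180 - 30 * (0:11))                                # outer lips
  pts[49:60, ] <- cbind(0.5 + 0.14 * cos(a12), 0.74 - 0.05 * sin(a12))
  a8 <- pi / 180 * (180 - 45 * (0:7))                                  # inner lips
  pts[61:68, ] <- cbind(0.5 + 0.09 * cos(a8), 0.74 - 0.02 * sin(a8))
  colnames(pts) <- c("x", "y")
  pts
}

## Per-class texture and blob-constellation parameters, derived from the
## seed. A class is a (texture, constellation) pair: textures cycle through
## 4 grating orientation/frequency combinations and constellations through 2
## blob layouts, so with 7 classes some pairs share their texture and differ
## only in the constellation (and vice versa) — neither feature family alone
## identifies every class, which is the rationale for fusing them.
class_params <- function(spec, class_id) {
  stopifnot(class_id >= 1, class_id <= spec$n_classes)
  texture_id <- (class_id - 1L) %% 4L
  constellation_id <- (class_id - 1L) %/% 4L
  orient <- texture_id * pi / 4
  freq <- c(10, 12, 14, 11)[texture_id + 1L]   # cycles per unit face width
  blobs <- withr::with_seed(seed_for(spec$seed, 0, constellation_id, 0, salt = 1L), {
    cbind(x = runif(spec$n_blobs, 0.16, 0.84),
          y = runif(spec$n_blobs, 0.20, 0.90))
  })
  list(texture_id = texture_id, constellation_id = constellation_id,
       orientation = orient, freq = freq, blobs = blobs,
       blob_sign = rep_len(c(1, -1), spec$n_blobs))
}

## Per-subject nuisance parameters: brightness, a mild similarity warp, and
## subject-specific distortion of the class signals (grating orientation and
## frequency, blob placement). The distortions are what make recognizing a
## *new* subject harder than recognizing held-out images of a known subject.
subject_params <- function(spec, subject_id) {
  stopifnot(subject_id >= 1, subject_id <= spec$n_subjects)
  withr::with_seed(seed_for(spec$seed, subject_id, 0, 0, salt = 2L), {
    list(brightness = runif(1, -25, 25),
         scale = runif(1, 0.95, 1.05),
         rot = runif(1, -3, 3) * pi / 180,
         tx = runif(1, -2, 2), ty = runif(1, -2, 2),
         orient_offset = runif(1, -18, 18) * pi / 180,
         freq_mult = runif(1, 0.9, 1.1),
         id_orient = runif(1, 0, pi),
         id_freq = runif(1, 13, 17),
         id_phase = runif(1, 0, 2 * pi),
         blob_jitter = matrix(rnorm(2 * spec$n_blobs, 0, 0.015),
                              spec$n_blobs, 2))
  })
}

## Similarity transform from unit face coordinates to image pixels.
face_transform <- function(spec, sp) {
  S <- spec$image_size
  box_scale <- 0.68 * S
  box_off <- 0.16 * S
  center <- (S + 1) / 2
  fwd <- function(u, v) {
    xi <- u * box_scale + box_off
    yi <- v * box_scale + box_off * 0.8
    dx <- xi - center; dy <- yi - center
    list(x = center + sp$scale * (cos(sp$rot) * dx - sin(sp$rot) * dy) + sp$tx,
         y = center + sp$scale * (sin(sp$rot) * dx + cos(sp$rot) * dy) + sp$ty)
  }
  inv <- function(x, y) {
    dx <- x - center - sp$tx; dy <- y - center - sp$ty
    xi <- center + ( cos(sp$rot) * dx + sin(sp$rot) * dy) / sp$scale
    yi <- center + (-sin(sp$rot) * dx + cos(sp$rot) * dy) / sp$scale
    list(u = (xi - box_off) / box_scale, v = (yi - box_off * 0.8) / box_scale)
  }
  list(fwd = fwd, inv = inv)
}

#' Generate one synthetic face image with ground truth
#'
#' Paints an oval face on a flat background, adds the class grating inside
#' the oval, draws dark eye/brow/nose/lip features at the landmark positions,
#' plants the class blob constellation (alternating bright and dark 3x3
#' squares, which the corner detector fires on), and adds Gaussian pixel
#' noise. Deterministic given `(spec$seed, subject_id, class_id, replicate)`.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_id Subject index in `1:n_subjects`.
#' @param class_id Class index in `1:n_classes`.
#' @param replicate Replicate index (>= 1).
#' @return List with `image` (integer matrix), `landmarks` (a
#'   [landmark_set()]), and `truth`: the crop box implied by points 1-27, the
#'   raw face patch under that box, blob centers in image and in cropped
#'   130x130 coordinates, and the class parameters.
#' @export
generate_face <- function(spec, subject_id, class_id, replicate = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (subject_id < 1 || subject_id > spec$n_subjects ||
      class_id < 1 || class_id > spec$n_classes || replicate < 1) {
    abort("subject/class/replicate id out of range for this spec")
  }
  cp <- class_params(spec, class_id)
  sp <- subject_params(spec, subject_id)
  tr <- face_transform(spec, sp)
  S <- spec$image_size

  tmpl <- landmark_template()
  lm_xy <- tr$fwd(tmpl[, "x"], tmpl[, "y"])
  landmarks <- landmark_set(lm_xy$x, lm_xy$y)

  ## unit coordinates of every pixel (X = col, Y = row)
  X <- matrix(rep(1:S, each = S), S, S)
  Y <- matrix(rep(1:S, times = S), S, S)
  uv <- tr$inv(X, Y)

  img <- matrix(spec$background, S, S)
  oval <- ((uv$u - 0.5) / 0.47)^2 + ((uv$v - 0.55) / 0.45)^2 <= 1

  ## the grating phase belongs to the (subject, class) pair — replicates are
  ## repeated photographs of the same face, alike up to small phase drift and
  ## pixel noise — which is what makes held-out replicates of a known subject
  ## easier than images of an unseen subject
  phase <- withr::with_seed(
    seed_for(spec$seed, subject_id, class_id, 0L, salt = 3L),
    runif(1, 0, 2 * pi)
  ) + withr::with_seed(
    seed_for(spec$seed, subject_id, class_id, replicate, salt = 5L),
    rnorm(1, 0, 0.4)
  )
  orient <- cp$orientation + sp$orient_offset
  grating <- spec$texture_contrast *
    sin(2 * pi * cp$freq * sp$freq_mult *
        (uv$u * cos(orient) + uv$v * sin(orient)) + phase)
  id_tex <- spec$subject_contrast *
    sin(2 * pi * sp$id_freq * (uv$u * cos(sp$id_orient) +
                               uv$v * sin(sp$id_orient)) + sp$id_phase)
  img[oval] <- spec$base_intensity + sp$brightness + grating[oval] + id_tex[oval]

  ## dark facial features at the landmark positions
  feat_pts <- landmarks[landmarks$point >= 18, ]
  for (i in seq_len(nrow(feat_pts))) {
    r <- round(feat_pts$y[i]); c <- round(feat_pts$x[i])
    rr <- max(1, r - 1):min(S, r + 1); cc <- max(1, c - 1):min(S, c + 1)
    img[rr, cc] <- 90
  }

  ## class blob constellation (subject-jittered): 3x3 squares, bright/dark
  blob_xy <- tr$fwd(cp$blobs[, "x"] + sp$blob_jitter[, 1],
                    cp$blobs[, "y"] + sp$blob_jitter[, 2])
  blob_rc <- cbind(row = round(blob_xy$y), col = round(blob_xy$x))
  for (i in seq_len(nrow(blob_rc))) {
    r <- blob_rc[i, "row"]; c <- blob_rc[i, "col"]
    rr <- max(1, r - 1):min(S, r + 1); cc <- max(1, c - 1):min(S, c + 1)
    img[rr, cc] <- if (cp$blob_sign[i] > 0) 255 else 0
  }

  noise <- withr::with_seed(
    seed_for(spec$seed, subject_id, class_id, replicate, salt = 4L),
    matrix(rnorm(S * S, 0, spec$noise_sd), S, S)
  )
  img <- pmin(pmax(round(img + noise), 0), 255)
  storage.mode(img) <- "integer"

  ## ground-truth crop box of points 1-27 (same clamping rule as crop_face)
  pts <- landmarks[landmarks$point <= 27, ]
  c0 <- floor(min(pmax(pts$x, 1))); c1 <- ceiling(max(pmin(pts$x, S)))
  r0 <- floor(min(pmax(pts$y, 1))); r1 <- ceiling(max(pmin(pts$y, S)))
  scale_r <- 130 / (r1 - r0 + 1); scale_c <- 130 / (c1 - c0 + 1)
  blob_crop <- cbind(row = (blob_rc[, "row"] - r0 + 0.5) * scale_r + 0.5,
                     col = (blob_rc[, "col"] - c0 + 0.5) * scale_c + 0.5)
  in_crop <- blob_rc[, "row"] >= r0 & blob_rc[, "row"] <= r1 &
             blob_rc[, "col"] >= c0 & blob_rc[, "col"] <= c1

  list(image = img, landmarks = landmarks,
       truth = list(crop_box = c(row0 = r0, row1 = r1, col0 = c0, col1 = c1),
                    face_patch = img[r0:r1, c0:c1],
                    blobs_image = blob_rc,
                    blobs_crop = blob_crop[in_crop, , drop = FALSE],
                    class_params = cp, subject_params = sp))
}

#' Generate a full synthetic dataset
#'
#' Full factorial over subjects x classes x replicates, in deterministic
#' order. Record ids follow `s<subject>_<label>_r<replicate>.png`.
#'
#' @param spec A [synthetic_spec()].
#' @return List of class `synthetic_dataset` with `images` (named list of
#'   intensity matrices), `landmarks` (named list of landmark sets),
#'   `manifest` (tibble with `path`, `label`, `subject`), `truth` (named
#'   list of per-image ground truth), and `spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_subjects = 2, n_classes = 2, reps = 1))
#' nrow(ds$manifest)
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  grid <- expand.grid(replicate = seq_len(spec$reps),
                      class_id = seq_len(spec$n_classes),
                      subject_id = seq_len(spec$n_subjects))
  grid <- grid[order(grid$subject_id, grid$class_id, grid$replicate), ]
  ids <- sprintf("s%02d_%s_r%d.png", grid$subject_id,
                 spec$labels[grid$class_id], grid$replicate)
  images <- vector("list", nrow(grid)); lms <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- generate_face(spec, grid$subject_id[i], grid$class_id[i],
                       grid$replicate[i])
    images[[i]] <- g$image; lms[[i]] <- g$landmarks; truth[[i]] <- g$truth
  }
  names(images) <- ids; names(lms) <- ids; names(truth) <- ids
  manifest <- tibble::tibble(path = ids,
                             label = spec$labels[grid$class_id],
                             subject = sprintf("S%02d", grid$subject_id))
  structure(list(images = images, landmarks = lms, manifest = manifest,
                 truth = truth, spec = spec),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d images (%d subjects x %d classes x %d reps), %dx%d px>\n",
              nrow(x$manifest), x$spec$n_subjects, x$spec$n_classes,
              x$spec$reps, x$spec$image_size, x$spec$image_size))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as PNG, each landmark set as a `.pts` sidecar (68 lines
#' of `x y`), and the manifest as `manifest.csv` with header
#' `path,label,subject`.
#'
#' @param dataset A `synthetic_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(dataset$images)) {
    write_image(dataset$images[[id]], file.path(dir, id))
    write_landmarks(dataset$landmarks[[id]],
                    file.path(dir, paste0(tools::file_path_sans_ext(id), ".pts")))
  }
  readr::write_csv(dataset$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}
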