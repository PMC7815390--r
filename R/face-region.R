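#' Construct a 68-point facial landmark set
#'
#' Landmarks follow the standard 68-point convention, 1-based: jaw 1-17, left
#' eyebrow 18-22, right eyebrow 23-27, nose 28-36, eyes 37-48, lips 49-68.
#' Coordinates are pixel positions (`x` = column, `y` = row, both 1-based, may
#' be fractional).
#'
#' @param x,y Numeric vectors of length 68, or `x` a 68x2 matrix/data frame
#'   with columns x, y.
#' @return A tibble of class `landmark_set` with columns `point`, `x`, `y`.
#' @export
#' @examples
#' lm <- landmark_set(runif(68, 1, 100), runif(68, 1, 100))
#' nrow(lm)
landmark_set <- function(x, y = NULL) {
  if (is.null(y)) {
    m <- as.matrix(as.data.frame(x))
    if (ncol(m) != 2) abort("landmark input must have two columns (x, y)")
    y <- m[, 2]
    x <- m[, 1]
  }
  if (length(x) != 68 || length(y) != 68) {
    abort(sprintf("a landmark set has exactly 68 points, got %d", length(x)),
          class = "exprfeat_invalid_landmarks")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("landmark coordinates must all be finite",
          class = "exprfeat_invalid_landmarks")
  }
  out <- tibble::tibble(point = 1:68, x = as.numeric(x), y = as.numeric(y))
  class(out) <- c("landmark_set", class(out))
  out
}

#' Read / write a landmark sidecar file
#'
#' The sidecar format is 68 whitespace-delimited lines of `x y`.
#'
#' @param path Text file path.
#' @param landmarks A [landmark_set()].
#' @return `read_landmarks()` returns a `landmark_set`; `write_landmarks()`
#'   returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  m <- as.matrix(utils::read.table(path, col.names = c("x", "y")))
  landmark_set(m)
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  writeLines(sprintf("%.6f %.6f", landmarks$x, landmarks$y), path)
  invisible(path)
}

#' Convert an image to 8-bit grayscale
#'
#' Color images are converted with ITU-R BT.601 luminance weights
#' (0.299 R + 0.587 G + 0.114 B) and rounded to the nearest integer; grayscale
#' input passes through unchanged (already-integer gray images are the
#' identity).
#'
#' @param image A numeric matrix (grayscale, values in \[0, 255\]) or an
#'   H x W x 3 array.
#' @return An integer-valued matrix in \[0, 255\].
#' @export
to_grayscale <- function(image) {
  as_int <- function(m) {
    m <- round(m)
    storage.mode(m) <- "integer"
    m
  }
  if (is.matrix(image)) {
    return(as_int(image))
  }
  if (length(dim(image)) == 3) {
    nc <- dim(image)[3]
    if (nc >= 3) {
      return(as_int(0.299 * image[, , 1] + 0.587 * image[, , 2] +
                    0.114 * image[, , 3]))
    }
    return(as_int(image[, , 1]))
  }
  abort("`image` must be a matrix or an H x W x C array")
}

#' Read a PNG or PGM image as an intensity matrix
#'
#' Returns a matrix of integer intensities in \[0, 255\] (rows = image rows).
#' Color PNGs are reduced to luminance via [to_grayscale()].
#'
#' @param path Image file; format inferred from the extension
#'   (`.png`, `.pgm`).
#' @return Integer-valued intensity matrix.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    return(to_grayscale(a * 255))
  }
  if (ext == "pgm") {
    return(read_pgm(path))
  }
  abort(sprintf("unsupported image format: '%s' (PNG and PGM are supported)", ext))
}

#' @rdname read_image
#' @param image Integer-valued matrix in \[0, 255\].
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  } else if (ext == "pgm") {
    write_pgm(image, path)
  } else {
    abort(sprintf("unsupported image format: '%s'", ext))
  }
  invisible(path)
}

## Minimal plain/raw PGM (P2/P5) reader-writer; no installed R package
## handles this format.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) abort("not a PGM file (expected P2 or P5 magic)")
  tokens <- character(0)
  while (length(tokens) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*$", "", line)
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    tokens <- c(tokens, tok[nzchar(tok)])
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "integer", n = w * h, size = 1, signed = FALSE))
  } else {
    vals <- integer(0)
    while (length(vals) < w * h) {
      line <- readLines(con, n = 1)
      tok <- strsplit(trimws(sub("#.*$", "", line)), "\\s+")[[1]]
      vals <- c(vals, as.integer(tok[nzchar(tok)]))
    }
  }
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  if (maxval != 255) m <- round(m * (255 / maxval))
  m
}

write_pgm <- function(image, path) {
  image <- pmin(pmax(round(image), 0), 255)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(image), nrow(image)), "255"), con)
  apply(image, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

#' Resize an intensity matrix with bilinear interpolation
#'
#' Thin wrapper over [EBImage::resize()] returning integer intensities.
#'
#' @param image Numeric matrix.
#' @param nrow,ncol Target dimensions.
#' @return Integer-valued matrix of the requested size.
#' @export
resize_bilinear <- function(image, nrow, ncol) {
  if (nrow(image) == nrow && ncol(image) == ncol) {
    m <- round(image)
  } else {
    out <- EBImage::resize(EBImage::Image(image), w = nrow, h = ncol,
                           filter = "bilinear")
    m <- pmin(pmax(round(EBImage::imageData(out)), 0), 255)
  }
  storage.mode(m) <- "integer"
  m
}

#' Crop the standardized face region from an image
#'
#' Cuts the axis-aligned bounding box of landmark points 1-27 (the jaw line
#' and both eyebrows — the region carrying the expressive parts of the face,
#' excluding forehead and ears), converts to grayscale if needed, and resizes
#' to a square `size` x `size` face region (130 x 130 by default) with
#' bilinear interpolation. Landmark coordinates are clamped to the image
#' bounds before the box is taken.
#'
#' @param image Intensity matrix or H x W x 3 array, values in \[0, 255\].
#' @param landmarks A [landmark_set()].
#' @param size Side of the square output region.
#' @return `size` x `size` integer intensity matrix (a face image).
#' @export
#' @examples
#' img <- matrix(sample(0:255, 200 * 200, TRUE), 200, 200)
#' lm <- landmark_set(runif(68, 20, 180), runif(68, 20, 180))
#' dim(crop_face(img, lm))
crop_face <- function(image, landmarks, size = 130L) {
  if (!inherits(landmarks, "landmark_set")) landmarks <- landmark_set(landmarks)
  gray <- to_grayscale(image)
  h <- nrow(gray); w <- ncol(gray)
  pts <- landmarks[landmarks$point <= 27, ]
  xs <- pmin(pmax(pts$x, 1), w)
  ys <- pmin(pmax(pts$y, 1), h)
  c0 <- floor(min(xs)); c1 <- ceiling(max(xs))
  r0 <- floor(min(ys)); r1 <- ceiling(max(ys))
  if (c1 - c0 < 1 || r1 - r0 < 1) {
    abort("face bounding box from points 1-27 has zero width or height",
          class = "exprfeat_degenerate_region")
  }
  crop <- gray[r0:r1, c0:c1, drop = FALSE]
  out <- resize_bilinear(crop, size, size)
  structure(out, face_box = c(row0 = r0, row1 = r1, col0 = c0, col1 = c1))
}
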