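#' Max-normalize a nonnegative feature vector to \[0, 1\]
#'
#' Divides every entry by the vector maximum (`L = l / max(l)`); the all-zero
#' vector is defined to map to itself. Applied to the LBP histogram counts
#' before fusion. Negative entries are a domain error: LBP features are
#' counts.
#'
#' @param v Nonnegative numeric vector.
#' @return Numeric vector in \[0, 1\] of the same length.
#' @export
#' @examples
#' max_normalize(c(2, 4, 8))
max_normalize <- function(v) {
  if (length(v) == 0) abort("`v` must be nonempty")
  if (any(v < 0)) abort("`v` must be nonnegative", class = "exprfeat_domain_error")
  m <- max(v)
  if (m == 0) return(v)
  v / m
}

## Standardize one block to mean C and population SD K; a constant block
## (sigma = 0) maps to the constant C.
zscore_block <- function(v, K, C) {
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))
  if (sigma == 0) return(rep(C, length(v)))
  K * (v - mu) / sigma + C
}

#' Fuse LBP and ORB feature vectors by Z-score standardization
#'
#' Each block is standardized independently over its own entries to mean `C`
#' and population standard deviation `K` (`K = 100` by default), then the
#' blocks are concatenated LBP-first. Standardization removes any positive
#' scaling of a block, so max-normalizing the LBP counts beforehand does not
#' change the fused vector; it is kept as an explicit step of the pipeline.
#'
#' @param lbp,orb Nonempty numeric vectors (the two feature blocks).
#' @param K Spread constant (population SD of each fused block).
#' @param C Offset constant (mean of each fused block).
#' @return Numeric vector of class `fused_feature`, length
#'   `length(lbp) + length(orb)`, with attributes `block_boundary` (the LBP
#'   block length), `K` and `C`.
#' @export
#' @examples
#' zscore_fuse(c(1, 2, 3), c(0, 1, 1, 0))
zscore_fuse <- function(lbp, orb, K = 100, C = 0) {
  if (length(lbp) == 0 || length(orb) == 0) abort("both blocks must be nonempty")
  out <- c(zscore_block(as.numeric(lbp), K, C),
           zscore_block(as.numeric(orb), K, C))
  structure(out, block_boundary = length(lbp), K = K, C = C,
            class = c("fused_feature", "numeric"))
}

#' Fuse per-image LBP and ORB feature matrices row-wise
#'
#' Applies [zscore_fuse()] to each image (row) of the two feature matrices.
#'
#' @param lbp_mat,orb_mat Numeric matrices with one row per image.
#' @inheritParams zscore_fuse
#' @return Numeric matrix `nrow(lbp_mat)` x `(ncol(lbp_mat) + ncol(orb_mat))`
#'   with attribute `block_boundary`.
#' @export
fuse_features <- function(lbp_mat, orb_mat, K = 100, C = 0) {
  stopifnot(nrow(lbp_mat) == nrow(orb_mat))
  out <- cbind(t(apply(lbp_mat, 1, zscore_block, K = K, C = C)),
               t(apply(orb_mat, 1, zscore_block, K = K, C = C)))
  attr(out, "block_boundary") <- ncol(lbp_mat)
  out
}
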