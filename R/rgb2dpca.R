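# Tri-channel (RGB) 2DPCA: per-channel column-scatter covariance,
# eigendecomposition into projection axes, projection, and component-wise
# reconstruction with Frobenius distortion.
#
# 2DPCA works on the image matrices directly: for each channel c the W x W
# scatter S_c = (1/N) sum_i (O_i^c - Obar^c)' (O_i^c - Obar^c) is
# eigendecomposed, its eigenvectors W_j are the projection axes, and the
# coefficient columns Y_j^c = O^c W_j^c are the projected feature vectors.
# By default the RAW image is projected and the mean is not re-added at
# reconstruction; `mean` arguments switch on the conventional centered
# variant.

CHANNELS <- c("R", "G", "B")

#' Elementwise mean image of a stack
#'
#' @param stack an [image_stack()].
#' @return `H x W x 3` numeric array, the arithmetic mean of the stack.
#' @examples
#' stk <- image_stack(list(array(0, c(2, 2, 3)), array(2, c(2, 2, 3))))
#' mean_image(stk)[1, 1, ]
#' @export
mean_image <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  Reduce(`+`, stack) / length(stack)
}

#' Per-channel column-scatter covariance matrices
#'
#' For each channel `c`, computes
#' `S_c = (1/N) * sum_i t(O_i^c - M^c) %*% (O_i^c - M^c)`,
#' a `W x W` symmetric positive semi-definite matrix (`1/N` normalisation,
#' not `1/(N-1)`).
#'
#' @param stack an [image_stack()].
#' @param mean mean image; defaults to [mean_image()] of the stack.
#' @return object of class `covariance_set`: a named list (`R`, `G`, `B`)
#'   of `W x W` matrices.
#' @export
channel_covariance <- function(stack, mean = mean_image(stack)) {
  stopifnot(inherits(stack, "image_stack"))
  if (!identical(dim(mean), dim(stack[[1]]))) {
    stop("mean image shape does not match stack", call. = FALSE)
  }
  n <- length(stack)
  w <- attr(stack, "width")
  out <- lapply(1:3, function(ch) {
    s <- matrix(0, w, w)
    for (img in stack) {
      d <- img[, , ch] - mean[, , ch]
      s <- s + crossprod(d)          # t(d) %*% d
    }
    s <- s / n
    (s + t(s)) / 2                    # enforce exact symmetry
  })
  names(out) <- CHANNELS
  structure(out, class = "covariance_set")
}

#' Eigendecompose a covariance set into projection axes
#'
#' Returns, per channel, the full orthonormal eigenvector basis with
#' eigenvalues sorted in non-increasing order. Each eigenvector's sign is
#' fixed so its first nonzero entry is non-negative, making bases
#' reproducible across platforms.
#'
#' @param cov a `covariance_set` from [channel_covariance()].
#' @param tol symmetry tolerance; inputs asymmetric beyond it are rejected.
#' @return object of class `projection_basis`: per channel a list with
#'   `vectors` (`W x W`, columns are axes) and `values` (length `W`).
#' @export
eigendecompose <- function(cov, tol = 1e-9) {
  stopifnot(inherits(cov, "covariance_set"))
  out <- lapply(cov, function(s) {
    asym <- max(abs(s - t(s)))
    if (asym > tol * max(1, max(abs(s)))) {
      stop("covariance matrix is not symmetric (max asymmetry ",
           fmt_num(asym), ")", call. = FALSE)
    }
    e <- eigen((s + t(s)) / 2, symmetric = TRUE)
    v <- e$vectors
    for (j in seq_len(ncol(v))) {
      nz <- which(abs(v[, j]) > 1e-12)
      if (length(nz) > 0 && v[nz[1], j] < 0) v[, j] <- -v[, j]
    }
    list(vectors = v, values = e$values)
  })
  names(out) <- CHANNELS
  structure(out, class = "projection_basis", d = ncol(out$R$vectors))
}

#' Build the projection basis of a stack in one call
#'
#' Convenience wrapper: mean, covariance, eigendecomposition.
#'
#' @param stack an [image_stack()].
#' @param centered if `TRUE`, the returned basis carries the stack mean in
#'   attribute `mean`, and downstream projection/reconstruction centre on it.
#' @return a `projection_basis`.
#' @export
projection_basis <- function(stack, centered = FALSE) {
  m <- mean_image(stack)
  b <- eigendecompose(channel_covariance(stack, m))
  if (centered) attr(b, "mean") <- m
  b
}

basis_dim <- function(basis) attr(basis, "d")

basis_mean <- function(basis) attr(basis, "mean")  # NULL unless centered

#' Project an image onto the basis axes
#'
#' Per channel, `Y^c = O^c %*% W^c`; column `j` of `Y^c` is the projected
#' feature vector of axis `j`. The raw image is projected unless the basis
#' was built with `centered = TRUE`, in which case the stack mean is
#' subtracted first.
#'
#' @param image `H x W x 3` numeric array.
#' @param basis a `projection_basis`.
#' @return object of class `feature_projection`: named list of `H x W`
#'   coefficient matrices.
#' @export
project_image <- function(image, basis) {
  stopifnot(inherits(basis, "projection_basis"))
  validate_image(image)
  if (dim(image)[2] != basis_dim(basis)) {
    stop("image width ", dim(image)[2], " does not match basis dimension ",
         basis_dim(basis), call. = FALSE)
  }
  m <- basis_mean(basis)
  out <- lapply(1:3, function(ch) {
    o <- image[, , ch]
    if (!is.null(m)) o <- o - m[, , ch]
    o %*% basis[[ch]]$vectors
  })
  names(out) <- CHANNELS
  structure(out, class = "feature_projection")
}

#' Reconstruct an image from selected projected feature vectors
#'
#' Per channel, `Ohat^c = sum_{j: mask[j, c] = 1} Y_j^c %*% t(W_j^c)`.
#' With the full basis and an all-ones mask this recovers the image exactly
#' (completeness of the orthonormal expansion). Values are NOT clipped here;
#' clipping happens only in the PNG writer.
#'
#' @param projection a `feature_projection` from [project_image()].
#' @param basis the matching `projection_basis`.
#' @param mask `d x 3` binary matrix (component x channel); entry
#'   `(j, c) = 1` keeps component `j` of channel `c`.
#' @return `H x W x 3` numeric array (unclipped; a centered basis re-adds
#'   its mean).
#' @export
reconstruct_image <- function(projection, basis, mask) {
  stopifnot(inherits(projection, "feature_projection"),
            inherits(basis, "projection_basis"))
  d <- basis_dim(basis)
  mask <- check_mask(mask, d)
  h <- nrow(projection$R)
  out <- array(0, c(h, d, 3L))
  m <- basis_mean(basis)
  for (ch in 1:3) {
    sel <- which(mask[, ch] == 1)
    plane <- if (length(sel) > 0) {
      projection[[ch]][, sel, drop = FALSE] %*%
        t(basis[[ch]]$vectors[, sel, drop = FALSE])
    } else {
      matrix(0, h, d)
    }
    if (!is.null(m)) plane <- plane + m[, , ch]
    out[, , ch] <- plane
  }
  out
}

check_mask <- function(mask, d) {
  if (is.vector(mask)) mask <- matrix(mask, ncol = 3)
  if (!is.matrix(mask) || ncol(mask) != 3L || nrow(mask) != d) {
    stop("mask must be a ", d, " x 3 binary matrix", call. = FALSE)
  }
  if (!all(mask %in% c(0, 1))) {
    stop("mask entries must be 0 or 1", call. = FALSE)
  }
  mask
}

#' Per-channel and summed Frobenius distortion between two images
#'
#' The Frobenius norm (root sum of squared entries) of `x - xhat`, computed
#' per channel; `total` is the sum of the three channel norms. This is the
#' reconstruction-error term of the selection fitness.
#'
#' @param x,xhat `H x W x 3` numeric arrays of equal shape.
#' @return list with `per_channel` (named length-3 vector) and `total`.
#' @examples
#' a <- array(0, c(2, 2, 3)); b <- a
#' b[, , 1] <- matrix(c(3, 0, 4, 0), 2)   # 3-4-5 triangle in channel R
#' frobenius_error(a, b)$per_channel
#' @export
frobenius_error <- function(x, xhat) {
  if (!identical(dim(x), dim(xhat))) {
    stop("shape mismatch between image and reconstruction", call. = FALSE)
  }
  per <- vapply(1:3, function(ch) sqrt(sum((x[, , ch] - xhat[, , ch])^2)),
                numeric(1))
  names(per) <- CHANNELS
  list(per_channel = per, total = sum(per))
}
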