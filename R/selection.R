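# Post-BPSO assembly of the final component set:
#   B1 = components the swarm selected in all three channels (consensus),
#   B2 = top-m components by pooled l2 energy of their coefficient columns,
#   B  = B1 union B2, applied to all three channels at reconstruction.
# Component indices are 1-based and live in the eigen-order index space.

#' Construct a set of component indices
#'
#' @param indices integer vector of component indices in `1..d`.
#' @param d number of components in the index space.
#' @param label one of `"B1"`, `"B2"`, `"B"` (or any short tag).
#' @return object of class `index_set`: list with sorted unique `indices`,
#'   `d`, `label`.
#' @export
index_set <- function(indices, d, label = "B") {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) > 0 && (min(indices) < 1L || max(indices) > d)) {
    stop("component index out of range 1..", d, call. = FALSE)
  }
  structure(list(indices = indices, d = as.integer(d), label = label),
            class = "index_set")
}

#' @export
print.index_set <- function(x, ...) {
  cat(sprintf("index_set %s: %d of %d components\n",
              x$label, length(x$indices), x$d))
  invisible(x)
}

#' Cross-channel consensus components of a swarm-selected mask
#'
#' The components the optimiser kept in all three channels — the
#' parameter-free reading of "highest similarity across channels".
#'
#' @param gbest `d x 3` binary mask (e.g. `bpso_result$gbest`).
#' @return an [index_set()] labelled `B1`.
#' @export
consensus_indices <- function(gbest) {
  d <- nrow(gbest)
  gbest <- check_mask(gbest, d)
  index_set(which(rowSums(gbest) == 3L), d, "B1")
}

#' Top-m components by pooled l2 energy
#'
#' For each component `j`, the energy is the l2 norm of its coefficient
#' column `||Y_j^c||_2`, averaged over the three channels and over all
#' images supplied — so the ranking is modality-level, not per-image.
#' Ties break toward the lower index; `m >= d` returns every component.
#'
#' @param projections a single `feature_projection` or a list of them
#'   (one per stack image).
#' @param m number of components to keep (>= 0).
#' @return an [index_set()] labelled `B2`, with the energies in attribute
#'   `energy`.
#' @export
l2_rank <- function(projections, m) {
  if (m < 0) stop("m must be non-negative", call. = FALSE)
  if (inherits(projections, "feature_projection")) {
    projections <- list(projections)
  }
  ener <- lapply(projections, function(pr) {
    d <- ncol(pr$R)
    en <- vapply(pr, function(y) sqrt(colSums(y^2)), numeric(d))
    rowMeans(matrix(en, nrow = d))
  })
  e <- Reduce(`+`, ener) / length(ener)
  d <- length(e)
  keep <- if (m >= d) seq_len(d) else
    order(-e, seq_len(d))[seq_len(m)]
  out <- index_set(keep, d, "B2")
  attr(out, "energy") <- e
  out
}

#' Union of two component sets
#'
#' @param b1,b2 [index_set()] objects over the same index space.
#' @return an [index_set()] labelled `B`.
#' @export
union_selection <- function(b1, b2) {
  stopifnot(inherits(b1, "index_set"), inherits(b2, "index_set"))
  if (b1$d != b2$d) stop("index sets have different dimensions", call. = FALSE)
  index_set(union(b1$indices, b2$indices), b1$d, "B")
}

#' Tri-channel mask induced by an index set
#'
#' @param b an [index_set()].
#' @return `d x 3` binary matrix selecting `b` in every channel.
#' @export
mask_from_indices <- function(b) {
  stopifnot(inherits(b, "index_set"))
  m <- matrix(0, b$d, 3L)
  m[b$indices, ] <- 1
  m
}

#' Reconstruct an image from a component index set
#'
#' Applies the set to all three channels and reconstructs; identical to
#' [reconstruct_image()] with the induced mask.
#'
#' @param image `H x W x 3` numeric array.
#' @param basis a `projection_basis`.
#' @param b an [index_set()] with `b$d` equal to the basis dimension.
#' @return `H x W x 3` numeric array.
#' @export
reconstruct_selected <- function(image, basis, b) {
  stopifnot(inherits(b, "index_set"))
  if (b$d != basis_dim(basis)) {
    stop("index set dimension ", b$d, " does not match basis dimension ",
         basis_dim(basis), call. = FALSE)
  }
  reconstruct_image(project_image(image, basis), basis, mask_from_indices(b))
}

#' Top-k eigenvalue baseline selection
#'
#' The conventional 2DPCA rule: keep the k components with the largest
#' eigenvalues. Eigenvalues are stored in non-increasing order, so this is
#' simply the first k indices (k = 160 is the customary baseline on
#' 640-wide images).
#'
#' @param basis a `projection_basis`.
#' @param k number of leading components, `1 <= k <= d`.
#' @return an [index_set()] labelled `topk`.
#' @export
baseline_topk <- function(basis, k) {
  d <- basis_dim(basis)
  if (k < 1 || k > d) stop("k must be in 1..", d, call. = FALSE)
  index_set(seq_len(k), d, "topk")
}

#' Run the full selection stage on a stack
#'
#' Improved-BPSO consensus (B1) plus top-m energy components (B2), unioned.
#'
#' @param stack an [image_stack()].
#' @param basis the stack's `projection_basis`.
#' @param config a [bpso_config()].
#' @param m size of the energy-ranked set B2 (default 100, truncated to d).
#' @return list with `b1`, `b2`, `b` ([index_set()]s) and `bpso`
#'   (the `bpso_result`).
#' @export
select_components <- function(stack, basis, config = bpso_config(), m = 100L) {
  res <- run_bpso(stack, basis, config)
  b1 <- consensus_indices(res$gbest)
  projections <- lapply(stack, project_image, basis = basis)
  b2 <- l2_rank(projections, min(m, basis_dim(basis)))
  list(b1 = b1, b2 = b2, b = union_selection(b1, b2), bpso = res)
}
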