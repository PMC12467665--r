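# Feature-level fusion of the two ultrasound modalities.
#
# The mixing parameter x in [0,1] is the contrast-enhanced (CEUS)
# proportion: F = x * ceus + (1 - x) * conv, pixelwise per channel.
# Because reconstruction is linear in the projected feature vectors,
# blending the two reconstructions is the same as blending the features
# under a shared basis; the blend is applied at the reconstruction level.

#' Fusion specification
#'
#' @param x CEUS proportion in `[0, 1]`; the conventional-sonography weight
#'   is `1 - x`.
#' @param mode `"flfsi"` (BPSO-selected tri-channel reconstruction),
#'   `"rgb_topk"` (per-channel top-k eigenvalue reconstruction) or
#'   `"gray_topk"` (luma grayscale, top-k, replicated to 3 channels).
#' @param top_k leading-component count for the baseline modes
#'   (conventionally 160 on 640-wide images).
#' @param m size of the energy-ranked set B2 in `flfsi` mode.
#' @return list of class `fusion_spec`.
#' @export
fusion_spec <- function(x = 0.2, mode = c("flfsi", "rgb_topk", "gray_topk"),
                        top_k = 160L, m = 100L) {
  mode <- match.arg(mode)
  if (x < 0 || x > 1) stop("fusion ratio x must be in [0, 1]", call. = FALSE)
  structure(list(x = x, mode = mode, top_k = as.integer(top_k),
                 m = as.integer(m)),
            class = "fusion_spec")
}

#' Fuse two reconstructions at CEUS proportion x
#'
#' `F = x * ceus + (1 - x) * conv`, elementwise. Exact at the endpoints and
#' linear in `x`; the output lies pixelwise between the two inputs.
#'
#' @param conv,ceus `H x W x 3` numeric arrays of equal shape.
#' @param x CEUS proportion in `[0, 1]`.
#' @return `H x W x 3` numeric array.
#' @examples
#' a <- array(0, c(2, 2, 3)); b <- array(1, c(2, 2, 3))
#' fuse_images(a, b, 0.2)[1, 1, 1]  # 0.2
#' @export
fuse_images <- function(conv, ceus, x) {
  if (!identical(dim(conv), dim(ceus))) {
    stop("modality images have different shapes", call. = FALSE)
  }
  if (x < 0 || x > 1) stop("fusion ratio x must be in [0, 1]", call. = FALSE)
  x * ceus + (1 - x) * conv
}

reconstruct_stack <- function(stack, basis, b) {
  image_stack(lapply(stack, reconstruct_selected, basis = basis, b = b),
              check = FALSE)
}

#' Build a fused dataset from paired modality stacks
#'
#' Per modality: build the per-channel basis, pick components according to
#' the mode (BPSO consensus + energy union for `flfsi`; leading
#' eigen-components for the baselines), reconstruct every image, then fuse
#' each conventional/CEUS pair at proportion `x`. Selection runs once per
#' modality on the whole stack and is applied to all its images.
#'
#' @param conv_stack,ceus_stack paired [image_stack()]s of equal length and
#'   shape (index i of one pairs with index i of the other).
#' @param spec a [fusion_spec()].
#' @param config a [bpso_config()] (used in `flfsi` mode; the CEUS run uses
#'   `seed + 1` so the two modalities draw independent streams).
#' @return an [image_stack()] of fused images, with attribute `selection`
#'   (per-modality index sets) and `spec`.
#' @export
build_fused_dataset <- function(conv_stack, ceus_stack, spec = fusion_spec(),
                                config = bpso_config()) {
  stopifnot(inherits(spec, "fusion_spec"))
  if (length(conv_stack) != length(ceus_stack) ||
      !identical(dim(conv_stack[[1]]), dim(ceus_stack[[1]]))) {
    stop("modality stacks are not paired 1:1 with equal shapes", call. = FALSE)
  }
  if (spec$mode == "gray_topk") {
    conv_stack <- image_stack(lapply(conv_stack, as_gray, replicate = TRUE))
    ceus_stack <- image_stack(lapply(ceus_stack, as_gray, replicate = TRUE))
  }
  pick <- function(stack, cfg) {
    basis <- projection_basis(stack)
    b <- if (spec$mode == "flfsi") {
      select_components(stack, basis, cfg, m = spec$m)$b
    } else {
      baseline_topk(basis, min(spec$top_k, basis_dim(basis)))
    }
    list(basis = basis, b = b)
  }
  cfg2 <- config
  cfg2$seed <- config$seed + 1L
  conv_sel <- pick(conv_stack, config)
  ceus_sel <- pick(ceus_stack, cfg2)
  conv_rec <- reconstruct_stack(conv_stack, conv_sel$basis, conv_sel$b)
  ceus_rec <- reconstruct_stack(ceus_stack, ceus_sel$basis, ceus_sel$b)
  fused <- image_stack(lapply(seq_along(conv_rec), function(i) {
    fuse_images(conv_rec[[i]], ceus_rec[[i]], spec$x)
  }), check = FALSE)
  attr(fused, "selection") <- list(conv = conv_sel$b, ceus = ceus_sel$b)
  attr(fused, "spec") <- spec
  fused
}
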