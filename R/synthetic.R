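# Seeded generator of paired conventional/CEUS-like ultrasound images with
# ground-truth elliptical region masks.
#
# Each pair shares one elliptical region of interest. The conventional
# image is a gray speckled scene with a moderately brighter region; the
# CEUS image has a stronger region gain (perfusion) and a fixed per-channel
# tint emulating the amber overlay of contrast-mode displays. Speckle is
# multiplicative mean-1 gamma noise, the standard first-order surrogate for
# ultrasound speckle; its shape parameter sets severity (sd = 1/sqrt(shape)).
# Tinting is applied after clipping, so cross-channel ratios equal the tint
# exactly.

#' Parameters of the synthetic paired-ultrasound generator
#'
#' Defaults describe a 64 x 64, 16-pair dataset: background level 0.15,
#' region gains 0.35 (conventional) and 0.55 (CEUS), amber CEUS tint
#' (1, 0.82, 0.55), speckle shape 25 (20% multiplicative noise). The
#' ellipse is drawn uniformly from the stated ranges (fractions of the
#' frame; rotation in radians).
#'
#' @param height,width frame size in pixels (>= 8).
#' @param n_pairs number of image pairs.
#' @param roi list of ranges: `center` (fraction of frame, both axes),
#'   `a` (semi-axis, fraction of width), `b` (semi-axis, fraction of
#'   height), `rotation` (radians).
#' @param background_level base echo intensity in `[0, 1]`.
#' @param roi_gain_conv,roi_gain_ceus added intensity inside the region
#'   for each modality (> 0).
#' @param ceus_tint length-3 per-channel gains in `(0, 1]` applied to the
#'   CEUS image after clipping.
#' @param speckle_shape gamma shape of the multiplicative speckle (> 0);
#'   larger means milder noise.
#' @param shared_speckle if `TRUE` the two modalities share one speckle
#'   field (useful for degenerate-equality checks).
#' @param seed integer; the dataset is a pure function of the parameters.
#' @return list of class `synthetic_params`.
#' @export
synthetic_params <- function(height = 64L, width = 64L, n_pairs = 16L,
                             roi = list(center = c(0.40, 0.60),
                                        a = c(0.15, 0.30),
                                        b = c(0.10, 0.20),
                                        rotation = c(0, pi)),
                             background_level = 0.15,
                             roi_gain_conv = 0.35,
                             roi_gain_ceus = 0.55,
                             ceus_tint = c(1.0, 0.82, 0.55),
                             speckle_shape = 25,
                             shared_speckle = FALSE,
                             seed = 1L) {
  stopifnot(height >= 8, width >= 8, n_pairs >= 1,
            background_level >= 0, roi_gain_conv > 0, roi_gain_ceus > 0,
            length(ceus_tint) == 3L, all(ceus_tint > 0),
            speckle_shape > 0)
  # the widest admissible ellipse must fit the frame on both axes
  ext <- max(roi$a[2] * width, roi$b[2] * height)
  if (min(roi$center) * min(height, width) - ext < 0 ||
      max(roi$center) * width + ext > width ||
      max(roi$center) * height + ext > height) {
    stop("ellipse ranges exceed the image frame", call. = FALSE)
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_pairs = as.integer(n_pairs), roi = roi,
                 background_level = background_level,
                 roi_gain_conv = roi_gain_conv, roi_gain_ceus = roi_gain_ceus,
                 ceus_tint = ceus_tint, speckle_shape = speckle_shape,
                 shared_speckle = isTRUE(shared_speckle),
                 seed = as.integer(seed)),
            class = "synthetic_params")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

ellipse_mask <- function(h, w, cx, cy, a, b, theta) {
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  u <- (x * cos(theta) + y * sin(theta)) / a
  v <- (-x * sin(theta) + y * cos(theta)) / b
  (u^2 + v^2 <= 1) * 1
}

pair_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 10007 + as.numeric(index) * 7919) %% 2147483647)
}

#' Generate one synthetic conventional/CEUS pair
#'
#' Deterministic in `(params$seed, index)`. Draw order: ellipse centre x,
#' centre y, semi-axes a and b, rotation; then the conventional speckle
#' field; then the CEUS speckle field (skipped under `shared_speckle`).
#'
#' @param params a [synthetic_params()].
#' @param index pair index (1-based); distinct indices give independent
#'   draws under one seed.
#' @return list with `conv` and `ceus` (`H x W x 3` arrays in `[0, 1]`),
#'   `mask` (binary `H x W` matrix) and `geometry` (the sampled ellipse).
#' @export
generate_pair <- function(params, index = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  h <- params$height
  w <- params$width
  with_seed(pair_seed(params$seed, index), {
    cx <- runif1(params$roi$center) * w
    cy <- runif1(params$roi$center) * h
    a <- runif1(params$roi$a) * w
    b <- runif1(params$roi$b) * h
    theta <- runif1(params$roi$rotation)
    mask <- ellipse_mask(h, w, cx, cy, a, b, theta)
    shp <- params$speckle_shape
    speckle_conv <- matrix(stats::rgamma(h * w, shape = shp, rate = shp), h, w)
    speckle_ceus <- if (params$shared_speckle) speckle_conv else
      matrix(stats::rgamma(h * w, shape = shp, rate = shp), h, w)
    conv_plane <- clamp01((params$background_level +
                             params$roi_gain_conv * mask) * speckle_conv)
    ceus_plane <- clamp01((params$background_level +
                             params$roi_gain_ceus * mask) * speckle_ceus)
    conv <- array(rep(conv_plane, 3L), c(h, w, 3L))
    ceus <- array(0, c(h, w, 3L))
    for (ch in 1:3) ceus[, , ch] <- ceus_plane * params$ceus_tint[ch]
    list(conv = conv, ceus = ceus, mask = mask,
         geometry = list(cx = cx, cy = cy, a = a, b = b, rotation = theta))
  })
}

#' Generate a paired synthetic dataset
#'
#' @param params a [synthetic_params()].
#' @return list with `conv` and `ceus` ([image_stack()]s of `n_pairs`
#'   images in identical order), `masks` (list of binary matrices) and
#'   `manifest` (data frame of all sampled ellipse geometry plus the seed).
#' @examples
#' ds <- generate_dataset(synthetic_params(n_pairs = 2, height = 16, width = 16))
#' ds$conv
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  pairs <- lapply(seq_len(params$n_pairs), generate_pair, params = params)
  manifest <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    g <- pairs[[i]]$geometry
    data.frame(index = i, seed = pair_seed(params$seed, i),
               cx = g$cx, cy = g$cy, a = g$a, b = g$b, rotation = g$rotation)
  }))
  list(conv = image_stack(lapply(pairs, `[[`, "conv")),
       ceus = image_stack(lapply(pairs, `[[`, "ceus")),
       masks = lapply(pairs, `[[`, "mask"),
       manifest = manifest)
}
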