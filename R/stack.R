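# Image tensors (H x W x 3 arrays in [0,1]) and ordered image stacks.

validate_image <- function(pixels, what = "image") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L) {
    stop(what, " must be at least 2 x 2 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop(what, " contains non-finite intensities", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop(what, " contains negative intensities", call. = FALSE)
  }
  invisible(pixels)
}

#' Create an ordered stack of same-size colour images
#'
#' An image stack is the unit the decomposition operates on: an ordered list
#' of `N` images, each an `H x W x 3` numeric array of non-negative
#' intensities (normally in `[0, 1]`). All images must share one shape.
#'
#' @param images list of `H x W x 3` numeric arrays.
#' @param check validate intensity invariants (finite, non-negative)?
#'   Derived stacks of unclipped reconstructions set this to `FALSE`
#'   internally; shape consistency is always enforced.
#' @return an object of class `image_stack`: the list of images with
#'   attributes `n`, `height`, `width`.
#' @examples
#' imgs <- replicate(3, array(runif(4 * 5 * 3), c(4, 5, 3)), simplify = FALSE)
#' stk <- image_stack(imgs)
#' stk
#' @export
image_stack <- function(images, check = TRUE) {
  if (!is.list(images) || length(images) == 0L) {
    stop("empty stack", call. = FALSE)
  }
  ref <- dim(images[[1]])
  if (is.null(ref) || length(ref) != 3L) {
    stop("image 1 must be an H x W x 3 array", call. = FALSE)
  }
  for (i in seq_along(images)) {
    if (check) validate_image(images[[i]], paste("image", i))
    if (is.null(dim(images[[i]])) || length(dim(images[[i]])) != 3L) {
      stop("image ", i, " must be an H x W x 3 array", call. = FALSE)
    }
    if (!identical(dim(images[[i]]), ref)) {
      stop("image ", i, " has shape ", paste(dim(images[[i]])[1:2], collapse = "x"),
           ", expected ", paste(ref[1:2], collapse = "x"), call. = FALSE)
    }
  }
  structure(images, class = "image_stack",
            n = length(images), height = ref[1], width = ref[2])
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d images of %d x %d x 3\n",
              attr(x, "n"), attr(x, "height"), attr(x, "width")))
  invisible(x)
}

#' Read a single colour image as an H x W x 3 array in [0, 1]
#'
#' PNG, TIFF and JPEG are supported; 8- and 16-bit integer data are rescaled
#' to `[0, 1]` by the readers. Grayscale images are replicated across the
#' three channels (with a warning); an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(px)) == 2L) {
    warning("grayscale image replicated across 3 channels: ", path, call. = FALSE)
    px <- array(rep(px, 3L), c(dim(px), 3L))
  } else if (dim(px)[3] == 1L) {
    warning("grayscale image replicated across 3 channels: ", path, call. = FALSE)
    px <- array(rep(px[, , 1], 3L), c(dim(px)[1:2], 3L))
  } else if (dim(px)[3] >= 4L) {
    px <- px[, , 1:3, drop = FALSE]
  }
  validate_image(px, path)
  px
}

#' Read a directory of images as a stack
#'
#' Files are taken in sorted lexicographic order, which defines the stack
#' order (and hence the pairing between two modality directories).
#'
#' @param dir directory containing PNG/TIFF/JPEG files.
#' @param pattern filename regexp, default all supported extensions.
#' @return an [image_stack()] with attribute `paths`.
#' @export
read_image_stack <- function(dir, pattern = "\\.(png|tiff?|jpe?g)$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) {
    stop("no images found in ", dir, call. = FALSE)
  }
  stk <- image_stack(lapply(files, read_image))
  attr(stk, "paths") <- files
  stk
}

#' Write an image as 8-bit PNG (clipped) or 32-bit float TIFF (unclipped)
#'
#' Clipping to `[0, 1]` happens only here, at export: reconstruction keeps
#' unbounded values so that numerical identities hold exactly.
#'
#' @param image `H x W x 3` numeric array.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(clamp01(image), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Convert a colour image to luma grayscale
#'
#' Uses the Rec. 601 weights (0.299, 0.587, 0.114). Returns either the
#' single-channel matrix or, with `replicate = TRUE`, the gray values
#' replicated across three channels (the form the tri-channel pipeline
#' consumes).
#'
#' @param image `H x W x 3` numeric array.
#' @param replicate replicate the gray plane to 3 channels?
#' @return `H x W` matrix, or `H x W x 3` array if `replicate`.
#' @export
as_gray <- function(image, replicate = FALSE) {
  validate_image(image)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  if (replicate) array(rep(g, 3L), c(dim(g), 3L)) else g
}
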