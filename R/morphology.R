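#' Create a structuring element
#'
#' Structuring elements are odd-sized binary matrices with a foreground
#' centre. The disc shape keeps every pixel whose Euclidean distance from
#' the centre is at most `size / 2`; the box shape is all ones.
#'
#' @param shape_tag `"disc"` or `"box"`.
#' @param size Odd positive side length in pixels.
#' @return An object of class `structuring_element` with fields `pattern`
#'   (binary matrix), `shape_tag` and `size`.
#' @export
make_structuring_element <- function(shape_tag = c("disc", "box"), size = 5) {
  shape_tag <- match.arg(shape_tag)
  if (length(size) != 1 || is.na(size) || size < 1 || size %% 2 == 0)
    stop("size must be odd and >= 1")
  size <- as.integer(size)
  r <- (size - 1L) / 2L
  if (shape_tag == "box") {
    pat <- matrix(1L, size, size)
  } else {
    off <- -r:r
    d2 <- outer(off^2, off^2, `+`)
    pat <- matrix(as.integer(d2 <= (size / 2)^2), size, size)
  }
  structure(list(pattern = pat, shape_tag = shape_tag, size = size),
            class = "structuring_element")
}

#' @export
print.structuring_element <- function(x, ...) {
  cat(sprintf("structuring_element: %s %dx%d (%d active pixels)\n",
              x$shape_tag, x$size, x$size, sum(x$pattern)))
  invisible(x)
}

se_pattern <- function(se) {
  if (inherits(se, "structuring_element")) return(se$pattern)
  if (is.matrix(se)) return(se)
  stop("se must be a structuring_element or binary matrix")
}

#' Global Otsu threshold of a grayscale stack
#'
#' Computes one threshold for the whole stack by maximizing between-class
#' variance over the pooled intensity histogram (256 bins for 8-bit-range
#' data, 1024 otherwise), then maps voxels above the threshold to 1 (bone).
#' A single global threshold keeps the bone/background split consistent
#' across slices.
#'
#' @param stack A grayscale [image_stack()] with at least two distinct
#'   intensities.
#' @return A binary [image_stack()]; the chosen threshold is attached as
#'   attribute `"threshold"`.
#' @export
otsu_threshold <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  v <- as.vector(stack$voxels)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("constant-intensity stack: cannot threshold")
  eightbit <- rng[1] >= 0 && rng[2] <= 255 && all(v == round(v))
  if (eightbit) {
    breaks <- seq(-0.5, 255.5, by = 1)
    mids <- 0:255
  } else {
    nb <- 1024L
    breaks <- seq(rng[1], rng[2], length.out = nb + 1)
    mids <- (breaks[-1] + breaks[-(nb + 1)]) / 2
  }
  h <- hist(v, breaks = breaks, plot = FALSE)$counts
  thr <- otsu_from_histogram(h, mids)
  bin <- array(as.integer(stack$voxels > thr), dim = dim(stack$voxels))
  out <- image_stack(bin, stack$spacing, stack$origin, is_binary = TRUE)
  attr(out, "threshold") <- thr
  out
}

# arg-max of between-class variance over all candidate cut points; the
# threshold returned is the bin centre of the last bin in the lower class
otsu_from_histogram <- function(counts, mids) {
  n <- sum(counts)
  p <- counts / n
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb2 <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

pad_matrix <- function(m, r, value) {
  out <- matrix(value, nrow(m) + 2 * r, ncol(m) + 2 * r)
  out[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m))] <- m
  out
}

morph_once <- function(m, pat, op, pad_value) {
  r <- (nrow(pat) - 1L) / 2L
  if (r == 0) return(m)
  mp <- pad_matrix(m, r, pad_value)
  res <- if (op == "dilate") EBImage::dilate(mp, pat) else EBImage::erode(mp, pat)
  res <- as.matrix(res)
  out <- res[(r + 1):(r + nrow(m)), (r + 1):(r + ncol(m)), drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

morph_iter <- function(m, se, n, op) {
  pat <- se_pattern(se)
  if (any(dim(pat) %% 2 == 0)) stop("structuring element dims must be odd")
  if (n < 0) stop("iteration count must be >= 0")
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  # out-of-image pixels are background for dilation and foreground for
  # erosion, so closing a shape that touches the image border does not eat
  # it from outside
  pad_value <- if (op == "dilate") 0L else 1L
  for (i in seq_len(n)) m <- morph_once(m, pat, op, pad_value)
  m
}

#' Iterated binary dilation of a 2D slice
#'
#' @param image 2D binary matrix (or 3D binary array, processed slice-wise
#'   along the third axis).
#' @param se A [make_structuring_element()] or odd-sized binary matrix.
#' @param n Number of iterations; `n = 0` is the identity.
#' @return Binary matrix/array of the same dimensions.
#' @export
dilate <- function(image, se, n = 1) {
  if (length(dim(image)) == 3) return(morph_stack(image, se, n, "dilate"))
  morph_iter(image, se, n, "dilate")
}

#' Iterated binary erosion of a 2D slice
#'
#' Dual of [dilate()]: with a symmetric structuring element,
#' `erode(x) == 1 - dilate(1 - x)` exactly, including at image borders
#' (out-of-image pixels count as foreground for erosion).
#'
#' @inheritParams dilate
#' @return Binary matrix/array of the same dimensions.
#' @export
erode <- function(image, se, n = 1) {
  if (length(dim(image)) == 3) return(morph_stack(image, se, n, "erode"))
  morph_iter(image, se, n, "erode")
}

# slice-wise along Z, using EBImage's frame-wise C path; border padding is
# applied on all slices at once
morph_stack <- function(vol, se, n, op) {
  pat <- se_pattern(se)
  r <- (nrow(pat) - 1L) / 2L
  if (n == 0 || r == 0) {
    storage.mode(vol) <- "integer"
    return(vol)
  }
  pad_value <- if (op == "dilate") 0L else 1L
  d <- dim(vol)
  big <- array(pad_value, c(d[1] + 2 * r * n, d[2] + 2 * r * n, d[3]))
  ix <- (r * n + 1):(r * n + d[1]); iy <- (r * n + 1):(r * n + d[2])
  big[ix, iy, ] <- vol
  for (i in seq_len(n))
    big <- if (op == "dilate") EBImage::dilate(big, pat) else
      EBImage::erode(big, pat)
  out <- as.array(big)[ix, iy, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

# Morphological closing evaluated on an enlarged zero canvas: the
# dilation can never reach the canvas edge, so the subsequent erosion
# reconstructs contours exactly (true Minkowski closing) instead of
# interacting with the image border. Bone touching the volume border is
# still never eaten, since closing only ever adds voxels.
closing_stack <- function(vol, se, n) {
  pat <- se_pattern(se)
  r <- (nrow(pat) - 1L) / 2L
  m <- 2L * r * n
  d <- dim(vol)
  big <- array(0L, c(d[1] + 2 * m, d[2] + 2 * m, d[3]))
  ix <- (m + 1):(m + d[1]); iy <- (m + 1):(m + d[2])
  big[ix, iy, ] <- vol
  for (i in seq_len(n))
    big <- EBImage::dilate(big, pat)
  for (i in seq_len(n))
    big <- EBImage::erode(big, pat)
  out <- as.array(big)[ix, iy, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

binary_like <- function(stack, vox) {
  storage.mode(vox) <- "integer"
  image_stack(vox, stack$spacing, stack$origin, is_binary = TRUE)
}

#' Isolate the cancellous compartment of a binarized bone stack
#'
#' Runs the five-step dilation/erosion protocol slice-wise along Z on a
#' binary micro-CT stack:
#' \enumerate{
#'   \item mask `c` = closing of the binary image `b` (`n_iter[1]`
#'     dilations then as many erosions) — fills the spaces inside the bone;
#'   \item voids `d = c - b` — everything enclosed that is not bone;
#'   \item interior `e` = closing of the voids (`n_iter[2]` iterations) —
#'     the cavity hosting cancellous bone and voids;
#'   \item cortical `f = c - e` — the compact shell;
#'   \item cancellous `g = c - d - f` — bone inside the cavity.
#' }
#' All subtractions are set differences (clamped at 0). By construction
#' voids, cortical and cancellous partition the mask exactly.
#'
#' @param binary A binary [image_stack()] with at least one foreground voxel.
#' @param se Structuring element; default disc 5x5.
#' @param n_iter Iteration counts for steps 1 and 3 (length 1 or 2);
#'   4 to 6 iterations with a 5x5 disc suit most micro-CT resolutions.
#' @return An object of class `bone_compartments`: a list of six binary
#'   [image_stack()]s named `binary`, `mask`, `voids`, `interior`,
#'   `cortical`, `cancellous`.
#' @export
split_bone <- function(binary, se = make_structuring_element("disc", 5),
                       n_iter = c(5, 5)) {
  stopifnot(inherits(binary, "image_stack"))
  if (!binary$is_binary) stop("split_bone needs a binary stack")
  if (sum(binary$voxels) == 0) stop("nothing to split: empty binary stack")
  n_iter <- as.integer(n_iter)
  if (length(n_iter) == 1) n_iter <- rep(n_iter, 2)
  if (any(n_iter < 1)) stop("iteration counts must be >= 1")
  b <- binary$voxels
  c_ <- closing_stack(b, se, n_iter[1])
  d <- pmax(c_ - b, 0L); dim(d) <- dim(b)
  e <- closing_stack(d, se, n_iter[2])
  e <- pmax(pmin(e, c_), 0L); dim(e) <- dim(b)  # interior cannot exceed mask
  f <- pmax(c_ - e, 0L); dim(f) <- dim(b)
  g <- pmax(c_ - d - f, 0L); dim(g) <- dim(b)
  structure(list(binary = binary,
                 mask = binary_like(binary, c_),
                 voids = binary_like(binary, d),
                 interior = binary_like(binary, e),
                 cortical = binary_like(binary, f),
                 cancellous = binary_like(binary, g)),
            class = "bone_compartments")
}

#' @export
print.bone_compartments <- function(x, ...) {
  cat("bone_compartments:\n")
  for (nm in c("binary", "mask", "voids", "interior", "cortical",
               "cancellous"))
    cat(sprintf("  %-10s %d voxels\n", nm, sum(x[[nm]]$voxels)))
  invisible(x)
}

#' Keep only the largest connected component
#'
#' Optional cleanup pass for residual cortical fragments left attached to
#' the cancellous compartment. Disabled in the default pipeline.
#'
#' @param stack Binary [image_stack()].
#' @param connectivity 6 (faces) or 26 (faces, edges, corners).
#' @return Binary [image_stack()] retaining the largest component (the
#'   input itself if it is empty).
#' @export
largest_component_filter <- function(stack, connectivity = c(26, 6)) {
  stopifnot(inherits(stack, "image_stack"), stack$is_binary)
  connectivity <- match.arg(as.character(connectivity[1]), c("26", "6"))
  v <- stack$voxels
  if (sum(v) == 0) return(stack)
  lab <- cpp_label_components(as.integer(v), dim(v), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  binary_like(stack, array(as.integer(lab == keep), dim(v)))
}
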