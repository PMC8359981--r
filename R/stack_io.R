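#' Create an image stack
#'
#' An `image_stack` wraps a 3D voxel array together with its physical
#' geometry. Dimensions are ordered (K, M, N) = image width, image height,
#' slice count; voxel indices are 0-based in all physical-coordinate
#' formulas, and the physical position of voxel (i, j, k) is
#' `origin + c(i, j, k) * spacing` (millimetres, voxel centres).
#'
#' @param voxels 3D numeric/integer array of intensities.
#' @param spacing Physical voxel size per axis in mm (length 3, all > 0).
#' @param origin Physical coordinate of voxel (0, 0, 0) in mm.
#' @param is_binary Logical; if `TRUE`, voxels must take values in {0, 1}.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing, origin = c(0, 0, 0),
                        is_binary = FALSE) {
  if (length(dim(voxels)) != 3)
    stop("voxels must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)")
  origin <- as.numeric(origin)
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  if (any(dim(voxels) < 1)) stop("all dimensions must be >= 1")
  if (is_binary) {
    u <- unique(as.vector(voxels))
    if (!all(u %in% c(0, 1)))
      stop("binary stack must contain only values 0 and 1")
    storage.mode(voxels) <- "integer"
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 is_binary = isTRUE(is_binary)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d voxels, spacing %s mm%s\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              if (x$is_binary) sprintf(", binary (%d foreground)",
                                       sum(x$voxels)) else ""))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read a 3D image stack from disk
#'
#' Reads a multi-page TIFF stack or a NIfTI-1 volume into an
#' [image_stack()]. NIfTI voxel spacing is taken from the header `pixdim`;
#' TIFF has no reliable 3D spacing metadata, so `spacing_override` is
#' required for TIFF input.
#'
#' @param path Path to a `.tif`/`.tiff` multi-page file or `.nii`/`.nii.gz`.
#' @param format `"tiff_stack"` or `"nifti"`; `"auto"` guesses from the
#'   file extension.
#' @param spacing_override Per-axis voxel size in mm, overriding (TIFF) or
#'   replacing (NIfTI) header spacing.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, format = c("auto", "tiff_stack", "nifti"),
                       spacing_override = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  }
  if (format == "tiff_stack") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dims <- unique(lapply(pages, dim))
    if (length(dims) != 1)
      stop("inconsistent page sizes in TIFF stack")
    if (is.null(spacing_override))
      stop("spacing unknown: TIFF stacks carry no 3D spacing; ",
           "supply spacing_override")
    # readTIFF returns row x col (height x width); transpose so the first
    # array index is image width K, matching the (K, M, N) convention
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]   # drop extra channels
      t(p)
    })
    vox <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    return(image_stack(vox, spacing = spacing_override))
  }
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) > 3) dim(vox) <- dim(vox)[1:3]
  sp <- RNifti::pixdim(img)[1:3]
  if (!is.null(spacing_override)) sp <- spacing_override
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    if (is.null(spacing_override))
      stop("spacing unknown: NIfTI header has no valid pixdim; ",
           "supply spacing_override")
  }
  image_stack(vox, spacing = sp)
}

#' Write a 3D image stack to disk
#'
#' Round-trips exactly through [read_stack()]: voxel values are preserved
#' bit-for-bit and spacing to float precision (NIfTI header) for NIfTI;
#' TIFF preserves voxels (16-bit integer encoding) but carries no spacing.
#'
#' @param stack An [image_stack()].
#' @param path Output path.
#' @param format `"tiff_stack"`, `"nifti"` or `"auto"` (from extension).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff_stack", "nifti")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "image_stack"))
  if (format == "auto") {
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "nifti"
  }
  if (format == "tiff_stack") {
    v <- round(stack$voxels)
    if (min(v) < 0 || max(v) > 65535)
      stop("TIFF output supports integer intensities in [0, 65535]")
    v <- v / 65535   # writeTIFF stores x*65535 at 16 bit, so this is exact
    pages <- lapply(seq_len(dim(v)[3]), function(k) t(v[, , k]))
    ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
              silent = TRUE)
    if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
    return(invisible(path))
  }
  v <- stack$voxels
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- stack$spacing
  ok <- try(suppressWarnings(
    RNifti::writeNifti(img, path,
                       datatype = if (stack$is_binary) "uint8" else
                         "auto")),
    silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path))
    stop("cannot write NIfTI: ", path)
  invisible(path)
}

#' Crop an image stack
#'
#' Half-open 0-based voxel box: voxel indices `lo <= i < hi` are kept. The
#' origin shifts by `lo * spacing` so physical coordinates of retained
#' voxels are unchanged.
#'
#' @param stack An [image_stack()].
#' @param lo,hi Integer triples, `0 <= lo < hi <= dim(stack)`.
#' @return Cropped [image_stack()].
#' @export
crop <- function(stack, lo, hi) {
  stopifnot(inherits(stack, "image_stack"))
  lo <- as.integer(lo); hi <- as.integer(hi)
  d <- dim(stack$voxels)
  if (length(lo) != 3 || length(hi) != 3) stop("lo and hi must be triples")
  if (any(lo < 0) || any(hi > d)) stop("crop box outside volume")
  if (any(lo >= hi)) stop("empty crop box (need lo < hi)")
  vox <- stack$voxels[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                      (lo[3] + 1):hi[3], drop = FALSE]
  image_stack(vox, spacing = stack$spacing,
              origin = stack$origin + lo * stack$spacing,
              is_binary = stack$is_binary)
}

#' Create a landmark set
#'
#' @param points n x 3 matrix of physical coordinates (mm).
#' @param labels Optional character vector of names.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points, labels = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3 || nrow(points) < 1)
    stop("points must be an n x 3 matrix with n >= 1")
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  if (!is.null(labels) && length(labels) != nrow(points))
    stop("labels length must match point count")
  structure(list(points = points, labels = labels), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points\n", nrow(x$points)))
  invisible(x)
}

#' Create a reference axis
#'
#' A directed axis between two physical points, used as the homologous
#' reference direction for the trabecular angle.
#'
#' @param start,end 3D points in mm; must differ.
#' @return An object of class `reference_axis`.
#' @export
reference_axis <- function(start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 3 || length(end) != 3)
    stop("start and end must be 3D points")
  if (any(!is.finite(c(start, end)))) stop("axis coordinates must be finite")
  if (sqrt(sum((end - start)^2)) == 0)
    stop("zero-length axis: start and end coincide")
  structure(list(start = start, end = end), class = "reference_axis")
}

axis_direction <- function(axis) {
  v <- axis$end - axis$start
  v / sqrt(sum(v^2))
}

#' Read an Amira LandmarkSet ASCII file
#'
#' Parses the `Markers`/`@1` sections of Amira's ASCII landmark export.
#' Coordinates are treated as physical mm unless `voxel_units = TRUE`, in
#' which case they are converted using `spacing` and `origin`.
#'
#' @param path Path to the `.landmarkAscii`/ASCII file.
#' @param voxel_units If `TRUE`, coordinates in the file are voxel indices.
#' @param spacing,origin Geometry used for voxel-to-mm conversion.
#' @return A [landmark_set()].
#' @export
read_amira_landmarks <- function(path, voxel_units = FALSE,
                                 spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ndef <- grep("define\\s+Markers\\s+\\d+", lines, value = TRUE)
  if (length(ndef) == 0) stop("malformed Amira landmark file: no Markers")
  n <- as.integer(sub(".*define\\s+Markers\\s+(\\d+).*", "\\1", ndef[1]))
  at <- grep("^\\s*@1\\s*$", lines)
  if (length(at) == 0) stop("malformed Amira landmark file: no @1 section")
  body <- lines[(at[1] + 1):length(lines)]
  body <- body[!grepl("^\\s*@", body)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  if (length(body) < n) stop("empty or truncated landmark data section")
  vals <- suppressWarnings(as.numeric(unlist(strsplit(
    paste(body[seq_len(n)], collapse = " "), "\\s+"))))
  if (any(is.na(vals))) stop("non-numeric landmark coordinates")
  if (length(vals) != 3 * n) stop("landmark coordinate count mismatch")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  if (voxel_units)
    pts <- sweep(sweep(pts, 2, spacing, `*`), 2, origin, `+`)
  landmark_set(pts)
}

#' Write an Amira LandmarkSet ASCII file
#'
#' @param lm A [landmark_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_amira_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  n <- nrow(lm$points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# AmiraMesh 3D ASCII 2.0", "",
               sprintf("define Markers %d", n), "",
               "Parameters {",
               "    NumSets 1,",
               "    ContentType \"LandmarkSet\"",
               "}", "",
               "Markers { float[3] Coordinates } @1", "", "@1"), con)
  writeLines(apply(lm$points, 1, function(p)
    paste(sprintf("%.10g", p), collapse = " ")), con)
  invisible(path)
}

#' Build a reference axis from two landmarks
#'
#' @param lm A [landmark_set()].
#' @param i,j 1-based indices of the start and end landmarks.
#' @return A [reference_axis()].
#' @export
axis_from_landmarks <- function(lm, i, j) {
  stopifnot(inherits(lm, "landmark_set"))
  n <- nrow(lm$points)
  if (i == j) stop("i and j must differ")
  if (i < 1 || j < 1 || i > n || j > n) stop("landmark index out of range")
  reference_axis(lm$points[i, ], lm$points[j, ])
}
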