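#' CT volume container
#'
#' Wraps a 3-D intensity array in Hounsfield-unit-like units together with its
#' voxel spacing. Arrays are indexed `[row, col, slice]` (1-based, the R
#' convention); every mask produced by the package shares this layout.
#'
#' @param voxels Numeric 3-D array `[row, col, slice]`, or a 2-D matrix which
#'   is treated as a single slice. Intensities must be finite.
#' @param spacing Numeric length-3 vector `(dy, dx, dz)` in mm: row, column
#'   and slice spacing.
#' @return An object of class `ct_volume` with elements `voxels`, `spacing`
#'   and `slice_shape`.
#' @examples
#' vol <- ct_volume(array(-1000, c(64, 64, 4)))
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3-D array [row, col, slice]")
  if (!all(is.finite(voxels))) stop("voxel intensities must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 positive numbers (dy, dx, dz) in mm")
  structure(
    list(voxels = voxels, spacing = spacing,
         slice_shape = dim(voxels)[1:2]),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("CT volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  intensity range [%.1f, %.1f]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

as_ct_volume <- function(x) {
  if (inherits(x, "ct_volume")) return(x)
  if (inherits(x, "labeled_volume")) return(x$volume)
  ct_volume(x)
}

#' Read a CT volume
#'
#' Reads a volume either from a NIfTI file or from a directory of per-slice
#' CSV matrices (headerless, one numeric matrix per file, slices ordered by
#' file name). NIfTI intensities are taken as already calibrated to HU;
#' spacing comes from the header, or `(1, 1, 1)` for CSV stacks.
#'
#' @param path File (`.nii` / `.nii.gz`) or directory path.
#' @param format `"auto"` (by path type/extension), `"nifti"` or `"slices"`.
#' @return A [ct_volume].
#' @seealso [write_volume()], [write_mask()]
#' @export
read_volume <- function(path, format = c("auto", "nifti", "slices")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "slices" else "nifti"
  if (format == "nifti") {
    if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    pd <- attr(img, "pixdim")
    spacing <- if (!is.null(pd) && length(pd) >= 3 && all(pd[1:3] > 0))
      as.numeric(pd[1:3]) else c(1, 1, 1)
    # pixdim order is (dx, dy, dz) over array dims; keep aligned with dims
    return(ct_volume(arr, spacing = spacing))
  }
  # slices: directory of per-slice CSV matrices
  if (!dir.exists(path)) stop("cannot read volume: no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0L) stop("no .csv slice files found in ", path)
  slices <- lapply(files, read_slice_csv)
  shapes <- vapply(slices, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("slices in ", path, " have non-uniform shapes: ",
         paste(unique(apply(shapes, 2, paste, collapse = "x")), collapse = ", "))
  arr <- array(unlist(slices, use.names = FALSE),
               c(shapes[1, 1], shapes[2, 1], length(slices)))
  ct_volume(arr)
}

read_slice_csv <- function(f) {
  first <- readLines(f, n = 1L)
  ncol <- length(strsplit(first, ",", fixed = TRUE)[[1]])
  vals <- scan(f, sep = ",", quiet = TRUE)
  matrix(vals, ncol = ncol, byrow = TRUE)
}

#' Write a CT volume or mask
#'
#' `write_volume()` writes intensities; `write_mask()` additionally validates
#' that the array is binary (0/1 or logical) and stores it as 8-bit. Formats:
#' NIfTI file, or a directory of per-slice CSV matrices. Round-trips through
#' [read_volume()] are value-preserving (integer HU arrays exactly).
#'
#' @param volume A [ct_volume] or 3-D array.
#' @param mask Binary 3-D array (logical, or numeric containing only 0/1),
#'   or a `seg_mask`.
#' @param path Output file (`.nii`/`.nii.gz`) or directory.
#' @param format `"auto"`, `"nifti"` or `"slices"`.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path, format = c("auto", "nifti", "slices")) {
  volume <- as_ct_volume(volume)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "slices"
  arr <- volume$voxels
  if (format == "nifti") {
    dtype <- if (all(arr == round(arr)) &&
                 min(arr) >= -32768 && max(arr) <= 32767) "int16" else "double"
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = dtype)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    ns <- dim(arr)[3]
    for (s in seq_len(ns)) {
      f <- file.path(path, sprintf("slice_%04d.csv", s))
      utils::write.table(arr[, , s], f, sep = ",", row.names = FALSE,
                         col.names = FALSE)
    }
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(mask, path, format = c("auto", "nifti", "slices")) {
  arr <- mask_array(mask)
  if (!all(arr %in% c(0, 1)))
    stop("mask contains non-binary values; expected only 0/1")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nii(\\.gz)?$", path)) "nifti" else "slices"
  if (format == "nifti") {
    img <- RNifti::asNifti(array(as.integer(arr), dim(arr)))
    RNifti::writeNifti(img, path, datatype = "uint8")
  } else {
    write_volume(ct_volume(array(as.numeric(arr), dim(arr))), path,
                 format = "slices")
  }
  invisible(path)
}

#' Read a mask written by [write_mask()]
#'
#' @param path File or directory path.
#' @return Logical 3-D array.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  arr <- v$voxels
  if (!all(arr %in% c(0, 1)))
    stop("file does not contain a binary mask: ", path)
  array(arr != 0, dim(arr))
}

# Accept seg_mask / logical / numeric-binary input uniformly.
mask_array <- function(mask) {
  if (inherits(mask, "seg_mask")) mask <- mask$mask
  if (inherits(mask, "ct_volume")) mask <- mask$voxels
  if (is.logical(mask)) mask <- array(as.numeric(mask), dim(mask))
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D array")
  mask
}

logical_mask <- function(mask) {
  arr <- mask_array(mask)
  array(arr != 0, dim(arr))
}
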