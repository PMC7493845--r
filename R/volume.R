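#' 3D intensity volume
#'
#' A minimal container for a 3D scalar intensity field plus voxel spacing.
#' The array is indexed `[z, y, x]` (axis 1 = z, axis 2 = y, axis 3 = x) and
#' all coordinates in the package are 1-based voxel indices in that order.
#' Spacing is physical voxel size in mm/voxel per axis, also in (z, y, x)
#' order. Strongly anisotropic volumes are accepted with a warning: the
#' filter scale parameter is interpreted in voxels, so such inputs should be
#' resampled beforehand.
#'
#' @param data 3D numeric array, each axis of length >= 3.
#' @param spacing positive numeric length-3, mm per voxel along (z, y, x).
#' @param origin numeric length-3 physical offset, default zeros.
#' @return An object of class `aneuscan_volume`: a list with elements
#'   `data`, `spacing`, `origin`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " axes")
  if (any(dim(data) < 3L))
    stop("each volume axis must have length >= 3")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers")
  if (max(spacing) / min(spacing) > 1.5)
    warning("strongly anisotropic spacing (", paste(signif(spacing, 3), collapse = " x "),
            "); the filter scale is in voxels, consider resampling")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "aneuscan_volume")
}

#' @export
print.aneuscan_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<aneuscan_volume> %d x %d x %d (z,y,x), spacing %s mm, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "aneuscan_volume")

.vol_ext <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii\\.gz$", p) || grepl("\\.nii$", p)) return("nifti")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  if (grepl("\\.tiff?$", p)) return("tiff")
  stop("unsupported volume format for '", path,
       "' (expected .nii/.nii.gz, .mha/.mhd or .tif/.tiff)")
}

#' Read a 3D volume
#'
#' Reads NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`, `.mhd`) or multi-page
#' TIFF stacks, chosen by file extension. Spacing is taken from the file
#' header; TIFF stacks carry no spacing, so they get `(1, 1, 1)` with a
#' warning. On-disk x-fastest storage (NIfTI/MetaImage) is permuted to the
#' package's (z, y, x) axis order.
#'
#' @param path path to an existing volume file.
#' @return An [as_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  kind <- .vol_ext(path)
  if (kind == "nifti") {
    img <- tryCatch(RNifti::readNifti(path),
                    error = function(e) stop("cannot read NIfTI file '", path, "': ",
                                             conditionMessage(e)))
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) { img <- array(img, d[1:3]); d <- d[1:3] }
    if (length(d) != 3L)
      stop("expected a 3D volume, '", path, "' has ", length(d), " axes")
    sp <- RNifti::pixdim(img)[1:3]
    arr <- aperm(as.array(img), c(3, 2, 1))
    return(as_volume(arr, spacing = rev(sp)))
  }
  if (kind %in% c("mha", "mhd")) return(read_meta_volume(path))
  # TIFF stack: one page per z slice, matrices are (y, x)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("cannot read TIFF file '", path, "': ",
                                             conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) != 2L)
    stop("expected grayscale TIFF slices, '", path, "' has multi-channel pages")
  nz <- length(pages)
  if (nz < 3L) stop("expected a 3D volume, TIFF stack '", path, "' has ", nz, " slices")
  arr <- array(0, c(nz, nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_len(nz)) arr[i, , ] <- pages[[i]]
  warning("TIFF stack carries no spacing metadata; assuming (1, 1, 1) voxels")
  as_volume(arr, spacing = c(1, 1, 1))
}

#' Write a 3D volume
#'
#' Writes in the format implied by the extension of `path` (see
#' [read_volume()]). NIfTI and MetaImage store doubles, so a round trip is
#' bit-exact up to the float32 spacing fields of the NIfTI header; TIFF
#' stores float32 samples.
#'
#' @param volume an [as_volume()] object.
#' @param path output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  kind <- .vol_ext(path)
  parent <- dirname(path)
  if (!dir.exists(parent)) stop("parent directory does not exist: ", parent)
  if (kind == "nifti") {
    img <- RNifti::asNifti(aperm(volume$data, c(3, 2, 1)))
    RNifti::pixdim(img) <- rev(volume$spacing)
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (kind %in% c("mha", "mhd")) {
    write_meta_volume(volume, path)
  } else {
    d <- dim(volume$data)
    if (min(volume$data) < 0 || max(volume$data) > 1)
      warning("TIFF output clips intensities outside [0, 1]; normalize first")
    slices <- lapply(seq_len(d[1]), function(i) {
      m <- volume$data[i, , ]
      m[m < 0] <- 0; m[m > 1] <- 1
      m
    })
    tiff::writeTIFF(slices, path, bits.per.sample = 32L)
  }
  invisible(path)
}

#' Maximum intensity projection
#'
#' Projects a volume to 2D by taking the per-ray maximum along one axis,
#' the standard way angiographic volumes are displayed.
#'
#' @param volume an [as_volume()] object.
#' @param axis projection axis: 1 (z), 2 (y) or 3 (x).
#' @return A 2D matrix of per-pixel maxima over the remaining two axes, in
#'   their original order.
#' @export
mip <- function(volume, axis = 1) {
  stopifnot(is_volume(volume))
  if (!(length(axis) == 1L && axis %in% 1:3))
    stop("axis must be 1, 2 or 3")
  apply(volume$data, setdiff(1:3, axis), max)
}

#' Write a 2D image (e.g. a MIP) as PNG
#'
#' Intensities are rescaled to `[0, 1]` for display.
#'
#' @param img 2D numeric matrix.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mip_png <- function(img, path) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  m <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  png::writePNG(m, path)
  invisible(path)
}
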