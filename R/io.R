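err <- function(class, msg, ...) {
  stop(structure(class = c(class, "unithresh_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct an image volume
#'
#' Lightweight container for a 3-D scalar image: the voxel data, the voxel
#' edge lengths in millimetres and the (opaque) NIfTI header it came from.
#' Most users will obtain one from [read_volume()] rather than build it.
#'
#' @param data 3-D numeric array of voxel intensities.
#' @param spacing Numeric length-3 vector of voxel edge lengths in mm; all
#'   components must be finite and positive.
#' @param header Optional NIfTI header carried along for provenance; not
#'   interpreted further.
#' @param source_path Optional provenance string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, header = NULL, source_path = NA_character_) {
  if (length(dim(data)) != 3L)
    err("unithresh_dim_error", "image data must be a 3-D array, got %d dims",
        length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    err("unithresh_header_error",
        "voxel spacing must be three finite positive values")
  if (anyNA(data))
    err("unithresh_io_error", "image data contains NaN/NA values")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing = spacing, header = header,
                 source_path = source_path),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm (%.4f ml/voxel)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              voxel_volume_ml(x)))
  invisible(x)
}

# Read a NIfTI data block and squeeze a trailing degenerate 4th axis.
read_nifti_array <- function(path) {
  if (!file.exists(path))
    err("unithresh_io_error", "file not found: %s", path)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  d <- dim(a)
  a <- array(as.vector(a), dim = d)   # drop niftiImage attributes
  if (length(d) == 4L && d[4L] == 1L) {
    dim(a) <- d[1:3]
  } else if (length(d) != 3L) {
    err("unithresh_dim_error",
        "expected a 3-D volume (or 4-D with a single time point), got dims %s in %s",
        paste(d, collapse = "x"), path)
  }
  list(data = a, header = RNifti::niftiHeader(img),
       spacing = RNifti::pixdim(img)[1:3])
}

#' Read a NIfTI image volume
#'
#' Reads a 3-D NIfTI-1 file (optionally gzipped).  The header's scale slope
#' and intercept are applied by the reader; no other intensity normalisation
#' is ever performed.  A trailing 4th axis of length 1 is squeezed; any other
#' 4-D input is rejected.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()] with spacing taken from the header.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1))
#' f <- tempfile(fileext = ".nii.gz")
#' write_volume(ph$volume, f)
#' v <- read_volume(f)
#' v$spacing
#' @export
read_volume <- function(path) {
  r <- read_nifti_array(path)
  if (!all(is.finite(r$spacing)) || any(r$spacing <= 0))
    err("unithresh_header_error",
        "non-positive voxel size in NIfTI header of %s", path)
  image_volume(r$data, r$spacing, header = r$header, source_path = path)
}

#' Write an image volume to NIfTI
#'
#' @param volume An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI on-disk datatype, e.g. `"double"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Construct a region-of-interest mask
#'
#' @param data 3-D logical (or coercible) array; `TRUE` marks voxels inside
#'   the coarse manual tracing.
#' @param reference_shape Integer length-3: the grid it annotates.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, reference_shape) {
  reference_shape <- as.integer(reference_shape)
  if (!identical(dim(data), reference_shape) &&
      !identical(as.integer(dim(data)), reference_shape))
    err("unithresh_alignment_error",
        "mask shape (%s) does not match reference shape (%s)",
        paste(dim(data), collapse = "x"),
        paste(reference_shape, collapse = "x"))
  m <- array(as.logical(data), dim = reference_shape)
  if (!any(m))
    err("unithresh_empty_roi_error", "ROI mask contains no foreground voxels")
  structure(list(data = m, reference_shape = reference_shape),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d foreground voxels on a %s grid\n",
              sum(x$data), paste(x$reference_shape, collapse = "x")))
  invisible(x)
}

#' Read a binary ROI mask aligned with a reference volume
#'
#' Mask files exported by tracing tools may store labels as floats or
#' integer label values; any voxel strictly greater than 0.5 is treated as
#' foreground.
#'
#' @param path Path to the NIfTI mask.
#' @param reference The [image_volume()] the mask annotates; shapes must
#'   match exactly (no resampling is attempted).
#' @return An `roi_mask`.
#' @export
read_mask <- function(path, reference) {
  r <- read_nifti_array(path)
  roi_mask(r$data > 0.5, dim(reference$data))
}

#' Write an ROI mask to NIfTI
#'
#' @param roi An `roi_mask`.
#' @param path Output path.
#' @param spacing Voxel spacing in mm to record in the header.
#' @return `path`, invisibly.
#' @export
write_mask <- function(roi, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(roi$data), dim = dim(roi$data)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Voxel volume in millilitres
#'
#' Product of the three voxel edge lengths (mm^3) divided by 1000.  At the
#' acquisition geometry of 1.0 x 1.0 mm in plane and 4.4 mm slices this is
#' 0.0044 ml per voxel.
#'
#' @param volume An [image_volume()].
#' @return Scalar, ml per voxel.
#' @export
voxel_volume_ml <- function(volume) {
  prod(volume$spacing) / 1000
}

stopifnot_aligned <- function(volume, roi) {
  if (!identical(as.integer(dim(volume$data)), as.integer(dim(roi$data))))
    err("unithresh_alignment_error",
        "image (%s) and ROI (%s) are on different grids",
        paste(dim(volume$data), collapse = "x"),
        paste(dim(roi$data), collapse = "x"))
}

#' Write a visual-feedback label overlay
#'
#' Encodes the segmentation as a NIfTI label volume: 0 = outside the ROI,
#' 1 = kept parenchyma, 2 = below the lower threshold, 3 = above the upper
#' threshold.  Optionally rasterises each axial slice that intersects the
#' ROI to PNG, with sub-threshold voxels in blue hues, supra-threshold
#' voxels in orange hues and the ROI boundary drawn as a red contour.
#'
#' @param volume The [image_volume()] the segmentation was computed on.
#' @param roi The `roi_mask` used.
#' @param result A `segmentation_result` from [apply_thresholds()] (the
#'   `$segmentation` element of a [unithresh()] fit).
#' @param path Output NIfTI path for the label volume.
#' @param png_dir Optional directory; if given, one PNG per ROI-bearing
#'   axial slice is written there.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(volume, roi, result, path, png_dir = NULL) {
  stopifnot_aligned(volume, roi)
  lab <- array(0L, dim = dim(volume$data))
  lab[result$kept_mask]  <- 1L
  lab[result$below_mask] <- 2L
  lab[result$above_mask] <- 3L
  ok <- tryCatch({
    img <- RNifti::asNifti(lab)
    RNifti::pixdim(img) <- volume$spacing
    RNifti::writeNifti(img, path, datatype = "uint8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    err("unithresh_io_error", "cannot write overlay to %s", path)
  if (!is.null(png_dir)) {
    dir.create(png_dir, showWarnings = FALSE, recursive = TRUE)
    write_overlay_pngs(volume, roi, lab, png_dir)
  }
  invisible(path)
}

# In-plane 4-neighbour boundary of a logical slice.
slice_boundary <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  inner <- m
  inner[] <- FALSE
  if (nx > 2 && ny > 2)
    inner[2:(nx - 1), 2:(ny - 1)] <-
      m[2:(nx - 1), 2:(ny - 1)] &
      m[1:(nx - 2), 2:(ny - 1)] & m[3:nx, 2:(ny - 1)] &
      m[2:(nx - 1), 1:(ny - 2)] & m[2:(nx - 1), 3:ny]
  m & !inner
}

write_overlay_pngs <- function(volume, roi, lab, png_dir) {
  qs <- stats::quantile(volume$data, c(0.01, 0.99))
  lo <- qs[[1]]; hi <- max(qs[[2]], lo + 1)
  zs <- which(apply(roi$data, 3, any))
  for (z in zs) {
    g <- pmin(pmax((volume$data[, , z] - lo) / (hi - lo), 0), 1)
    r <- g; gg <- g; b <- g
    l <- lab[, , z]
    below <- l == 2L; above <- l == 3L
    # blue hues for sub-threshold, orange hues for supra-threshold
    r[below] <- 0.2 * g[below]; gg[below] <- 0.4 * g[below] + 0.2
    b[below] <- 0.6 + 0.4 * g[below]
    r[above] <- 0.7 + 0.3 * g[above]; gg[above] <- 0.4 + 0.3 * g[above]
    b[above] <- 0.1 * g[above]
    edge <- slice_boundary(roi$data[, , z])
    r[edge] <- 1; gg[edge] <- 0; b[edge] <- 0
    # array() transpose: PNG rows are the second array index
    rgb <- array(c(t(r), t(gg), t(b)), dim = c(ncol(r), nrow(r), 3))
    png::writePNG(rgb, file.path(png_dir, sprintf("slice_%03d.png", z)))
  }
  invisible(NULL)
}
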