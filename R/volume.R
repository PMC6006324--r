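#' Image volume container
#'
#' A 3D scalar grid (in Hounsfield units for CT data) together with a 4x4
#' affine mapping 0-based voxel indices to world coordinates in mm.  Voxels
#' may be anisotropic, as in clinical CT (e.g. 0.31 x 0.31 mm in-plane with
#' 1.5 mm slices).
#'
#' @param data 3D numeric array of voxel values.
#' @param spacing numeric length-3, voxel size in mm along each axis.
#' @param origin numeric length-3, world position of voxel (0,0,0) in mm.
#' @param affine optional 4x4 matrix overriding `spacing`/`origin`; must be
#'   invertible.
#' @return An object of class `image_volume` with elements `data`, `affine`
#'   and `spacing`.
#' @examples
#' v <- image_volume(array(0, c(8, 8, 4)), spacing = c(0.5, 0.5, 1.5))
#' voxel_to_world(v, cbind(1, 2, 3))
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         affine = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, length(origin) == 3L)
    if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing)
    affine[1:3, 4] <- origin
  } else {
    if (!all(dim(affine) == c(4L, 4L))) stop("`affine` must be 4x4")
    if (abs(det(affine)) < 1e-12) stop("`affine` must be invertible")
    spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  structure(list(data = data, affine = affine, spacing = as.numeric(spacing)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  value range:", paste(signif(range(x$data), 5), collapse = " .. "), "\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based and continuous; world coordinates are mm.
#'
#' @param volume an [image_volume].
#' @param pts n x 3 matrix of points (rows).
#' @return n x 3 matrix of transformed points.
#' @export
voxel_to_world <- function(volume, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  t((volume$affine %*% pts)[1:3, , drop = FALSE])
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(volume, pts) {
  pts <- rbind(t(as.matrix(pts)), 1)
  t((solve(volume$affine) %*% pts)[1:3, , drop = FALSE])
}

#' Read a 3D volume from disk
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) via the RNifti package and
#' uncompressed MetaImage (`.mha`).  Any modality rescale slope/intercept
#' stored in a NIfTI header is applied at load so values arrive in HU.
#'
#' @param path file path.
#' @return An [image_volume].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::readNifti(path)
    aff <- structure(RNifti::xform(img), class = "matrix")
    data <- array(as.numeric(img), dim = dim(img))
    # RNifti xforms are RAS with possibly negative axes; keep as-is.
    return(image_volume(data, affine = matrix(aff, 4, 4)))
  }
  if (ext == ".mha") return(read_mha(path))
  stop("unsupported volume format: ", ext)
}

#' Write a 3D volume to disk
#'
#' @param volume an [image_volume].
#' @param path output path; format chosen by extension (`.nii`, `.nii.gz`,
#'   `.mha`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path) {
  ext <- tolower(sub("^.*?(\\.nii\\.gz|\\.[[:alnum:]]+)$", "\\1", path))
  if (ext %in% c(".nii", ".nii.gz")) {
    img <- RNifti::asNifti(volume$data)
    img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = "double")
    return(invisible(path))
  }
  if (ext == ".mha") return(write_mha(volume, path))
  stop("unsupported volume format: ", ext)
}

# Minimal uncompressed MetaImage (.mha) I/O: plain-text header + raw voxels.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("malformed MetaImage header")
    kv <- strsplit(line, "\\s*=\\s*")[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL"))
    stop("only LOCAL MetaImage data supported")
  dims <- as.integer(strsplit(hdr[["DimSize"]], " +")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]], " +")[[1]])
  origin <- if (!is.null(hdr[["Offset"]]))
    as.numeric(strsplit(hdr[["Offset"]], " +")[[1]]) else c(0, 0, 0)
  type <- hdr[["ElementType"]]
  n <- prod(dims)
  data <- switch(type,
    "MET_DOUBLE" = readBin(con, "double", n, size = 8),
    "MET_FLOAT"  = readBin(con, "double", n, size = 4),
    "MET_SHORT"  = readBin(con, "integer", n, size = 2, signed = TRUE),
    "MET_UCHAR"  = readBin(con, "integer", n, size = 1, signed = FALSE),
    stop("unsupported ElementType: ", type))
  image_volume(array(as.numeric(data), dim = dims), spacing = spacing,
               origin = origin)
}

write_mha <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(volume$data), collapse = " ")),
           paste("ElementSpacing =", paste(volume$spacing, collapse = " ")),
           paste("Offset =", paste(volume$affine[1:3, 4], collapse = " ")),
           "ElementType = MET_DOUBLE", "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.numeric(volume$data), con, size = 8)
  invisible(path)
}

#' Sample an interpolated 1D density profile along a ray
#'
#' Samples the volume at `origin + t * direction` for `t` on a uniform grid,
#' interpolating voxel values.  This is the elementary operation behind
#' per-vertex joint space measurement: each joint space patch vertex casts a
#' ray along its outward normal and the resulting HU profile is fitted.
#'
#' Samples falling outside the grid take the nearest-edge value and are
#' flagged; a profile with more than `max_oob_frac` flagged samples is
#' rejected with an error.
#'
#' @param volume an [image_volume].
#' @param origin world point in mm (the patch vertex; `t = 0` here).
#' @param direction unit vector (outward normal; positive `t` crosses the
#'   joint space).
#' @param t_min,t_max sampling extent in mm.
#' @param step sample spacing in mm.
#' @param interp `"cubic"` (Catmull-Rom, default) or `"linear"`.
#' @param max_oob_frac maximum tolerated fraction of out-of-grid samples.
#' @return A `line_profile`: list with `t`, `values`, `origin`, `direction`,
#'   `oob` (logical flags).
#' @export
sample_profile <- function(volume, origin, direction, t_min = -6, t_max = 10,
                           step = 0.1, interp = c("cubic", "linear"),
                           max_oob_frac = 0.2) {
  interp <- match.arg(interp)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    if (nrm < 1e-12) stop("direction must be non-zero")
    direction <- direction / nrm
  }
  t <- seq(t_min, t_max, by = step)
  pts <- cbind(origin[1] + t * direction[1],
               origin[2] + t * direction[2],
               origin[3] + t * direction[3])
  vox <- world_to_voxel(volume, pts)
  res <- sample_volume_cpp(as.numeric(volume$data), dim(volume$data), vox,
                           if (interp == "cubic") 3L else 1L)
  if (all(res$oob)) stop("profile lies entirely outside the volume")
  if (mean(res$oob) > max_oob_frac)
    stop("profile rejected: ", round(100 * mean(res$oob)),
         "% of samples outside the volume")
  structure(list(t = t, values = res$values, origin = origin,
                 direction = direction, oob = res$oob),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat("line_profile:", length(x$t), "samples, t in [",
      min(x$t), ",", max(x$t), "] mm\n")
  invisible(x)
}

# Gaussian blur of a volume with per-axis sigmas in mm (separable kernels,
# replicate edge handling).  sigma of 0 along an axis skips that axis.
blur_volume <- function(volume, sigma_mm) {
  data <- as.numeric(volume$data)
  dims <- dim(volume$data)
  for (ax in 1:3) {
    s_vox <- sigma_mm[ax] / volume$spacing[ax]
    if (s_vox <= 1e-6) next
    r <- max(1L, ceiling(4 * s_vox))
    k <- dnorm(seq(-r, r), sd = s_vox)
    k <- k / sum(k)
    data <- conv_axis_cpp(data, dims, k, ax - 1L)
  }
  image_volume(array(data, dims), affine = volume$affine)
}
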