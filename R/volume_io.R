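#' Labeled voxel volume
#'
#' Integer label map on a regular, axis-aligned voxel grid. World coordinates
#' follow the voxel-centre convention: voxel index `(i, j, k)` (0-based) sits
#' at `origin + c(i, j, k) * spacing` (mm). Oblique orientations are not
#' representable; [read_label_volume()] rejects them.
#'
#' @param voxels 3-D integer array of label IDs (0 = background).
#' @param spacing length-3 numeric, mm per voxel along each axis (> 0).
#' @param origin length-3 numeric, world mm position of the centre of voxel
#'   (0, 0, 0).
#' @param label_names optional named character vector mapping label IDs
#'   (names) to structure names, e.g. `c("1" = "bone", "2" = "cochlea")`.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(voxels, spacing, origin = c(0, 0, 0),
                         label_names = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3 || length(voxels) == 0)
    stop("voxels must be a non-empty 3-D array")
  if (is.double(voxels)) {
    if (any(!is.finite(voxels)) || any(voxels != round(voxels)))
      stop("voxels must hold integer labels")
    storage.mode(voxels) <- "integer"
  }
  if (!is.integer(voxels)) stop("voxels must hold integer labels")
  if (any(voxels < 0L)) stop("labels must be >= 0")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be three positive numbers")
  if (length(origin) != 3 || any(!is.finite(origin)))
    stop("origin must be three finite numbers")
  if (!is.null(label_names)) {
    label_names <- stats::setNames(as.character(label_names), names(label_names))
    if (is.null(names(label_names)) || any(names(label_names) == ""))
      stop("label_names must be named by label ID")
  }
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 label_names = label_names),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$voxels)
  labs <- sort(unique(as.vector(x$voxels)))
  labs <- labs[labs != 0L]
  cat(sprintf("<label_volume> %d x %d x %d voxels, spacing %s mm, %d label(s)\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              length(labs)))
  invisible(x)
}

# integer NIfTI datatype codes (uint8, int16, int32, int8, uint16, uint32, int64, uint64)
.nifti_int_codes <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)

#' Read a labeled NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` integer label map. The affine must be axis-aligned
#' up to axis permutation and flips; the volume is canonicalised so that the
#' stored array satisfies the voxel-centre convention with positive spacing.
#' Oblique or sheared affines raise an error rather than being silently
#' reinterpreted.
#'
#' @param path NIfTI file path.
#' @param label_names optional named character vector (see [label_volume()]).
#' @return a [label_volume()].
#' @export
read_label_volume <- function(path, label_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  if (!(hdr$datatype %in% .nifti_int_codes))
    stop("label volume must have an integer datatype (got NIfTI code ",
         hdr$datatype, ")")
  vox <- as.array(img)
  if (length(dim(vox)) != 3) stop("expected a 3-D volume")
  aff <- RNifti::xform(img)
  A <- unclass(aff)[1:3, 1:3]
  t0 <- unclass(aff)[1:3, 4]
  # every index axis must map to exactly one world axis (permutation + flip)
  perm <- integer(3); sgn <- numeric(3); sp <- numeric(3)
  for (j in 1:3) {
    col <- A[, j]
    nz <- which(abs(col) > 1e-6 * max(abs(col), 1e-12))
    if (length(nz) != 1)
      stop("unsupported oblique/sheared NIfTI orientation; resample to an ",
           "axis-aligned grid first")
    perm[j] <- nz
    sgn[j] <- sign(col[nz])
    sp[j] <- abs(col[nz])
  }
  if (anyDuplicated(perm))
    stop("unsupported degenerate NIfTI orientation matrix")
  # canonicalise: flip negative axes, then permute index axes to world order
  d <- dim(vox)
  origin_w <- numeric(3)
  for (j in 1:3) {
    w <- perm[j]
    if (sgn[j] < 0) {
      vox <- .flip_axis(vox, j)
      origin_w[w] <- t0[w] - sp[j] * (d[j] - 1)
    } else {
      origin_w[w] <- t0[w]
    }
  }
  vox <- aperm(vox, order(perm))
  spacing_w <- sp[order(perm)]
  storage.mode(vox) <- "integer"
  label_volume(vox, spacing = spacing_w, origin = origin_w,
               label_names = label_names)
}

.flip_axis <- function(a, axis) {
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- rev(seq_len(dim(a)[axis]))
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Write a label volume to NIfTI
#'
#' Int32 data with a diagonal sform/qform encoding spacing and origin, so
#' that a write/read round trip preserves voxels exactly and spacing/origin
#' to floating precision.
#'
#' @param volume a [label_volume()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(volume, path) {
  stopifnot(inherits(volume, "label_volume"))
  a <- volume$voxels
  attr(a, "pixdim") <- volume$spacing
  img <- RNifti::asNifti(a, datatype = "int32", internal = FALSE)
  aff <- diag(c(volume$spacing, 1))
  aff[1:3, 4] <- volume$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Threshold an intensity volume
#'
#' Bone extraction from CT by simple thresholding: a voxel is foreground iff
#' its intensity is greater than or equal to `threshold` (Hounsfield units
#' for CT input).
#'
#' @param intensities 3-D numeric array.
#' @param threshold scalar threshold.
#' @return logical 3-D mask of the same dimensions.
#' @export
threshold_mask <- function(intensities, threshold) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be a 3-D array")
  if (any(is.na(intensities)) || any(is.nan(intensities)))
    stop("intensities contain NaN/NA values")
  intensities >= threshold
}

#' Dilate a binary mask by a metric margin
#'
#' Euclidean, anisotropy-aware morphological dilation: the output foreground
#' is the set of voxels whose centre lies within `margin_mm` (mm) of some
#' input foreground voxel centre. Used to grow the brain/dura mask into a
#' safety margin before planning.
#'
#' @param mask logical (or 0/1) 3-D array.
#' @param margin_mm dilation radius in mm (>= 0); 0 returns the input.
#' @param spacing length-3 voxel spacing in mm.
#' @return logical 3-D mask.
#' @export
dilate_mask <- function(mask, margin_mm, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("mask must be a 3-D array")
  if (!is.numeric(margin_mm) || length(margin_mm) != 1 || is.na(margin_mm) ||
      margin_mm < 0)
    stop("margin_mm must be a single non-negative number")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) stop("invalid spacing")
  d <- dim(mask)
  storage.mode(mask) <- "logical"
  if (margin_mm == 0) return(mask)
  r <- floor(margin_mm / spacing + 1e-9)
  off <- as.matrix(expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3]))
  keep <- sqrt((off[, 1] * spacing[1])^2 + (off[, 2] * spacing[2])^2 +
                 (off[, 3] * spacing[3])^2) <= margin_mm + 1e-9
  off <- off[keep, , drop = FALSE]
  out <- cpp_dilate(as.vector(mask), as.integer(d), off)
  array(out, d)
}

#' Extract the triangle surface of one label
#'
#' Isosurface of the binary indicator of `label` at level 0.5, computed by
#' marching tetrahedra on a grid padded with background so the surface is
#' closed (watertight). By default the indicator is first filtered with a
#' separable 3x3x3 box mean, which removes the voxelisation staircase bias
#' so that surface areas of digitised solids converge to the continuous
#' values; set `smooth = FALSE` for the raw binary isosurface.
#'
#' @param volume a [label_volume()].
#' @param label integer label to extract; an absent label yields an empty
#'   mesh, not an error.
#' @param smooth filter the indicator before isosurfacing (default `TRUE`).
#' @param name structure name; defaults to the volume's `label_names` entry.
#' @param critical criticality flag for the returned mesh.
#' @return a [structure_mesh()] in world mm coordinates.
#' @export
extract_surface <- function(volume, label, smooth = TRUE, name = NULL,
                            critical = FALSE) {
  stopifnot(inherits(volume, "label_volume"))
  label <- as.integer(label)
  if (is.null(name)) {
    nm <- volume$label_names[as.character(label)]
    name <- if (length(nm) == 1 && !is.na(nm)) unname(nm) else paste0("label_", label)
  }
  res <- cpp_marching_tets(as.vector(volume$voxels), dim(volume$voxels),
                           label, volume$spacing, volume$origin, smooth)
  structure_mesh(res$vertices, res$faces, name = name, label = label,
                 critical = critical)
}
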