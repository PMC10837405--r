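#' Binary region-of-interest mask
#'
#' A `binary_mask` is a logical 3D array on some image grid, with the grid's
#' voxel-to-world affine. Masks are kept strictly binary: resampling between
#' grids is nearest-neighbor, never interpolated.
#'
#' @param data logical (or coercible) 3D array; nonzero/`TRUE` = inside.
#' @param affine 4x4 voxel-to-world transform of the grid the mask lives on.
#' @param label text label, e.g. `"lesion"`, `"ring"`, `"core"`.
#' @return An object of class `binary_mask` with elements `data`, `affine`,
#'   `label` and `np` (number of in-mask voxels).
#' @export
binary_mask <- function(data, affine, label = "roi") {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_dimensionality("mask `data` must be a 3D array")
  data <- array(as.logical(data), dim = dim(data))
  if (anyNA(data))
    abort_validation("mask contains NA values")
  affine <- validate_affine(affine)
  structure(
    list(data = data, affine = affine, label = as.character(label)[1],
         np = sum(data)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_mask> '%s': %d / %d voxels on a %d x %d x %d grid\n",
              x$label, x$np, prod(d), d[1], d[2], d[3]))
  invisible(x)
}

#' Read a binary mask from NIfTI
#'
#' Any nonzero voxel is inside.
#'
#' @param path path to a NIfTI mask (integer payload).
#' @param label label to attach.
#' @return A [binary_mask()].
#' @export
read_mask <- function(path, label = "roi") {
  vol <- tryCatch(read_volume(path), error = function(e) {
    if (inherits(e, "suvhist_error")) stop(e)
    abort_io(sprintf("failed to read mask '%s'", path))
  })
  binary_mask(vol$data != 0, vol$affine, label = label)
}

#' Write a binary mask to NIfTI
#'
#' @param mask a [binary_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$data), dim = dim(mask$data)))
  RNifti::pixdim(img) <- sqrt(colSums(mask$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(mask$affine, code = 2L)
  RNifti::qform(img) <- structure(mask$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Spherical reference ROI in world coordinates
#'
#' Reference regions for normal-brain uptake are 1 cm diameter spheres placed
#' in world (mm) coordinates; they are rasterized onto a specific grid only
#' when voxels are extracted.
#'
#' @param center world-coordinate center, mm (length-3 numeric).
#' @param diameter sphere diameter in mm (default 10, i.e. 1 cm).
#' @return An object of class `sphere_roi`.
#' @export
sphere_roi <- function(center, diameter = 10) {
  center <- as.numeric(center)
  if (length(center) != 3L || anyNA(center) || any(!is.finite(center)))
    abort_validation("`center` must be a finite length-3 world coordinate")
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0)
    abort_validation("`diameter` must be a single positive number")
  structure(list(center = center, diameter = diameter), class = "sphere_roi")
}

#' Rasterize a sphere onto an image grid
#'
#' A voxel belongs to the sphere iff its world-coordinate center lies within
#' `diameter / 2` (inclusive) of the sphere center. Membership is evaluated
#' only inside a conservative bounding box derived from the sphere's world
#' extent, so rasterization cost scales with the sphere, not the grid.
#'
#' @param sphere a [sphere_roi()].
#' @param grid an [suv_volume()] (or any object with `data` dims and `affine`)
#'   defining the target grid.
#' @param label label for the resulting mask.
#' @return A [binary_mask()] on `grid`'s grid.
#' @export
rasterize_sphere <- function(sphere, grid, label = "reference") {
  stopifnot(inherits(sphere, "sphere_roi"))
  dims <- dim(grid$data)
  affine <- grid$affine
  r <- sphere$diameter / 2

  # conservative voxel-space bounding box from the 8 corners of the world box
  corners <- as.matrix(expand.grid(
    sphere$center[1] + c(-r, r),
    sphere$center[2] + c(-r, r),
    sphere$center[3] + c(-r, r)))
  vox <- world_to_voxel(corners, affine)
  lo <- pmax(1L, floor(apply(vox, 2, min)) - 1L)
  hi <- pmin(dims, ceiling(apply(vox, 2, max)) + 1L)
  mask <- array(FALSE, dim = dims)
  if (all(lo <= hi)) {
    ijk <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    xyz <- voxel_to_world(ijk, affine)
    d2 <- (xyz[, 1] - sphere$center[1])^2 + (xyz[, 2] - sphere$center[2])^2 +
      (xyz[, 3] - sphere$center[3])^2
    inside <- d2 <= r^2
    if (any(inside))
      mask[ijk[inside, , drop = FALSE]] <- TRUE
  }
  if (!any(mask))
    abort_empty_roi("sphere does not cover any voxel center of the grid")
  binary_mask(mask, affine, label = label)
}

#' Mirror reference spheres to the contralateral hemisphere
#'
#' Places `n` reference spheres in the hemisphere opposite the lesion: the
#' lesion centroid (world mm) is reflected across the midsagittal plane
#' `x = x_mid`, and the given offsets are added to spread the spheres. The
#' default offsets displace the second and third spheres by +/- 12 mm along
#' the superior-inferior (world z) axis, keeping 1 cm spheres disjoint.
#'
#' @param lesion_mask a non-empty [binary_mask()] of the lesion.
#' @param grid an [suv_volume()] supplying the world extent.
#' @param n number of spheres (default 3).
#' @param offsets list (or n x 3 matrix) of world-mm offsets added to the
#'   reflected centroid; defaults to `(0,0,0)`, `(0,0,12)`, `(0,0,-12)`
#'   truncated/recycled to `n`.
#' @param x_mid world x of the midsagittal plane; default the midpoint of the
#'   grid's world-x extent.
#' @param diameter sphere diameter in mm.
#' @return A list of `n` [sphere_roi()] objects.
#' @export
mirror_spheres <- function(lesion_mask, grid, n = 3, offsets = NULL,
                           x_mid = NULL, diameter = 10) {
  stopifnot(inherits(lesion_mask, "binary_mask"))
  if (lesion_mask$np == 0L)
    abort_empty_roi("lesion mask is empty; cannot mirror reference spheres")
  dims <- dim(grid$data)
  corners <- as.matrix(expand.grid(c(1, dims[1]), c(1, dims[2]), c(1, dims[3])))
  world_corners <- voxel_to_world(corners, grid$affine)
  if (is.null(x_mid))
    x_mid <- mean(range(world_corners[, 1]))

  idx <- which(lesion_mask$data, arr.ind = TRUE)
  centroid <- colMeans(voxel_to_world(idx, lesion_mask$affine))
  if (abs(centroid[1] - x_mid) < diameter / 2)
    warning("lesion centroid lies on or near the midsagittal plane; ",
            "mirrored spheres may overlap the lesion", call. = FALSE)
  reflected <- centroid
  reflected[1] <- 2 * x_mid - centroid[1]

  lo <- apply(world_corners, 2, min)
  hi <- apply(world_corners, 2, max)
  if (any(reflected < lo) || any(reflected > hi))
    abort_placement("reflected sphere center falls outside the image volume")

  if (is.null(offsets)) {
    offsets <- list(c(0, 0, 0), c(0, 0, 12), c(0, 0, -12))
    while (length(offsets) < n) {
      k <- length(offsets) - 1
      offsets[[length(offsets) + 1L]] <- c(0, 0, 12 * (k %/% 2 + 1) *
                                             ifelse(k %% 2 == 0, 1, -1))
    }
  }
  if (is.matrix(offsets)) offsets <- asplit(offsets, 1)
  if (length(offsets) < n)
    abort_validation(sprintf("need %d offsets, got %d", n, length(offsets)))
  lapply(seq_len(n), function(i)
    sphere_roi(reflected + as.numeric(offsets[[i]]), diameter = diameter))
}

#' Resample a binary mask onto another grid
#'
#' Nearest-neighbor resampling through world coordinates: a target voxel is
#' inside iff its world center, mapped into the source grid, lands on (the
#' nearest voxel of) the source mask. Identity on identical grids. Masks stay
#' binary by construction; images themselves are never resampled.
#'
#' @param mask a [binary_mask()].
#' @param target an [suv_volume()] (or mask) defining the output grid.
#' @return A [binary_mask()] on `target`'s grid.
#' @export
resample_mask <- function(mask, target) {
  stopifnot(inherits(mask, "binary_mask"))
  tdims <- dim(target$data)
  if (identical(tdims, dim(mask$data)) &&
      isTRUE(all.equal(mask$affine, target$affine, tolerance = 1e-8))) {
    return(binary_mask(mask$data, target$affine, label = mask$label))
  }
  ijk <- as.matrix(expand.grid(seq_len(tdims[1]), seq_len(tdims[2]),
                               seq_len(tdims[3])))
  xyz <- voxel_to_world(ijk, target$affine)
  src <- round(world_to_voxel(xyz, mask$affine))
  sdims <- dim(mask$data)
  ok <- src[, 1] >= 1 & src[, 1] <= sdims[1] &
    src[, 2] >= 1 & src[, 2] <= sdims[2] &
    src[, 3] >= 1 & src[, 3] <= sdims[3]
  inside <- logical(nrow(src))
  inside[ok] <- mask$data[src[ok, , drop = FALSE]]
  out <- array(inside, dim = tdims)
  if (!any(out))
    abort_empty_roi("mask is empty after resampling onto the target grid")
  binary_mask(out, target$affine, label = mask$label)
}

#' Extract the voxel series of an ROI
#'
#' Collects the SUVs of all in-mask voxels into an ordered series X(i),
#' i = 1..Np -- the substrate of every feature. The scan order is ascending
#' linear (column-major) index: irrelevant to the order-invariant statistics
#' computed from it, but fixed for reproducibility.
#'
#' @param vol an [suv_volume()].
#' @param mask a [binary_mask()] on the same grid (resample first otherwise).
#' @return An object of class `voxel_series` with `values`, `np` and
#'   `voxel_volume` (mL).
#' @export
extract_voxels <- function(vol, mask) {
  stopifnot(inherits(vol, "suv_volume"), inherits(mask, "binary_mask"))
  if (!identical(dim(vol$data), dim(mask$data)) ||
      !isTRUE(all.equal(vol$affine, mask$affine, tolerance = 1e-6)))
    abort_grid("mask and volume are on different grids; resample the mask first")
  if (mask$np == 0L)
    abort_empty_roi("mask is empty; no voxels to extract")
  voxel_series(vol$data[mask$data], vol$voxel_volume)
}

#' Construct a voxel series directly
#'
#' @param values numeric vector of SUVs.
#' @param voxel_volume mL per voxel.
#' @return An object of class `voxel_series`.
#' @export
voxel_series <- function(values, voxel_volume) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    abort_empty_roi("voxel series is empty")
  if (anyNA(values) || any(!is.finite(values)))
    abort_validation("voxel series contains non-finite values")
  if (!is.numeric(voxel_volume) || length(voxel_volume) != 1L ||
      !is.finite(voxel_volume) || voxel_volume <= 0)
    abort_validation("`voxel_volume` must be a single positive number (mL)")
  structure(list(values = values, np = length(values),
                 voxel_volume = voxel_volume),
            class = "voxel_series")
}

#' @export
print.voxel_series <- function(x, ...) {
  cat(sprintf("<voxel_series> Np = %d, %.4g mL/voxel, SUV range [%.3g, %.3g]\n",
              x$np, x$voxel_volume, min(x$values), max(x$values)))
  invisible(x)
}

#' Union of binary masks on a common grid
#'
#' Used to pool the reference spheres into one normal-brain voxel set.
#'
#' @param masks list of [binary_mask()] objects on the same grid.
#' @param label label for the union.
#' @return A [binary_mask()].
#' @export
mask_union <- function(masks, label = "union") {
  stopifnot(length(masks) >= 1L)
  out <- masks[[1]]$data
  for (m in masks[-1]) {
    if (!identical(dim(m$data), dim(out)))
      abort_grid("cannot union masks on different grids")
    out <- out | m$data
  }
  binary_mask(out, masks[[1]]$affine, label = label)
}
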