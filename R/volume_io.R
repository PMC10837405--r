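#' SUV volumes: construction, NIfTI input/output, and SUV normalization
#'
#' An `suv_volume` is a 3D scalar grid of standard-uptake values together with
#' the 4x4 affine mapping zero-based voxel indices to world coordinates in mm
#' (RAS+ convention), the per-voxel volume in mL, and optional acquisition
#' metadata. All geometric operations in the package (sphere rasterization,
#' mirroring, resampling) go through this affine; voxel indices are never used
#' as spatial coordinates directly.
#'
#' @param data numeric 3D array of SUVs; all values must be finite and >= 0.
#' @param affine numeric 4x4 voxel-to-world transform (zero-based indices,
#'   world mm). Must be invertible.
#' @param meta acquisition metadata from [acquisition_meta()], or `NULL`.
#' @return An object of class `suv_volume` with elements `data`, `affine`,
#'   `voxel_volume` (mL, from the determinant of the spatial 3x3 block) and
#'   `meta`.
#' @examples
#' vol <- suv_volume(array(1, dim = c(2, 2, 2)), diag(4))
#' vol$voxel_volume  # 1 mm^3 = 0.001 mL
#' @export
suv_volume <- function(data, affine, meta = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    abort_dimensionality("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data)))
    abort_validation("SUV volume contains non-finite values")
  if (any(data < 0))
    abort_validation("SUV volume contains negative values; SUV is non-negative")
  affine <- validate_affine(affine)
  structure(
    list(
      data = data,
      affine = affine,
      voxel_volume = voxel_volume_from_affine(affine),
      meta = meta
    ),
    class = "suv_volume"
  )
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || anyNA(affine) || any(!is.finite(affine)))
    abort_validation("`affine` must be a finite 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    abort_validation("`affine` spatial block is singular")
  storage.mode(affine) <- "double"
  dimnames(affine) <- NULL
  affine
}

# mm^3 per voxel -> mL
voxel_volume_from_affine <- function(affine) {
  abs(det(affine[1:3, 1:3])) / 1000
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<suv_volume> %d x %d x %d voxels, %.4g mL/voxel\n",
              d[1], d[2], d[3], x$voxel_volume))
  cat(sprintf("  SUV range [%.3g, %.3g], mean %.3g\n",
              min(x$data), max(x$data), mean(x$data)))
  invisible(x)
}

#' Acquisition metadata for SUV normalization
#'
#' Body-weight SUV normalization needs the subject weight, the injected dose
#' and a decay factor. The decay factor is an explicit input in (0, 1] rather
#' than being computed internally from a half-life, so the correction applied
#' (to injection time or scan start) is always auditable from the metadata.
#'
#' @param body_weight body weight in kg, > 0.
#' @param injected_dose injected activity in MBq, > 0.
#' @param decay_factor dimensionless decay correction in (0, 1].
#' @param frame free-text label for the decay reference frame
#'   (e.g. "injection").
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(body_weight, injected_dose, decay_factor = 1,
                             frame = "injection") {
  for (nm in c("body_weight", "injected_dose", "decay_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      abort_validation(sprintf("`%s` must be a single positive finite number", nm))
  }
  if (decay_factor > 1)
    abort_validation("`decay_factor` must lie in (0, 1]")
  structure(
    list(body_weight = body_weight, injected_dose = injected_dose,
         decay_factor = decay_factor, frame = as.character(frame)[1]),
    class = "acquisition_meta"
  )
}

#' Read a 3D volume from NIfTI
#'
#' Reads a NIfTI-1/2 file (`.nii` or `.nii.gz`), applies any on-disk
#' scale/intercept, and wraps it as an [suv_volume()] carrying the image's
#' sform/qform affine. Trailing singleton dimensions are dropped; a genuinely
#' 4D image is rejected.
#'
#' @param path path to a readable NIfTI file.
#' @param meta optional [acquisition_meta()] to attach. If `NULL` and a JSON
#'   sidecar `<path minus extension>.json` exists, it is read with
#'   [read_acquisition_meta()].
#' @return An [suv_volume()].
#' @export
read_volume <- function(path, meta = NULL) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read volume: no such file '%s'", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort_io(
                    sprintf("failed to read NIfTI '%s': %s", path, conditionMessage(e))))
  arr <- as.array(img)
  d <- dim(arr)
  while (length(d) > 3L && d[length(d)] == 1L) {
    d <- d[-length(d)]
    dim(arr) <- d
  }
  if (length(d) != 3L)
    abort_dimensionality(sprintf(
      "'%s' has %d non-singleton dimensions; expected a 3D volume", path, length(d)))
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = dim(affine))
  if (is.null(meta)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    if (file.exists(sidecar)) meta <- read_acquisition_meta(sidecar)
  }
  suv_volume(arr, affine, meta = meta)
}

#' Read acquisition metadata from a JSON sidecar
#'
#' Expects keys `body_weight_kg`, `injected_dose_MBq`, `decay_factor` and
#' optionally `frame`.
#'
#' @param path path to a JSON file.
#' @return An [acquisition_meta()].
#' @export
read_acquisition_meta <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read metadata: no such file '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  acquisition_meta(
    body_weight = j$body_weight_kg,
    injected_dose = j$injected_dose_MBq,
    decay_factor = if (is.null(j$decay_factor)) 1 else j$decay_factor,
    frame = if (is.null(j$frame)) "injection" else j$frame
  )
}

#' Convert an activity-concentration volume to SUV
#'
#' Body-weight SUV: `SUV = activity [Bq/mL] * weight [g] / (dose [Bq] * decay)`.
#' Weight enters in grams and the dose in Bq, so SUV is the usual dimensionless
#' g/mL-normalized quantity. The transform is linear in activity and inversely
#' linear in injected dose.
#'
#' @param activity numeric 3D array of activity concentration in Bq/mL, or an
#'   `suv_volume`-like list with `data` and `affine` holding raw activity.
#' @param meta an [acquisition_meta()] (kg, MBq).
#' @param affine 4x4 affine; required when `activity` is a bare array.
#' @return An [suv_volume()] in SUV units, with `meta` attached.
#' @examples
#' m <- acquisition_meta(body_weight = 70, injected_dose = 259)
#' v <- activity_to_suv(array(5000, dim = c(2, 2, 2)), m, affine = diag(4))
#' v$data[1, 1, 1]  # 5000 * 70000 / 259e6 = 1.3514
#' @export
activity_to_suv <- function(activity, meta, affine = NULL) {
  if (!inherits(meta, "acquisition_meta"))
    abort_validation("`meta` must be an `acquisition_meta` object")
  if (is.list(activity) && !is.null(activity$data)) {
    affine <- activity$affine
    activity <- activity$data
  }
  if (is.null(affine))
    abort_validation("`affine` is required when `activity` is a bare array")
  suv <- activity * (meta$body_weight * 1000) /
    (meta$injected_dose * 1e6 * meta$decay_factor)
  suv_volume(suv, affine, meta = meta)
}

#' Write an SUV volume to NIfTI
#'
#' Writes `float32` data (ample for the PET SUV dynamic range) with the
#' volume's affine stored as both sform and qform.
#'
#' @param vol an [suv_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_suv_volume <- function(vol, path) {
  stopifnot(inherits(vol, "suv_volume"))
  if (!dir.exists(dirname(path)))
    abort_io(sprintf("cannot write volume: no such directory '%s'", dirname(path)))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  tryCatch(RNifti::writeNifti(img, path, datatype = "float"),
           error = function(e) abort_io(
             sprintf("failed to write NIfTI '%s': %s", path, conditionMessage(e))))
  invisible(path)
}

# World coordinates of voxel centers for 1-based array indices `ijk`
# (n x 3 matrix). The affine follows the NIfTI zero-based convention.
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz <- cbind(ijk - 1, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

# Continuous 1-based voxel indices of world points `xyz` (n x 3 matrix).
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  ijk <- cbind(xyz, 1) %*% t(solve(affine))
  ijk[, 1:3, drop = FALSE] + 1
}
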