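#' Intensity laws for synthetic lesions
#'
#' Lesion voxel SUVs are drawn i.i.d. from a parametric law with closed-form
#' population skewness, so pipeline estimates can be checked against exact
#' ground truth:
#' * `law_gaussian(mean, sd)` -- symmetric uptake (proliferating tumor);
#'   population skewness 0.
#' * `law_gamma(shape, scale, shift)` -- right-skewed uptake (necrosis,
#'   inflammation); population skewness `2 / sqrt(shape)`, mean
#'   `shift + shape * scale`.
#' * `law_mixture(laws, weights)` -- weighted mixture (e.g. ring + core);
#'   skewness from the combined central moments.
#'
#' A shifted gamma is used for the skewed law (rather than e.g. a skew-normal)
#' precisely because its skewness is closed-form, which keeps parameter
#' recovery exactly testable.
#'
#' @param mean,sd Gaussian mean and SD (SUV); `sd > 0`.
#' @return An `intensity_law` object with a `sample(n)` routine and moments.
#' @name intensity_law
NULL

#' @rdname intensity_law
#' @export
law_gaussian <- function(mean, sd) {
  if (sd <= 0) abort_validation("gaussian `sd` must be > 0")
  structure(list(type = "gaussian", mean = mean, sd = sd), class = "intensity_law")
}

#' @rdname intensity_law
#' @param shape,scale,shift gamma shape (> 0), scale (> 0) and location shift.
#' @export
law_gamma <- function(shape, scale, shift = 0) {
  if (shape <= 0 || scale <= 0)
    abort_validation("gamma `shape` and `scale` must be > 0")
  structure(list(type = "gamma", shape = shape, scale = scale, shift = shift),
            class = "intensity_law")
}

#' @rdname intensity_law
#' @param laws list of component `intensity_law`s.
#' @param weights mixing weights, summing to 1.
#' @export
law_mixture <- function(laws, weights) {
  stopifnot(length(laws) == length(weights))
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    abort_validation("mixture `weights` must be non-negative and sum to 1")
  structure(list(type = "mixture", laws = laws, weights = as.numeric(weights)),
            class = "intensity_law")
}

# First three central moments of a law: list(mean, var, mu3)
law_moments <- function(law) {
  switch(law$type,
    gaussian = list(mean = law$mean, var = law$sd^2, mu3 = 0),
    gamma = list(mean = law$shift + law$shape * law$scale,
                 var = law$shape * law$scale^2,
                 mu3 = 2 * law$shape * law$scale^3),
    mixture = {
      ms <- lapply(law$laws, law_moments)
      w <- law$weights
      m <- sum(w * vapply(ms, `[[`, numeric(1), "mean"))
      d <- vapply(ms, `[[`, numeric(1), "mean") - m
      v <- sum(w * (vapply(ms, `[[`, numeric(1), "var") + d^2))
      mu3 <- sum(w * (vapply(ms, `[[`, numeric(1), "mu3") +
                        3 * vapply(ms, `[[`, numeric(1), "var") * d + d^3))
      list(mean = m, var = v, mu3 = mu3)
    },
    abort_validation(sprintf("unknown intensity law '%s'", law$type)))
}

#' Population skewness of an intensity law
#'
#' Closed form: 0 for a Gaussian, `2 / sqrt(shape)` for a (shifted) gamma, and
#' the standardized third central moment of the mixture otherwise.
#'
#' @param law an `intensity_law`.
#' @return Population skewness (scalar).
#' @export
population_skewness <- function(law) {
  m <- law_moments(law)
  m$mu3 / m$var^1.5
}

draw_law <- function(law, n) {
  switch(law$type,
    gaussian = stats::rnorm(n, law$mean, law$sd),
    gamma = law$shift + stats::rgamma(n, shape = law$shape, scale = law$scale),
    mixture = {
      comp <- sample.int(length(law$laws), n, replace = TRUE, prob = law$weights)
      out <- numeric(n)
      for (k in seq_along(law$laws)) {
        idx <- comp == k
        if (any(idx)) out[idx] <- draw_law(law$laws[[k]], sum(idx))
      }
      out
    })
}

#' Specification of a synthetic PET subject
#'
#' Describes one phantom: grid geometry, a low uniform normal-brain background
#' (default mean 0.1 SUV, noise SD 0.01 -- a tumor-to-background regime of
#' roughly 20 for a lesion with SUVmax near 2.5), a spherical lesion (or
#' two-shell ring + core), and the lesion intensity law.
#'
#' @param grid_shape voxel counts, default `c(96, 96, 60)` -- large enough for
#'   lesions of order a thousand voxels at 2 mm spacing, small enough that a
#'   phantom generates in well under a second.
#' @param voxel_size mm per voxel per axis, default 2 mm isotropic.
#' @param background list with `mean` and `sd` (SUV) of the truncated-at-zero
#'   Gaussian background.
#' @param lesion list with world-mm `center` and either `radius` (single
#'   sphere) or `outer_radius` + `inner_radius` (ring + core).
#' @param law lesion `intensity_law` (single-sphere phantoms).
#' @param ring_law,core_law intensity laws for the two shells (ring + core
#'   phantoms).
#' @param group truth group label (`"neoplastic"` / `"non-neoplastic"`).
#' @param seed integer seed; phantoms are bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 60),
                         voxel_size = c(2, 2, 2),
                         background = list(mean = 0.1, sd = 0.01),
                         lesion = list(center = c(30, 0, 0), radius = 15),
                         law = law_gaussian(1.1, 0.4),
                         ring_law = NULL, core_law = NULL,
                         group = "neoplastic", seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L)
  if (any(grid_shape < 4L) || any(voxel_size <= 0))
    abort_validation("invalid grid: shapes must be >= 4 voxels, sizes positive")
  if (is.null(background$mean) || is.null(background$sd) ||
      background$mean < 0 || background$sd < 0)
    abort_validation("background needs non-negative `mean` and `sd`")
  if (is.null(lesion$center) || length(lesion$center) != 3L)
    abort_validation("lesion needs a length-3 world-mm `center`")
  two_shell <- !is.null(lesion$outer_radius)
  if (two_shell) {
    if (is.null(lesion$inner_radius) ||
        lesion$inner_radius <= 0 || lesion$outer_radius <= lesion$inner_radius)
      abort_validation("ring + core lesion needs 0 < inner_radius < outer_radius")
    if (is.null(ring_law) || is.null(core_law))
      abort_validation("ring + core lesion needs `ring_law` and `core_law`")
  } else {
    if (is.null(lesion$radius) || lesion$radius <= 0)
      abort_validation("lesion `radius` must be > 0")
    if (!inherits(law, "intensity_law"))
      abort_validation("`law` must be an intensity_law")
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 background = background, lesion = lesion, law = law,
                 ring_law = ring_law, core_law = core_law,
                 group = group, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Centered affine: world origin at the grid center, axes along voxel axes.
phantom_affine <- function(grid_shape, voxel_size) {
  aff <- diag(4)
  aff[1, 1] <- voxel_size[1]
  aff[2, 2] <- voxel_size[2]
  aff[3, 3] <- voxel_size[3]
  aff[1:3, 4] <- -voxel_size * (grid_shape - 1) / 2
  aff
}

#' Generate a synthetic subject from a phantom specification
#'
#' Background voxels are truncated-at-zero Gaussian; lesion voxels are drawn
#' i.i.d. from the spec's intensity law and clipped at 0 (the laws used by
#' default put negligible mass below 0, so the clip perturbs the ground-truth
#' skewness by far less than sampling error). Reference spheres are mirrored
#' to the contralateral hemisphere automatically. The same spec and seed
#' always produce bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `synthetic_subject`: `suv_volume`,
#'   `lesion_mask`, `sub_masks` (ring/core when applicable, else `NULL`),
#'   `reference_spheres`, and `truth` (`group`, `population_skewness`, the
#'   generating law).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$lesion$outer_radius))
    return(make_ring_core_phantom(spec))
  affine <- phantom_affine(spec$grid_shape, spec$voxel_size)
  proto <- list(data = array(0, dim = spec$grid_shape), affine = affine)
  lesion_sphere <- sphere_roi(spec$lesion$center, 2 * spec$lesion$radius)
  mask <- tryCatch(rasterize_sphere(lesion_sphere, proto, label = "lesion"),
                   error = function(e) {
                     if (inherits(e, "suvhist_empty_roi_error"))
                       abort_placement("lesion sphere lies outside the phantom grid")
                     stop(e)
                   })
  vals <- withr::with_seed(spec$seed, {
    bg <- stats::rnorm(prod(spec$grid_shape), spec$background$mean,
                       spec$background$sd)
    les <- draw_law(spec$law, mask$np)
    list(bg = bg, les = les)
  })
  data <- array(pmax(vals$bg, 0), dim = spec$grid_shape)
  data[mask$data] <- pmax(vals$les, 0)
  vol <- suv_volume(data, affine,
                    meta = acquisition_meta(70, 259, 1, frame = "synthetic"))
  spheres <- mirror_spheres(mask, vol)
  structure(
    list(suv_volume = vol, lesion_mask = mask, sub_masks = NULL,
         reference_spheres = spheres,
         truth = list(group = spec$group,
                      population_skewness = population_skewness(spec$law),
                      law = spec$law),
         spec = spec),
    class = "synthetic_subject"
  )
}

#' Generate a two-compartment ring + core phantom
#'
#' Emulates a ring-enhancing lesion: an outer shell of symmetric
#' (Gaussian-law) uptake around a low-mean, right-skewed (gamma-law) core.
#' The whole-lesion voxel distribution is then the volume-weighted mixture of
#' the two laws and shows a dual-peaked histogram; the sub-masks carry ring
#' and core separately so each compartment can be quantified on its own.
#'
#' @param spec a [phantom_spec()] whose `lesion` has `outer_radius` and
#'   `inner_radius` and which carries `ring_law` and `core_law`.
#' @return A `synthetic_subject` whose `sub_masks` list holds `ring` and
#'   `core`; their union is exactly the lesion mask.
#' @export
make_ring_core_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  les <- spec$lesion
  if (is.null(les$outer_radius) || is.null(les$inner_radius) ||
      les$outer_radius <= les$inner_radius)
    abort_validation("ring + core phantom needs 0 < inner_radius < outer_radius")
  affine <- phantom_affine(spec$grid_shape, spec$voxel_size)
  proto <- list(data = array(0, dim = spec$grid_shape), affine = affine)
  outer <- rasterize_sphere(sphere_roi(les$center, 2 * les$outer_radius), proto,
                            label = "lesion")
  core_data <- rasterize_sphere(sphere_roi(les$center, 2 * les$inner_radius),
                                proto, label = "core")$data
  ring_data <- outer$data & !core_data
  if (!any(ring_data) || !any(core_data))
    abort_validation("degenerate shell: ring or core contains no voxels")
  core <- binary_mask(core_data, affine, label = "core")
  ring <- binary_mask(ring_data, affine, label = "ring")

  vals <- withr::with_seed(spec$seed, {
    bg <- stats::rnorm(prod(spec$grid_shape), spec$background$mean,
                       spec$background$sd)
    ring_v <- draw_law(spec$ring_law, ring$np)
    core_v <- draw_law(spec$core_law, core$np)
    list(bg = bg, ring = ring_v, core = core_v)
  })
  data <- array(pmax(vals$bg, 0), dim = spec$grid_shape)
  data[ring$data] <- pmax(vals$ring, 0)
  data[core$data] <- pmax(vals$core, 0)
  vol <- suv_volume(data, affine,
                    meta = acquisition_meta(70, 259, 1, frame = "synthetic"))
  w <- c(ring$np, core$np) / outer$np
  law <- law_mixture(list(spec$ring_law, spec$core_law), w)
  spheres <- mirror_spheres(outer, vol)
  structure(
    list(suv_volume = vol, lesion_mask = outer,
         sub_masks = list(ring = ring, core = core),
         reference_spheres = spheres,
         truth = list(group = spec$group,
                      population_skewness = population_skewness(law),
                      law = law),
         spec = spec),
    class = "synthetic_subject"
  )
}

#' Generate a synthetic cohort of neoplastic and non-neoplastic subjects
#'
#' Builds a cohort with the group structure the analysis assumes: neoplastic
#' subjects carry symmetric Gaussian uptake (population skewness 0) and
#' non-neoplastic subjects right-skewed gamma uptake with shape jittered
#' around 4.57 (population skewness `2/sqrt(4.57)`, about 0.94). Per-subject
#' parameters get multiplicative lognormal jitter:
#' * neoplastic: `mean = 1.1 * exp(N(0, 0.2))`, `sd = 0.4 * exp(N(0, 0.3))`,
#'   placing per-subject SUVmax around 2.5 with a spread of roughly 0.5;
#' * non-neoplastic: `shape = 4.57 * exp(N(0, 0.2))`,
#'   `mean = 0.9 * exp(N(0, 0.25))`, scale set from mean and shape.
#'
#' Lesion radii are uniform on 9-20 mm (volumes of a few to ~30 mL) and lesion
#' centers are jittered a few mm in-plane. Everything derives from `seed`, so
#' cohorts are fully reproducible.
#'
#' @param n_neoplastic,n_nonneoplastic group sizes (defaults 18 and 3).
#' @param seed integer master seed.
#' @param grid_shape,voxel_size passed to [phantom_spec()].
#' @param out_dir optional directory: when given, each subject's SUV volume,
#'   lesion mask, ROI-set JSON and acquisition metadata are written as
#'   NIfTI/JSON, plus a `manifest.csv`, ready for the file-based pipeline.
#' @return An object of class `synthetic_cohort`: `subjects` (list of
#'   `synthetic_subject`) and `manifest` (data frame with subject id, group,
#'   generator parameters, ground-truth skewness and, when written, paths).
#' @export
make_cohort <- function(n_neoplastic = 18, n_nonneoplastic = 3, seed = 1L,
                        grid_shape = c(96, 96, 60), voxel_size = c(2, 2, 2),
                        out_dir = NULL) {
  if (n_neoplastic < 1 || n_nonneoplastic < 1)
    abort_validation("both group sizes must be >= 1")
  n <- n_neoplastic + n_nonneoplastic
  groups <- c(rep("neoplastic", n_neoplastic),
              rep("non-neoplastic", n_nonneoplastic))

  params <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      p <- list(
        subject_id = sprintf("S%02d", i),
        group = groups[i],
        radius = stats::runif(1, 9, 20),
        center = c(30, stats::runif(1, -8, 8), stats::runif(1, -6, 6)),
        seed = sample.int(.Machine$integer.max - 1L, 1)
      )
      if (groups[i] == "neoplastic") {
        p$law <- law_gaussian(1.1 * exp(stats::rnorm(1, 0, 0.2)),
                              0.4 * exp(stats::rnorm(1, 0, 0.3)))
      } else {
        shape <- 4.57 * exp(stats::rnorm(1, 0, 0.2))
        mean_i <- 0.9 * exp(stats::rnorm(1, 0, 0.25))
        p$law <- law_gamma(shape = shape, scale = mean_i / shape)
      }
      p
    })
  })

  subjects <- lapply(params, function(p) {
    spec <- phantom_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                         lesion = list(center = p$center, radius = p$radius),
                         law = p$law, group = p$group, seed = p$seed)
    make_phantom(spec)
  })
  names(subjects) <- vapply(params, `[[`, character(1), "subject_id")

  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    p <- params[[i]]
    data.frame(subject_id = p$subject_id, group = p$group, seed = p$seed,
               radius_mm = p$radius, law = p$law$type,
               truth_skewness = subjects[[i]]$truth$population_skewness,
               suv_path = NA_character_, roi_path = NA_character_,
               stringsAsFactors = FALSE)
  }))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      id <- manifest$subject_id[i]
      paths <- write_subject(subjects[[i]], out_dir, id)
      manifest$suv_path[i] <- paths$suv
      manifest$roi_path[i] <- paths$roi
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(subjects = subjects, manifest = manifest),
            class = "synthetic_cohort")
}

#' Write one subject's volumes and ROI set to disk
#'
#' Emits `<id>_suv.nii.gz`, `<id>_lesion.nii.gz` (plus any sub-masks),
#' an acquisition-metadata JSON sidecar, and an ROI-set JSON listing the
#' lesion mask, sub-masks and reference spheres as `[x, y, z, diameter]`.
#'
#' @param subject a `synthetic_subject` (or compatible list).
#' @param dir output directory.
#' @param id subject identifier used as filename stem.
#' @return Invisibly, a list with the `suv` and `roi` paths.
#' @export
write_subject <- function(subject, dir, id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  suv_path <- file.path(dir, paste0(id, "_suv.nii.gz"))
  write_suv_volume(subject$suv_volume, suv_path)
  meta <- subject$suv_volume$meta
  if (!is.null(meta)) {
    jsonlite::write_json(
      list(body_weight_kg = meta$body_weight,
           injected_dose_MBq = meta$injected_dose,
           decay_factor = meta$decay_factor, frame = meta$frame),
      file.path(dir, paste0(id, "_suv.json")), auto_unbox = TRUE)
  }
  lesion_path <- file.path(dir, paste0(id, "_lesion.nii.gz"))
  write_mask(subject$lesion_mask, lesion_path)
  sub_paths <- list()
  for (nm in names(subject$sub_masks)) {
    p <- file.path(dir, paste0(id, "_", nm, ".nii.gz"))
    write_mask(subject$sub_masks[[nm]], p)
    sub_paths[[nm]] <- p
  }
  roi <- list(
    lesion_mask = lesion_path,
    sub_masks = sub_paths,
    reference_spheres = lapply(subject$reference_spheres,
                               function(s) c(s$center, s$diameter))
  )
  roi_path <- file.path(dir, paste0(id, "_roi.json"))
  jsonlite::write_json(roi, roi_path, auto_unbox = TRUE, digits = NA)
  invisible(list(suv = suv_path, roi = roi_path))
}

#' Read an ROI set written by [write_subject()]
#'
#' @param path path to the ROI-set JSON.
#' @return A list with `lesion_mask` ([binary_mask()]), `sub_masks` and
#'   `reference_spheres` (list of [sphere_roi()] or the string
#'   `"auto-mirror"`).
#' @export
read_roi_set <- function(path) {
  if (!file.exists(path))
    abort_io(sprintf("cannot read ROI set: no such file '%s'", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  lesion <- read_mask(j$lesion_mask, label = "lesion")
  subs <- lapply(j$sub_masks, function(p) read_mask(p))
  for (nm in names(subs)) subs[[nm]]$label <- nm
  spheres <- if (identical(j$reference_spheres, "auto-mirror")) {
    "auto-mirror"
  } else {
    lapply(j$reference_spheres, function(s) {
      s <- as.numeric(s)
      sphere_roi(s[1:3], diameter = if (length(s) >= 4) s[4] else 10)
    })
  }
  list(lesion_mask = lesion, sub_masks = subs, reference_spheres = spheres)
}
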