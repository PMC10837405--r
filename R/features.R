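#' Histogram skewness of an ROI voxel series
#'
#' The population (divide-by-Np) third standardized moment of the SUVs inside
#' the ROI:
#' \deqn{g_1 = \frac{\frac{1}{N_p}\sum_i (X_i - \bar X)^3}
#'             {\left(\sqrt{\frac{1}{N_p}\sum_i (X_i - \bar X)^2}\right)^3}}
#' No small-sample (Fisher-Pearson) correction is applied; the biased
#' estimator is the definition used throughout. Symmetric uptake (proliferating
#' tumor) gives values near 0; left-peaked uptake with a right tail (necrosis,
#' inflammation) gives positive values.
#'
#' @param series a [voxel_series()] or bare numeric vector with Np >= 2.
#' @return Skewness (dimensionless scalar). `NaN` with a warning when the
#'   series has zero variance (skewness is undefined there, never silently 0).
#' @examples
#' suv_skewness(c(1, 2, 3))     # 0: symmetric
#' suv_skewness(c(0, 0, 0, 1))  # 2/sqrt(3)
#' @export
suv_skewness <- function(series) {
  x <- series_values(series)
  if (length(x) < 2L)
    abort_validation("skewness needs at least 2 voxels")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) {
    warning("zero variance: skewness is undefined (NaN)", call. = FALSE)
    return(NaN)
  }
  mean(xc^3) / sqrt(m2)^3
}

#' Histogram tendency of an ROI voxel series
#'
#' Tendency = SUVmean - SUVmedian, in SUV units. For a right-skewed
#' distribution the mean exceeds the median, so tendency is positive; it is 0
#' for any exactly symmetric sample. The median of an even-length series is
#' the midpoint of the two central order statistics.
#'
#' @param series a [voxel_series()] or bare numeric vector with Np >= 1.
#' @return Tendency (SUV units).
#' @examples
#' suv_tendency(c(0, 0, 0, 10))  # mean 2.5, median 0 -> 2.5
#' @export
suv_tendency <- function(series) {
  x <- series_values(series)
  mean(x) - stats::median(x)
}

series_values <- function(series) {
  if (inherits(series, "voxel_series")) return(series$values)
  x <- as.numeric(series)
  if (length(x) == 0L) abort_validation("series is empty")
  if (anyNA(x) || any(!is.finite(x)))
    abort_validation("series contains non-finite values")
  x
}

#' Traditional metabolic parameters of a lesion
#'
#' Computes the five classical PET quantifiers from the lesion voxel series
#' and a pooled normal-brain reference series:
#' * `suv_max`, `suv_mean`, `suv_median` -- max / mean / median SUV in the ROI;
#' * `mtv` -- metabolic tumor volume, `Np * voxel_volume` (mL);
#' * `tla` -- total lesion activity, `suv_mean * mtv` (mL SUV), algebraically
#'   equal to `sum(X) * voxel_volume`;
#' * `n_max`, `n_mean` -- max / mean SUV of the pooled reference voxels;
#' * `tn_ratio` -- tumor-to-normal brain ratio, `suv_max / n_max`.
#'
#' @param lesion a [voxel_series()] for the lesion ROI.
#' @param reference a [voxel_series()] pooling the reference-sphere voxels.
#' @return A named list of class `lesion_features` (without the histogram
#'   features; see [lesion_features()] for the full set).
#' @export
traditional_features <- function(lesion, reference) {
  stopifnot(inherits(lesion, "voxel_series"))
  stopifnot(inherits(reference, "voxel_series"))
  n_max <- max(reference$values)
  if (n_max <= 0)
    abort_undefined_ratio("reference Nmax is 0; T/N ratio undefined")
  mtv <- lesion$np * lesion$voxel_volume
  suv_mean <- mean(lesion$values)
  # sum(X) * voxel_volume is algebraically suv_mean * mtv but conserves
  # total activity exactly in floating point
  structure(
    list(
      suv_max = max(lesion$values),
      suv_mean = suv_mean,
      suv_median = stats::median(lesion$values),
      mtv = mtv,
      tla = sum(lesion$values) * lesion$voxel_volume,
      n_max = n_max,
      n_mean = mean(reference$values),
      tn_ratio = max(lesion$values) / n_max,
      np = lesion$np
    ),
    class = "lesion_features"
  )
}

#' Full feature set of a lesion: traditional plus histogram parameters
#'
#' Adds `skewness` and `tendency` to [traditional_features()]. These two are
#' always computed from the raw voxel series, never from binned histogram
#' counts, so the histogram bin width cannot affect them.
#'
#' @inheritParams traditional_features
#' @return A `lesion_features` list with all ten parameters.
#' @export
lesion_features <- function(lesion, reference) {
  f <- traditional_features(lesion, reference)
  f$skewness <- suv_skewness(lesion)
  f$tendency <- suv_tendency(lesion)
  f
}

#' @export
print.lesion_features <- function(x, ...) {
  cat("<lesion_features>\n")
  fmt <- function(v) formatC(v, digits = 4, format = "g")
  for (nm in names(x))
    cat(sprintf("  %-10s %s\n", nm, fmt(x[[nm]])))
  invisible(x)
}

#' Visualization histogram of a voxel series
#'
#' Bins the SUVs over a fixed display range (default `[0, 4]`, matching the
#' clean-background, moderate-uptake regime of amino-acid brain PET) with
#' uniform bins. Values outside the range are accumulated into the terminal
#' bins with a warning, so counts always conserve Np. A Gaussian reference
#' curve (`normal_fit`) records the series mean and population SD -- the
#' overlay used to judge visually whether uptake looks normally distributed.
#'
#' @param series a [voxel_series()] or numeric vector.
#' @param bins number of bins (>= 2); default 64. A display knob only: the
#'   skewness/tendency statistics never touch binned counts.
#' @param range length-2 numeric display range.
#' @return An object of class `suv_histogram` with `bin_edges` (length
#'   `bins + 1`), `counts` (length `bins`) and `normal_fit` (`mu`, `sigma`).
#' @export
suv_histogram <- function(series, bins = 64, range = c(0, 4)) {
  x <- series_values(series)
  if (!is.numeric(bins) || length(bins) != 1L || bins < 2)
    abort_validation("`bins` must be a single number >= 2")
  bins <- as.integer(bins)
  range <- sort(as.numeric(range))
  edges <- seq(range[1], range[2], length.out = bins + 1L)
  n_out <- sum(x < range[1] | x > range[2])
  if (n_out > 0)
    warning(sprintf("%d voxel(s) outside [%g, %g] accumulated into terminal bins",
                    n_out, range[1], range[2]), call. = FALSE)
  clamped <- pmin(pmax(x, range[1]), range[2])
  idx <- findInterval(clamped, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  structure(
    list(bin_edges = edges, counts = counts,
         normal_fit = list(mu = mean(x), sigma = sqrt(mean((x - mean(x))^2)))),
    class = "suv_histogram"
  )
}

#' @export
print.suv_histogram <- function(x, ...) {
  cat(sprintf("<suv_histogram> %d bins on [%g, %g], %d voxels, fit N(%.3g, %.3g)\n",
              length(x$counts), x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              sum(x$counts), x$normal_fit$mu, x$normal_fit$sigma))
  invisible(x)
}

#' Export a histogram as a data frame
#'
#' @param hist an [suv_histogram()].
#' @return A data frame with columns `bin_left`, `bin_right`, `count`.
#' @export
histogram_table <- function(hist) {
  stopifnot(inherits(hist, "suv_histogram"))
  nb <- length(hist$counts)
  data.frame(bin_left = hist$bin_edges[-(nb + 1L)],
             bin_right = hist$bin_edges[-1L],
             count = hist$counts)
}
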