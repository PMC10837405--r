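#' Threshold rule for neoplastic vs non-neoplastic classification
#'
#' A lesion feature votes "non-neoplastic" when its value strictly exceeds its
#' threshold (a value exactly at the threshold is called neoplastic; the tie
#' convention is deliberate and documented here). The default thresholds,
#' skewness 0.624 and tendency 0.084 SUV, are published clinical calibration
#' constants for amino-acid PET histogram analysis; they are configuration,
#' not quantities this package derives (see [derive_threshold()] for candidate
#' derivations from your own cohort).
#'
#' The default combine mode is `skewness_only`: the two features can disagree
#' (a central-necrosis region can show high skewness with tendency still below
#' threshold), and skewness is the primary discriminator. The other modes are
#' exposed for sensitivity analysis.
#'
#' @param skewness_threshold skewness cut (dimensionless), default 0.624.
#' @param tendency_threshold tendency cut (SUV), default 0.084.
#' @param combine one of `"skewness_only"`, `"tendency_only"`, `"either"`,
#'   `"both"` -- how per-feature votes are merged into a label.
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(skewness_threshold = 0.624,
                                tendency_threshold = 0.084,
                                combine = c("skewness_only", "tendency_only",
                                            "either", "both")) {
  combine <- match.arg(combine)
  for (v in c(skewness_threshold, tendency_threshold))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      abort_validation("thresholds must be single finite numbers")
  structure(list(skewness_threshold = skewness_threshold,
                 tendency_threshold = tendency_threshold,
                 combine = combine),
            class = "classification_rule")
}

#' Classify one lesion from its histogram features
#'
#' @param features a `lesion_features` object, or any list/row with `skewness`
#'   and `tendency` entries.
#' @param rule a [classification_rule()].
#' @return A list of class `classification` with `label` (`"neoplastic"`,
#'   `"non-neoplastic"`, or `"abstained"` when the deciding feature is
#'   undefined) and `votes`, the per-feature calls (always reported, also when
#'   discordant).
#' @examples
#' classify_lesion(list(skewness = 0.721, tendency = 0.109))  # non-neoplastic
#' classify_lesion(list(skewness = -0.043, tendency = -0.017))  # neoplastic
#' @export
classify_lesion <- function(features, rule = classification_rule()) {
  stopifnot(inherits(rule, "classification_rule"))
  sk <- as.numeric(features[["skewness"]])
  td <- as.numeric(features[["tendency"]])
  vote <- function(value, threshold) {
    if (length(value) != 1L || is.na(value)) return(NA_character_)
    if (value > threshold) "non-neoplastic" else "neoplastic"
  }
  votes <- c(skewness = vote(sk, rule$skewness_threshold),
             tendency = vote(td, rule$tendency_threshold))
  needed <- switch(rule$combine,
                   skewness_only = votes["skewness"],
                   tendency_only = votes["tendency"],
                   votes)
  label <- if (anyNA(needed)) {
    "abstained"
  } else {
    switch(rule$combine,
           skewness_only = unname(votes["skewness"]),
           tendency_only = unname(votes["tendency"]),
           either = if (any(needed == "non-neoplastic")) "non-neoplastic"
                    else "neoplastic",
           both = if (all(needed == "non-neoplastic")) "non-neoplastic"
                  else "neoplastic")
  }
  structure(list(label = label, votes = votes, rule = rule),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification> %s (skewness: %s, tendency: %s; combine = %s)\n",
              x$label, x$votes["skewness"], x$votes["tendency"],
              x$rule$combine))
  invisible(x)
}

#' Compare feature distributions between two diagnostic groups
#'
#' For each feature column, reports group means and sample (n-1) standard
#' deviations -- the "mean +/- SD" convention of clinical tables -- together
#' with two-sided p-values from both the Wilcoxon rank-sum test (exact when
#' the pooled n is <= 25 and the data are tie-free, otherwise the normal
#' approximation with tie correction) and Welch's unequal-variance t test.
#' Both tests are always reported side by side so the reader can judge the
#' parametric assumption rather than trusting a single choice.
#'
#' @param data data frame with a group column and numeric feature columns.
#' @param features character vector of feature column names; default all
#'   numeric columns except the group column.
#' @param group_col name of the group column (must have exactly 2 levels).
#' @return A data frame of class `group_comparison`, one row per feature:
#'   `feature`, `mean_<A>`, `sd_<A>`, `n_<A>`, likewise for B,
#'   `rank_sum_p`, `t_test_p`.
#' @export
compare_groups <- function(data, features = NULL, group_col = "group") {
  data <- as.data.frame(data)
  if (!group_col %in% names(data))
    abort_validation(sprintf("no '%s' column in `data`", group_col))
  grp <- as.character(data[[group_col]])
  levels <- sort(unique(grp))
  if (length(levels) != 2L)
    abort_validation(sprintf("need exactly 2 groups, found %d", length(levels)))
  if (is.null(features)) {
    features <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                        group_col)
  }
  if (length(features) == 0L)
    abort_validation("no numeric feature columns to compare")

  rows <- lapply(features, function(f) {
    a <- data[[f]][grp == levels[1]]
    b <- data[[f]][grp == levels[2]]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    n_tot <- length(a) + length(b)
    rs <- tryCatch(
      suppressWarnings(stats::wilcox.test(a, b, exact = n_tot <= 25))$p.value,
      error = function(e) NA_real_)
    tt <- tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
                   error = function(e) NA_real_)
    out <- data.frame(feature = f,
                      mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                      mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                      rank_sum_p = rs, t_test_p = tt)
    out
  })
  res <- do.call(rbind, rows)
  names(res) <- c("feature",
                  paste0(c("mean_", "sd_", "n_"), levels[1]),
                  paste0(c("mean_", "sd_", "n_"), levels[2]),
                  "rank_sum_p", "t_test_p")
  attr(res, "groups") <- levels
  class(res) <- c("group_comparison", "data.frame")
  res
}

#' Derive a candidate classification threshold from two groups
#'
#' The origin of published clinical thresholds is often unstated; this
#' function implements two transparent candidates so any threshold used can
#' be reproduced from patient-level values:
#' * `midpoint_of_means`: the arithmetic midpoint of the two group means.
#'   Computable from summary statistics alone.
#' * `youden`: the cut maximizing the empirical Youden index
#'   (sensitivity + specificity - 1) over the observed values, calling the
#'   higher-mean group positive when `value >= cut`; among ties the smallest
#'   such cut is returned (the boundary sits at the lowest positive value that
#'   achieves the optimum). Needs patient-level values.
#'
#' Neither candidate is guaranteed to reproduce a threshold derived elsewhere
#' by an unreported method; [run_cohort()] flags that explicitly in its report.
#'
#' @param values numeric vector of feature values.
#' @param groups group label per value (exactly 2 levels).
#' @param method `"midpoint_of_means"` or `"youden"`.
#' @return The threshold (scalar), with attributes `method` and (for youden)
#'   `youden_index`. Warns when the groups are indistinguishable.
#' @export
derive_threshold <- function(values, groups,
                             method = c("midpoint_of_means", "youden")) {
  method <- match.arg(method)
  values <- as.numeric(values)
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- groups[ok]
  levels <- sort(unique(groups))
  if (length(levels) != 2L)
    abort_validation("threshold derivation needs exactly 2 non-empty groups")
  means <- vapply(levels, function(g) mean(values[groups == g]), numeric(1))

  if (method == "midpoint_of_means") {
    if (isTRUE(all.equal(unname(means[1]), unname(means[2]))))
      warning("group means coincide: threshold is degenerate", call. = FALSE)
    thr <- mean(means)
    return(structure(thr, method = method))
  }

  pos <- levels[which.max(means)]
  is_pos <- groups == pos
  cuts <- sort(unique(values))
  j <- vapply(cuts, function(cut) {
    sens <- mean(values[is_pos] >= cut)
    spec <- mean(values[!is_pos] < cut)
    sens + spec - 1
  }, numeric(1))
  best <- max(j)
  if (best <= 0)
    warning("group distributions are indistinguishable: threshold is degenerate",
            call. = FALSE)
  thr <- cuts[which(j == best)[1]]
  structure(thr, method = method, youden_index = best)
}
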