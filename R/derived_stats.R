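#' Limit-of-detection filter
#'
#' Retains measurements strictly greater than three times the limit of
#' detection; values at exactly 3 x LOD are dropped (the retention rule
#' is "above", not "at or above").
#'
#' @param values Numeric vector of measurements.
#' @param lod Limit of detection (> 0), same units as `values`.
#' @return The retained values.  An empty result is returned with a
#'   warning flagging the sample for exclusion.
#' @export
lod_filter <- function(values, lod) {
  if (!is.numeric(lod) || lod <= 0) abort("`lod` must be > 0.")
  kept <- values[values > 3 * lod]
  if (length(kept) == 0L && length(values) > 0L) {
    warn("all values at or below 3 x LOD; sample flagged for exclusion.")
  }
  kept
}

#' Mean Cu:Zn ratio of replicate metal measurements
#'
#' Applies the 3 x LOD retention rule to the copper and zinc counts of
#' each replicate, computes the per-replicate Cu/Zn ratio on replicates
#' where both channels survive, and returns the mean and sample standard
#' deviation of those ratios (mean-of-ratios; the sd of ratios requires
#' per-replicate ratios).  `method = "ratio_of_means"` instead divides
#' the mean retained copper by the mean retained zinc, with `sd_ratio`
#' reported as `NA`.
#'
#' A fully metallated dimer carries two copper and two zinc ions, so
#' noise-free replicates at that stoichiometry give a ratio of exactly 1.
#'
#' @param reps Data frame with numeric columns `cu` and `zn` (one row per
#'   replicate).
#' @param lod_cu,lod_zn Limits of detection; `NULL` disables the filter
#'   for that channel.
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return A one-row tibble with `mean_ratio`, `sd_ratio` and `n_used`.
#' @examples
#' cu_zn_ratio(data.frame(cu = c(2, 4, 6), zn = c(2, 4, 6)))
#' @export
cu_zn_ratio <- function(reps, lod_cu = NULL, lod_zn = NULL,
                        method = c("mean_of_ratios", "ratio_of_means")) {
  method <- match.arg(method)
  if (!all(c("cu", "zn") %in% names(reps))) abort("`reps` needs columns `cu` and `zn`.")
  keep <- rep(TRUE, nrow(reps))
  if (!is.null(lod_cu)) keep <- keep & reps$cu > 3 * lod_cu
  if (!is.null(lod_zn)) keep <- keep & reps$zn > 3 * lod_zn
  reps <- reps[keep, ]
  if (nrow(reps) == 0L) abort("no replicate survives the 3 x LOD filter on both channels.")
  zero_zn <- reps$zn == 0
  if (any(zero_zn)) {
    warn(sprintf("%d replicate(s) with zero zinc excluded from the ratio.", sum(zero_zn)))
    reps <- reps[!zero_zn, ]
  }
  if (nrow(reps) == 0L) abort("no usable replicate after excluding zero-zinc rows.")
  if (method == "mean_of_ratios") {
    r <- reps$cu / reps$zn
    tibble(mean_ratio = mean(r),
           sd_ratio = if (length(r) > 1) sd(r) else 0,
           n_used = length(r))
  } else {
    tibble(mean_ratio = mean(reps$cu) / mean(reps$zn),
           sd_ratio = NA_real_, n_used = nrow(reps))
  }
}

#' Dopamine turnover
#'
#' The ratio of the dopamine metabolite homovanillic acid (HVA) to
#' dopamine, an index of dopaminergic activity.
#'
#' @param hva HVA level (ng/mg protein).
#' @param dopamine Dopamine level (ng/mg protein, > 0).
#' @return `hva / dopamine` (dimensionless); vectorized.
#' @export
turnover <- function(hva, dopamine) {
  if (any(dopamine <= 0)) abort("`dopamine` must be > 0.")
  hva / dopamine
}

#' Proportion of alpha-synuclein phosphorylated at S129
#'
#' @param ps129 Phosphorylated S129 alpha-synuclein (ng/mg total protein).
#' @param total Total alpha-synuclein (ng/mg total protein, > 0).
#' @return `100 * ps129 / total`, a percentage; vectorized.
#' @export
ps129_percent <- function(ps129, total) {
  if (any(total <= 0)) abort("`total` must be > 0.")
  100 * ps129 / total
}

#' Enzymatic activity per unit protein
#'
#' Normalizes a total activity measurement to the amount of the protein
#' responsible for it, yielding activity per unit protein.
#'
#' @param total_activity Total measured activity.
#' @param protein_level Protein level (> 0), same sample.
#' @return `total_activity / protein_level`; vectorized.
#' @export
activity_per_unit <- function(total_activity, protein_level) {
  if (any(protein_level <= 0)) abort("`protein_level` must be > 0.")
  total_activity / protein_level
}

#' Neuron density and percent of a reference density
#'
#' Density is the neuron count divided by the region volume; the percent
#' measure expresses a density relative to a reference mean (for example
#' the age-matched control average), and is invariant to a common change
#' of volume units.
#'
#' @param count Neuron count (>= 0).
#' @param region_volume Region volume (> 0), any volume unit.
#' @return `neuron_density()` returns neurons per unit volume.
#' @export
neuron_density <- function(count, region_volume) {
  if (any(region_volume <= 0)) abort("`region_volume` must be > 0.")
  count / region_volume
}

#' @rdname neuron_density
#' @param density A density from [neuron_density()].
#' @param reference_mean Reference mean density (> 0), same units.
#' @return `percent_of_reference()` returns `100 * density / reference_mean`.
#' @export
percent_of_reference <- function(density, reference_mean) {
  if (any(reference_mean <= 0)) abort("`reference_mean` must be > 0.")
  100 * density / reference_mean
}

#' Cronbach's alpha for interrater reliability
#'
#' Treats each rater as an "item" of a reliability scale over the rated
#' images: `alpha = k / (k - 1) * (1 - sum_i s2_i / s2_T)`, where `k` is
#' the number of raters, `s2_i` the sample variance of rater `i`'s scores
#' over items and `s2_T` the sample variance of the per-item totals.
#' Alpha is at most 1, equals 1 exactly when all raters' score vectors
#' are identical up to additive constants, and is undefined when the
#' per-item totals have zero variance.
#'
#' @param scores Numeric matrix or data frame, raters in rows and rated
#'   items in columns (>= 2 raters, >= 2 items, finite entries).
#' @return An object of class `cronbach_alpha`: a list with `alpha`,
#'   `n_raters` and `n_items`.  `tidy()` and `glance()` methods return
#'   one-row tibbles.
#' @examples
#' cronbach_alpha(rbind(c(1, 2, 3), c(2, 4, 6)))
#' @export
cronbach_alpha <- function(scores) {
  m <- as.matrix(scores)
  if (nrow(m) < 2L || ncol(m) < 2L) abort("need >= 2 raters and >= 2 items.")
  if (any(!is.finite(m))) abort("scores must be finite.")
  k <- nrow(m)
  s2_i <- apply(m, 1, var)
  s2_t <- var(colSums(m))
  if (s2_t == 0) abort("zero total-score variance: alpha undefined.")
  structure(list(alpha = k / (k - 1) * (1 - sum(s2_i) / s2_t),
                 n_raters = k, n_items = ncol(m)),
            class = "cronbach_alpha")
}

#' @export
print.cronbach_alpha <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.4f (%d raters, %d items)\n",
              x$alpha, x$n_raters, x$n_items))
  invisible(x)
}

#' @rdname cronbach_alpha
#' @param x A `cronbach_alpha` object.
#' @param ... Unused.
#' @export
tidy.cronbach_alpha <- function(x, ...) {
  tibble(alpha = x$alpha, n_raters = x$n_raters, n_items = x$n_items)
}

#' @rdname cronbach_alpha
#' @export
glance.cronbach_alpha <- function(x, ...) tidy(x)

#' Exclude extreme values by the 3 x IQR fence rule
#'
#' Flags values at or beyond `Q3 + 3 * IQR` / `Q1 - 3 * IQR` as extreme
#' and splits them from the retained values.  Quartiles use linear
#' interpolation between order statistics (the default convention of
#' [stats::quantile()], type 7), which makes the fences reproducible.
#' When the IQR is zero the fences collapse onto the quartiles and
#' values equal to the fence are retained, so a constant sample loses
#' nothing.  The rule is idempotent.  An alternative rule excluding
#' values beyond `k` standard deviations of the mean is available via
#' `rule = "sd"`.
#'
#' @param values Numeric vector; with fewer than 4 values the data pass
#'   through unchanged with a warning (quartiles are not meaningful).
#' @param rule `"iqr"` (default) or `"sd"`.
#' @param k Fence multiplier: 3 for the IQR rule, 2 for the sd rule.
#' @return A list with `retained` and `excluded` numeric vectors and the
#'   `fences` used.
#' @examples
#' exclude_outliers(c(1, 2, 3, 4, 100))
#' @export
exclude_outliers <- function(values, rule = c("iqr", "sd"), k = NULL) {
  rule <- match.arg(rule)
  if (length(values) < 4L) {
    warn("fewer than 4 values: quartiles not meaningful, passing data through.")
    return(list(retained = values, excluded = numeric(0),
                fences = c(-Inf, Inf)))
  }
  if (rule == "iqr") {
    if (is.null(k)) k <- 3
    q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    fences <- c(q[1] - k * iqr, q[2] + k * iqr)
    out <- if (iqr > 0) values <= fences[1] | values >= fences[2]
           else values < fences[1] | values > fences[2]
  } else {
    if (is.null(k)) k <- 2
    m <- mean(values); s <- sd(values)
    fences <- c(m - k * s, m + k * s)
    out <- values < fences[1] | values > fences[2]
  }
  list(retained = values[!out], excluded = values[out], fences = fences)
}
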