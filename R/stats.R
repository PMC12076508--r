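# Descriptive statistics for optical-rotation distributions: z-filtered
# moment summaries, the heavy-tail outlier census, and the correlation
# between R/S configuration and rotation sign.

#' Filtered distribution summary
#'
#' Removes values with |z| > `z_cut` in a single pass (z-scores computed
#' once from the unfiltered mean and standard deviation) and reports the
#' first four moments of the remainder. Skewness is the standardized third
#' moment `m3 / m2^(3/2)` and kurtosis is reported in the excess (Fisher)
#' convention `m4 / m2^2 - 3`, so a normal distribution scores near 0.
#'
#' @param values Numeric vector (e.g. specific rotations in degrees).
#' @param z_cut Outlier threshold in unfiltered standard deviations;
#'   `Inf` disables filtering.
#' @param wavelength,class_tag Optional labels carried into the summary.
#' @return List of class `distribution_summary`: `n_used`, `n_filtered`,
#'   `mean`, `sd`, `skewness`, `kurtosis`, plus the tags.
#' @export
describe_rotations <- function(values, z_cut = 3, wavelength = NA,
                               class_tag = NA) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("values must be finite")
  n0 <- length(values)
  if (is.finite(z_cut)) {
    mu0 <- mean(values)
    sd0 <- stats::sd(values)
    if (!is.finite(sd0) || sd0 == 0) {
      stop("zero variance: z-scores (and higher moments) are undefined")
    }
    keep <- abs((values - mu0) / sd0) <= z_cut
    values <- values[keep]
  }
  n <- length(values)
  if (n < 4L) stop("fewer than 4 values after filtering; ",
                   "kurtosis is undefined")
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 == 0) stop("zero variance after filtering; ",
                    "skewness/kurtosis are undefined")
  structure(list(n_used = n, n_filtered = n0 - n,
                 mean = m, sd = stats::sd(values),
                 skewness = mean(d^3) / m2^1.5,
                 kurtosis = mean(d^4) / m2^2 - 3,
                 wavelength = wavelength, class_tag = class_tag),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "distribution summary%s%s: n = %d (%d filtered), mean %.4g, sd %.4g, skewness %.4g, excess kurtosis %.4g\n",
    if (!is.na(x$class_tag)) paste0(" class ", x$class_tag) else "",
    if (!is.na(x$wavelength)) paste0(" @ ", x$wavelength, " nm") else "",
    x$n_used, x$n_filtered, x$mean, x$sd, x$skewness, x$kurtosis))
  invisible(x)
}

#' Summary table over classes and wavelengths
#'
#' Applies [describe_rotations()] to every class/wavelength combination of
#' a record list and returns one row per combination, mirroring the usual
#' rotation-distribution summary layout.
#'
#' @param records List of records with `rotations` and `n_centers`.
#' @param classes Stereocenter counts to summarize.
#' @param wavelengths Wavelength tags to summarize (names of `rotations`).
#' @param z_cut Passed to [describe_rotations()].
#' @return Data frame with columns class, wavelength, n_used, n_filtered,
#'   mean, sd, skewness, kurtosis.
#' @export
rotation_summary_table <- function(records, classes = c(0, 1),
                                   wavelengths = c("355", "589.3", "633"),
                                   z_cut = 3) {
  rows <- list()
  n_centers <- vapply(records, function(r) as.numeric(r$n_centers),
                      numeric(1))
  for (cl in classes) {
    for (wl in wavelengths) {
      v <- vapply(records[n_centers == cl],
                  function(r) r$rotations[[wl]], numeric(1))
      s <- describe_rotations(v, z_cut = z_cut, wavelength = wl,
                              class_tag = cl)
      rows[[length(rows) + 1L]] <-
        data.frame(class = cl, wavelength = wl, n_used = s$n_used,
                   n_filtered = s$n_filtered, mean = s$mean, sd = s$sd,
                   skewness = s$skewness, kurtosis = s$kurtosis)
    }
  }
  do.call(rbind, rows)
}

#' Outlier census of a rotation distribution
#'
#' @param values Numeric vector.
#' @param threshold Absolute-value threshold (degrees).
#' @return List with `fraction` (share of |value| > threshold) and
#'   `max_abs`.
#' @export
outlier_census <- function(values, threshold = 1000) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must be nonempty")
  list(fraction = mean(abs(values) > threshold),
       max_abs = max(abs(values)))
}

#' Correlation between R/S configuration and rotation sign
#'
#' Encodes labels as +1 (R) / -1 (S) and rotations by their sign, then
#' returns the Pearson correlation of the two sign vectors with the
#' standard two-sided test for non-correlation. Zero-valued rotations are
#' excluded (their count is reported).
#'
#' @param labels Character vector of `"R"`/`"S"` labels.
#' @param rotations Signed numeric vector, same length.
#' @return List with `r`, `p_value`, `n_used`, `n_zero_excluded`.
#' @export
label_sign_correlation <- function(labels, rotations) {
  if (length(labels) != length(rotations)) {
    stop("labels and rotations must have the same length")
  }
  if (!all(labels %in% c("R", "S"))) stop("labels must be 'R' or 'S'")
  keep <- is.finite(rotations) & rotations != 0
  x <- ifelse(labels[keep] == "R", 1, -1)
  y <- sign(rotations[keep])
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    # a constant vector has no defined correlation
    return(list(r = NA_real_, p_value = NA_real_, n_used = length(x),
                n_zero_excluded = sum(!keep)))
  }
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n_used = length(x),
       n_zero_excluded = sum(!keep))
}
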