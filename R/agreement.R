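#' Bland-Altman agreement between two instruments
#'
#' Summarises paired measurements from a reference instrument and a
#' candidate instrument by the mean difference (bias), the sample SD of
#' the differences, and the limits of agreement at mean +/- 1.96 SD --
#' the interval expected to contain about 95% of differences. Differences
#' are taken as candidate - reference.
#'
#' The 1.96 multiplier is fixed (no small-sample t correction) and the SD
#' uses the n - 1 denominator.
#'
#' @param reference Numeric vector of reference-instrument forces (gf), or
#'   a data frame with columns `reference_gf` and `measured_gf` (as
#'   returned by [generate_pairs()] or [read_pairs_csv()]).
#' @param candidate Numeric vector of candidate-instrument forces, same
#'   length; ignored when `reference` is a data frame.
#'
#' @return An object of class `"agreement_result"`: `n`,
#'   `mean_difference`, `sd_difference`, `loa_lower`, `loa_upper` (gf) and
#'   `table`, a plot-ready data frame of pair means and differences.
#'
#' @examples
#' ba <- bland_altman(c(10, 20, 30), c(10.2, 20.1, 30.4))
#' ba$mean_difference
#' @export
bland_altman <- function(reference, candidate = NULL) {
  if (is.data.frame(reference)) {
    if (!all(c("reference_gf", "measured_gf") %in% names(reference)))
      stop("data frame input needs columns reference_gf and measured_gf",
           call. = FALSE)
    candidate <- reference$measured_gf
    reference <- reference$reference_gf
  }
  stopifnot(is.numeric(reference), is.numeric(candidate))
  if (length(reference) != length(candidate))
    stop("reference and candidate must have the same length", call. = FALSE)
  n <- length(reference)
  if (n < 2L) stop("at least two pairs are required", call. = FALSE)
  if (any(!is.finite(reference)) || any(!is.finite(candidate)))
    stop("measurements must be finite", call. = FALSE)
  d <- candidate - reference
  md <- mean(d)
  s <- stats::sd(d)
  structure(list(
    n = n,
    mean_difference = md,
    sd_difference = s,
    loa_lower = md - 1.96 * s,
    loa_upper = md + 1.96 * s,
    table = data.frame(mean_gf = (reference + candidate) / 2,
                       difference_gf = d)
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Bland-Altman agreement (candidate - reference), n = %d\n",
    "  bias = %.4f gf, SD = %.4f gf\n",
    "  limits of agreement: [%.4f, %.4f] gf\n"),
    x$n, x$mean_difference, x$sd_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Per-reference-point summary statistics
#'
#' Mean and sample SD of repeated measurements at each reference point
#' (e.g. thirty bench repeats at 6, 10, 15, ... gf). Groups are reported
#' in order of first appearance.
#'
#' @param values Numeric vector of measurements (gf).
#' @param group Grouping key per measurement (reference point), same
#'   length.
#'
#' @return A data frame with columns `group`, `n`, `mean`, `sd`.
#'
#' @examples
#' reference_point_summary(c(11.2, 11.3, 11.4, 16.6, 16.8),
#'                         c(10, 10, 10, 15, 15))
#' @export
reference_point_summary <- function(values, group) {
  stopifnot(is.numeric(values), length(values) == length(group))
  if (length(values) == 0L) stop("no measurements", call. = FALSE)
  groups <- unique(group)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0)
  }))
  rownames(out) <- NULL
  out
}

#' Mean relative error of candidate vs reference
#'
#' Mean over pairs of 100 * |candidate - reference| / reference, in
#' percent. Scale-invariant; zero (or negative) reference values are a
#' domain error.
#'
#' @inheritParams bland_altman
#' @return Mean relative error in percent.
#'
#' @examples
#' mean_relative_error(c(10, 20), c(10.1, 19.8))  # 1.0
#' @export
mean_relative_error <- function(reference, candidate = NULL) {
  if (is.data.frame(reference)) {
    candidate <- reference$measured_gf
    reference <- reference$reference_gf
  }
  stopifnot(is.numeric(reference), is.numeric(candidate),
            length(reference) == length(candidate))
  if (any(reference == 0))
    stop("reference values must be non-zero", call. = FALSE)
  mean(100 * abs(candidate - reference) / reference)
}
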