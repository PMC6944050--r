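#' Distance sample from a query set to one class
#'
#' Measures the distance from a query sequence-set to every member of a
#' labeled class, giving a sample of distance values whose summary
#' statistics drive the decision rules: sample mean (xi-hat), sample
#' variance (theta-hat, divisor n - 1, zero for a single member),
#' minimum, and median (even-length samples average the two middle order
#' statistics).
#'
#' @param query A [seq_set()].
#' @param class A [seq_collection()] (nonempty).
#' @inheritParams cov_of_set
#' @return An object of class `distance_sample`: list with
#'   `class_label`, `values` (named by member set ids, in class order),
#'   `mean`, `variance`, `min`, `median`, `n`.
#' @export
distance_sample <- function(query, class, words = one_grams(dna_alphabet()),
                            phi = phi_identity(), centered = TRUE) {
  stopifnot(inherits(query, "seq_set"), inherits(class, "seq_collection"))
  psi_q <- cov_of_set(query, words = words, phi = phi, centered = centered)
  vals <- vapply(class$sets, function(s) {
    delta(psi_q, cov_of_set(s, words = words, phi = phi, centered = centered))$value
  }, numeric(1L))
  names(vals) <- vapply(class$sets, `[[`, character(1L), "set_id")
  new_distance_sample(class$label, vals)
}

new_distance_sample <- function(label, vals) {
  n <- length(vals)
  structure(list(
    class_label = label,
    values = vals,
    mean = mean(vals),
    variance = if (n >= 2L) stats::var(vals) else 0,
    min = min(vals),
    median = stats::median(vals),
    n = n
  ), class = "distance_sample")
}

#' @export
print.distance_sample <- function(x, ...) {
  cat(sprintf("<distance_sample> class '%s': n=%d mean=%g var=%g min=%g median=%g\n",
              x$class_label, x$n, x$mean, x$variance, x$min, x$median))
  invisible(x)
}

#' Classify a query sequence-set against labeled classes
#'
#' Nearest-class rule on the distance samples: the query is labeled with
#' the class minimizing the chosen statistic (mean, min, or median) of
#' its distance sample. The mean rule is the recommended default: the
#' sample mean has variance theta/n, below the variance of the median or
#' minimum, and is a consistent (and, under normality, sufficient)
#' estimator of the class's expected distance. Ties within 1e-12 go to
#' the first class in input order, with `tie = TRUE`.
#'
#' @param query A [seq_set()].
#' @param classes List of >= 2 [seq_collection()] objects.
#' @param rule Decision statistic: `"mean"` (default), `"min"`, or
#'   `"median"`.
#' @inheritParams cov_of_set
#' @return An object of class `classification_result`: list with
#'   `query_id`, `rule`, `per_class` (list of [distance_sample()]),
#'   `label`, `tie`, `statistics` (named per-class rule values).
#' @export
classify_seqset <- function(query, classes, rule = c("mean", "min", "median"),
                            words = one_grams(dna_alphabet()),
                            phi = phi_identity(), centered = TRUE) {
  rule <- match.arg(rule)
  if (!is.list(classes) || length(classes) < 2L) {
    stop("need >= 2 classes for classification")
  }
  samples <- lapply(classes, distance_sample, query = query,
                    words = words, phi = phi, centered = centered)
  stats_ <- vapply(samples, `[[`, numeric(1L), rule)
  names(stats_) <- vapply(samples, `[[`, character(1L), "class_label")
  best <- which.min(stats_)
  tie <- sum(stats_ - stats_[best] <= 1e-12) >= 2L
  structure(list(
    query_id = query$set_id,
    rule = rule,
    per_class = samples,
    statistics = stats_,
    label = names(stats_)[best],
    tie = tie
  ), class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> query '%s' -> '%s' (rule=%s%s)\n",
              x$query_id, x$label, x$rule, if (x$tie) ", TIE" else ""))
  print(round(x$statistics, 6))
  invisible(x)
}

#' Monte-Carlo variance of the mean/min/median decision statistics
#'
#' Draws `reps` samples of size `n` from a normal distribution with mean
#' `xi` and variance `vartheta`, records the three decision statistics
#' for each, and reports their empirical variances next to the exact
#' variance `vartheta / n` of the sample mean. For normal samples the
#' mean's variance is the smallest (the median's is asymptotically
#' `pi * vartheta / (2 n)`), which is why the mean rule is preferred.
#'
#' @param xi,vartheta Mean and variance (>= 0) of the distance
#'   distribution.
#' @param n Sample size per replicate (>= 2).
#' @param reps Number of replicates (>= 100).
#' @param seed Integer seed.
#' @return A data.frame with columns `rule`, `empirical_variance`, and
#'   `theoretical_variance` (`vartheta / n` for the mean, `NA`
#'   otherwise).
#' @examples
#' rule_variance_experiment(xi = 5, vartheta = 1, n = 30, reps = 1000, seed = 1)
#' @export
rule_variance_experiment <- function(xi, vartheta, n, reps = 10000L, seed) {
  stopifnot(is.numeric(xi), length(xi) == 1L,
            is.numeric(vartheta), length(vartheta) == 1L, vartheta >= 0,
            n >= 2L, reps >= 100L)
  set.seed(as.integer(seed))
  draws <- matrix(stats::rnorm(reps * n, mean = xi, sd = sqrt(vartheta)),
                  nrow = reps, ncol = n)
  stat_mean <- rowMeans(draws)
  stat_min <- apply(draws, 1L, min)
  stat_median <- apply(draws, 1L, stats::median)
  data.frame(
    rule = c("mean", "min", "median"),
    empirical_variance = c(stats::var(stat_mean), stats::var(stat_min),
                           stats::var(stat_median)),
    theoretical_variance = c(vartheta / n, NA_real_, NA_real_)
  )
}

#' Chebyshev consistency bound for the decision rules
#'
#' Lower bound on the probability that the decision statistic falls
#' within `rho` of its expectation: `1 - vartheta / (n * rho^2)` for the
#' mean rule, `1 - vartheta / rho^2` for the min and median rules (the
#' comparison form used for those order statistics; it is not sharpened
#' for them). Only the mean rule's bound tends to 1 as the class grows,
#' which is the consistency argument for preferring it. The raw bound is
#' returned and may be negative (vacuous).
#'
#' @param vartheta Variance of the distance distribution (>= 0).
#' @param n Class size (positive integer; used by the mean rule).
#' @param rho Half-width of the interval, > 0.
#' @param rule `"mean"`, `"min"`, or `"median"`.
#' @return The bound, a real number <= 1.
#' @examples
#' chebyshev_bound(1, 100, 1, "mean")  # 0.99
#' @export
chebyshev_bound <- function(vartheta, n, rho, rule = c("mean", "min", "median")) {
  rule <- match.arg(rule)
  stopifnot(is.numeric(vartheta), vartheta >= 0, n >= 1L)
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0) stop("rho must be > 0")
  if (rule == "mean") 1 - vartheta / (n * rho^2) else 1 - vartheta / rho^2
}
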