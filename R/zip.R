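#' Inference policy thresholds
#'
#' Thresholds controlling when the coverage adjustment is attempted and how
#' uncertainty is quantified.
#'
#' @param lambda_method_max_median Adjustment is attempted only when the
#'   median nonzero multiplicity m is at or below this value (the correction
#'   factor `1 - exp(-lambda)` is negligible beyond it). Default 3.
#' @param robust_mean_max_median Upper m bound of the robust-mean branch of
#'   [effective_coverage()]. Default 15.
#' @param tail_prob Poisson upper-tail probability defining the robust-mean
#'   outlier cutoff alpha. Default 1e-10.
#' @param min_kmers Genomes with at most this many sketch k-mers are refused
#'   (too little information). Default 50.
#' @param bootstrap_iters Number of bootstrap resamples. Default 100.
#' @param bootstrap_min_valid Confidence interval reported only when strictly
#'   more than this many resamples are valid. Default 50.
#' @param ci_percentiles Lower and upper percentile of the interval.
#'   Default `c(5, 95)` (a 90% interval).
#' @return An object of class `coverage_policy`.
#' @export
coverage_policy <- function(lambda_method_max_median = 3,
                            robust_mean_max_median = 15,
                            tail_prob = 1e-10,
                            min_kmers = 50L,
                            bootstrap_iters = 100L,
                            bootstrap_min_valid = 50L,
                            ci_percentiles = c(5, 95)) {
  stopifnot(lambda_method_max_median > 0, robust_mean_max_median > 0,
            tail_prob > 0, min_kmers > 0, bootstrap_iters > 0,
            bootstrap_min_valid > 0, length(ci_percentiles) == 2L,
            all(ci_percentiles > 0), all(ci_percentiles < 100))
  structure(list(lambda_method_max_median = lambda_method_max_median,
                 robust_mean_max_median = robust_mean_max_median,
                 tail_prob = tail_prob,
                 min_kmers = as.integer(min_kmers),
                 bootstrap_iters = as.integer(bootstrap_iters),
                 bootstrap_min_valid = as.integer(bootstrap_min_valid),
                 ci_percentiles = as.numeric(ci_percentiles)),
            class = "coverage_policy")
}

#' Multiplicity histogram of a genome's k-mers in a sample
#'
#' Tallies, for one (genome sketch, sample sketch) pair, how many genome
#' k-mers occur `a` times in the sample for each multiplicity `a >= 1`. This
#' histogram is the sufficient statistic for all downstream inference; the
#' count of genome k-mers absent from the sample is implicit as
#' `n_sketch_kmers - n_contained`.
#'
#' @param genome A [sketch_genome()] result.
#' @param sample A [sketch_reads()] result with matching parameters.
#' @return A `mult_histogram`: list with `n_sketch_kmers` (N), `counts`
#'   (named integer vector, names are multiplicities `a`), `n_contained`
#'   (|A intersect B|), `mode_a` (multiplicity with the most k-mers, smallest
#'   on ties) and `median_nonzero` (m, median over nonzero multiplicities).
#' @export
build_histogram <- function(genome, sample) {
  stopifnot(inherits(genome, "genome_sketch"),
            inherits(sample, "sample_sketch"))
  check_params_match(genome, sample)
  idx <- match(genome$kmers, sample$hashes)
  mult <- sample$counts[idx[!is.na(idx)]]
  new_histogram(genome$n_kmers, mult)
}

# Construct a mult_histogram from the vector of nonzero multiplicities.
new_histogram <- function(n_sketch_kmers, mult) {
  if (length(mult)) {
    tab <- table(mult)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    a_vals <- as.integer(names(tab))
    mode_a <- a_vals[which.max(counts)]  # which.max takes the smallest tie
    med <- median(mult)
  } else {
    counts <- integer(0)
    mode_a <- NA_integer_
    med <- NA_real_
  }
  structure(list(n_sketch_kmers = n_sketch_kmers,
                 counts = counts,
                 n_contained = length(mult),
                 mode_a = mode_a,
                 median_nonzero = med),
            class = "mult_histogram")
}

#' @export
print.mult_histogram <- function(x, ...) {
  cat(sprintf("mult_histogram: N=%d, contained=%d, mode a=%s, m=%s\n",
              x$n_sketch_kmers, x$n_contained, format(x$mode_a),
              format(x$median_nonzero)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

hist_count <- function(hist, a) {
  v <- unname(hist$counts[as.character(a)])
  ifelse(is.na(v), 0L, as.integer(v))
}

#' Naive containment ANI
#'
#' `(|A intersect B| / |A|)^(1/k)`: the ANI implied by the containment index
#' without any correction for read sampling. Underestimates the true ANI when
#' coverage is low, because uncovered k-mers are indistinguishable from
#' mutated ones.
#'
#' @param hist A [build_histogram()] result.
#' @param k K-mer length.
#' @return ANI as a fraction in `[0, 1]`.
#' @export
naive_ani <- function(hist, k) {
  stopifnot(inherits(hist, "mult_histogram"))
  if (hist$n_sketch_kmers <= 0)
    stop("naive ANI undefined: genome sketch has no k-mers", call. = FALSE)
  (hist$n_contained / hist$n_sketch_kmers)^(1 / k)
}

#' Ratio-of-multiplicity estimator of the effective coverage
#'
#' With `a` the most frequent nonzero multiplicity (usually 1), the estimator
#' is `lambda_hat = (N_{a+1} / N_a) * (a + 1)`; the zero-inflation parameter
#' cancels out of the ratio, making the estimate ANI-free. The estimate is
#' returned only when both `N_a >= 3` and `N_{a+1} >= 3`; otherwise there is
#' too little information and `NA` is returned.
#'
#' @param hist A [build_histogram()] result.
#' @param policy A [coverage_policy()].
#' @return `lambda_hat`, or `NA_real_` when the filter fails.
#' @export
estimate_lambda <- function(hist, policy = coverage_policy()) {
  stopifnot(inherits(hist, "mult_histogram"))
  if (is.na(hist$mode_a)) return(NA_real_)
  a <- hist$mode_a
  na_ <- hist_count(hist, a)
  na1 <- hist_count(hist, a + 1L)
  if (na_ < 3L || na1 < 3L) return(NA_real_)
  (na1 / na_) * (a + 1)
}

#' Coverage-adjusted containment ANI
#'
#' Under the zero-inflated Poisson model the expected containment index is
#' `tau^k * (1 - exp(-lambda))`, so dividing by `1 - exp(-lambda)` before
#' taking the k-th root removes the coverage bias:
#' `tau_hat = ((|A n B|/|A|) / (1 - exp(-lambda)))^(1/k)`, thresholded at 1.
#'
#' @param hist A [build_histogram()] result.
#' @param lambda_hat Estimated effective coverage, `> 0`.
#' @param k K-mer length.
#' @return Adjusted ANI as a fraction in `[0, 1]`.
#' @export
adjusted_ani <- function(hist, lambda_hat, k) {
  stopifnot(inherits(hist, "mult_histogram"))
  if (!is.finite(lambda_hat) || lambda_hat <= 0)
    stop("lambda_hat must be positive", call. = FALSE)
  cont <- hist$n_contained / hist$n_sketch_kmers
  min(1, (cont / (1 - exp(-lambda_hat)))^(1 / k))
}

#' Bootstrap confidence interval for the adjusted ANI
#'
#' Resamples the N k-mer multiplicities (zeros included) with replacement,
#' recomputes the coverage-adjusted ANI for each resample using the original
#' histogram's mode `a`, and discards resamples in which `N_a` or `N_{a+1}`
#' is zero. The interval (by default the 5th and 95th percentiles, i.e. a 90%
#' interval) is reported only when strictly more than
#' `policy$bootstrap_min_valid` resamples are valid. Percentiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param hist A [build_histogram()] result.
#' @param k K-mer length.
#' @param policy A [coverage_policy()].
#' @param seed Integer seed; the interval is deterministic given it.
#' @return Numeric `c(ci_low, ci_high)`, or `NULL` when too few resamples
#'   are valid.
#' @export
bootstrap_ci <- function(hist, k, policy = coverage_policy(), seed = 1L) {
  stopifnot(inherits(hist, "mult_histogram"))
  if (hist$n_contained == 0L || is.na(hist$mode_a)) return(NULL)
  N <- hist$n_sketch_kmers
  a <- hist$mode_a
  vals <- c(0L, as.integer(names(hist$counts)))
  prob <- c(N - hist$n_contained, as.integer(hist$counts)) / N
  anis <- with_seed(seed, {
    draws <- rmultinom(policy$bootstrap_iters, N, prob)
    apply(draws, 2L, function(cnt) {
      names(cnt) <- vals
      na_ <- if (as.character(a) %in% names(cnt)) cnt[[as.character(a)]] else 0L
      na1 <- if (as.character(a + 1L) %in% names(cnt))
        cnt[[as.character(a + 1L)]] else 0L
      if (na_ == 0L || na1 == 0L) return(NA_real_)
      lam <- (na1 / na_) * (a + 1)
      cont <- sum(cnt[names(cnt) != "0"]) / N
      min(1, (cont / (1 - exp(-lam)))^(1 / k))
    })
  })
  anis <- anis[!is.na(anis)]
  if (length(anis) <= policy$bootstrap_min_valid) return(NULL)
  unname(quantile(anis, policy$ci_percentiles / 100, type = 7))
}

#' Effective coverage of a genome in a sample
#'
#' Returns the effective coverage lambda: the ratio-of-multiplicity estimate
#' when the median nonzero multiplicity m is at most 3 (and the estimate is
#' available, otherwise m is used as a fallback); a robust mean when
#' `4 <= m <= 15`, i.e. the mean multiplicity over k-mers with multiplicity
#' below alpha, where alpha is the smallest integer with
#' `Pr(Pois(m) > alpha) < tail_prob`; and m itself for deeper samples, where
#' the integer-valued median is accurate enough.
#'
#' @param hist A [build_histogram()] result with `n_contained > 0`.
#' @param lambda_hat Ratio-of-multiplicity estimate, or `NA`.
#' @param policy A [coverage_policy()].
#' @return Effective coverage lambda.
#' @export
effective_coverage <- function(hist, lambda_hat = NA_real_,
                               policy = coverage_policy()) {
  stopifnot(inherits(hist, "mult_histogram"))
  if (hist$n_contained == 0L)
    stop("effective coverage undefined for an empty intersection",
         call. = FALSE)
  m <- hist$median_nonzero
  if (m <= policy$lambda_method_max_median) {
    if (is.finite(lambda_hat)) return(lambda_hat)
    return(m)
  }
  if (m <= policy$robust_mean_max_median) {
    alpha <- poisson_tail_cutoff(m, policy$tail_prob)
    a_vals <- as.integer(names(hist$counts))
    keep <- a_vals < alpha
    if (!any(keep)) return(m)
    return(sum(a_vals[keep] * hist$counts[keep]) / sum(hist$counts[keep]))
  }
  m
}

# Smallest integer alpha with Pr(Pois(m) > alpha) < tail_prob.
poisson_tail_cutoff <- function(m, tail_prob) {
  alpha <- as.integer(ceiling(m))
  while (ppois(alpha, m, lower.tail = FALSE) >= tail_prob)
    alpha <- alpha + 1L
  alpha
}

#' Sample-wide k-mer error model
#'
#' Estimates `E = E[(1 - eps)^k]`, the probability that a k-mer survives
#' read error. With a user-supplied error rate, `E = (1 - eps)^k`. Otherwise
#' E is estimated from the sample-wide multiplicity histogram `n_a` as
#' `E = 1 - n_1 / sum_{a>1} a * n_a`, on the reasoning that
#' multiplicity-1 k-mers are mostly erroneous k-mers shed by well-covered
#' genomes and each error is unique. Degenerate estimates fall back to
#' `E = 1` with a warning (supplying an approximate eps of 0.001-0.010 is
#' then recommended).
#'
#' @param sample A [sketch_reads()] result.
#' @param user_epsilon Optional per-base error rate in `[0, 1)`.
#' @param k K-mer length (defaults to the sample's own k).
#' @return A `sample_error_model`: list with `E`, `source`
#'   (`"user_epsilon"` or `"auto"`) and `sample_counts` (the `n_a` table).
#' @export
estimate_error_term <- function(sample, user_epsilon = NULL, k = NULL) {
  stopifnot(inherits(sample, "sample_sketch"))
  if (is.null(k)) k <- sample$params$k
  tab <- table(sample$counts)
  n_a <- as.numeric(tab)
  a_vals <- as.numeric(names(tab))
  if (!is.null(user_epsilon)) {
    stopifnot(user_epsilon >= 0, user_epsilon < 1)
    E <- (1 - user_epsilon)^k
    src <- "user_epsilon"
  } else {
    n1 <- if ("1" %in% names(tab)) n_a[names(tab) == "1"] else 0
    denom <- sum(a_vals[a_vals > 1] * n_a[a_vals > 1])
    if (denom <= 0) {
      warning("cannot auto-estimate the error term (no repeated k-mers); ",
              "using E = 1; consider supplying an approximate error rate ",
              "of 0.001-0.010", call. = FALSE)
      E <- 1
    } else {
      E <- 1 - n1 / denom
      if (E <= 0) {
        warning("auto-estimated error term is degenerate (E <= 0); using ",
                "E = 1; consider supplying an approximate error rate of ",
                "0.001-0.010", call. = FALSE)
        E <- 1
      }
    }
    src <- "auto"
  }
  structure(list(E = min(E, 1), source = src,
                 sample_counts = setNames(as.integer(n_a), names(tab))),
            class = "sample_error_model")
}

#' True coverage from effective coverage
#'
#' Inverts the effective-coverage relation
#' `lambda = delta * E * (L - k + 1) / L`: `delta = lambda * (L/(L-k+1)) / E`.
#'
#' @param lambda Effective coverage.
#' @param L Mean single-ended read length in bases; must exceed `k`.
#' @param k K-mer length.
#' @param E K-mer error-survival probability in `(0, 1]`.
#' @return True coverage delta.
#' @export
true_coverage <- function(lambda, L, k, E = 1) {
  if (!is.finite(L) || L <= k)
    stop("true coverage undefined: read length must exceed k", call. = FALSE)
  stopifnot(E > 0)
  lambda * (L / (L - k + 1)) / E
}

#' Containment ANI estimate for one genome against one sample
#'
#' Orchestrates the full estimation path. Genomes with at most
#' `policy$min_kmers` sketch k-mers are refused (returns `NULL` with a
#' message). The naive ANI is always computed; the coverage adjustment is
#' attempted only when the median nonzero multiplicity m is at most 3 and the
#' ratio-of-multiplicity estimate passes its count filter, in which case the
#' adjusted ANI, its bootstrap confidence interval and
#' `effective_coverage = lambda_hat` are reported. Otherwise the adjusted ANI
#' mirrors the naive ANI with `adjustment_applied = FALSE`. The true coverage
#' is derived from the error model and the sample's mean read length.
#'
#' @param genome A [sketch_genome()] result.
#' @param sample A [sketch_reads()] result with matching parameters.
#' @param policy A [coverage_policy()].
#' @param error_model A [estimate_error_term()] result, or `NULL` to
#'   auto-estimate from `sample`.
#' @param seed Integer seed for the bootstrap.
#' @return An `ani_estimate` (or `NULL` when the genome is refused): list
#'   with `genome_id`, `naive_ani`, `adjusted_ani`, `lambda_hat`,
#'   `effective_coverage`, `true_coverage`, `ci_low`, `ci_high`,
#'   `n_sketch_kmers`, `n_contained`, `adjustment_applied`, `genome_length`.
#' @export
estimate_ani <- function(genome, sample, policy = coverage_policy(),
                         error_model = NULL, seed = 1L) {
  stopifnot(inherits(genome, "genome_sketch"),
            inherits(sample, "sample_sketch"))
  check_params_match(genome, sample)
  hist <- build_histogram(genome, sample)
  estimate_ani_from_hist(hist, genome, sample, policy, error_model, seed)
}

# Core estimator working from a precomputed histogram (the profiler re-runs
# it on reassigned histograms).
estimate_ani_from_hist <- function(hist, genome, sample,
                                   policy = coverage_policy(),
                                   error_model = NULL, seed = 1L) {
  if (hist$n_sketch_kmers <= policy$min_kmers) {
    message(sprintf(
      "skipping genome '%s': %d sketch k-mers (need > %d)",
      genome$genome_id, hist$n_sketch_kmers, policy$min_kmers))
    return(NULL)
  }
  if (is.null(error_model)) error_model <- estimate_error_term(sample)
  k <- genome$params$k
  naive <- naive_ani(hist, k)

  lam_hat <- NA_real_
  adj <- naive
  applied <- FALSE
  ci <- NULL
  if (hist$n_contained > 0L &&
      hist$median_nonzero <= policy$lambda_method_max_median) {
    lam_hat <- estimate_lambda(hist, policy)
    if (is.finite(lam_hat) && lam_hat > 0) {
      adj <- adjusted_ani(hist, lam_hat, k)
      applied <- TRUE
      ci <- bootstrap_ci(hist, k, policy, seed)
    }
  }

  eff <- if (hist$n_contained > 0L)
    effective_coverage(hist, lam_hat, policy) else NA_real_
  L <- sample$mean_read_length
  tru <- if (is.finite(eff) && is.finite(L) && L > k)
    true_coverage(eff, L, k, error_model$E) else NA_real_

  structure(
    list(genome_id = genome$genome_id,
         naive_ani = naive,
         adjusted_ani = adj,
         lambda_hat = lam_hat,
         effective_coverage = eff,
         true_coverage = tru,
         ci_low = if (is.null(ci)) NA_real_ else ci[1],
         ci_high = if (is.null(ci)) NA_real_ else ci[2],
         n_sketch_kmers = hist$n_sketch_kmers,
         n_contained = hist$n_contained,
         adjustment_applied = applied,
         genome_length = genome$genome_length),
    class = "ani_estimate"
  )
}

#' @export
print.ani_estimate <- function(x, ...) {
  cat(sprintf(
    "ani_estimate '%s': adjusted %.4f%% (naive %.4f%%)%s, eff_cov=%s\n",
    x$genome_id, 100 * x$adjusted_ani, 100 * x$naive_ani,
    if (!is.na(x$ci_low))
      sprintf(" CI [%.4f%%, %.4f%%]", 100 * x$ci_low, 100 * x$ci_high)
    else "",
    format(x$effective_coverage, digits = 4)))
  invisible(x)
}
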