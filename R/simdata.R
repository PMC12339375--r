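# Synthetic data with exactly the statistical structure the coverage model
# assumes: i.i.d. uniform genomes, independent substitutions at rate theta,
# uniform read starts at a target per-base coverage, i.i.d. per-base read
# errors, optional paired ends and verbatim PCR duplicates.

BASES <- c("A", "C", "G", "T")

#' Random genome sequence
#'
#' @param length Genome length in bases, `> 0`.
#' @param seed Integer seed; output is deterministic given it.
#' @return A single character string of i.i.d. uniform A/C/G/T.
#' @export
random_genome <- function(length, seed = 1L) {
  stopifnot(length > 0)
  with_seed(seed,
    paste(sample(BASES, length, replace = TRUE), collapse = ""))
}

#' Mutate a genome by independent substitutions
#'
#' Every base independently mutates to one of the three other bases with
#' probability `theta`; the implied true ANI is `tau = 1 - theta`.
#'
#' @param sequence Genome string.
#' @param theta Substitution rate in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `sequence` (mutated string), `n_substitutions`
#'   (realized count), `theta` and `tau`.
#' @export
mutate_genome <- function(sequence, theta, seed = 1L) {
  stopifnot(theta >= 0, theta < 1)
  n <- nchar(sequence)
  if (theta == 0)
    return(list(sequence = sequence, n_substitutions = 0L, theta = 0,
                tau = 1))
  with_seed(seed, {
    v <- strsplit(sequence, NULL, fixed = TRUE)[[1]]
    pos <- which(runif(n) < theta)
    if (length(pos)) {
      cur <- match(v[pos], BASES)
      shift <- sample.int(3L, length(pos), replace = TRUE)
      v[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    list(sequence = paste(v, collapse = ""),
         n_substitutions = length(pos), theta = theta, tau = 1 - theta)
  })
}

# Inject i.i.d. substitution errors at rate epsilon into a vector of
# equal-importance reads (vectorized over the concatenation).
inject_errors <- function(reads, epsilon) {
  if (epsilon <= 0 || length(reads) == 0L) return(reads)
  lens <- nchar(reads)
  big <- strsplit(paste(reads, collapse = ""), NULL, fixed = TRUE)[[1]]
  pos <- which(runif(length(big)) < epsilon)
  if (length(pos)) {
    cur <- match(big[pos], BASES)
    ok <- !is.na(cur)
    pos <- pos[ok]; cur <- cur[ok]
    shift <- sample.int(3L, length(pos), replace = TRUE)
    big[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  ends <- cumsum(lens)
  substring(paste(big, collapse = ""), ends - lens + 1L, ends)
}

#' Expected effective coverage of a simulation
#'
#' `lambda = delta * (1 - epsilon)^k * (L - k + 1) / L`.
#'
#' @param delta True per-base coverage.
#' @param L Read length.
#' @param k K-mer length.
#' @param epsilon Per-base error rate.
#' @return Effective coverage lambda.
#' @export
expected_effective_coverage <- function(delta, L, k, epsilon = 0) {
  delta * (1 - epsilon)^k * (L - k + 1) / L
}

#' True coverage needed for a target effective coverage
#'
#' Inverse of [expected_effective_coverage()].
#'
#' @inheritParams expected_effective_coverage
#' @param lambda Target effective coverage.
#' @return True coverage delta.
#' @export
delta_for_lambda <- function(lambda, L, k, epsilon = 0) {
  lambda / ((1 - epsilon)^k * (L - k + 1) / L)
}

#' Sample reads uniformly from a genome
#'
#' Read (or fragment) start positions are uniform over the genome (linear,
#' non-circular); per-base errors are i.i.d. substitutions at rate `epsilon`;
#' in paired mode, mates of length `L` are taken from the two ends of a
#' normal-length fragment with mate 2 reverse-complemented; with probability
#' `pcr_duplicate_rate` a read (pair) is emitted again, verbatim by default
#' or with `pcr_duplicate_substitutions` extra random substitutions.
#'
#' @param sequence Source genome string (typically the mutated genome).
#' @param target_delta Target per-base true coverage; the number of reads is
#'   `round(target_delta * nchar(sequence) / (reads per unit * L))`.
#' @param L Read length in bases.
#' @param epsilon Per-base error rate. Default 0.
#' @param paired Emit read pairs. Default `FALSE`.
#' @param fragment_mean,fragment_sd Fragment length distribution for paired
#'   mode. Defaults 400 and 40.
#' @param pcr_duplicate_rate Probability that a read (pair) is duplicated.
#'   Default 0.
#' @param pcr_duplicate_substitutions Substitutions injected into each
#'   duplicate copy (0 = verbatim). Default 0.
#' @param seed Integer seed.
#' @return List with `reads1`, `reads2` (`NULL` unless paired), and `truth`
#'   (a list recording delta, epsilon, L, paired, fragment spec, duplicate
#'   rate, seed and the expected effective coverage).
#' @export
sample_reads <- function(sequence, target_delta, L = 150L, epsilon = 0,
                         paired = FALSE, fragment_mean = 400,
                         fragment_sd = 40, pcr_duplicate_rate = 0,
                         pcr_duplicate_substitutions = 0L, seed = 1L) {
  stopifnot(target_delta > 0, L >= 1, epsilon >= 0, epsilon < 1,
            pcr_duplicate_rate >= 0, pcr_duplicate_rate <= 1)
  glen <- nchar(sequence)
  stopifnot(glen >= L)
  with_seed(seed, {
    if (paired) {
      n_pairs <- max(1L, round(target_delta * glen / (2 * L)))
      frag <- pmax(2 * L, pmin(glen, round(rnorm(n_pairs, fragment_mean,
                                                 fragment_sd))))
      starts <- floor(runif(n_pairs) * (glen - frag + 1)) + 1L
      r1 <- substring(sequence, starts, starts + L - 1L)
      r2 <- revcomp(substring(sequence, starts + frag - L, starts + frag - 1L))
      r1 <- inject_errors(r1, epsilon)
      r2 <- inject_errors(r2, epsilon)
      idx <- seq_len(n_pairs)
      dup <- runif(n_pairs) < pcr_duplicate_rate
      take <- rep(idx, times = 1L + dup)
      reads1 <- r1[take]; reads2 <- r2[take]
      if (pcr_duplicate_substitutions > 0L && any(dup)) {
        is_dup <- duplicated(take)
        reads1[is_dup] <- add_substitutions(reads1[is_dup],
                                            pcr_duplicate_substitutions)
        reads2[is_dup] <- add_substitutions(reads2[is_dup],
                                            pcr_duplicate_substitutions)
      }
      n_dup <- sum(dup)
    } else {
      n_reads <- max(1L, round(target_delta * glen / L))
      starts <- floor(runif(n_reads) * (glen - L + 1)) + 1L
      r1 <- substring(sequence, starts, starts + L - 1L)
      r1 <- inject_errors(r1, epsilon)
      dup <- runif(n_reads) < pcr_duplicate_rate
      take <- rep(seq_len(n_reads), times = 1L + dup)
      reads1 <- r1[take]
      if (pcr_duplicate_substitutions > 0L && any(dup)) {
        is_dup <- duplicated(take)
        reads1[is_dup] <- add_substitutions(reads1[is_dup],
                                            pcr_duplicate_substitutions)
      }
      reads2 <- NULL
      n_dup <- sum(dup)
    }
    list(reads1 = reads1, reads2 = reads2,
         truth = list(delta = target_delta, epsilon = epsilon, L = L,
                      paired = paired,
                      fragment_mean = if (paired) fragment_mean else NA,
                      fragment_sd = if (paired) fragment_sd else NA,
                      pcr_duplicate_rate = pcr_duplicate_rate,
                      n_duplicates = n_dup, seed = seed))
  })
}

# Exactly n random substitutions per read (for duplicate-tolerance tests).
add_substitutions <- function(reads, n_subs) {
  vapply(reads, function(r) {
    v <- strsplit(r, NULL, fixed = TRUE)[[1]]
    pos <- sample.int(length(v), min(n_subs, length(v)))
    cur <- match(v[pos], BASES)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    v[pos] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Brute-force containment ANI oracle
#'
#' `(|A intersect B| / |A|)^(1/k)` over the complete (unsubsampled) canonical
#' k-mer sets of two sequences; the ground truth against which sketch-based
#' estimates are compared.
#'
#' @param seq_a Reference sequence (or a precomputed numeric hash set).
#' @param seq_b Other sequence (or hash set).
#' @param params A [sketch_params()]; only `k` and `hash_seed` matter.
#' @return Containment ANI as a fraction.
#' @export
brute_containment_ani <- function(seq_a, seq_b, params = sketch_params()) {
  a <- full_kmer_set(seq_a, params)
  b <- full_kmer_set(seq_b, params)
  if (length(a) == 0L) stop("reference k-mer set is empty", call. = FALSE)
  (sum(!is.na(match(a, b))) / length(a))^(1 / params$k)
}

full_kmer_set <- function(x, params) {
  if (is.numeric(x)) return(unique(x))
  unique(unlist(lapply(as.character(x), function(s)
    .cpp_kmer_hashes(s, params$k, params$hash_seed)$hash),
    use.names = FALSE))
}
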