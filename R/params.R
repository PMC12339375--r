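#' Sketching parameters
#'
#' Bundle of the parameters governing k-mer sketching. Two sketches are only
#' comparable when their `k`, `c` and `hash_seed` agree.
#'
#' Hashes live in a 53-bit space (`M = 2^53`) so that every hash value is
#' exactly representable as an R double; a k-mer is retained by FracMinHash
#' when its hash is below `floor(M / c)`, so the expected retained fraction
#' is `1/c`.
#'
#' @param k K-mer length in bases; must be odd and between 1 and 31. Odd
#'   lengths avoid palindromic self-complementary k-mers. Default 31.
#' @param c FracMinHash subsampling rate (dimensionless, `>= 1`); on average
#'   one in `c` distinct k-mers is retained. Default 200.
#' @param hash_seed Integer seed of the 64-bit mixing hash. Default 0.
#' @param dedup_fp_rate Target false-positive probability of the approximate
#'   membership structure used for PCR duplicate detection. Default 1e-4.
#' @return An object of class `sketch_params`.
#' @examples
#' sketch_params(k = 21, c = 50)
#' @export
sketch_params <- function(k = 31L, c = 200, hash_seed = 0L,
                          dedup_fp_rate = 1e-4) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 31L || k %% 2L == 0L)
    stop("k must be odd and between 1 and 31", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || is.na(c) || c < 1)
    stop("c must be a single number >= 1", call. = FALSE)
  hash_seed <- as.integer(hash_seed)
  if (is.na(hash_seed)) stop("hash_seed must be an integer", call. = FALSE)
  if (!is.numeric(dedup_fp_rate) || dedup_fp_rate <= 0 || dedup_fp_rate >= 1)
    stop("dedup_fp_rate must be in (0, 1)", call. = FALSE)
  structure(
    list(k = k, c = as.numeric(c), M = 2^53, hash_seed = hash_seed,
         dedup_fp_rate = dedup_fp_rate),
    class = "sketch_params"
  )
}

#' @export
print.sketch_params <- function(x, ...) {
  cat(sprintf("sketch_params: k=%d c=%g hash_seed=%d (M=2^53)\n",
              x$k, x$c, x$hash_seed))
  invisible(x)
}

#' FracMinHash retention threshold
#'
#' `floor(M / c)` for the 53-bit hash space; a hash is retained iff it is
#' strictly below this value.
#'
#' @param params A [sketch_params()] object.
#' @return The threshold as a double.
#' @export
keep_threshold <- function(params) {
  stopifnot(inherits(params, "sketch_params"))
  .cpp_keep_threshold(params$c)
}

#' FracMinHash keep rule
#'
#' @param hash Numeric vector of k-mer hashes (values in `[0, 2^53)`).
#' @param params A [sketch_params()] object.
#' @return Logical vector: `TRUE` where `hash < floor(M/c)`.
#' @examples
#' p <- sketch_params(c = 1)
#' fracminhash_keep(c(0, 2^53 - 1), p)  # c = 1 keeps everything
#' @export
fracminhash_keep <- function(hash, params) {
  stopifnot(inherits(params, "sketch_params"))
  hash < keep_threshold(params)
}

#' Canonical k-mer hashes of a sequence
#'
#' Slides a window of length `k` over `sequence`, skipping windows containing
#' non-ACGT characters, and emits for each window the 0-based start position
#' and the hash of the canonical k-mer (the lexicographic minimum, on the
#' 2-bit encoding, of the k-mer and its reverse complement) mixed through a
#' fixed invertible 64-bit finalizer seeded by `hash_seed` and truncated to
#' 53 bits.
#'
#' @param sequence A single nucleotide string.
#' @param params A [sketch_params()] object.
#' @return A data frame with columns `pos` (0-based start) and `hash`.
#' @examples
#' canonical_kmer_hashes("ACGT", sketch_params(k = 3, c = 1))
#' @export
canonical_kmer_hashes <- function(sequence, params) {
  stopifnot(inherits(params, "sketch_params"),
            is.character(sequence), length(sequence) == 1L)
  res <- .cpp_kmer_hashes(sequence, params$k, params$hash_seed)
  data.frame(pos = res$pos, hash = res$hash)
}

#' Hash individual k-mer strings
#'
#' Canonical hash of each string in `kmers` (each must have `nchar == k`);
#' `NA` where a string has the wrong length or contains non-ACGT characters.
#' Primarily an oracle/debugging primitive.
#'
#' @param kmers Character vector of k-mer strings.
#' @param params A [sketch_params()] object.
#' @return Numeric vector of hashes.
#' @export
hash_kmers <- function(kmers, params) {
  stopifnot(inherits(params, "sketch_params"))
  .cpp_hash_kmers(as.character(kmers), params$k, params$hash_seed)
}

# Error if two sketches were built under incompatible parameters.
check_params_match <- function(a, b) {
  for (f in c("k", "c", "hash_seed")) {
    if (!identical(as.numeric(a$params[[f]]), as.numeric(b$params[[f]])))
      stop(sprintf("sketch parameter mismatch: %s (%s vs %s)",
                   f, format(a$params[[f]]), format(b$params[[f]])),
           call. = FALSE)
  }
  invisible(TRUE)
}
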