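#' Sketch a reference genome
#'
#' Builds the masked FracMinHash k-mer set of one genome. K-mers are retained
#' when their hash falls below `floor(M/c)`, then two masking rules are
#' applied: (i) every k-mer whose canonical form occurs more than once
#' anywhere in the genome is removed entirely (all copies), because the
#' coverage model assumes genome k-mers are unique; (ii) scanning each contig
#' left to right, a retained k-mer starting fewer than `spacing` bases after
#' the previously kept k-mer is dropped, so that retained k-mers have
#' approximately independent coverage.
#'
#' @param records Character vector of contig sequences (one genome), or a
#'   named list with elements `seq`.
#' @param params A [sketch_params()] object.
#' @param genome_id Identifier recorded in the sketch.
#' @param spacing Minimum distance in bases between starts of retained
#'   k-mers within a contig. Default 30.
#' @return A `genome_sketch`: list with `genome_id`, `genome_length`,
#'   `params`, `kmers` (sorted numeric hash vector) and `n_kmers`.
#' @examples
#' p <- sketch_params(k = 5, c = 1)
#' g <- sketch_genome("ACGTACGGTTACGGA", p, genome_id = "toy", spacing = 0)
#' g$n_kmers
#' @export
sketch_genome <- function(records, params, genome_id = "genome",
                          spacing = 30L) {
  stopifnot(inherits(params, "sketch_params"))
  seqs <- as.character(unlist(records, use.names = FALSE))
  if (length(seqs) < 1L) stop("at least one sequence record required",
                              call. = FALSE)
  res <- .cpp_sketch_genome(seqs, params$k, params$c, params$hash_seed,
                            as.integer(spacing))
  structure(
    list(genome_id = as.character(genome_id),
         genome_length = res$genome_length,
         params = params,
         kmers = res$hashes,
         n_kmers = length(res$hashes)),
    class = "genome_sketch"
  )
}

#' @export
print.genome_sketch <- function(x, ...) {
  cat(sprintf("genome_sketch '%s': %d k-mers, %.0f bp (k=%d, c=%g)\n",
              x$genome_id, x$n_kmers, x$genome_length, x$params$k,
              x$params$c))
  invisible(x)
}

#' Sketch a read set
#'
#' Counts the multiplicity of every retained FracMinHash k-mer across a set
#' of reads. In paired mode, a k-mer occurring twice across one read pair is
#' counted once (overlapping pairs would otherwise double-count k-mers). With
#' `dedup = TRUE`, PCR duplicates are suppressed by a locality-sensitive
#' scheme: the first 32-mers of the two mates are each reduced by the two
#' alternating base masks to 16-mers, and the two (k-mer, 16-mer, 16-mer)
#' tuples are checked against an approximate membership structure — if either
#' is present the observation is discarded. Duplicates differing by at most
#' one substitution are guaranteed to be caught, since one of the two masks
#' is unaffected. For single-end reads, reads longer than 400 bp are never
#' deduplicated, the second window starts at the middle of the read, and
#' deduplication applies only while the k-mer's running multiplicity is
#' below 4.
#'
#' @param reads Character vector of read sequences (or mate-1 sequences).
#' @param reads2 Optional character vector of mate-2 sequences; enables
#'   paired mode and must have the same length as `reads`.
#' @param params A [sketch_params()] object.
#' @param sample_id Identifier recorded in the sketch.
#' @param dedup Apply PCR duplicate detection. Default `TRUE`.
#' @return A `sample_sketch`: list with `sample_id`, `params`, `hashes`,
#'   `counts` (parallel sorted vectors, the multiset B), `total_bases`,
#'   `n_reads`, `mean_read_length`, `paired`, `dedup_applied`.
#' @examples
#' p <- sketch_params(k = 5, c = 1)
#' s <- sketch_reads(c("ACGTACGGT", "ACGTACGGT"), params = p, dedup = FALSE)
#' s$counts
#' @export
sketch_reads <- function(reads, reads2 = NULL, params = sketch_params(),
                         sample_id = "sample", dedup = TRUE) {
  stopifnot(inherits(params, "sketch_params"))
  reads <- as.character(reads)
  paired <- !is.null(reads2)
  if (paired) {
    reads2 <- as.character(reads2)
    if (length(reads2) != length(reads))
      stop(sprintf(
        "paired read streams differ in record count: %d vs %d (first %s)",
        length(reads), length(reads2),
        if (length(reads) > length(reads2))
          sprintf("missing mate-2 record %d", length(reads2) + 1L)
        else sprintf("missing mate-1 record %d", length(reads) + 1L)),
        call. = FALSE)
  }
  res <- .cpp_sketch_reads(reads, reads2, params$k, params$c,
                           params$hash_seed, isTRUE(dedup))
  structure(
    list(sample_id = as.character(sample_id),
         params = params,
         hashes = res$hashes,
         counts = res$counts,
         total_bases = res$total_bases,
         n_reads = res$n_reads,
         mean_read_length = res$mean_read_length,
         paired = paired,
         dedup_applied = isTRUE(dedup)),
    class = "sample_sketch"
  )
}

#' @export
print.sample_sketch <- function(x, ...) {
  cat(sprintf(
    "sample_sketch '%s': %d distinct k-mers, %.0f bases in %.0f reads (L=%.1f, %s%s)\n",
    x$sample_id, length(x$hashes), x$total_bases, x$n_reads,
    x$mean_read_length, if (x$paired) "paired" else "single-end",
    if (x$dedup_applied) ", dedup" else ""))
  invisible(x)
}

#' PCR duplicate membership structure
#'
#' Creates an empty approximate-membership store for duplicate detection,
#' usable with [pcr_duplicate_check()]. The store keeps 64-bit fingerprints
#' of (k-mer, masked-16-mer, masked-16-mer) tuples; its false-positive rate
#' is far below `dedup_fp_rate` of the owning [sketch_params()].
#'
#' @param params A [sketch_params()] object (the hash seed salts the store).
#' @return An external pointer of class `dedup_store`.
#' @export
dedup_store <- function(params = sketch_params()) {
  stopifnot(inherits(params, "sketch_params"))
  structure(list(ptr = .cpp_dedup_new(params$hash_seed)),
            class = "dedup_store")
}

#' Check one k-mer observation for PCR duplication
#'
#' Applies the locality-sensitive duplicate rule for a single FracMinHash
#' k-mer observed in a read or read pair: the flanking 32-mer windows are
#' masked with the two alternating patterns, and the resulting tuples are
#' queried against (and, when absent, inserted into) `store`.
#'
#' @param kmer_hash Hash of the observed FracMinHash k-mer.
#' @param read1 The read (single-end) or mate-1 sequence.
#' @param read2 Mate-2 sequence, or `NULL` for single-end mode.
#' @param store A [dedup_store()].
#' @param multiplicity Running multiplicity of the k-mer so far (single-end
#'   mode deduplicates only while this is `< 4`). Default 0.
#' @return `TRUE` if the observation is a duplicate and must not be counted.
#' @export
pcr_duplicate_check <- function(kmer_hash, read1, read2 = NULL, store,
                                multiplicity = 0L) {
  stopifnot(inherits(store, "dedup_store"))
  single <- is.null(read2)
  .cpp_dedup_check(store$ptr, as.numeric(kmer_hash),
                   as.character(read1),
                   if (single) "" else as.character(read2),
                   single, as.integer(multiplicity))
}
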