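#' Query a sample with a set of genomes
#'
#' Runs [estimate_ani()] independently for every genome (no k-mer
#' reassignment) and returns the estimates sorted by adjusted ANI descending,
#' ties broken by genome id. Genomes refused for having too few sketch
#' k-mers are omitted.
#'
#' @param genomes List of [sketch_genome()] results.
#' @param sample A [sketch_reads()] result.
#' @param policy A [coverage_policy()].
#' @param error_model A [estimate_error_term()] result, or `NULL` to
#'   auto-estimate once from `sample`.
#' @param seed Integer seed (per-genome bootstrap seeds are derived from it).
#' @return List of `ani_estimate` objects; convert with [ani_table()].
#' @export
query_sample <- function(genomes, sample, policy = coverage_policy(),
                         error_model = NULL, seed = 1L) {
  stopifnot(inherits(sample, "sample_sketch"))
  if (length(genomes) == 0L) return(list())
  if (is.null(error_model)) error_model <- estimate_error_term(sample)
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  ord <- order(ids)
  ests <- lapply(ord, function(i)
    estimate_ani(genomes[[i]], sample, policy, error_model,
                 seed = derive_seed(seed, i)))
  ests <- ests[!vapply(ests, is.null, logical(1))]
  sort_estimates(ests)
}

sort_estimates <- function(ests) {
  if (length(ests) == 0L) return(ests)
  adj <- vapply(ests, function(e) e$adjusted_ani, numeric(1))
  ids <- vapply(ests, function(e) e$genome_id, character(1))
  ests[order(-adj, ids)]
}

#' Tabulate ANI estimates
#'
#' @param estimates List of `ani_estimate` objects from [query_sample()].
#' @return A data frame with one row per genome.
#' @export
ani_table <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(genome = e$genome_id,
               adjusted_ani = e$adjusted_ani,
               naive_ani = e$naive_ani,
               ci_low = e$ci_low, ci_high = e$ci_high,
               lambda_hat = e$lambda_hat,
               effective_coverage = e$effective_coverage,
               true_coverage = e$true_coverage,
               n_sketch_kmers = e$n_sketch_kmers,
               n_contained = e$n_contained,
               adjustment_applied = e$adjustment_applied,
               genome_length = e$genome_length)))
}

#' Winner-take-all k-mer reassignment
#'
#' Every sample k-mer present in two or more candidate genome sketches is
#' assigned, with its full multiplicity, to the single genome with the
#' highest putative ANI (ties broken lexicographically by genome id). Losing
#' genomes treat the k-mer as absent from the sample, while it still counts
#' toward their sketch size N.
#'
#' @param genomes List of [sketch_genome()] results (the candidates).
#' @param sample A [sketch_reads()] result.
#' @param putative Named numeric vector of putative ANIs (names are genome
#'   ids), or a list of `ani_estimate` objects.
#' @return Named list: per genome a `mult_histogram` of its reassigned
#'   k-mers plus attribute `n_kmers_reassigned` (shared k-mers this genome
#'   won).
#' @export
reassign_kmers <- function(genomes, sample, putative) {
  stopifnot(inherits(sample, "sample_sketch"))
  if (is.list(putative) && length(putative) &&
      inherits(putative[[1]], "ani_estimate"))
    putative <- setNames(
      vapply(putative, function(e) e$adjusted_ani, numeric(1)),
      vapply(putative, function(e) e$genome_id, character(1)))
  ids <- vapply(genomes, function(g) g$genome_id, character(1))
  if (!all(ids %in% names(putative)))
    stop("putative ANIs missing for some candidate genomes", call. = FALSE)

  hash <- unlist(lapply(genomes, function(g) g$kmers), use.names = FALSE)
  gid <- rep(ids, times = vapply(genomes, function(g) length(g$kmers),
                                 integer(1)))
  ani <- putative[gid]
  # Winner per hash: order by hash, then ANI descending, then genome id.
  ord <- order(hash, -ani, gid, method = "radix")
  first <- !duplicated(hash[ord])
  win_hash <- hash[ord][first]              # sorted unique hashes
  win_gid <- gid[ord][first]                # their winning genome
  shared_hash <- unique(hash[ord][!first])  # hashes in >= 2 genomes

  out <- setNames(vector("list", length(genomes)), ids)
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    win <- win_gid[match(g$kmers, win_hash)] == g$genome_id
    kept <- g$kmers[win]
    idx <- match(kept, sample$hashes)
    mult <- sample$counts[idx[!is.na(idx)]]
    h <- new_histogram(g$n_kmers, mult)
    attr(h, "n_kmers_reassigned") <-
      sum(win & !is.na(match(g$kmers, shared_hash)))
    out[[g$genome_id]] <- h
  }
  out
}

#' Percentage of reads detected
#'
#' `100 * sum(delta_i * GL_i) / total_bases`, capped at 100: the share of the
#' sample's sequenced bases explained by the detected genomes at their
#' estimated true coverages.
#'
#' @param true_cov Numeric vector of per-genome true coverages `delta_i`.
#' @param genome_lengths Numeric vector of genome lengths `GL_i`.
#' @param total_bases Total sequenced bases in the sample; must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
percent_reads_detected <- function(true_cov, genome_lengths, total_bases) {
  stopifnot(total_bases > 0, length(true_cov) == length(genome_lengths))
  if (length(true_cov) == 0L) return(0)
  min(100, 100 * sum(true_cov * genome_lengths) / total_bases)
}

#' Profile a sample against a genome database
#'
#' The profiling pipeline: putative ANIs per genome as in [query_sample()];
#' winner-take-all [reassign_kmers()] among candidates passing a permissive
#' naive-ANI pre-filter; re-estimation of ANI and coverage from the
#' reassigned histograms; detection filtering at `min_ani`; and abundance
#' computation. Taxonomic abundance is `lambda_i / sum(lambda_i) * 100` and
#' sequence abundance `lambda_i * GL_i / sum(lambda_i * GL_i) * 100` over the
#' detected genomes. With `unknown_scaling`, both abundance columns are
#' multiplied by `percent_reads_detected / 100` so they total the share of
#' the sample explained by the database.
#'
#' @param genomes List of [sketch_genome()] results (the database).
#' @param sample A [sketch_reads()] result.
#' @param policy A [coverage_policy()].
#' @param error_model A [estimate_error_term()] result, or `NULL`.
#' @param min_ani Detection threshold on the post-reassignment adjusted ANI
#'   (fraction). Default 0.95.
#' @param prefilter_ani Naive-ANI floor a genome must reach in the putative
#'   pass to enter reassignment (bounds cost; permissive). Default 0.90.
#' @param unknown_scaling Scale abundances by the detected fraction.
#' @param seed Integer seed.
#' @return A `profile_report`: list with `sample_id`, `records` (data frame
#'   with one row per detected genome: ids, post-reassignment adjusted ANI,
#'   effective/true coverage, genome length, abundances,
#'   `n_kmers_reassigned`), `percent_reads_detected`, `unknown_scaled`,
#'   `min_ani`.
#' @export
profile_sample <- function(genomes, sample, policy = coverage_policy(),
                           error_model = NULL, min_ani = 0.95,
                           prefilter_ani = 0.90, unknown_scaling = FALSE,
                           seed = 1L) {
  stopifnot(inherits(sample, "sample_sketch"))
  if (is.null(error_model)) error_model <- estimate_error_term(sample)
  putative <- query_sample(genomes, sample, policy, error_model, seed)
  keep_ids <- vapply(
    putative[vapply(putative, function(e) e$naive_ani >= prefilter_ani,
                    logical(1))],
    function(e) e$genome_id, character(1))
  empty <- function() structure(
    list(sample_id = sample$sample_id, records = empty_profile_records(),
         percent_reads_detected = 0, unknown_scaled = unknown_scaling,
         min_ani = min_ani),
    class = "profile_report")
  if (length(keep_ids) == 0L) return(empty())

  ids_all <- vapply(genomes, function(g) g$genome_id, character(1))
  cand <- genomes[match(keep_ids, ids_all)]
  cand <- cand[order(vapply(cand, function(g) g$genome_id, character(1)))]
  hists <- reassign_kmers(cand, sample, putative)

  finals <- list()
  for (i in seq_along(cand)) {
    g <- cand[[i]]
    est <- estimate_ani_from_hist(hists[[g$genome_id]], g, sample, policy,
                                  error_model,
                                  seed = derive_seed(seed, 10000 + i))
    if (is.null(est)) next
    if (est$adjusted_ani >= min_ani) {
      est$n_kmers_reassigned <-
        attr(hists[[g$genome_id]], "n_kmers_reassigned")
      finals[[length(finals) + 1L]] <- est
    }
  }
  if (length(finals) == 0L) return(empty())

  lam <- vapply(finals, function(e) e$effective_coverage, numeric(1))
  gl <- vapply(finals, function(e) e$genome_length, numeric(1))
  tru <- vapply(finals, function(e) e$true_coverage, numeric(1))
  tax <- 100 * lam / sum(lam)
  seqab <- 100 * lam * gl / sum(lam * gl)
  prd <- percent_reads_detected(tru, gl, sample$total_bases)
  if (unknown_scaling) {
    tax <- tax * prd / 100
    seqab <- seqab * prd / 100
  }
  rec <- data.frame(
    genome = vapply(finals, function(e) e$genome_id, character(1)),
    taxonomic_abundance = tax,
    sequence_abundance = seqab,
    adjusted_ani = vapply(finals, function(e) e$adjusted_ani, numeric(1)),
    naive_ani = vapply(finals, function(e) e$naive_ani, numeric(1)),
    effective_coverage = lam,
    true_coverage = tru,
    genome_length = gl,
    n_kmers_reassigned = vapply(
      finals, function(e) as.integer(e$n_kmers_reassigned), integer(1)),
    n_contained = vapply(finals, function(e) e$n_contained, integer(1)))
  rec <- rec[order(-rec$taxonomic_abundance, rec$genome), , drop = FALSE]
  rownames(rec) <- NULL
  structure(
    list(sample_id = sample$sample_id, records = rec,
         percent_reads_detected = prd, unknown_scaled = unknown_scaling,
         min_ani = min_ani),
    class = "profile_report")
}

empty_profile_records <- function() {
  data.frame(genome = character(0), taxonomic_abundance = numeric(0),
             sequence_abundance = numeric(0), adjusted_ani = numeric(0),
             naive_ani = numeric(0), effective_coverage = numeric(0),
             true_coverage = numeric(0), genome_length = numeric(0),
             n_kmers_reassigned = integer(0), n_contained = integer(0))
}

#' @export
print.profile_report <- function(x, ...) {
  cat(sprintf("profile_report '%s': %d genomes, %.2f%% reads detected%s\n",
              x$sample_id, nrow(x$records), x$percent_reads_detected,
              if (x$unknown_scaled) " (abundances scaled)" else ""))
  if (nrow(x$records))
    print(head(x$records[, c("genome", "taxonomic_abundance",
                             "sequence_abundance", "adjusted_ani",
                             "effective_coverage")], 20))
  invisible(x)
}
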