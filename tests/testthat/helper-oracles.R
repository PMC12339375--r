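# Independent oracles used across the suite. They share only the low-level
# single-k-mer hash primitive (hash_kmers) with the implementation; all
# enumeration, filtering and counting logic is reimplemented in plain R.

# Enumerate every k-mer window of a sequence in R: returns data.frame with
# 0-based pos and hash (NA for windows containing non-ACGT).
oracle_windows <- function(seq, params) {
  k <- params$k
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(0), hash = numeric(0)))
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  data.frame(pos = starts - 1L, hash = hash_kmers(kmers, params))
}

# Brute-force genome sketcher applying the same three rules in R:
# FracMinHash keep -> genome-wide uniqueness -> greedy per-contig spacing.
oracle_sketch_genome <- function(seqs, params, spacing = 30L) {
  thr <- keep_threshold(params)
  wins <- lapply(seqs, function(s) {
    w <- oracle_windows(s, params)
    w[!is.na(w$hash) & w$hash < thr, , drop = FALSE]
  })
  all_hash <- unlist(lapply(wins, `[[`, "hash"), use.names = FALSE)
  multi <- unique(all_hash[duplicated(all_hash)])
  kept <- numeric(0)
  for (w in wins) {
    w <- w[!(w$hash %in% multi), , drop = FALSE]
    last <- -Inf
    for (i in seq_len(nrow(w))) {
      if (w$pos[i] >= last + spacing) {
        kept <- c(kept, w$hash[i])
        last <- w$pos[i]
      }
    }
  }
  sort(kept)
}

# Brute-force multiplicity counting of retained k-mers in reads, pair rule
# optional, no dedup.
oracle_count_reads <- function(reads1, reads2 = NULL, params,
                               pair_rule = !is.null(reads2)) {
  thr <- keep_threshold(params)
  get <- function(r) {
    h <- oracle_windows(r, params)$hash
    h[!is.na(h) & h < thr]
  }
  acc <- list()
  for (i in seq_along(reads1)) {
    h <- get(reads1[[i]])
    if (!is.null(reads2)) h <- c(h, get(reads2[[i]]))
    if (pair_rule) h <- unique(h)
    acc[[i]] <- h
  }
  v <- sort(unlist(acc, use.names = FALSE))
  r <- rle(v)
  data.frame(hash = r$values, count = r$lengths)
}

# Draw n zero-inflated Poisson variates: Pois(lambda) * Bern(pi1).
rzip <- function(n, pi1, lambda) {
  rpois(n, lambda) * rbinom(n, 1L, pi1)
}

# Maximum-likelihood fit of ZIP(pi1, lambda) from a multiplicity vector
# (zeros included), by direct optimization of the log-likelihood.
oracle_zip_ml <- function(x) {
  n0 <- sum(x == 0)
  xp <- x[x > 0]
  nll <- function(par) {
    p <- plogis(par[1]); lam <- exp(par[2])
    ll0 <- n0 * log((1 - p) + p * exp(-lam))
    llp <- sum(log(p) + dpois(xp, lam, log = TRUE))
    -(ll0 + llp)
  }
  fit <- optim(c(qlogis(0.5), log(max(mean(xp), 0.1))), nll,
               method = "Nelder-Mead")
  list(pi1 = plogis(fit$par[1]), lambda = exp(fit$par[2]))
}

# Construct sketch objects directly (controlled fixtures).
make_genome_sketch <- function(hashes, params, id = "g",
                               genome_length = 1e6) {
  structure(list(genome_id = id, genome_length = genome_length,
                 params = params, kmers = sort(as.numeric(hashes)),
                 n_kmers = length(hashes)),
            class = "genome_sketch")
}

make_sample_sketch <- function(hashes, counts, params, id = "s",
                               total_bases = 1e6, mean_read_length = 150,
                               paired = FALSE) {
  o <- order(hashes)
  structure(list(sample_id = id, params = params,
                 hashes = as.numeric(hashes)[o],
                 counts = as.integer(counts)[o],
                 total_bases = total_bases,
                 n_reads = round(total_bases / mean_read_length),
                 mean_read_length = mean_read_length, paired = paired,
                 dedup_applied = FALSE),
            class = "sample_sketch")
}

# Histogram fixture from a named multiplicity spec, e.g. c(`1` = 100, `2` = 50)
# over N sketch k-mers total.
make_hist <- function(N, counts) {
  mult <- rep(as.integer(names(counts)), times = counts)
  sketchani:::new_histogram(as.integer(N), mult)
}

# One random substitution (uses the ambient RNG stream).
add_one_sub <- function(read) {
  v <- strsplit(read, NULL, fixed = TRUE)[[1]]
  i <- sample.int(length(v), 1L)
  v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}
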