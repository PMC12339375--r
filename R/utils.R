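# Run code with a local RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed derived from a base seed, kept below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index)) %% 2147483647
}

#' Reverse complement
#'
#' @param seqs Character vector of nucleotide sequences; non-ACGT characters
#'   map to `N`.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  .cpp_revcomp(as.character(seqs))
}
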