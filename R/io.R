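# Sketch file format, versioned. Binary dialect: little-endian, magic "NYSK",
# int32 version, int32 k, double c, int32 hash_seed, uint8 type (1 = genome,
# 2 = sample), then the payload. Hashes are written as doubles (all values
# are < 2^53 and therefore exact). A plain-text JSON debug dialect is
# selected by a ".json" extension.

SKETCH_MAGIC <- charToRaw("NYSK")
SKETCH_VERSION <- 1L

is_json_path <- function(path) grepl("\\.json$", path, ignore.case = TRUE)

#' Write a sketch to disk
#'
#' @param x A `genome_sketch` or `sample_sketch`.
#' @param path Output path; a `.json` extension selects the plain-text debug
#'   dialect, anything else the binary format.
#' @return `path`, invisibly.
#' @export
write_sketch <- function(x, path) {
  type <- if (inherits(x, "genome_sketch")) "genome"
  else if (inherits(x, "sample_sketch")) "sample"
  else stop("not a sketch object", call. = FALSE)
  if (is_json_path(path)) {
    payload <- list(magic = "NYSK", version = SKETCH_VERSION, type = type,
                    k = x$params$k, c = x$params$c,
                    hash_seed = x$params$hash_seed,
                    dedup_fp_rate = x$params$dedup_fp_rate)
    if (type == "genome") {
      payload$genome_id <- x$genome_id
      payload$genome_length <- x$genome_length
      payload$hashes <- x$kmers
    } else {
      payload$sample_id <- x$sample_id
      payload$total_bases <- x$total_bases
      payload$n_reads <- x$n_reads
      payload$mean_read_length <- x$mean_read_length
      payload$paired <- x$paired
      payload$dedup_applied <- x$dedup_applied
      payload$hashes <- x$hashes
      payload$counts <- x$counts
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wstr <- function(s) {
    raw <- charToRaw(enc2utf8(s))
    writeBin(length(raw), con, size = 4L, endian = "little")
    writeBin(raw, con)
  }
  writeBin(SKETCH_MAGIC, con)
  writeBin(c(SKETCH_VERSION, x$params$k), con, size = 4L, endian = "little")
  writeBin(x$params$c, con, size = 8L, endian = "little")
  writeBin(x$params$hash_seed, con, size = 4L, endian = "little")
  writeBin(x$params$dedup_fp_rate, con, size = 8L, endian = "little")
  writeBin(as.raw(if (type == "genome") 1L else 2L), con)
  if (type == "genome") {
    wstr(x$genome_id)
    writeBin(x$genome_length, con, size = 8L, endian = "little")
    writeBin(length(x$kmers), con, size = 4L, endian = "little")
    writeBin(x$kmers, con, size = 8L, endian = "little")
  } else {
    wstr(x$sample_id)
    writeBin(c(x$total_bases, x$n_reads, x$mean_read_length), con,
             size = 8L, endian = "little")
    writeBin(as.raw(c(x$paired, x$dedup_applied)), con)
    writeBin(length(x$hashes), con, size = 4L, endian = "little")
    writeBin(x$hashes, con, size = 8L, endian = "little")
    writeBin(as.integer(x$counts), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a sketch from disk
#'
#' Reads either dialect of the sketch format written by [write_sketch()].
#'
#' @param path Input path.
#' @return A `genome_sketch` or `sample_sketch`.
#' @export
read_sketch <- function(path) {
  if (is_json_path(path)) {
    p <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(p$magic, "NYSK")) stop("not a sketch file: ", path,
                                          call. = FALSE)
    if (p$version != SKETCH_VERSION)
      stop("unsupported sketch version: ", p$version, call. = FALSE)
    params <- sketch_params(p$k, p$c, p$hash_seed, p$dedup_fp_rate)
    if (p$type == "genome")
      return(structure(list(genome_id = p$genome_id,
                            genome_length = p$genome_length,
                            params = params,
                            kmers = as.numeric(p$hashes %||% numeric(0)),
                            n_kmers = length(p$hashes)),
                       class = "genome_sketch"))
    return(structure(list(sample_id = p$sample_id, params = params,
                          hashes = as.numeric(p$hashes %||% numeric(0)),
                          counts = as.integer(p$counts %||% integer(0)),
                          total_bases = p$total_bases, n_reads = p$n_reads,
                          mean_read_length = p$mean_read_length,
                          paired = p$paired,
                          dedup_applied = p$dedup_applied),
                     class = "sample_sketch"))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rstr <- function() {
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  magic <- readBin(con, "raw", 4L)
  if (!identical(magic, SKETCH_MAGIC)) stop("not a sketch file: ", path,
                                            call. = FALSE)
  hdr <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (hdr[1] != SKETCH_VERSION)
    stop("unsupported sketch version: ", hdr[1], call. = FALSE)
  c_ <- readBin(con, "double", 1L, size = 8L, endian = "little")
  hash_seed <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  fp <- readBin(con, "double", 1L, size = 8L, endian = "little")
  params <- sketch_params(hdr[2], c_, hash_seed, fp)
  type <- as.integer(readBin(con, "raw", 1L))
  if (type == 1L) {
    id <- rstr()
    gl <- readBin(con, "double", 1L, size = 8L, endian = "little")
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    hashes <- readBin(con, "double", n, size = 8L, endian = "little")
    structure(list(genome_id = id, genome_length = gl, params = params,
                   kmers = hashes, n_kmers = n),
              class = "genome_sketch")
  } else if (type == 2L) {
    id <- rstr()
    meta <- readBin(con, "double", 3L, size = 8L, endian = "little")
    flags <- as.logical(readBin(con, "raw", 2L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    hashes <- readBin(con, "double", n, size = 8L, endian = "little")
    counts <- readBin(con, "integer", n, size = 4L, endian = "little")
    structure(list(sample_id = id, params = params, hashes = hashes,
                   counts = counts, total_bases = meta[1], n_reads = meta[2],
                   mean_read_length = meta[3], paired = flags[1],
                   dedup_applied = flags[2]),
              class = "sample_sketch")
  } else stop("corrupt sketch file: unknown type byte", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read sequences from FASTA or FASTQ
#'
#' Format is detected from the first non-empty character (`>` FASTA, `@`
#' FASTQ); gzip compression is transparent.
#'
#' @param path Input path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) stop("empty sequence file: ", path, call. = FALSE)
  fmt <- if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else stop("unrecognized sequence format in ", path,
            " (record 1 starts with '", substr(first, 1, 1), "')",
            call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  setNames(as.character(x), names(x))
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path (gzip if it ends in `.gz`).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0(">", names(seqs), "\n", seqs), con)
  invisible(path)
}

#' Write a FASTQ file
#'
#' Qualities are a fixed high-quality symbol; the generator models errors
#' explicitly, so qualities carry no information.
#'
#' @param seqs Character vector of read sequences.
#' @param path Output path (gzip if it ends in `.gz`).
#' @param ids Optional read identifiers.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}
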