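# Internal helpers shared across stages.

#' Derive a reproducible substream seed from a root seed and a stage name
#'
#' All randomness in the package flows from one root seed; each stage
#' (genome, srna, degradome, rnaseq, ...) draws from its own named
#' substream so stages can be regenerated independently.
#'
#' @param seed integer root seed.
#' @param stream character stage name.
#' @return An integer seed < 2^31, deterministic in both arguments.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(seed) * 1009 + h) %% .Machine$integer.max)
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

# reverse complement of a plain character string (DNA alphabet)
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- rna_to_dna(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

random_dna <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Write named character vector as FASTA (plain text, 70-col wrap)
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = 70)
    writeLines(substring(s, starts, pmin(starts + 69, nchar(s))), con)
  }
  invisible(path)
}

read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
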