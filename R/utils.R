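#' Reverse-complement a nucleotide sequence
#'
#' Works on plain character vectors in the DNA or RNA alphabet (case kept).
#' U is complemented like T, so miRNA (RNA) and transcript (DNA) sequences
#' can be mixed freely.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements, in the DNA alphabet.
#' @export
revcomp <- function(seq) {
  flipped <- chartr("ACGTUacgtu", "TGCAAtgcaa", seq)
  vapply(strsplit(flipped, ""), function(x) paste(rev(x), collapse = ""), "")
}

# Normalize to uppercase DNA alphabet (U -> T); internal canonical form.
norm_dna <- function(seq) chartr("acgtuU", "ACGTTT", seq)

# Uppercase RNA form (T -> U), used when writing miRNA sequences out.
as_rna <- function(seq) chartr("acgtT", "ACGUU", seq)

# Random DNA of given lengths, vectorized over `len`.
random_dna <- function(len) {
  vapply(len, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
}

# Watson-Crick complement (no reversal), DNA alphabet out.
wc_complement <- function(seq) chartr("ACGTU", "TGCAA", seq)

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
}

# Write a TSV with a single '# stage: ...' provenance comment, as emitted by
# every pipeline stage.
write_stage_tsv <- function(df, path, stage = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(stage)) {
    writeLines(sprintf("# stage: %s", stage), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
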