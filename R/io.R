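#' Write synthetic references to FASTA and an annotation TSV
#'
#' @param refs list from [generate_references()].
#' @param dir output directory (created if missing).
#' @return invisible named vector of the written paths (transcripts_fasta,
#'   mirnas_fasta, annotation_tsv, seed_sites_tsv).
#' @export
write_references <- function(refs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx_path <- file.path(dir, "transcripts.fa")
  mir_path <- file.path(dir, "mirnas.fa")
  ann_path <- file.path(dir, "annotation.tsv")
  sites_path <- file.path(dir, "seed_sites.tsv")
  tx <- Biostrings::DNAStringSet(refs$transcripts$sequence)
  names(tx) <- refs$transcripts$transcript_id
  Biostrings::writeXStringSet(tx, tx_path)
  mir <- Biostrings::RNAStringSet(as_rna(refs$mirnas$sequence))
  names(mir) <- refs$mirnas$name
  Biostrings::writeXStringSet(mir, mir_path)
  con <- file(ann_path, "w")
  writeLines("# cds_start/cds_end are 0-based half-open transcript coordinates",
             con)
  utils::write.table(
    refs$transcripts[, c("transcript_id", "gene_id", "length", "cds_start",
                         "cds_end")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (!is.null(refs$seed_sites)) {
    write_stage_tsv(refs$seed_sites, sites_path, "generate_references")
  }
  invisible(c(transcripts_fasta = tx_path, mirnas_fasta = mir_path,
              annotation_tsv = ann_path, seed_sites_tsv = sites_path))
}

#' Read a FASTA file into a two-column data.frame
#'
#' @param path FASTA path.
#' @param id_col name for the id column.
#' @return data.frame with the id column and `sequence`.
#' @export
read_fasta_df <- function(path, id_col = "id") {
  x <- Biostrings::readBStringSet(path)
  df <- data.frame(id = names(x), sequence = as.character(x),
                   stringsAsFactors = FALSE, row.names = NULL)
  names(df)[1] <- id_col
  df
}

#' Write a simulated library to paired FASTQ plus ground truth
#'
#' @param sim a `qclash_sim` object.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return invisible named vector of paths (r1, r2, truth).
#' @export
write_sim_library <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r1 <- file.path(dir, paste0(prefix, "_R1.fastq"))
  r2 <- file.path(dir, paste0(prefix, "_R2.fastq"))
  tr <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write_fastq(sim$reads$read_id, sim$reads$seq1, sim$reads$qual1, r1)
  write_fastq(sim$reads$read_id, sim$reads$seq2, sim$reads$qual2, r2)
  write_stage_tsv(sim$truth, tr, "simulate_library")
  invisible(c(r1 = r1, r2 = r2, truth = tr))
}

#' Write sequences and qualities to a FASTQ file
#'
#' @param ids,seqs,quals equal-length character vectors.
#' @param path output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  q <- Biostrings::PhredQuality(quals)
  x <- Biostrings::QualityScaledDNAStringSet(Biostrings::DNAStringSet(seqs),
                                             q)
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Read a paired-end FASTQ library
#'
#' @param r1_path,r2_path mate FASTQ paths.
#' @return data.frame with read_id, seq1, qual1, seq2, qual2.
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  read1 <- function(p) {
    # Biostrings warns that FASTQ metadata columns are dropped; they carry
    # nothing this pipeline uses
    withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(p),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  x1 <- read1(r1_path)
  x2 <- read1(r2_path)
  stopifnot(length(x1) == length(x2))
  data.frame(
    read_id = sub("\\s.*$", "", names(x1)),
    seq1 = as.character(x1), qual1 = as.character(Biostrings::quality(x1)),
    seq2 = as.character(x2), qual2 = as.character(Biostrings::quality(x2)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write hybrid calls as a hyb-style TSV
#'
#' Coordinates are converted from the internal 0-based half-open convention
#' to 1-based inclusive in the file.
#'
#' @param calls data.frame from [call_hybrids()] (optionally annotated).
#' @param path output path.
#' @param stage stage label for the header comment.
#' @export
write_hyb_tsv <- function(calls, path, stage = "hybcall") {
  df <- calls[calls$call == "hybrid",
              setdiff(names(calls), "sequence"), drop = FALSE]
  for (col in c("mirna_ref_start", "target_ref_start")) {
    df[[col]] <- df[[col]] + 1L
  }
  write_stage_tsv(df, path, stage)
}

#' Write duplex folds in a viennad-like format
#'
#' Five lines per hybrid: a header with ids and 1-based inclusive target
#' coordinates, the miRNA sequence, its dot-bracket string, the target
#' fragment sequence, its dot-bracket string, then the duplex score.
#'
#' @param calls data.frame from [call_hybrids()].
#' @param path output path.
#' @export
write_viennad <- function(calls, path) {
  folds <- attr(calls, "folds")
  con <- file(path, "w")
  on.exit(close(con))
  hyb <- calls[calls$call == "hybrid", ]
  for (i in seq_len(nrow(hyb))) {
    f <- folds[[hyb$read_id[i]]]
    writeLines(c(
      sprintf(">%s %s %s:%d-%d", hyb$read_id[i], hyb$mirna_name[i],
              hyb$transcript_id[i], hyb$target_ref_start[i] + 1L,
              hyb$target_ref_end[i]),
      as_rna(f$mirna_seq),
      f$mirna_dotbracket,
      f$target_seq,
      f$target_dotbracket,
      sprintf("score\t%g", f$score)
    ), con)
  }
  invisible(path)
}

#' Write target sites as a BED-like transcript-space table
#'
#' @param sites data.frame from [merge_sites()].
#' @param path output path.
#' @export
write_sites_tsv <- function(sites, path) {
  write_stage_tsv(sites, path, "cluster")
}

#' Read a fold-change TSV (gene_id, log2fc, pvalue)
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_fold_changes <- function(path) {
  fc <- read_stage_tsv(path)
  if (!all(c("gene_id", "log2fc") %in% names(fc))) {
    stop("fold-change table needs gene_id and log2fc columns",
         call. = FALSE)
  }
  fc
}
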