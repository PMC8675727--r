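#' Trim a 3' sequencing adapter from a read
#'
#' Removes the best-scoring adapter occurrence and everything 3' of it. An
#' occurrence is either the full adapter anywhere in the read or a 3'
#' terminal prefix of the adapter of at least `min_overlap` nt; in both
#' cases at most `max_err_frac` of the aligned bases may mismatch. Score is
#' matches minus 2x mismatches; ties go to the 5'-most occurrence. Reads
#' without an acceptable occurrence are returned unchanged.
#'
#' @param seq character vector of read sequences.
#' @param adapter3 adapter sequence (nonempty).
#' @param min_overlap minimum aligned adapter prefix at the read 3' end
#'   (>= 5).
#' @param max_err_frac maximum mismatch fraction over the aligned bases.
#' @return character vector of trimmed sequences.
#' @export
trim_adapter <- function(seq, adapter3, min_overlap = 5L,
                         max_err_frac = 0.1) {
  if (!nzchar(adapter3)) stop("adapter must be nonempty", call. = FALSE)
  if (min_overlap < 5L) stop("min_overlap must be >= 5", call. = FALSE)
  adapter3 <- norm_dna(adapter3)
  achars <- strsplit(adapter3, "")[[1]]
  alen <- length(achars)
  vapply(seq, USE.NAMES = FALSE, FUN.VALUE = "", function(s) {
    n <- nchar(s)
    # fast path: leftmost exact full-adapter occurrence is always optimal
    hit <- regexpr(adapter3, s, fixed = TRUE)
    if (hit > 0L) return(substr(s, 1L, hit - 1L))
    chars <- strsplit(s, "")[[1]]
    best_score <- -Inf
    best_pos <- NA_integer_
    for (p in seq_len(n)) {
      len <- min(alen, n - p + 1L)
      if (len < alen && p + len - 1L < n) break  # not 3'-terminal
      if (len < min_overlap) break
      mm <- sum(chars[p:(p + len - 1L)] != achars[seq_len(len)])
      if (mm / len > max_err_frac) next
      score <- (len - mm) - 2L * mm
      if (score > best_score) {
        best_score <- score
        best_pos <- p
      }
    }
    if (is.na(best_pos)) s else substr(s, 1L, best_pos - 1L)
  })
}

#' Merge a read pair into a single insert sequence
#'
#' Reverse-complements mate 2 and scans for the longest suffix(mate 1) /
#' prefix(rc mate 2) overlap of at least `min_overlap` nt with mismatch
#' fraction at most `max_mismatch_frac`. At disagreeing overlap positions
#' the higher-quality base wins (mate 1 on quality ties).
#'
#' @param seq1,qual1 mate 1 sequence and quality string.
#' @param seq2,qual2 mate 2 sequence and quality string (original
#'   orientation).
#' @param min_overlap minimum overlap length.
#' @param max_mismatch_frac maximum mismatch fraction in the overlap.
#' @return list(seq, qual) on success or NULL on merge failure.
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 10L,
                        max_mismatch_frac = 0.1) {
  if (!nzchar(seq1) || !nzchar(seq2)) return(NULL)
  c1 <- strsplit(seq1, "")[[1]]
  q1 <- strsplit(qual1, "")[[1]]
  c2 <- rev(strsplit(chartr("ACGTUacgtu", "TGCAAtgcaa", seq2), "")[[1]])
  q2 <- rev(strsplit(qual2, "")[[1]])
  n1 <- length(c1)
  n2 <- length(c2)
  if (min(n1, n2) < min_overlap) return(NULL)
  for (o in seq(min(n1, n2), min_overlap)) {
    i1 <- (n1 - o + 1L):n1
    i2 <- seq_len(o)
    mm <- c1[i1] != c2[i2]
    if (sum(mm) / o > max_mismatch_frac) next
    ov_seq <- c1[i1]
    ov_qual <- q1[i1]
    use2 <- mm & (q2[i2] > q1[i1])
    ov_seq[use2] <- c2[i2][use2]
    ov_qual[use2] <- q2[i2][use2]
    better2 <- !mm & (q2[i2] > q1[i1])
    ov_qual[better2] <- q2[i2][better2]
    return(list(
      seq = paste(c(c1[seq_len(n1 - o)], ov_seq, c2[-(seq_len(o))]),
                  collapse = ""),
      qual = paste(c(q1[seq_len(n1 - o)], ov_qual, q2[-(seq_len(o))]),
                   collapse = "")
    ))
  }
  NULL
}

#' Collapse exact duplicate sequences
#'
#' One record per distinct sequence; counts sum to the input size. Output is
#' ordered by descending count, ties broken lexicographically by sequence.
#'
#' @param seqs character vector of sequences.
#' @param ids optional read ids; the first-seen id becomes the
#'   representative.
#' @return data.frame with columns sequence, count, representative_id.
#' @export
collapse_duplicates <- function(seqs, ids = NULL) {
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      representative_id = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(ids)) ids <- sprintf("seq%06d", seq_along(seqs))
  tab <- table(seqs)
  uniq <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, uniq)
  data.frame(
    sequence = uniq[ord],
    count = counts[ord],
    representative_id = ids[match(uniq[ord], seqs)],
    stringsAsFactors = FALSE
  )
}

#' Strip degenerate UMI nucleotides from both ends of an insert
#'
#' Removes the first `n5` and last `n3` bases (the adapter-derived unique
#' molecular identifiers). Reads whose remaining insert would be shorter
#' than `min_insert` are discarded (returned as NA and counted by the
#' caller).
#'
#' @param seq character vector of insert sequences.
#' @param n5,n3 UMI lengths on the 5' and 3' ends.
#' @param min_insert minimum interior insert length to keep a read.
#' @return character vector; NA for discarded reads.
#' @export
trim_umi <- function(seq, n5 = 4L, n3 = 4L, min_insert = 16L) {
  len <- nchar(seq)
  out <- ifelse(len > n5 + n3 + min_insert - 1L,
                substr(seq, n5 + 1L, len - n3), NA_character_)
  out[len <= n5 + n3] <- NA_character_
  out
}

#' Run the read-preprocessing chain on a paired-end library
#'
#' Applies the fixed stage order: adapter trimming (mate 1 at its 3' end;
#' mate 2 at its 5' end, which is the adapter's reverse complement side),
#' pair merging, exact duplicate collapsing (UMIs still attached, so
#' identical inserts from distinct molecules stay distinct), then UMI
#' trimming with a minimum-length filter.
#'
#' @param reads data.frame with columns read_id, seq1, qual1, seq2, qual2,
#'   or a `qclash_sim` object.
#' @param adapter3 3' adapter sequence.
#' @param umi_len UMI length per end.
#' @param min_insert minimum UMI-stripped insert length.
#' @param min_overlap,max_mismatch_frac pair-merging parameters.
#' @return list with `inserts` (data.frame: sequence, count,
#'   representative_id) and `log` (named integer vector of per-stage read
#'   counts).
#' @export
preprocess_reads <- function(reads, adapter3, umi_len = 4L,
                             min_insert = 16L, min_overlap = 10L,
                             max_mismatch_frac = 0.1) {
  if (inherits(reads, "qclash_sim")) reads <- reads$reads
  n_in <- nrow(reads)
  t1 <- trim_adapter(reads$seq1, adapter3)
  # the mate-2 contaminant is the reverse complement of the 3' adapter at
  # its 5' end: trim in reverse-complement space, then flip back
  rc2 <- trim_adapter(revcomp(reads$seq2), adapter3)
  q1 <- substr(reads$qual1, 1L, nchar(t1))
  l2 <- nchar(rc2)
  seq2 <- revcomp(rc2)
  q2 <- substr(reads$qual2, nchar(reads$seq2) - l2 + 1L, nchar(reads$seq2))

  merged <- character(n_in)
  ok <- logical(n_in)
  for (i in seq_len(n_in)) {
    m <- merge_pairs(t1[i], q1[i], seq2[i], q2[i],
                     min_overlap = min_overlap,
                     max_mismatch_frac = max_mismatch_frac)
    if (!is.null(m)) {
      merged[i] <- m$seq
      ok[i] <- TRUE
    }
  }
  collapsed <- collapse_duplicates(merged[ok], reads$read_id[ok])
  trimmed <- trim_umi(collapsed$sequence, umi_len, umi_len, min_insert)
  keep <- !is.na(trimmed)
  inserts <- data.frame(
    sequence = trimmed[keep],
    count = collapsed$count[keep],
    representative_id = collapsed$representative_id[keep],
    stringsAsFactors = FALSE
  )
  list(
    inserts = inserts,
    log = c(
      reads_in = n_in,
      pairs_merged = sum(ok),
      merge_failed = sum(!ok),
      unique_after_collapse = nrow(collapsed),
      discarded_short = sum(!keep),
      inserts_out = nrow(inserts)
    )
  )
}
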