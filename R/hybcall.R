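#' Build a k-mer index over miRNA and transcript references
#'
#' Every k-mer of every reference is stored with its (reference, offset)
#' origin; U and T are treated as equivalent. The index seeds the ungapped
#' arm alignments of [detect_hybrid()].
#'
#' @param mirnas data.frame with columns name, sequence.
#' @param transcripts data.frame with columns transcript_id, sequence.
#' @param k k-mer size; must not exceed the shortest miRNA.
#' @return object of class `ref_index`.
#' @export
build_index <- function(mirnas, transcripts, k = 12L) {
  stopifnot(nrow(mirnas) > 0, nrow(transcripts) > 0)
  ids <- c(mirnas$name, transcripts$transcript_id)
  if (anyDuplicated(ids)) stop("duplicate reference ids", call. = FALSE)
  seqs <- norm_dna(c(mirnas$sequence, transcripts$sequence))
  if (k > min(nchar(norm_dna(mirnas$sequence)))) {
    stop("k must not exceed the shortest miRNA", call. = FALSE)
  }
  cls <- rep(c("mirna", "transcript"), c(nrow(mirnas), nrow(transcripts)))
  lens <- nchar(seqs)
  nk <- lens - k + 1L
  kmers <- unlist(lapply(seq_along(seqs), function(i) {
    substring(seqs[i], seq_len(nk[i]), seq_len(nk[i]) + k - 1L)
  }))
  kmer_ref <- rep(seq_along(seqs), nk)
  kmer_off <- unlist(lapply(nk, seq_len)) - 1L  # 0-based offsets
  env <- list2env(split(seq_along(kmers), kmers), hash = TRUE,
                  size = length(kmers))
  structure(list(
    k = as.integer(k),
    env = env,
    ref_id = ids,
    ref_class = cls,
    ref_seq = seqs,
    ref_chars = strsplit(seqs, ""),
    kmer_ref = kmer_ref,
    kmer_off = kmer_off
  ), class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("k-mer reference index: k=%d, %d miRNAs, %d transcripts\n",
              x$k, sum(x$ref_class == "mirna"),
              sum(x$ref_class == "transcript")))
  invisible(x)
}

# Best ungapped segment on one diagonal: takes the match/mismatch logical
# vector over the valid window (read coords a..b) and returns the segment
# with <= max_mm mismatches maximizing score (match +1, mismatch -2).
# Optimal segments start and end on matches, so candidate boundaries are the
# mismatch positions.
.best_segment <- function(cmp, a, max_mm) {
  b <- a + length(cmp) - 1L
  mm_pos <- a - 1L + which(!cmp)
  bound <- c(a - 1L, mm_pos, b + 1L)
  nb <- length(bound)
  best <- NULL
  for (j in 0:max_mm) {
    if (nb - 1L - j < 1L) break
    for (i in seq_len(nb - 1L - j)) {
      s <- bound[i] + 1L
      e <- bound[i + j + 1L] - 1L
      len <- e - s + 1L
      if (len <= 0L) next
      score <- (len - j) - 2L * j
      if (is.null(best) || score > best$score ||
          (score == best$score && j < best$mm)) {
        best <- list(start = s, end = e, mm = j, score = score,
                     mm_pos = mm_pos[mm_pos > s & mm_pos < e])
      }
    }
  }
  best
}

# Shrink an arm by `d` read positions from one side, then strip any
# mismatches newly exposed at either end (segments should end on matches).
.trim_arm <- function(arm, side, d) {
  rs <- arm$read_start
  re <- arm$read_end
  if (side == "right") re <- re - d else rs <- rs + d
  mp <- arm$mm_pos
  repeat {
    if (re < rs) return(NULL)
    if (re %in% mp) { re <- re - 1L; next }
    if (rs %in% mp) { rs <- rs + 1L; next }
    break
  }
  mp <- mp[mp >= rs & mp <= re]
  len <- re - rs + 1L
  arm$read_start <- rs
  arm$read_end <- re
  arm$ref_start <- rs + arm$diag
  arm$ref_end <- re + arm$diag
  arm$mm_pos <- mp
  arm$mm <- length(mp)
  arm$score <- (len - arm$mm) - 2L * arm$mm
  arm
}

#' Resolve one insert into miRNA and target arms
#'
#' Seeds candidate ungapped alignments by k-mer hits, extends each diagonal
#' allowing at most `max_mismatch` mismatches (match +1, mismatch -2), and
#' calls a hybrid when a miRNA-class arm and a transcript-class arm of at
#' least `min_arm_len` nt each can be arranged on the read without overlap
#' and with an inter-arm gap of at most 4 nt. Overlapping candidate arms are
#' reconciled by trimming the junction-facing end of whichever arm loses
#' less score. Among feasible pairs the summed score is maximized; ties are
#' broken by fewer total mismatches, then lexicographic reference ids, then
#' leftmost target then miRNA reference start. An insert matching only one
#' reference class yields a single-arm call.
#'
#' @param seq insert sequence (one string).
#' @param index a `ref_index` from [build_index()].
#' @param min_arm_len minimum arm length in nt.
#' @param max_mismatch maximum mismatches per arm.
#' @return list with `call` in {"hybrid", "single_arm_mirna",
#'   "single_arm_transcript", "unmapped"}; for hybrids, `mirna` and `target`
#'   arm lists (ref_id, ref_start, ref_end, read_start, read_end 0-based
#'   half-open, mm, score) and `order`; for single-arm calls, `arm`.
#' @export
detect_hybrid <- function(seq, index, min_arm_len = 16L, max_mismatch = 2L) {
  n <- nchar(seq)
  k <- index$k
  if (n < max(min_arm_len, k)) return(list(call = "unmapped"))
  seq <- norm_dna(seq)
  chars <- strsplit(seq, "")[[1]]
  nk <- n - k + 1L
  kmers <- substring(seq, seq_len(nk), seq_len(nk) + k - 1L)
  hits <- mget(kmers, envir = index$env, ifnotfound = list(NULL))
  nh <- lengths(hits)
  if (sum(nh) == 0L) return(list(call = "unmapped"))
  glob <- unlist(hits, use.names = FALSE)
  read_off <- rep.int(seq_len(nk) - 1L, nh)
  ref <- index$kmer_ref[glob]
  dg <- index$kmer_off[glob] - read_off  # ref_pos(0b) - read_pos(0b)
  key <- ref * 10000000 + dg
  first <- !duplicated(key)

  arms <- list()
  for (ci in which(first)) {
    r <- ref[ci]
    d <- dg[ci]
    rc <- index$ref_chars[[r]]
    lr <- length(rc)
    a <- max(1L, 1L - d)           # 1-based read positions; ref pos = i + d
    b <- min(n, lr - d)
    if (b - a + 1L < min_arm_len) next
    cmp <- chars[a:b] == rc[(a:b) + d]
    seg <- .best_segment(cmp, a, max_mismatch)
    if (is.null(seg) || seg$end - seg$start + 1L < min_arm_len) next
    arms[[length(arms) + 1L]] <- list(
      ref = r, ref_id = index$ref_id[r], class = index$ref_class[r],
      diag = d, read_start = seg$start, read_end = seg$end,
      ref_start = seg$start + d, ref_end = seg$end + d,
      mm = seg$mm, mm_pos = seg$mm_pos, score = seg$score
    )
  }
  if (!length(arms)) return(list(call = "unmapped"))
  cls <- vapply(arms, `[[`, "", "class")
  scores <- vapply(arms, `[[`, 0L, "score")

  pick_best <- function(sel) {
    cand <- arms[sel]
    o <- order(-vapply(cand, `[[`, 0L, "score"),
               vapply(cand, `[[`, 0L, "mm"),
               vapply(cand, `[[`, "", "ref_id"),
               vapply(cand, `[[`, 0L, "ref_start"))
    cand[[o[1]]]
  }

  has_mir <- any(cls == "mirna")
  has_tx <- any(cls == "transcript")
  if (!has_mir || !has_tx) {
    arm <- pick_best(seq_along(arms))
    arm$read_start <- arm$read_start - 1L  # to 0-based half-open
    arm$ref_start <- arm$ref_start - 1L
    return(list(
      call = if (has_mir) "single_arm_mirna" else "single_arm_transcript",
      arm = arm
    ))
  }

  top_k <- function(which_cls, kmax = 8L) {
    sel <- which(cls == which_cls)
    sel[order(-scores[sel])][seq_len(min(kmax, length(sel)))]
  }
  best <- NULL
  for (mi in top_k("mirna")) {
    for (ti in top_k("transcript")) {
      m <- arms[[mi]]
      t <- arms[[ti]]
      if (m$read_start <= t$read_start) {
        left <- m; right <- t; ord <- "mirna_first"
      } else {
        left <- t; right <- m; ord <- "mirna_last"
      }
      gap <- right$read_start - left$read_end - 1L
      if (gap > 4L) next
      if (gap < 0L) {
        d <- -gap
        o1l <- .trim_arm(left, "right", d)
        o2r <- .trim_arm(right, "left", d)
        s1 <- if (is.null(o1l)) -Inf else o1l$score + right$score
        s2 <- if (is.null(o2r)) -Inf else left$score + o2r$score
        if (s1 == -Inf && s2 == -Inf) next
        # prefer the trim losing less score; on ties trim the target arm
        trim_left_arm <- s1 > s2 ||
          (s1 == s2 && left$class == "transcript")
        if (trim_left_arm) left <- o1l else right <- o2r
      }
      if (left$read_end - left$read_start + 1L < min_arm_len ||
          right$read_end - right$read_start + 1L < min_arm_len) next
      marm <- if (ord == "mirna_first") left else right
      tarm <- if (ord == "mirna_first") right else left
      cand <- list(
        mirna = marm, target = tarm, order = ord,
        score = marm$score + tarm$score, mm = marm$mm + tarm$mm
      )
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && (cand$mm < best$mm ||
            (cand$mm == best$mm && (cand$mirna$ref_id < best$mirna$ref_id ||
              (cand$mirna$ref_id == best$mirna$ref_id &&
                (cand$target$ref_id < best$target$ref_id ||
                  (cand$target$ref_id == best$target$ref_id &&
                    (cand$target$ref_start < best$target$ref_start ||
                      (cand$target$ref_start == best$target$ref_start &&
                        cand$mirna$ref_start < best$mirna$ref_start)))))))))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    arm <- pick_best(seq_along(arms))
    arm$read_start <- arm$read_start - 1L
    arm$ref_start <- arm$ref_start - 1L
    return(list(
      call = if (arm$class == "mirna") "single_arm_mirna"
             else "single_arm_transcript",
      arm = arm
    ))
  }
  for (nm in c("mirna", "target")) {  # to 0-based half-open
    best[[nm]]$read_start <- best[[nm]]$read_start - 1L
    best[[nm]]$ref_start <- best[[nm]]$ref_start - 1L
  }
  list(call = "hybrid", mirna = best$mirna, target = best$target,
       order = best$order, score = best$score)
}

#' Call hybrids for a table of collapsed inserts
#'
#' Runs [detect_hybrid()] on every insert, folds the miRNA:target duplex of
#' each hybrid with [fold_duplex()] and classifies seed binding with
#' [classify_seed()].
#'
#' @param inserts data.frame from [preprocess_reads()] (columns sequence,
#'   count, representative_id).
#' @param index a `ref_index`.
#' @param min_arm_len,max_mismatch arm-calling parameters.
#' @return data.frame with one row per insert: read_id, sequence, count,
#'   call, mirna_name, mirna_ref_start, mirna_ref_end, mirna_mm,
#'   transcript_id, target_ref_start, target_ref_end, target_mm, order,
#'   duplex_score, seed_class (coordinates 0-based half-open). The duplex
#'   folds of hybrid rows are attached as attribute "folds" (named by
#'   read_id) for the viennad writer.
#' @export
call_hybrids <- function(inserts, index, min_arm_len = 16L,
                         max_mismatch = 2L) {
  nr <- nrow(inserts)
  out <- data.frame(
    read_id = inserts$representative_id,
    sequence = inserts$sequence,
    count = inserts$count,
    call = character(nr),
    mirna_name = NA_character_,
    mirna_ref_start = NA_integer_, mirna_ref_end = NA_integer_,
    mirna_mm = NA_integer_,
    transcript_id = NA_character_,
    target_ref_start = NA_integer_, target_ref_end = NA_integer_,
    target_mm = NA_integer_,
    order = NA_character_,
    duplex_score = NA_real_,
    seed_class = NA_character_,
    stringsAsFactors = FALSE
  )
  folds <- list()
  for (i in seq_len(nr)) {
    h <- detect_hybrid(inserts$sequence[i], index, min_arm_len, max_mismatch)
    out$call[i] <- h$call
    if (h$call == "hybrid") {
      out$mirna_name[i] <- h$mirna$ref_id
      out$mirna_ref_start[i] <- h$mirna$ref_start
      out$mirna_ref_end[i] <- h$mirna$ref_end
      out$mirna_mm[i] <- h$mirna$mm
      out$transcript_id[i] <- h$target$ref_id
      out$target_ref_start[i] <- h$target$ref_start
      out$target_ref_end[i] <- h$target$ref_end
      out$target_mm[i] <- h$target$mm
      out$order[i] <- h$order
      mir_seq <- index$ref_seq[h$mirna$ref]
      tgt_seq <- substr(index$ref_seq[h$target$ref],
                        h$target$ref_start + 1L, h$target$ref_end)
      fold <- fold_duplex(mir_seq, tgt_seq)
      out$duplex_score[i] <- fold$score
      out$seed_class[i] <- classify_seed(fold, mir_seq)
      folds[[out$read_id[i]]] <- fold
    } else if (h$call != "unmapped") {
      if (h$arm$class == "mirna") {
        out$mirna_name[i] <- h$arm$ref_id
        out$mirna_ref_start[i] <- h$arm$ref_start
        out$mirna_ref_end[i] <- h$arm$ref_end
        out$mirna_mm[i] <- h$arm$mm
      } else {
        out$transcript_id[i] <- h$arm$ref_id
        out$target_ref_start[i] <- h$arm$ref_start
        out$target_ref_end[i] <- h$arm$ref_end
        out$target_mm[i] <- h$arm$mm
      }
    }
  }
  attr(out, "folds") <- folds
  out
}

#' Per-miRNA normalized counts from single-arm miRNA calls
#'
#' Sums collapsed-read copies per miRNA over single-arm miRNA-class calls
#' and normalizes to counts per million of the miRNA-class total.
#'
#' @param calls data.frame from [call_hybrids()].
#' @return data.frame with columns mirna_name, count, cpm, sorted by
#'   descending count.
#' @export
count_mirnas <- function(calls) {
  sel <- calls$call == "single_arm_mirna"
  if (!any(sel)) stop("no miRNA-class single-arm calls", call. = FALSE)
  agg <- stats::aggregate(count ~ mirna_name, data = calls[sel, ],
                          FUN = sum)
  total <- sum(agg$count)
  agg$cpm <- agg$count / total * 1e6
  agg[order(-agg$count, agg$mirna_name), ]
}
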