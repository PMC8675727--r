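#' Fold the intermolecular duplex between a miRNA and its target fragment
#'
#' Aligns the miRNA (5'->3') against the reversed target by dynamic
#' programming with a simple additive pairing model: Watson-Crick pair +2,
#' G:U wobble +1, opposed-but-unpaired (mismatch) -1, internal unaligned
#' base (gap) -2. As in duplex-folding tools, dangling ends are free: bases
#' outside the aligned block on either molecule are not penalized, so a
#' short contiguous helix (such as a canonical seed match) is preferred
#' over a diffuse weave of isolated chance pairs. Only Watson-Crick and
#' G:U columns become base pairs in the output. Among score-optimal
#' alignments the one with the most base pairs is reported, with traceback
#' preferring pairings toward the miRNA 5' end. The pair list is
#' antiparallel-monotone and non-crossing by construction.
#'
#' The model deliberately replaces nearest-neighbor thermodynamics: seed
#' classification depends only on the pairing topology, which the additive
#' scores preserve.
#'
#' @param mirna_seq miRNA sequence (RNA or DNA alphabet).
#' @param target_seq target fragment sequence.
#' @param scoring named numeric vector with elements wc, gu, mismatch, gap.
#' @return object of class `duplex_fold`: list with `pairs` (integer matrix,
#'   columns mirna_pos/target_pos, 1-based, miRNA ascending and target
#'   descending), `mirna_dotbracket`, `target_dotbracket`, `score`,
#'   `mirna_seq`, `target_seq`.
#' @export
fold_duplex <- function(mirna_seq, target_seq,
                        scoring = c(wc = 2, gu = 1, mismatch = -1,
                                    gap = -2)) {
  if (!nzchar(mirna_seq) || !nzchar(target_seq)) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  m <- strsplit(norm_dna(mirna_seq), "")[[1]]
  t5 <- strsplit(norm_dna(target_seq), "")[[1]]
  nm <- length(m)
  nt <- length(t5)
  tr <- rev(t5)  # antiparallel: miRNA 5'->3' vs target 3'->5'

  # combined integer DP value: 256 * score + npairs, so the optimum is
  # lexicographic (max score, then max pairs); |score| and npairs both stay
  # far below the packing radix for <= 60 nt inputs
  pair_val <- function(a, b) {
    wc <- (a == "A" & b == "T") | (a == "T" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
    gu <- (a == "G" & b == "T") | (a == "T" & b == "G")
    ifelse(wc, 256 * scoring[["wc"]] + 1,
           ifelse(gu, 256 * scoring[["gu"]] + 1,
                  256 * scoring[["mismatch"]]))
  }
  g <- 256 * scoring[["gap"]]
  H <- matrix(0, nm + 1L, nt + 1L)
  jj <- 0:nt
  for (i in seq_len(nm)) {
    sv <- pair_val(m[i], tr)
    A <- c(0, pmax(H[i, 1:nt] + sv, H[i, 2:(nt + 1)] + g))
    # the 0 floor lets the aligned block start anywhere (free leading ends)
    H[i + 1L, ] <- pmax(0, cummax(A - g * jj) + g * jj)
  }
  # free trailing ends: the block may end anywhere; among score maxima take
  # the 5'-most (smallest miRNA, then target-reversed index) end point
  hv <- max(H)
  ends <- which(H == hv, arr.ind = TRUE)
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  i <- ends[1, 1] - 1L
  j <- ends[1, 2] - 1L
  npairs <- hv %% 256
  score <- (hv - npairs) / 256

  # traceback, preferring diagonal, then up (miRNA base unaligned last)
  pairs <- NULL
  while (i > 0L && j > 0L) {
    v <- H[i + 1L, j + 1L]
    if (v == 0) break
    sv <- pair_val(m[i], tr[j])
    if (v == H[i, j] + sv) {
      if (sv > 0) pairs <- rbind(pairs, c(i, nt - j + 1L))
      i <- i - 1L
      j <- j - 1L
    } else if (v == H[i, j + 1L] + g) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  pairs <- if (is.null(pairs)) {
    matrix(integer(), 0, 2, dimnames = list(NULL, c("mirna_pos",
                                                    "target_pos")))
  } else {
    colnames(pairs) <- c("mirna_pos", "target_pos")
    pairs[order(pairs[, 1]), , drop = FALSE]
  }
  stopifnot(nrow(pairs) == npairs)
  mdb <- rep(".", nm)
  mdb[pairs[, 1]] <- "("
  tdb <- rep(".", nt)
  tdb[pairs[, 2]] <- ")"
  structure(list(
    pairs = pairs,
    mirna_dotbracket = paste(mdb, collapse = ""),
    target_dotbracket = paste(tdb, collapse = ""),
    score = score,
    mirna_seq = mirna_seq,
    target_seq = target_seq
  ), class = "duplex_fold")
}

#' @export
print.duplex_fold <- function(x, ...) {
  cat(sprintf("duplex fold: %d pairs, score %g\n", nrow(x$pairs), x$score))
  cat(" miRNA  5' ", as_rna(x$mirna_seq), " 3'\n", sep = "")
  cat("           ", x$mirna_dotbracket, "\n", sep = "")
  cat(" target 5' ", x$target_seq, " 3'\n", sep = "")
  cat("           ", x$target_dotbracket, "\n", sep = "")
  invisible(x)
}

#' Classify seed binding of a folded miRNA:target duplex
#'
#' Canonical targeting pairs the miRNA seed (nucleotides 2-7, sometimes
#' extended to 8) with the target by Watson-Crick base pairing. A duplex is
#' `seed_m2_8` when miRNA positions 2-8 are all Watson-Crick paired with
#' consecutive target positions, `seed_m2_7` when positions 2-7 are,
#' otherwise `non_seed` (G:U wobbles and bulged seeds do not count as
#' canonical).
#'
#' @param fold a `duplex_fold` produced from `mirna_seq`.
#' @param mirna_seq the miRNA sequence the fold was computed from.
#' @return one of "seed_m2_8", "seed_m2_7", "non_seed".
#' @export
classify_seed <- function(fold, mirna_seq) {
  m <- strsplit(norm_dna(mirna_seq), "")[[1]]
  t5 <- strsplit(norm_dna(fold$target_seq), "")[[1]]
  seed_paired <- function(last_pos) {
    pos <- 2:last_pos
    idx <- match(pos, fold$pairs[, 1])
    if (anyNA(idx)) return(FALSE)
    tpos <- fold$pairs[idx, 2]
    if (any(diff(tpos) != -1L)) return(FALSE)  # consecutive, antiparallel
    all(wc_complement(m[pos]) == t5[tpos])
  }
  if (length(fold$pairs) && seed_paired(8L)) return("seed_m2_8")
  if (length(fold$pairs) && seed_paired(7L)) return("seed_m2_7")
  "non_seed"
}
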