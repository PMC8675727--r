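# Implanted target sites pair miRNA nucleotides 2-13: a canonical seed match
# (nt 2-8) extended by 3'-supplementary pairing, as commonly seen in CLASH
# duplexes. The extension makes the intended helix decisively the best
# scoring block under the additive duplex model.
.SITE_LEN <- 12L

#' Generate synthetic transcriptome and miRNA references
#'
#' Builds a random transcriptome in which every transcript carries an
#' interior CDS (so that 5'UTR, CDS and 3'UTR regions all exist), a panel of
#' 18-23 nt miRNAs with heavy-tailed (log-normal) abundance weights, and a
#' table of canonical target sites implanted into the transcript sequences.
#' One site (the reverse complement of miRNA nucleotides 2-13: a seed match
#' with 3'-supplementary extension) is implanted per miRNA per region,
#' placed at least 20 nt inside the region boundaries, so that the library
#' simulator can draw seed-paired chimeras from any region.
#'
#' @param params a [sim_params()] object.
#' @return list with elements `transcripts` (data.frame: transcript_id,
#'   gene_id, length, cds_start, cds_end, sequence; CDS coordinates 0-based
#'   half-open), `mirnas` (data.frame: name, sequence (RNA), abundance_weight
#'   summing to 1) and `seed_sites` (data.frame: mirna_name, transcript_id,
#'   site_start, region).
#' @export
generate_references <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$rng_seed)

  n_mir <- params$n_mirnas
  mir_len <- sample(18:23, n_mir, replace = TRUE)
  mir_seq <- random_dna(mir_len)
  w <- stats::rlnorm(n_mir, meanlog = 0, sdlog = 1.5)
  mirnas <- data.frame(
    name = sprintf("mir-%03d", seq_len(n_mir)),
    sequence = as_rna(mir_seq),
    abundance_weight = w / sum(w),
    stringsAsFactors = FALSE
  )

  n_tx <- params$n_transcripts
  lr <- params$transcript_length_range
  tx_len <- sample(seq(lr[1], lr[2]), n_tx, replace = TRUE)
  # interior CDS: 5'UTR >= 60 nt, 3'UTR >= 100 nt, remainder is CDS
  utr5 <- pmax(60L, as.integer(round(stats::runif(n_tx, 0.04, 0.15) * tx_len)))
  utr3 <- pmax(100L, as.integer(round(stats::runif(n_tx, 0.20, 0.35) * tx_len)))
  transcripts <- data.frame(
    transcript_id = sprintf("TX%04d", seq_len(n_tx)),
    gene_id = sprintf("GENE%04d", seq_len(n_tx)),
    length = tx_len,
    cds_start = utr5,
    cds_end = tx_len - utr3,
    sequence = random_dna(tx_len),
    stringsAsFactors = FALSE
  )
  stopifnot(all(transcripts$cds_start > 0),
            all(transcripts$cds_end > transcripts$cds_start),
            all(transcripts$cds_end < transcripts$length))

  # implant one canonical seed site per miRNA x region, away from boundaries
  occupied <- vector("list", n_tx)
  sites <- list()
  margin <- 20L
  for (mi in seq_len(n_mir)) {
    site_seq <- revcomp(norm_dna(substr(mir_seq[mi], 2L, 2L + .SITE_LEN - 1L)))
    for (region in c("utr5", "cds", "utr3")) {
      placed <- FALSE
      for (try in 1:100) {
        ti <- sample.int(n_tx, 1L)
        bounds <- switch(region,
          utr5 = c(0L, transcripts$cds_start[ti]),
          cds  = c(transcripts$cds_start[ti], transcripts$cds_end[ti]),
          utr3 = c(transcripts$cds_end[ti], transcripts$length[ti]))
        lo <- bounds[1] + margin
        hi <- bounds[2] - margin - .SITE_LEN
        if (hi < lo) next
        pos <- lo + sample.int(hi - lo + 1L, 1L) - 1L
        clash <- any(vapply(occupied[[ti]], function(iv) {
          pos < iv[2] + 4L && iv[1] < pos + .SITE_LEN + 4L
        }, logical(1)))
        if (clash) next
        occupied[[ti]] <- c(occupied[[ti]], list(c(pos, pos + .SITE_LEN)))
        substr(transcripts$sequence[ti], pos + 1L, pos + .SITE_LEN) <- site_seq
        sites[[length(sites) + 1L]] <- data.frame(
          mirna_name = mirnas$name[mi], transcript_id = transcripts$transcript_id[ti],
          site_start = pos, region = region, stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        warning(sprintf("could not place a %s seed site for %s",
                        region, mirnas$name[mi]))
      }
    }
  }
  list(transcripts = transcripts, mirnas = mirnas,
       seed_sites = do.call(rbind, sites))
}

# Sample a fragment window of length frag_len containing the implanted site
# whose midpoint stays inside region [rs, re); returns 0-based start.
.sample_site_window <- function(site, frag_len, rs, re, tx_len) {
  half <- frag_len %/% 2L
  lo <- max(0L, site + .SITE_LEN - frag_len, rs - half)
  hi <- min(tx_len - frag_len, site, re - 1L - half)
  if (hi < lo) {  # fall back to a short window, guaranteed by the margins
    frag_len <- 24L
    half <- 12L
    lo <- max(0L, site + .SITE_LEN - frag_len, rs - half)
    hi <- min(tx_len - frag_len, site, re - 1L - half)
  }
  c(lo + sample.int(hi - lo + 1L, 1L) - 1L, frag_len)
}

#' Simulate a qCLASH sequencing library with ground truth
#'
#' Each molecule is either a chimera (a full miRNA ligated directly to a
#' 20-50 nt target fragment, in miRNA-first or miRNA-last order) or a lone
#' miRNA / lone mRNA fragment. The insert is flanked by `umi_len` degenerate
#' nucleotides on each side followed by the 3' adapter; substitution errors
#' are applied once per molecule, then the molecule is PCR-amplified
#' (geometric copy number) into byte-identical read pairs. Mate 1 reads the
#' template from the 5' end, mate 2 is the reverse complement of the 3' end;
#' with the default read length the mates always overlap enough to merge.
#'
#' @param transcripts,mirnas reference tables from [generate_references()].
#' @param params a [sim_params()] object.
#' @param seed_sites seed-site table from [generate_references()]; when NULL
#'   no seed-paired chimeras are drawn regardless of `seed_site_fraction`.
#' @return object of class `qclash_sim`: list with `reads` (data.frame:
#'   read_id, seq1, qual1, seq2, qual2; one row per PCR copy) and `truth`
#'   (data.frame, one row per distinct molecule: read_id, is_hybrid,
#'   mirna_name, transcript_id, target_start, target_end, order,
#'   n_pcr_copies, seed_implanted, insert_seq; coordinates 0-based
#'   half-open).
#' @export
simulate_library <- function(transcripts, mirnas, params, seed_sites = NULL) {
  stopifnot(inherits(params, "sim_params"),
            nrow(transcripts) > 0, nrow(mirnas) > 0)
  set.seed(params$rng_seed + 1L)
  n <- params$n_reads
  mir_dna <- norm_dna(mirnas$sequence)
  tx_seq <- transcripts$sequence
  tx_len <- transcripts$length

  is_hybrid <- stats::runif(n) < params$hybrid_fraction
  lone_mirna <- !is_hybrid & stats::runif(n) < 0.5
  mir_idx <- sample.int(nrow(mirnas), n, replace = TRUE,
                        prob = mirnas$abundance_weight)
  seeded <- is_hybrid & stats::runif(n) < params$seed_site_fraction &
    !is.null(seed_sites)
  region_id <- sample.int(3L, n, replace = TRUE,
                          prob = params$target_region_weights)
  region <- c("utr5", "cds", "utr3")[region_id]
  fl <- params$frag_len_range
  frag_len <- sample(seq(fl[1], fl[2]), n, replace = TRUE)
  mirna_first <- stats::runif(n) < params$mirna_first_fraction

  tx_idx <- integer(n)
  tstart <- integer(n)
  needs_tx <- is_hybrid | (!is_hybrid & !lone_mirna)

  if (!is.null(seed_sites)) {
    site_key <- paste(seed_sites$mirna_name, seed_sites$region)
  }
  # seed-paired chimeras: look up the implanted site for (miRNA, region)
  for (i in which(seeded)) {
    si <- match(paste(mirnas$name[mir_idx[i]], region[i]), site_key)
    if (is.na(si)) { seeded[i] <- FALSE; next }
    ti <- match(seed_sites$transcript_id[si], transcripts$transcript_id)
    bounds <- switch(region[i],
      utr5 = c(0L, transcripts$cds_start[ti]),
      cds  = c(transcripts$cds_start[ti], transcripts$cds_end[ti]),
      utr3 = c(transcripts$cds_end[ti], tx_len[ti]))
    sw <- .sample_site_window(seed_sites$site_start[si], frag_len[i],
                              bounds[1], bounds[2], tx_len[ti])
    tx_idx[i] <- ti
    tstart[i] <- sw[1]
    frag_len[i] <- sw[2]
  }
  # unseeded fragments: uniform transcript, midpoint uniform in the region
  un <- which(needs_tx & !seeded)
  if (length(un)) {
    ti <- sample.int(nrow(transcripts), length(un), replace = TRUE)
    tx_idx[un] <- ti
    rs <- ifelse(region[un] == "utr5", 0L,
          ifelse(region[un] == "cds", transcripts$cds_start[ti],
                 transcripts$cds_end[ti]))
    re <- ifelse(region[un] == "utr5", transcripts$cds_start[ti],
          ifelse(region[un] == "cds", transcripts$cds_end[ti], tx_len[ti]))
    half <- frag_len[un] %/% 2L
    lo <- pmax(0L, rs - half)
    hi <- pmin(tx_len[ti] - frag_len[un], re - 1L - half)
    bad <- hi < lo  # region too small for this fragment: shrink to minimum
    if (any(bad)) {
      frag_len[un][bad] <- fl[1]
      half <- frag_len[un] %/% 2L
      lo <- pmax(0L, rs - half)
      hi <- pmin(tx_len[ti] - frag_len[un], re - 1L - half)
    }
    tstart[un] <- lo + floor(stats::runif(length(un)) * (hi - lo + 1L))
  }

  tend <- tstart + frag_len
  frag <- character(n)
  frag[needs_tx] <- substring(tx_seq[tx_idx[needs_tx]],
                              tstart[needs_tx] + 1L, tend[needs_tx])
  mir_part <- mir_dna[mir_idx]
  core <- ifelse(is_hybrid,
                 ifelse(mirna_first, paste0(mir_part, frag),
                        paste0(frag, mir_part)),
                 ifelse(lone_mirna, mir_part, frag))

  # substitution errors, once per molecule (PCR copies stay identical)
  if (params$error_rate > 0) {
    n_err <- stats::rbinom(n, nchar(core), params$error_rate)
    for (i in which(n_err > 0)) {
      pos <- sample.int(nchar(core[i]), n_err[i])
      ch <- strsplit(core[i], "")[[1]]
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
      core[i] <- paste(ch, collapse = "")
    }
  }

  umi5 <- random_dna(rep(params$umi_len, n))
  umi3 <- random_dna(rep(params$umi_len, n))
  template <- paste0(umi5, core, umi3, params$adapter3)
  tlen <- nchar(template)
  rl <- params$read_len
  seq1 <- substring(template, 1L, pmin(rl, tlen))
  seq2 <- revcomp(substring(template, pmax(1L, tlen - rl + 1L), tlen))

  copies <- 1L + stats::rgeom(n, prob = 1 / params$pcr_dup_mean)
  mol_id <- sprintf("MOL%06d", seq_len(n))
  idx <- rep(seq_len(n), copies)
  copy_no <- sequence(copies)

  reads <- data.frame(
    read_id = paste0(mol_id[idx], "/", copy_no),
    seq1 = seq1[idx], qual1 = strrep("I", nchar(seq1[idx])),
    seq2 = seq2[idx], qual2 = strrep("I", nchar(seq2[idx])),
    stringsAsFactors = FALSE
  )
  txid <- rep("", n)
  txid[needs_tx] <- transcripts$transcript_id[tx_idx[needs_tx]]
  truth <- data.frame(
    read_id = mol_id,
    is_hybrid = is_hybrid,
    mirna_name = ifelse(is_hybrid | lone_mirna, mirnas$name[mir_idx], ""),
    transcript_id = txid,
    target_start = ifelse(needs_tx, tstart, NA_integer_),
    target_end = ifelse(needs_tx, tend, NA_integer_),
    order = ifelse(is_hybrid,
                   ifelse(mirna_first, "mirna_first", "mirna_last"), ""),
    n_pcr_copies = copies,
    seed_implanted = seeded,
    insert_seq = core,
    stringsAsFactors = FALSE
  )
  structure(list(reads = reads, truth = truth, params = params),
            class = "qclash_sim")
}

#' @export
print.qclash_sim <- function(x, ...) {
  cat(sprintf(
    "qCLASH synthetic library: %d molecules (%d hybrid), %d read pairs\n",
    nrow(x$truth), sum(x$truth$is_hybrid), nrow(x$reads)))
  invisible(x)
}

#' Simulate a mimic/antagomir fold-change table
#'
#' Background genes draw log2 fold changes from Normal(0, noise_sd); target
#' genes are shifted by -|effect| under a miRNA mimic (repression) and
#' +|effect| under an antagomir (derepression). Two-sided p-values are
#' computed from the same draws against the background null.
#'
#' @param target_genes character vector of true target gene ids.
#' @param n_genes total number of genes in the table.
#' @param effect shift magnitude in log2 units.
#' @param noise_sd background standard deviation (> 0) in log2 units.
#' @param direction "mimic" (targets repressed) or "antagomir" (derepressed).
#' @param rng_seed integer seed.
#' @param gene_universe optional character vector of gene ids to use; padded
#'   with synthetic background ids up to `n_genes` when shorter.
#' @return data.frame with columns gene_id, log2fc, pvalue.
#' @export
simulate_fold_changes <- function(target_genes, n_genes, effect, noise_sd,
                                  direction = c("mimic", "antagomir"),
                                  rng_seed = 320L, gene_universe = NULL) {
  direction <- match.arg(direction)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  genes <- unique(c(target_genes, gene_universe))
  if (length(genes) < n_genes) {
    genes <- c(genes, sprintf("BG%05d", seq_len(n_genes - length(genes))))
  } else {
    genes <- genes[seq_len(n_genes)]
  }
  if (!all(target_genes %in% genes)) {
    stop("target_genes must be contained in the gene universe", call. = FALSE)
  }
  set.seed(rng_seed)
  lfc <- stats::rnorm(n_genes, 0, noise_sd)
  shift <- if (direction == "mimic") -abs(effect) else abs(effect)
  is_target <- genes %in% target_genes
  lfc[is_target] <- lfc[is_target] + shift
  data.frame(
    gene_id = genes,
    log2fc = lfc,
    pvalue = 2 * stats::pnorm(-abs(lfc) / noise_sd),
    stringsAsFactors = FALSE
  )
}

#' Score hybrid calls against simulation ground truth
#'
#' Joins calls to true molecules by insert sequence. A true chimera counts as
#' recovered when its insert received a hybrid call naming the right miRNA
#' and transcript with a target interval covering at least half of the true
#' fragment; a hybrid call counts as correct when some true chimera matches
#' it the same way.
#'
#' @param calls data.frame from [call_hybrids()].
#' @param truth ground-truth data.frame from [simulate_library()].
#' @return list with recall, precision, n_true_hybrids, n_called_hybrids.
#' @export
evaluate_hybrid_calls <- function(calls, truth) {
  th <- truth[truth$is_hybrid, ]
  ci <- match(th$insert_seq, calls$sequence)
  ok <- !is.na(ci)
  correct <- rep(FALSE, nrow(th))
  if (any(ok)) {
    cc <- calls[ci[ok], ]
    ov <- pmin(cc$target_ref_end, th$target_end[ok]) -
      pmax(cc$target_ref_start, th$target_start[ok])
    correct[ok] <- cc$call == "hybrid" &
      cc$mirna_name == th$mirna_name[ok] &
      cc$transcript_id == th$transcript_id[ok] &
      !is.na(ov) & ov >= 0.5 * (th$target_end[ok] - th$target_start[ok])
  }
  called <- calls[calls$call == "hybrid", ]
  true_key <- paste(th$insert_seq, th$mirna_name, th$transcript_id)
  call_ok <- logical(nrow(called))
  ti <- match(paste(called$sequence, called$mirna_name, called$transcript_id),
              true_key)
  okc <- !is.na(ti)
  if (any(okc)) {
    tt <- th[ti[okc], ]
    ov <- pmin(called$target_ref_end[okc], tt$target_end) -
      pmax(called$target_ref_start[okc], tt$target_start)
    call_ok[okc] <- ov >= 0.5 * (tt$target_end - tt$target_start)
  }
  list(
    recall = mean(correct),
    precision = if (nrow(called)) mean(call_ok) else NA_real_,
    n_true_hybrids = nrow(th),
    n_called_hybrids = nrow(called)
  )
}
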