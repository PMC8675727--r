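#' Merge target intervals within and across replicates into sites
#'
#' For each (miRNA, transcript) group, intervals overlapping by at least
#' `min_overlap` nt are merged by single linkage (transitively) into their
#' union span. Replicate support is the union of contributing replicate
#' ids and peak reads is the sum of collapsed-read copy counts over all
#' contributing hybrids, across all replicates.
#'
#' @param hybrids data.frame of annotated hybrid calls carrying columns
#'   mirna_name, transcript_id, target_ref_start, target_ref_end, count and
#'   replicate (plus optional gene_id, seed_class).
#' @param min_overlap minimum overlap in nt for two intervals to join
#'   (>= 1).
#' @return data.frame of target sites, sorted by (mirna, transcript,
#'   start): mirna_name, transcript_id, gene_id, start, end, n_replicates,
#'   replicates (comma-joined), peak_reads, n_hybrids, seed_classes.
#' @export
merge_sites <- function(hybrids, min_overlap = 1L) {
  stopifnot(min_overlap >= 1L)
  h <- if ("call" %in% names(hybrids)) {
    hybrids[hybrids$call == "hybrid", , drop = FALSE]
  } else {
    hybrids
  }
  if (is.null(h$gene_id)) h$gene_id <- NA_character_
  if (is.null(h$seed_class)) h$seed_class <- NA_character_
  if (is.null(h$replicate)) h$replicate <- "R1"
  if (!nrow(h)) {
    return(data.frame(mirna_name = character(), transcript_id = character(),
                      gene_id = character(), start = integer(),
                      end = integer(), n_replicates = integer(),
                      replicates = character(), peak_reads = integer(),
                      n_hybrids = integer(), seed_classes = character(),
                      stringsAsFactors = FALSE))
  }
  grp <- paste(h$mirna_name, h$transcript_id, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    hh <- h[grp == g, ]
    hh <- hh[order(hh$target_ref_start, hh$target_ref_end), ]
    cl <- integer(nrow(hh))
    cl[1] <- 1L
    cur_end <- hh$target_ref_end[1]
    for (i in seq_len(nrow(hh))[-1]) {
      # half-open intervals sorted by start: overlap with the growing
      # cluster is cur_end - start
      if (cur_end - hh$target_ref_start[i] >= min_overlap) {
        cl[i] <- cl[i - 1L]
        cur_end <- max(cur_end, hh$target_ref_end[i])
      } else {
        cl[i] <- cl[i - 1L] + 1L
        cur_end <- hh$target_ref_end[i]
      }
    }
    for (ci in unique(cl)) {
      s <- hh[cl == ci, ]
      reps <- sort(unique(s$replicate))
      sc <- sort(s$seed_class[!is.na(s$seed_class)])
      out[[length(out) + 1L]] <- data.frame(
        mirna_name = s$mirna_name[1],
        transcript_id = s$transcript_id[1],
        gene_id = s$gene_id[1],
        start = min(s$target_ref_start),
        end = max(s$target_ref_end),
        n_replicates = length(reps),
        replicates = paste(reps, collapse = ","),
        peak_reads = sum(s$count),
        n_hybrids = nrow(s),
        seed_classes = if (length(sc)) {
          paste(sprintf("%s:%d", names(table(sc)), as.integer(table(sc))),
                collapse = ",")
        } else "",
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  res[order(res$mirna_name, res$transcript_id, res$start), , drop = FALSE]
}

#' Keep sites supported by enough biological replicates
#'
#' @param sites data.frame from [merge_sites()].
#' @param min_replicates minimum number of distinct supporting replicates
#'   (>= 1).
#' @return filtered data.frame, input order preserved.
#' @export
select_high_confidence <- function(sites, min_replicates) {
  stopifnot(min_replicates >= 1L)
  sites[sites$n_replicates >= min_replicates, , drop = FALSE]
}

#' Collapse target sites to genes
#'
#' Gene-level support is the maximum replicate support over the gene's
#' sites for that miRNA; peak reads are summed.
#'
#' @param sites data.frame from [merge_sites()].
#' @return data.frame: mirna_name, gene_id, n_replicates, peak_reads,
#'   n_sites.
#' @export
sites_to_genes <- function(sites) {
  if (!nrow(sites)) {
    return(data.frame(mirna_name = character(), gene_id = character(),
                      n_replicates = integer(), peak_reads = integer(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(sites$mirna_name, sites$gene_id, sep = "\r")
  idx <- split(seq_len(nrow(sites)), key)
  res <- do.call(rbind, lapply(idx, function(i) {
    data.frame(
      mirna_name = sites$mirna_name[i[1]],
      gene_id = sites$gene_id[i[1]],
      n_replicates = max(sites$n_replicates[i]),
      peak_reads = sum(sites$peak_reads[i]),
      n_sites = length(i),
      stringsAsFactors = FALSE
    )
  }))
  rownames(res) <- NULL
  res[order(res$mirna_name, res$gene_id), , drop = FALSE]
}

#' Summarize hybrid counts per replicate with a focus miRNA
#'
#' Produces the per-replicate accounting used for library summaries: total
#' miRNA/mRNA hybrids, hybrids of the focus miRNA, and the focus percentage
#' (focus / total x 100, rounded to 2 decimals; undefined — NA — when a
#' total is zero). Replicates sharing a group label get a group-total row.
#'
#' @param tables named list of per-replicate hybrid tables (data.frames
#'   with columns mirna_name and count; copy-weighted counts).
#' @param focus_mirna miRNA name to break out.
#' @param groups optional character vector (same names as `tables`) mapping
#'   each replicate to a sample group.
#' @return data.frame: replicate, group, total_hybrids, focus_hybrids,
#'   percent; group rows have replicate == "total".
#' @export
summarize_hybrids <- function(tables, focus_mirna, groups = NULL) {
  stopifnot(length(tables) >= 1L)
  if (is.null(names(tables))) {
    names(tables) <- sprintf("BR%d", seq_along(tables))
  }
  if (is.null(groups)) {
    groups <- stats::setNames(rep("all", length(tables)), names(tables))
  }
  pct <- function(f, t) if (t > 0) round(f / t * 100, 2) else NA_real_
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    tot <- sum(tb$count)
    foc <- sum(tb$count[tb$mirna_name == focus_mirna])
    data.frame(replicate = nm, group = groups[[nm]], total_hybrids = tot,
               focus_hybrids = foc, percent = pct(foc, tot),
               stringsAsFactors = FALSE)
  })
  per_rep <- do.call(rbind, rows)
  group_rows <- do.call(rbind, lapply(unique(per_rep$group), function(gr) {
    tot <- sum(per_rep$total_hybrids[per_rep$group == gr])
    foc <- sum(per_rep$focus_hybrids[per_rep$group == gr])
    data.frame(replicate = "total", group = gr, total_hybrids = tot,
               focus_hybrids = foc, percent = pct(foc, tot),
               stringsAsFactors = FALSE)
  }))
  rbind(per_rep, group_rows)
}

#' Filter hybrid calls to a single miRNA
#'
#' @param hybrids data.frame with a mirna_name column.
#' @param mirna_name exact miRNA name to retain.
#' @return filtered data.frame.
#' @export
filter_by_mirna <- function(hybrids, mirna_name) {
  hybrids[!is.na(hybrids$mirna_name) & hybrids$mirna_name == mirna_name, ,
          drop = FALSE]
}
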