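#' Assign a target interval to 5'UTR, CDS or 3'UTR
#'
#' A site is labeled by the region containing its midpoint
#' (floor((start + end) / 2)) relative to the transcript's CDS boundaries;
#' a midpoint exactly at cds_start is CDS and exactly at cds_end is 3'UTR.
#' Sites on transcripts without an annotation entry are `unannotated` and
#' excluded from downstream proportions.
#'
#' @param target_start,target_end 0-based half-open transcript coordinates
#'   (vectorized).
#' @param cds_start,cds_end 0-based half-open CDS coordinates (NA when the
#'   transcript is not annotated).
#' @param tx_length transcript length in nt.
#' @return character vector over {"utr5", "cds", "utr3", "unannotated"}.
#' @export
assign_region <- function(target_start, target_end, cds_start, cds_end,
                          tx_length = NULL) {
  if (any(target_start >= target_end, na.rm = TRUE) ||
      any(target_start < 0, na.rm = TRUE)) {
    stop("target intervals must be nonempty with start >= 0", call. = FALSE)
  }
  if (!is.null(tx_length) &&
      any(!is.na(cds_start) & target_end > tx_length)) {
    stop("target interval outside transcript", call. = FALSE)
  }
  mid <- (target_start + target_end) %/% 2L
  out <- rep("unannotated", length(target_start))
  ann <- !is.na(cds_start) & !is.na(cds_end)
  out[ann & mid < cds_start] <- "utr5"
  out[ann & mid >= cds_start & mid < cds_end] <- "cds"
  out[ann & mid >= cds_end] <- "utr3"
  out
}

#' Annotate hybrid calls with target regions
#'
#' @param calls data.frame from [call_hybrids()].
#' @param annotation data.frame with columns transcript_id, gene_id, length,
#'   cds_start, cds_end (0-based half-open), e.g. from
#'   [generate_references()]`$transcripts` or [read_annotation()].
#' @return `calls` with `gene_id` and `region` columns added (non-hybrid
#'   rows get NA).
#' @export
annotate_hybrids <- function(calls, annotation) {
  idx <- match(calls$transcript_id, annotation$transcript_id)
  hyb <- calls$call == "hybrid"
  region <- rep(NA_character_, nrow(calls))
  region[hyb] <- assign_region(
    calls$target_ref_start[hyb], calls$target_ref_end[hyb],
    annotation$cds_start[idx[hyb]], annotation$cds_end[idx[hyb]],
    annotation$length[idx[hyb]]
  )
  calls$gene_id <- annotation$gene_id[idx]
  calls$region <- region
  calls
}

#' Region proportions over annotated hybrids
#'
#' @param regions character vector of region labels (e.g.
#'   `annotate_hybrids()$region`); `unannotated` and NA entries are
#'   excluded.
#' @param weights optional nonnegative weights (e.g. collapsed-read counts).
#' @return named numeric vector (utr5, cds, utr3) summing to 1.
#' @export
region_proportions <- function(regions, weights = NULL) {
  keep <- !is.na(regions) & regions %in% c("utr5", "cds", "utr3")
  if (!any(keep)) stop("no annotated hybrids", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(regions))
  tot <- vapply(c(utr5 = "utr5", cds = "cds", utr3 = "utr3"),
                function(r) sum(weights[keep & regions == r]), 0)
  tot / sum(tot)
}

#' Read a transcript annotation TSV
#'
#' Expected columns: transcript_id, gene_id, length, cds_start, cds_end
#' with 0-based half-open CDS coordinates (stated in the file's header
#' comment by [write_references()]).
#'
#' @param path TSV path.
#' @return annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- read_stage_tsv(path)
  need <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  if (!all(need %in% names(ann))) {
    stop("annotation must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ann
}

#' Convert a transcript-space GFF3 file to the annotation table
#'
#' A small utility for GFF3 files whose coordinates are already in
#' transcript space (one sequence region per transcript): `CDS` features
#' give the CDS span, and the region length gives the transcript length.
#' GFF coordinates are 1-based inclusive and are converted to the package's
#' 0-based half-open convention.
#'
#' @param path GFF3 path.
#' @return annotation data.frame as in [read_annotation()].
#' @export
gff_to_annotation <- function(path) {
  lines <- readLines(path)
  lens <- list()
  for (l in grep("^##sequence-region", lines, value = TRUE)) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    lens[[f[2]]] <- as.integer(f[4])
  }
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(body, "\t")
  df <- data.frame(
    seqid = vapply(f, `[`, "", 1),
    type = vapply(f, `[`, "", 3),
    start = as.integer(vapply(f, `[`, "", 4)),
    end = as.integer(vapply(f, `[`, "", 5)),
    attr = vapply(f, `[`, "", 9),
    stringsAsFactors = FALSE
  )
  cds <- df[df$type == "CDS", ]
  if (!nrow(cds)) stop("no CDS features in GFF", call. = FALSE)
  gene <- sub(".*gene_id=([^;]+).*", "\\1", cds$attr)
  gene[gene == cds$attr] <- cds$seqid[gene == cds$attr]
  agg_s <- tapply(cds$start, cds$seqid, min)
  agg_e <- tapply(cds$end, cds$seqid, max)
  tx <- names(agg_s)
  data.frame(
    transcript_id = tx,
    gene_id = gene[match(tx, cds$seqid)],
    length = vapply(tx, function(s) {
      if (!is.null(lens[[s]])) lens[[s]]
      else max(df$end[df$seqid == s])
    }, 0L),
    cds_start = as.integer(agg_s) - 1L,
    cds_end = as.integer(agg_e),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
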