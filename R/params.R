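#' Simulation parameters for a synthetic qCLASH library
#'
#' Bundles every knob of the synthetic-reference and library generator into a
#' validated list. Defaults describe a small but realistic AGO-qCLASH
#' experiment: a few hundred transcripts, tens of miRNAs with heavy-tailed
#' (log-normal) abundance so that a single miRNA can dominate the library the
#' way miR-320a dominates a DROSHA-knockout cell line, chimeric inserts
#' flanked by 4-nt degenerate UMIs and a 3' sequencing adapter, geometric PCR
#' duplication, and a low per-base substitution error rate.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param transcript_length_range integer length 2, min/max transcript length
#'   in nt.
#' @param n_mirnas number of miRNAs (18-23 nt each).
#' @param n_reads number of distinct molecules sampled (before PCR
#'   duplication; FASTQ pairs = sum of per-molecule PCR copies).
#' @param hybrid_fraction probability a molecule is a miRNA:target chimera
#'   rather than a lone miRNA or lone mRNA fragment.
#' @param mirna_first_fraction probability a chimeric insert carries the
#'   miRNA 5' of the target fragment (ligation order is not fixed by the
#'   protocol, so both orders are generated).
#' @param seed_site_fraction probability a chimeric molecule is drawn from an
#'   implanted canonical seed site (miRNA nucleotides 2-8 paired
#'   Watson-Crick) rather than an arbitrary fragment.
#' @param target_region_weights numeric length 3 summing to 1: sampling
#'   weights for the 5'UTR, CDS and 3'UTR of the target fragment midpoint.
#' @param error_rate per-base substitution probability, applied once per
#'   molecule so PCR duplicates stay byte-identical.
#' @param umi_len degenerate nucleotides on each end of the insert.
#' @param adapter3 3' sequencing adapter appended after the insert.
#' @param pcr_dup_mean mean PCR copy number (>= 1); copies are
#'   1 + Geometric so the mean is exactly this value.
#' @param read_len sequenced length of each mate; the default reads through
#'   the short insert into the adapter on both sides, as paired-end
#'   protocols on small-RNA-sized inserts do, so the mates always overlap.
#' @param frag_len_range integer length 2, target-fragment length range in nt
#'   (RNase footprints in CLASH libraries are short).
#' @param rng_seed integer seed; identical parameters give byte-identical
#'   FASTQ and ground-truth output.
#'
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n_transcripts = 200L,
                       transcript_length_range = c(600L, 2000L),
                       n_mirnas = 60L,
                       n_reads = 10000L,
                       hybrid_fraction = 0.5,
                       mirna_first_fraction = 0.9,
                       seed_site_fraction = 0.35,
                       target_region_weights = c(0.05, 0.45, 0.50),
                       error_rate = 0.005,
                       umi_len = 4L,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       pcr_dup_mean = 1.8,
                       read_len = 110L,
                       frag_len_range = c(20L, 50L),
                       rng_seed = 320L) {
  if (n_transcripts < 1L || n_mirnas < 1L || n_reads < 1L) {
    stop("counts (n_transcripts, n_mirnas, n_reads) must be positive",
         call. = FALSE)
  }
  if (length(transcript_length_range) != 2L ||
      transcript_length_range[1] > transcript_length_range[2] ||
      transcript_length_range[1] < 300L) {
    stop("transcript_length_range must be (min, max) with min >= 300 nt",
         call. = FALSE)
  }
  for (nm in c("hybrid_fraction", "mirna_first_fraction",
               "seed_site_fraction", "error_rate")) {
    stopifnot_scalar_prob(get(nm), nm)
  }
  if (length(target_region_weights) != 3L ||
      any(target_region_weights < 0) ||
      abs(sum(target_region_weights) - 1) > 1e-8) {
    stop("target_region_weights must be 3 nonnegative weights summing to 1",
         call. = FALSE)
  }
  if (!nzchar(adapter3)) stop("adapter3 must be nonempty", call. = FALSE)
  if (pcr_dup_mean < 1) stop("pcr_dup_mean must be >= 1", call. = FALSE)
  if (length(frag_len_range) != 2L || frag_len_range[1] < 16L ||
      frag_len_range[1] > frag_len_range[2]) {
    stop("frag_len_range must be (min, max) with min >= 16 nt", call. = FALSE)
  }
  p <- list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length_range = as.integer(transcript_length_range),
    n_mirnas = as.integer(n_mirnas),
    n_reads = as.integer(n_reads),
    hybrid_fraction = hybrid_fraction,
    mirna_first_fraction = mirna_first_fraction,
    seed_site_fraction = seed_site_fraction,
    target_region_weights = target_region_weights,
    error_rate = error_rate,
    umi_len = as.integer(umi_len),
    adapter3 = norm_dna(adapter3),
    pcr_dup_mean = pcr_dup_mean,
    read_len = as.integer(read_len),
    frag_len_range = as.integer(frag_len_range),
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "sim_params"
  p
}
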