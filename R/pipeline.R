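#' Configuration for a full qCLASH analysis run
#'
#' Collects the stage parameters and input locations for [run_pipeline()].
#' Inputs can be either real files (a replicate manifest of FASTQ pairs
#' plus reference FASTA/annotation paths) or a simulation request (`sim`),
#' in which case references and replicate libraries are generated on the
#' fly with per-replicate seeds derived from `sim$rng_seed`.
#'
#' @param output_dir run directory for all outputs.
#' @param replicates named list, one element per biological replicate,
#'   each `list(r1 = path, r2 = path)`; ignored when `sim` is given.
#' @param mirna_fasta,transcript_fasta,annotation_tsv reference paths;
#'   ignored when `sim` is given.
#' @param sim optional [sim_params()] object: simulate `n_replicates`
#'   libraries instead of reading FASTQ files.
#' @param n_replicates number of simulated replicates.
#' @param adapter3 3' adapter sequence (required for real data; for
#'   simulations the simulator's adapter is used).
#' @param umi_len,min_insert,merge_min_overlap,max_mismatch_frac
#'   preprocessing parameters.
#' @param k,min_arm_len,max_mismatch hybrid-calling parameters.
#' @param min_overlap_sites,min_replicates clustering parameters.
#' @param focus_mirna miRNA broken out in the library summary; defaults to
#'   the most hybrid-rich miRNA.
#' @param fold_change_tsv optional fold-change table to compare
#'   high-confidence targets against.
#' @param rng_seed integer seed for the simulated branch.
#' @return list of class `qclash_config`.
#' @export
qclash_config <- function(output_dir,
                          replicates = NULL,
                          mirna_fasta = NULL,
                          transcript_fasta = NULL,
                          annotation_tsv = NULL,
                          sim = NULL,
                          n_replicates = 3L,
                          adapter3 = NULL,
                          umi_len = 4L,
                          min_insert = 16L,
                          merge_min_overlap = 10L,
                          max_mismatch_frac = 0.1,
                          k = 12L,
                          min_arm_len = 16L,
                          max_mismatch = 2L,
                          min_overlap_sites = 1L,
                          min_replicates = 2L,
                          focus_mirna = NULL,
                          fold_change_tsv = NULL,
                          rng_seed = 320L) {
  if (is.null(sim)) {
    if (is.null(replicates) || is.null(mirna_fasta) ||
        is.null(transcript_fasta) || is.null(annotation_tsv) ||
        is.null(adapter3)) {
      stop(paste("without `sim`, replicates, reference paths and adapter3",
                 "are required"), call. = FALSE)
    }
    for (p in c(unlist(replicates), mirna_fasta, transcript_fasta,
                annotation_tsv)) {
      if (!file.exists(p)) stop("missing input file: ", p, call. = FALSE)
    }
  } else {
    stopifnot(inherits(sim, "sim_params"))
  }
  cfg <- list(
    output_dir = output_dir, replicates = replicates,
    mirna_fasta = mirna_fasta, transcript_fasta = transcript_fasta,
    annotation_tsv = annotation_tsv, sim = sim,
    n_replicates = as.integer(n_replicates), adapter3 = adapter3,
    umi_len = as.integer(umi_len), min_insert = as.integer(min_insert),
    merge_min_overlap = as.integer(merge_min_overlap),
    max_mismatch_frac = max_mismatch_frac, k = as.integer(k),
    min_arm_len = as.integer(min_arm_len),
    max_mismatch = as.integer(max_mismatch),
    min_overlap_sites = as.integer(min_overlap_sites),
    min_replicates = as.integer(min_replicates),
    focus_mirna = focus_mirna, fold_change_tsv = fold_change_tsv,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "qclash_config"
  cfg
}

#' Run the qCLASH pipeline end to end
#'
#' Executes (optional simulation) -> preprocessing -> hybrid calling ->
#' region annotation -> cross-replicate clustering -> summaries, writing
#' per-stage TSVs, viennad-like duplex files, a library summary table, a
#' region-proportion table, a seed-class table, site- and gene-level target
#' tables and a machine-readable JSON manifest into the run directory.
#' Rerunning with an identical configuration reproduces identical outputs.
#'
#' @param config a [qclash_config()] object.
#' @return object of class `qclash_run`: list with the key tables (calls
#'   per replicate, sites, high-confidence sites and genes, summary,
#'   region/seed proportions, optional fold-change comparison), the
#'   manifest, and the run directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qclash_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "qclashr",
    version = as.character(utils::packageVersion("qclashr")),
    parameters = config[setdiff(names(config),
                                c("replicates", "sim"))],
    seed = config$rng_seed,
    stages = list()
  )

  truths <- NULL
  if (!is.null(config$sim)) {
    refs <- generate_references(config$sim)
    write_references(refs, file.path(config$output_dir, "references"))
    mirnas <- refs$mirnas
    transcripts <- refs$transcripts
    annotation <- refs$transcripts
    adapter3 <- config$sim$adapter3
    rep_names <- sprintf("BR%d", seq_len(config$n_replicates))
    libs <- list()
    truths <- list()
    for (i in seq_along(rep_names)) {
      p <- config$sim
      p$rng_seed <- config$sim$rng_seed + 1000L * i
      sim <- simulate_library(transcripts, mirnas, p, refs$seed_sites)
      write_sim_library(sim, file.path(config$output_dir, "reads"),
                        rep_names[i])
      libs[[rep_names[i]]] <- sim$reads
      truths[[rep_names[i]]] <- sim$truth
    }
  } else {
    mirnas <- read_fasta_df(config$mirna_fasta, "name")
    transcripts <- read_fasta_df(config$transcript_fasta, "transcript_id")
    annotation <- read_annotation(config$annotation_tsv)
    adapter3 <- config$adapter3
    rep_names <- names(config$replicates)
    libs <- lapply(config$replicates, function(rp) {
      read_fastq_pairs(rp$r1, rp$r2)
    })
  }

  index <- build_index(mirnas, transcripts, k = config$k)
  per_rep <- list()
  for (rn in rep_names) {
    pp <- preprocess_reads(libs[[rn]], adapter3,
                           umi_len = config$umi_len,
                           min_insert = config$min_insert,
                           min_overlap = config$merge_min_overlap,
                           max_mismatch_frac = config$max_mismatch_frac)
    calls <- call_hybrids(pp$inserts, index,
                          min_arm_len = config$min_arm_len,
                          max_mismatch = config$max_mismatch)
    calls <- annotate_hybrids(calls, annotation)
    calls$replicate <- rn
    write_hyb_tsv(calls, file.path(config$output_dir,
                                   sprintf("hybrids_%s.tsv", rn)))
    write_viennad(calls, file.path(config$output_dir,
                                   sprintf("duplexes_%s.viennad", rn)))
    n_hyb <- sum(calls$call == "hybrid")
    manifest$stages[[rn]] <- c(
      as.list(pp$log),
      list(hybrid_calls = n_hyb,
           single_arm_mirna = sum(calls$call == "single_arm_mirna"),
           single_arm_transcript = sum(calls$call == "single_arm_transcript"),
           unmapped = sum(calls$call == "unmapped"))
    )
    per_rep[[rn]] <- calls
  }

  all_calls <- do.call(rbind, lapply(per_rep, function(x) {
    x[, setdiff(names(x), "sequence")]
  }))
  hyb_tables <- lapply(per_rep, function(x) {
    x[x$call == "hybrid", c("mirna_name", "count")]
  })
  focus <- config$focus_mirna
  if (is.null(focus)) {
    agg <- stats::aggregate(
      count ~ mirna_name,
      data = do.call(rbind, hyb_tables), FUN = sum)
    focus <- agg$mirna_name[which.max(agg$count)]
  }
  summary_tbl <- summarize_hybrids(hyb_tables, focus)
  write_stage_tsv(summary_tbl,
                  file.path(config$output_dir, "library_summary.tsv"),
                  "summarize_hybrids")

  hyb <- all_calls[all_calls$call == "hybrid", ]
  region_tbl <- data.frame(
    region = c("utr5", "cds", "utr3"),
    proportion = as.numeric(region_proportions(hyb$region, hyb$count)),
    stringsAsFactors = FALSE
  )
  write_stage_tsv(region_tbl,
                  file.path(config$output_dir, "region_proportions.tsv"),
                  "annotate")
  seed_tab <- tapply(hyb$count, hyb$seed_class, sum)
  seed_tbl <- data.frame(
    seed_class = names(seed_tab),
    proportion = as.numeric(seed_tab) / sum(seed_tab),
    stringsAsFactors = FALSE
  )
  write_stage_tsv(seed_tbl,
                  file.path(config$output_dir, "seed_proportions.tsv"),
                  "hybcall")

  sites <- merge_sites(hyb, min_overlap = config$min_overlap_sites)
  write_sites_tsv(sites, file.path(config$output_dir, "target_sites.tsv"))
  if (config$min_replicates > length(rep_names)) {
    warning("min_replicates exceeds the number of replicates; ",
            "high-confidence tables will be empty")
  }
  hc_sites <- select_high_confidence(sites, config$min_replicates)
  write_sites_tsv(hc_sites,
                  file.path(config$output_dir,
                            "target_sites_high_confidence.tsv"))
  genes <- sites_to_genes(sites)
  hc_genes <- genes[genes$n_replicates >= config$min_replicates, ,
                    drop = FALSE]
  write_stage_tsv(hc_genes,
                  file.path(config$output_dir,
                            "target_genes_high_confidence.tsv"),
                  "cluster")

  comparison <- NULL
  if (!is.null(config$fold_change_tsv)) {
    fc <- read_fold_changes(config$fold_change_tsv)
    focus_genes <- hc_genes$gene_id[hc_genes$mirna_name == focus]
    if (length(focus_genes) > 0) {
      comparison <- cdf_compare(fc, list(high_confidence = focus_genes))
      write_stage_tsv(cdf_compare_table(comparison),
                      file.path(config$output_dir, "cdf_comparison.tsv"),
                      "stats")
    }
  }

  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  structure(list(
    calls = per_rep,
    truths = truths,
    sites = sites,
    high_confidence_sites = hc_sites,
    high_confidence_genes = hc_genes,
    summary = summary_tbl,
    region_proportions = region_tbl,
    seed_proportions = seed_tbl,
    comparison = comparison,
    focus_mirna = focus,
    manifest = manifest,
    output_dir = config$output_dir
  ), class = "qclash_run")
}

#' @export
print.qclash_run <- function(x, ...) {
  n_hyb <- sum(vapply(x$calls, function(c) sum(c$call == "hybrid"), 0))
  cat(sprintf(
    "qCLASH run: %d replicates, %d hybrid calls, %d merged sites (%d high-confidence)\n",
    length(x$calls), n_hyb, nrow(x$sites), nrow(x$high_confidence_sites)))
  cat(sprintf("focus miRNA: %s; outputs in %s\n", x$focus_mirna,
              x$output_dir))
  invisible(x)
}

#' @export
summary.qclash_run <- function(object, ...) {
  cat("Library summary (focus miRNA:", object$focus_mirna, ")\n")
  print(object$summary, row.names = FALSE)
  cat("\nTarget-site regions:\n")
  print(object$region_proportions, row.names = FALSE)
  cat("\nSeed-binding classes:\n")
  print(object$seed_proportions, row.names = FALSE)
  if (!is.null(object$comparison)) {
    cat("\n")
    print(object$comparison)
  }
  invisible(object)
}
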