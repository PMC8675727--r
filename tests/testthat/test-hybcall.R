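mk_refs <- function() {
  set.seed(2024)
  list(
    mirnas = data.frame(
      name = c("mir-a", "mir-b"),
      sequence = c("ACGGUUACGGAUCCAAGGUCCA",      # 22 nt
                   "UUGGCCAAUUGGCCAAUUGACG"),     # 22 nt
      stringsAsFactors = FALSE
    ),
    transcripts = data.frame(
      transcript_id = c("TXa", "TXb"),
      sequence = vapply(1:2, function(i) {
        paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
      }, ""),
      stringsAsFactors = FALSE
    )
  )
}

test_that("index stores every k-mer and round-trips offsets", {
  refs <- mk_refs()
  idx <- build_index(refs$mirnas, refs$transcripts, k = 12)
  # a 22-nt miRNA yields 22 - 12 + 1 = 11 k-mers
  expect_equal(sum(idx$kmer_ref == 1), 11)
  # querying a stored k-mer returns its own (id, offset)
  km <- substr(chartr("U", "T", refs$mirnas$sequence[1]), 3, 14)
  hits <- get(km, idx$env)
  expect_true(any(idx$kmer_ref[hits] == 1 & idx$kmer_off[hits] == 2))
  tx_dup <- data.frame(transcript_id = "mir-a",
                       sequence = refs$transcripts$sequence[1],
                       stringsAsFactors = FALSE)
  expect_error(build_index(refs$mirnas, tx_dup, k = 12), "duplicate")
  expect_error(build_index(refs$mirnas, refs$transcripts, k = 30),
               "shortest miRNA")
})

test_that("random index entries all round-trip to their k-mer", {
  set.seed(33)
  mir <- data.frame(
    name = sprintf("m%02d", 1:10),
    sequence = vapply(1:10, function(i) random_rna(20), ""),
    stringsAsFactors = FALSE
  )
  tx <- data.frame(
    transcript_id = sprintf("t%02d", 1:40),
    sequence = vapply(1:40, function(i) {
      paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
            collapse = "")
    }, ""),
    stringsAsFactors = FALSE
  )
  idx <- build_index(mir, tx, k = 12)
  seqs <- chartr("U", "T", c(mir$sequence, tx$sequence))
  # exhaustive self-check: every stored (id, offset) yields its k-mer
  for (km in sample(ls(idx$env), 200)) {
    for (g in get(km, idx$env)) {
      r <- idx$kmer_ref[g]
      off <- idx$kmer_off[g]
      expect_identical(substr(seqs[r], off + 1, off + 12), km)
    }
  }
})

test_that("exact chimeric inserts are resolved with exact coordinates", {
  refs <- mk_refs()
  idx <- build_index(refs$mirnas, refs$transcripts, k = 12)
  mir <- chartr("U", "T", refs$mirnas$sequence[1])
  frag <- substr(refs$transcripts$sequence[2], 101, 130)

  h <- detect_hybrid(paste0(mir, frag), idx)
  expect_equal(h$call, "hybrid")
  expect_equal(h$order, "mirna_first")
  expect_equal(h$mirna$ref_id, "mir-a")
  expect_equal(h$mirna$ref_start, 0)
  expect_equal(h$mirna$ref_end, 22)
  expect_equal(h$target$ref_id, "TXb")
  expect_equal(h$target$ref_start, 100)
  expect_equal(h$target$ref_end, 130)

  # miRNA-last order is recovered symmetrically
  h2 <- detect_hybrid(paste0(frag, mir), idx)
  expect_equal(h2$call, "hybrid")
  expect_equal(h2$order, "mirna_last")
  expect_equal(h2$target$ref_start, 100)

  # a pure transcript fragment is a single-arm call, not a hybrid
  h3 <- detect_hybrid(substr(refs$transcripts$sequence[1], 51, 90), idx)
  expect_equal(h3$call, "single_arm_transcript")
  h4 <- detect_hybrid(mir, idx)
  expect_equal(h4$call, "single_arm_mirna")
  expect_equal(detect_hybrid("ACGT", idx)$call, "unmapped")
})

test_that("arm coordinates reconstruct the read up to the mismatch budget", {
  exp <- small_experiment()
  pp <- preprocess_reads(exp$sim, exp$params$adapter3)
  calls <- call_hybrids(pp$inserts, exp$index)
  hyb <- calls[calls$call == "hybrid", ][1:50, ]
  mirseq <- setNames(chartr("U", "T", exp$refs$mirnas$sequence),
                     exp$refs$mirnas$name)
  txseq <- setNames(exp$refs$transcripts$sequence,
                    exp$refs$transcripts$transcript_id)
  for (i in seq_len(nrow(hyb))) {
    mref <- substr(mirseq[hyb$mirna_name[i]], hyb$mirna_ref_start[i] + 1,
                   hyb$mirna_ref_end[i])
    tref <- substr(txseq[hyb$transcript_id[i]], hyb$target_ref_start[i] + 1,
                   hyb$target_ref_end[i])
    expect_true(grepl(mref, hyb$sequence[i], fixed = TRUE) ||
                  adist(mref, hyb$sequence[i]) <= 2)
    expect_true(grepl(tref, hyb$sequence[i], fixed = TRUE))
  }
})

test_that("error-free hybrid calling reaches recall and precision 0.99", {
  exp <- small_experiment()
  pp <- preprocess_reads(exp$sim, exp$params$adapter3)
  calls <- call_hybrids(pp$inserts, exp$index)
  ev <- evaluate_hybrid_calls(calls, exp$sim$truth)
  expect_gte(ev$recall, 0.99)
  expect_gte(ev$precision, 0.99)
})

test_that("substitution errors degrade recall gracefully", {
  p <- small_params(error_rate = 0.01, n_reads = 800L, rng_seed = 17L)
  refs <- generate_references(p)
  sim <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  idx <- build_index(refs$mirnas, refs$transcripts)
  pp <- preprocess_reads(sim, p$adapter3)
  calls <- call_hybrids(pp$inserts, idx)
  ev <- evaluate_hybrid_calls(calls, sim$truth)
  expect_gte(ev$recall, 0.9)
})

test_that("per-miRNA counts normalize to CPM and match ground truth", {
  calls <- data.frame(
    call = c("single_arm_mirna", "single_arm_mirna", "hybrid"),
    mirna_name = c("A", "B", "A"),
    count = c(10L, 90L, 5L),
    stringsAsFactors = FALSE
  )
  cm <- count_mirnas(calls)
  expect_equal(cm$cpm[cm$mirna_name == "A"], 1e5)
  expect_equal(cm$cpm[cm$mirna_name == "B"], 9e5)
  single <- calls[2, ]
  expect_equal(count_mirnas(single)$cpm, 1e6)
  expect_error(count_mirnas(calls[calls$call == "hybrid", ]), "single-arm")

  # ground-truth oracle on the simulated library
  exp <- small_experiment()
  pp <- preprocess_reads(exp$sim, exp$params$adapter3)
  cc <- call_hybrids(pp$inserts, exp$index)
  cm <- count_mirnas(cc)
  tr <- exp$sim$truth
  lone <- tr[!tr$is_hybrid & nzchar(tr$mirna_name), ]
  truth_counts <- tapply(lone$n_pcr_copies, lone$mirna_name, sum)
  expect_equal(cm$count, as.integer(truth_counts[cm$mirna_name]),
               ignore_attr = TRUE)
})
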