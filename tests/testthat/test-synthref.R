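test_that("reference generation is deterministic and structurally valid", {
  p <- small_params()
  r1 <- generate_references(p)
  r2 <- generate_references(p)
  expect_identical(r1, r2)

  tx <- r1$transcripts
  expect_true(all(tx$cds_start > 0))
  expect_true(all(tx$cds_start < tx$cds_end))
  expect_true(all(tx$cds_end < tx$length))
  expect_equal(nchar(tx$sequence), tx$length)
  expect_true(all(grepl("^[ACGT]+$", tx$sequence)))

  mir <- r1$mirnas
  expect_true(all(nchar(mir$sequence) >= 18 & nchar(mir$sequence) <= 23))
  expect_true(all(grepl("^[ACGU]+$", mir$sequence)))
  expect_equal(sum(mir$abundance_weight), 1)

  # implanted sites really sit in the transcript at the recorded position
  ss <- r1$seed_sites
  for (i in sample(nrow(ss), 10)) {
    m <- chartr("U", "T", mir$sequence[mir$name == ss$mirna_name[i]])
    site <- revcomp(substr(m, 2, 13))
    s <- tx$sequence[tx$transcript_id == ss$transcript_id[i]]
    expect_identical(substr(s, ss$site_start[i] + 1, ss$site_start[i] + 12),
                     site)
  }
})

test_that("same seed gives byte-identical FASTA and ground truth output", {
  p <- small_params(n_reads = 200L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  for (d in c(dir1, dir2)) {
    refs <- generate_references(p)
    write_references(refs, d)
    sim <- simulate_library(refs$transcripts, refs$mirnas, p,
                            refs$seed_sites)
    write_sim_library(sim, d)
  }
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }
})

test_that("simulated library respects its own ground truth", {
  p <- small_params(n_reads = 600L, pcr_dup_mean = 1.7)
  refs <- generate_references(p)
  sim <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  tr <- sim$truth

  # conservation: FASTQ pairs = sum of PCR copies
  expect_equal(nrow(sim$reads), sum(tr$n_pcr_copies))

  # error-free inserts reconstruct exactly from the ground-truth row
  mirseq <- setNames(chartr("U", "T", refs$mirnas$sequence),
                     refs$mirnas$name)
  txseq <- setNames(refs$transcripts$sequence,
                    refs$transcripts$transcript_id)
  hy <- tr[tr$is_hybrid, ]
  frag <- substr(txseq[hy$transcript_id], hy$target_start + 1, hy$target_end)
  expected <- ifelse(hy$order == "mirna_first",
                     paste0(mirseq[hy$mirna_name], frag),
                     paste0(frag, mirseq[hy$mirna_name]))
  expect_identical(unname(expected), hy$insert_seq)

  # hybrid flags imply complete records
  expect_true(all(nzchar(hy$mirna_name) & nzchar(hy$transcript_id)))
  expect_true(all(hy$target_end > hy$target_start))

  # PCR duplicates are byte-identical within each molecule
  dup <- tr$read_id[tr$n_pcr_copies > 1][1]
  copies <- sim$reads[startsWith(sim$reads$read_id, paste0(dup, "/")), ]
  expect_true(all(copies$seq1 == copies$seq1[1]))
  expect_true(all(copies$seq2 == copies$seq2[1]))
})

test_that("hybrid fraction behaves binomially and zero gives none", {
  p0 <- small_params(n_reads = 300L, hybrid_fraction = 0)
  refs <- generate_references(p0)
  s0 <- simulate_library(refs$transcripts, refs$mirnas, p0, refs$seed_sites)
  expect_equal(sum(s0$truth$is_hybrid), 0)

  p <- sim_params(n_transcripts = 40L, n_mirnas = 15L, n_reads = 10000L,
                  hybrid_fraction = 0.5, error_rate = 0, rng_seed = 7L)
  refs <- generate_references(p)
  s <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  # binomial oracle: within 3 * sqrt(n p (1-p)) of n p
  expect_lt(abs(sum(s$truth$is_hybrid) - 5000), 3 * sqrt(10000 * 0.25))
})

test_that("one miRNA forces all hybrids to carry it", {
  p <- sim_params(n_transcripts = 20L, n_mirnas = 1L, n_reads = 200L,
                  error_rate = 0, rng_seed = 5L)
  refs <- generate_references(p)
  s <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  hy <- s$truth[s$truth$is_hybrid, ]
  expect_true(all(hy$mirna_name == refs$mirnas$name[1]))
})

test_that("realized region proportions match the sampling weights", {
  p <- sim_params(n_transcripts = 60L, n_mirnas = 20L, n_reads = 6000L,
                  error_rate = 0, rng_seed = 11L)
  refs <- generate_references(p)
  s <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  hy <- s$truth[s$truth$is_hybrid, ]
  ann <- refs$transcripts[match(hy$transcript_id,
                                refs$transcripts$transcript_id), ]
  lab <- assign_region(hy$target_start, hy$target_end,
                       ann$cds_start, ann$cds_end, ann$length)
  prop <- region_proportions(lab)
  n <- nrow(hy)
  w <- p$target_region_weights
  # multinomial 99% bounds per category
  for (i in 1:3) {
    expect_lt(abs(prop[i] - w[i]),
              qnorm(0.995) * sqrt(w[i] * (1 - w[i]) / n) + 1e-9)
  }
})

test_that("miRNA abundance correlates with hybrid counts on log scale", {
  p <- sim_params(n_transcripts = 60L, n_mirnas = 60L, n_reads = 8000L,
                  error_rate = 0, rng_seed = 13L)
  refs <- generate_references(p)
  s <- simulate_library(refs$transcripts, refs$mirnas, p, refs$seed_sites)
  hy <- s$truth[s$truth$is_hybrid, ]
  counts <- table(factor(hy$mirna_name, levels = refs$mirnas$name))
  r <- pearson_r(refs$mirnas$abundance_weight * sum(counts),
                 as.numeric(counts), log10_transform = TRUE)
  expect_gte(r$r, 0.7)
})

test_that("fold-change simulation shifts targets as directed", {
  targets <- sprintf("T%03d", 1:150)
  fc_m <- simulate_fold_changes(targets, 2000, effect = 0.5,
                                noise_sd = 0.3, direction = "mimic",
                                rng_seed = 3L)
  expect_equal(nrow(fc_m), 2000)
  expect_false(anyDuplicated(fc_m$gene_id) > 0)
  expect_true(all(is.finite(fc_m$log2fc)))
  expect_true(all(fc_m$pvalue >= 0 & fc_m$pvalue <= 1))
  mt <- mean(fc_m$log2fc[fc_m$gene_id %in% targets])
  # law-of-large-numbers oracle: mean within 4 SE of -0.5
  expect_lt(abs(mt - (-0.5)), 4 * 0.3 / sqrt(150))

  # antagomir with the same seed flips the target shift
  fc_a <- simulate_fold_changes(targets, 2000, effect = 0.5,
                                noise_sd = 0.3, direction = "antagomir",
                                rng_seed = 3L)
  ma <- mean(fc_a$log2fc[fc_a$gene_id %in% targets])
  expect_equal(ma - mt, 1.0, tolerance = 1e-12)

  # effect zero: target and background means agree within 4 SE
  fc0 <- simulate_fold_changes(targets, 2000, effect = 0, noise_sd = 0.3,
                               rng_seed = 4L)
  d <- mean(fc0$log2fc[fc0$gene_id %in% targets]) -
    mean(fc0$log2fc[!(fc0$gene_id %in% targets)])
  expect_lt(abs(d), 4 * 0.3 / sqrt(150))

  expect_error(simulate_fold_changes(targets, 2000, 0.5, noise_sd = 0),
               "noise_sd")
})

test_that("parameter validation rejects bad inputs", {
  expect_error(sim_params(n_transcripts = 0), "positive")
  expect_error(sim_params(hybrid_fraction = 1.2), "probability")
  expect_error(sim_params(target_region_weights = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(sim_params(adapter3 = ""), "nonempty")
  expect_error(sim_params(pcr_dup_mean = 0.5), ">= 1")
  expect_error(sim_params(transcript_length_range = c(2000, 600)),
               "min, max")
})
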