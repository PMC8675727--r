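adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming removes full and terminal-prefix occurrences", {
  insert <- "ACGTACGTACGTACGT"
  expect_identical(trim_adapter(paste0(insert, adapter), adapter), insert)
  # read with no adapter substring is unchanged
  expect_identical(trim_adapter(insert, adapter), insert)
  # trailing adapter prefix shorter than min_overlap is kept
  expect_identical(trim_adapter(paste0(insert, substr(adapter, 1, 4)),
                                adapter),
                   paste0(insert, substr(adapter, 1, 4)))
  # internal occurrence: everything 3' of it goes too
  expect_identical(trim_adapter(paste0(insert, adapter, "GGGTTT"), adapter),
                   insert)
  expect_error(trim_adapter("ACGT", ""), "nonempty")
  expect_error(trim_adapter("ACGT", adapter, min_overlap = 3), ">= 5")
})

test_that("mismatched terminal prefixes are trimmed per the scan oracle", {
  set.seed(42)
  # brute-force oracle over all (position, length) candidates
  oracle <- function(s, ad, min_ov, mef) {
    ach <- strsplit(ad, "")[[1]]
    sch <- strsplit(s, "")[[1]]
    n <- length(sch)
    best <- c(score = -Inf, pos = NA)
    for (p in seq_len(n)) {
      len <- min(length(ach), n - p + 1)
      if (len < length(ach) && p + len - 1 < n) next
      if (len < min_ov) next
      mm <- sum(sch[p:(p + len - 1)] != ach[seq_len(len)])
      if (mm / len > mef) next
      sc <- (len - mm) - 2 * mm
      if (sc > best["score"]) best <- c(score = sc, pos = p)
    }
    if (is.na(best["pos"])) s else substr(s, 1, best["pos"] - 1)
  }
  for (rep in 1:50) {
    core <- paste(sample(c("A", "C", "G", "T"), sample(15:40, 1),
                         replace = TRUE), collapse = "")
    plen <- sample(5:12, 1)
    pref <- strsplit(substr(adapter, 1, plen), "")[[1]]
    # corrupt up to one base of the adapter prefix
    if (runif(1) < 0.7) {
      i <- sample(plen, 1)
      pref[i] <- sample(setdiff(c("A", "C", "G", "T"), pref[i]), 1)
    }
    read <- paste0(core, paste(pref, collapse = ""))
    expect_identical(trim_adapter(read, adapter, 5, 0.2),
                     oracle(read, adapter, 5, 0.2))
  }
})

test_that("pair merging reconstructs inserts and applies quality consensus", {
  set.seed(314)
  insert <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  r1 <- substr(insert, 1, 40)
  r2 <- revcomp(substr(insert, 21, 60))
  m <- merge_pairs(r1, strrep("I", 40), r2, strrep("I", 40))
  expect_identical(m$seq, insert)

  # disjoint halves with too little overlap fail
  r2b <- revcomp(substr(insert, 38, 60))
  expect_null(merge_pairs(substr(insert, 1, 40), strrep("I", 40),
                          r2b, strrep("I", 23), min_overlap = 10))

  # two-case oracle: the higher-quality base wins the disagreement
  a1 <- "ACGTACGTACGTACGTACGT"
  bad <- paste0(substr(a1, 1, 11), "A", substr(a1, 13, 20))  # pos 12 T->A
  q_hi <- strrep("I", 20)
  q_lo <- paste0(strrep("I", 11), "#", strrep("I", 8))
  # mate 2 carries the disagreeing base at low quality -> mate 1 wins
  m1 <- merge_pairs(a1, q_hi, revcomp(bad), rev_string(q_lo))
  expect_identical(m1$seq, a1)
  # mate 2 at high quality, mate 1 low -> mate 2 wins
  m2 <- merge_pairs(a1, q_lo, revcomp(bad), rev_string(q_hi))
  expect_identical(m2$seq, bad)
})

test_that("duplicate collapsing counts exactly and orders deterministically", {
  out <- collapse_duplicates(c("X", "X", "Y"), c("a", "b", "c"))
  expect_equal(out$sequence, c("X", "Y"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(out$representative_id, c("a", "c"))

  all_distinct <- collapse_duplicates(sprintf("S%02d", 1:20))
  expect_equal(nrow(all_distinct), 20)
  expect_true(all(all_distinct$count == 1))

  # hash-count oracle on 1,000 draws from 10 sequences
  set.seed(9)
  pool <- vapply(1:10, function(i) {
    paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  }, "")
  draws <- sample(pool, 1000, replace = TRUE)
  out <- collapse_duplicates(draws)
  tally <- table(draws)
  expect_equal(sum(out$count), 1000)
  expect_equal(out$count, as.integer(tally[out$sequence]),
               ignore_attr = TRUE)
  expect_false(is.unsorted(rev(out$count)))
})

test_that("UMI trimming strips 4+4 bases and discards short reads", {
  s20 <- strrep("ACGT", 5)
  expect_identical(trim_umi(s20, min_insert = 12),
                   substr(s20, 5, 16))
  # surviving reads shrink by exactly 8 nt with defaults
  s30 <- strrep("ACGTAC", 5)
  expect_equal(nchar(trim_umi(s30)), nchar(s30) - 8)
  # too-short reads yield the discard signal
  expect_true(is.na(trim_umi("ACGTACGTAC")))
  expect_true(is.na(trim_umi(s20)))  # 12-nt insert < 16-nt default minimum
})

test_that("preprocessing recovers the exact insert multiset error-free", {
  exp <- small_experiment()
  pp <- preprocess_reads(exp$sim, exp$params$adapter3)
  expect_equal(pp$log[["reads_in"]], nrow(exp$sim$reads))
  expect_equal(pp$log[["merge_failed"]], 0)
  # recall = 1: every distinct true insert appears, with the right
  # molecule multiplicity (counts are PCR copies summed per sequence)
  truth_tab <- table(exp$sim$truth$insert_seq)
  expect_setequal(pp$inserts$sequence, names(truth_tab))
  copy_tab <- tapply(exp$sim$truth$n_pcr_copies, exp$sim$truth$insert_seq,
                     sum)
  # molecules sharing an insert but differing in UMIs stay distinct through
  # collapsing; aggregate rows per insert before comparing to the truth
  agg <- tapply(pp$inserts$count, pp$inserts$sequence, sum)
  expect_equal(as.integer(agg[names(copy_tab)]),
               as.integer(copy_tab),
               ignore_attr = TRUE)
  # conservation through collapsing
  expect_equal(sum(pp$inserts$count), nrow(exp$sim$reads))
})

test_that("stage operations never lengthen a sequence", {
  set.seed(21)
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:80, 1),
                      replace = TRUE), collapse = "")
    expect_lte(nchar(trim_adapter(s, adapter)), nchar(s))
    tu <- trim_umi(s)
    if (!is.na(tu)) expect_lte(nchar(tu), nchar(s))
  }
})
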