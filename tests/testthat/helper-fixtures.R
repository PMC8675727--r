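# Shared fixtures, built in code at test time.

# Small but complete simulated experiment used by several test files.
small_params <- function(...) {
  defaults <- list(n_transcripts = 40L,
                   transcript_length_range = c(600L, 1200L),
                   n_mirnas = 15L, n_reads = 1200L, error_rate = 0,
                   rng_seed = 101L)
  do.call(sim_params, utils::modifyList(defaults, list(...)))
}

small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- small_params()
      refs <- generate_references(p)
      sim <- simulate_library(refs$transcripts, refs$mirnas, p,
                              refs$seed_sites)
      idx <- build_index(refs$mirnas, refs$transcripts)
      cache <<- list(params = p, refs = refs, sim = sim, index = idx)
    }
    cache
  }
})

rev_string <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# Independent union-find merger used as the interval-clustering oracle.
union_find_merge <- function(starts, ends, min_overlap = 1L) {
  n <- length(starts)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          min(ends[i], ends[j]) - max(starts[i], starts[j]) >= min_overlap) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(n), find, 0L)
  lapply(split(seq_len(n), root), function(ix) {
    c(min(starts[ix]), max(ends[ix]))
  })
}

# Brute-force duplex alignment oracle: enumerate every monotone set of
# aligned columns of the miRNA vs the reversed target; each column is a
# Watson-Crick pair (+2), G:U pair (+1) or mismatch (-1); positions skipped
# BETWEEN consecutive columns cost -2 each, dangling ends are free.
# Returns the maximum score and, among score maxima, the maximum pair count.
brute_force_duplex <- function(mirna_seq, target_seq) {
  m <- strsplit(chartr("Uu", "Tt", toupper(mirna_seq)), "")[[1]]
  tr <- rev(strsplit(chartr("Uu", "Tt", toupper(target_seq)), "")[[1]])
  col_score <- function(a, b) {
    if ((a == "A" && b == "T") || (a == "T" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) {
      c(2, 1)
    } else if ((a == "G" && b == "T") || (a == "T" && b == "G")) {
      c(1, 1)
    } else {
      c(-1, 0)
    }
  }
  best <- c(0, 0)  # empty alignment
  rec <- function(i, j, score, pairs, started, li, lj) {
    # close the alignment here (trailing skips free)
    if (score > best[1] || (score == best[1] && pairs > best[2])) {
      best <<- c(score, pairs)
    }
    if (i > length(m) || j > length(tr)) return()
    for (ii in i:length(m)) {
      for (jj in j:length(tr)) {
        cs <- col_score(m[ii], tr[jj])
        gap_cost <- if (started) 2 * ((ii - li - 1) + (jj - lj - 1)) else 0
        rec(ii + 1L, jj + 1L, score + cs[1] - gap_cost, pairs + cs[2],
            TRUE, ii, jj)
      }
    }
  }
  rec(1L, 1L, 0, 0, FALSE, 0L, 0L)
  list(score = best[1], npairs = best[2])
}

# Exhaustive small-sample two-sample KS p-value oracle.
enumerate_ks_p <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  ecdf_d <- function(x, y) {
    pts <- sort(unique(c(x, y)))
    max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
  }
  D <- ecdf_d(a, b)
  combs <- combn(length(pool), n1)
  Ds <- apply(combs, 2, function(ix) ecdf_d(pool[ix], pool[-ix]))
  mean(Ds >= D - 1e-12)
}
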