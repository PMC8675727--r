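#' Pearson correlation with optional log10 transform
#'
#' @param x,y numeric vectors of equal length (>= 3 pairs).
#' @param log10_transform correlate on log10(value + pseudocount) as done
#'   for count data on logarithmic axes.
#' @param pseudocount added before the log (> 0 when transforming).
#' @return object of class `correlation_result`: list(r, n,
#'   log_transformed). `r` is NA (with a warning) when either vector has
#'   zero variance.
#' @export
pearson_r <- function(x, y, log10_transform = FALSE, pseudocount = 1) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must be equal-length vectors with at least 3 pairs",
         call. = FALSE)
  }
  if (log10_transform) {
    if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
    x <- log10(x + pseudocount)
    y <- log10(y + pseudocount)
  }
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: correlation undefined")
    NA_real_
  } else {
    stats::cor(x, y)
  }
  structure(list(r = r, n = length(x), log_transformed = log10_transform),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d%s)\n", x$r, x$n,
              if (x$log_transformed) ", log10 scale" else ""))
  invisible(x)
}

# D statistic: max |ECDF_a - ECDF_b| over the pooled support.
.ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, sort(a)) / length(a)
  Fb <- findInterval(pts, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference between the two empirical CDFs.
#' The p-value is computed by exhaustive enumeration of all assignments of
#' the pooled sample when n1 + n2 <= 12, and otherwise from the asymptotic
#' Kolmogorov distribution with the two-term small-sample correction of the
#' effective size n1*n2/(n1+n2).
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return object of class `ks_result`: list(D, pvalue, n1, n2, method).
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  n1 <- length(a)
  n2 <- length(b)
  D <- .ks_D(a, b)
  if (n1 + n2 <= 12L) {
    pool <- c(a, b)
    combs <- utils::combn(n1 + n2, n1)
    Ds <- apply(combs, 2, function(ix) .ks_D(pool[ix], pool[-ix]))
    p <- mean(Ds >= D - 1e-12)
    method <- "exact enumeration"
  } else {
    ne <- n1 * n2 / (n1 + n2)
    lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
    j <- 1:100
    p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    p <- min(max(p, .Machine$double.xmin), 1)
    if (D == 0) p <- 1
    method <- "asymptotic"
  }
  structure(list(D = D, pvalue = p, n1 = n1, n2 = n2, method = method),
            class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample KS: D = %.4f, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$D, x$pvalue, x$n1, x$n2, x$method))
  invisible(x)
}

#' Empirical CDF curve
#'
#' @param values numeric vector.
#' @return data.frame (class `ecdf_curve`) with columns value (sorted) and
#'   cumfrac (nondecreasing, ending at 1).
#' @export
ecdf_curve <- function(values) {
  stopifnot(length(values) >= 1L)
  v <- sort(values)
  structure(data.frame(value = v,
                       cumfrac = seq_along(v) / length(v)),
            class = c("ecdf_curve", "data.frame"))
}

#' Compare fold-change CDFs of target sets against the background
#'
#' For each named gene set, builds the empirical CDF of log2 fold changes
#' and tests it against the background with a two-sample KS test. Genes
#' absent from the fold-change table are dropped (and counted). By default
#' the background excludes the tested set so the two samples are disjoint
#' and the test is calibrated; set `exclude_set_from_background = FALSE`
#' to test against the full table instead.
#'
#' @param fc fold-change data.frame (gene_id, log2fc).
#' @param target_sets named list of character vectors of gene ids.
#' @param exclude_set_from_background logical, see above.
#' @return object of class `cdf_comparison`: named list, one element per
#'   set with (set, n, n_dropped, ecdf, ks); sets with empty intersection
#'   yield NULL with a warning. The background ECDF is in
#'   `attr(, "background")`.
#' @export
cdf_compare <- function(fc, target_sets,
                        exclude_set_from_background = TRUE) {
  stopifnot(is.list(target_sets), !is.null(names(target_sets)))
  out <- stats::setNames(vector("list", length(target_sets)),
                         names(target_sets))
  for (nm in names(target_sets)) {
    genes <- unique(target_sets[[nm]])
    in_fc <- genes %in% fc$gene_id
    if (!any(in_fc)) {
      warning(sprintf("target set '%s' has no genes in the table", nm))
      next
    }
    sel <- fc$gene_id %in% genes[in_fc]
    vals <- fc$log2fc[sel]
    bg <- if (exclude_set_from_background) fc$log2fc[!sel] else fc$log2fc
    out[[nm]] <- list(
      set = nm,
      n = length(vals),
      n_dropped = sum(!in_fc),
      ecdf = ecdf_curve(vals),
      ks = ks_two_sample(vals, bg)
    )
  }
  attr(out, "background") <- ecdf_curve(fc$log2fc)
  class(out) <- "cdf_comparison"
  out
}

#' @export
print.cdf_comparison <- function(x, ...) {
  cat("fold-change CDF comparison vs background:\n")
  for (nm in names(x)) {
    el <- x[[nm]]
    if (is.null(el)) {
      cat(sprintf("  %-20s (no genes in table)\n", nm))
    } else {
      cat(sprintf("  %-20s n = %4d  D = %.4f  p = %.3g\n",
                  nm, el$n, el$ks$D, el$ks$pvalue))
    }
  }
  invisible(x)
}

#' Tabulate a `cdf_comparison`
#'
#' @param x object from [cdf_compare()].
#' @return data.frame with columns set, n, n_dropped, D, pvalue.
#' @export
cdf_compare_table <- function(x) {
  do.call(rbind, lapply(names(x), function(nm) {
    el <- x[[nm]]
    if (is.null(el)) {
      data.frame(set = nm, n = 0L, n_dropped = NA_integer_, D = NA_real_,
                 pvalue = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(set = nm, n = el$n, n_dropped = el$n_dropped, D = el$ks$D,
                 pvalue = el$ks$pvalue, stringsAsFactors = FALSE)
    }
  }))
}

#' Comparative-Ct (2^-ddCt) fold change
#'
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control); the fold change is 2^-ddCt.
#'
#' @param ct_target_treated,ct_target_control,ct_ref_treated,ct_ref_control
#'   Ct values in cycles (finite).
#' @return list (class `ddct_result`) with ddct and fold_change.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_target_control,
                             ct_ref_treated, ct_ref_control) {
  vals <- c(ct_target_treated, ct_target_control, ct_ref_treated,
            ct_ref_control)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  structure(list(ddct = ddct, fold_change = 2^(-ddct)),
            class = "ddct_result")
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("ddCt = %.3f cycles, fold change = %.3f\n",
              x$ddct, x$fold_change))
  invisible(x)
}

#' Rank shift of top miRNAs between two conditions
#'
#' Ranks miRNAs (1 = highest count, ties broken lexicographically by name)
#' in each condition and reports, for the top `top_n` of condition a, the
#' rank in both conditions. miRNAs absent from condition b get NA.
#'
#' @param counts_a,counts_b named numeric vectors of per-miRNA normalized
#'   counts.
#' @param top_n how many of condition a's top miRNAs to report.
#' @return data.frame: mirna, rank_a, rank_b.
#' @export
rank_shift <- function(counts_a, counts_b, top_n) {
  stopifnot(top_n <= length(counts_a))
  rank_of <- function(counts) {
    nm <- names(counts)[order(-counts, names(counts))]
    stats::setNames(seq_along(nm), nm)
  }
  ra <- rank_of(counts_a)
  rb <- rank_of(counts_b)
  top <- names(ra)[seq_len(top_n)]
  data.frame(
    mirna = top,
    rank_a = as.integer(ra[top]),
    rank_b = as.integer(rb[top]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
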