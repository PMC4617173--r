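# Normalization and differential expression for unreplicated tag counts.

#' Tags-per-million normalization for small-RNA counts
#'
#' `TPM = count / total clean reads * 1e6`. Zero counts normalize to zero;
#' flooring for fold-change computation is handled by [log2fc()].
#'
#' @param count tag count(s), >= 0.
#' @param total_clean total clean reads in the library (> 0).
#' @return normalized expression, same length as `count`.
#' @export
tpm <- function(count, total_clean) {
  stopifnot(all(count >= 0))
  if (length(total_clean) != 1L || total_clean <= 0) {
    stop("total_clean must be a single positive count")
  }
  count / total_clean * 1e6
}

#' RPKM normalization for gene counts
#'
#' `RPKM = 1e9 * C / (N * L)` where `C` is the number of reads uniquely
#' aligned to the gene, `N` the total reads uniquely aligned to all genes,
#' and `L` the gene length in bases.
#'
#' @param C per-gene read count(s).
#' @param N total aligned reads (> 0).
#' @param L gene length(s) in bases (> 0).
#' @return normalized expression.
#' @export
rpkm <- function(C, N, L) {
  stopifnot(all(C >= 0))
  if (any(L <= 0)) stop("gene length L must be positive")
  if (length(N) != 1L || N <= 0) stop("N must be a single positive count")
  1e9 * as.numeric(C) / (as.numeric(N) * as.numeric(L))
}

#' Log2 fold change of normalized expression (CMS vs control)
#'
#' `log2(norm_cms / norm_control)`. A zero on exactly one side is floored
#' to `floor_at` (default 0.01 normalized units) so the ratio is defined;
#' features zero in both samples have no defined fold change and must be
#' excluded upstream (this function returns `NA` for them).
#'
#' @param norm_control,norm_cms normalized expression values (>= 0).
#' @param floor_at floor applied to one-sided zeros.
#' @return log2 fold changes.
#' @export
log2fc <- function(norm_control, norm_cms, floor_at = 0.01) {
  stopifnot(length(norm_control) == length(norm_cms),
            all(norm_control >= 0), all(norm_cms >= 0))
  both_zero <- norm_control == 0 & norm_cms == 0
  a <- ifelse(norm_control == 0, floor_at, norm_control)
  b <- ifelse(norm_cms == 0, floor_at, norm_cms)
  out <- log2(b / a)
  out[both_zero] <- NA_real_
  out
}

#' Audic-Claverie test for a pair of tag counts
#'
#' Exact test for equality of underlying rates of one feature observed
#' `x` times in a library of size `N1` and `y` times in a library of size
#' `N2` (the standard test for unreplicated SAGE/tag-count designs). The
#' conditional distribution of the second count given the first is
#' negative binomial with size `x + 1` and probability `N1 / (N1 + N2)`;
#' the two-sided p-value sums the probability of every outcome whose mass
#' does not exceed that of the observed `y` (minimum-likelihood method),
#' so `p = 1` exactly when `x = y` and `N1 = N2`.
#'
#' @param x,y observed counts (non-negative integers).
#' @param N1,N2 library sizes (> 0).
#' @return p-value in (0, 1].
#' @export
tag_count_test <- function(x, y, N1, N2) {
  stopifnot(length(x) == length(y))
  if (length(x) > 1L) {
    return(mapply(tag_count_test, x, y, MoreArgs = list(N1 = N1, N2 = N2)))
  }
  stopifnot(x >= 0, y >= 0, N1 > 0, N2 > 0)
  size <- x + 1
  prob <- N1 / (N1 + N2)
  lm <- function(yy) dnbinom(yy, size = size, prob = prob, log = TRUE)
  tol <- 1e-9  # log-space tie tolerance
  thr <- lm(y) + tol
  # the mass is unimodal in y'; outcomes no heavier than the observed one
  # form a left tail [0, yL] and a right tail [yR, Inf), summed exactly
  # through the CDF
  mode_y <- max(0, floor((size - 1) * (1 - prob) / prob))
  if (lm(mode_y) <= thr) return(1)
  # left boundary: last y' < mode with mass <= observed (mass increasing)
  lo <- 0L; hi <- mode_y
  if (lm(0) > thr) {
    yL <- -1L
  } else {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (lm(mid) <= thr) lo <- mid else hi <- mid
    }
    yL <- lo
  }
  # right boundary: first y' > mode with mass <= observed (mass decreasing)
  hi <- max(y, mode_y + 1L)
  while (lm(hi) > thr) hi <- hi * 2L + 1L
  lo <- mode_y
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (lm(mid) <= thr) hi <- mid else lo <- mid
  }
  yR <- hi
  p <- (if (yL >= 0) stats::pnbinom(yL, size = size, prob = prob) else 0) +
    stats::pnbinom(yR - 1, size = size, prob = prob, lower.tail = FALSE)
  min(1, p)
}

#' Pearson chi-squared test for a pair of counts against library totals
#'
#' One-degree-of-freedom Pearson chi-squared on the 2x2 table
#' `[[c1, N1 - c1], [c2, N2 - c2]]` (the "general chi-squared" method for
#' unreplicated count comparison). When any expected cell falls below 1 the
#' test is unreliable and the exact [tag_count_test()] is used instead; the
#' fallback is flagged in the result.
#'
#' @param c1,c2 per-feature counts.
#' @param N1,N2 library totals.
#' @return list with `p_value`, `statistic` (NA when the fallback fired)
#'   and `fallback` (logical).
#' @export
chi2_test <- function(c1, c2, N1, N2) {
  stopifnot(c1 >= 0, c2 >= 0, N1 > 0, N2 > 0)
  tab <- matrix(c(c1, N1 - c1, c2, N2 - c2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    return(list(p_value = tag_count_test(c1, c2, N1, N2),
                statistic = NA_real_, fallback = TRUE))
  }
  stat <- sum((tab - expected)^2 / expected)
  list(p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       statistic = stat, fallback = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (wrapper over `stats::p.adjust`, kept as the
#' single point where the multiple-testing method is chosen).
#'
#' @param p vector of p-values in `[0, 1]` (0 arises from underflow of
#'   extreme chi-squared statistics).
#' @return q-values, monotone in the ranks of `p`.
#' @export
bh_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Differential-expression regulation calls
#'
#' Applies the two-fold rule plus a significance gate to a table of
#' normalized expression pairs. The miRNA layer gates on the raw p-value
#' (`p < 1e-3` by default, matching the unreplicated tag-count design); the
#' mRNA layer gates on the BH q-value (`q < 1e-2` generally, with a
#' stricter `1e-3` preset used when reporting validated targets). When no
#' p/q column is supplied the call reduces to the fold-change rule alone,
#' which is how printed, already-filtered tables are re-checked.
#'
#' @param norm_control,norm_cms normalized expression vectors.
#' @param p_value optional p-values (miRNA layer gate).
#' @param q_value optional q-values (mRNA layer gate).
#' @param layer `"mirna"` or `"mrna"`.
#' @param lfc_min minimum |log2 fold change| (default 1, i.e. two-fold).
#' @param p_max,q_max significance ceilings for the respective layer.
#' @param floor_at zero-flooring for the fold change, see [log2fc()].
#' @return data.frame with `norm_control`, `norm_cms`, `log2fc`, `call`
#'   (`"up"`, `"down"`, `"ns"`; `NA` log2fc gives `"excluded"`).
#' @export
call_de <- function(norm_control, norm_cms, p_value = NULL, q_value = NULL,
                    layer = c("mirna", "mrna"), lfc_min = 1,
                    p_max = 1e-3, q_max = 1e-2, floor_at = 0.01) {
  layer <- match.arg(layer)
  lfc <- log2fc(norm_control, norm_cms, floor_at = floor_at)
  sig <- rep(TRUE, length(lfc))
  if (layer == "mirna" && !is.null(p_value)) sig <- p_value < p_max
  if (layer == "mrna" && !is.null(q_value)) sig <- q_value < q_max
  call <- ifelse(is.na(lfc), "excluded",
                 ifelse(sig & lfc >= lfc_min, "up",
                        ifelse(sig & lfc <= -lfc_min, "down", "ns")))
  data.frame(norm_control = norm_control, norm_cms = norm_cms,
             log2fc = lfc, call = call, stringsAsFactors = FALSE)
}

#' Differential expression of a two-sample count table
#'
#' End-to-end DE for one layer: normalize (TPM for miRNA tags, RPKM for
#' genes), test (Audic-Claverie for the miRNA layer, chi-squared with exact
#' fallback for the mRNA layer), adjust (BH), and call regulation.
#' Features with zero counts in both samples are excluded and reported.
#'
#' @param counts data.frame with columns `feature`, `count_control`,
#'   `count_cms`.
#' @param totals length-2 numeric `(control, cms)` library totals (clean
#'   reads for the miRNA layer, mapped reads for the mRNA layer).
#' @param layer `"mirna"` or `"mrna"`.
#' @param gene_lengths named vector of gene lengths (mRNA layer only).
#' @param ... thresholds passed on to [call_de()].
#' @return data.frame, one row per retained feature: feature, counts,
#'   normalized pair, log2fc, p_value, q_value, call; excluded features in
#'   `attr(, "excluded")`.
#' @export
diff_expression <- function(counts, totals, layer = c("mirna", "mrna"),
                            gene_lengths = NULL, ...) {
  layer <- match.arg(layer)
  stopifnot(all(c("feature", "count_control", "count_cms") %in% names(counts)),
            length(totals) == 2L, all(totals > 0))
  zero <- counts$count_control == 0 & counts$count_cms == 0
  excluded <- counts$feature[zero]
  x <- counts[!zero, , drop = FALSE]
  if (layer == "mirna") {
    nc <- tpm(x$count_control, totals[1])
    nm <- tpm(x$count_cms, totals[2])
    p <- tag_count_test(x$count_control, x$count_cms, totals[1], totals[2])
  } else {
    stopifnot(!is.null(gene_lengths))
    L <- gene_lengths[x$feature]
    if (anyNA(L)) stop("missing gene length for: ",
                       paste(head(x$feature[is.na(L)]), collapse = ", "))
    nc <- rpkm(x$count_control, totals[1], L)
    nm <- rpkm(x$count_cms, totals[2], L)
    p <- vapply(seq_len(nrow(x)), function(i) {
      chi2_test(x$count_control[i], x$count_cms[i], totals[1], totals[2])$p_value
    }, numeric(1))
  }
  q <- bh_fdr(p)
  calls <- call_de(nc, nm, p_value = p, q_value = q, layer = layer, ...)
  out <- data.frame(feature = x$feature,
                    count_control = x$count_control,
                    count_cms = x$count_cms,
                    norm_control = nc, norm_cms = nm,
                    log2fc = calls$log2fc, p_value = p, q_value = q,
                    call = calls$call, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}
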