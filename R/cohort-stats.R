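# Cohort-level statistics: per-patient paired tests of metric values
# (tumor vs normal), FDR correction across the cohort, direction calls,
# and Spearman correlation utilities.
#
# Note on terminology: figures of this kind are often labelled "paired
# Wilcoxon rank sum test", but a rank-sum test cannot be paired; the test
# actually performed on paired values is the Wilcoxon signed-rank test,
# which is what this module implements.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values.  Zero differences are
#' dropped (the classical treatment); the null distribution is exact for
#' n <= 25 informative pairs without ties, and a normal approximation with
#' continuity correction otherwise.  With fewer than `min_n` informative
#' pairs the test is uninformative and `p = 1` is returned with a warning;
#' all-zero differences likewise give `p = 1`.
#'
#' @param tumor,normal Equal-length paired numeric vectors.
#' @param min_n Minimum number of pairs to attempt the test (default 6).
#' @param zero_method `"wilcox"` (drop zero differences, default) or
#'   `"pratt"` (rank zeros, then discard their ranks).
#' @return Two-sided p-value.
#' @export
paired_wilcoxon <- function(tumor, normal, min_n = 6L,
                            zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(tumor) == length(normal))
  ok <- complete.cases(tumor, normal)
  d <- tumor[ok] - normal[ok]
  if (length(d) < min_n) {
    warning("fewer than ", min_n, " pairs; returning p = 1", call. = FALSE)
    return(1)
  }
  if (all(d == 0)) return(1)
  if (zero_method == "wilcox") {
    d <- d[d != 0]
    n <- length(d)
    ties <- any(duplicated(abs(d)))
    suppressWarnings(
      wilcox.test(d, exact = (n <= 25L && !ties), correct = TRUE)$p.value)
  } else {
    .wilcoxon_pratt(d)
  }
}

# Pratt zero handling: rank |d| including zeros, drop zero ranks, normal
# approximation with tie/zero-corrected variance.
.wilcoxon_pratt <- function(d) {
  r <- rank(abs(d))
  nz <- d != 0
  V <- sum(r[nz][d[nz] > 0])
  n <- length(d)
  n0 <- sum(!nz)
  mu <- (n * (n + 1) / 2 - n0 * (n0 + 1) / 2) / 2
  tie_tab <- table(r[nz])
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (V - mu) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR correction; a thin wrapper around [stats::p.adjust()] so the
#' adjustment family used across the cohort is explicit and testable.
#'
#' @param p Vector of p-values.
#' @return q-values, same order as `p`.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Direction call for one patient
#'
#' A patient's tumor is called `"lower"` (stronger NMD than normal) when
#' the FDR-adjusted p-value is below `alpha` and the median tumor/normal
#' ratio is below 1; `"higher"` when significant with ratio above 1;
#' otherwise `"ns"`.
#'
#' @param q_value FDR-adjusted p-value.
#' @param median_ratio Median per-feature tumor/normal ratio.
#' @param alpha Significance level (default 0.05).
#' @return `"lower"`, `"higher"`, or `"ns"`.
#' @export
call_direction <- function(q_value, median_ratio, alpha = 0.05) {
  if (is.na(q_value) || is.na(median_ratio) || q_value >= alpha) return("ns")
  if (median_ratio < 1) "lower" else if (median_ratio > 1) "higher" else "ns"
}

#' Spearman rank correlation with p-value
#'
#' Average ranks for ties; two-sided p-value by exact permutation for
#' n <= 10 and the t approximation otherwise.  Degenerate (constant or
#' too-short) input yields `NA` for both.
#'
#' @param x,y Numeric vectors of equal length (pairs with `NA` dropped).
#' @return Named list: `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = (n <= 10L)))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Per-patient paired comparisons of a metric across a cohort
#'
#' For each patient, tests the paired per-feature metric values (tumor vs
#' normal) with [paired_wilcoxon()], adjusts p-values across the patients
#' of the cohort with [bh_fdr()] (the adjustment family is the cohort
#' within one metric), and calls a direction per patient with
#' [call_direction()].
#'
#' @param values Long metric data.frame (`metric`, `feature_id`,
#'   `sample_id`, `value`) for one metric.
#' @param samples Sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @param alpha Significance level for direction calls (default 0.05).
#' @param min_n,zero_method Passed to [paired_wilcoxon()].
#' @return Data.frame of class `nmd_comparison`: `patient_id`, `metric`,
#'   `n_features`, `median_ratio`, `p_value`, `q_value`, `direction`.
#' @export
compare_patients <- function(values, samples, alpha = 0.05, min_n = 6L,
                             zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  metric <- if (nrow(values)) values$metric[1L] else NA_character_
  pr <- patient_ratios(values, samples)
  s <- pr$summary
  p <- vapply(s$patient_id, function(pid) {
    pp <- pr$pairs[pr$pairs$patient_id == pid, ]
    if (!nrow(pp)) return(NA_real_)
    suppressWarnings(
      paired_wilcoxon(pp$tumor, pp$normal, min_n = min_n,
                      zero_method = zero_method))
  }, 0)
  out <- data.frame(patient_id = s$patient_id, metric = metric,
                    n_features = s$n_features,
                    median_ratio = s$median_ratio,
                    p_value = p, q_value = bh_fdr(p),
                    stringsAsFactors = FALSE)
  out$direction <- mapply(call_direction, out$q_value, out$median_ratio,
                          MoreArgs = list(alpha = alpha))
  class(out) <- c("nmd_comparison", "data.frame")
  out
}

#' @export
print.nmd_comparison <- function(x, ...) {
  cat("Paired tumor/normal comparisons (", x$metric[1L], "), ",
      nrow(x), " patient(s): ", sum(x$direction == "lower"), " lower, ",
      sum(x$direction == "higher"), " higher, ",
      sum(x$direction == "ns"), " ns\n", sep = "")
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more)\n", sep = "")
  invisible(x)
}

#' Correlate NMD metrics with NMD-effector expression
#'
#' For each effector gene, computes the Spearman correlation between its
#' expression and a per-sample metric summary (`mode = "per_sample"`), or
#' between its tumor/normal expression ratio and the patient's median
#' metric ratio (`mode = "ratio"`).  Stronger NMD should give *smaller*
#' metric values, so effectors that drive the pathway are expected to
#' correlate negatively.
#'
#' @param values Long metric data.frame for one metric.
#' @param effector_expr Numeric matrix, effector genes x samples.
#' @param samples Sample metadata.
#' @param mode `"per_sample"` (default) or `"ratio"`.
#' @return Data.frame: `effector`, `metric`, `mode`, `rho`, `p_value`, `n`.
#'   Effectors with degenerate expression yield `NA` correlations.
#' @export
effector_correlations <- function(values, effector_expr, samples,
                                  mode = c("per_sample", "ratio")) {
  mode <- match.arg(mode)
  metric <- if (nrow(values)) values$metric[1L] else NA_character_
  if (mode == "per_sample") {
    med <- tapply(values$value, values$sample_id, median)
    ids <- intersect(colnames(effector_expr), names(med))
    yy <- med[ids]
    xx <- effector_expr[, ids, drop = FALSE]
  } else {
    pr <- patient_ratios(values, samples)$summary
    tum <- samples$sample_id[match(paste0(pr$patient_id, "tumor"),
                                   paste0(samples$patient_id, samples$tissue))]
    nor <- samples$sample_id[match(paste0(pr$patient_id, "normal"),
                                   paste0(samples$patient_id, samples$tissue))]
    yy <- pr$median_ratio
    xx <- effector_expr[, tum, drop = FALSE] / effector_expr[, nor, drop = FALSE]
  }
  rows <- lapply(rownames(effector_expr), function(e) {
    ct <- spearman_cor(as.numeric(xx[e, ]), as.numeric(yy))
    data.frame(effector = e, metric = metric, mode = mode,
               rho = ct$rho, p_value = ct$p_value, n = ct$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The canonical NMD effector panel
#'
#' The nine core factors whose expression is correlated against the
#' metrics: UPF1, UPF2, UPF3A, UPF3B, SMG1, SMG5, SMG6, SMG7, PNRC2.
#'
#' @return Character vector of gene symbols.
#' @export
nmd_effectors <- function() {
  c("UPF1", "UPF2", "UPF3A", "UPF3B", "SMG1", "SMG5", "SMG6", "SMG7", "PNRC2")
}
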