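# Cohort assessment: the package's central interface.  Takes the prepared
# inputs of whichever metrics are available, applies the preprocessing and
# per-patient filters, and returns a classed result with per-patient
# comparisons, cross-metric correlations and full exclusion accounting.

#' Assess NMD activity across a paired cohort
#'
#' Computes every metric whose inputs are supplied, then per-patient paired
#' Wilcoxon comparisons with BH correction across the cohort
#' ([compare_patients()]), Spearman correlations between the metrics'
#' per-patient median ratios, and (when effector expression is given)
#' effector correlations.
#'
#' * **R_mRNA** needs `expression` (+ optionally `raw_counts` for the
#'   low-expression filter) and `target_set`.  Expression is
#'   upper-quartile-normalized before use.
#' * **R_isoform** needs `event_counts` and `events`; the per-patient depth
#'   filter ([filter_events_by_depth()]) is applied first.  With
#'   `shared_events_only = TRUE` only events informative in every patient
#'   are used.
#' * **R_allele** needs `allele_counts`; the per-patient site filter
#'   ([filter_allele_sites()]) is applied first.
#'
#' @param samples Sample metadata (`sample_id`, `patient_id`, `tissue`);
#'   every patient must have exactly one tumor and one normal sample.
#' @param expression FPKM matrix (genes x samples), or `NULL`.
#' @param raw_counts Raw read-count matrix matching `expression`, or
#'   `NULL` to skip the low-expression filter.
#' @param target_set A `target_gene_set` ([select_target_set()]), or `NULL`.
#' @param event_counts,events Event junction counts and the classified
#'   event table, or `NULL`.
#' @param allele_counts Allele counts (`site_id`, `sample_id`, `n_nmd`,
#'   `n_nonnmd`), or `NULL`.
#' @param effector_expr Effector expression matrix (genes x samples), or
#'   `NULL`.
#' @param alpha Significance level for direction calls.
#' @param min_event_reads,min_allele_depth,allele_scope Filter settings.
#' @param min_low_reads Low-expression filter cutoff.
#' @param shared_events_only Restrict R_isoform to events informative in
#'   all patients.
#' @param pseudocount Pseudocount for [r_allele()].
#' @param zero_method Zero-difference handling for [paired_wilcoxon()].
#' @param effector_mode Correlation mode for [effector_correlations()].
#' @return Object of class `nmd_assessment`: list with `metrics` (long
#'   value data.frames), `comparisons` (`nmd_comparison` per metric),
#'   `ratios` (`patient_ratios` per metric), `cross_metric` (pairwise
#'   Spearman of median ratios), `effectors`, `exclusions` (named
#'   counters), `samples`, and the parameters used.
#' @export
nmd_assess <- function(samples,
                       expression = NULL, raw_counts = NULL, target_set = NULL,
                       event_counts = NULL, events = NULL,
                       allele_counts = NULL, effector_expr = NULL,
                       alpha = 0.05, min_event_reads = 10L,
                       min_allele_depth = 5L,
                       allele_scope = c("per_tissue", "pooled"),
                       min_low_reads = 10L, shared_events_only = FALSE,
                       pseudocount = 0,
                       zero_method = c("wilcox", "pratt"),
                       effector_mode = c("per_sample", "ratio")) {
  allele_scope <- match.arg(allele_scope)
  zero_method <- match.arg(zero_method)
  effector_mode <- match.arg(effector_mode)
  .check_samples(samples)

  metrics <- list(); comparisons <- list(); ratios <- list()
  excl <- list()

  if (!is.null(expression) && !is.null(target_set)) {
    expr <- as.matrix(expression)
    if (!is.null(raw_counts)) {
      keep <- filter_low_expressed(as.matrix(raw_counts), min_low_reads)
      excl$genes_low_expressed <- nrow(expr) - length(intersect(keep, rownames(expr)))
      expr <- expr[intersect(keep, rownames(expr)), , drop = FALSE]
    }
    expr <- normalize_q75(expr)
    metrics$R_mRNA <- r_mrna(expr, names(target_set$targets),
                             target_set$nontargets)
  }

  if (!is.null(event_counts) && !is.null(events)) {
    n_in <- nrow(event_counts)
    kept <- filter_events_by_depth(event_counts, samples, min_event_reads)
    excl$event_rows_depth_filtered <- n_in - nrow(kept)
    if (shared_events_only && nrow(kept)) {
      per_patient <- tapply(
        samples$patient_id[match(kept$sample_id, samples$sample_id)],
        kept$event_id, function(p) length(unique(p)))
      shared <- names(per_patient)[per_patient == length(unique(samples$patient_id))]
      excl$events_not_shared <- length(unique(kept$event_id)) - length(shared)
      kept <- kept[kept$event_id %in% shared, , drop = FALSE]
    }
    metrics$R_isoform <- r_isoform(kept, events)
    excl$event_rows_zero_total <- attr(metrics$R_isoform, "n_excluded")
  }

  if (!is.null(allele_counts)) {
    n_in <- nrow(allele_counts)
    kept <- filter_allele_sites(allele_counts, samples, min_allele_depth,
                                allele_scope)
    excl$allele_rows_site_filtered <- n_in - nrow(kept)
    metrics$R_allele <- r_allele(kept, pseudocount)
    excl$allele_rows_zero_nonnmd <- attr(metrics$R_allele, "n_excluded")
  }

  if (!length(metrics)) stop("no metric has sufficient inputs")

  for (m in names(metrics)) {
    comparisons[[m]] <- compare_patients(metrics[[m]], samples, alpha = alpha,
                                         zero_method = zero_method)
    ratios[[m]] <- patient_ratios(metrics[[m]], samples)
    excl[[paste0(m, "_zero_normal_ratio")]] <-
      sum(ratios[[m]]$summary$n_excluded_zero_normal)
  }

  cross <- NULL
  if (length(comparisons) > 1L) {
    combs <- utils::combn(names(comparisons), 2L)
    cross <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
      a <- comparisons[[combs[1L, i]]]; b <- comparisons[[combs[2L, i]]]
      shared <- intersect(a$patient_id, b$patient_id)
      ct <- spearman_cor(a$median_ratio[match(shared, a$patient_id)],
                         b$median_ratio[match(shared, b$patient_id)])
      data.frame(metric_a = combs[1L, i], metric_b = combs[2L, i],
                 rho = ct$rho, p_value = ct$p_value, n = ct$n,
                 stringsAsFactors = FALSE)
    }))
  }

  eff <- NULL
  if (!is.null(effector_expr)) {
    eff <- do.call(rbind, lapply(names(metrics), function(m)
      effector_correlations(metrics[[m]], as.matrix(effector_expr), samples,
                            mode = effector_mode)))
  }

  structure(list(metrics = metrics, comparisons = comparisons,
                 ratios = ratios, cross_metric = cross, effectors = eff,
                 exclusions = excl, samples = samples,
                 params = list(alpha = alpha,
                               min_event_reads = min_event_reads,
                               min_allele_depth = min_allele_depth,
                               allele_scope = allele_scope,
                               min_low_reads = min_low_reads,
                               shared_events_only = shared_events_only,
                               pseudocount = pseudocount,
                               zero_method = zero_method,
                               effector_mode = effector_mode)),
            class = "nmd_assessment")
}

.check_samples <- function(samples) {
  stopifnot(all(c("sample_id", "patient_id", "tissue") %in% names(samples)))
  tab <- table(samples$patient_id, samples$tissue)
  if (!all(tab[, "tumor"] == 1L) || !all(tab[, "normal"] == 1L)) {
    stop("every patient needs exactly one tumor and one normal sample")
  }
  invisible(TRUE)
}

#' @export
print.nmd_assessment <- function(x, ...) {
  cat("NMD activity assessment:", length(unique(x$samples$patient_id)),
      "patients,", paste(names(x$metrics), collapse = ", "), "\n")
  for (m in names(x$comparisons)) {
    cc <- x$comparisons[[m]]
    cat(sprintf("  %-10s %3d lower / %3d higher / %3d ns (alpha = %g)\n",
                m, sum(cc$direction == "lower"),
                sum(cc$direction == "higher"), sum(cc$direction == "ns"),
                x$params$alpha))
  }
  invisible(x)
}

#' @method summary nmd_assessment
#' @export
summary.nmd_assessment <- function(object, ...) {
  print(object)
  if (!is.null(object$cross_metric)) {
    cat("Cross-metric Spearman correlations (per-patient median ratios):\n")
    print.data.frame(object$cross_metric, digits = 3, row.names = FALSE)
  }
  if (!is.null(object$effectors)) {
    cat("Effector correlations:\n")
    print.data.frame(object$effectors, digits = 3, row.names = FALSE)
  }
  cat("Exclusion counters:\n")
  for (n in names(object$exclusions)) {
    cat("  ", n, "=", object$exclusions[[n]], "\n")
  }
  invisible(object)
}

#' Plot per-patient tumor/normal median ratios
#'
#' One panel per metric: patients ordered by median ratio (log scale),
#' colored by direction call (blue = significantly lower in tumor, red =
#' higher, grey = not significant).
#'
#' @param x An `nmd_assessment`.
#' @param ... Unused.
#' @method plot nmd_assessment
#' @export
plot.nmd_assessment <- function(x, ...) {
  old <- graphics::par(mfrow = c(length(x$comparisons), 1L),
                       mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in names(x$comparisons)) {
    cc <- x$comparisons[[m]]
    ord <- order(cc$median_ratio)
    col <- c(lower = "dodgerblue3", higher = "firebrick3",
             ns = "grey60")[cc$direction[ord]]
    graphics::plot(seq_len(nrow(cc)), cc$median_ratio[ord], log = "y",
                   pch = 19, col = col, xlab = "", ylab = "tumor/normal ratio",
                   main = m)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}
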