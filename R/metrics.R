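# The three NMD activity metrics and their expression preprocessing.
#
# All three metrics shrink when NMD is stronger: R_mRNA is target-gene
# expression over the median non-target expression of the same sample;
# R_isoform is the NMD-inducing splice form's share of an event's junction
# reads; R_allele is the PTC allele's read count over the PTC-free
# allele's.  Sample metadata is a data.frame with columns `sample_id`,
# `patient_id`, `tissue` ("tumor"/"normal"), one tumor and one normal
# sample per patient.

#' Drop extremely low expressed genes
#'
#' A gene is removed when it has fewer than `min_reads` raw reads in half
#' or more of the samples.
#'
#' @param raw_counts Integer matrix, genes x samples.
#' @param min_reads Read cutoff (default 10).
#' @return Character vector of kept gene names.
#' @export
filter_low_expressed <- function(raw_counts, min_reads = 10L) {
  n_low <- rowSums(raw_counts < min_reads)
  rownames(raw_counts)[n_low < ceiling(ncol(raw_counts) / 2)]
}

#' Upper-quartile normalization of an expression matrix
#'
#' Divides each sample (column) by its own 75th percentile (linear
#' interpolation quantile over the kept genes), so every normalized
#' sample has an upper quartile of exactly 1.
#'
#' @param fpkm Numeric matrix, genes x samples (FPKM).
#' @return Normalized matrix of the same shape.
#' @export
normalize_q75 <- function(fpkm) {
  q <- apply(fpkm, 2L, quantile, probs = 0.75, names = FALSE, type = 7)
  if (any(q <= 0)) {
    stop("75th percentile is zero in sample(s): ",
         paste(colnames(fpkm)[q <= 0], collapse = ", "))
  }
  sweep(fpkm, 2L, q, "/")
}

#' R_mRNA: normalized NMD-target expression
#'
#' For each target gene and sample, `R_mRNA = mE_NMD / median(mE_nonNMD)`:
#' the gene's expression divided by the median expression of all non-target
#' genes in the same sample.
#'
#' @param expr Numeric matrix, genes x samples (normalized FPKM).
#' @param targets Character vector of NMD target gene ids (must be rows of
#'   `expr`).
#' @param nontargets Character vector of non-target gene ids used as the
#'   per-sample normalizer; must be non-empty in `expr`.
#' @return Long data.frame: `metric` (`"R_mRNA"`), `feature_id` (gene),
#'   `sample_id`, `value`.
#' @export
r_mrna <- function(expr, targets, nontargets) {
  targets <- intersect(targets, rownames(expr))
  nontargets <- intersect(nontargets, rownames(expr))
  if (!length(nontargets)) stop("no non-target genes present in the expression matrix")
  med <- apply(expr[nontargets, , drop = FALSE], 2L, median)
  if (any(med <= 0)) {
    stop("median non-target expression is zero in sample(s): ",
         paste(colnames(expr)[med <= 0], collapse = ", "))
  }
  vals <- sweep(expr[targets, , drop = FALSE], 2L, med, "/")
  data.frame(metric = "R_mRNA",
             feature_id = rep(targets, times = ncol(expr)),
             sample_id = rep(colnames(expr), each = length(targets)),
             value = as.vector(vals),
             stringsAsFactors = FALSE)
}

#' R_isoform: NMD-inducing splice-form usage
#'
#' `R_isoform = sE_NMD / (sE_NMD + sE_nonNMD)` per event and sample, where
#' `sE_NMD` is the junction-read count of whichever splice form (inclusion
#' or exclusion) triggers NMD for that event.  Always in `[0, 1]`.
#' Event/sample pairs with zero total reads are excluded (counted in
#' `attr(, "n_excluded")`); the depth filter
#' ([filter_events_by_depth()]) is applied separately, per patient.
#'
#' @param event_counts Data.frame with `event_id`, `sample_id`,
#'   `n_inclusion`, `n_exclusion` (from [count_events()] or the simulator).
#' @param events Event table carrying `event_id` and `nmd_form`.
#' @return Long data.frame: `metric` (`"R_isoform"`), `feature_id` (event),
#'   `sample_id`, `value`.
#' @export
r_isoform <- function(event_counts, events) {
  form <- events$nmd_form[match(event_counts$event_id, events$event_id)]
  if (anyNA(form)) stop("event_counts contains events absent from the event table")
  s_nmd <- ifelse(form == "inclusion", event_counts$n_inclusion,
                  event_counts$n_exclusion)
  total <- event_counts$n_inclusion + event_counts$n_exclusion
  keep <- total > 0L
  out <- data.frame(metric = rep("R_isoform", sum(keep)),
                    feature_id = event_counts$event_id[keep],
                    sample_id = event_counts$sample_id[keep],
                    value = s_nmd[keep] / total[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' R_allele: PTC-allele expression ratio
#'
#' `R_allele = aE_NMD / aE_nonNMD` per heterozygous PTC site and sample.
#' Sites with zero PTC-free-allele reads in a sample are excluded (no
#' pseudocount by default) and counted in `attr(, "n_excluded")`; set
#' `pseudocount` to retain them.
#'
#' @param allele_counts Data.frame with `site_id`, `sample_id`, `n_nmd`,
#'   `n_nonnmd`.
#' @param pseudocount Added to both counts before the ratio (default 0 =
#'   exclusion policy).
#' @return Long data.frame: `metric` (`"R_allele"`), `feature_id` (site),
#'   `sample_id`, `value`.
#' @export
r_allele <- function(allele_counts, pseudocount = 0) {
  nmd <- allele_counts$n_nmd + pseudocount
  non <- allele_counts$n_nonnmd + pseudocount
  keep <- non > 0
  out <- data.frame(metric = rep("R_allele", sum(keep)),
                    feature_id = allele_counts$site_id[keep],
                    sample_id = allele_counts$sample_id[keep],
                    value = nmd[keep] / non[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Apply the per-patient event depth filter to a counts table
#'
#' Keeps, for each patient, the events with more than `min_reads`
#' supporting reads in both the tumor and the normal sample
#' ([event_depth_pass()]).  The informative event set therefore differs
#' between patients.
#'
#' @param event_counts Data.frame with `event_id`, `sample_id`,
#'   `n_inclusion`, `n_exclusion`.
#' @param samples Sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @param min_reads Depth cutoff (default 10).
#' @return Subset of `event_counts` restricted, per patient, to passing
#'   events.
#' @export
filter_events_by_depth <- function(event_counts, samples, min_reads = 10L) {
  total <- event_counts$n_inclusion + event_counts$n_exclusion
  m <- match(event_counts$sample_id, samples$sample_id)
  patient <- samples$patient_id[m]
  tissue <- samples$tissue[m]
  keep_key <- character(0)
  for (p in unique(patient)) {
    t_rows <- patient == p & tissue == "tumor"
    n_rows <- patient == p & tissue == "normal"
    t_ok <- event_counts$event_id[t_rows][total[t_rows] > min_reads]
    n_ok <- event_counts$event_id[n_rows][total[n_rows] > min_reads]
    keep_key <- c(keep_key, paste0(p, ":", intersect(t_ok, n_ok)))
  }
  event_counts[paste0(patient, ":", event_counts$event_id) %in% keep_key, ,
               drop = FALSE]
}

#' Apply the per-patient allele-site filter to a counts table
#'
#' Keeps, per patient, sites passing [allele_site_pass()] in both tissues.
#'
#' @param allele_counts Data.frame with `site_id`, `sample_id`, `n_nmd`,
#'   `n_nonnmd`.
#' @param samples Sample metadata.
#' @param min_depth,scope Passed to [allele_site_pass()].
#' @return Filtered subset of `allele_counts`.
#' @export
filter_allele_sites <- function(allele_counts, samples, min_depth = 5L,
                                scope = c("per_tissue", "pooled")) {
  scope <- match.arg(scope)
  m <- match(allele_counts$sample_id, samples$sample_id)
  patient <- samples$patient_id[m]
  tissue <- samples$tissue[m]
  keep_key <- character(0)
  for (p in unique(patient)) {
    tr <- allele_counts[patient == p & tissue == "tumor", , drop = FALSE]
    nr <- allele_counts[patient == p & tissue == "normal", , drop = FALSE]
    shared <- intersect(tr$site_id, nr$site_id)
    for (s in shared) {
      if (allele_site_pass(tr[tr$site_id == s, ][1, ],
                           nr[nr$site_id == s, ][1, ],
                           min_depth = min_depth, scope = scope)) {
        keep_key <- c(keep_key, paste0(p, ":", s))
      }
    }
  }
  allele_counts[paste0(patient, ":", allele_counts$site_id) %in% keep_key, ,
                drop = FALSE]
}

#' Per-patient tumor/normal metric ratios
#'
#' For each patient and each feature measured in both tissues, computes
#' `value(tumor) / value(normal)`; features with a zero normal value are
#' excluded and counted.  The patient-level point estimate is the median
#' per-feature ratio.
#'
#' @param values Long metric data.frame (`feature_id`, `sample_id`,
#'   `value`) for one metric.
#' @param samples Sample metadata (`sample_id`, `patient_id`, `tissue`).
#' @return A list of class `patient_ratios`: `pairs` (data.frame
#'   `patient_id`, `feature_id`, `tumor`, `normal`, `ratio`; excluded
#'   features carry `NA` ratio) and `summary` (data.frame `patient_id`,
#'   `n_features`, `n_excluded_zero_normal`, `median_ratio`).
#' @export
patient_ratios <- function(values, samples) {
  m <- match(values$sample_id, samples$sample_id)
  if (anyNA(m)) stop("values contain samples absent from the metadata")
  values$patient_id <- samples$patient_id[m]
  values$tissue <- samples$tissue[m]
  pairs <- list(); summ <- list()
  for (p in unique(samples$patient_id)) {
    tv <- values[values$patient_id == p & values$tissue == "tumor", ]
    nv <- values[values$patient_id == p & values$tissue == "normal", ]
    shared <- intersect(tv$feature_id, nv$feature_id)
    tt <- tv$value[match(shared, tv$feature_id)]
    nn <- nv$value[match(shared, nv$feature_id)]
    ratio <- ifelse(nn > 0, tt / nn, NA_real_)
    pairs[[p]] <- data.frame(patient_id = p, feature_id = shared,
                             tumor = tt, normal = nn, ratio = ratio,
                             stringsAsFactors = FALSE)
    summ[[p]] <- data.frame(
      patient_id = p, n_features = length(shared),
      n_excluded_zero_normal = sum(is.na(ratio)),
      median_ratio = if (any(!is.na(ratio))) median(ratio, na.rm = TRUE)
                     else NA_real_,
      stringsAsFactors = FALSE)
  }
  structure(list(pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
                 summary = do.call(rbind, c(summ, make.row.names = FALSE))),
            class = "patient_ratios")
}

#' @export
print.patient_ratios <- function(x, ...) {
  cat("patient_ratios:", nrow(x$summary), "patient(s); median of median ratios =",
      signif(median(x$summary$median_ratio, na.rm = TRUE), 4), "\n")
  invisible(x)
}
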