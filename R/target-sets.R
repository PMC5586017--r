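# NMD target / non-target gene classification from NMD-inhibition
# fold-change evidence.
#
# Evidence comes from four kinds of studies of UPF1 knockdown: two
# expression arrays (A1, A2; gene-level fold changes), one mRNA-stability
# study (B; a boolean "stabilized" call), and one isoform-resolution RNA-seq
# study (C; per-isoform fold change and post-knockdown FPKM).  Fold changes
# are knockdown/control ratios, so values > 1 mean upregulation when NMD is
# inhibited.

#' Read an NMD-inhibition evidence table
#'
#' Expected TSV columns: `gene_id`, `a1_fold`, `a2_fold` (gene fold changes
#' in the two array studies; `NA` = no probe), `b_stabilized`,
#' `b_meets_standards` (logicals for the stability study), and
#' `c_isoform_folds` (semicolon-separated `fold:fpkm` pairs for the isoform
#' study; empty = not expressed there).
#'
#' @param path TSV path.
#' @return Data.frame with the columns above; `c_isoform_folds` parsed into
#'   a list column `c_isoforms` of two-column matrices (`fold`, `fpkm`).
#'   Non-positive fold changes are rejected.
#' @export
read_evidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(gene_id = "character",
                                  c_isoform_folds = "character"))
  ev$b_stabilized <- as.logical(ev$b_stabilized)
  ev$b_meets_standards <- as.logical(ev$b_meets_standards)
  if (any(c(ev$a1_fold, ev$a2_fold) <= 0, na.rm = TRUE)) {
    stop("fold changes must be positive (knockdown/control ratios)")
  }
  ev$c_isoforms <- lapply(ev$c_isoform_folds, .parse_isoforms)
  ev
}

.parse_isoforms <- function(s) {
  if (is.na(s) || !nzchar(s)) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("fold", "fpkm"))))
  }
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":", fixed = TRUE)
  m <- do.call(rbind, lapply(parts, as.numeric))
  colnames(m) <- c("fold", "fpkm")
  if (any(m[, "fold"] <= 0)) stop("fold changes must be positive: ", s)
  m
}

#' Is a gene eligible for the classification background?
#'
#' Genes absent or unexpressed in any of the four studies are excluded
#' before classification, to avoid background bias: eligibility requires a
#' probe in both array studies, meeting the stability study's standards,
#' and at least one isoform with >= 1 FPKM after UPF1 knockdown in the
#' isoform study.
#'
#' @param evidence One row of [read_evidence()] output (data.frame row or
#'   list with the same fields).
#' @return Logical.
#' @export
background_eligible <- function(evidence) {
  iso <- if (!is.null(evidence$c_isoforms)) evidence$c_isoforms[[1L]]
         else .parse_isoforms(evidence$c_isoform_folds)
  !is.na(evidence$a1_fold) && !is.na(evidence$a2_fold) &&
    isTRUE(evidence$b_meets_standards) &&
    nrow(iso) > 0L && any(iso[, "fpkm"] >= 1)
}

#' Classify genes as NMD targets, non-targets, or unclassified
#'
#' Applied to background-eligible genes only (others are marked
#' `excluded`).  A gene is a *target* when at least one study supports it:
#' >= 2-fold upregulation in array A1 or A2, stabilized in study B, or at
#' least one isoform >= 3-fold upregulated and expressed >= 5 FPKM in study
#' C; `support` counts the supporting studies (1-4).  A gene is a
#' *non-target* only when every study argues against targeting: < 1.5-fold
#' in both arrays, not stabilized, and every C isoform < 2-fold.  Genes
#' meeting neither rule are `unclassified` and enter neither set.
#'
#' @param evidence Data.frame from [read_evidence()].
#' @return Data.frame: `gene_id`, `class` in
#'   `{"target","nontarget","unclassified","excluded"}`, `support`
#'   (0 for non-targets).
#' @export
classify_genes <- function(evidence) {
  n <- nrow(evidence)
  class <- character(n); support <- integer(n)
  for (i in seq_len(n)) {
    row <- evidence[i, ]
    if (!background_eligible(row)) {
      class[i] <- "excluded"; next
    }
    iso <- row$c_isoforms[[1L]]
    crit <- c(row$a1_fold >= 2,
              row$a2_fold >= 2,
              isTRUE(row$b_stabilized),
              any(iso[, "fold"] >= 3 & iso[, "fpkm"] >= 5))
    k <- sum(crit)
    if (k >= 1L) {
      class[i] <- "target"; support[i] <- k
    } else if (row$a1_fold < 1.5 && row$a2_fold < 1.5 &&
               !isTRUE(row$b_stabilized) && all(iso[, "fold"] < 2)) {
      class[i] <- "nontarget"
    } else {
      class[i] <- "unclassified"
    }
  }
  data.frame(gene_id = evidence$gene_id, class = class, support = support,
             stringsAsFactors = FALSE)
}

#' Select the working NMD target set
#'
#' Keeps targets supported by at least `min_support` studies (the
#' high-confidence set used by R_mRNA) and passes non-targets through as
#' the normalization background.
#'
#' @param classified Output of [classify_genes()].
#' @param min_support Minimum supporting studies for a target (default 3).
#' @return A list of class `target_gene_set`: `targets` (named integer
#'   vector of support counts), `nontargets` (character vector).  The two
#'   sets are guaranteed disjoint.
#' @export
select_target_set <- function(classified, min_support = 3L) {
  t_rows <- classified$class == "target" & classified$support >= min_support
  targets <- setNames(classified$support[t_rows], classified$gene_id[t_rows])
  nontargets <- classified$gene_id[classified$class == "nontarget"]
  stopifnot(!any(names(targets) %in% nontargets))
  structure(list(targets = targets, nontargets = nontargets),
            class = "target_gene_set")
}

#' @export
print.target_gene_set <- function(x, ...) {
  cat("target_gene_set:", length(x$targets), "target(s),",
      length(x$nontargets), "non-target(s)\n")
  invisible(x)
}
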