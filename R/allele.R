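# Heterozygous PTC-site extraction from effect-annotated VCFs, and the
# per-site depth/allele filters applied before R_allele.

#' Extract heterozygous PTC sites from an annotated VCF
#'
#' Reads a VCF for one patient (tumor and normal genotype columns) whose
#' INFO field carries SnpEff-style effect annotations (`ANN=` or `EFF=`),
#' and returns single-nucleotide variants that are heterozygous in both
#' samples and annotated as PTC-introducing (`stop_gained`).  The
#' PTC-introducing allele is recorded as `nmd_allele` (the alternate allele
#' for a stop-gained SNV).  Indels are skipped; multiallelic records are
#' evaluated per alternate allele.
#'
#' @param vcf_file Path to a VCF with genotypes for exactly the two samples
#'   of one patient.
#' @param effect_regex Regular expression marking a PTC-introducing effect
#'   (default `"stop_gained"`).
#' @return Data.frame of class site table: `site_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `nmd_allele` (`"alt"`), `gene_id`.
#' @export
extract_ptc_sites <- function(vcf_file, effect_regex = "stop_gained") {
  vcf <- VariantAnnotation::readVcf(vcf_file)
  rr <- SummarizedExperiment::rowRanges(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF must contain genotypes for the tumor and normal sample")
  }
  info <- VariantAnnotation::info(vcf)
  eff_field <- intersect(c("ANN", "EFF"), names(info))
  if (!length(eff_field)) stop("VCF INFO has neither ANN nor EFF annotations")
  eff_field <- eff_field[1L]

  out <- list()
  for (i in seq_len(nrow(vcf))) {
    ref <- as.character(rr$REF[i])
    alts <- as.character(rr$ALT[[i]])
    anns <- unlist(info[[eff_field]][i])
    for (ai in seq_along(alts)) {
      alt <- alts[ai]
      if (nchar(ref) != 1L || nchar(alt) != 1L) next          # SNVs only
      # heterozygous ref/alt in both samples
      het <- vapply(gt[i, 1:2], function(g) {
        a <- strsplit(g, "[/|]")[[1L]]
        length(a) == 2L && setequal(a, c("0", as.character(ai)))
      }, TRUE)
      if (!all(het)) next
      hit <- anns[grepl(effect_regex, anns)]
      if (eff_field == "ANN") {
        # ANN entries: Allele|Annotation|Impact|Gene_Name|Gene_ID|...
        hit <- hit[vapply(hit, function(a)
          identical(strsplit(a, "|", fixed = TRUE)[[1L]][1L], alt), TRUE)]
        gene <- if (length(hit))
          strsplit(hit[1L], "|", fixed = TRUE)[[1L]][4L] else NA_character_
      } else {
        # EFF entries: Effect(Impact|Class|Codon|AA|Len|Gene_Name|...)
        gene <- if (length(hit)) {
          fields <- strsplit(sub("^[^(]*\\(", "", sub("\\)$", "", hit[1L])),
                             "|", fixed = TRUE)[[1L]]
          fields[6L]
        } else NA_character_
      }
      if (!length(hit)) next
      chrom <- as.character(GenomicRanges::seqnames(rr))[i]
      pos <- GenomicRanges::start(rr)[i]
      out[[length(out) + 1L]] <- data.frame(
        site_id = paste0(chrom, ":", pos, ":", ref, ">", alt),
        chrom = chrom, pos = pos, ref = ref, alt = alt,
        nmd_allele = "alt", gene_id = gene, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(site_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), nmd_allele = character(0),
                      gene_id = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Allele-count filter for one PTC site in one patient
#'
#' A site enters R_allele for a patient only when it is covered by at least
#' `min_depth` reads in both tissues and both alleles are seen in mapped
#' reads.  The both-alleles requirement is evaluated per tissue by default
#' (the stricter reading); `scope = "pooled"` requires each allele to be
#' seen only somewhere across the two tissues.
#'
#' @param tumor,normal Named vectors or one-row data.frames with
#'   `n_nmd` and `n_nonnmd` read counts for the same site.
#' @param min_depth Minimum total reads per tissue (default 5).
#' @param scope `"per_tissue"` (default) or `"pooled"` for the
#'   both-alleles-seen requirement.
#' @return Logical.
#' @export
allele_site_pass <- function(tumor, normal, min_depth = 5L,
                             scope = c("per_tissue", "pooled")) {
  scope <- match.arg(scope)
  t_nmd <- tumor[["n_nmd"]]; t_non <- tumor[["n_nonnmd"]]
  n_nmd <- normal[["n_nmd"]]; n_non <- normal[["n_nonnmd"]]
  if (t_nmd + t_non < min_depth || n_nmd + n_non < min_depth) return(FALSE)
  if (scope == "per_tissue") {
    t_nmd >= 1L && t_non >= 1L && n_nmd >= 1L && n_non >= 1L
  } else {
    (t_nmd + n_nmd) >= 1L && (t_non + n_non) >= 1L
  }
}
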