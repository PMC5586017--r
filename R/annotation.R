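# Gene-model loading: GTF + genome FASTA -> per-gene transcript structures
# with spliced mRNA sequences and CDS starts in mRNA coordinates.
#
# Internal convention: genomic coordinates are 1-based inclusive (the
# GTF/Bioconductor convention); mRNA coordinates are 1-based and always run
# 5'->3' (minus-strand sequences are reverse-complemented at load time).

#' Load gene models from a GTF and a genome FASTA
#'
#' Parses exon, CDS and start_codon features (Ensembl-style `gene_id` /
#' `transcript_id` attributes), groups them into transcripts and genes,
#' splices out each transcript's mRNA sequence, and converts the annotated
#' CDS start into mRNA coordinates.  Transcripts without any CDS annotation
#' are retained but flagged CDS-less (`cds_start = NA`); they are never
#' scanned for PTCs, since the package does not infer open reading frames.
#'
#' @param gtf_file Path to a GTF file with `exon` (and optionally `CDS`,
#'   `start_codon`) features.
#' @param fasta_file Path to a genome FASTA containing every chromosome the
#'   GTF references.  A missing chromosome is a hard error.
#' @return An object of class `gene_models`: a named list of genes, each a
#'   list with `gene_id`, `chrom`, `strand` and `transcripts`; each
#'   transcript holds `transcript_id`, `exons` (data.frame of genomic
#'   `start`/`end` in transcription order), `mrna` (spliced 5'->3' sequence),
#'   `cds_start` (1-based mRNA position or `NA`), and `cds_len`.
#' @export
load_gene_models <- function(gtf_file, fasta_file) {
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  genome <- Biostrings::readDNAStringSet(fasta_file)
  names(genome) <- sub("\\s.*$", "", names(genome))

  feats <- as.data.frame(gr)[, c("seqnames", "start", "end", "strand",
                                 "type", "gene_id", "transcript_id")]
  feats$seqnames <- as.character(feats$seqnames)
  feats$strand <- as.character(feats$strand)
  feats$type <- as.character(feats$type)
  feats <- feats[feats$type %in% c("exon", "CDS", "start_codon"), ]
  if (!nrow(feats)) stop("GTF contains no exon features")

  missing_chrom <- setdiff(unique(feats$seqnames), names(genome))
  if (length(missing_chrom)) {
    stop("chromosome(s) absent from FASTA: ", paste(missing_chrom, collapse = ", "))
  }

  models <- list()
  for (gid in unique(feats$gene_id)) {
    gf <- feats[feats$gene_id == gid, ]
    chrom <- gf$seqnames[1L]
    strand <- gf$strand[1L]
    if (!all(gf$seqnames == chrom) || !all(gf$strand == strand)) {
      stop("gene ", gid, " mixes chromosomes or strands")
    }
    transcripts <- list()
    for (tid in unique(gf$transcript_id)) {
      tf <- gf[gf$transcript_id == tid, ]
      ex <- tf[tf$type == "exon", c("start", "end")]
      if (!nrow(ex)) next
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        stop("overlapping exons in transcript ", tid)
      }
      if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
      rownames(ex) <- NULL
      mrna <- .splice_seq(genome[[chrom]], ex, strand)
      cds_rows <- tf[tf$type %in% c("CDS", "start_codon"), ]
      cds_start <- NA_integer_
      cds_len <- 0L
      if (nrow(cds_rows)) {
        cds_only <- cds_rows[cds_rows$type == "CDS", ]
        if (nrow(cds_only)) cds_len <- as.integer(sum(cds_only$end - cds_only$start + 1L))
        sc <- cds_rows[cds_rows$type == "start_codon", ]
        anchor <- if (nrow(sc)) sc else cds_rows
        gpos <- if (strand == "+") min(anchor$start) else max(anchor$end)
        cds_start <- genomic_to_mrna(ex, strand, gpos)
        if (is.na(cds_start)) stop("CDS start of ", tid, " falls outside its exons")
      }
      transcripts[[tid]] <- list(transcript_id = tid, exons = ex, mrna = mrna,
                                 cds_start = cds_start, cds_len = cds_len)
    }
    models[[gid]] <- structure(
      list(gene_id = gid, chrom = chrom, strand = strand,
           transcripts = transcripts),
      class = "gene_model")
  }
  structure(models, class = "gene_models")
}

# Spliced 5'->3' mRNA from a chromosome sequence and exons in transcription
# order.
.splice_seq <- function(chrom_seq, exons, strand) {
  parts <- character(nrow(exons))
  for (i in seq_len(nrow(exons))) {
    s <- Biostrings::subseq(chrom_seq, exons$start[i], exons$end[i])
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    parts[i] <- as.character(s)
  }
  paste(parts, collapse = "")
}

#' Map a genomic position onto transcript (mRNA) coordinates
#'
#' @param exons data.frame with `start`/`end` in transcription order.
#' @param strand `"+"` or `"-"`.
#' @param gpos Genomic position (1-based).
#' @return 1-based mRNA coordinate, or `NA` if `gpos` is intronic/outside.
#' @keywords internal
genomic_to_mrna <- function(exons, strand, gpos) {
  offset <- 0L
  for (i in seq_len(nrow(exons))) {
    w <- exons$end[i] - exons$start[i] + 1L
    if (gpos >= exons$start[i] && gpos <= exons$end[i]) {
      within <- if (strand == "+") gpos - exons$start[i] + 1L
                else exons$end[i] - gpos + 1L
      return(offset + within)
    }
    offset <- offset + w
  }
  NA_integer_
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", length(x), "gene(s),",
      sum(vapply(x, function(g) length(g$transcripts), 1L)), "transcript(s)\n")
  invisible(x)
}
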