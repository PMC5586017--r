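# In-code fixtures: tiny annotations, VCFs and synthetic reads built at
# test time.

write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  path
}

gtf_row <- function(chrom, feat, s, e, strand, gid, tid) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          chrom, feat, s, e, strand, gid, tid)
}

# Mirror a single-chromosome annotation: reverse-complement the genome and
# flip all coordinates and strands.  Event discovery must be invariant.
mirror_annotation <- function(gtf_path, fasta_path, dir) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  L <- Biostrings::width(genome)[1]
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- names(genome)
  fa2 <- file.path(dir, "mirror.fa")
  Biostrings::writeXStringSet(rc, fa2)
  lines <- readLines(gtf_path)
  parts <- strsplit(lines, "\t")
  out <- vapply(parts, function(p) {
    s <- as.integer(p[4]); e <- as.integer(p[5])
    p[4] <- as.character(L - e + 1L)
    p[5] <- as.character(L - s + 1L)
    p[7] <- if (p[7] == "+") "-" else "+"
    paste(p, collapse = "\t")
  }, "")
  gtf2 <- file.path(dir, "mirror.gtf")
  writeLines(out, gtf2)
  list(gtf = gtf2, fasta = fa2, L = L)
}

# A synthetic aligned read in the parsed representation used by the
# junction filters.
make_read <- function(qname = "r1", chrom = "chrS", blocks, mapq = 50L,
                      dirty = integer(0)) {
  list(qname = qname, chrom = chrom, pos = blocks[1, 1], mapq = mapq,
       cigar = NA_character_, blocks = blocks, dirty = dirty)
}

# Minimal two-sample VCF with SnpEff-style annotations.
write_tiny_vcf <- function(path, dialect = c("ANN", "EFF")) {
  dialect <- match.arg(dialect)
  info_hdr <- if (dialect == "ANN") {
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">"
  } else {
    "##INFO=<ID=EFF,Number=.,Type=String,Description=\"Predicted effects\">"
  }
  mk_info <- function(alt, effect, gene) {
    if (dialect == "ANN") {
      sprintf("ANN=%s|%s|HIGH|%s|%s|transcript|t1|protein_coding|1/2|c.1A>T|p.K1*",
              alt, effect, gene, gene)
    } else {
      sprintf("EFF=%s(HIGH|NONSENSE|aaA/taA|K1*|100|%s|protein_coding|CODING|t1|1)",
              effect, gene)
    }
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=10000>",
    info_hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL",
    # het stop_gained in both samples -> kept
    paste("chr1", 100, ".", "C", "T", 50, "PASS",
          mk_info("T", "stop_gained", "GENE1"), "GT", "0/1", "0/1", sep = "\t"),
    # synonymous het -> excluded
    paste("chr1", 200, ".", "G", "A", 50, "PASS",
          mk_info("A", "synonymous_variant", "GENE2"), "GT", "0/1", "0/1", sep = "\t"),
    # hom-alt stop_gained -> excluded (no NMD-free allele)
    paste("chr1", 300, ".", "C", "A", 50, "PASS",
          mk_info("A", "stop_gained", "GENE3"), "GT", "1/1", "1/1", sep = "\t"),
    # stop_gained het in tumor only -> excluded
    paste("chr1", 400, ".", "T", "A", 50, "PASS",
          mk_info("A", "stop_gained", "GENE4"), "GT", "0/1", "0/0", sep = "\t"),
    # indel stop_gained -> skipped
    paste("chr1", 500, ".", "CT", "C", 50, "PASS",
          mk_info("C", "stop_gained", "GENE5"), "GT", "0/1", "0/1", sep = "\t"))
  writeLines(lines, path)
  path
}
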