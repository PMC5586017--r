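# Independent oracles: deliberately simple, loop-based re-implementations
# used only to check the package's vectorized code paths.

# Codon-by-codon translation oracle: position of the first in-frame stop.
oracle_first_stop <- function(seq, cds_start) {
  p <- as.integer(cds_start)
  n <- nchar(seq)
  while (p + 2L <= n) {
    codon <- substr(seq, p, p + 2L)
    if (codon == "TAA" || codon == "TAG" || codon == "TGA") return(p)
    p <- p + 3L
  }
  NA_integer_
}

# Translate-and-measure NMD oracle for a spliced transcript.
oracle_nmd <- function(seq, cds_start, exon_lengths, threshold = 50) {
  s <- oracle_first_stop(seq, cds_start)
  if (is.na(s)) return(NA)
  if (length(exon_lengths) < 2) return(FALSE)
  junction <- 0
  for (i in seq_len(length(exon_lengths) - 1)) junction <- junction + exon_lengths[i]
  (junction - (s + 2)) >= threshold
}

# Random mRNA over ACGT (optionally with N).
random_mrna <- function(len, with_n = FALSE) {
  alph <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(alph, len, replace = TRUE), collapse = "")
}

# Random partition of len into >= 2 exon lengths.
random_exon_lengths <- function(len, max_exons = 6) {
  k <- sample(2:max_exons, 1)
  cuts <- sort(sample(seq_len(len - 1), k - 1))
  diff(c(0, cuts, len))
}

# Build a gene_model by hand from exon coordinate lists (no sequences).
toy_gene <- function(transcript_exons, strand = "+", gene_id = "g1",
                     chrom = "chr1") {
  trs <- lapply(names(transcript_exons), function(tid) {
    ex <- transcript_exons[[tid]]
    ex <- ex[order(ex$start, decreasing = (strand == "-")), , drop = FALSE]
    rownames(ex) <- NULL
    list(transcript_id = tid, exons = ex, mrna = NULL,
         cds_start = NA_integer_, cds_len = 0L)
  })
  names(trs) <- names(transcript_exons)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 transcripts = trs), class = "gene_model")
}

# Exhaustive enumeration oracle for cassette-exon discovery: checks every
# exon triple of every transcript against the three rules directly.
oracle_find_events <- function(gene) {
  key <- function(e) paste(e[1], e[2], sep = "-")
  all_ex <- list()
  tr_keys <- list()
  for (tr in gene$transcripts) {
    ex <- tr$exons[order(tr$exons$start), , drop = FALSE]
    ks <- apply(ex, 1, function(r) key(c(r[["start"]], r[["end"]])))
    tr_keys[[tr$transcript_id]] <- ks
    for (i in seq_len(nrow(ex))) {
      all_ex[[length(all_ex) + 1]] <- c(ex$start[i], ex$end[i])
    }
  }
  found <- character(0)
  for (ka in tr_keys) {
    if (length(ka) < 3) next
    for (j in seq_len(length(ka) - 2)) {
      trip <- ka[j:(j + 2)]
      # rule b: some transcript has the two flanks adjacent
      skipped <- any(vapply(tr_keys, function(kb) {
        idx <- which(kb == trip[1])
        length(idx) > 0 && any(kb[pmin(idx + 1, length(kb))] == trip[3])
      }, TRUE))
      if (!skipped) next
      # rule c: flanks constitutive
      flank_ok <- TRUE
      for (f in trip[c(1, 3)]) {
        fe <- as.numeric(strsplit(f, "-")[[1]])
        for (e in all_ex) {
          if (e[1] <= fe[2] && e[2] >= fe[1] && !(e[1] == fe[1] && e[2] == fe[2])) {
            flank_ok <- FALSE
          }
        }
      }
      if (flank_ok) found <- c(found, paste(trip, collapse = ";"))
    }
  }
  sort(unique(found))
}

event_keys <- function(events) {
  sort(vapply(events, function(ev) {
    trio <- rbind(ev$upstream, ev$focal, ev$downstream)
    trio <- trio[order(trio[, 1]), , drop = FALSE]
    paste(paste(trio[, 1], trio[, 2], sep = "-"), collapse = ";")
  }, ""))
}

# Exact paired Wilcoxon oracle by enumeration of all sign patterns
# (zeros dropped beforehand; no ties in |d| assumed).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  tot <- n * (n + 1) / 2
  vals <- 0
  for (m in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(m))[1:n]
    vals <- c(vals, sum(r[signs == 1]))
  }
  vals <- vals[-1]
  p <- min(1, 2 * min(mean(vals <= V), mean(vals >= V)))
  p
}

# Normal-approximation signed-rank oracle with continuity and tie
# correction (matches the classical large-sample formula).
oracle_wilcoxon_approx <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * pnorm(-abs(z)))
}

# Hand-rolled BH step-up.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman oracle: Pearson product-moment formula on average ranks, t
# approximation for the p-value.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(tstat), n - 2))
}

# Manual type-7 (linear interpolation) quantile.
oracle_q75 <- function(x) {
  x <- sort(x)
  h <- (length(x) - 1) * 0.75 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
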