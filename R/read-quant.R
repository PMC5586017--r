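# Splice-junction read counting under the quality filters used for
# R_isoform, and heterozygous PTC-site extraction for R_allele.
#
# A junction is given as genomic (donor, acceptor) = (last base of the
# genomically left exon, first base of the right exon), both 1-based.  A read
# supports a junction when its alignment places an N gap exactly there, the
# mapping quality passes, both flanking aligned blocks are long enough, and
# no mismatch or indel falls near any junction the read spans.

#' Junction read filter parameters
#'
#' @param required_mapq Mapping-quality cutoff (default 50, TopHat2's
#'   unique-mapper value).  By default reads with `mapq >= required_mapq`
#'   pass, since other aligners use different scales; set
#'   `mapq_exact = TRUE` to require exact equality.
#' @param min_overhang_nt Minimum aligned length on each of the two joined
#'   exons (default 6).  Soft-clipped bases do not count.
#' @param clean_window_nt Total width of the mismatch/indel exclusion zone
#'   per junction (default 12, i.e. 6 nt on each side of every junction the
#'   read spans).  Must be even.
#' @param mapq_exact Require `mapq == required_mapq` instead of `>=`.
#' @return A list of class `junction_filter_params`.
#' @export
junction_filter_params <- function(required_mapq = 50L, min_overhang_nt = 6L,
                                   clean_window_nt = 12L, mapq_exact = FALSE) {
  stopifnot(required_mapq > 0, min_overhang_nt > 0, clean_window_nt > 0,
            clean_window_nt %% 2L == 0L)
  structure(list(required_mapq = as.integer(required_mapq),
                 min_overhang_nt = as.integer(min_overhang_nt),
                 clean_window_nt = as.integer(clean_window_nt),
                 mapq_exact = isTRUE(mapq_exact)),
            class = "junction_filter_params")
}

#' Load spliced alignments from a SAM or BAM file
#'
#' SAM input is converted to BAM via `Rsamtools::asBam()` and read with
#' `scanBam()`.  For each read, aligned blocks on the reference (split at N
#' gaps, merging over deletions) and the genomic positions of mismatches and
#' indels (from the MD tag) are derived.  When no read carries an MD tag the
#' mismatch filter degrades to indel-only, with a loud warning.
#'
#' @param path SAM or BAM file.
#' @return A list of reads, each a list with `qname`, `chrom`, `pos`,
#'   `mapq`, `cigar`, `blocks` (2-column matrix of block start/end),
#'   `dirty` (genomic positions of mismatches, deleted bases, and insertion
#'   anchors).  Reads with unparsable CIGARs are skipped;
#'   `attr(, "n_malformed")` counts them.
#' @export
read_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "cigar"),
    tag = "MD"))[[1L]]
  md <- x$tag$MD
  has_md <- !is.null(md) && any(!is.na(md))
  if (!has_md) {
    warning("no MD tags found in ", path,
            ": mismatch filter degraded to indel-only", call. = FALSE)
  }
  reads <- vector("list", length(x$qname))
  n_malformed <- 0L
  for (i in seq_along(x$qname)) {
    r <- tryCatch(
      .parse_read(x$qname[i], as.character(x$rname[i]), x$pos[i], x$mapq[i],
                  x$cigar[i], if (has_md) md[i] else NA_character_),
      error = function(e) NULL)
    if (is.null(r)) n_malformed <- n_malformed + 1L else reads[[i]] <- r
  }
  reads <- reads[!vapply(reads, is.null, TRUE)]
  attr(reads, "n_malformed") <- n_malformed
  attr(reads, "has_md") <- has_md
  reads
}

# Derive blocks and dirty positions for one alignment.
.parse_read <- function(qname, chrom, pos, mapq, cigar, md) {
  if (is.na(cigar) || is.na(pos)) stop("unaligned record")
  toks <- regmatches(cigar, gregexpr("\\d+[A-Z=]", cigar))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  lens <- as.integer(sub("[A-Z=]", "", toks))
  ops <- sub("\\d+", "", toks)
  if (!all(ops %in% c("M", "I", "D", "N", "S", "H", "=", "X"))) {
    stop("unsupported CIGAR op in ", cigar)
  }
  gpos <- pos
  block_start <- NA_integer_
  blocks <- NULL
  refpos <- integer(0)   # ref positions consumed by M/D ops, in order
  is_del <- logical(0)
  ins_anchor <- integer(0)
  for (k in seq_along(ops)) {
    op <- ops[k]; len <- lens[k]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(block_start)) block_start <- gpos
      refpos <- c(refpos, seq.int(gpos, length.out = len))
      is_del <- c(is_del, rep(op == "D", len))
      gpos <- gpos + len
    } else if (op == "N") {
      if (!is.na(block_start)) {
        blocks <- rbind(blocks, c(block_start, gpos - 1L))
        block_start <- NA_integer_
      }
      gpos <- gpos + len
    } else if (op == "I") {
      ins_anchor <- c(ins_anchor, gpos - 1L)
    } # S/H consume neither reference nor blocks
  }
  if (!is.na(block_start)) blocks <- rbind(blocks, c(block_start, gpos - 1L))
  mm <- integer(0)
  if (!is.na(md)) mm <- .md_mismatches(md, refpos, is_del)
  list(qname = qname, chrom = chrom, pos = pos, mapq = mapq, cigar = cigar,
       blocks = blocks,
       dirty = c(mm, refpos[is_del], ins_anchor))
}

# Genomic positions of mismatched bases from an MD tag, given the ordered
# reference positions consumed by M/D ops and which of them are deletions.
.md_mismatches <- function(md, refpos, is_del) {
  toks <- regmatches(md, gregexpr("\\d+|\\^[A-Za-z]+|[A-Za-z]", md))[[1L]]
  p <- 1L
  mm <- integer(0)
  for (t in toks) {
    if (grepl("^\\d+$", t)) {
      p <- p + as.integer(t)
    } else if (startsWith(t, "^")) {
      p <- p + nchar(t) - 1L
    } else {
      if (p <= length(refpos)) mm <- c(mm, refpos[p])
      p <- p + 1L
    }
  }
  mm
}

#' Does one read support one splice junction?
#'
#' All filters are applied: the read's alignment must place an N gap exactly
#' at the junction; the mapping quality must pass (`>=` or `==` the
#' threshold per `params$mapq_exact`); the aligned blocks flanking the
#' junction must each cover at least `min_overhang_nt` bases; and no
#' mismatch or indel may fall within `clean_window_nt / 2` bases of *any*
#' junction the read spans.
#'
#' @param read One element of [read_alignments()] output.
#' @param junction Numeric length-2: genomic (donor, acceptor) = (last base
#'   of the left exon, first base of the right exon).
#' @param params [junction_filter_params()].
#' @return Logical.
#' @export
read_supports_junction <- function(read, junction, params = junction_filter_params()) {
  b <- read$blocks
  if (is.null(b) || nrow(b) < 2L) return(FALSE)
  i <- which(b[-nrow(b), 2L] == junction[1L] & b[-1L, 1L] == junction[2L])
  if (!length(i)) return(FALSE)
  mq_ok <- if (params$mapq_exact) read$mapq == params$required_mapq
           else read$mapq >= params$required_mapq
  if (is.na(mq_ok) || !mq_ok) return(FALSE)
  w <- b[, 2L] - b[, 1L] + 1L
  if (w[i] < params$min_overhang_nt || w[i + 1L] < params$min_overhang_nt) {
    return(FALSE)
  }
  .junctions_clean(read, params)
}

# TRUE when no dirty position falls within clean_window/2 nt of any
# junction the read spans.
.junctions_clean <- function(read, params) {
  b <- read$blocks
  if (nrow(b) < 2L) return(TRUE)
  d <- read$dirty
  if (!length(d)) return(TRUE)
  half <- params$clean_window_nt %/% 2L
  for (k in seq_len(nrow(b) - 1L)) {
    e <- b[k, 2L]; s <- b[k + 1L, 1L]
    if (any(d >= e - half + 1L & d <= e) || any(d >= s & d <= s + half - 1L)) {
      return(FALSE)
    }
  }
  TRUE
}

# Per-read table of supported junction keys ("donor|acceptor"), filters
# applied; used for fast event counting.
.junction_support_table <- function(reads, params) {
  qn <- character(0); key <- character(0)
  for (r in reads) {
    b <- r$blocks
    if (is.null(b) || nrow(b) < 2L) next
    mq_ok <- if (params$mapq_exact) r$mapq == params$required_mapq
             else r$mapq >= params$required_mapq
    if (is.na(mq_ok) || !mq_ok) next
    if (!.junctions_clean(r, params)) next
    w <- b[, 2L] - b[, 1L] + 1L
    for (k in seq_len(nrow(b) - 1L)) {
      if (w[k] >= params$min_overhang_nt && w[k + 1L] >= params$min_overhang_nt) {
        qn <- c(qn, r$qname)
        key <- c(key, paste0(r$chrom, ":", b[k, 2L], "|", b[k + 1L, 1L]))
      }
    }
  }
  data.frame(qname = qn, key = key, stringsAsFactors = FALSE)
}

#' Count reads supporting the two splice forms of one event
#'
#' The inclusion form is supported by reads spanning either
#' upstream-focal or focal-downstream junction; the exclusion form by reads
#' spanning the direct flank-to-flank junction.  Counts are deduplicated by
#' read name, so a fragment contributes at most once per form; a read name
#' observed on both forms (a guard against degenerate input) is dropped
#' from both.
#'
#' @param reads Output of [read_alignments()].
#' @param event One row of a [discover_nmd_events()] data.frame (or any list
#'   with `chrom`, `incl_j1_donor/acceptor`, `incl_j2_donor/acceptor`,
#'   `excl_donor/acceptor`).
#' @param params [junction_filter_params()].
#' @return Named integer vector `c(n_inclusion =, n_exclusion =)`.
#' @export
count_event_isoforms <- function(reads, event, params = junction_filter_params()) {
  tab <- .junction_support_table(reads, params)
  .count_one_event(tab, event)
}

.count_one_event <- function(tab, event) {
  k1 <- paste0(event$chrom, ":", event$incl_j1_donor, "|", event$incl_j1_acceptor)
  k2 <- paste0(event$chrom, ":", event$incl_j2_donor, "|", event$incl_j2_acceptor)
  kx <- paste0(event$chrom, ":", event$excl_donor, "|", event$excl_acceptor)
  incl <- unique(tab$qname[tab$key %in% c(k1, k2)])
  excl <- unique(tab$qname[tab$key == kx])
  both <- intersect(incl, excl)
  c(n_inclusion = length(setdiff(incl, both)),
    n_exclusion = length(setdiff(excl, both)))
}

#' Count splice-form support for a table of events in one sample
#'
#' @param reads Output of [read_alignments()] for one sample.
#' @param events Event data.frame from [discover_nmd_events()].
#' @param sample_id Sample label for the output.
#' @param params [junction_filter_params()].
#' @return Data.frame: `event_id`, `sample_id`, `n_inclusion`,
#'   `n_exclusion`.
#' @export
count_events <- function(reads, events, sample_id,
                         params = junction_filter_params()) {
  tab <- .junction_support_table(reads, params)
  res <- t(vapply(seq_len(nrow(events)),
                  function(i) .count_one_event(tab, events[i, ]),
                  c(n_inclusion = 0L, n_exclusion = 0L)))
  data.frame(event_id = events$event_id, sample_id = sample_id,
             n_inclusion = res[, 1L], n_exclusion = res[, 2L],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Event read-depth filter for one patient
#'
#' An event is informative for a patient only when it has more than
#' `min_reads` supporting reads (both forms combined) in the tumor *and* in
#' the normal sample (strict inequality).
#'
#' @param tumor,normal Named vectors or one-row data.frames with
#'   `n_inclusion` and `n_exclusion` for the same event.
#' @param min_reads Depth cutoff (default 10).
#' @return Logical.
#' @export
event_depth_pass <- function(tumor, normal, min_reads = 10L) {
  tt <- sum(tumor[["n_inclusion"]], tumor[["n_exclusion"]])
  nt <- sum(normal[["n_inclusion"]], normal[["n_exclusion"]])
  tt > min_reads && nt > min_reads
}
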