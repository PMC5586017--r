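#' Locate the first in-frame stop codon of a spliced mRNA
#'
#' Scans codon-by-codon from the annotated translation start and reports the
#' first TAA/TAG/TGA encountered in frame, together with the mRNA position of
#' the final exon-exon junction.  Both quantities feed the 50/55-nt rule
#' ([is_nmd_ptc()]): a termination codon well upstream of the last junction
#' marks the transcript as an NMD substrate.
#'
#' Codons containing `N` are never called as stop codons.
#'
#' @param mrna Character scalar, the spliced mRNA sequence (5'->3') over
#'   `A,C,G,T,N`.
#' @param cds_start 1-based mRNA position of the first base of the start
#'   codon.
#' @param exon_lengths Optional integer vector of exon lengths in
#'   transcription order; used to locate the final exon-exon junction.  If
#'   omitted or of length 1 the transcript is treated as single-exon (no
#'   junction).
#' @return An object of class `stop_scan`: a list with `stop_pos` (1-based
#'   mRNA position of the first base of the first in-frame stop codon, or
#'   `NA` if none) and `last_junction_pos` (1-based mRNA position of the last
#'   base *before* the final exon-exon junction, or `NA` for single-exon
#'   transcripts).
#' @examples
#' scan_first_stop("ATGTAA", 1)$stop_pos           # 4
#' scan_first_stop("ATGAAATGA", 1)$stop_pos        # 7 (out-of-frame TGA skipped)
#' @seealso [is_nmd_ptc()]
#' @export
scan_first_stop <- function(mrna, cds_start, exon_lengths = NULL) {
  stopifnot(is.character(mrna), length(mrna) == 1L)
  n <- nchar(mrna)
  if (!is.numeric(cds_start) || length(cds_start) != 1L || is.na(cds_start) ||
      cds_start < 1L || cds_start > n) {
    stop("cds_start (", cds_start, ") out of range for sequence of length ", n)
  }
  cds_start <- as.integer(cds_start)
  stop_pos <- NA_integer_
  if (cds_start + 2L <= n) {
    starts <- seq.int(cds_start, n - 2L, by = 3L)
    codons <- substring(mrna, starts, starts + 2L)
    hit <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (length(hit)) stop_pos <- starts[hit[1L]]
  }
  last_junction_pos <- NA_integer_
  if (!is.null(exon_lengths) && length(exon_lengths) >= 2L) {
    last_junction_pos <- as.integer(sum(exon_lengths[-length(exon_lengths)]))
  }
  structure(list(stop_pos = stop_pos, last_junction_pos = last_junction_pos),
            class = "stop_scan")
}

#' Apply the 50/55-nt last-junction rule
#'
#' A termination codon whose last base lies at least `threshold_nt`
#' nucleotides upstream of the final exon-exon junction is predicted to
#' trigger NMD.  Stops in the last exon (or in single-exon transcripts,
#' which have no junction) never trigger.
#'
#' The literature quotes the boundary as "50-55 nt"; the cutoff is therefore
#' configurable, with 50 as the default.  The distance is measured from the
#' last base of the stop codon to the final junction.
#'
#' @param scan A `stop_scan` result from [scan_first_stop()]; must contain a
#'   stop position.
#' @param threshold_nt Minimum distance (nt) between the end of the stop
#'   codon and the final junction for NMD to be predicted.  Default 50.
#' @return `TRUE` if the transcript is predicted to be an NMD substrate.
#' @examples
#' sc <- scan_first_stop("ATGTAAACGT", 1, exon_lengths = c(8, 2))
#' is_nmd_ptc(sc)  # FALSE: stop only 2 nt upstream of the junction
#' @export
is_nmd_ptc <- function(scan, threshold_nt = 50L) {
  if (is.na(scan$stop_pos)) {
    stop("stop_scan has no stop codon; check before calling is_nmd_ptc()")
  }
  if (is.na(scan$last_junction_pos)) return(FALSE)
  (scan$last_junction_pos - (scan$stop_pos + 2L)) >= threshold_nt
}
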