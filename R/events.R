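# Cassette-exon (exon-skipping) event discovery and NMD-fate classification.
#
# An event is a focal exon with two constitutive flanks: some transcript
# includes all three consecutively, another joins the flanks directly.  The
# two splice forms are rebuilt from the same CDS start and each is tested
# with the 50/55-nt rule; only events where exactly one form triggers NMD
# are emitted, labelled with that form.

#' Find candidate exon-skipping events in one gene
#'
#' Returns all (upstream, focal, downstream) exon triples such that (a) some
#' transcript of the gene contains the three exons consecutively, (b) some
#' transcript joins upstream and downstream directly without the focal exon,
#' and (c) both flanking exons are constitutive: every exon of every
#' transcript of the gene that overlaps a flank has exactly the flank's
#' boundaries, so no alternative donor/acceptor use touches the flanks.
#'
#' @param gene A `gene_model` (one element of [load_gene_models()] output).
#' @return A list of candidate events, each a list with `gene_id`, `chrom`,
#'   `strand` and `upstream`/`focal`/`downstream` exons (each `c(start,
#'   end)`, genomic).  Upstream/downstream are in *transcription* order.
#'   Empty list when the gene has fewer than two transcripts or no cassette
#'   structure.
#' @export
find_skipping_events <- function(gene) {
  trs <- gene$transcripts
  if (length(trs) < 2L) return(list())

  # per transcript, exons sorted genomically (ascending)
  ex_sorted <- lapply(trs, function(tr) {
    ex <- tr$exons[order(tr$exons$start), , drop = FALSE]
    rownames(ex) <- NULL
    ex
  })
  key <- function(s, e) paste0(s, "-", e)
  pair_key <- function(a, b) paste(a, b, sep = "|")

  # adjacent exon pairs (genomic order) per transcript
  adj <- unlist(lapply(ex_sorted, function(ex) {
    n <- nrow(ex)
    if (n < 2L) return(character(0))
    pair_key(key(ex$start[-n], ex$end[-n]), key(ex$start[-1L], ex$end[-1L]))
  }), use.names = FALSE)

  all_exons <- unique(do.call(rbind, ex_sorted))

  constitutive <- function(exon) {
    # every overlapping exon anywhere in the gene must equal this exon
    ov <- all_exons$start <= exon[2L] & all_exons$end >= exon[1L]
    all(all_exons$start[ov] == exon[1L] & all_exons$end[ov] == exon[2L])
  }

  seen <- character(0)
  out <- list()
  for (ex in ex_sorted) {
    n <- nrow(ex)
    if (n < 3L) next
    for (j in seq_len(n - 2L)) {
      left  <- c(ex$start[j],      ex$end[j])
      focal <- c(ex$start[j + 1L], ex$end[j + 1L])
      right <- c(ex$start[j + 2L], ex$end[j + 2L])
      id <- paste(key(left[1], left[2]), key(focal[1], focal[2]),
                  key(right[1], right[2]), sep = ";")
      if (id %in% seen) next
      seen <- c(seen, id)
      skip_pair <- pair_key(key(left[1], left[2]), key(right[1], right[2]))
      if (!skip_pair %in% adj) next
      if (!constitutive(left) || !constitutive(right)) next
      if (gene$strand == "+") {
        up <- left; dn <- right
      } else {
        up <- right; dn <- left
      }
      out[[length(out) + 1L]] <- list(
        gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
        upstream = up, focal = focal, downstream = dn)
    }
  }
  out
}

#' Classify the NMD fate of a candidate skipping event
#'
#' Rebuilds the inclusion-form and exclusion-form mRNAs from the same
#' annotated CDS start, scans each for its first in-frame stop
#' ([scan_first_stop()]) and applies the 50/55-nt rule ([is_nmd_ptc()]).
#' The event is emitted only when exactly one form is an NMD substrate;
#' otherwise it is discarded with a reason.
#'
#' The reference transcript supplying exon context and CDS start is the
#' transcript with the longest annotated CDS among those containing all
#' three exons consecutively.  The CDS start must lie 5' of the focal exon;
#' forms containing `N` in the scanned region are discarded.
#'
#' @param candidate One element of [find_skipping_events()] output.
#' @param gene The `gene_model` the candidate came from.
#' @param threshold_nt Cutoff for [is_nmd_ptc()] (default 50).
#' @return A list with either `event` (a classified event list carrying
#'   `nmd_form` in `{"inclusion","exclusion"}`, the reference
#'   `transcript_id`, and genomic junction coordinates) or `reason` (a
#'   string naming why the candidate was discarded); exactly one is
#'   non-`NULL`.
#' @export
classify_event_nmd_form <- function(candidate, gene, threshold_nt = 50L) {
  discard <- function(reason) list(event = NULL, reason = reason)
  trio <- rbind(candidate$upstream, candidate$focal, candidate$downstream)

  # reference transcript: longest CDS among those containing the trio
  # consecutively (in genomic order)
  ref <- NULL
  trio_srt <- trio[order(trio[, 1L]), , drop = FALSE]
  trio_keys <- paste(trio_srt[, 1L], trio_srt[, 2L], sep = "-")
  for (tr in gene$transcripts) {
    if (is.na(tr$cds_start)) next
    ex <- tr$exons[order(tr$exons$start), , drop = FALSE]
    keys <- paste(ex$start, ex$end, sep = "-")
    i <- match(trio_keys[1L], keys)
    if (is.na(i) || i + 2L > length(keys)) next
    if (!identical(keys[i:(i + 2L)], trio_keys)) next
    if (is.null(ref) || tr$cds_len > ref$cds_len) ref <- tr
  }
  if (is.null(ref)) return(discard("no_cds_transcript_with_trio"))

  # focal exon position in transcription order of the reference transcript
  tkeys <- paste(ref$exons$start, ref$exons$end, sep = "-")
  fidx <- match(paste(candidate$focal, collapse = "-"), tkeys)
  widths <- ref$exons$end - ref$exons$start + 1L
  focal_mrna_start <- if (fidx == 1L) 1L else sum(widths[seq_len(fidx - 1L)]) + 1L
  if (ref$cds_start >= focal_mrna_start) return(discard("cds_start_not_upstream_of_focal"))

  incl_mrna <- ref$mrna
  incl_lens <- widths
  cum <- cumsum(widths)
  f_from <- focal_mrna_start
  f_to <- cum[fidx]
  excl_mrna <- paste0(substring(incl_mrna, 1L, f_from - 1L),
                      substring(incl_mrna, f_to + 1L, nchar(incl_mrna)))
  excl_lens <- widths[-fidx]

  if (grepl("N", substring(incl_mrna, ref$cds_start), fixed = TRUE) ||
      grepl("N", substring(excl_mrna, ref$cds_start), fixed = TRUE)) {
    return(discard("ambiguous_base_in_cds"))
  }

  sc_in <- scan_first_stop(incl_mrna, ref$cds_start, incl_lens)
  sc_ex <- scan_first_stop(excl_mrna, ref$cds_start, excl_lens)
  if (is.na(sc_in$stop_pos) || is.na(sc_ex$stop_pos)) return(discard("no_stop_codon"))

  nmd_in <- is_nmd_ptc(sc_in, threshold_nt)
  nmd_ex <- is_nmd_ptc(sc_ex, threshold_nt)
  if (nmd_in == nmd_ex) {
    return(discard(if (nmd_in) "both_forms_nmd" else "neither_form_nmd"))
  }

  srt <- trio[order(trio[, 1L]), , drop = FALSE]
  ev <- c(candidate, list(
    nmd_form = if (nmd_in) "inclusion" else "exclusion",
    transcript_id = ref$transcript_id,
    inclusion_junctions = list(c(srt[1L, 2L], srt[2L, 1L]),
                               c(srt[2L, 2L], srt[3L, 1L])),
    exclusion_junction = c(srt[1L, 2L], srt[3L, 1L])))
  list(event = ev, reason = NULL)
}

#' Discover NMD-informative exon-skipping events across gene models
#'
#' Runs [find_skipping_events()] and [classify_event_nmd_form()] over every
#' gene and tabulates the events where exactly one splice form triggers NMD.
#'
#' @param models A `gene_models` object.
#' @param threshold_nt Cutoff for the 50/55-nt rule (default 50).
#' @return A data.frame with one row per event: `event_id`, `gene_id`,
#'   `chrom`, `strand`, exon coordinates, `nmd_form`, reference
#'   `transcript_id`, and the genomic junction coordinates
#'   (`incl_j1_donor/acceptor`, `incl_j2_donor/acceptor`,
#'   `excl_donor/acceptor`; donor = last base of the genomically left exon,
#'   acceptor = first base of the right exon).  Discard reasons are attached
#'   as `attr(, "discards")`.
#' @export
discover_nmd_events <- function(models, threshold_nt = 50L) {
  rows <- list()
  discards <- list()
  for (gene in models) {
    for (cand in find_skipping_events(gene)) {
      res <- classify_event_nmd_form(cand, gene, threshold_nt)
      if (is.null(res$event)) {
        discards[[length(discards) + 1L]] <- data.frame(
          gene_id = gene$gene_id, reason = res$reason,
          stringsAsFactors = FALSE)
        next
      }
      ev <- res$event
      rows[[length(rows) + 1L]] <- data.frame(
        event_id = paste0(ev$gene_id, ":", ev$chrom, ":",
                          ev$focal[1L], "-", ev$focal[2L]),
        gene_id = ev$gene_id, chrom = ev$chrom, strand = ev$strand,
        upstream_start = ev$upstream[1L], upstream_end = ev$upstream[2L],
        focal_start = ev$focal[1L], focal_end = ev$focal[2L],
        downstream_start = ev$downstream[1L], downstream_end = ev$downstream[2L],
        nmd_form = ev$nmd_form, transcript_id = ev$transcript_id,
        incl_j1_donor = ev$inclusion_junctions[[1L]][1L],
        incl_j1_acceptor = ev$inclusion_junctions[[1L]][2L],
        incl_j2_donor = ev$inclusion_junctions[[2L]][1L],
        incl_j2_acceptor = ev$inclusion_junctions[[2L]][2L],
        excl_donor = ev$exclusion_junction[1L],
        excl_acceptor = ev$exclusion_junction[2L],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(out, "discards") <- if (length(discards)) do.call(rbind, discards) else
    data.frame(gene_id = character(0), reason = character(0))
  out
}

#' Write / read a discovered event table
#'
#' Events are stored as a TSV (one row per event, the columns of
#' [discover_nmd_events()]) plus a JSON sidecar (`<path>.json`) carrying the
#' NMD form and junction coordinates for downstream tools.
#'
#' @param events Event data.frame from [discover_nmd_events()].
#' @param path Output TSV path.
#' @return `path`, invisibly (`write_events`); the event data.frame
#'   (`read_events`).
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- lapply(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    list(event_id = e$event_id, nmd_form = e$nmd_form,
         inclusion_junctions = list(c(e$incl_j1_donor, e$incl_j1_acceptor),
                                    c(e$incl_j2_donor, e$incl_j2_acceptor)),
         exclusion_junction = c(e$excl_donor, e$excl_acceptor))
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
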