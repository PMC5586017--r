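test_that("a minimal cassette exon is found and flanks must be constitutive", {
  ex <- function(s, e) data.frame(start = s, end = e)
  g <- toy_gene(list(
    tA = data.frame(start = c(100, 300, 500), end = c(200, 380, 600)),
    tB = data.frame(start = c(100, 500), end = c(200, 600))))
  ev <- find_skipping_events(g)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$focal, c(300, 380))
  expect_equal(ev[[1]]$upstream, c(100, 200))

  # third transcript with an alternative 3' boundary of the upstream exon:
  # flank no longer constitutive -> no event
  g2 <- toy_gene(list(
    tA = data.frame(start = c(100, 300, 500), end = c(200, 380, 600)),
    tB = data.frame(start = c(100, 500), end = c(200, 600)),
    tC = data.frame(start = c(100, 500), end = c(180, 600))))
  expect_length(find_skipping_events(g2), 0)

  # fewer than two transcripts -> nothing
  expect_length(find_skipping_events(toy_gene(list(
    tA = data.frame(start = c(100, 300), end = c(200, 380))))), 0)
})

test_that("candidate discovery matches an exhaustive enumeration oracle", {
  set.seed(13)
  for (rep in 1:40) {
    n_ex <- sample(4:7, 1)
    starts <- cumsum(sample(150:250, n_ex))
    ends <- starts + sample(40:90, n_ex, replace = TRUE)
    full <- data.frame(start = starts, end = ends)
    trs <- list(tA = full)
    # skip transcripts missing one or two internal exons
    for (k in seq_len(sample(1:3, 1))) {
      drop <- sample(2:(n_ex - 1), sample(1:2, 1))
      trs[[paste0("tS", k)]] <- full[-drop, ]
    }
    # sometimes a transcript with a shifted boundary, breaking a flank
    if (rep %% 3 == 0) {
      alt <- full
      i <- sample(seq_len(n_ex), 1)
      alt$end[i] <- alt$end[i] - 5
      trs$tAlt <- alt
    }
    g <- toy_gene(trs, strand = sample(c("+", "-"), 1))
    expect_identical(event_keys(find_skipping_events(g)), oracle_find_events(g))
  }
})

test_that("NMD-form classification matches the brute-force translation oracle", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_events = 200, n_decoys = 12, seed = 19)
  ann <- simulate_annotation(cfg, dir)
  models <- load_gene_models(ann$gtf, ann$fasta)
  events <- discover_nmd_events(models)

  # planted truth reproduced exactly, decoys yield nothing
  expect_equal(nrow(events), 200)
  m <- merge(ann$truth_events[, c("event_id", "nmd_form")],
             events[, c("event_id", "nmd_form")], by = "event_id")
  expect_equal(nrow(m), 200)
  expect_identical(m$nmd_form.x, m$nmd_form.y)

  # independent oracle: rebuild both splice forms from the reference
  # transcript and translate nucleotide-by-nucleotide
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    tr <- models[[e$gene_id]]$transcripts[[e$transcript_id]]
    widths <- tr$exons$end - tr$exons$start + 1
    keys <- paste(tr$exons$start, tr$exons$end, sep = "-")
    fidx <- match(paste0(e$focal_start, "-", e$focal_end), keys)
    f_from <- if (fidx == 1) 1 else sum(widths[1:(fidx - 1)]) + 1
    f_to <- cumsum(widths)[fidx]
    excl <- paste0(substr(tr$mrna, 1, f_from - 1),
                   substr(tr$mrna, f_to + 1, nchar(tr$mrna)))
    nmd_in <- oracle_nmd(tr$mrna, tr$cds_start, widths)
    nmd_ex <- oracle_nmd(excl, tr$cds_start, widths[-fidx])
    expect_false(is.na(nmd_in) || is.na(nmd_ex))
    expect_identical(e$nmd_form == "inclusion", nmd_in && !nmd_ex)
    expect_identical(e$nmd_form == "exclusion", nmd_ex && !nmd_in)
  }

  # every stored junction corresponds to exon boundaries present in the
  # gene's transcripts
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    bounds_l <- unlist(lapply(models[[e$gene_id]]$transcripts,
                              function(t) t$exons$end))
    bounds_r <- unlist(lapply(models[[e$gene_id]]$transcripts,
                              function(t) t$exons$start))
    expect_true(all(c(e$incl_j1_donor, e$incl_j2_donor, e$excl_donor) %in% bounds_l))
    expect_true(all(c(e$incl_j1_acceptor, e$incl_j2_acceptor, e$excl_acceptor) %in% bounds_r))
  }
})

test_that("event discovery is invariant under a whole-genome strand flip", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_events = 15, n_decoys = 3, seed = 23)
  ann <- simulate_annotation(cfg, dir)
  ev1 <- discover_nmd_events(load_gene_models(ann$gtf, ann$fasta))
  mir <- mirror_annotation(ann$gtf, ann$fasta, dir)
  ev2 <- discover_nmd_events(load_gene_models(mir$gtf, mir$fasta))
  expect_equal(nrow(ev2), nrow(ev1))
  m <- merge(ev1[, c("gene_id", "nmd_form", "focal_start", "focal_end")],
             ev2[, c("gene_id", "nmd_form", "focal_start", "focal_end")],
             by = "gene_id")
  expect_identical(m$nmd_form.x, m$nmd_form.y)
  # focal coordinates mirror exactly
  expect_equal(m$focal_start.y, mir$L - m$focal_end.x + 1)
})

test_that("events with no CDS upstream of the focal exon are discarded", {
  dir <- withr::local_tempdir()
  fa <- write_fasta(c(chr1 = paste0(strrep("A", 30), "CCC", strrep("A", 100),
                                    "ATGAAATAA", strrep("G", 60))),
                    file.path(dir, "g.fa"))
  gtf <- file.path(dir, "a.gtf")
  # start codon inside the downstream exon (3' of the focal exon)
  writeLines(c(gtf_row("chr1", "exon", 1, 30, "+", "g1", "t1"),
               gtf_row("chr1", "exon", 61, 90, "+", "g1", "t1"),
               gtf_row("chr1", "exon", 134, 190, "+", "g1", "t1"),
               gtf_row("chr1", "start_codon", 134, 136, "+", "g1", "t1"),
               gtf_row("chr1", "exon", 1, 30, "+", "g1", "t2"),
               gtf_row("chr1", "exon", 134, 190, "+", "g1", "t2")), gtf)
  models <- load_gene_models(gtf, fa)
  ev <- discover_nmd_events(models)
  expect_equal(nrow(ev), 0)
  expect_true("cds_start_not_upstream_of_focal" %in% attr(ev, "discards")$reason)
})
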