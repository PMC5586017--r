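test_that("junction support applies mapq, overhang and clean-window filters", {
  j <- c(200, 401)  # donor = last base of left exon, acceptor = first of right
  b <- rbind(c(191, 200), c(401, 410))  # 10 nt on each side
  p <- junction_filter_params()

  expect_true(read_supports_junction(make_read(blocks = b), j, p))
  # mapping quality below the cutoff
  expect_false(read_supports_junction(make_read(blocks = b, mapq = 49L), j, p))
  # mismatch 3 nt into the acceptor exon
  expect_false(read_supports_junction(make_read(blocks = b, dirty = 403L), j, p))
  # mismatch outside the 6-nt windows is tolerated
  expect_true(read_supports_junction(make_read(blocks = b, dirty = 407L), j, p))
  # only 5 nt on the acceptor exon
  b5 <- rbind(c(191, 200), c(401, 405))
  expect_false(read_supports_junction(make_read(blocks = b5), j, p))
  # read not spanning the junction at all
  expect_false(read_supports_junction(make_read(blocks = rbind(c(100, 150))), j, p))
  # N gap at a different acceptor
  b_off <- rbind(c(191, 200), c(402, 411))
  expect_false(read_supports_junction(make_read(blocks = b_off), j, p))
  # exact-mapq mode rejects higher values too
  pe <- junction_filter_params(mapq_exact = TRUE)
  expect_false(read_supports_junction(make_read(blocks = b, mapq = 60L), j, pe))
  expect_true(read_supports_junction(make_read(blocks = b, mapq = 50L), j, pe))
})

test_that("event counting deduplicates by read name and drops ambiguous names", {
  ev <- list(chrom = "chrS", incl_j1_donor = 200, incl_j1_acceptor = 401,
             incl_j2_donor = 500, incl_j2_acceptor = 701,
             excl_donor = 200, excl_acceptor = 701)
  b_j1 <- rbind(c(191, 200), c(401, 410))
  b_j2 <- rbind(c(491, 500), c(701, 710))
  b_jx <- rbind(c(191, 200), c(701, 710))
  reads <- list(
    make_read("a", blocks = b_j1), make_read("b", blocks = b_j1),
    make_read("c", blocks = b_j1),
    make_read("d", blocks = b_j2), make_read("e", blocks = b_j2),
    make_read("x1", blocks = b_jx), make_read("x2", blocks = b_jx),
    make_read("x3", blocks = b_jx), make_read("x4", blocks = b_jx))
  expect_equal(count_event_isoforms(reads, ev),
               c(n_inclusion = 5L, n_exclusion = 4L))
  # same name on both inclusion junctions: counted once
  reads2 <- c(reads, list(make_read("a", blocks = b_j2)))
  expect_equal(count_event_isoforms(reads2, ev)[["n_inclusion"]], 5L)
  # a name seen on both forms is dropped from both
  reads3 <- c(reads, list(make_read("x1", blocks = b_j1)))
  expect_equal(count_event_isoforms(reads3, ev),
               c(n_inclusion = 5L, n_exclusion = 3L))
  # order independence
  set.seed(1)
  expect_equal(count_event_isoforms(sample(reads), ev),
               count_event_isoforms(reads, ev))
})

test_that("the event depth filter requires > min_reads in both samples", {
  ec <- function(i, e) c(n_inclusion = i, n_exclusion = e)
  expect_true(event_depth_pass(ec(5, 6), ec(6, 5)))     # 11 and 11
  expect_false(event_depth_pass(ec(5, 5), ec(20, 5)))   # 10 is not > 10
  expect_false(event_depth_pass(ec(0, 0), ec(0, 0)))
  set.seed(2)
  for (i in 1:50) {
    t <- sample(0:30, 2); n <- sample(0:30, 2)
    expect_identical(event_depth_pass(ec(t[1], t[2]), ec(n[1], n[2])),
                     sum(t) > 10 && sum(n) > 10)
  }
})

test_that("planted SAM pileups are counted exactly and filters are monotone", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_events = 25, n_decoys = 0, seed = 31)
  ann <- simulate_annotation(cfg, dir)
  sam <- file.path(dir, "reads.sam")
  planted <- simulate_junction_sam(ann$truth_events, ann$fasta, sam, config = cfg)
  reads <- read_alignments(sam)
  expect_equal(attr(reads, "n_malformed"), 0L)
  cnt <- count_events(reads, ann$truth_events, "s1")
  expect_equal(cnt$n_inclusion, planted$n_j1 + planted$n_j2)
  expect_equal(cnt$n_exclusion, planted$n_jx)

  # relaxing any single filter can only increase counts
  relaxed <- list(junction_filter_params(required_mapq = 1),
                  junction_filter_params(min_overhang_nt = 1),
                  junction_filter_params(clean_window_nt = 2))
  for (p in relaxed) {
    cr <- count_events(reads, ann$truth_events, "s1", p)
    expect_true(all(cr$n_inclusion >= cnt$n_inclusion))
    expect_true(all(cr$n_exclusion >= cnt$n_exclusion))
  }
  # and each dirty class is actually recovered by its own relaxation:
  # relaxing everything at once recovers all planted dirty reads
  all_relaxed <- junction_filter_params(required_mapq = 1, min_overhang_nt = 1,
                                        clean_window_nt = 2)
  ca <- count_events(reads, ann$truth_events, "s1", all_relaxed)
  per_junction_dirty <- 3 * cfg$dirty_reads_per_junction
  expect_equal(ca$n_inclusion, cnt$n_inclusion + 2L * per_junction_dirty)
  expect_equal(ca$n_exclusion, cnt$n_exclusion + per_junction_dirty)
})

test_that("unsupported CIGAR operations are skipped with a counter", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "bad.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
               paste("ok", 0, "chr1", 10, 50, "10M", "*", 0, 0,
                     strrep("A", 10), strrep("I", 10), "MD:Z:10", sep = "\t"),
               paste("bad", 0, "chr1", 10, 50, "4M2P4M", "*", 0, 0,
                     strrep("A", 8), strrep("I", 8), "MD:Z:8", sep = "\t")),
             sam)
  reads <- read_alignments(sam)
  expect_length(reads, 1)
  expect_equal(attr(reads, "n_malformed"), 1L)
})

test_that("missing MD tags degrade the mismatch filter with a warning", {
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "nomd.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:1000",
               paste("r1", 0, "chr1", 10, 50, "8M100N8M", "*", 0, 0,
                     strrep("A", 16), strrep("I", 16), sep = "\t")), sam)
  expect_warning(reads <- read_alignments(sam), "indel-only")
  expect_true(read_supports_junction(reads[[1]], c(17, 118)))
})

test_that("PTC sites are extracted from ANN and EFF VCF dialects", {
  for (dialect in c("ANN", "EFF")) {
    dir <- withr::local_tempdir()
    vcf <- write_tiny_vcf(file.path(dir, "v.vcf"), dialect)
    sites <- extract_ptc_sites(vcf)
    expect_equal(nrow(sites), 1)
    expect_equal(sites$pos, 100L)
    expect_equal(sites$ref, "C")
    expect_equal(sites$alt, "T")
    expect_equal(sites$nmd_allele, "alt")
    expect_equal(sites$gene_id, "GENE1")
  }
})

test_that("allele-site filter enforces depth and both-alleles support", {
  ac <- function(nmd, non) c(n_nmd = nmd, n_nonnmd = non)
  expect_true(allele_site_pass(ac(3, 3), ac(2, 3)))
  expect_false(allele_site_pass(ac(2, 2), ac(2, 3)))   # tumor depth 4 < 5
  # one allele unseen in normal: fails per-tissue, passes pooled
  expect_false(allele_site_pass(ac(3, 3), ac(5, 0)))
  expect_true(allele_site_pass(ac(3, 3), ac(5, 0), scope = "pooled"))
})
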