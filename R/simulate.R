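# Synthetic paired-cohort generator.
#
# Generates a fully self-contained cohort -- annotation + genome, junction
# read records, event/allele/expression count tables, target-classification
# evidence -- with known per-sample NMD strength lambda, so that every
# upstream module can be validated against planted ground truth.
#
# Generative model: the NMD-inducing form of a feature is produced at the
# same rate as its NMD-free counterpart but decays lambda * k times faster
# (k = the feature's NMD susceptibility), so its expected abundance is
# divided by lambda * k.  Expected values: R_isoform = 1/(1 + lambda*k),
# R_allele = c/lambda (c = baseline allelic imbalance), target-gene
# expression proportional to 1/lambda.  Counts are negative binomial around
# the expectations.
#
# Sequence construction trick: exon bodies are drawn from the {A,C,G}
# alphabet -- with no T, no stop codon can arise in any reading frame -- and
# explicit ATG / TAA codons are planted where needed, so each event's NMD
# form is known by construction, not by running the package's own
# classifier.

SAFE <- c("A", "C", "G")

.safe_nt <- function(n) paste(sample(SAFE, n, replace = TRUE), collapse = "")
.safe_codons <- function(n) .safe_nt(3L * n)
.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

#' Simulation configuration
#'
#' Defaults emulate the study conditions of a 72-patient paired lung-cancer
#' cohort: 50 high-confidence NMD target genes, 4074 non-target background
#' genes, 776 cassette-exon events (68% triggering NMD on inclusion), and a
#' modest number of heterozygous PTC sites.  Per-sample NMD strength is
#' `lambda`; tumors have `lambda = normal lambda * f` with per-patient
#' factor `f` (default: lognormal around 1, i.e. most tumors close to their
#' normal baseline, some clearly above or below).
#'
#' @param n_patients Patients (each contributes a tumor + normal pair).
#' @param n_target_genes,n_nontarget_genes,n_low_genes Expression-matrix
#'   composition (targets, background non-targets, and genes planted below
#'   the low-expression filter).
#' @param n_events Cassette-exon events; `prop_inclusion` of them trigger
#'   NMD on inclusion, the rest on exclusion.
#' @param n_decoys Decoy genes (both-forms-NMD, neither-form-NMD,
#'   non-constitutive-flank), which must yield no event.
#' @param n_ptc_sites Heterozygous PTC sites for R_allele.
#' @param base_strength Baseline NMD strength of normal tissue.
#' @param normal_strength_sdlog Lognormal spread of normal-tissue strength
#'   across patients.
#' @param strength_factors Per-patient tumor/normal strength factors `f`
#'   (recycled); `NULL` draws them lognormal(0, `strength_factor_sdlog`).
#' @param strength_factor_sdlog Spread of `f` when drawn.
#' @param nmd_k_meanlog,nmd_k_sdlog Lognormal NMD susceptibility `k` of
#'   events (default: median 12-fold decay acceleration).
#' @param junction_depth Mean junction reads on the NMD-free form per event.
#' @param allele_depth Mean reads on the NMD-free allele per site.
#' @param allele_imbalance_sdlog Baseline (NMD-independent) allelic
#'   imbalance spread.
#' @param nb_size Negative-binomial size (inverse overdispersion).
#' @param depth_sdlog Between-feature lognormal spread of baseline depth.
#' @param library_sdlog Between-sample library-size spread.
#' @param effector_coupling Named vector over [nmd_effectors()]: exponent
#'   linking effector expression to NMD strength (1 = proportional, 0 =
#'   uncoupled).
#' @param clean_reads_per_junction,dirty_reads_per_junction Read counts for
#'   the SAM writer (clean mean; dirty reads *per violation type* per
#'   junction).
#' @param write_sam Write per-sample SAM files in [simulate_cohort()]
#'   (default `FALSE`: the count tables carry the quantification; SAM
#'   output is intended for exercising the read filters).
#' @param seed Integer seed; every output stream derives from it.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 72L,
                              n_target_genes = 50L,
                              n_nontarget_genes = 4074L,
                              n_low_genes = 50L,
                              n_events = 776L,
                              prop_inclusion = 528 / 776,
                              n_decoys = 12L,
                              n_ptc_sites = 60L,
                              base_strength = 1,
                              normal_strength_sdlog = 0.1,
                              strength_factors = NULL,
                              strength_factor_sdlog = 0.3,
                              nmd_k_meanlog = log(12),
                              nmd_k_sdlog = 0.35,
                              junction_depth = 60,
                              allele_depth = 30,
                              allele_imbalance_sdlog = 0.25,
                              nb_size = 10,
                              depth_sdlog = 0.3,
                              library_sdlog = 0.2,
                              effector_coupling = c(UPF1 = 0, UPF2 = 1,
                                                    UPF3A = 0, UPF3B = 0,
                                                    SMG1 = 1, SMG5 = 0,
                                                    SMG6 = 0, SMG7 = 1,
                                                    PNRC2 = 1),
                              clean_reads_per_junction = 20L,
                              dirty_reads_per_junction = 2L,
                              write_sam = FALSE,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_patients > 0, n_events > 0, n_target_genes > 0,
            n_nontarget_genes > 0, n_ptc_sites > 0,
            base_strength > 0, junction_depth > 0, allele_depth > 0,
            nb_size > 0, prop_inclusion >= 0, prop_inclusion <= 1,
            is.null(strength_factors) || all(strength_factors > 0))
  structure(cfg, class = "simulation_config")
}

# ---- annotation -----------------------------------------------------------

# One gene layout in local (gene, plus-strand) coordinates.
# type: "inclusion", "exclusion", "decoy_both", "decoy_neither",
# "decoy_altflank".
.build_gene <- function(type, intron_len = 150L) {
  utr5 <- 21L
  n1 <- sample(8:30, 1L)
  e1_cds <- paste0("ATG", .safe_codons(n1))
  e1 <- paste0(.safe_nt(utr5), e1_cds)

  if (type == "decoy_both") {
    # stop inside e1, > 55 nt upstream of the end of e1
    e1 <- paste0(.safe_nt(utr5), "ATG", .safe_codons(n1), "TAA", .safe_nt(60L))
  }
  atg_local <- utr5 + 1L

  if (type %in% c("inclusion", "decoy_both", "decoy_neither", "decoy_altflank")) {
    focal <- if (type == "inclusion") {
      paste0(.safe_codons(3L), "TAA", .safe_nt(75L))
    } else {
      .safe_nt(87L)   # length 0 mod 3, no stop in any frame
    }
    e3 <- paste0(.safe_codons(sample(5:15, 1L)), "TAA", "C", .safe_nt(20L))
    exon_seqs <- list(e1, focal, e3)
  } else {  # exclusion: 4 exons, frameshifting focal
    focal <- .safe_nt(31L)                       # 31 = 1 mod 3
    e3 <- paste0(.safe_codons(4L), "TAA", .safe_nt(70L + 1L))  # len 86 = 2 mod 3
    e4 <- paste0(.safe_nt(6L), "TAA", "C", .safe_nt(20L))
    exon_seqs <- list(e1, focal, e3, e4)
  }
  lens <- vapply(exon_seqs, nchar, 1L)
  n_ex <- length(lens)
  starts <- integer(n_ex); ends <- integer(n_ex)
  pos <- 1L
  seq_parts <- character(0)
  for (i in seq_len(n_ex)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    seq_parts <- c(seq_parts, exon_seqs[[i]])
    pos <- ends[i] + 1L
    if (i < n_ex) {
      seq_parts <- c(seq_parts, .rand_nt(intron_len))
      pos <- pos + intron_len
    }
  }
  list(type = type, seq = paste(seq_parts, collapse = ""),
       exon_start = starts, exon_end = ends, atg_local = atg_local,
       focal_idx = 2L)
}

#' Simulate annotation: GTF + genome FASTA with planted cassette events
#'
#' Builds one gene per event (plus decoy genes that must yield no event),
#' places them on a single chromosome with random strand, and writes
#' `annotation.gtf` and `genome.fa`.  Each event gene has an inclusion
#' transcript (with start_codon annotation) and an exclusion transcript;
#' exactly one splice form carries a PTC satisfying the 50/55-nt rule, so
#' running [discover_nmd_events()] on the output must reproduce the planted
#' `nmd_form` for every non-decoy gene and nothing for decoys.
#'
#' @param config [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return List: `gtf`, `fasta` (paths), `truth_events` (data.frame with
#'   `gene_id`, `event_id`, `nmd_form`, `chrom`, `strand`, junction
#'   coordinates), `n_decoys`.
#' @export
simulate_annotation <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 1L)

  n_inc <- round(config$n_events * config$prop_inclusion)
  types <- c(rep("inclusion", n_inc),
             rep("exclusion", config$n_events - n_inc),
             rep(c("decoy_both", "decoy_neither", "decoy_altflank"),
                 length.out = config$n_decoys))

  chrom <- "chrS"
  gpos <- 1L
  chrom_parts <- character(0)
  gtf <- character(0)
  truth <- list()
  gtf_line <- function(feat, s, e, strand, gid, tid) {
    sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            chrom, feat, s, e, strand, gid, tid)
  }

  for (gi in seq_along(types)) {
    g <- .build_gene(types[gi])
    gid <- sprintf("EVG%04d", gi)
    strand <- sample(c("+", "-"), 1L)
    L <- nchar(g$seq)
    spacer <- .rand_nt(100L)
    gseq <- if (strand == "+") g$seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$seq)))
    chrom_parts <- c(chrom_parts, gseq, spacer)
    gstart <- gpos
    gpos <- gpos + L + 100L

    loc2gen <- function(a, b) {
      if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
      else c(gstart + L - b, gstart + L - a)
    }
    n_ex <- length(g$exon_start)
    ex_gen <- t(mapply(loc2gen, g$exon_start, g$exon_end))  # n_ex x 2, genomic

    # transcription order: local order always 5'->3'
    t1 <- seq_len(n_ex)                   # inclusion form
    t2 <- setdiff(t1, g$focal_idx)        # exclusion form
    atg <- loc2gen(g$atg_local, g$atg_local + 2L)

    tid1 <- paste0(gid, ".inc"); tid2 <- paste0(gid, ".exc")
    for (i in t1) gtf <- c(gtf, gtf_line("exon", ex_gen[i, 1L], ex_gen[i, 2L],
                                         strand, gid, tid1))
    gtf <- c(gtf, gtf_line("start_codon", atg[1L], atg[2L], strand, gid, tid1))
    for (i in t2) gtf <- c(gtf, gtf_line("exon", ex_gen[i, 1L], ex_gen[i, 2L],
                                         strand, gid, tid2))
    if (types[gi] == "decoy_altflank") {
      # third transcript with an alternative e1 3' boundary (local): flank
      # not constitutive, so no event may be emitted
      alt_e1 <- if (strand == "+")
        c(ex_gen[1L, 1L], ex_gen[1L, 2L] - 6L) else
        c(ex_gen[1L, 1L] + 6L, ex_gen[1L, 2L])
      tid3 <- paste0(gid, ".alt")
      gtf <- c(gtf, gtf_line("exon", alt_e1[1L], alt_e1[2L], strand, gid, tid3))
      for (i in setdiff(t1, 1L)) {
        gtf <- c(gtf, gtf_line("exon", ex_gen[i, 1L], ex_gen[i, 2L],
                               strand, gid, tid3))
      }
    }

    if (types[gi] %in% c("inclusion", "exclusion")) {
      # junctions around the focal exon, in genomic left-to-right order
      ord <- order(ex_gen[, 1L])
      ex_srt <- ex_gen[ord, , drop = FALSE]
      fpos <- which(ord == g$focal_idx)
      focal_gen <- ex_srt[fpos, ]
      truth[[length(truth) + 1L]] <- data.frame(
        gene_id = gid,
        event_id = paste0(gid, ":", chrom, ":", focal_gen[1L], "-", focal_gen[2L]),
        nmd_form = types[gi], chrom = chrom, strand = strand,
        focal_start = focal_gen[1L], focal_end = focal_gen[2L],
        incl_j1_donor = ex_srt[fpos - 1L, 2L], incl_j1_acceptor = focal_gen[1L],
        incl_j2_donor = focal_gen[2L], incl_j2_acceptor = ex_srt[fpos + 1L, 1L],
        excl_donor = ex_srt[fpos - 1L, 2L], excl_acceptor = ex_srt[fpos + 1L, 1L],
        stringsAsFactors = FALSE)
    }
  }

  genome <- Biostrings::DNAStringSet(paste(chrom_parts, collapse = ""))
  names(genome) <- chrom
  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome, fasta, width = 80L)
  gtf_path <- file.path(dir, "annotation.gtf")
  writeLines(gtf, gtf_path)

  list(gtf = gtf_path, fasta = fasta,
       truth_events = do.call(rbind, truth),
       n_decoys = sum(startsWith(types, "decoy")))
}

# ---- strengths and counts -------------------------------------------------

#' Simulate per-sample NMD strengths
#'
#' @param config [simulation_config()].
#' @return List: `samples` (data.frame `sample_id`, `patient_id`, `tissue`,
#'   `lambda`), `factors` (per-patient `f`).
#' @export
simulate_strengths <- function(config) {
  set.seed(config$seed + 2L)
  pid <- sprintf("P%03d", seq_len(config$n_patients))
  f <- if (is.null(config$strength_factors)) {
    rlnorm(config$n_patients, 0, config$strength_factor_sdlog)
  } else {
    rep_len(config$strength_factors, config$n_patients)
  }
  lam_n <- config$base_strength *
    rlnorm(config$n_patients, 0, config$normal_strength_sdlog)
  samples <- data.frame(
    sample_id = c(paste0(pid, "_T"), paste0(pid, "_N")),
    patient_id = c(pid, pid),
    tissue = rep(c("tumor", "normal"), each = config$n_patients),
    lambda = c(lam_n * f, lam_n),
    stringsAsFactors = FALSE)
  samples <- samples[order(samples$patient_id, samples$tissue), ]
  rownames(samples) <- NULL
  list(samples = samples, factors = setNames(f, pid))
}

#' Simulate count tables for a cohort
#'
#' Draws negative-binomial event junction counts, allele counts, and an
#' FPKM expression matrix (with raw counts) from the generative model, plus
#' a target-classification evidence table with planted classes.
#'
#' @param config [simulation_config()].
#' @param truth_events Event truth from [simulate_annotation()]; `NULL`
#'   uses abstract event ids `EV0001...` (no annotation needed).
#' @return List: `samples`, `factors`, `event_counts`, `allele_counts`,
#'   `expression` (FPKM matrix), `raw_counts`, `effector_expr`, `evidence`,
#'   `truth` (per-feature baselines, susceptibilities, expectations).
#' @export
simulate_counts <- function(config, truth_events = NULL) {
  st <- simulate_strengths(config)
  samples <- st$samples
  lam <- setNames(samples$lambda, samples$sample_id)
  ns <- nrow(samples)

  # --- events ---
  set.seed(config$seed + 4L)
  if (is.null(truth_events)) {
    n_inc <- round(config$n_events * config$prop_inclusion)
    ev_id <- sprintf("EV%04d", seq_len(config$n_events))
    nmd_form <- c(rep("inclusion", n_inc),
                  rep("exclusion", config$n_events - n_inc))
  } else {
    ev_id <- truth_events$event_id
    nmd_form <- truth_events$nmd_form
  }
  n_ev <- length(ev_id)
  k_ev <- rlnorm(n_ev, config$nmd_k_meanlog, config$nmd_k_sdlog)
  d_ev <- config$junction_depth * rlnorm(n_ev, 0, config$depth_sdlog)
  mu_non <- outer(d_ev, rep(1, ns))
  mu_nmd <- outer(d_ev, rep(1, ns)) / (outer(k_ev, lam))
  n_non <- matrix(rnbinom(n_ev * ns, mu = mu_non, size = config$nb_size),
                  n_ev, ns)
  n_nmd <- matrix(rnbinom(n_ev * ns, mu = mu_nmd, size = config$nb_size),
                  n_ev, ns)
  inc <- nmd_form == "inclusion"
  n_inclusion <- ifelse(inc[row(n_non)], n_nmd, n_non)
  n_exclusion <- ifelse(inc[row(n_non)], n_non, n_nmd)
  event_counts <- data.frame(
    event_id = rep(ev_id, ns),
    sample_id = rep(samples$sample_id, each = n_ev),
    n_inclusion = as.vector(n_inclusion),
    n_exclusion = as.vector(n_exclusion),
    stringsAsFactors = FALSE)

  # --- alleles ---
  set.seed(config$seed + 5L)
  site_id <- sprintf("SITE%04d", seq_len(config$n_ptc_sites))
  a_site <- config$allele_depth * rlnorm(config$n_ptc_sites, 0, config$depth_sdlog)
  c_site <- rlnorm(config$n_ptc_sites, 0, config$allele_imbalance_sdlog)
  nsite <- config$n_ptc_sites
  mu_a_non <- outer(a_site, rep(1, ns))
  mu_a_nmd <- outer(a_site * c_site, 1 / lam)
  allele_counts <- data.frame(
    site_id = rep(site_id, ns),
    sample_id = rep(samples$sample_id, each = nsite),
    n_nmd = as.vector(matrix(rnbinom(nsite * ns, mu = mu_a_nmd,
                                     size = config$nb_size), nsite, ns)),
    n_nonnmd = as.vector(matrix(rnbinom(nsite * ns, mu = mu_a_non,
                                        size = config$nb_size), nsite, ns)),
    stringsAsFactors = FALSE)

  # --- expression ---
  set.seed(config$seed + 3L)
  tg <- sprintf("TG%04d", seq_len(config$n_target_genes))
  ng <- sprintf("NG%04d", seq_len(config$n_nontarget_genes))
  lg <- sprintf("LG%04d", seq_len(config$n_low_genes))
  eff <- nmd_effectors()
  base_t <- rlnorm(length(tg), log(10), 1)
  base_n <- rlnorm(length(ng), log(20), 1.2)
  base_l <- rlnorm(length(lg), log(0.05), 0.3)
  base_e <- rlnorm(length(eff), log(30), 0.3)
  coupling <- config$effector_coupling[eff]
  coupling[is.na(coupling)] <- 0
  mu <- rbind(outer(base_t, 1 / lam),
              outer(base_n, rep(1, ns)),
              outer(base_l, rep(1, ns)),
              outer(base_e, rep(1, ns)) * exp(outer(coupling, log(lam))))
  rownames(mu) <- c(tg, ng, lg, eff)
  colnames(mu) <- samples$sample_id
  sf <- rlnorm(ns, 0, config$library_sdlog)
  raw_counts <- matrix(rnbinom(length(mu), mu = sweep(mu, 2, sf, "*"),
                               size = config$nb_size),
                       nrow(mu), ns, dimnames = dimnames(mu))
  fpkm <- sweep(raw_counts, 2, sf, "/")
  effector_expr <- fpkm[eff, , drop = FALSE]

  # --- evidence ---
  set.seed(config$seed + 7L)
  evidence <- .simulate_evidence(tg, ng)

  truth <- list(samples = samples, factors = st$factors,
                event_k = setNames(k_ev, ev_id),
                event_depth = setNames(d_ev, ev_id),
                nmd_form = setNames(nmd_form, ev_id),
                site_imbalance = setNames(c_site, site_id),
                site_depth = setNames(a_site, site_id),
                expected_r_isoform = outer(1 / k_ev, 1 / lam) /
                  (1 + outer(1 / k_ev, 1 / lam)),
                expected_r_allele = outer(c_site, 1 / lam))
  dimnames(truth$expected_r_isoform) <- list(ev_id, samples$sample_id)
  dimnames(truth$expected_r_allele) <- list(site_id, samples$sample_id)

  list(samples = samples, factors = st$factors, event_counts = event_counts,
       allele_counts = allele_counts, expression = fpkm,
       raw_counts = raw_counts, effector_expr = effector_expr,
       evidence = evidence, truth = truth)
}

# Evidence with planted classes: strong targets (support >= 3), weak
# targets (support 1), non-targets, plus a sprinkle of unclassified and
# background-excluded genes.
.simulate_evidence <- function(target_ids, nontarget_ids) {
  iso <- function(fold, fpkm) paste0(round(fold, 3), ":", round(fpkm, 3))
  n_t <- length(target_ids); n_n <- length(nontarget_ids)
  t_stab <- runif(n_t) < 0.7
  t_rows <- data.frame(
    gene_id = target_ids,
    a1_fold = runif(n_t, 2, 6), a2_fold = runif(n_t, 2, 6),
    b_stabilized = t_stab, b_meets_standards = TRUE,
    c_isoform_folds = ifelse(
      t_stab, iso(runif(n_t, 1, 1.8), runif(n_t, 1, 4)),       # support 3
      iso(runif(n_t, 3, 6), runif(n_t, 5, 20))),               # support 3
    stringsAsFactors = FALSE)
  n_rows <- data.frame(
    gene_id = nontarget_ids,
    a1_fold = runif(n_n, 0.7, 1.4), a2_fold = runif(n_n, 0.7, 1.4),
    b_stabilized = FALSE, b_meets_standards = TRUE,
    c_isoform_folds = iso(runif(n_n, 0.6, 1.9), runif(n_n, 1, 10)),
    stringsAsFactors = FALSE)
  n_u <- 30L
  u_rows <- data.frame(
    gene_id = sprintf("UG%04d", seq_len(n_u)),
    a1_fold = runif(n_u, 1.55, 1.95), a2_fold = runif(n_u, 0.8, 1.4),
    b_stabilized = FALSE, b_meets_standards = TRUE,
    c_isoform_folds = iso(runif(n_u, 0.6, 1.9), runif(n_u, 1, 10)),
    stringsAsFactors = FALSE)
  n_x <- 20L
  x_rows <- data.frame(
    gene_id = sprintf("XG%04d", seq_len(n_x)),
    a1_fold = NA_real_, a2_fold = runif(n_x, 0.7, 6),
    b_stabilized = FALSE, b_meets_standards = TRUE,
    c_isoform_folds = iso(runif(n_x, 0.6, 1.9), runif(n_x, 1, 10)),
    stringsAsFactors = FALSE)
  ev <- rbind(t_rows, n_rows, u_rows, x_rows)
  ev$c_isoforms <- lapply(ev$c_isoform_folds, .parse_isoforms)
  ev
}

# ---- SAM writer -----------------------------------------------------------

#' Simulate spliced junction reads as a SAM file
#'
#' For each planted event junction, emits a planted number of clean spliced
#' reads (all filters pass) plus contaminating reads each violating exactly
#' one filter: mapping quality 49, a 5-nt overhang, or a mismatch 3 nt into
#' the acceptor exon.  Running the junction counter on the file must return
#' exactly the planted clean counts.
#'
#' @param truth_events Event truth from [simulate_annotation()].
#' @param genome_fasta Path to the simulated genome (for read sequences).
#' @param path Output SAM path.
#' @param clean_counts Optional matrix (events x 3 junctions: `j1`, `j2`,
#'   `jx`) of planted clean read counts; `NULL` draws them Poisson around
#'   `config$clean_reads_per_junction`.
#' @param config [simulation_config()] (read depths and seed).
#' @param seed_offset Added to `config$seed` for this file's RNG stream.
#' @return Data.frame of planted truth: `event_id`, `n_j1`, `n_j2`, `n_jx`
#'   (clean counts), `n_dirty`.
#' @export
simulate_junction_sam <- function(truth_events, genome_fasta, path,
                                  clean_counts = NULL,
                                  config = simulation_config(),
                                  seed_offset = 6L) {
  set.seed(config$seed + seed_offset)
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  n_ev <- nrow(truth_events)
  if (is.null(clean_counts)) {
    clean_counts <- matrix(stats::rpois(n_ev * 3L,
                                        config$clean_reads_per_junction),
                           n_ev, 3L, dimnames = list(NULL, c("j1", "j2", "jx")))
  }
  lines <- character(0)
  rid <- 0L
  mk_read <- function(chrom, a, b, mapq, o5, o3, mismatch_at = NA) {
    rid <<- rid + 1L
    pos <- a - o5 + 1L
    gap <- b - a - 1L
    cigar <- sprintf("%dM%dN%dM", o5, gap, o3)
    s5 <- as.character(Biostrings::subseq(genome[[chrom]], pos, a))
    s3 <- as.character(Biostrings::subseq(genome[[chrom]], b, b + o3 - 1L))
    seq <- paste0(s5, s3)
    md <- sprintf("%d", o5 + o3)
    if (!is.na(mismatch_at)) {
      # mismatch_at: offset (1-based) into the acceptor-exon part
      idx <- o5 + mismatch_at
      ref_base <- substring(seq, idx, idx)
      alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
      substring(seq, idx, idx) <- alt
      md <- sprintf("%d%s%d", o5 + mismatch_at - 1L, ref_base,
                    o3 - mismatch_at)
    }
    sprintf("sr%06d\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tMD:Z:%s",
            rid, chrom, pos, mapq, cigar, seq, strrep("I", nchar(seq)), md)
  }
  n_dirty <- 0L
  for (i in seq_len(n_ev)) {
    e <- truth_events[i, ]
    juncs <- list(j1 = c(e$incl_j1_donor, e$incl_j1_acceptor),
                  j2 = c(e$incl_j2_donor, e$incl_j2_acceptor),
                  jx = c(e$excl_donor, e$excl_acceptor))
    for (jn in names(juncs)) {
      j <- juncs[[jn]]
      for (r in seq_len(clean_counts[i, jn])) {
        lines <- c(lines, mk_read(e$chrom, j[1L], j[2L], 50L,
                                  sample(6:15, 1L), sample(6:15, 1L)))
      }
      for (r in seq_len(config$dirty_reads_per_junction)) {
        lines <- c(lines,
                   mk_read(e$chrom, j[1L], j[2L], 49L, 10L, 10L),
                   mk_read(e$chrom, j[1L], j[2L], 50L, 5L, 10L),
                   mk_read(e$chrom, j[1L], j[2L], 50L, 10L, 10L,
                           mismatch_at = 3L))
        n_dirty <- n_dirty + 3L
      }
    }
  }
  hdr <- c("@HD\tVN:1.6",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  writeLines(c(hdr, lines), path)
  data.frame(event_id = truth_events$event_id,
             n_j1 = clean_counts[, "j1"], n_j2 = clean_counts[, "j2"],
             n_jx = clean_counts[, "jx"], n_dirty = n_dirty,
             stringsAsFactors = FALSE)
}

# ---- full cohort ----------------------------------------------------------

#' Simulate a complete paired cohort into a directory
#'
#' Writes `genome.fa`, `annotation.gtf`, `samples.tsv`, `expression.tsv`,
#' `raw_counts.tsv`, `event_counts.tsv`, `allele_counts.tsv`,
#' `evidence.tsv`, `truth.json`, and (when `config$write_sam`) one
#' `reads_<sample>.sam` per sample.  All randomness derives from
#' `config$seed`; rerunning with the same config is byte-identical.
#'
#' @param config [simulation_config()].
#' @param dir Output directory.
#' @return Invisibly, the [simulate_counts()] result plus `annotation`
#'   (the [simulate_annotation()] result).
#' @export
simulate_cohort <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(config, dir)
  sim <- simulate_counts(config, ann$truth_events)

  wt <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(sim$samples, "samples.tsv")
  wt(sim$event_counts, "event_counts.tsv")
  wt(sim$allele_counts, "allele_counts.tsv")
  wt(sim$evidence[, setdiff(names(sim$evidence), "c_isoforms")], "evidence.tsv")
  expr <- data.frame(gene_id = rownames(sim$expression), sim$expression,
                     check.names = FALSE, stringsAsFactors = FALSE)
  wt(expr, "expression.tsv")
  cnt <- data.frame(gene_id = rownames(sim$raw_counts), sim$raw_counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  wt(cnt, "raw_counts.tsv")

  if (isTRUE(config$write_sam)) {
    for (s in sim$samples$sample_id) {
      simulate_junction_sam(ann$truth_events, ann$fasta,
                            file.path(dir, paste0("reads_", s, ".sam")),
                            config = config,
                            seed_offset = 6L + match(s, sim$samples$sample_id))
    }
  }

  truth_json <- list(
    seed = config$seed,
    factors = as.list(sim$factors),
    lambda = setNames(as.list(sim$samples$lambda), sim$samples$sample_id),
    event_k = as.list(sim$truth$event_k),
    nmd_form = as.list(sim$truth$nmd_form),
    site_imbalance = as.list(sim$truth$site_imbalance))
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sim, list(annotation = ann)))
}
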