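test_that("low-expression filter uses the half-or-more rule exactly", {
  n <- 144
  m <- rbind(
    dropped  = c(rep(0, 72), rep(50, 72)),    # < 10 in exactly half
    kept_hi  = rep(50, n),
    kept_edge = c(rep(0, 71), rep(50, 73)))   # < 10 in 71 of 144
  expect_setequal(filter_low_expressed(m), c("kept_hi", "kept_edge"))
  # odd sample count: ceiling(n/2)
  m2 <- rbind(a = c(0, 0, 50), b = c(0, 50, 50))
  expect_setequal(filter_low_expressed(m2), "b")
})

test_that("upper-quartile normalization matches an independent quantile", {
  set.seed(8)
  m <- matrix(rlnorm(600, 2, 1), 100, 6,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:6)))
  nm <- normalize_q75(m)
  expect_equal(unname(apply(nm, 2, quantile, 0.75)), rep(1, 6),
               tolerance = 1e-12)
  for (j in 1:6) {
    expect_equal(nm[, j], m[, j] / oracle_q75(m[, j]), tolerance = 1e-12)
  }
  # constant column normalizes to all ones
  mc <- cbind(s1 = rep(3, 10))
  expect_true(all(normalize_q75(mc) == 1))
  expect_error(normalize_q75(cbind(s1 = rep(0, 10))), "zero")
})

test_that("R_mRNA is target expression over median non-target expression", {
  expr <- rbind(t1 = c(4, 8), n1 = c(1, 2), n2 = c(2, 4), n3 = c(4, 8))
  colnames(expr) <- c("sA", "sB")
  v <- r_mrna(expr, "t1", c("n1", "n2", "n3"))
  expect_equal(v$value, c(2, 2))
  expect_equal(r_mrna(rbind(expr, t0 = c(0, 0)), "t0",
                      c("n1", "n2", "n3"))$value, c(0, 0))
  expect_error(r_mrna(expr, "t1", character(0)), "non-target")
  expect_error(r_mrna(rbind(t1 = c(1, 1), n1 = c(0, 0)), "t1", "n1"), "zero")

  # random matrices: brute-force recomputation, and scale invariance under
  # multiplying one sample by a constant
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(rlnorm(400), 40, 10,
                dimnames = list(paste0("g", 1:40), paste0("s", 1:10)))
    tg <- paste0("g", 1:5); ng <- paste0("g", 6:40)
    v <- r_mrna(m, tg, ng)
    for (k in sample(nrow(v), 5)) {
      expect_equal(v$value[k],
                   m[v$feature_id[k], v$sample_id[k]] / median(m[ng, v$sample_id[k]]),
                   tolerance = 1e-12)
    }
    m2 <- m; m2[, 3] <- m2[, 3] * 17
    expect_equal(r_mrna(m2, tg, ng)$value, v$value, tolerance = 1e-12)
  }
})

test_that("R_isoform is the NMD-form fraction with [0,1] bounds", {
  events <- data.frame(event_id = c("e1", "e2"),
                       nmd_form = c("inclusion", "exclusion"),
                       stringsAsFactors = FALSE)
  ec <- data.frame(event_id = c("e1", "e2", "e1", "e1"),
                   sample_id = c("s1", "s1", "s2", "s3"),
                   n_inclusion = c(5L, 12L, 0L, 10L),
                   n_exclusion = c(15L, 4L, 7L, 0L))
  v <- r_isoform(ec, events)
  expect_equal(v$value, c(0.25, 0.25, 0, 1))
  expect_true(all(v$value >= 0 & v$value <= 1))
  # zero totals are excluded and counted
  ec0 <- rbind(ec, data.frame(event_id = "e2", sample_id = "s9",
                              n_inclusion = 0L, n_exclusion = 0L))
  v0 <- r_isoform(ec0, events)
  expect_equal(nrow(v0), 4)
  expect_equal(attr(v0, "n_excluded"), 1L)
  expect_error(r_isoform(data.frame(event_id = "zz", sample_id = "s",
                                    n_inclusion = 1L, n_exclusion = 1L),
                         events), "absent")
})

test_that("R_allele divides PTC-allele by PTC-free-allele reads", {
  ac <- data.frame(site_id = c("v1", "v2", "v3"), sample_id = "s1",
                   n_nmd = c(3L, 0L, 3L), n_nonnmd = c(6L, 6L, 0L))
  v <- r_allele(ac)
  expect_equal(v$value, c(0.5, 0))
  expect_equal(attr(v, "n_excluded"), 1L)
  # pseudocount mode retains the zero-denominator site
  vp <- r_allele(ac, pseudocount = 0.5)
  expect_equal(nrow(vp), 3)
  expect_equal(vp$value[3], 3.5 / 0.5)
})

test_that("per-patient depth and allele filters work per patient", {
  samples <- data.frame(sample_id = c("p1_T", "p1_N", "p2_T", "p2_N"),
                        patient_id = c("p1", "p1", "p2", "p2"),
                        tissue = c("tumor", "normal", "tumor", "normal"),
                        stringsAsFactors = FALSE)
  ec <- data.frame(event_id = "e1",
                   sample_id = c("p1_T", "p1_N", "p2_T", "p2_N"),
                   n_inclusion = c(6L, 6L, 6L, 5L),
                   n_exclusion = c(6L, 6L, 6L, 5L))
  kept <- filter_events_by_depth(ec, samples)
  expect_setequal(kept$sample_id, c("p1_T", "p1_N"))  # p2 normal total 10

  ac <- data.frame(site_id = "v1",
                   sample_id = c("p1_T", "p1_N", "p2_T", "p2_N"),
                   n_nmd = c(3L, 2L, 3L, 0L), n_nonnmd = c(3L, 3L, 3L, 9L))
  kept2 <- filter_allele_sites(ac, samples)
  expect_setequal(kept2$sample_id, c("p1_T", "p1_N"))
  kept3 <- filter_allele_sites(ac, samples, scope = "pooled")
  expect_equal(nrow(kept3), 4)
})

test_that("patient ratios are per-feature with zero-normal exclusion", {
  samples <- data.frame(sample_id = c("p1_T", "p1_N"), patient_id = "p1",
                        tissue = c("tumor", "normal"), stringsAsFactors = FALSE)
  v <- data.frame(metric = "m", feature_id = c("f1", "f1", "f2", "f2"),
                  sample_id = c("p1_T", "p1_N", "p1_T", "p1_N"),
                  value = c(2, 1, 5, 0), stringsAsFactors = FALSE)
  pr <- patient_ratios(v, samples)
  expect_equal(pr$summary$median_ratio, 2)
  expect_equal(pr$summary$n_excluded_zero_normal, 1L)
  # identical tumor and normal values: all ratios 1
  v2 <- v; v2$value <- c(3, 3, 7, 7)
  expect_equal(patient_ratios(v2, samples)$summary$median_ratio, 1)
  # random values match direct recomputation
  set.seed(10)
  for (rep in 1:20) {
    nf <- sample(5:40, 1)
    tv <- runif(nf); nv <- runif(nf)
    vv <- data.frame(metric = "m",
                     feature_id = rep(paste0("f", 1:nf), 2),
                     sample_id = rep(c("p1_T", "p1_N"), each = nf),
                     value = c(tv, nv), stringsAsFactors = FALSE)
    expect_equal(patient_ratios(vv, samples)$summary$median_ratio,
                 median(tv / nv), tolerance = 1e-12)
  }
})

test_that("per-sample metric medians decrease monotonically in NMD strength", {
  # 20 strength levels; normal-tissue spread switched off so tumor lambda
  # equals the planted factor exactly
  fs <- seq(0.3, 3, length.out = 20)
  cfg <- simulation_config(n_patients = 20L, strength_factors = fs,
                           normal_strength_sdlog = 0, n_nontarget_genes = 300L,
                           n_events = 300L, n_ptc_sites = 200L, seed = 12)
  sim <- simulate_counts(cfg)
  tum <- sim$samples[sim$samples$tissue == "tumor", ]
  lam <- tum$lambda
  events <- data.frame(event_id = names(sim$truth$nmd_form),
                       nmd_form = unname(sim$truth$nmd_form),
                       stringsAsFactors = FALSE)
  vi <- r_isoform(sim$event_counts, events)
  va <- r_allele(sim$allele_counts)
  ts <- list(targets = sprintf("TG%04d", 1:50),
             nontargets = sprintf("NG%04d", 1:300))
  vm <- r_mrna(normalize_q75(sim$expression), ts$targets, ts$nontargets)
  for (v in list(vi, va, vm)) {
    med <- tapply(v$value, v$sample_id, median)[tum$sample_id]
    expect_true(spearman_cor(lam, med)$rho < -0.9)
  }
})
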