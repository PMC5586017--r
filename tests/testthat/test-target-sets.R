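mk_evidence <- function(gene_id = "g", a1 = 1, a2 = 1, stab = FALSE,
                        std = TRUE, c_iso = "1:2") {
  ev <- data.frame(gene_id = gene_id, a1_fold = a1, a2_fold = a2,
                   b_stabilized = stab, b_meets_standards = std,
                   c_isoform_folds = c_iso, stringsAsFactors = FALSE)
  ev$c_isoforms <- lapply(ev$c_isoform_folds, nmdactivity:::.parse_isoforms)
  ev
}

test_that("background eligibility requires presence in all four studies", {
  expect_true(background_eligible(mk_evidence()))
  expect_false(background_eligible(mk_evidence(a1 = NA)))          # no probe
  expect_false(background_eligible(mk_evidence(std = FALSE)))
  expect_false(background_eligible(mk_evidence(c_iso = "1:0.5"))) # < 1 FPKM
  expect_false(background_eligible(mk_evidence(c_iso = "")))      # absent
})

test_that("target / non-target / unclassified rules are applied exactly", {
  cl <- function(...) classify_genes(mk_evidence(...))
  # one array >= 2-fold: target with support 1
  r <- cl(a1 = 2.1, a2 = 1.0, c_iso = "1.2:6")
  expect_equal(r$class, "target"); expect_equal(r$support, 1L)
  # everything below the non-target ceilings
  expect_equal(cl(a1 = 1.1, a2 = 1.2, c_iso = "1.4:6")$class, "nontarget")
  # in between: neither target nor non-target
  expect_equal(cl(a1 = 1.7, a2 = 1.4, c_iso = "2.5:4")$class, "unclassified")
  # C criterion needs both >= 3-fold and >= 5 FPKM
  expect_equal(cl(c_iso = "3.5:6")$class, "target")
  expect_equal(cl(c_iso = "3.5:4")$class, "unclassified")
  # stabilized alone supports targeting
  r <- cl(stab = TRUE)
  expect_equal(r$class, "target"); expect_equal(r$support, 1L)
  # all four studies
  r <- cl(a1 = 3, a2 = 4, stab = TRUE, c_iso = "3:7")
  expect_equal(r$support, 4L)
  # ineligible genes are excluded before classification
  expect_equal(cl(a1 = NA)$class, "excluded")
})

test_that("classification agrees with an independent re-encoding of the rules", {
  set.seed(5)
  n <- 300
  ev <- do.call(rbind, lapply(seq_len(n), function(i) {
    mk_evidence(gene_id = paste0("g", i),
                a1 = sample(c(NA, runif(1, 0.5, 4)), 1, prob = c(.1, .9)),
                a2 = runif(1, 0.5, 4),
                stab = runif(1) < 0.3,
                std = runif(1) < 0.9,
                c_iso = paste0(round(runif(1, 0.5, 4), 2), ":",
                               round(runif(1, 0, 10), 2)))
  }))
  got <- classify_genes(ev)
  for (i in seq_len(n)) {
    row <- ev[i, ]
    iso <- row$c_isoforms[[1]]
    want <- if (is.na(row$a1_fold) || is.na(row$a2_fold) ||
                !row$b_meets_standards || !any(iso[, "fpkm"] >= 1)) {
      "excluded"
    } else {
      k <- (row$a1_fold >= 2) + (row$a2_fold >= 2) + row$b_stabilized +
        any(iso[, "fold"] >= 3 & iso[, "fpkm"] >= 5)
      if (k >= 1) "target"
      else if (row$a1_fold < 1.5 && row$a2_fold < 1.5 && !row$b_stabilized &&
               all(iso[, "fold"] < 2)) "nontarget"
      else "unclassified"
    }
    expect_identical(got$class[i], want)
  }
})

test_that("target-set selection filters by support and stays disjoint", {
  cls <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "g5"),
                    class = c("target", "target", "target", "nontarget",
                              "unclassified"),
                    support = c(4L, 3L, 1L, 0L, 0L), stringsAsFactors = FALSE)
  ts <- select_target_set(cls, min_support = 3)
  expect_setequal(names(ts$targets), c("g1", "g2"))
  expect_setequal(ts$nontargets, "g4")
  expect_setequal(names(select_target_set(cls, 1)$targets), c("g1", "g2", "g3"))

  # raising min_support never grows the set
  set.seed(6)
  cls2 <- data.frame(gene_id = paste0("g", 1:200),
                     class = sample(c("target", "nontarget", "unclassified"),
                                    200, replace = TRUE),
                     support = sample(0:4, 200, replace = TRUE),
                     stringsAsFactors = FALSE)
  cls2$support[cls2$class != "target"] <- 0L
  cls2$support[cls2$class == "target" & cls2$support == 0L] <- 1L
  sizes <- vapply(1:4, function(k)
    length(select_target_set(cls2, k)$targets), 1L)
  expect_true(all(diff(sizes) <= 0))
  for (k in 1:4) {
    ts <- select_target_set(cls2, k)
    expect_length(intersect(names(ts$targets), ts$nontargets), 0)
  }
})

test_that("evidence round-trips through its TSV schema", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(n_nontarget_genes = 300L, n_patients = 4L, seed = 3)
  sim <- simulate_counts(cfg)
  f <- file.path(dir, "evidence.tsv")
  write.table(sim$evidence[, setdiff(names(sim$evidence), "c_isoforms")],
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  ev2 <- read_evidence(f)
  cls <- classify_genes(ev2)
  # planted strong targets all have support >= 3; planted non-targets all
  # classify as non-targets
  tg <- startsWith(cls$gene_id, "TG")
  expect_true(all(cls$class[tg] == "target" & cls$support[tg] >= 3))
  ng <- startsWith(cls$gene_id, "NG")
  expect_true(all(cls$class[ng] == "nontarget"))
  expect_true(all(cls$class[startsWith(cls$gene_id, "UG")] == "unclassified"))
  expect_true(all(cls$class[startsWith(cls$gene_id, "XG")] == "excluded"))
})

test_that("non-positive fold changes are rejected at parse time", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "bad.tsv")
  writeLines(c("gene_id\ta1_fold\ta2_fold\tb_stabilized\tb_meets_standards\tc_isoform_folds",
               "g1\t-1\t2\tFALSE\tTRUE\t1:2"), f)
  expect_error(read_evidence(f), "positive")
})
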