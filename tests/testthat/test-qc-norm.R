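test_that("low-data filter removes genes then samples at the 60% rule", {
  ## fully observed: unchanged
  ct <- matrix(20 + seq_len(20) / 10, 4, 5)
  q <- toy_qpcr(ct)
  expect_identical(dim(filterLowData(q)), dim(q))

  ## 5 genes x 10 samples, one gene present in 5/10 (0.5 < 0.6): removed
  ct <- matrix(rep(20, 50), 5, 10)
  ct[3, 1:5] <- NA
  q <- toy_qpcr(ct)
  f <- filterLowData(q, minPresent = 0.6)
  expect_identical(rownames(f), paste0("g", c(1, 2, 4, 5)))
  expect_identical(qcReport(f)$filter$removedGenes, "g3")

  ## a sample below 60% over the retained genes is removed second
  ct <- matrix(rep(20, 50), 5, 10)
  ct[1:3, 7] <- NA
  f2 <- filterLowData(toy_qpcr(ct), minPresent = 0.6)
  expect_identical(ncol(f2), 9L)
  expect_identical(qcReport(f2)$filter$removedSamples, "s7")

  ## all genes below the rule: error
  ct[] <- NA_real_
  ct[1, 1] <- 20
  expect_error(filterLowData(toy_qpcr(ct)), "empty matrix after QC")
})

test_that("QC monotonicity: lowering the cutoff never removes more genes", {
  set.seed(1)
  ct <- matrix(20 + rnorm(200), 10, 20)
  ct[sample(length(ct), 40)] <- NA
  q <- toy_qpcr(ct)
  removed <- vapply(c(0.8, 0.6, 0.4, 0.2), function(p)
    length(qcReport(filterLowData(q, minPresent = p))$filter$removedGenes),
    numeric(1))
  expect_true(all(diff(removed) <= 0))
})

test_that("chip replicate merging follows the agreement band", {
  base <- c(20, 22, 24, 26)
  make_pair <- function(rep2) {
    ct <- cbind(s1 = base, s2 = rep2)
    rownames(ct) <- paste0("g", 1:4)
    meta <- data.frame(strain = "SHR", sex = "F", organ = "adrenal",
                       age_weeks = 8, animal_id = c("a1", "a1"),
                       chip_id = c("chip1", "chip2"),
                       row.names = colnames(ct))
    QpcrSet(ct, meta)
  }
  ## identical duplicates: merged column equals either input
  m <- mergeChipReplicates(make_pair(base))
  expect_identical(ncol(m), 1L)
  expect_equal(unname(assay(m, "ct")[, 1]), base)
  expect_length(qcReport(m)$replicates$merges, 1L)

  ## scaled x1.2: slope 1.2 outside the band, not averaged
  m2 <- mergeChipReplicates(make_pair(base * 1.2))
  expect_identical(ncol(m2), 1L)
  expect_equal(unname(assay(m2, "ct")[, 1]), base)  # kept replicate 1
  expect_length(qcReport(m2)$replicates$exclusions, 1L)
  expect_equal(qcReport(m2)$replicates$exclusions[[1]]$slope, 1.2,
               tolerance = 1e-12)

  ## no duplicates: no-op
  ct <- matrix(20 + seq_len(8), 4, 2,
               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  q <- toy_qpcr(ct)
  expect_identical(assay(mergeChipReplicates(q), "ct"), assay(q, "ct"))

  ## >2 replicates per sample: unsupported
  ct3 <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(ct3) <- paste0("g", 1:4)
  meta3 <- data.frame(strain = "SHR", sex = "F", organ = "adrenal",
                      age_weeks = 8, animal_id = rep("a1", 3),
                      chip_id = c("chip1", "chip2", "chip3"),
                      row.names = colnames(ct3))
  expect_error(mergeChipReplicates(QpcrSet(ct3, meta3)),
               "unsupported replicate multiplicity")
})

test_that("delta-Ct normalizes against the per-sample robust-gene median", {
  ## 3 genes, Ct {20, 22, 30}: median 22, dCt = {-2, 0, 8}
  ct <- matrix(c(20, 22, 30), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  q <- deltaCt(toy_qpcr(ct))
  expect_equal(unname(assay(q, "dct")[, 1]), c(-2, 0, 8))
  expect_identical(qcReport(q)$reference$robustGenes$adrenal,
                   paste0("g", 1:3))

  ## organs are normalized independently
  set.seed(2)
  ct2 <- matrix(20 + rnorm(40), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  meta <- data.frame(strain = "SHR", sex = "F",
                     organ = rep(c("adrenal", "kidney"), each = 5),
                     age_weeks = 8, animal_id = paste0("a", 1:10),
                     chip_id = "chip1", row.names = colnames(ct2))
  qa <- deltaCt(QpcrSet(ct2, meta))
  ct2b <- ct2
  ct2b[, 6:10] <- ct2[, c(8, 10, 6, 9, 7)]  # permute organ B samples
  qb <- deltaCt(QpcrSet(ct2b, meta))
  expect_identical(assay(qa, "dct")[, 1:5], assay(qb, "dct")[, 1:5])

  ## location invariance: shifting one sample leaves its dCt unchanged
  ct2c <- ct2
  ct2c[, 3] <- ct2[, 3] + 5
  qc_ <- deltaCt(QpcrSet(ct2c, meta))
  expect_equal(assay(qc_, "dct")[, 3], assay(qa, "dct")[, 3])

  ## no robust genes: error
  ct3 <- matrix(NA_real_, 2, 4,
                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  ct3[1, 1] <- 20
  expect_error(deltaCt(toy_qpcr(ct3), robustMinPresent = 0.6),
               "no reference subset")
})

test_that("-ddCt centers by the per-gene cross-sample median", {
  ## constant gene maps to zero
  ct <- matrix(c(1, 2, 3, 4, 10,
                 5, 5, 5, 5, 5), 2, 5, byrow = TRUE,
               dimnames = list(c("gA", "gB"), paste0("s", 1:5)))
  q <- toy_qpcr(ct)
  assays(q, withDimnames = FALSE)$dct <- ct   # treat as already-referenced
  out <- negDeltaDeltaCt(q)
  expect_equal(unname(assay(out, "nddct")["gA", ]),
               c(2, 1, 0, -1, -7), ignore_attr = TRUE)
  expect_equal(unname(assay(out, "nddct")["gB", ]), rep(0, 5),
               ignore_attr = TRUE)
  ## sign contract: below-median dCt (higher expression) => positive -ddCt
  expect_gt(assay(out, "nddct")["gA", 1], 0)

  ## a gene present in < 2 samples becomes missing, logged
  ct2 <- ct
  ct2["gB", 2:5] <- NA
  q2 <- toy_qpcr(ct2)
  assays(q2, withDimnames = FALSE)$dct <- ct2
  out2 <- negDeltaDeltaCt(q2)
  expect_true(all(is.na(assay(out2, "nddct")["gB", ])))
  expect_identical(qcReport(out2)$centering$tooSparseGenes$adrenal, "gB")

  ## idempotence: recentering already-centered rows changes nothing
  dct3 <- assay(out, "nddct") * -1   # centered rows (medians 0)
  q3 <- toy_qpcr(ct)
  assays(q3, withDimnames = FALSE)$dct <- dct3
  out3 <- negDeltaDeltaCt(q3)
  expect_equal(assay(out3, "nddct"), -dct3)
})

test_that("noiseless synthetic data round-trips through normalization", {
  ## genes half pinned (constant housekeeping trajectories) so the robust
  ## median reference is constant across samples; then -ddCt must equal the
  ## true log2-scale state up to a per-gene constant
  design <- studyDesign("adrenal", "SHR", c(8, 10, 12, 16, 24), 2,
                        as.character(defaultGenePanel(8)$gene))
  v <- rbind(matrix(0.5, 5, 5),                    # 5 pinned genes
             matrix(runif(15, 0.2, 1), 3, 5))      # 3 dynamic genes
  rownames(v) <- paste("adrenal", genePanel(design)$gene, sep = ":")
  traj <- traj_from_matrix(v, c(0, 2, 4, 8, 16))
  q <- sampleQpcrDataset(traj, design, noiseSd = 0, seed = 1)
  nq <- normalizeQpcr(q)
  x <- assay(nq, "nddct")
  meta <- colData(nq)
  for (g in seq_len(8)) {
    for (s in which(meta$strain == "SHR")) {
      a <- match(meta$age_weeks[s], agesWeeks(design))
      got <- x[g, s]
      want <- unname(v[g, a] - median(v[g, ]))
      expect_equal(unname(got), want, tolerance = 1e-10)
    }
  }
})

test_that("reference stability ranking flags unstable candidates", {
  set.seed(3)
  base <- 20 + rnorm(10)
  ct <- rbind(gA = base, gB = base + 2,          # proportional pair
              gC = base + rnorm(10, 0, 2))       # noisy candidate
  q <- toy_qpcr(ct)
  rk <- rankReferenceStability(q)
  expect_identical(rk$gene[3], "gC")
  ## exact-proportional pair contributes a zero pairwise term
  expect_lt(sd(ct["gA", ] - ct["gB", ]), 1e-12)

  ## invariant to adding a constant to one sample (all genes shift equally)
  ct2 <- ct
  ct2[, 4] <- ct[, 4] + 3
  rk2 <- rankReferenceStability(toy_qpcr(ct2))
  expect_identical(rk$gene, rk2$gene)
  expect_equal(rk$stability, rk2$stability, tolerance = 1e-12)

  ## < 3 fully observed candidates: error
  ct3 <- ct
  ct3["gC", 1] <- NA
  expect_error(rankReferenceStability(toy_qpcr(ct3[c(1, 3), ])),
               "insufficient candidates")
})

test_that("the study-mimic fixture reproduces the QC outcome by design", {
  ds <- suppressWarnings(studyMimicDataset(seed = 1))
  expect_identical(dim(assay(ds@qpcr, "ct")), c(96L, 150L))
  f <- filterLowData(ds@qpcr, minPresent = 0.6)
  expect_identical(dim(f), c(92L, 146L))
})
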