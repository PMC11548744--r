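## Build a QpcrSet with a given nddct matrix (bypassing normalization).
with_nddct <- function(x, meta) {
  q <- QpcrSet(x, meta)
  assays(q, withDimnames = FALSE)$nddct <- x
  q
}

test_that("PCA isolates a rank-one group difference on PC1", {
  ## two duplicated sample groups differing in one gene
  x <- matrix(0, 5, 8, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  x["g3", 5:8] <- 4
  meta <- data.frame(strain = rep(c("SHR", "WKY"), each = 4), sex = "F",
                     organ = "adrenal", age_weeks = 8,
                     animal_id = paste0("a", 1:8), chip_id = "chip1",
                     row.names = colnames(x))
  p <- runPca(with_nddct(x, meta))
  expect_gt(p$varianceExplained[1], 0.999)
  expect_identical(rownames(p$loadings)[which.max(abs(p$loadings[, 1]))],
                   "g3")

  ## loadings orthonormal; reconstruction from all components
  set.seed(4)
  x2 <- matrix(rnorm(60), 6, 10,
               dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  meta2 <- data.frame(strain = "SHR", sex = "F", organ = "adrenal",
                      age_weeks = 8, animal_id = paste0("a", 1:10),
                      chip_id = "chip1", row.names = colnames(x2))
  p2 <- runPca(with_nddct(x2, meta2))
  L <- p2$loadings
  expect_lt(max(abs(crossprod(L) - diag(ncol(L)))), 1e-8)
  centered <- t(scale(t(x2), center = TRUE, scale = FALSE))
  recon <- L %*% t(p2$scores)
  expect_lt(max(abs(recon - centered)), 1e-8)

  ## genes with missing values are dropped for the PCA only
  x3 <- x2
  x3["g2", 3] <- NA
  p3 <- runPca(with_nddct(x3, meta2))
  expect_identical(p3$droppedGenes, "g2")
  expect_false("g2" %in% rownames(p3$loadings))
})

test_that("top loading gene lists respect sign, ties and coverage", {
  x <- matrix(0, 5, 8, dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  x["g3", 5:8] <- 4
  x["g1", 5:8] <- -1
  meta <- data.frame(strain = "SHR", sex = "F", organ = "adrenal",
                     age_weeks = 8, animal_id = paste0("a", 1:8),
                     chip_id = "chip1", row.names = colnames(x))
  p <- runPca(with_nddct(x, meta))
  tl <- topLoadingGenes(p, component = 1, n = 1)
  ## the informative gene heads one of the two lists (sign convention free)
  expect_true("g3" %in% c(tl$positive[1], tl$negative[1]))

  tl_all <- topLoadingGenes(p, component = 1, n = 5)
  expect_setequal(union(tl_all$positive, tl_all$negative),
                  paste0("g", 1:5))
  ## sign flip exchanges the lists
  pf <- p
  pf$loadings[, 1] <- -pf$loadings[, 1]
  tlf <- topLoadingGenes(pf, component = 1, n = 5)
  expect_identical(tlf$positive, tl_all$negative)
  expect_identical(tlf$negative, tl_all$positive)
})

## independent textbook sums-of-squares oracle for a balanced 2-factor design
ss_oracle <- function(y, A, B) {
  g <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - g)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - g)^2))
  cellm <- tapply(y, list(A, B), mean)
  ncell <- tapply(y, list(A, B), length)
  ssCells <- sum(ncell * (cellm - g)^2)
  ssAB <- ssCells - ssA - ssB
  ssE <- sum((y - cellm[cbind(A, B)])^2)
  c(A = ssA, B = ssB, AB = ssAB, error = ssE)
}

test_that("two-way ANOVA matches the sums-of-squares oracle", {
  ## 2x2 balanced with cell means (10, 10, 10, 14), n = 3
  mu <- c(10, 10, 10, 14)
  set.seed(7)
  d <- expand.grid(rep = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- mu[as.integer(interaction(d$A, d$B))] + rnorm(12, 0, 1)
  oracle <- ss_oracle(d$y, as.character(d$A), as.character(d$B))

  x <- matrix(d$y, 1, 12, dimnames = list("g1", paste0("s", 1:12)))
  meta <- data.frame(strain = as.character(d$B), sex = "F",
                     organ = "adrenal", age_weeks = ifelse(d$A == "a1", 8, 12),
                     animal_id = paste0("a", 1:12), chip_id = "chip1",
                     row.names = colnames(x))
  res <- twoWayAnova(with_nddct(x, meta))
  st <- res$stats
  f_oracle_A <- (oracle["A"] / 1) / (oracle["error"] / 8)
  f_oracle_B <- (oracle["B"] / 1) / (oracle["error"] / 8)
  f_oracle_AB <- (oracle["AB"] / 1) / (oracle["error"] / 8)
  expect_equal(st$F_age_weeks, unname(f_oracle_A), tolerance = 1e-10)
  expect_equal(st$F_strain, unname(f_oracle_B), tolerance = 1e-10)
  expect_equal(st$F_interaction, unname(f_oracle_AB), tolerance = 1e-10)
  expect_equal(st$p_strain,
               unname(pf(f_oracle_B, 1, 8, lower.tail = FALSE)),
               tolerance = 1e-10)
  ## SS conservation (balanced): parts add to the total
  expect_equal(sum(oracle), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
})

test_that("degenerate (all-equal) data use the F = 0, p = 1 convention", {
  x <- matrix(5, 1, 12, dimnames = list("g1", paste0("s", 1:12)))
  meta <- data.frame(strain = rep(c("SHR", "WKY"), each = 6), sex = "F",
                     organ = "adrenal", age_weeks = rep(c(8, 12), 6),
                     animal_id = paste0("a", 1:12), chip_id = "chip1",
                     row.names = colnames(x))
  res <- twoWayAnova(with_nddct(x, meta))
  expect_identical(res$stats$F_strain, 0)
  expect_identical(res$stats$p_strain, 1)
})

test_that("a 2-unit strain effect at sigma 0.5, n = 3 is reliably detected", {
  ## power over 200 seeded simulations, 5 ages x 2 strains
  hits <- 0L
  for (i in 1:200) {
    set.seed(i)
    d <- expand.grid(rep = 1:3, age = c(8, 10, 12, 16, 24),
                     strain = c("SHR", "WKY"))
    d$y <- ifelse(d$strain == "SHR", 2, 0) + rnorm(30, 0, 0.5)
    x <- matrix(d$y, 1, 30, dimnames = list("g1", paste0("s", 1:30)))
    meta <- data.frame(strain = as.character(d$strain), sex = "F",
                       organ = "adrenal", age_weeks = d$age,
                       animal_id = paste0("a", 1:30), chip_id = "chip1",
                       row.names = colnames(x))
    res <- twoWayAnova(with_nddct(x, meta))
    if (res$stats$p_strain < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

make_sex_set <- function(delta_shr, sex, seed = 1) {
  ## 2 strains x 3 ages x 3 animals, 2 genes; SHR shifted by delta_shr
  set.seed(seed)
  d <- expand.grid(rep = 1:3, age = c(8, 12, 16),
                   strain = c("SHR", "WKY"))
  x <- rbind(
    gA = ifelse(d$strain == "SHR", delta_shr, 0) + rnorm(18, 0, 0.01),
    gB = rnorm(18, 0, 0.01))
  colnames(x) <- paste0("s", seq_len(ncol(x)))
  meta <- data.frame(strain = as.character(d$strain), sex = sex,
                     organ = "adrenal", age_weeks = d$age,
                     animal_id = paste0("a", seq_len(ncol(x))),
                     chip_id = "chip1", row.names = colnames(x))
  with_nddct(x, meta)
}

test_that("sex contrast detects opposite strain effects across sexes", {
  qf <- make_sex_set(+1, "F", seed = 1)
  qm <- make_sex_set(-1, "M", seed = 2)
  res <- sexContrast(qf, qm)
  st <- res$stats[res$stats$gene == "gA", ]
  expect_lt(st$p_sex, 0.05)
  ## deltas near +1 (F) and -1 (M)
  dg <- res$deltas[res$deltas$gene == "gA", ]
  expect_equal(mean(dg$delta[dg$sex == "F"]), 1, tolerance = 0.05)
  expect_equal(mean(dg$delta[dg$sex == "M"]), -1, tolerance = 0.05)

  ## identical inputs: all deltas zero, sex effect null under F=0 convention
  res0 <- sexContrast(make_sex_set(0, "F", 3), make_sex_set(0, "M", 3))
  expect_true(all(abs(res0$deltas$delta) < 0.1))

  ## restriction contract: output genes = intersection of panels
  qm2 <- qm[1, ]   # male panel reduced to gA
  res2 <- sexContrast(qf, qm2)
  expect_identical(res2$sharedGenes, "gA")
  expect_true("gB" %in% res2$excludedGenes)
})

test_that("null p-values for the strain effect are uniform in aggregate", {
  ## pooled p-value distribution over 100 seeded null simulations
  ps <- vapply(1:100, function(i) {
    set.seed(i)
    d <- expand.grid(rep = 1:3, age = c(8, 10, 12, 16, 24),
                     strain = c("SHR", "WKY"))
    x <- matrix(rnorm(30), 1, 30,
                dimnames = list("g1", paste0("s", 1:30)))
    meta <- data.frame(strain = as.character(d$strain), sex = "F",
                       organ = "adrenal", age_weeks = d$age,
                       animal_id = paste0("a", 1:30), chip_id = "chip1",
                       row.names = colnames(x))
    twoWayAnova(with_nddct(x, meta))$stats$p_strain
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})
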