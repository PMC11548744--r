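## Shared fixtures, all built in code at test time.

suppressPackageStartupMessages({
  library(SummarizedExperiment)
  library(S4Vectors)
})

## Small factorial design: 2 strains x 3 ages x 2 organs x 2 animals, 4 genes.
tiny_design <- function(nGenes = 4L, organs = c("adrenal", "kidney"),
                        ages = c(8, 12, 16), reps = 2L) {
  studyDesign(organs = organs, strains = c("SHR", "WKY"), agesWeeks = ages,
              replicatesPerCell = reps,
              genes = as.character(defaultGenePanel(nGenes)$gene))
}

## Hand-built QpcrSet from an explicit Ct matrix; one organ unless given.
toy_qpcr <- function(ct, organ = "adrenal", strain = "SHR", age = 8,
                     chip = "chip1") {
  n <- ncol(ct)
  if (is.null(colnames(ct))) colnames(ct) <- paste0("s", seq_len(n))
  if (is.null(rownames(ct))) rownames(ct) <- paste0("g", seq_len(nrow(ct)))
  meta <- data.frame(
    strain = rep_len(strain, n), sex = "F", organ = rep_len(organ, n),
    age_weeks = rep_len(age, n),
    animal_id = paste0("a", seq_len(n)), chip_id = rep_len(chip, n),
    row.names = colnames(ct))
  QpcrSet(ct, meta)
}

## A designed, identifiable 3-node network: well-separated eigenvalues
## (-0.54, -0.27, -0.12) and weakly correlated trajectories, so the
## coupling structure is recoverable from a single trajectory.
fixture_network3 <- function() {
  g3 <- c("Th", "Ren", "Il1b")
  K <- matrix(c(-0.35, 0, 0.12,
                0.2, -0.08, 0,
                0, -0.15, -0.5), 3, 3, byrow = TRUE)
  nd <- DataFrame(organ = "adrenal", gene = g3)
  labels <- paste("adrenal", g3, sep = ":")
  dimnames(K) <- list(labels, labels)
  new("InteractionNetwork", K = K, nodeData = nd,
      diagnostics = list(kind = "test_fixture"))
}

fixture_traj3 <- function(nGrid = 257L, T = 16) {
  net <- fixture_network3()
  simulateTrajectories(net, seq(0, T, length.out = nGrid), c(0.9, 0.3, 0.6))
}

## Config used by recovery tests: pure lasso, penalty grid to 1e-8 so the
## zero-noise shrinkage bias can vanish.
recovery_config <- function(M = 8L) {
  defaultHmfConfig(M = M, l1Ratio = 1,
                   penaltyGrid = 10^seq(-8, 0, length.out = 25L))
}

## TrajectorySet from an explicit matrix.
traj_from_matrix <- function(values, times, organ = "adrenal") {
  if (is.null(rownames(values)))
    rownames(values) <- paste(organ, paste0("g", seq_len(nrow(values))),
                              sep = ":")
  genes <- sub("^[^:]*:", "", rownames(values))
  orgs <- sub(":.*$", "", rownames(values))
  new("TrajectorySet", values = values, times = times,
      nodeData = DataFrame(organ = orgs, gene = genes),
      scaling = DataFrame(min = numeric(0), max = numeric(0)))
}
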