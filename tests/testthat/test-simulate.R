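test_that("zero divergence targets yield identical sequences; seeds reproduce bit-identically", {
  spec0 <- taxonomySpec(2, 2, 2, itsTargets = c(within = 0, species = 0,
                                                genus = 0))
  sim0 <- simulateDataset(spec0, seed = 5)
  for (a in sim0$alignments)
    expect_length(unique(as.character(sequenceSet(a))), 1L)

  s1 <- simulateDataset(taxonomySpec(2, 2, 2), seed = 7)
  s2 <- simulateDataset(taxonomySpec(2, 2, 2), seed = 7)
  expect_identical(as.character(sequenceSet(s1$alignments$ITS)),
                   as.character(sequenceSet(s2$alignments$ITS)))
  s3 <- simulateDataset(taxonomySpec(2, 2, 2), seed = 8)
  expect_false(identical(as.character(sequenceSet(s1$alignments$ITS)),
                         as.character(sequenceSet(s3$alignments$ITS))))
})

test_that("saturating targets are rejected and levels must be ordered", {
  expect_error(taxonomySpec(itsTargets = c(within = 0.01, species = 0.05,
                                           genus = 0.76)), "0.75")
  expect_error(taxonomySpec(itsTargets = c(within = 0.05, species = 0.01,
                                           genus = 0.18)), "non-decreasing")
  expect_error(jcDistance(0.8), "0.75")
})

test_that("between-genus ITS divergence is calibrated to its target", {
  # 2 genera x 1 species x 2 seqs at length 5000; target 0.18
  target <- 0.18
  L <- 5000L
  ps <- vapply(1:20, function(s) {
    sim <- simulateDataset(taxonomySpec(2, 1, 2,
      locusLengths = c(ITS = L, LSU28S = 100L, SSU18S = 100L)), seed = s)
    v <- distValues(distanceMatrix(sim$alignments$ITS))
    st <- sim$truth$genus[match(sub("_ITS$", "",
                                    recordIds(sim$alignments$ITS)),
                                sim$truth$strain)]
    mean(v[st == st[1], st != st[1]])
  }, 0)
  tol <- 3 * sqrt(target * (1 - target) / L) / sqrt(20)
  expect_lt(abs(mean(ps) - target), tol)
})

test_that("per-level mean divergences converge to their targets at long sequences", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3,
    locusLengths = c(ITS = 5000L, LSU28S = 5000L, SSU18S = 5000L)), seed = 33)
  truth <- sim$truth
  for (loc in c("ITS", "LSU28S")) {
    scale <- if (loc == "ITS") 1 else 0.35
    v <- distValues(distanceMatrix(sim$alignments[[loc]]))
    strain <- sub(paste0("_", loc, "$"), "", rownames(v))
    sp <- truth$species[match(strain, truth$strain)]
    ge <- truth$genus[match(strain, truth$strain)]
    idx <- which(upper.tri(v), arr.ind = TRUE)
    cls <- ifelse(sp[idx[, 1]] == sp[idx[, 2]], "w",
                  ifelse(ge[idx[, 1]] == ge[idx[, 2]], "s", "g"))
    targets <- c(w = 0.01, s = 0.05, g = 0.18) * scale
    for (cl in c("w", "s", "g")) {
      obs <- mean(v[idx][cls == cl])
      tol <- 3 * sqrt(targets[[cl]] * (1 - targets[[cl]]) / 5000) + 2 / 5000
      expect_lt(abs(obs - targets[[cl]]), tol)
    }
  }
})

test_that("planted levels separate cleanly at default lengths", {
  # within-species max < between-species min < between-genus min
  ok <- vapply(1:25, function(s) {
    sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = s)
    v <- distValues(distanceMatrix(sim$alignments$ITS))
    truth <- sim$truth
    strain <- sub("_ITS$", "", rownames(v))
    sp <- truth$species[match(strain, truth$strain)]
    ge <- truth$genus[match(strain, truth$strain)]
    idx <- which(upper.tri(v), arr.ind = TRUE)
    w <- v[idx][sp[idx[, 1]] == sp[idx[, 2]]]
    s2 <- v[idx][sp[idx[, 1]] != sp[idx[, 2]] & ge[idx[, 1]] == ge[idx[, 2]]]
    g <- v[idx][ge[idx[, 1]] != ge[idx[, 2]]]
    max(w) < min(s2) && min(s2) < min(g)
  }, NA)
  expect_gte(mean(ok), 0.95)
})

test_that("degradation drops loci and truncates without touching retained residues", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = 9)
  # identity when nothing is requested
  same <- degradeDataset(sim, dropLocusFraction = 0, seed = 1)
  expect_identical(as.character(sequenceSet(same$alignments$ITS)),
                   as.character(sequenceSet(sim$alignments$ITS)))

  deg <- degradeDataset(sim, dropLocusFraction = 0.25, dropLocus = "ITS",
                        seed = 2)
  nIts <- length(deg$alignments$ITS)
  expect_equal(nIts, length(sim$alignments$ITS) - 3L)  # 25% of 12 strains
  # retained records are untouched at every locus
  keptIds <- recordIds(deg$alignments$ITS)
  expect_identical(as.character(sequenceSet(deg$alignments$ITS)),
                   as.character(sequenceSet(sim$alignments$ITS))[keptIds])
  expect_identical(as.character(sequenceSet(deg$alignments$LSU28S)),
                   as.character(sequenceSet(sim$alignments$LSU28S)))
  # truth labels unchanged
  expect_identical(deg$truth, sim$truth)
  # metadata pruned in step
  expect_false(any(deg$metadata$locus == "ITS" &
                     !(deg$metadata$strain %in%
                         recordInfo(deg$alignments$ITS)$strain)))

  # truncation pushes a record below the representative length bar
  tr <- degradeDataset(sim, truncateTo = 381, truncateFraction = 1 / 12,
                       seed = 3)
  lens <- pdelim:::ungappedLength(sequenceSet(tr$alignments$ITS))
  expect_equal(sum(lens == 381L), 1L)
  expect_equal(sum(lens == 500L), 11L)
})

test_that("recovery scoring: perfect, degenerate and permuted predictions", {
  truth <- data.frame(strain = sprintf("s%d", 1:6),
                      genus = rep(c("GA", "GB"), each = 3),
                      species = rep(c("x", "y", "z"), each = 2))
  perfect <- list(species = setNames(rep(c("1", "2", "3"), each = 2),
                                     truth$strain),
                  genus = setNames(rep(c("A", "B"), each = 3), truth$strain))
  sc <- scoreRecovery(perfect, truth)
  expect_equal(sc$ariSpecies, 1.0)
  expect_equal(sc$ariGenus, 1.0)
  expect_true(sc$exactSpecies && sc$exactGenus)

  # all records lumped vs 3 true species: hand-computed ARI is exactly 0
  # (sum C(nij,2) = 3 equals its expectation 15*3/15; see contingency form)
  lumped <- list(species = setNames(rep("all", 6), truth$strain),
                 genus = setNames(rep("all", 6), truth$strain))
  sc0 <- scoreRecovery(lumped, truth)
  expect_equal(sc0$ariSpecies, 0)
  expect_lte(sc0$ariSpecies, 0)
  expect_true(all(sc0$confusion$nPredictedClusters == 1L))

  # relabelling leaves the index unchanged
  relab <- list(species = setNames(rep(c("Q9", "Q1", "Q5"), each = 2),
                                   truth$strain),
                genus = perfect$genus)
  expect_equal(scoreRecovery(relab, truth)$ariSpecies, 1.0)

  expect_error(scoreRecovery(list(species = setNames("a", "s99"),
                                  genus = setNames("a", "s99")), truth),
               "different strains")
})

test_that("the generating tree mirrors the planted hierarchy", {
  sim <- simulateDataset(taxonomySpec(2, 2, 2), seed = 10)
  tr <- sim$tree
  expect_setequal(tr$tip.label, sim$truth$strain)
  for (g in unique(sim$truth$genus)) {
    tips <- sim$truth$strain[sim$truth$genus == g]
    expect_true(pdelim:::isMonophyleticSplit(tr, tips))
  }
})
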