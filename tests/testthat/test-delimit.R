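mkGroup <- function(ids, within = c(0, 0.01), locus = "ITS") {
  new("TaxonGroup", groupId = "G1", memberIds = ids, locus = locus,
      withinRange = within, nearestGroup = NA_character_,
      betweenMin = NA_real_, representatives = character())
}

test_that("representative selection filters by length and maximises distance", {
  # lengths 400 / 470 / 500 / 520: the 400 nt record is not a candidate
  seqs <- c(a = strrep("A", 400), b = strrep("C", 470),
            c = strrep("G", 500), d = strrep("T", 520))
  seqs <- vapply(seqs, function(s) paste0(s, strrep("-", 520 - nchar(s))), "")
  aln <- LocusAlignment(seqs, "ITS")
  ids <- c("a", "b", "c", "d")
  v <- matrix(0.2, 4, 4, dimnames = list(ids, ids))
  diag(v) <- 0
  v["b", "c"] <- v["c", "b"] <- 0.25     # unique maximal pair among candidates
  v["a", "d"] <- v["d", "a"] <- 0.30     # larger, but involves the short record
  dm <- asPDist(v)
  grp <- mkGroup(ids, within = c(0.2, 0.3))
  sel <- selectRepresentatives(grp, aln, dm, thresholdProfile(), k = 2)
  expect_true(all(c("b", "c") %in% sel))
  expect_false("a" %in% sel)

  # exhaustive pair-scan oracle on random matrices (all candidates long enough)
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- 5L
      ids <- sprintf("m%d", 1:n)
      v <- matrix(0, n, n, dimnames = list(ids, ids))
      v[upper.tri(v)] <- runif(n * (n - 1) / 2, 0.01, 0.02)
      v <- v + t(v)
      best <- which(v == max(v), arr.ind = TRUE)[1, ]
      aln <- LocusAlignment(setNames(rep(strrep("A", 500), n), ids), "ITS")
      sel <- selectRepresentatives(mkGroup(ids, c(0.01, 0.02)), aln,
                                   asPDist(v), thresholdProfile(), k = 2)
      expect_setequal(sel, ids[best])
    }
  })
})

test_that("representative selection: singletons, fallback warning, diverse groups", {
  aln1 <- LocusAlignment(c(solo = strrep("A", 100)), "ITS")
  expect_identical(selectRepresentatives(mkGroup("solo",
                                                 c(NA_real_, NA_real_)), aln1,
                                         asPDist(matrix(0, 1, 1,
                                           dimnames = list("solo", "solo")))),
                   "solo")

  # all members below the length bar: warning, then unfiltered candidates
  ids <- c("x", "y")
  aln2 <- LocusAlignment(setNames(rep(strrep("A", 100), 2), ids), "ITS")
  v <- matrix(c(0, .01, .01, 0), 2, dimnames = list(ids, ids))
  expect_warning(sel <- selectRepresentatives(mkGroup(ids), aln2, asPDist(v)),
                 "450")
  expect_setequal(sel, ids)

  # a chained group broader than the species threshold gets extra
  # representatives covering each sub-cluster
  ids <- c("p1", "p2", "q1", "q2")
  v <- matrix(0.05, 4, 4, dimnames = list(ids, ids))
  diag(v) <- 0
  v["p1", "p2"] <- v["p2", "p1"] <- 0.01
  v["q1", "q2"] <- v["q2", "q1"] <- 0.01
  aln3 <- LocusAlignment(setNames(rep(strrep("A", 500), 4), ids), "ITS")
  sel <- selectRepresentatives(mkGroup(ids, within = c(0.01, 0.05)), aln3,
                               asPDist(v), thresholdProfile())
  expect_true(any(c("p1", "p2") %in% sel) && any(c("q1", "q2") %in% sel))

  # type strains win ties
  meta <- data.frame(strain = ids, taxonLabel = NA,
                     isTypeStrain = c(FALSE, FALSE, TRUE, FALSE), source = NA)
  aln4 <- LocusAlignment(setNames(rep(strrep("A", 500), 4), ids), "ITS", meta)
  vt <- matrix(0.02, 4, 4, dimnames = list(ids, ids))
  diag(vt) <- 0
  sel <- selectRepresentatives(mkGroup(ids, c(0.02, 0.02)), aln4, asPDist(vt),
                               thresholdProfile())
  expect_true("q1" %in% sel)
})

test_that("the rank rule engine reproduces the printed decision patterns", {
  # strongly divergent type strain with distinct morphology: new genus
  d1 <- assignRank(0.17, 0.07, hasTypeStrain = TRUE,
                   morphologyDistinct = TRUE)
  expect_identical(decisionRank(d1), "distinct_genus")
  expect_identical(decisionStatus(d1), "established")

  # congeneric species pattern: ITS 5%, 28S 2%
  d2 <- assignRank(0.05, 0.02, hasTypeStrain = TRUE)
  expect_identical(decisionRank(d2), "distinct_species")
  expect_identical(decisionStatus(d2), "established")
  expect_true(any(grepl("same genus", evidence(d2))))

  # 28S-only divergence at 10%, no type strain: putative new genus
  d3 <- assignRank(NA, 0.10)
  expect_identical(decisionRank(d3), "distinct_genus")
  expect_identical(decisionStatus(d3), "putative")
  expect_false(decisionFlags(d3)[["has_its"]])

  # identical sequences: same species
  d4 <- assignRank(0.0, 0.0, hasTypeStrain = TRUE)
  expect_identical(decisionRank(d4), "same_species")

  # contradiction between loci: borderline + inconclusive
  d5 <- assignRank(0.01, 0.08, hasTypeStrain = TRUE)
  expect_identical(decisionRank(d5), "borderline")
  expect_identical(decisionStatus(d5), "inconclusive")

  expect_error(assignRank(NA, NA), "no locus")
})

test_that("assignRank is a pure function of distances, flags and profile", {
  grid <- expand.grid(its = c(NA, 0.01, 0.05, 0.09, 0.13),
                      lsu = c(NA, 0.005, 0.03, 0.06),
                      type = c(TRUE, FALSE), morph = c(TRUE, FALSE))
  for (r in seq_len(nrow(grid))) {
    if (is.na(grid$its[r]) && is.na(grid$lsu[r])) next
    a <- assignRank(grid$its[r], grid$lsu[r], hasTypeStrain = grid$type[r],
                    morphologyDistinct = grid$morph[r])
    b <- assignRank(grid$its[r], grid$lsu[r], hasTypeStrain = grid$type[r],
                    morphologyDistinct = grid$morph[r])
    expect_identical(decisionRank(a), decisionRank(b))
    expect_identical(decisionStatus(a), decisionStatus(b))
    expect_gte(length(evidence(a)), 1L)
    # morphology lowers the genus bar into the 8-12% ITS band
    if (!is.na(grid$its[r]) && grid$its[r] == 0.09 && grid$morph[r] &&
        (is.na(grid$lsu[r]) || grid$lsu[r] > 0.01))
      expect_identical(decisionRank(a), "distinct_genus")
  }
})

test_that("delimitation recovers planted partitions and refines genus by species", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = 3)
  del <- delimitDataset(sim$alignments)
  sc <- scoreRecovery(del, sim$truth)
  expect_equal(sc$ariSpecies, 1.0)
  expect_equal(sc$ariGenus, 1.0)
  # species partition refines genus partition
  tab <- unique(data.frame(sp = speciesPartition(del),
                           ge = genusPartition(del)))
  expect_false(anyDuplicated(tab$sp) > 0)
  # every species has a type strain and ITS here: established
  expect_true(all(speciesInfo(del)$status == "established"))

  # single-species dataset: one species, one genus, no distinct_* decisions
  one <- simulateDataset(taxonomySpec(1, 1, 4), seed = 2)
  delOne <- delimitDataset(one$alignments)
  expect_length(unique(speciesPartition(delOne)), 1L)
  expect_length(unique(genusPartition(delOne)), 1L)
  expect_length(decisions(delOne), 0L)
})

test_that("delimitation is invariant to record order", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = 6)
  del1 <- delimitDataset(sim$alignments)
  shuffled <- withr::with_seed(1, lapply(sim$alignments, function(a)
    a[sample(length(a))]))
  del2 <- delimitDataset(shuffled)
  expect_identical(speciesPartition(del1)[names(speciesPartition(del2))],
                   speciesPartition(del2))
  expect_identical(genusPartition(del1)[names(genusPartition(del2))],
                   genusPartition(del2))
})

test_that("a species with only 28S data is carried through as putative", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = 4)
  # drop ITS for every strain of one true species
  victims <- sim$truth$strain[sim$truth$species == sim$truth$species[1]]
  its <- sim$alignments$ITS
  keep <- !(as.character(recordInfo(its)$strain) %in% victims)
  sim$alignments$ITS <- its[keep]
  del <- delimitDataset(sim$alignments)
  spOfVictim <- speciesPartition(del)[victims[1]]
  info <- speciesInfo(del)
  row <- info[info$speciesId == spOfVictim, ]
  expect_false(row$hasIts)
  expect_identical(row$status, "putative")
  # the putative species still lands in its own genus assignment
  expect_true(spOfVictim %in% info$speciesId)
})

test_that("18S report declares overlapping ranges non-discriminative", {
  sim <- simulateDataset(taxonomySpec(2, 2, 3), seed = 5)
  del <- delimitDataset(sim$alignments)
  dm18 <- distanceMatrix(sim$alignments$SSU18S)
  strainOf <- setNames(as.character(recordInfo(sim$alignments$SSU18S)$strain),
                       recordIds(sim$alignments$SSU18S))
  rep18 <- ssuReport(dm18, speciesPartition(del), genusPartition(del),
                     strainOf)
  expect_identical(rep18$verdict, "non-discriminative")

  # identical 18S across all records: all ranges zero, non-discriminative
  ids <- sprintf("r%d", 1:4)
  same <- LocusAlignment(setNames(rep("ACGTACGT", 4), ids), "SSU18S")
  sp <- setNames(c("S1", "S1", "S2", "S2"), ids)
  ge <- setNames(c("G1", "G1", "G2", "G2"), ids)
  repSame <- ssuReport(distanceMatrix(same), sp, ge)
  expect_identical(repSame$verdict, "non-discriminative")
  expect_true(all(repSame$classes$max == 0, na.rm = TRUE))

  # sanity inversion: planted 18S gap 4% vs within 0% is discriminative
  gap <- LocusAlignment(setNames(c(strrep("A", 100), strrep("A", 100),
    paste0(strrep("C", 4), strrep("A", 96)),
    paste0(strrep("C", 4), strrep("A", 96))), ids), "SSU18S")
  repGap <- ssuReport(distanceMatrix(gap), sp, ge)
  expect_identical(repGap$verdict, "discriminative")
})
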