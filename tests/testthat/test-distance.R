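test_that("pDistance honours the pairwise-deletion contract", {
  expect_equal(pDistance("ACGT", "ACGT"), list(p = 0, nCompared = 4L))
  expect_equal(pDistance("ACGT", "ACGA"), list(p = 0.25, nCompared = 4L))
  d <- pDistance("AC-TN", "ACGTA")
  expect_equal(d$p, 0)
  expect_equal(d$nCompared, 3L)       # '-' and 'N' columns excluded
  expect_error(pDistance("ACGT", "ACG"), "equal length")
  # zero overlap is missing, not 0 or 1
  expect_true(is.na(pDistance("NN--", "AC??")$p))
})

test_that("pDistance is symmetric and bounded on random gappy pairs", {
  withr::with_seed(42, {
    for (i in 1:25) {
      aln <- randomAlignment(2, 80, gapProb = 0.2, ambProb = 0.1)
      s <- as.character(sequenceSet(aln))
      ab <- pDistance(s[1], s[2])
      ba <- pDistance(s[2], s[1])
      expect_identical(ab, ba)
      if (!is.na(ab$p)) expect_true(ab$p >= 0 && ab$p <= 1)
    }
  })
})

test_that("distanceMatrix equals looped pDistance calls and the site oracle", {
  withr::with_seed(7, {
    aln <- randomAlignment(10, 200, gapProb = 0.15, ambProb = 0.08)
    dm <- distanceMatrix(aln)
    s <- as.character(sequenceSet(aln))
    o <- oracleDistanceMatrix(aln)
    expect_equal(distValues(dm), o$values)
    expect_identical(nCompared(dm), o$nCompared)
    for (i in 1:9) for (j in (i + 1):10) {
      loop <- pDistance(s[i], s[j])
      expect_equal(distValues(dm)[i, j], loop$p)
    }
  })
})

test_that("distanceMatrix matches ape's raw pairwise-deletion distance", {
  # independent cross-check against the established implementation, on a
  # gap-free alignment (ape handles ambiguity partial-matching differently)
  withr::with_seed(13, {
    aln <- randomAlignment(8, 150, gapProb = 0, ambProb = 0)
    dm <- distanceMatrix(aln)
    bin <- ape::as.DNAbin(strsplit(tolower(as.character(sequenceSet(aln))), ""))
    ref <- as.matrix(ape::dist.dna(bin, model = "raw",
                                   pairwise.deletion = TRUE))
    expect_equal(unname(distValues(dm)), unname(ref), tolerance = 1e-12)
  })
})

test_that("distance matrix contracts: identical records, missing pairs, <2 records", {
  dm <- distanceMatrix(LocusAlignment(c(a = "ACGT", b = "ACGT"), "ITS"))
  expect_equal(unname(distValues(dm)), matrix(0, 2, 2))
  # one pair with zero overlap stays missing, other pairs defined
  aln <- LocusAlignment(c(a = "ACGTNNNN", b = "ACGANNNN", c = "NNNNACGT"),
                        "ITS")
  v <- distValues(distanceMatrix(aln))
  expect_true(is.na(v["a", "c"]) && is.na(v["b", "c"]))
  expect_equal(v["a", "b"], 0.25)
  expect_error(distanceMatrix(LocusAlignment(c(a = "ACGT"), "ITS")),
               "at least 2")
})

test_that("column exclusion is local: removing an excluded column leaves a pair's distance unchanged", {
  withr::with_seed(99, {
    aln <- randomAlignment(4, 60, gapProb = 0.25, ambProb = 0.1)
    s <- as.character(sequenceSet(aln))
    ch1 <- strsplit(s[1], "")[[1]]
    ch2 <- strsplit(s[2], "")[[1]]
    excl <- which(!(ch1 %in% c("A", "C", "G", "T")) |
                    !(ch2 %in% c("A", "C", "G", "T")))
    if (length(excl)) {
      keep <- setdiff(seq_along(ch1), excl[1])
      d1 <- pDistance(s[1], s[2])
      d2 <- pDistance(paste(ch1[keep], collapse = ""),
                      paste(ch2[keep], collapse = ""))
      expect_identical(d1$p, d2$p)
    }
  })
})

test_that("bootstrap SEs: zero for identical pairs, deterministic per seed, near the binomial closed form", {
  aln <- LocusAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC", c = "ACGTACGAAC"),
                        "ITS")
  se1 <- distSE(bootstrapSE(aln, replicates = 50, seed = 5))
  se2 <- distSE(bootstrapSE(aln, replicates = 50, seed = 5))
  expect_identical(se1, se2)                  # same seed -> bit-identical
  expect_equal(se1["a", "b"], 0)              # identical sequences

  # gap-free pair with known p: bootstrap SE approximates sqrt(p(1-p)/L)
  withr::with_seed(3, {
    L <- 400L
    base <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                  collapse = "")
    ch <- strsplit(base, "")[[1]]
    flip <- seq_len(60)                        # p = 0.15 exactly
    ch[flip] <- vapply(ch[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    pair <- LocusAlignment(c(x = base, y = paste(ch, collapse = "")), "ITS")
    B <- 2000L
    se <- distSE(bootstrapSE(pair, replicates = B, seed = 8))["x", "y"]
    p <- 0.15
    target <- sqrt(p * (1 - p) / L)
    mcSE <- target / sqrt(2 * (B - 1))         # SD of a bootstrap SD estimate
    expect_lt(abs(se - target), 3 * mcSE + 0.1 * target)
  })

  # analytic option
  sa <- distSE(bootstrapSE(aln, seed = 1, method = "analytic"))
  expect_equal(sa["a", "c"], sqrt(0.1 * 0.9 / 10))
})

test_that("percent reporting rounds half away from zero and dashes missing values", {
  expect_identical(percentReport(c(0.004, 0.135, 0.1099, 0.125)),
                   c(0L, 14L, 11L, 13L))
  expect_identical(formatPercent(NA_real_), "—")
  expect_identical(formatPercent(0.155), "16%")
})

test_that("distance matrices write as square and long TSV", {
  dm <- distanceMatrix(LocusAlignment(c(a = "ACGT", b = "ACGA", c = "TCGA"),
                                      "ITS"))
  sq <- withr::local_tempfile(fileext = ".tsv")
  lg <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(dm, sq, "square")
  writeDistanceMatrix(dm, lg, "long")
  sqt <- read.delim(sq, check.names = FALSE)
  expect_identical(sqt$id, c("a", "b", "c"))
  expect_equal(sqt[["b"]], c(0.25, 0, 0.25))
  lgt <- read.delim(lg)
  expect_equal(nrow(lgt), 3L)
  expect_equal(lgt$p[lgt$id_a == "a" & lgt$id_b == "c"], 0.5)
})
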