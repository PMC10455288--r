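# Truth-labelled multi-locus simulator of hierarchical rDNA divergence.
#
# Jukes-Cantor substitution (uniform rates, no indels) along a fixed
# genus/species/individual hierarchy. Edge lengths (expected substitutions
# per site) are chosen so that the EXPECTED OBSERVED p-distance between
# two tips at each level matches the requested target, via the JC
# inversion d = -(3/4) log(1 - (4/3) p). Gap/missing structure is
# injected afterwards by degradeDataset(), never by the evolution model.

#' Jukes-Cantor distance from an observed p-distance
#'
#' @param p Proportion(s) of differing sites, each < 0.75.
#' @return Expected substitutions per site.
#' @export
jcDistance <- function(p) {
  if (any(p >= 0.75)) stop("p >= 0.75 saturates the Jukes-Cantor model")
  -0.75 * log(1 - 4 * p / 3)
}

# expected observed p after evolving a path of d substitutions/site
jcExpectedP <- function(d) 0.75 * (1 - exp(-4 * d / 3))

#' Specify a simulated taxonomy
#'
#' Defines the hierarchical divergence structure the delimitation analysis
#' assumes: within-species ITS p-distance about 1\% (below the 3\%
#' species bar), between congeneric species about 5\% (inside the 3-11\%
#' band), between genera about 18\%; 28S divergence scaled to roughly a
#' third of ITS and 18S nearly invariant (5\% of ITS), mirroring the
#' empirical ITS > 28S >> 18S ordering of ribosomal loci.
#'
#' @param nGenera Number of genera.
#' @param speciesPerGenus Species per genus (scalar or per-genus vector).
#' @param seqsPerSpecies Sequences per species (scalar or recycled vector).
#' @param locusLengths Named integer vector of per-locus lengths (>= 50).
#' @param itsTargets Target observed p-distances for ITS at the three
#'   levels `within`, `species`, `genus` (non-decreasing, < 0.75).
#' @param locusScale Named multipliers applied to the ITS targets per
#'   locus.
#' @return A list of class `TaxonomySpec`.
#' @export
taxonomySpec <- function(nGenera = 3L, speciesPerGenus = 3L,
                         seqsPerSpecies = 4L,
                         locusLengths = c(ITS = 500L, LSU28S = 800L,
                                          SSU18S = 1000L),
                         itsTargets = c(within = 0.01, species = 0.05,
                                        genus = 0.18),
                         locusScale = c(ITS = 1, LSU28S = 0.35,
                                        SSU18S = 0.05)) {
  stopifnot(nGenera >= 1L, all(speciesPerGenus >= 1L),
            all(seqsPerSpecies >= 1L), all(locusLengths >= 50L),
            identical(names(itsTargets), c("within", "species", "genus")))
  expectedP <- lapply(locusScale, function(s) itsTargets * s)
  for (p in expectedP) {
    if (any(p >= 0.75)) stop("expected_p >= 0.75 saturates Jukes-Cantor")
    if (is.unsorted(p)) stop("expected_p must be non-decreasing with level")
  }
  structure(list(nGenera = as.integer(nGenera),
                 speciesPerGenus = rep_len(as.integer(speciesPerGenus), nGenera),
                 seqsPerSpecies = as.integer(seqsPerSpecies),
                 locusLengths = locusLengths,
                 expectedP = expectedP),
            class = "TaxonomySpec")
}

# Apply substitutions for an edge of length d (expected substitutions per
# site) to an integer-coded sequence. The per-edge substitution
# probability q = jcExpectedP(d) already folds in multiple hits, so edges
# compose: the expected observed p over a path equals jcExpectedP(sum d).
# The number of substituted sites is planted as the fixed count round(qL)
# at uniformly sampled distinct sites (each changed to a uniformly chosen
# different base), so realized divergences concentrate at their targets
# instead of carrying full binomial noise; see the methods vignette.
jcEvolve <- function(seq, d) {
  q <- jcExpectedP(d)
  n <- round(q * length(seq))
  if (n > 0L) {
    hit <- sample.int(length(seq), n)
    seq[hit] <- ((seq[hit] - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
  }
  seq
}

#' Simulate a truth-labelled multi-locus dataset
#'
#' Draws a root sequence per locus uniformly over A/C/G/T, then evolves it
#' down a genus/species/individual hierarchy under Jukes-Cantor with edge
#' lengths calibrated so the expected observed p-distance between tips
#' matches the per-level targets of the [taxonomySpec()]. All loci share
#' the topology (star-like within species); rates differ per locus. The
#' lexicographically first strain of each species is flagged as its type
#' strain. Fully reproducible for a fixed seed.
#'
#' @param spec A `TaxonomySpec` from [taxonomySpec()].
#' @param seed Integer seed (caller's RNG state restored).
#' @return A list with `alignments` (named list of
#'   [LocusAlignment-class]), `metadata` (data.frame in the sidecar
#'   dialect), `truth` (data.frame strain/genus/species) and `tree`
#'   (the generating topology as [ape::phylo], ITS-scaled edge lengths).
#' @examples
#' sim <- simulateDataset(taxonomySpec(2, 1, 2), seed = 1)
#' names(sim$alignments)
#' @export
simulateDataset <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "TaxonomySpec"))
  withSeed(seed, {
    # strain layout
    strains <- character(); genusOf <- character(); speciesOf <- character()
    for (g in seq_len(spec$nGenera)) {
      for (s in seq_len(spec$speciesPerGenus[g])) {
        for (r in seq_len(spec$seqsPerSpecies)) {
          strains <- c(strains, sprintf("g%02ds%02dr%02d", g, s, r))
          genusOf <- c(genusOf, sprintf("Genus_%02d", g))
          speciesOf <- c(speciesOf, sprintf("Species_%02d_%02d", g, s))
        }
      }
    }
    isType <- !duplicated(speciesOf)  # lexicographically first per species
    alignments <- list()
    metadata <- NULL
    for (loc in names(spec$locusLengths)) {
      L <- spec$locusLengths[[loc]]
      p <- spec$expectedP[[loc]]
      dW <- jcDistance(p[["within"]])
      dS <- jcDistance(p[["species"]])
      dG <- jcDistance(p[["genus"]])
      eI <- dW / 2                 # species ancestor -> tip
      eS <- dS / 2 - eI            # genus ancestor -> species ancestor
      eG <- dG / 2 - eS - eI       # root -> genus ancestor
      root <- sample.int(4L, L, replace = TRUE)
      seqs <- character(length(strains))
      k <- 0L
      for (g in seq_len(spec$nGenera)) {
        ganc <- jcEvolve(root, eG)
        for (s in seq_len(spec$speciesPerGenus[g])) {
          sanc <- jcEvolve(ganc, eS)
          for (r in seq_len(spec$seqsPerSpecies)) {
            k <- k + 1L
            seqs[k] <- paste(c("A", "C", "G", "T")[jcEvolve(sanc, eI)],
                             collapse = "")
          }
        }
      }
      ids <- paste(strains, loc, sep = "_")
      names(seqs) <- ids
      meta <- DataFrame(strain = strains, taxonLabel = speciesOf,
                        isTypeStrain = isType, source = "synthetic")
      alignments[[loc]] <- LocusAlignment(seqs, loc, meta)
      metadata <- rbind(metadata, data.frame(
        record_id = ids, strain = strains, taxon_label = speciesOf,
        locus = loc, is_type_strain = isType, source = "synthetic",
        stringsAsFactors = FALSE))
    }
    truth <- data.frame(strain = strains, genus = genusOf,
                        species = speciesOf, stringsAsFactors = FALSE)
    list(alignments = alignments, metadata = metadata, truth = truth,
         tree = generatingTree(spec, strains, genusOf, speciesOf))
  })
}

# multifurcating genus/species/individual topology with ITS-scaled edges
generatingTree <- function(spec, strains, genusOf, speciesOf) {
  p <- spec$expectedP[[1L]]
  eI <- jcDistance(p[["within"]]) / 2
  eS <- jcDistance(p[["species"]]) / 2 - eI
  eG <- jcDistance(p[["genus"]]) / 2 - eS - eI
  gclades <- vapply(unique(genusOf), function(g) {
    sp <- unique(speciesOf[genusOf == g])
    sclades <- vapply(sp, function(s) {
      tips <- strains[speciesOf == s]
      sprintf("(%s):%g", paste(sprintf("%s:%g", tips, eI), collapse = ","), eS)
    }, "")
    sprintf("(%s):%g", paste(sclades, collapse = ","), eG)
  }, "")
  ape::read.tree(text = sprintf("(%s);", paste(gclades, collapse = ",")))
}

#' Degrade a simulated dataset
#'
#' Emulates the missing-locus records and short sequences that real
#' datasets carry: removes one locus from a random fraction of strains,
#' and/or truncates a fraction of a locus's records to a fixed number of
#' leading residues (the remainder becoming `?`), pushing them below the
#' representative length bar. Truth labels are unchanged; residues of
#' retained loci are never altered.
#'
#' @param dataset A list as returned by [simulateDataset()].
#' @param dropLocusFraction Fraction of strains losing `dropLocus`.
#' @param dropLocus Locus to drop (default `"ITS"`).
#' @param truncateTo Keep only this many leading residues for truncated
#'   records (`NULL` = no truncation).
#' @param truncateFraction Fraction of `truncateLocus` records truncated.
#' @param truncateLocus Locus to truncate (default `"ITS"`).
#' @param seed Integer seed.
#' @return The degraded dataset (same shape).
#' @export
degradeDataset <- function(dataset, dropLocusFraction = 0,
                           dropLocus = "ITS", truncateTo = NULL,
                           truncateFraction = 0, truncateLocus = "ITS",
                           seed = 1L) {
  stopifnot(dropLocusFraction >= 0, dropLocusFraction <= 1,
            truncateFraction >= 0, truncateFraction <= 1)
  withSeed(seed, {
    if (dropLocusFraction > 0 && dropLocus %in% names(dataset$alignments)) {
      a <- dataset$alignments[[dropLocus]]
      strains <- as.character(recordInfo(a)$strain)
      nDrop <- round(dropLocusFraction * length(strains))
      if (nDrop >= length(strains)) {
        dataset$alignments[[dropLocus]] <- NULL
        dropped <- strains
      } else if (nDrop > 0L) {
        dropped <- sort(sample(strains, nDrop))
        keep <- !(strains %in% dropped)
        dataset$alignments[[dropLocus]] <- a[keep]
      } else dropped <- character()
      if (length(dropped))
        dataset$metadata <- dataset$metadata[
          !(dataset$metadata$locus == dropLocus &
              dataset$metadata$strain %in% dropped), , drop = FALSE]
    }
    if (!is.null(truncateTo) && truncateFraction > 0 &&
        truncateLocus %in% names(dataset$alignments)) {
      a <- dataset$alignments[[truncateLocus]]
      n <- length(a)
      nTrunc <- max(1L, round(truncateFraction * n))
      pick <- sort(sample.int(n, min(nTrunc, n)))
      s <- as.character(sequenceSet(a))
      for (i in pick) {
        ch <- strsplit(s[i], "", fixed = TRUE)[[1L]]
        resid <- which(!(ch %in% GAP_CHARS))
        if (length(resid) > truncateTo)
          ch[resid[(truncateTo + 1L):length(resid)]] <- "?"
        s[i] <- paste(ch, collapse = "")
      }
      seqs <- Biostrings::BStringSet(s)
      names(seqs) <- recordIds(a)
      dataset$alignments[[truncateLocus]] <-
        new("LocusAlignment", locus = a@locus, seqs = seqs, meta = a@meta,
            columnMap = a@columnMap)
    }
    dataset
  })
}

#' Score recovery of the true partitions
#'
#' Compares predicted species/genus partitions against the simulator's
#' truth labels with the adjusted Rand index (1 = identical up to
#' relabelling), exact-match booleans, and a confusion listing of true
#' taxa that were merged or split.
#'
#' @param predicted A [Delimitation-class], or a list with named character
#'   vectors `species` and `genus` (strain -> ID).
#' @param truth Truth data.frame (`strain`, `genus`, `species`) as from
#'   [simulateDataset()].
#' @return A list with `ariSpecies`, `ariGenus`, `exactSpecies`,
#'   `exactGenus`, and `confusion` (data.frame of true taxa vs number of
#'   predicted clusters they span).
#' @export
scoreRecovery <- function(predicted, truth) {
  if (is(predicted, "Delimitation"))
    predicted <- list(species = speciesPartition(predicted),
                      genus = genusPartition(predicted))
  if (!setequal(names(predicted$species), truth$strain))
    stop("predicted and truth partitions cover different strains")
  ord <- truth$strain
  predSp <- predicted$species[ord]
  predGe <- predicted$genus[ord]
  ariSp <- mclust::adjustedRandIndex(predSp, truth$species)
  ariGe <- mclust::adjustedRandIndex(predGe, truth$genus)
  confusion <- do.call(rbind, lapply(split(predSp, truth$species),
    function(x) data.frame(nPredictedClusters = length(unique(x)))))
  confusion <- data.frame(trueSpecies = rownames(confusion), confusion,
                          row.names = NULL)
  list(ariSpecies = ariSp, ariGenus = ariGe,
       exactSpecies = isTRUE(all.equal(ariSp, 1)),
       exactGenus = isTRUE(all.equal(ariGe, 1)),
       confusion = confusion)
}
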