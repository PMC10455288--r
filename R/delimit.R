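# Representative selection, rank-assignment rules, end-to-end delimitation.

# ranking key: type strains first, then records whose strain has both
# ITS and 28S, then lexicographic record ID
repOrder <- function(ids, isType, hasBoth) {
  order(!isType, !hasBoth, ids)
}

#' Select representative sequences for a group
#'
#' Implements the three representative criteria used for global
#' evaluations: (i) sufficient sequence length (default at least 450 nt
#' for ITS, 500 nt for 28S, ungapped), (ii) type-strain membership and
#' (iii) two-locus coverage — in that order of relevance — while picking
#' the two most distant qualifying sequences so the group's known
#' diversity is spanned. Groups whose within-group maximum exceeds the
#' species threshold get one extra representative per sub-cluster.
#'
#' @param group A [TaxonGroup-class].
#' @param aln The [LocusAlignment-class] the group was formed on.
#' @param dm The matching [PDistanceMatrix-class].
#' @param profile A [ThresholdProfile-class] (for `minLength` and
#'   `speciesMax`).
#' @param k Base number of representatives (default 2).
#' @param coverage Optional named logical: record ID -> strain has both
#'   ITS and 28S sequences.
#' @return Character vector of representative record IDs.
#' @export
selectRepresentatives <- function(group, aln, dm, profile = thresholdProfile(),
                                  k = 2L, coverage = NULL) {
  mem <- sort(memberIds(group))
  if (length(mem) == 1L) return(mem)
  loc <- locus(aln)
  lens <- ungappedLength(sequenceSet(aln))[match(mem, recordIds(aln))]
  minLen <- if (loc %in% names(profile@minLength))
    profile@minLength[[loc]] else 0L
  cand <- mem[lens >= minLen]
  if (!length(cand)) {
    warning("no member of group ", groupId(group), " reaches ", minLen,
            " nt; falling back to unfiltered candidates")
    cand <- mem
  }
  meta <- recordInfo(aln)
  isType <- as.logical(meta$isTypeStrain)[match(cand, recordIds(aln))]
  isType[is.na(isType)] <- FALSE
  hasBoth <- if (is.null(coverage)) rep(FALSE, length(cand))
             else coverage[cand] %in% TRUE
  rank <- repOrder(cand, isType, hasBoth)
  if (length(cand) <= k) {
    sel <- cand[rank]
  } else {
    v <- distValues(dm)[cand, cand, drop = FALSE]
    pairs <- which(upper.tri(v), arr.ind = TRUE)
    pd <- v[pairs]
    pd[is.na(pd)] <- -Inf
    if (all(pd <= 0)) {
      sel <- cand[rank][seq_len(k)]
    } else {
      best <- which(pd >= max(pd) - 1e-12)
      # tie-break among maximal pairs: type strains, coverage, lexicographic
      key <- vapply(best, function(i) {
        a <- pairs[i, 1L]; b <- pairs[i, 2L]
        sprintf("%d|%d|%s", 2L - (isType[a] + isType[b]),
                2L - (hasBoth[a] + hasBoth[b]),
                paste(sort(c(cand[a], cand[b])), collapse = "|"))
      }, "")
      pick <- best[order(key)][1L]
      sel <- sort(c(cand[pairs[pick, 1L]], cand[pairs[pick, 2L]]))
      if (k > 2L) {
        extra <- setdiff(cand[rank], sel)
        sel <- c(sel, extra[seq_len(min(k - 2L, length(extra)))])
      }
    }
  }
  # diverse groups: one extra representative per species-level sub-cluster
  spMax <- if (loc %in% names(profile@speciesMax))
    profile@speciesMax[[loc]] else Inf
  wr <- withinRange(group)
  if (!anyNA(wr) && wr[2L] > spMax) {
    sub <- thresholdCluster(subsetDistance(dm, mem), spMax)
    for (s in sub) {
      if (!length(intersect(memberIds(s), sel))) {
        # extra representatives still have to meet the length bar
        cs <- intersect(cand, memberIds(s))
        if (!length(cs)) next
        it <- isType[match(cs, cand)]
        hb <- hasBoth[match(cs, cand)]
        sel <- c(sel, cs[repOrder(cs, it, hb)][1L])
      }
    }
  }
  unique(sel)
}

# restrict a PDistanceMatrix to a set of ids
subsetDistance <- function(dm, ids) {
  new("PDistanceMatrix", locus = dm@locus,
      values = dm@values[ids, ids, drop = FALSE],
      nCompared = dm@nCompared[ids, ids, drop = FALSE],
      se = if (is.null(dm@se)) NULL else dm@se[ids, ids, drop = FALSE])
}

# per-locus verdict on a between-group minimum distance
locusVerdict <- function(d, sp, gl, gh, morph) {
  if (is.na(d)) return(NA_character_)
  if (d <= sp) "same_species"
  else if (d >= gh || (morph && d >= gl)) "distinct_genus"
  else if (d < gl) "distinct_species"
  else "borderline"
}

#' Assign a taxonomic rank to a pair of groups
#'
#' The multi-locus rule engine, evaluated on the between-group minimum
#' p-distance per locus. ITS is the primary locus, 28S a second level of
#' validation; ITS data are required for a decision to reach `established`
#' status (a per-taxon `override` covers genera validated on 28S alone).
#'
#' Rules, with the default [thresholdProfile()]:
#' \enumerate{
#'   \item `same_species` if ITS <= 3\% and 28S (if present) <= 1\%;
#'   \item `distinct_species` (congeneric) if ITS lies in (3\%, 8\%) and
#'     28S does not contradict (< 5\%);
#'   \item `distinct_genus` if ITS >= 12\%, or ITS >= 8\% with distinct
#'     morphology, or — with no ITS data — 28S >= 5\% (or >= 2\% with
#'     distinct morphology);
#'   \item otherwise `borderline`.
#' }
#' Contradictory loci (one saying `same_species`, the other
#' `distinct_genus`) yield `borderline` with `inconclusive` status.
#' `established` requires a type strain and ITS data (or `override`);
#' otherwise the call is `putative` (a pNGenus/pNSpecies).
#'
#' @param itsMin,lsuMin Between-group minimum p-distances (proportions);
#'   `NA` when the locus has no data for the pair.
#' @param profile A [ThresholdProfile-class].
#' @param hasTypeStrain Does the subject taxon include a type strain?
#' @param morphologyDistinct Are the taxa morphologically distinct?
#' @param override Per-taxon override allowing establishment without ITS.
#' @param subject Label stored on the decision.
#' @return A [RankDecision-class].
#' @examples
#' # a strongly divergent type strain: distinct genus, established
#' decisionRank(assignRank(0.17, 0.07, hasTypeStrain = TRUE,
#'                         morphologyDistinct = TRUE))
#' @export
assignRank <- function(itsMin = NA_real_, lsuMin = NA_real_,
                       profile = thresholdProfile(), hasTypeStrain = FALSE,
                       morphologyDistinct = FALSE, override = FALSE,
                       subject = "pair") {
  if (is.na(itsMin) && is.na(lsuMin))
    stop("no locus with a defined between-group distance")
  sp <- profile@speciesMax; gl <- profile@genusLow; gh <- profile@genusHigh
  vIts <- locusVerdict(itsMin, sp[["ITS"]], gl[["ITS"]], gh[["ITS"]],
                       morphologyDistinct)
  vLsu <- locusVerdict(lsuMin, sp[["LSU28S"]], gl[["LSU28S"]], gh[["LSU28S"]],
                       morphologyDistinct)
  ev <- character()
  if (!is.na(itsMin))
    ev <- c(ev, sprintf("ITS between-min %.3f -> %s", itsMin, vIts))
  if (!is.na(lsuMin))
    ev <- c(ev, sprintf("28S between-min %.3f -> %s", lsuMin, vLsu))
  hasIts <- !is.na(itsMin)
  contradiction <- !is.na(vIts) && !is.na(vLsu) &&
    setequal(c(vIts, vLsu), c("same_species", "distinct_genus"))
  if (contradiction) {
    rank <- "borderline"
    status <- "inconclusive"
    ev <- c(ev, "loci contradict (same_species vs distinct_genus)")
  } else if (hasIts) {
    if (vIts == "same_species" && (is.na(lsuMin) ||
                                   lsuMin <= sp[["LSU28S"]])) {
      rank <- "same_species"
      ev <- c(ev, "rule: ITS within species threshold, 28S concordant or absent")
    } else if (vIts == "distinct_species" &&
               (is.na(lsuMin) || lsuMin < gh[["LSU28S"]])) {
      rank <- "distinct_species"
      ev <- c(ev, "rule: ITS in the congeneric band -> distinct species, same genus")
    } else if (vIts == "distinct_genus") {
      rank <- "distinct_genus"
      ev <- c(ev, if (itsMin >= gh[["ITS"]])
        "rule: ITS at or above the upper generic threshold"
        else "rule: ITS above the lower generic threshold with distinct morphology")
    } else {
      rank <- "borderline"
      ev <- c(ev, "rule: no species/genus rule fired cleanly")
    }
  } else {
    if (identical(vLsu, "distinct_genus")) {
      rank <- "distinct_genus"
      ev <- c(ev, "rule: no ITS data; 28S at or above the generic threshold")
    } else {
      rank <- "borderline"
      ev <- c(ev, "rule: no ITS data and 28S below the generic threshold")
    }
  }
  status <- if (rank == "borderline") "inconclusive"
            else if (hasTypeStrain && (hasIts || override)) "established"
            else "putative"
  flags <- c(has_its = hasIts, has_28s = !is.na(lsuMin),
             has_type_strain = hasTypeStrain,
             morphology_distinct = morphologyDistinct, override = override)
  new("RankDecision", subject = subject, rank = rank, status = status,
      evidence = ev, flags = flags)
}

# minimum defined distance between two strain sets, through a record->strain map
betweenMinOnStrains <- function(dm, strainOf, strainsA, strainsB,
                                restrictStrains = NULL) {
  ids <- recordIds(dm)
  if (!is.null(restrictStrains))
    ids <- ids[strainOf[ids] %in% restrictStrains]
  a <- ids[strainOf[ids] %in% strainsA]
  b <- ids[strainOf[ids] %in% strainsB]
  if (!length(a) || !length(b)) return(NA_real_)
  v <- distValues(dm)[a, b, drop = FALSE]
  if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
}

#' Delimit species and genera across loci
#'
#' The end-to-end delimitation used for global evaluations:
#' \enumerate{
#'   \item cluster each locus at its species threshold (single linkage);
#'   \item reconcile loci over strains — the ITS partition is primary and is
#'     never split nor merged against ITS evidence; 28S co-membership
#'     assigns the strains ITS cannot resolve (strains present in only one
#'     locus inherit that locus's assignment), and 28S links between
#'     distinct ITS species are flagged as conflicts;
#'   \item select representatives per species (length, type strain,
#'     coverage, maximal diversity);
#'   \item link species into genera when the representative-level minimum
#'     distance falls below the lower generic threshold (ITS primary, 28S
#'     used where ITS is absent), and emit a [RankDecision-class] for every
#'     species pair.
#' }
#' Species lacking ITS data or a type strain are carried through with
#' `putative` status. Deterministic given inputs: group labels follow
#' size, then lexicographically smallest member.
#'
#' @param alignments Named list of [LocusAlignment-class] objects (`ITS`
#'   and/or `LSU28S`; an `SSU18S` element is ignored here — see
#'   [ssuReport()]).
#' @param profile A [ThresholdProfile-class].
#' @param morphology Optional function `(speciesA, speciesB) -> logical` or
#'   `NULL`; morphology only ever lowers the generic bar.
#' @param overrides Optional character vector of species IDs allowed to be
#'   established without ITS data.
#' @return A [Delimitation-class].
#' @export
delimitDataset <- function(alignments, profile = thresholdProfile(),
                           morphology = NULL, overrides = character()) {
  alignments <- alignments[intersect(c("ITS", "LSU28S"), names(alignments))]
  if (!length(alignments))
    stop("need an ITS and/or LSU28S alignment")
  # strain bookkeeping across loci
  strainOf <- character()
  typeOf <- logical()
  for (a in alignments) {
    st <- as.character(recordInfo(a)$strain)
    names(st) <- recordIds(a)
    strainOf <- c(strainOf, st)
    ty <- as.logical(recordInfo(a)$isTypeStrain)
    ty[is.na(ty)] <- FALSE
    names(ty) <- recordIds(a)
    typeOf <- c(typeOf, ty)
  }
  strains <- sort(unique(strainOf))
  matrices <- lapply(alignments, distanceMatrix)
  clusters <- mapply(function(a, dm) {
    thresholdCluster(dm, profile@speciesMax[[locus(a)]])
  }, alignments, matrices, SIMPLIFY = FALSE)

  # stage 2: reconcile over strains (union-find; ITS primary, 28S merge-only)
  parent <- seq_along(strains)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  itsSpecies <- rep(NA_integer_, length(strains))
  names(itsSpecies) <- strains
  if ("ITS" %in% names(clusters)) {
    for (g in seq_along(clusters$ITS)) {
      mem <- unique(strainOf[memberIds(clusters$ITS[[g]])])
      itsSpecies[mem] <- g
      idx <- match(mem, strains)
      for (i in idx[-1L]) union2(idx[1L], i)
    }
  }
  conflicts <- character()
  if ("LSU28S" %in% names(clusters)) {
    for (g in clusters$LSU28S) {
      mem <- unique(strainOf[memberIds(g)])
      anchors <- sort(mem[!is.na(itsSpecies[mem])])
      free <- setdiff(mem, anchors)
      itsG <- unique(itsSpecies[anchors])
      if (length(itsG) > 1L)
        conflicts <- c(conflicts, sprintf(
          "28S cluster {%s} links %d ITS species (ITS kept primary)",
          paste(sort(mem), collapse = ","), length(itsG)))
      # 28S assigns only strains unresolved by ITS; ITS species are
      # never split and never merged against ITS evidence
      if (length(free)) {
        if (length(itsG) > 1L)
          conflicts <- c(conflicts, sprintf(
            "strain(s) %s attach ambiguously; joined to the species of %s",
            paste(free, collapse = ","), anchors[1L]))
        target <- if (length(anchors)) anchors[1L] else free[1L]
        idx <- match(c(target, free), strains)
        for (i in idx[-1L]) union2(idx[1L], i)
      }
    }
  }
  comp <- vapply(seq_along(strains), find, 0L)
  spMembers <- split(strains, comp)
  ord <- order(-lengths(spMembers),
               vapply(spMembers, function(m) sort(m)[1L], ""))
  spMembers <- spMembers[ord]
  spIds <- sprintf("SP%02d", seq_along(spMembers))
  species <- character(length(strains))
  names(species) <- strains
  for (s in seq_along(spMembers)) species[spMembers[[s]]] <- spIds[s]

  # per-species locus availability and flags
  lociOf <- lapply(alignments, function(a) unique(recordInfo(a)$strain))
  hasItsStrain <- strains %in% (if ("ITS" %in% names(lociOf)) lociOf$ITS
                                else character())
  has28sStrain <- strains %in% (if ("LSU28S" %in% names(lociOf)) lociOf$LSU28S
                                else character())
  names(hasItsStrain) <- names(has28sStrain) <- strains
  coverageRec <- (hasItsStrain & has28sStrain)[strainOf]
  names(coverageRec) <- names(strainOf)

  # stage 3: representatives per species (ITS preferred, 28S fallback)
  reps <- stats::setNames(vector("list", length(spIds)), spIds)
  for (s in seq_along(spIds)) {
    mem <- spMembers[[s]]
    loc <- if ("ITS" %in% names(alignments) && any(hasItsStrain[mem])) "ITS"
           else "LSU28S"
    a <- alignments[[loc]]
    recs <- recordIds(a)[recordInfo(a)$strain %in% mem]
    dmS <- subsetDistance(matrices[[loc]], recs)
    v <- distValues(dmS)[upper.tri(distValues(dmS))]
    wr <- if (length(v[!is.na(v)])) range(v, na.rm = TRUE)
          else c(NA_real_, NA_real_)
    grp <- new("TaxonGroup", groupId = spIds[s], memberIds = recs,
               locus = loc, withinRange = wr, nearestGroup = NA_character_,
               betweenMin = NA_real_, representatives = character())
    reps[[s]] <- selectRepresentatives(grp, a, matrices[[loc]],
                                       profile, coverage = coverageRec)
  }
  repRecords <- unlist(reps, use.names = FALSE)
  repStrains <- unique(strainOf[repRecords])

  # stage 4: genus linking on representative-level minima
  nSp <- length(spIds)
  itsMin <- lsuMin <- matrix(NA_real_, nSp, nSp, dimnames = list(spIds, spIds))
  for (i in seq_len(nSp)) for (j in seq_len(nSp)) {
    if (j <= i) next
    if ("ITS" %in% names(matrices))
      itsMin[i, j] <- itsMin[j, i] <- betweenMinOnStrains(
        matrices$ITS, strainOf, spMembers[[i]], spMembers[[j]], repStrains)
    if ("LSU28S" %in% names(matrices))
      lsuMin[i, j] <- lsuMin[j, i] <- betweenMinOnStrains(
        matrices$LSU28S, strainOf, spMembers[[i]], spMembers[[j]], repStrains)
  }
  spHasType <- vapply(spMembers, function(mem)
    any(typeOf[names(strainOf)[strainOf %in% mem]]), NA)
  spHasIts <- vapply(spMembers, function(mem) any(hasItsStrain[mem]), NA)
  spHas28s <- vapply(spMembers, function(mem) any(has28sStrain[mem]), NA)

  gparent <- seq_len(nSp)
  gfind <- function(i) { while (gparent[i] != i) i <- gparent[i]; i }
  decisionsL <- list()
  for (i in seq_len(nSp)) for (j in seq_len(nSp)) {
    if (j <= i) next
    dIts <- itsMin[i, j]; dLsu <- lsuMin[i, j]
    if (is.na(dIts) && is.na(dLsu)) next
    morph <- if (is.null(morphology)) FALSE
             else isTRUE(morphology(spIds[i], spIds[j]))
    dec <- assignRank(dIts, dLsu, profile,
                      hasTypeStrain = spHasType[i] && spHasType[j],
                      morphologyDistinct = morph,
                      override = all(c(spIds[i], spIds[j]) %in% overrides |
                                       c(spHasIts[i], spHasIts[j])),
                      subject = paste(spIds[i], spIds[j], sep = "|"))
    decisionsL[[dec@subject]] <- dec
    sameGenus <- if (!is.na(dIts)) dIts < profile@genusLow[["ITS"]]
                 else dLsu < profile@genusLow[["LSU28S"]]
    if (isTRUE(sameGenus)) {
      ri <- gfind(i); rj <- gfind(j)
      if (ri != rj) gparent[min(ri, rj)] <- gparent[max(ri, rj)] <- min(ri, rj)
    }
  }
  gcomp <- vapply(seq_len(nSp), gfind, 0L)
  geMembers <- split(spIds, gcomp)
  gord <- order(-lengths(geMembers),
                vapply(geMembers, function(m) sort(m)[1L], ""))
  geMembers <- geMembers[gord]
  geIds <- sprintf("GE%02d", seq_along(geMembers))
  genusOfSpecies <- character(nSp)
  names(genusOfSpecies) <- spIds
  for (g in seq_along(geMembers)) genusOfSpecies[geMembers[[g]]] <- geIds[g]
  genus <- genusOfSpecies[species]
  names(genus) <- names(species)

  spStatus <- unname(ifelse(spHasType & (spHasIts | spIds %in% overrides),
                            "established", "putative"))
  speciesInfo <- DataFrame(
    speciesId = spIds, genusId = unname(genusOfSpecies),
    nStrains = unname(lengths(spMembers)),
    hasIts = unname(spHasIts), has28s = unname(spHas28s),
    hasTypeStrain = unname(spHasType), status = spStatus,
    representatives = unname(vapply(reps, paste, "", collapse = ",")))
  geHasType <- vapply(geMembers, function(m) any(spHasType[match(m, spIds)]), NA)
  geHasIts <- vapply(geMembers, function(m) any(spHasIts[match(m, spIds)]), NA)
  geStatus <- ifelse(geHasType &
                       (geHasIts | vapply(geMembers, function(m)
                         any(m %in% overrides), NA)),
                     "established", "putative")
  genusInfo <- DataFrame(
    genusId = geIds, nSpecies = unname(lengths(geMembers)),
    hasIts = unname(geHasIts), hasTypeStrain = unname(geHasType),
    status = unname(geStatus),
    species = unname(vapply(geMembers, paste, "", collapse = ",")))
  new("Delimitation", species = species, genus = genus,
      speciesInfo = speciesInfo, genusInfo = genusInfo,
      decisions = decisionsL, representatives = reps, conflicts = conflicts)
}

#' Report on 18S discriminability
#'
#' The 18S gene is evaluated in report-only mode: its pairwise distances
#' are binned by the species/genus partitions obtained from ITS/28S, and
#' the ranges are compared. The verdict is `"discriminative"` only when
#' the between-genus distances sit strictly above every within-genus
#' distance AND clear the minimum unequivocal divergence (`minGap`,
#' default 3\%: below that, 18S values are routinely shared by congeneric
#' and allogeneric pairs alike). Overlapping ranges, or between-genus
#' divergence entirely below `minGap`, give `"non-discriminative"` — the
#' usual outcome, since 18S barely varies below the genus level. The
#' report never alters the partitions.
#'
#' @param dm An 18S [PDistanceMatrix-class] over records whose strains are
#'   covered by the partitions.
#' @param species,genus Named character partitions (strain -> ID), e.g.
#'   from [delimitDataset()].
#' @param strainOf Optional named map record ID -> strain (defaults to
#'   record IDs being strains).
#' @param minGap Smallest between-genus p-distance regarded as
#'   unequivocally inter-generic (default 0.03).
#' @return A list with `classes` (data.frame: class, n, min, max) and
#'   `verdict`.
#' @export
ssuReport <- function(dm, species, genus, strainOf = NULL, minGap = 0.03) {
  ids <- recordIds(dm)
  if (is.null(strainOf)) strainOf <- stats::setNames(ids, ids)
  v <- distValues(dm)
  idx <- which(upper.tri(v), arr.ind = TRUE)
  sa <- strainOf[ids[idx[, 1L]]]; sb <- strainOf[ids[idx[, 2L]]]
  keep <- sa %in% names(species) & sb %in% names(species) & !is.na(v[idx])
  idx <- idx[keep, , drop = FALSE]; sa <- sa[keep]; sb <- sb[keep]
  d <- v[idx]
  cls <- ifelse(species[sa] == species[sb], "within_species",
         ifelse(genus[sa] == genus[sb], "within_genus_between_species",
                "between_genus"))
  classes <- do.call(rbind, lapply(
    c("within_species", "within_genus_between_species", "between_genus"),
    function(cl) {
      x <- d[cls == cl]
      data.frame(class = cl, n = length(x),
                 min = if (length(x)) min(x) else NA_real_,
                 max = if (length(x)) max(x) else NA_real_)
    }))
  intra <- d[cls != "between_genus"]
  inter <- d[cls == "between_genus"]
  verdict <- if (length(inter) && length(intra) &&
                 min(inter) > max(intra) && min(inter) >= minGap)
    "discriminative" else "non-discriminative"
  list(classes = classes, verdict = verdict)
}
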