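# Stage drivers for the four-step evaluation protocol:
# complex disentangling / sectorial / global / concatenated.

#' Set aside records too divergent to share a label
#'
#' Pre-filter mirroring the curation of mislabelled public sequences:
#' within each current taxon label, a record whose p-distance to EVERY
#' other record of the same label exceeds `1 - identityFloor` (default:
#' identity below 90\%, i.e. p > 0.10) is set aside before analysis.
#' External identification (e.g. BLAST against public databases) is out
#' of scope; only the within-dataset screen is automated.
#'
#' @param aln A [LocusAlignment-class] whose metadata carries
#'   `taxonLabel`.
#' @param identityFloor Minimum within-label identity (default 0.90).
#' @return A list with `kept` (a [LocusAlignment-class]) and `excluded`
#'   (data.frame of record, label, minimum within-label distance).
#' @export
excludeDivergentRecords <- function(aln, identityFloor = 0.90) {
  ids <- recordIds(aln)
  labels <- as.character(recordInfo(aln)$taxonLabel)
  maxP <- 1 - identityFloor
  excluded <- data.frame(record_id = character(), taxon_label = character(),
                         min_within_label_p = numeric())
  if (length(ids) >= 2L) {
    dm <- distanceMatrix(aln)
    v <- distValues(dm)
    for (i in seq_along(ids)) {
      same <- which(labels == labels[i] & seq_along(ids) != i &
                      !is.na(labels[i]))
      if (!length(same)) next
      dmin <- suppressWarnings(min(v[i, same], na.rm = TRUE))
      if (is.finite(dmin) && dmin > maxP)
        excluded <- rbind(excluded, data.frame(
          record_id = ids[i], taxon_label = labels[i],
          min_within_label_p = dmin))
    }
  }
  keep <- !(ids %in% excluded$record_id)
  list(kept = aln[keep], excluded = excluded)
}

#' Sectorial evaluation: diversity within each current species label
#'
#' For every current taxon label and locus: record counts, within-label
#' p-distance range, the number of species-threshold clusters the label
#' splits into (with a split flag when there is more than one), and the
#' representatives chosen per cluster. Labels with fewer than two records
#' at a locus are reported with dashes, not treated as errors. Divergent
#' records are set aside first (see [excludeDivergentRecords()]).
#'
#' @param alignments Named list of [LocusAlignment-class] (`ITS`,
#'   `LSU28S`).
#' @param profile A [ThresholdProfile-class].
#' @param identityFloor Passed to [excludeDivergentRecords()].
#' @param outDir Optional directory for the summary/exclusion TSVs.
#' @param seed Recorded in output provenance headers.
#' @return A list with `summary` (data.frame, one row per label),
#'   `representatives` (named list label -> record IDs), `exclusions`
#'   (data.frame) and `log` (character).
#' @export
runSectorial <- function(alignments, profile = thresholdProfile(),
                         identityFloor = 0.90, outDir = NULL, seed = NA) {
  alignments <- alignments[intersect(c("ITS", "LSU28S"), names(alignments))]
  stopifnot(length(alignments) >= 1L)
  logLines <- character()
  exclusions <- NULL
  kept <- list()
  for (loc in names(alignments)) {
    scr <- excludeDivergentRecords(alignments[[loc]], identityFloor)
    kept[[loc]] <- scr$kept
    if (nrow(scr$excluded)) {
      scr$excluded$locus <- loc
      exclusions <- rbind(exclusions, scr$excluded)
    }
    logLines <- c(logLines, sprintf(
      "%s: %d records read, %d excluded (identity < %.0f%%), %d positions",
      loc, length(alignments[[loc]]), nrow(scr$excluded),
      100 * identityFloor, nPositions(alignments[[loc]])))
  }
  labels <- sort(unique(unlist(lapply(kept, function(a)
    as.character(recordInfo(a)$taxonLabel)))))
  labels <- labels[!is.na(labels)]
  repsOut <- list()
  rows <- lapply(labels, function(lb) {
    row <- data.frame(taxon_label = lb, stringsAsFactors = FALSE)
    for (loc in c("ITS", "LSU28S")) {
      pre <- if (loc == "ITS") "its" else "lsu"
      if (!loc %in% names(kept)) {
        row[[paste0(pre, "_n")]] <- 0L
        row[[paste0(pre, "_within_min")]] <- "—"
        row[[paste0(pre, "_within_max")]] <- "—"
        row[[paste0(pre, "_clusters")]] <- NA_integer_
        row[[paste0(pre, "_split")]] <- NA
        next
      }
      a <- kept[[loc]]
      sel <- which(as.character(recordInfo(a)$taxonLabel) == lb)
      row[[paste0(pre, "_n")]] <- length(sel)
      if (length(sel) < 2L) {
        row[[paste0(pre, "_within_min")]] <- "—"
        row[[paste0(pre, "_within_max")]] <- "—"
        row[[paste0(pre, "_clusters")]] <- length(sel)
        row[[paste0(pre, "_split")]] <- FALSE
        if (length(sel) == 1L)
          repsOut[[lb]] <<- union(repsOut[[lb]], recordIds(a)[sel])
        next
      }
      sub <- a[sel]
      dm <- distanceMatrix(sub)
      v <- distValues(dm)[upper.tri(distValues(dm))]
      row[[paste0(pre, "_within_min")]] <-
        formatPercent(suppressWarnings(min(v, na.rm = TRUE)))
      row[[paste0(pre, "_within_max")]] <-
        formatPercent(suppressWarnings(max(v, na.rm = TRUE)))
      groups <- thresholdCluster(dm, profile@speciesMax[[loc]])
      row[[paste0(pre, "_clusters")]] <- length(groups)
      row[[paste0(pre, "_split")]] <- length(groups) > 1L
      for (g in groups)
        repsOut[[lb]] <<- union(repsOut[[lb]],
          selectRepresentatives(g, sub, dm, profile))
    }
    row
  })
  summary <- do.call(rbind, rows)
  logLines <- c(logLines, sprintf("%d labels summarised; %d flagged as split",
    nrow(summary), sum(summary$its_split %in% TRUE |
                         summary$lsu_split %in% TRUE)))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeTableWithHeader(summary, file.path(outDir, "sectorial_summary.tsv"),
                         seed = seed)
    if (!is.null(exclusions))
      writeTableWithHeader(exclusions, file.path(outDir, "exclusions.tsv"),
                           seed = seed)
  }
  list(summary = summary, representatives = repsOut,
       exclusions = if (is.null(exclusions)) data.frame() else exclusions,
       log = logLines)
}

#' Global evaluation: delimit species and genera, build scaffold trees
#'
#' Runs [delimitDataset()] over the supplied alignments, builds an NJ
#' scaffold tree per locus over the selected representatives (with
#' bootstrap support), and tabulates every pairwise rank decision. When
#' `outDir` is given, writes the partition TSV, the decision TSV, a
#' genus-pair p-distance range table (the branch-annotation companion to
#' the trees) and one Newick file per locus, all with provenance headers.
#'
#' @param alignments Named list of [LocusAlignment-class].
#' @param profile A [ThresholdProfile-class].
#' @param bootstrapReplicates Bootstrap replicates for tree support.
#' @param seed Integer seed for the bootstrap.
#' @param outDir Optional output directory.
#' @param ... Passed on to [delimitDataset()] (`morphology`, `overrides`).
#' @return A list with `delimitation` ([Delimitation-class]), `trees`
#'   (named list of [ape::phylo]), `decisionTable` (data.frame) and
#'   `genusRanges` (data.frame).
#' @export
runGlobal <- function(alignments, profile = thresholdProfile(),
                      bootstrapReplicates = 100L, seed = 1L, outDir = NULL,
                      ...) {
  del <- delimitDataset(alignments, profile, ...)
  repRecords <- unlist(representatives(del), use.names = FALSE)
  repStrains <- unique(unlist(lapply(alignments, function(a)
    as.character(recordInfo(a)$strain)[recordIds(a) %in% repRecords])))
  trees <- list()
  for (loc in intersect(c("ITS", "LSU28S"), names(alignments))) {
    a <- alignments[[loc]]
    sel <- as.character(recordInfo(a)$strain) %in% repStrains
    if (sum(sel) >= 3L) {
      sub <- a[sel]
      dm <- distanceMatrix(sub)
      if (!anyNA(distValues(dm)[upper.tri(distValues(dm))]))
        trees[[loc]] <- bootstrapSupport(sub, bootstrapReplicates, seed)
    }
  }
  decisionTable <- do.call(rbind, lapply(decisions(del), function(d)
    data.frame(subject = d@subject, rank = d@rank, status = d@status,
               has_its = d@flags[["has_its"]],
               has_28s = d@flags[["has_28s"]],
               evidence = paste(d@evidence, collapse = "; "),
               stringsAsFactors = FALSE)))
  if (is.null(decisionTable)) decisionTable <- data.frame()
  genusRanges <- genusPairRanges(del, alignments)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    part <- data.frame(strain = names(speciesPartition(del)),
                       species_id = unname(speciesPartition(del)),
                       genus_id = unname(genusPartition(del)))
    writeTableWithHeader(part, file.path(outDir, "partitions.tsv"),
                         seed = seed)
    writeTableWithHeader(decisionTable, file.path(outDir, "decisions.tsv"),
                         seed = seed)
    writeTableWithHeader(genusRanges, file.path(outDir, "genus_ranges.tsv"),
                         seed = seed)
    for (loc in names(trees))
      writeNewickTree(trees[[loc]], file.path(outDir,
                                              paste0("nj_", loc, ".nwk")))
  }
  list(delimitation = del, trees = trees, decisionTable = decisionTable,
       genusRanges = genusRanges)
}

# per genus pair: min/max p-distance per locus (integer percents)
genusPairRanges <- function(del, alignments) {
  ge <- genusPartition(del)
  gids <- sort(unique(ge))
  if (length(gids) < 2L) return(data.frame())
  rows <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (j <= i) next
    row <- data.frame(genus_a = gids[i], genus_b = gids[j],
                      stringsAsFactors = FALSE)
    for (loc in intersect(c("ITS", "LSU28S"), names(alignments))) {
      a <- alignments[[loc]]
      st <- as.character(recordInfo(a)$strain)
      ia <- which(st %in% names(ge)[ge == gids[i]])
      ib <- which(st %in% names(ge)[ge == gids[j]])
      pre <- if (loc == "ITS") "its" else "lsu"
      if (length(ia) && length(ib)) {
        dm <- distanceMatrix(a)
        v <- distValues(dm)[ia, ib, drop = FALSE]
        if (any(!is.na(v))) {
          row[[paste0(pre, "_min")]] <- formatPercent(min(v, na.rm = TRUE))
          row[[paste0(pre, "_max")]] <- formatPercent(max(v, na.rm = TRUE))
          next
        }
      }
      row[[paste0(pre, "_min")]] <- "—"
      row[[paste0(pre, "_max")]] <- "—"
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Concatenated evaluation: supermatrix NJ tree
#'
#' Concatenates all supplied loci into a supermatrix (missing loci filled
#' with `?`), computes pairwise-deletion p-distances over the defined
#' sites, and builds an NJ tree with bootstrap support. Requires at least
#' two loci; with a single locus, use [runGlobal()] instead.
#'
#' @param alignments Named list of at least two [LocusAlignment-class].
#' @param bootstrapReplicates Bootstrap replicates.
#' @param seed Integer seed.
#' @param outDir Optional output directory (Newick + block TSV).
#' @return A list with `supermatrix` ([Supermatrix-class]), `tree`
#'   ([ape::phylo] with support) and `distances`
#'   ([PDistanceMatrix-class]).
#' @export
runConcatenated <- function(alignments, bootstrapReplicates = 100L,
                            seed = 1L, outDir = NULL) {
  if (length(alignments) < 2L)
    stop("concatenated evaluation needs at least two loci; ",
         "for a single locus run the global evaluation (runGlobal)")
  sm <- concatenateLoci(alignments)
  dm <- distanceMatrix(sequenceSet(sm), locus = "concat")
  tree <- bootstrapSupport(sequenceSet(sm), bootstrapReplicates, seed)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeSupermatrix(sm, file.path(outDir, "supermatrix.fasta"),
                     file.path(outDir, "supermatrix_blocks.tsv"))
    writeNewickTree(tree, file.path(outDir, "nj_concat.nwk"))
  }
  list(supermatrix = sm, tree = tree, distances = dm)
}
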