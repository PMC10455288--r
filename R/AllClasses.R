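#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' LocusAlignment: an aligned set of sequences for one ribosomal locus
#'
#' Container for a per-locus multiple sequence alignment together with the
#' strain metadata that drives delimitation (strain, current species label,
#' type-strain flag) and a column map tracing retained alignment columns back
#' to the original column indices (updated by [filterGapColumns()]).
#'
#' Residues are stored as a [Biostrings::BStringSet] restricted to
#' `A,C,G,T`, IUPAC ambiguity codes, `-` (gap) and `?` (missing); `?` is kept
#' in the alphabet because concatenated supermatrices use it to fill absent
#' loci. Names of the set are the record IDs and must be unique.
#'
#' @slot locus One of `"ITS"`, `"LSU28S"`, `"SSU18S"` (see [LOCI]).
#' @slot seqs A [Biostrings::BStringSet] of equal-width aligned sequences.
#' @slot meta A [S4Vectors::DataFrame] with one row per record, columns
#'   `strain`, `taxonLabel`, `isTypeStrain`, `source`.
#' @slot columnMap Integer vector, strictly increasing, mapping current
#'   columns to original alignment columns.
#'
#' @seealso [readLocusFasta()], [filterGapColumns()], [distanceMatrix()]
#' @export
setClass("LocusAlignment",
  representation(locus = "character", seqs = "BStringSet",
                 meta = "DataFrame", columnMap = "integer"))

setValidity("LocusAlignment", function(object) {
  msg <- character()
  if (length(object@locus) != 1L || !(object@locus %in% LOCI))
    msg <- c(msg, sprintf("locus must be one of %s", paste(LOCI, collapse = ", ")))
  n <- length(object@seqs)
  if (n == 0L) msg <- c(msg, "alignment has no records")
  ids <- names(object@seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all records must be named by a record ID")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate record IDs: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1L)
    msg <- c(msg, "sequences have unequal widths (not aligned)")
  else if (length(w) == 1L) {
    if (length(object@columnMap) != w)
      msg <- c(msg, "columnMap length must equal alignment width")
    if (is.unsorted(object@columnMap, strictly = TRUE))
      msg <- c(msg, "columnMap must be strictly increasing")
    bad <- setdiff(unique(unlist(strsplit(as.character(object@seqs), "",
                                          fixed = TRUE))), RESIDUE_ALPHABET)
    if (length(bad))
      msg <- c(msg, sprintf("residues outside alphabet: %s",
                            paste(bad, collapse = " ")))
  }
  if (nrow(object@meta) != n)
    msg <- c(msg, "meta must have one row per record")
  need <- c("strain", "taxonLabel", "isTypeStrain", "source")
  if (!all(need %in% colnames(object@meta)))
    msg <- c(msg, sprintf("meta must have columns %s", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LocusAlignment
#'
#' @param seqs A [Biostrings::BStringSet] (or named character vector) of
#'   aligned sequences; names are record IDs.
#' @param locus Locus identifier, one of [LOCI].
#' @param meta Optional data.frame/DataFrame with columns `strain`,
#'   `taxonLabel`, `isTypeStrain`, `source` (defaults derived from IDs).
#' @param columnMap Integer map of columns to original indices (default
#'   identity).
#' @return A [LocusAlignment-class] object.
#' @export
LocusAlignment <- function(seqs, locus, meta = NULL, columnMap = NULL) {
  if (!is(seqs, "BStringSet")) seqs <- Biostrings::BStringSet(seqs)
  ids <- names(seqs)
  if (is.null(meta)) {
    meta <- DataFrame(strain = ids, taxonLabel = NA_character_,
                      isTypeStrain = FALSE, source = NA_character_)
  } else {
    meta <- as(as.data.frame(meta), "DataFrame")
  }
  rownames(meta) <- ids
  if (is.null(columnMap)) {
    w <- if (length(seqs)) Biostrings::width(seqs)[1L] else 0L
    columnMap <- seq_len(w)
  }
  new("LocusAlignment", locus = locus, seqs = seqs, meta = meta,
      columnMap = as.integer(columnMap))
}

#' PDistanceMatrix: pairwise p-distances under pairwise deletion
#'
#' Symmetric matrix of uncorrected p-distances (proportion of differing
#' sites among sites where both sequences have an unambiguous base), the
#' matrix of compared-site counts, and optionally a matrix of bootstrap
#' standard errors. An entry is defined (non-`NA`) iff the pair shares at
#' least one comparable site.
#'
#' @slot locus Locus identifier (or `"concat"` for supermatrix distances).
#' @slot values Symmetric numeric matrix in \[0,1\], diagonal 0, `NA` where
#'   no site is comparable; dimnames are record IDs.
#' @slot nCompared Symmetric integer matrix of compared-site counts.
#' @slot se Optional symmetric matrix of standard errors (`NULL` if absent).
#' @seealso [distanceMatrix()], [bootstrapSE()], [thresholdCluster()]
#' @export
setClass("PDistanceMatrix",
  representation(locus = "character", values = "matrix",
                 nCompared = "matrix", se = "matrixOrNULL"))

setValidity("PDistanceMatrix", function(object) {
  v <- object@values; nc <- object@nCompared
  msg <- character()
  if (length(object@locus) != 1L || is.na(object@locus) || !nzchar(object@locus))
    msg <- c(msg, "locus must be a non-empty string")
  if (!identical(dim(v), dim(nc)))
    msg <- c(msg, "values and nCompared must have identical dimensions")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must carry identical row/col record IDs")
  if (!isTRUE(all.equal(v, t(v))) && !identical(v, t(v)))
    msg <- c(msg, "values must be symmetric")
  if (any(diag(v) != 0, na.rm = TRUE) || anyNA(diag(nc)) ||
      any(diag(nc) > 0 & is.na(diag(v))))
    msg <- c(msg, "diagonal must be exactly 0 where defined")
  if (any(v < 0 | v > 1, na.rm = TRUE))
    msg <- c(msg, "distances must lie in [0, 1]")
  if (any(nc < 0)) msg <- c(msg, "nCompared must be nonnegative")
  if (any(is.na(v) & nc > 0) || any(!is.na(v) & nc == 0))
    msg <- c(msg, "an entry must be defined iff nCompared > 0")
  if (!is.null(object@se) && !identical(dim(object@se), dim(v)))
    msg <- c(msg, "se must match values in dimension")
  if (length(msg)) msg else TRUE
})

#' ThresholdProfile: per-locus delimitation thresholds
#'
#' The p-distance thresholds that drive species and genus segregation,
#' and the minimum sequence lengths for representative candidacy. Defaults
#' follow the divergence bars commonly applied to marine Halosphaeriaceae
#' rDNA: species are segregated at ITS/28S p-distances of at least 3%/1%;
#' genera at 8%/2% when morphology is distinctive and 12%/5% otherwise;
#' representatives must span at least 450 nt (ITS) / 500 nt (28S).
#'
#' @slot speciesMax Named numeric: largest within-species p-distance.
#' @slot genusLow Named numeric: lowest p-distance accepted for generic
#'   segregation (with distinct morphology).
#' @slot genusHigh Named numeric: p-distance above which genera are
#'   segregated on molecular data alone.
#' @slot minLength Named integer: minimum ungapped length for a sequence to
#'   be a representative candidate.
#' @export
setClass("ThresholdProfile",
  representation(speciesMax = "numeric", genusLow = "numeric",
                 genusHigh = "numeric", minLength = "integer"))

setValidity("ThresholdProfile", function(object) {
  msg <- character()
  loci <- names(object@speciesMax)
  if (is.null(loci) || !all(loci %in% LOCI))
    msg <- c(msg, "thresholds must be named by locus")
  for (sl in c("genusLow", "genusHigh", "minLength")) {
    if (!identical(names(slot(object, sl)), loci))
      msg <- c(msg, sprintf("%s must be named like speciesMax", sl))
  }
  ok <- length(msg) == 0L
  if (ok && (any(object@speciesMax <= 0) |
             any(object@speciesMax > object@genusLow) ||
             any(object@genusLow > object@genusHigh) ||
             any(object@genusHigh >= 1)))
    msg <- c(msg, "need 0 < speciesMax <= genusLow <= genusHigh < 1 per locus")
  if (ok && any(object@minLength <= 0L))
    msg <- c(msg, "minLength must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a ThresholdProfile
#'
#' @param speciesMax,genusLow,genusHigh Named numeric vectors of per-locus
#'   p-distance thresholds (proportions).
#' @param minLength Named integer vector of minimum ungapped lengths.
#' @return A [ThresholdProfile-class] object.
#' @examples
#' thresholdProfile()  # the default ITS/28S profile
#' @export
thresholdProfile <- function(speciesMax = c(ITS = 0.03, LSU28S = 0.01),
                             genusLow   = c(ITS = 0.08, LSU28S = 0.02),
                             genusHigh  = c(ITS = 0.12, LSU28S = 0.05),
                             minLength  = c(ITS = 450L, LSU28S = 500L)) {
  minLength <- stats::setNames(as.integer(minLength), names(minLength))
  new("ThresholdProfile", speciesMax = speciesMax, genusLow = genusLow,
      genusHigh = genusHigh, minLength = minLength)
}

#' TaxonGroup: one threshold cluster
#'
#' A single-linkage cluster of records at a p-distance threshold, with its
#' within-group distance range, its nearest other group, and (once chosen)
#' its representative records.
#'
#' @slot groupId Group identifier.
#' @slot memberIds Record IDs of the members.
#' @slot locus Locus the clustering was computed on.
#' @slot withinRange Numeric length-2 (min, max) of defined within-group
#'   distances; `NA` for singletons.
#' @slot nearestGroup ID of the closest other group (`NA` if none).
#' @slot betweenMin Minimum defined distance to the nearest group.
#' @slot representatives Selected representative record IDs (may be empty).
#' @seealso [thresholdCluster()], [selectRepresentatives()]
#' @export
setClass("TaxonGroup",
  representation(groupId = "character", memberIds = "character",
                 locus = "character", withinRange = "numeric",
                 nearestGroup = "character", betweenMin = "numeric",
                 representatives = "character"))

setValidity("TaxonGroup", function(object) {
  msg <- character()
  if (length(object@memberIds) == 0L) msg <- c(msg, "group has no members")
  if (length(object@withinRange) != 2L)
    msg <- c(msg, "withinRange must be (min, max)")
  else if (!anyNA(object@withinRange) &&
           object@withinRange[1L] > object@withinRange[2L])
    msg <- c(msg, "withinRange min must not exceed max")
  if (length(msg)) msg else TRUE
})

#' RankDecision: outcome of the rank-assignment rule engine
#'
#' The taxonomic call for a pair of groups (or a single group), the
#' confidence status, and the trace of rules that fired.
#'
#' @slot subject Identifier of the group or group pair judged.
#' @slot rank One of `same_species`, `distinct_species`, `same_genus`,
#'   `distinct_genus`, `borderline`.
#' @slot status One of `established`, `putative`, `inconclusive`.
#' @slot evidence Character vector of fired rules (at least one).
#' @slot flags Named logicals: `has_its`, `has_28s`, `has_type_strain`,
#'   `morphology_distinct`.
#' @seealso [assignRank()]
#' @export
setClass("RankDecision",
  representation(subject = "character", rank = "character",
                 status = "character", evidence = "character",
                 flags = "logical"))

setValidity("RankDecision", function(object) {
  msg <- character()
  if (!(object@rank %in% c("same_species", "distinct_species", "same_genus",
                           "distinct_genus", "borderline")))
    msg <- c(msg, "invalid rank")
  if (!(object@status %in% c("established", "putative", "inconclusive")))
    msg <- c(msg, "invalid status")
  if (length(object@evidence) < 1L)
    msg <- c(msg, "every decision must carry at least one evidence rule")
  fl <- object@flags
  if (identical(object@status, "established") &&
      !(isTRUE(fl[["has_type_strain"]]) &&
        (isTRUE(fl[["has_its"]]) || isTRUE(fl[["override"]]))))
    msg <- c(msg, "established requires a type strain and ITS data (or override)")
  if (length(msg)) msg else TRUE
})

#' Supermatrix: concatenated multi-locus alignment
#'
#' Per-strain concatenation of the per-locus alignments, with loci absent
#' for a strain filled by `?` and half-open (0-based) column blocks
#' recording where each locus sits.
#'
#' @slot seqs [Biostrings::BStringSet] named by strain.
#' @slot blocks [S4Vectors::DataFrame] with columns `locus`, `start`, `end`
#'   (0-based, half-open), non-overlapping, contiguous and covering all
#'   columns.
#' @seealso [concatenateLoci()], [sliceSupermatrix()]
#' @export
setClass("Supermatrix",
  representation(seqs = "BStringSet", blocks = "DataFrame"))

setValidity("Supermatrix", function(object) {
  msg <- character()
  b <- object@blocks
  if (!all(c("locus", "start", "end") %in% colnames(b)))
    msg <- c(msg, "blocks must have columns locus, start, end")
  else {
    if (nrow(b) && (b$start[1L] != 0L ||
        (nrow(b) > 1L && any(b$start[-1L] != b$end[-nrow(b)]))))
      msg <- c(msg, "blocks must be contiguous from column 0")
    w <- unique(Biostrings::width(object@seqs))
    if (length(w) != 1L)
      msg <- c(msg, "all strains must have equal total length")
    else if (nrow(b) && b$end[nrow(b)] != w)
      msg <- c(msg, "blocks must cover all columns")
  }
  if (anyDuplicated(names(object@seqs)))
    msg <- c(msg, "duplicate strains in supermatrix")
  if (length(msg)) msg else TRUE
})

#' Delimitation: result of the end-to-end delimitation pipeline
#'
#' Species- and genus-level partitions over strains, per-species and
#' per-genus summaries (with established/putative status), the pairwise
#' rank decisions, the representatives used for the genus stage, and any
#' inter-locus conflicts flagged during reconciliation.
#'
#' @slot species Named character: strain -> species ID.
#' @slot genus Named character: strain -> genus ID.
#' @slot speciesInfo [S4Vectors::DataFrame], one row per species.
#' @slot genusInfo [S4Vectors::DataFrame], one row per genus.
#' @slot decisions List of [RankDecision-class] objects (one per species pair).
#' @slot representatives Named list: species ID -> representative record IDs.
#' @slot conflicts Character vector of flagged inter-locus conflicts.
#' @seealso [delimitDataset()]
#' @export
setClass("Delimitation",
  representation(species = "character", genus = "character",
                 speciesInfo = "DataFrame", genusInfo = "DataFrame",
                 decisions = "list", representatives = "list",
                 conflicts = "character"))

setValidity("Delimitation", function(object) {
  msg <- character()
  if (!identical(names(object@species), names(object@genus)))
    msg <- c(msg, "species and genus partitions must cover the same strains")
  # species partition must refine the genus partition
  if (length(object@species)) {
    tab <- unique(data.frame(sp = object@species, ge = object@genus))
    if (anyDuplicated(tab$sp))
      msg <- c(msg, "a species must lie wholly inside one genus")
  }
  if (length(msg)) msg else TRUE
})
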