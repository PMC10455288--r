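# Generics, accessors and show methods.

#' @rdname LocusAlignment-class
#' @param x,object A package object.
#' @export
setGeneric("locus", function(x) standardGeneric("locus"))
#' @rdname LocusAlignment-class
#' @export
setMethod("locus", "LocusAlignment", function(x) x@locus)
#' @rdname PDistanceMatrix-class
#' @export
setMethod("locus", "PDistanceMatrix", function(x) x@locus)

#' @rdname LocusAlignment-class
#' @export
setGeneric("sequenceSet", function(x) standardGeneric("sequenceSet"))
#' @rdname LocusAlignment-class
#' @export
setMethod("sequenceSet", "LocusAlignment", function(x) x@seqs)
#' @rdname Supermatrix-class
#' @export
setMethod("sequenceSet", "Supermatrix", function(x) x@seqs)

#' @rdname LocusAlignment-class
#' @export
setGeneric("recordInfo", function(x) standardGeneric("recordInfo"))
#' @rdname LocusAlignment-class
#' @export
setMethod("recordInfo", "LocusAlignment", function(x) x@meta)

#' @rdname LocusAlignment-class
#' @export
setGeneric("columnMap", function(x) standardGeneric("columnMap"))
#' @rdname LocusAlignment-class
#' @export
setMethod("columnMap", "LocusAlignment", function(x) x@columnMap)

#' @rdname LocusAlignment-class
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))
#' @rdname LocusAlignment-class
#' @export
setMethod("recordIds", "LocusAlignment", function(x) names(x@seqs))
#' @rdname PDistanceMatrix-class
#' @export
setMethod("recordIds", "PDistanceMatrix", function(x) rownames(x@values))

#' @rdname LocusAlignment-class
#' @export
setMethod("length", "LocusAlignment", function(x) length(x@seqs))

#' @rdname LocusAlignment-class
#' @export
setGeneric("nPositions", function(x) standardGeneric("nPositions"))
#' @rdname LocusAlignment-class
#' @export
setMethod("nPositions", "LocusAlignment", function(x)
  if (length(x@seqs)) Biostrings::width(x@seqs)[1L] else 0L)

#' Subset a LocusAlignment by record
#'
#' @param x A [LocusAlignment-class].
#' @param i Record indices, IDs or logical mask.
#' @param j,...,drop Ignored.
#' @export
setMethod("[", "LocusAlignment", function(x, i, j, ..., drop = FALSE) {
  new("LocusAlignment", locus = x@locus, seqs = x@seqs[i],
      meta = x@meta[i, , drop = FALSE], columnMap = x@columnMap)
})

#' @rdname PDistanceMatrix-class
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))
#' @rdname PDistanceMatrix-class
#' @export
setMethod("distValues", "PDistanceMatrix", function(x) x@values)

#' @rdname PDistanceMatrix-class
#' @export
setGeneric("nCompared", function(x) standardGeneric("nCompared"))
#' @rdname PDistanceMatrix-class
#' @export
setMethod("nCompared", "PDistanceMatrix", function(x) x@nCompared)

#' @rdname PDistanceMatrix-class
#' @export
setGeneric("distSE", function(x) standardGeneric("distSE"))
#' @rdname PDistanceMatrix-class
#' @export
setMethod("distSE", "PDistanceMatrix", function(x) x@se)

#' @rdname TaxonGroup-class
#' @export
setGeneric("groupId", function(x) standardGeneric("groupId"))
#' @rdname TaxonGroup-class
#' @export
setMethod("groupId", "TaxonGroup", function(x) x@groupId)

#' @rdname TaxonGroup-class
#' @export
setGeneric("memberIds", function(x) standardGeneric("memberIds"))
#' @rdname TaxonGroup-class
#' @export
setMethod("memberIds", "TaxonGroup", function(x) x@memberIds)

#' @rdname TaxonGroup-class
#' @export
setGeneric("withinRange", function(x) standardGeneric("withinRange"))
#' @rdname TaxonGroup-class
#' @export
setMethod("withinRange", "TaxonGroup", function(x) x@withinRange)

#' @rdname TaxonGroup-class
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname TaxonGroup-class
#' @export
setMethod("representatives", "TaxonGroup", function(x) x@representatives)
#' @rdname Delimitation-class
#' @export
setMethod("representatives", "Delimitation", function(x) x@representatives)

#' @rdname RankDecision-class
#' @export
setGeneric("decisionRank", function(x) standardGeneric("decisionRank"))
#' @rdname RankDecision-class
#' @export
setMethod("decisionRank", "RankDecision", function(x) x@rank)

#' @rdname RankDecision-class
#' @export
setGeneric("decisionStatus", function(x) standardGeneric("decisionStatus"))
#' @rdname RankDecision-class
#' @export
setMethod("decisionStatus", "RankDecision", function(x) x@status)

#' @rdname RankDecision-class
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))
#' @rdname RankDecision-class
#' @export
setMethod("evidence", "RankDecision", function(x) x@evidence)

#' @rdname RankDecision-class
#' @export
setGeneric("decisionFlags", function(x) standardGeneric("decisionFlags"))
#' @rdname RankDecision-class
#' @export
setMethod("decisionFlags", "RankDecision", function(x) x@flags)

#' @rdname Delimitation-class
#' @export
setGeneric("speciesPartition", function(x) standardGeneric("speciesPartition"))
#' @rdname Delimitation-class
#' @export
setMethod("speciesPartition", "Delimitation", function(x) x@species)

#' @rdname Delimitation-class
#' @export
setGeneric("genusPartition", function(x) standardGeneric("genusPartition"))
#' @rdname Delimitation-class
#' @export
setMethod("genusPartition", "Delimitation", function(x) x@genus)

#' @rdname Delimitation-class
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))
#' @rdname Delimitation-class
#' @export
setMethod("decisions", "Delimitation", function(x) x@decisions)

#' @rdname Delimitation-class
#' @export
setGeneric("speciesInfo", function(x) standardGeneric("speciesInfo"))
#' @rdname Delimitation-class
#' @export
setMethod("speciesInfo", "Delimitation", function(x) x@speciesInfo)

#' @rdname Delimitation-class
#' @export
setGeneric("genusInfo", function(x) standardGeneric("genusInfo"))
#' @rdname Delimitation-class
#' @export
setMethod("genusInfo", "Delimitation", function(x) x@genusInfo)

#' @rdname Supermatrix-class
#' @export
setGeneric("lociBlocks", function(x) standardGeneric("lociBlocks"))
#' @rdname Supermatrix-class
#' @export
setMethod("lociBlocks", "Supermatrix", function(x) x@blocks)

setMethod("show", "LocusAlignment", function(object) {
  cat(sprintf("LocusAlignment [%s]: %d records x %d positions\n",
              object@locus, length(object@seqs), nPositions(object)))
  n_type <- sum(object@meta$isTypeStrain, na.rm = TRUE)
  cat(sprintf("  strains: %d unique; type strains: %d\n",
              length(unique(object@meta$strain)), n_type))
})

setMethod("show", "PDistanceMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("PDistanceMatrix [%s]: %d records", object@locus,
              nrow(object@values)))
  if (length(v))
    cat(sprintf("; p-distance range %.3f-%.3f (%d undefined pairs)",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  cat(if (is.null(object@se)) "\n" else "; bootstrap SEs attached\n")
})

setMethod("show", "ThresholdProfile", function(object) {
  cat("ThresholdProfile (p-distance, proportions):\n")
  for (l in names(object@speciesMax))
    cat(sprintf("  %-7s species<=%.3f genus in [%.3f, %.3f); minLength %d nt\n",
                l, object@speciesMax[[l]], object@genusLow[[l]],
                object@genusHigh[[l]], object@minLength[[l]]))
})

setMethod("show", "TaxonGroup", function(object) {
  wr <- if (anyNA(object@withinRange)) "singleton"
        else sprintf("within %.3f-%.3f", object@withinRange[1L],
                     object@withinRange[2L])
  cat(sprintf("TaxonGroup %s [%s]: %d members (%s); nearest %s at %.3f\n",
              object@groupId, object@locus, length(object@memberIds), wr,
              object@nearestGroup, object@betweenMin))
})

setMethod("show", "RankDecision", function(object) {
  cat(sprintf("RankDecision %s: %s (%s)\n", object@subject, object@rank,
              object@status))
  cat(paste0("  - ", object@evidence, collapse = "\n"), "\n")
})

setMethod("show", "Supermatrix", function(object) {
  cat(sprintf("Supermatrix: %d strains x %d positions; blocks: %s\n",
              length(object@seqs),
              if (length(object@seqs)) Biostrings::width(object@seqs)[1L] else 0L,
              paste(sprintf("%s[%d,%d)", object@blocks$locus,
                            object@blocks$start, object@blocks$end),
                    collapse = " ")))
})

setMethod("show", "Delimitation", function(object) {
  cat(sprintf("Delimitation: %d strains -> %d species in %d genera\n",
              length(object@species), length(unique(object@species)),
              length(unique(object@genus))))
  st <- table(object@speciesInfo$status)
  cat(sprintf("  species status: %s\n",
              paste(names(st), st, sep = "=", collapse = ", ")))
  if (length(object@conflicts))
    cat(sprintf("  %d inter-locus conflict(s) flagged\n",
                length(object@conflicts)))
})
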