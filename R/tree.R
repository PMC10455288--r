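# Neighbor-joining scaffold trees with nonparametric bootstrap support.
#
# The package's trees are distance-based NJ scaffolds: delimitation is
# driven by the p-distance thresholds, and the trees provide a clade-level
# sanity check (monophyly of the inferred genera) rather than model-based
# inference. Model-corrected ML/Bayesian reconstruction is deliberately
# out of scope.

#' Neighbor-joining tree from a p-distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]). NJ is exact on
#' additive matrices, so clades separated by clean distance gaps are
#' recovered deterministically. Negative branch-length estimates are
#' clamped to zero for display; the raw values are retained in
#' `tree$raw.edge.length`.
#'
#' @param dm A [PDistanceMatrix-class] with at least 3 records and no
#'   missing entries.
#' @return An [ape::phylo] tree.
#' @export
njTree <- function(dm) {
  v <- distValues(dm)
  if (nrow(v) < 3L) stop("need at least 3 records for a tree")
  off <- v[upper.tri(v)]
  if (anyNA(off))
    stop("missing pairwise distances; impute them or drop the affected ",
         "records before tree building")
  tr <- ape::nj(v)
  tr$raw.edge.length <- tr$edge.length
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# distance matrix + NJ from an integer-coded alignment (internal, used by
# the bootstrap loop)
njFromCodes <- function(codes) {
  pc <- pairCounts(codes)
  if (any(pc$shared[upper.tri(pc$shared)] == 0)) return(NULL)
  p <- pc$diffs / pc$shared
  dimnames(p) <- list(rownames(codes), rownames(codes))
  tr <- ape::nj(p)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Nonparametric column bootstrap: alignment columns are resampled with
#' replacement, an NJ tree is built per replicate, and the frequency of
#' each internal split of the full-data tree among the replicate trees is
#' mapped onto that tree. Support is stored as a proportion in
#' `tree$support` (one value per internal node, `NA`-free); Newick output
#' renders it as an integer percent node label.
#'
#' @param x A [LocusAlignment-class], [Biostrings::BStringSet] or named
#'   character vector of aligned sequences (>= 3 records).
#' @param replicates Bootstrap replicates (default 1000).
#' @param seed Integer seed (RNG state restored on exit).
#' @return An [ape::phylo] with a `support` field (proportions in \[0,1\]).
#' @export
bootstrapSupport <- function(x, replicates = 1000L, seed = 1L) {
  seqs <- if (is(x, "LocusAlignment")) sequenceSet(x) else x
  loc <- if (is(x, "LocusAlignment")) locus(x) else "concat"
  stopifnot(replicates >= 1L)
  dm <- distanceMatrixCore(seqs, loc)
  main <- njTree(dm)
  codes <- encodeResidues(seqs)
  L <- ncol(codes)
  boots <- withSeed(seed, {
    out <- vector("list", replicates)
    for (k in seq_len(replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      out[[k]] <- njFromCodes(codes[, idx, drop = FALSE])
    }
    out
  })
  boots <- Filter(Negate(is.null), boots)
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  main$support <- counts / length(boots)
  main
}

#' Write / read Newick trees with support labels
#'
#' Branch lengths are written as-is; support proportions (if present in
#' `tree$support`) are written as integer-percent internal node labels.
#' Reading converts numeric node labels back to proportions (labels above
#' 1 are taken as percents). Malformed files raise a parse error that
#' points at the first unbalanced parenthesis.
#'
#' @param tree An [ape::phylo].
#' @param path File path.
#' @return `writeNewickTree`: `path` invisibly; `readNewickTree`: an
#'   [ape::phylo] with a `support` field when node labels are numeric.
#' @export
writeNewickTree <- function(tree, path) {
  if (!is.null(tree$support))
    tree$node.label <- as.character(round(100 * tree$support))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewickTree
#' @export
readNewickTree <- function(path) {
  stopifnot(file.exists(path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum(ifelse(strsplit(txt, "")[[1]] == "(", 1L,
                         ifelse(strsplit(txt, "")[[1]] == ")", -1L, 0L)))
  if (any(depth < 0))
    stop("malformed Newick: unbalanced ')' at position ",
         which(depth < 0)[1L])
  if (length(depth) && depth[length(depth)] != 0)
    stop("malformed Newick: ", depth[length(depth)],
         " unclosed '(' at end of input")
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e)
    stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick: parser returned no tree")
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    if (any(!is.na(sup))) {
      if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100
      tree$support <- sup
    }
  }
  tree
}

# do the leaves in `tips` form a clade (split) of the unrooted tree?
isMonophyleticSplit <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  target <- sort(match(tips, labs))
  comp <- sort(setdiff(seq_along(labs), target))
  any(vapply(parts, function(p)
    identical(sort(p), target) || identical(sort(p), comp), NA))
}
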