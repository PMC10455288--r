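# Pairwise-deletion p-distances and bootstrap standard errors.
#
# Only the four unambiguous bases are compared; IUPAC ambiguity codes,
# gaps and '?' are treated as missing and excluded per pair (pairwise
# deletion), matching how MEGA computes uncorrected p-distances.

# integer codes 1..4 for A,C,G,T; NA otherwise
encodeResidues <- function(x) {
  m <- charMatrix(x)
  codes <- matrix(match(m, c("A", "C", "G", "T")), nrow = nrow(m))
  rownames(codes) <- rownames(m)
  codes
}

# all-pairs (differences, shared sites) via indicator cross-products
pairCounts <- function(codes) {
  V <- (!is.na(codes)) * 1
  shared <- tcrossprod(V)
  matches <- matrix(0, nrow(codes), nrow(codes))
  for (b in 1:4) {
    I <- (!is.na(codes) & codes == b) * 1
    matches <- matches + tcrossprod(I)
  }
  list(diffs = shared - matches, shared = shared)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among sites where both sequences carry an
#' unambiguous base (`A`, `C`, `G`, `T`). Sites where either sequence has a
#' gap, `?`, `N` or any other ambiguity code are excluded (pairwise
#' deletion). Transitions and transversions count equally.
#'
#' @param a,b Aligned residue strings of equal length.
#' @return A list with `p` (proportion, `NA` if no site is comparable) and
#'   `nCompared` (number of retained sites).
#' @examples
#' pDistance("ACGT", "ACGA")   # p = 0.25 over 4 sites
#' pDistance("AC-TN", "ACGTA") # '-' and 'N' columns excluded: p = 0 over 3
#' @export
pDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("sequences must be aligned (equal length): ", nchar(a), " vs ",
         nchar(b))
  codes <- encodeResidues(c(x = a, y = b))
  ok <- !is.na(codes[1L, ]) & !is.na(codes[2L, ])
  n <- sum(ok)
  p <- if (n > 0L) sum(codes[1L, ok] != codes[2L, ok]) / n else NA_real_
  list(p = p, nCompared = n)
}

#' All-pairs p-distance matrix for an alignment
#'
#' Computes every pairwise p-distance under pairwise deletion. Pairs
#' sharing no unambiguous site get an `NA` distance (never 0 or 1), which
#' downstream clustering treats as "no edge".
#'
#' @param x A [LocusAlignment-class], [Biostrings::BStringSet], or named
#'   character vector of aligned sequences (at least 2 records).
#' @param locus Locus tag recorded on the result (taken from `x` when it is
#'   a [LocusAlignment-class]).
#' @return A [PDistanceMatrix-class].
#' @export
setGeneric("distanceMatrix", function(x, locus = "concat")
  standardGeneric("distanceMatrix"))

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "LocusAlignment", function(x, locus = "concat") {
  dm <- distanceMatrixCore(sequenceSet(x), x@locus)
  dm
})

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "BStringSet", function(x, locus = "concat")
  distanceMatrixCore(x, locus))

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "character", function(x, locus = "concat")
  distanceMatrixCore(x, locus))

distanceMatrixCore <- function(seqs, locus) {
  if (length(seqs) < 2L)
    stop("need at least 2 records to build a distance matrix")
  codes <- encodeResidues(seqs)
  pc <- pairCounts(codes)
  p <- pc$diffs / pc$shared
  p[pc$shared == 0] <- NA_real_
  d <- diag(p)
  d[diag(pc$shared) > 0] <- 0
  diag(p) <- d
  ids <- names(seqs)
  dimnames(p) <- dimnames(pc$shared) <- list(ids, ids)
  mode(pc$shared) <- "integer"
  new("PDistanceMatrix", locus = locus, values = p, nCompared = pc$shared,
      se = NULL)
}

#' Bootstrap standard errors for a p-distance matrix
#'
#' Nonparametric column bootstrap: alignment columns are resampled with
#' replacement, the full p-distance matrix is recomputed per replicate, and
#' the per-pair standard deviation across replicates is reported, as is
#' conventional for distance variance estimation (default 1000 replicates).
#' An analytic binomial alternative `sqrt(p(1-p)/n)` is available via
#' `method = "analytic"`.
#'
#' @param x A [LocusAlignment-class], [Biostrings::BStringSet] or named
#'   character vector of aligned sequences.
#' @param replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param method `"bootstrap"` (default) or `"analytic"`.
#' @return A [PDistanceMatrix-class] with the `se` slot filled.
#' @export
bootstrapSE <- function(x, replicates = 1000L, seed = 1L,
                        method = c("bootstrap", "analytic")) {
  method <- match.arg(method)
  seqs <- if (is(x, "LocusAlignment")) sequenceSet(x) else x
  loc <- if (is(x, "LocusAlignment")) locus(x) else "concat"
  dm <- distanceMatrixCore(seqs, loc)
  if (method == "analytic") {
    se <- sqrt(dm@values * (1 - dm@values) / dm@nCompared)
    se[dm@nCompared == 0] <- NA_real_
    dm@se <- se
    return(dm)
  }
  stopifnot(replicates >= 1L)
  codes <- encodeResidues(seqs)
  L <- ncol(codes)
  n <- nrow(codes)
  reps <- withSeed(seed, {
    r <- array(NA_real_, dim = c(n, n, replicates))
    for (k in seq_len(replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      pc <- pairCounts(codes[, idx, drop = FALSE])
      pk <- pc$diffs / pc$shared
      pk[pc$shared == 0] <- NA_real_
      r[, , k] <- pk
    }
    r
  })
  se <- apply(reps, c(1L, 2L), stats::sd, na.rm = TRUE)
  se[dm@nCompared == 0] <- NA_real_
  dimnames(se) <- dimnames(dm@values)
  dm@se <- se
  dm
}

#' Render a proportion as the integer percent used in report tables
#'
#' Rounds half away from zero, so 0.135 prints as 14 (not the banker's 13).
#' Missing values stay `NA`; [formatPercent()] renders them as an em dash,
#' as report tables do for unavailable loci.
#'
#' @param value Numeric proportion(s) in \[0, 1\] (NA allowed).
#' @return Integer percent(s).
#' @examples
#' percentReport(c(0.004, 0.135, 0.1099))  # 0 14 11
#' @export
percentReport <- function(value) {
  stopifnot(all(value >= 0 & value <= 1, na.rm = TRUE))
  as.integer(floor(100 * value + 0.5))
}

#' @rdname percentReport
#' @export
formatPercent <- function(value) {
  out <- ifelse(is.na(value), "—", sprintf("%d%%", percentReport(value)))
  out
}

#' Write a distance matrix as TSV
#'
#' `format = "square"` writes the full symmetric matrix with an ID header
#' row/column; `format = "long"` writes one row per pair
#' (`id_a`, `id_b`, `p`, `n_compared`, `se`).
#'
#' @param dm A [PDistanceMatrix-class].
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path, format = c("square", "long")) {
  format <- match.arg(format)
  if (format == "square") {
    df <- data.frame(id = recordIds(dm), distValues(dm), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    ids <- recordIds(dm)
    idx <- which(upper.tri(distValues(dm)), arr.ind = TRUE)
    df <- data.frame(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
                     p = distValues(dm)[idx],
                     n_compared = nCompared(dm)[idx],
                     se = if (is.null(distSE(dm))) NA_real_ else distSE(dm)[idx])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
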