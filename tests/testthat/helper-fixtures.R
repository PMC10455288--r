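# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# random aligned sequences with controllable gap/ambiguity content
randomAlignment <- function(n, L, gapProb = 0.1, ambProb = 0.05,
                            locus = "ITS") {
  pool <- c("A", "C", "G", "T")
  amb <- c("N", "R", "Y", "W", "S", "-", "?")
  seqs <- vapply(seq_len(n), function(i) {
    ch <- sample(pool, L, replace = TRUE)
    k <- stats::rbinom(1L, L, gapProb + ambProb)
    if (k > 0) {
      at <- sample.int(L, k)
      ch[at] <- sample(amb, k, replace = TRUE)
    }
    paste(ch, collapse = "")
  }, "")
  names(seqs) <- sprintf("r%02d", seq_len(n))
  LocusAlignment(seqs, locus)
}

# site-by-site brute-force p-distance oracle: compares characters
# directly per site, independent of the package's integer-coded
# cross-product route
oraclePDistance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  ok <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(ok)
  list(p = if (n > 0) sum(ca[ok] != cb[ok]) / n else NA_real_,
       nCompared = as.integer(n))
}

oracleDistanceMatrix <- function(aln) {
  s <- as.character(sequenceSet(aln))
  n <- length(s)
  v <- matrix(NA_real_, n, n, dimnames = list(names(s), names(s)))
  nc <- matrix(0L, n, n, dimnames = list(names(s), names(s)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    o <- oraclePDistance(s[i], s[j])
    v[i, j] <- o$p
    nc[i, j] <- o$nCompared
  }
  list(values = v, nCompared = nc)
}

# union-find clustering oracle (independent of the BFS implementation)
unionFindClusters <- function(values, t, inclusive = TRUE) {
  n <- nrow(values)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    d <- values[i, j]
    edge <- !is.na(d) && if (inclusive) d <= t else d < t
    if (edge) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  unname(split(rownames(values), comp))
}

# random symmetric distance matrix wrapped as PDistanceMatrix
randomDistanceMatrix <- function(n, naFrac = 0) {
  ids <- sprintf("s%02d", seq_len(n))
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  v[upper.tri(v)] <- stats::runif(n * (n - 1) / 2)
  v <- v + t(v)
  nc <- matrix(100L, n, n, dimnames = list(ids, ids))
  if (naFrac > 0) {
    drop <- which(upper.tri(v) & stats::runif(n * n) < naFrac)
    v[drop] <- NA_real_
    nc[drop] <- 0L
    v <- pmin(v, t(v), na.rm = FALSE)  # propagate NAs symmetrically
    nc[is.na(v)] <- 0L
  }
  diag(v) <- 0
  new("PDistanceMatrix", locus = "ITS", values = v, nCompared = nc, se = NULL)
}

# PDistanceMatrix from an explicit symmetric matrix
asPDist <- function(v, locus = "ITS") {
  nc <- matrix(100L, nrow(v), ncol(v), dimnames = dimnames(v))
  nc[is.na(v)] <- 0L
  new("PDistanceMatrix", locus = locus, values = v, nCompared = nc, se = NULL)
}

# partition as canonical signature for set comparison
partitionSignature <- function(groups) {
  sig <- sort(vapply(groups, function(g) paste(sort(g), collapse = ","), ""))
  paste(sig, collapse = ";")
}
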