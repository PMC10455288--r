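# Sequence and metadata I/O, gap-column filtering, concatenation.

#' Read an aligned FASTA file for one locus
#'
#' Reads a multi-record aligned FASTA, normalises residues (uppercase, RNA
#' `U` mapped to `T`) and attaches strain metadata. FASTA headers are
#' truncated at the first whitespace to form record IDs and must be unique.
#' Headers without a metadata row get defaults (strain = record ID,
#' `isTypeStrain = FALSE`) with a warning.
#'
#' @param path Path to the FASTA file.
#' @param locus Locus identifier, one of [LOCI].
#' @param metadata Optional data.frame as read by [readMetadataTable()]
#'   (columns `record_id`, `strain`, `taxon_label`, `locus`,
#'   `is_type_strain`, and optionally `source`).
#' @return A [LocusAlignment-class].
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
#' readLocusFasta(fa, "ITS")
#' @export
readLocusFasta <- function(path, locus, metadata = NULL) {
  stopifnot(file.exists(path))
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate FASTA record IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- Biostrings::BStringSet(chartr("U", "T", toupper(as.character(seqs))))
  names(seqs) <- ids
  meta <- NULL
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("locus" %in% colnames(metadata))
      metadata <- metadata[metadata$locus %in% c(locus, NA, ""), , drop = FALSE]
    hit <- match(ids, metadata$record_id)
    if (anyNA(hit))
      warning("no metadata for record(s) ",
              paste(ids[is.na(hit)], collapse = ", "),
              "; applying defaults (is_type_strain = FALSE)")
    meta <- DataFrame(
      strain = ifelse(is.na(hit), ids, as.character(metadata$strain)[hit]),
      taxonLabel = if ("taxon_label" %in% colnames(metadata))
        as.character(metadata$taxon_label)[hit] else NA_character_,
      isTypeStrain = ifelse(is.na(hit), FALSE,
        as.logical(metadata$is_type_strain)[hit]),
      source = if ("source" %in% colnames(metadata))
        as.character(metadata$source)[hit] else NA_character_)
  }
  LocusAlignment(seqs, locus, meta)
}

#' Write a LocusAlignment to FASTA
#'
#' @param x A [LocusAlignment-class].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
writeLocusFasta <- function(x, path) {
  Biostrings::writeXStringSet(sequenceSet(x), path, width = 80L)
  invisible(path)
}

#' Read / write the metadata sidecar table
#'
#' Tab-separated table with columns `record_id`, `strain`, `taxon_label`,
#' `locus`, `is_type_strain` and optionally `source`. The table is the
#' explicit carrier of the type-strain flags and current species labels
#' that the delimitation rules depend on.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
readMetadataTable <- function(path) {
  stopifnot(file.exists(path))
  md <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("record_id", "strain", "taxon_label", "locus", "is_type_strain")
  if (!all(need %in% colnames(md)))
    stop("metadata table must have columns: ", paste(need, collapse = ", "))
  md$is_type_strain <- as.logical(md$is_type_strain)
  md
}

#' @rdname readMetadataTable
#' @param md Metadata data.frame.
#' @export
writeMetadataTable <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove gap-rich alignment columns
#'
#' Drops every column in which gaps (`-`) or missing characters (`?`)
#' occur in more than `maxGapFraction` of the sequences (strictly more:
#' a column gapped in exactly half of the records is retained at the 0.5
#' default). Ambiguity codes are not counted as gaps. The surviving
#' columns are recorded in the column map so positions remain traceable to
#' the original alignment. Idempotent.
#'
#' @param x A [LocusAlignment-class].
#' @param maxGapFraction Highest tolerated gap fraction per column, in
#'   \[0, 1\] (default 0.5).
#' @return A filtered [LocusAlignment-class].
#' @examples
#' aln <- LocusAlignment(c(a = "AC-T", b = "AC-T", c = "ACGT", d = "AC-T"), "ITS")
#' nPositions(filterGapColumns(aln))  # column 3 (3/4 gapped) removed
#' @export
filterGapColumns <- function(x, maxGapFraction = 0.5) {
  stopifnot(is(x, "LocusAlignment"), maxGapFraction >= 0, maxGapFraction <= 1)
  if (length(x) == 0L) stop("empty alignment")
  m <- charMatrix(sequenceSet(x))
  gapFrac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  keep <- gapFrac <= maxGapFraction
  kept <- m[, keep, drop = FALSE]
  strings <- if (ncol(kept)) apply(kept, 1L, paste, collapse = "")
             else rep("", nrow(m))
  seqs <- Biostrings::BStringSet(strings)
  names(seqs) <- recordIds(x)
  new("LocusAlignment", locus = x@locus, seqs = seqs, meta = x@meta,
      columnMap = x@columnMap[keep])
}

#' Concatenate per-locus alignments into a supermatrix
#'
#' Builds one row per strain by concatenating its per-locus sequences in
#' the order the alignments are supplied; loci absent for a strain are
#' filled with `?` across the whole block. Strain rows are ordered
#' lexicographically. Block boundaries (0-based, half-open) are recorded.
#'
#' @param alignments Named list of [LocusAlignment-class] objects (names =
#'   loci, used for the block table).
#' @return A [Supermatrix-class].
#' @export
concatenateLoci <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1L)
  strainsPer <- lapply(alignments, function(a) {
    st <- as.character(recordInfo(a)$strain)
    if (anyDuplicated(st))
      stop("strain(s) appearing twice within locus ", locus(a), ": ",
           paste(unique(st[duplicated(st)]), collapse = ", "))
    st
  })
  strains <- sort(unique(unlist(strainsPer)))
  widths <- vapply(alignments, nPositions, 0L)
  ends <- cumsum(widths)
  starts <- c(0L, ends[-length(ends)])
  rows <- vapply(strains, function(s) {
    paste(vapply(seq_along(alignments), function(k) {
      a <- alignments[[k]]
      i <- match(s, strainsPer[[k]])
      if (is.na(i)) strrep("?", widths[k])
      else as.character(sequenceSet(a)[[i]])
    }, ""), collapse = "")
  }, "")
  seqs <- Biostrings::BStringSet(rows)
  names(seqs) <- strains
  blocks <- DataFrame(locus = vapply(alignments, locus, ""),
                      start = as.integer(starts), end = as.integer(ends))
  new("Supermatrix", seqs = seqs, blocks = blocks)
}

#' Extract one locus block from a supermatrix
#'
#' @param x A [Supermatrix-class].
#' @param locus Locus identifier present in the block table.
#' @return A [LocusAlignment-class] over all strains (absent strains are
#'   all-`?` rows).
#' @export
sliceSupermatrix <- function(x, locus) {
  b <- x@blocks
  i <- match(locus, b$locus)
  if (is.na(i)) stop("locus ", locus, " not present in supermatrix")
  seqs <- Biostrings::subseq(x@seqs, start = b$start[i] + 1L, end = b$end[i])
  LocusAlignment(seqs, locus)
}

#' Write a supermatrix as FASTA plus a block-definition TSV
#'
#' @param x A [Supermatrix-class].
#' @param fastaPath Output FASTA path.
#' @param blocksPath Output TSV path for `(locus, start, end)` (0-based,
#'   half-open).
#' @return `fastaPath`, invisibly.
#' @export
writeSupermatrix <- function(x, fastaPath, blocksPath) {
  Biostrings::writeXStringSet(x@seqs, fastaPath, width = 80L)
  utils::write.table(as.data.frame(x@blocks), blocksPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}
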