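# Internal helpers shared across modules.

#' Supported ribosomal loci
#'
#' Locus identifiers used throughout the package: the ITS region (internal
#' transcribed spacers + 5.8S), the 28S large-subunit gene and the 18S
#' small-subunit gene of the nuclear ribosomal cistron.
#'
#' @format Character vector of length 3: `"ITS"`, `"LSU28S"`, `"SSU18S"`.
#' @export
LOCI <- c("ITS", "LSU28S", "SSU18S")

# IUPAC nucleotide codes + alignment gap '-' and missing '?'
RESIDUE_ALPHABET <- c("A", "C", "G", "T",
                      "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N",
                      "-", "?")

GAP_CHARS <- c("-", "?")

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# character matrix (rows = records) from sequences
charMatrix <- function(x) {
  s <- as.character(x)
  if (length(s) == 0L) stop("empty sequence set")
  w <- unique(nchar(s))
  if (length(w) != 1L)
    stop("sequences are not aligned: lengths ", paste(w, collapse = ", "))
  m <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
              nrow = length(s), byrow = TRUE)
  rownames(m) <- names(x)
  m
}

# ungapped length (residues that are not '-' or '?') per sequence
ungappedLength <- function(x) {
  s <- as.character(x)
  nchar(s) - nchar(gsub("[^-?]", "", s))
}

# tiny polynomial rolling hash of a character scalar, for provenance headers
configHash <- function(txt) {
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# provenance header lines for output TSVs
provenanceHeader <- function(seed = NA, config = list()) {
  cfg <- paste(names(config), vapply(config, function(v)
    paste(format(v), collapse = ","), ""), sep = "=", collapse = "; ")
  c(sprintf("# pdelim %s", as.character(utils::packageVersion("pdelim"))),
    sprintf("# seed: %s", format(seed)),
    sprintf("# config-hash: %s", configHash(cfg)))
}

writeTableWithHeader <- function(df, path, seed = NA, config = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenanceHeader(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
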