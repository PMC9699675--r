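#' @importFrom Biostrings DNAString RNAString DNAStringSet RNAStringSet
#'   reverseComplement
NULL

#' Convert between RNA and DNA alphabets
#'
#' Mature miRNAs are conventionally written in the RNA alphabet (U) while
#' genomic 3'UTR sequences use DNA (T); these helpers convert plain
#' character vectors between the two conventions.
#'
#' @param x character vector of sequences.
#' @return character vector of the same length.
#' @examples
#' rnaToDna("UGAGGUAG")
#' dnaToRna("TGAGGTAG")
#' @export
rnaToDna <- function(x) chartr("Uu", "Tt", x)

#' @rdname rnaToDna
#' @export
dnaToRna <- function(x) chartr("Tt", "Ut", x)

# reverse complement of a DNA character vector, without Biostrings overhead
.revcompDna <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]])
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.checkAlphabet <- function(x, allowed, what = "sequence") {
  chars <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad))
    stop(what, " contains characters outside {",
         paste(allowed, collapse = ","), "}: ",
         paste(bad, collapse = ","), call. = FALSE)
  invisible(TRUE)
}

# provenance header written at the top of every output table
.provenanceHeader <- function(seed = NA, config = NULL) {
  cfgHash <- if (is.null(config)) "none" else {
    slots <- slotNames(class(config))
    vals <- vapply(slots, function(s)
      paste(format(slot(config, s), digits = 12), collapse = ","),
      character(1))
    # polynomial rolling hash over the serialized parameter string
    bytes <- utf8ToInt(paste(slots, vals, sep = "=", collapse = ";"))
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    sprintf("%08x", h)
  }
  sprintf("# cephamir %s | seed=%s | config=%s",
          as.character(utils::packageVersion("cephamir")),
          as.character(seed), cfgHash)
}

#' Write a table with a provenance header
#'
#' All tabular outputs carry a comment line recording the package version,
#' the seed, and a hash of the generating configuration, so that any result
#' file can be traced to the run that produced it.
#'
#' @param df a data.frame.
#' @param path output path.
#' @param seed the seed used by the producing computation.
#' @param config optional \linkS4class{SyntheticConfig} (hashed into the
#'   header).
#' @return \code{path}, invisibly.
#' @export
writeTableWithProvenance <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written with a provenance header
#'
#' @param path path to a TSV written by
#'   \code{\link{writeTableWithProvenance}} (plain TSVs are read too).
#' @return a data.frame.
#' @export
readTableWithProvenance <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Counts-per-million normalisation
#'
#' @param counts numeric matrix of raw counts (features x libraries).
#' @param librarySize optional library sizes; defaults to column sums.
#' @return matrix of CPM values.
#' @examples
#' cpmFromCounts(matrix(c(10, 90, 20, 180), 2))
#' @export
cpmFromCounts <- function(counts, librarySize = colSums(counts)) {
  if (any(librarySize <= 0))
    stop("library sizes must be positive", call. = FALSE)
  sweep(counts, 2, librarySize, "/") * 1e6
}
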