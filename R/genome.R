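#' Read a genome from a FASTA file
#'
#' Loads contigs into the simple named-character representation used
#' throughout the package (uppercase A/C/G/T/N strings keyed by contig name).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of contig sequences.
#' @export
read_genome <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(dss))
  names(g) <- sub("\\s.*$", "", names(dss))
  validate_genome(g)
  g
}

#' Write a genome to a FASTA file
#'
#' @param genome Named character vector of contig sequences.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_genome <- function(genome, path) {
  genome <- validate_genome(genome)
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Validate a genome object
#'
#' Checks contig-name uniqueness, non-empty sequences and the A/C/G/T/N
#' alphabet. `DNAStringSet` input is coerced to the named-character form.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @return The validated genome as a named character vector.
#' @export
validate_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  if (!is.character(genome) || length(genome) == 0) {
    stop("genome must be a non-empty named character vector", call. = FALSE)
  }
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
    stop("all contigs must be named", call. = FALSE)
  }
  if (anyDuplicated(names(genome))) {
    stop("contig names must be unique", call. = FALSE)
  }
  genome <- toupper(genome)
  if (any(nchar(genome) == 0)) {
    stop("contig sequences must be non-empty", call. = FALSE)
  }
  if (any(grepl("[^ACGTN]", genome))) {
    stop("genome contains characters outside the A/C/G/T/N alphabet",
         call. = FALSE)
  }
  genome
}

# reverse complement on plain character strings (vectorized)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a string into a character vector of single bases
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
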