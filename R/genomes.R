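#' Construct a genome set
#'
#' The package represents a collection of genomes as a
#' [Biostrings::DNAStringSet] whose element metadata (`S4Vectors::mcols`)
#' carries two per-genome columns: `circular` (logical; polyomavirus
#' genomes are circular molecules deposited in linearized form) and
#' `source_orientation` (`"forward"` or `"reverse_complemented"`, recording
#' whether strand correspondence flipped the sequence relative to its
#' source). All user-facing functions accept and return this container.
#'
#' @param sequences character vector of nucleotide sequences, or a
#'   `DNAStringSet`. Lowercase letters are uppercased and `U` is mapped to
#'   `T` so a single internal DNA alphabet is used throughout.
#' @param ids unique sequence identifiers; defaults to the names of
#'   `sequences`.
#' @param circular logical, recycled to one flag per genome.
#' @return a `DNAStringSet` with `circular` and `source_orientation`
#'   metadata columns.
#' @examples
#' gs <- genome_set(c(vole1 = "ACGTACGT", vole2 = "acgu"))
#' S4Vectors::mcols(gs)$circular
#' @export
genome_set <- function(sequences, ids = names(sequences), circular = FALSE) {
  if (is(sequences, "DNAStringSet")) {
    seqs <- as.character(sequences)
    if (is.null(ids)) ids <- names(sequences)
  } else {
    seqs <- as.character(sequences)
  }
  if (is.null(ids)) {
    stop("genome ids are required (name the sequences or pass `ids`)")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("u", "t", tolower(seqs))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < 1)) {
    stop("zero-length sequence for id(s): ",
         paste(ids[nchar(seqs) < 1], collapse = ", "))
  }
  bad <- grepl(sprintf("[^%s]", .iupac_alphabet), seqs)
  if (any(bad)) {
    stop("non-IUPAC characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    circular = rep_len(as.logical(circular), length(out)),
    source_orientation = rep("forward", length(out))
  )
  out
}

.iupac_alphabet <- "ACGTRYSWKMBDHVN"

#' Read genomes from a FASTA file
#'
#' Reads a (possibly wrapped) multi-FASTA file into a genome set. Sequences
#' are uppercased and `U` is mapped to `T`; record order is preserved and
#' the identifier is the first whitespace-delimited token of each header.
#' Duplicate identifiers are an error. An empty file yields an empty set
#' with a warning.
#'
#' @param path path to a FASTA file.
#' @param circular logical flag (recycled) stored on every genome.
#' @return a genome set (see [genome_set()]).
#' @export
read_fasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0) {
    warning("no FASTA records in ", path)
    out <- Biostrings::DNAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      circular = logical(0), source_orientation = character(0))
    return(out)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genome_set(as.character(set), ids = ids, circular = circular)
}

#' Write genomes to a FASTA file
#'
#' @param genomes a genome set.
#' @param path output path.
#' @param width line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 60L) {
  Biostrings::writeXStringSet(genomes, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of genomes
#'
#' Reverse-complements every genome and toggles its `source_orientation`
#' flag. Applying the operation twice restores the input exactly.
#'
#' @param genomes a genome set.
#' @return a genome set on the opposite strand.
#' @export
revcomp_genomes <- function(genomes) {
  out <- Biostrings::reverseComplement(genomes)
  mc <- S4Vectors::mcols(genomes)
  mc$source_orientation <- ifelse(mc$source_orientation == "forward",
                                  "reverse_complemented", "forward")
  S4Vectors::mcols(out) <- mc
  out
}

# single-sequence reverse complement, character in/out
.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# encode a nucleotide string for the C++ kernel: A,C,G,T -> 0..3,
# everything else (IUPAC ambiguity codes) -> -1 (never matches)
.encode_seq <- function(x) {
  codes <- utf8ToInt(x)
  map <- rep(-1L, 128L)
  map[utf8ToInt("A")] <- 0L
  map[utf8ToInt("C")] <- 1L
  map[utf8ToInt("G")] <- 2L
  map[utf8ToInt("T")] <- 3L
  map[codes]
}

# fetch one genome's sequence as character
.seq_chr <- function(genomes, i) as.character(genomes[[i]])
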