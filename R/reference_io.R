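#' Load a reference genome from FASTA
#'
#' Reads a (possibly multi-contig) FASTA file into an in-memory reference
#' index with random access by contig and 0-based, half-open coordinates.
#' Sequences are folded to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return A `ReferenceIndex` object (list with `seqs`, a named character
#'   vector of uppercase sequences, and `lengths`, named integer contig
#'   lengths in file order).
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path)
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) {
    stop("malformed FASTA '", path, "': no sequence records")
  }
  seqs <- toupper(as.character(set))
  # FASTA headers: contig name is the first whitespace-delimited token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  reference_index(seqs)
}

#' Build a reference index from named sequences
#'
#' @param seqs Named character vector of nucleotide sequences (one per
#'   contig), or a [Biostrings::DNAStringSet].
#' @return A `ReferenceIndex` object.
#' @export
reference_index <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
    stop("every contig needs a name")
  }
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("contig '", names(seqs)[bad][1L],
         "' contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(seqs = seqs, lengths = stats::setNames(nchar(seqs), names(seqs))),
    class = "ReferenceIndex"
  )
}

#' @export
print.ReferenceIndex <- function(x, ...) {
  cat("ReferenceIndex:", length(x$seqs), "contig(s),",
      format(sum(as.numeric(x$lengths)), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Fetch a reference subsequence with clamping
#'
#' Coordinates are 0-based, half-open and are clamped to
#' `[0, contig_length]`; an empty (or fully out-of-range) interval yields
#' the empty string.
#'
#' @param ref A `ReferenceIndex`.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return Uppercase subsequence as a character scalar.
#' @export
fetch_region <- function(ref, contig, start, end) {
  stopifnot(inherits(ref, "ReferenceIndex"))
  if (!contig %in% names(ref$lengths)) stop("unknown contig: ", contig)
  len <- ref$lengths[[contig]]
  s <- max(0L, as.integer(start))
  e <- min(len, as.integer(end))
  if (e <= s) return("")
  substr(ref$seqs[[contig]], s + 1L, e)
}

#' Reverse complement
#'
#' Vectorised reverse complement over the alphabet {A,C,G,T,N}; any other
#' character is an error (IUPAC ambiguity codes signal upstream corruption
#' rather than valid input here).
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Write a reference index to FASTA
#'
#' @param ref A `ReferenceIndex`.
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path, width = 70L) {
  stopifnot(inherits(ref, "ReferenceIndex"))
  set <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
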