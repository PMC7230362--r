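#' Construct a set of sequencing reads
#'
#' A `read_set` is the package's container for basecalled reads: a data frame
#' with one row per read holding the read identifier, the base string over
#' `{A,C,G,T,N}`, the per-base Phred qualities (stored compactly as the
#' offset-33 ASCII string, exactly as they appear in FASTQ), and a strand
#' orientation label. Orientation starts out `"unknown"`; demultiplexing and
#' clustering set it.
#'
#' @param read_id character vector of unique read identifiers.
#' @param bases character vector of DNA sequences (`A/C/G/T/N`; lowercase is
#'   accepted and uppercased).
#' @param quals per-base Phred qualities: either a list of integer vectors
#'   (one per read, same length as the read) or a character vector of
#'   offset-33 encoded quality strings.
#' @param orientation strand labels, one of `"forward"`, `"reverse"`,
#'   `"unknown"`; recycled if length 1.
#'
#' @return A data frame of class `read_set` with columns `read_id`, `bases`,
#'   `quals` (ASCII offset-33), `orientation`.
#' @examples
#' rs <- read_set("r1", "ACGT", list(c(40L, 40L, 40L, 40L)))
#' read_quals(rs)[[1]]
#' @export
read_set <- function(read_id, bases, quals, orientation = "unknown") {
  read_id <- as.character(read_id)
  bases <- toupper(as.character(bases))
  if (anyDuplicated(read_id)) {
    stop("duplicate read ids: ", paste(read_id[duplicated(read_id)][1]))
  }
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad)) {
    stop("read '", read_id[which(bad)[1]], "' contains non-DNA characters")
  }
  if (is.list(quals)) {
    qlen <- lengths(quals)
    qual_chr <- vapply(quals, phred_to_ascii, character(1))
  } else {
    qual_chr <- as.character(quals)
    qlen <- nchar(qual_chr)
  }
  mism <- which(qlen != nchar(bases))
  if (length(mism)) {
    stop("read '", read_id[mism[1]],
         "': quality length does not match sequence length")
  }
  orientation <- rep_len(as.character(orientation), length(read_id))
  stopifnot(all(orientation %in% c("forward", "reverse", "unknown")))
  out <- data.frame(read_id = read_id, bases = bases, quals = qual_chr,
                    orientation = orientation, stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set with %d read(s)\n", nrow(x)))
  if (nrow(x)) {
    ln <- nchar(x$bases)
    cat(sprintf("  length: %d-%d (mean %.1f)\n", min(ln), max(ln), mean(ln)))
    cat(sprintf("  mean read quality: %.2f\n",
                mean(vapply(seq_len(nrow(x)), function(i)
                  mean_read_quality(x[i, , drop = FALSE]), numeric(1)))))
  }
  invisible(x)
}

#' @export
`[.read_set` <- function(x, i, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("read_id", "bases", "quals") %in% names(out))) {
    class(out) <- c("read_set", "data.frame")
  }
  out
}

#' Per-base Phred qualities of a read set
#'
#' @param reads a [read_set()].
#' @return A list of integer vectors, one per read.
#' @export
read_quals <- function(reads) {
  lapply(reads$quals, ascii_to_phred)
}

# offset-33 codecs; the modern FASTQ dialect is fixed here by design
phred_to_ascii <- function(q) {
  q <- as.integer(q)
  if (length(q) && (anyNA(q) || any(q < 0L))) stop("Phred scores must be >= 0")
  intToUtf8(pmin(q, 93L) + 33L)
}

ascii_to_phred <- function(s) {
  if (!nchar(s)) return(integer(0))
  utf8ToInt(s) - 33L
}

#' Reverse complement of DNA sequences
#'
#' Length-preserving involution over the alphabet `{A,C,G,T,N}` (`N` maps to
#' `N`). Vectorised over its input.
#'
#' @param bases character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAAC")  # "GTTT"
#' @export
reverse_complement <- function(bases) {
  bases <- toupper(bases)
  if (any(grepl("[^ACGTN]", bases))) {
    stop("reverse_complement: input contains non-DNA characters")
  }
  if (!length(bases)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(bases)))
}

# reverse-complement whole reads (sequence, reversed qualities, flipped strand)
rc_read_set <- function(reads) {
  if (!nrow(reads)) return(reads)
  reads$bases <- reverse_complement(reads$bases)
  reads$quals <- vapply(reads$quals, function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1))
  reads$orientation <- c(forward = "reverse", reverse = "forward",
                         unknown = "unknown")[reads$orientation]
  reads
}
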