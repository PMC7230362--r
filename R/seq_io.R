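#' Read a FASTQ file into a read set
#'
#' Reads plain or gzip-compressed FASTQ (4-line records, offset-33 qualities)
#' and returns a [read_set()] in file order. Each record is validated: a
#' quality line whose length differs from the sequence line is a hard error
#' naming the offending read, as silently mispaired qualities would corrupt
#' every downstream quality computation.
#'
#' @param path path to a FASTQ file (`.fastq`, `.fq`, optionally `.gz`).
#' @return A [read_set()]; empty files yield an empty read set.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- gzfile(path, open = "rt")  # transparently handles uncompressed input
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) {
    return(read_set(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (", path, "): number of lines is not a multiple of 4")
  }
  hdr <- lines[seq(1L, length(lines), by = 4L)]
  seq <- lines[seq(2L, length(lines), by = 4L)]
  plus <- lines[seq(3L, length(lines), by = 4L)]
  qual <- lines[seq(4L, length(lines), by = 4L)]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop("malformed FASTQ (", path, "): header line missing '@'")
  }
  if (any(substr(plus, 1L, 1L) != "+")) {
    stop("malformed FASTQ (", path, "): separator line missing '+'")
  }
  id <- sub("\\s.*$", "", substring(hdr, 2L))
  bad <- which(nchar(qual) != nchar(seq))
  if (length(bad)) {
    stop("malformed FASTQ record '", id[bad[1]],
         "': quality line length differs from sequence line length")
  }
  read_set(id, seq, qual)
}

#' Write a read set to FASTQ
#'
#' Writes offset-33 FASTQ; a `.gz` suffix selects gzip compression. Writing
#' then reading back reproduces the read set exactly (bit-exact round trip).
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(inherits(reads, "read_set"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$read_id), reads$bases, "+", reads$quals)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Construct reference sequences
#'
#' References are the short, unambiguous sequences the pipeline aligns reads
#' and consensuses against: amplicon references (barcode sequences), PCR
#' primers and sample indexes. Primers and indexes must be `N`-free so that
#' edit distances against them are well defined.
#'
#' @param name character vector of unique names.
#' @param bases character vector of DNA sequences.
#' @param role one of `"amplicon_reference"`, `"primer"`, `"index"`;
#'   recycled.
#' @return A data frame of class `reference_set` with columns `name`,
#'   `bases`, `role`.
#' @export
reference_set <- function(name, bases, role = "amplicon_reference") {
  name <- as.character(name)
  bases <- toupper(as.character(bases))
  role <- rep_len(as.character(role), length(name))
  stopifnot(all(role %in% c("amplicon_reference", "primer", "index")))
  if (anyDuplicated(name)) {
    stop("duplicate reference names: ", name[duplicated(name)][1])
  }
  if (any(!nchar(bases))) stop("reference sequences must be non-empty")
  if (any(grepl("[^ACGTN]", bases))) stop("non-DNA characters in reference")
  short <- role %in% c("primer", "index")
  if (any(short & grepl("N", bases, fixed = TRUE))) {
    stop("primers and indexes must not contain N")
  }
  if (any(short & nchar(bases) >= 50L)) {
    stop("primers and indexes are expected to be short (< 50 nt)")
  }
  out <- data.frame(name = name, bases = bases, role = role,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_set", "data.frame")
  out
}

#' Read reference sequences from FASTA
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param role role to assign to all records (see [reference_set()]).
#' @return A [reference_set()] in file order; lowercase input is uppercased.
#' @export
read_fasta <- function(path, role = "amplicon_reference") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    stop("duplicate FASTA names in ", path, ": ", nm[duplicated(nm)][1])
  }
  reference_set(nm, as.character(x), role)
}

#' Write reference sequences to FASTA
#'
#' @param refs a [reference_set()] or named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(refs, path) {
  if (is.character(refs)) {
    refs <- reference_set(names(refs), refs)
  }
  x <- Biostrings::DNAStringSet(refs$bases)
  names(x) <- refs$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
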