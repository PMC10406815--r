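#' Construct a barcode reference library
#'
#' A barcode library is the reference repertoire of clone labels: a mapping of
#' barcode IDs to nucleotide sequences, all of equal length. The study design
#' this package targets uses a lentiviral library of ~2500 unique barcodes;
#' any size >= 1 is accepted.
#'
#' @param barcode_id character vector of unique barcode identifiers.
#' @param sequence character vector of unique, equal-length A/C/G/T sequences.
#'
#' @return A data frame of class `barcode_library` with columns `barcode_id`
#'   and `sequence`.
#' @seealso [read_barcode_library()], [generate_barcode_library()]
#' @export
#' @examples
#' barcode_library(c("b1", "b2"), c("ACGTACG", "TTGCATG"))
barcode_library <- function(barcode_id, sequence) {
  barcode_id <- as.character(barcode_id)
  sequence <- toupper(as.character(sequence))
  if (length(barcode_id) != length(sequence)) {
    stop("`barcode_id` and `sequence` must have the same length", call. = FALSE)
  }
  if (length(barcode_id) < 1L) {
    stop("a barcode library needs at least one entry", call. = FALSE)
  }
  if (anyDuplicated(barcode_id)) {
    stop("duplicate barcode IDs: ",
         paste(unique(barcode_id[duplicated(barcode_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sequence)) {
    stop("duplicate barcode sequences (IDs: ",
         paste(barcode_id[sequence %in% sequence[duplicated(sequence)]],
               collapse = ", "), ")", call. = FALSE)
  }
  if (length(unique(nchar(sequence))) != 1L) {
    stop("all barcode sequences must have the same length", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sequence))) {
    stop("barcode sequences may contain only A/C/G/T", call. = FALSE)
  }
  structure(
    data.frame(barcode_id = barcode_id, sequence = sequence,
               stringsAsFactors = FALSE),
    class = c("barcode_library", "data.frame")
  )
}

#' Read a barcode library from TSV or FASTA
#'
#' The TSV format is two tab-separated columns, `barcode_id<TAB>sequence`, with
#' an optional header line. In FASTA the record identifier is the barcode ID.
#'
#' @param path path to the library file.
#' @param format `"auto"` (by extension), `"tsv"` or `"fasta"`.
#'
#' @return A [barcode_library()].
#' @export
read_barcode_library <- function(path, format = c("auto", "tsv", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)(\\.gz)?$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readDNAStringSet(path)
    return(barcode_library(names(seqs), as.character(seqs)))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty library file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    stop("malformed library record at line ", bad[1L], " of ", path,
         " (expected 2 tab-separated fields)", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  seqs <- vapply(fields, `[[`, "", 2L)
  # tolerate a header line such as "barcode_id\tsequence"
  if (grepl("[^ACGTacgt]", seqs[1L])) {
    if (length(ids) == 1L) stop("no data rows in ", path, call. = FALSE)
    ids <- ids[-1L]
    seqs <- seqs[-1L]
  }
  barcode_library(ids, seqs)
}

#' Write a barcode library to a two-column TSV
#'
#' @param library a [barcode_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_barcode_library <- function(library, path) {
  stopifnot(inherits(library, "barcode_library"))
  write.table(as.data.frame(library), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode library: %d barcodes of %d nt\n",
              nrow(x), nchar(x$sequence[1L])))
  print(head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}
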