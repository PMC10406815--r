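#' Describe the amplicon read architecture
#'
#' Reads are expected to contain a constant anchor sequence immediately 5' of
#' the barcode. The default anchor is the 3' end of the common forward
#' amplification primer (TopLib, `TGCTGCCGTCAACTAGAACA`); the barcode is read
#' as the fixed-length window immediately after the located anchor. The exact
#' index placement and barcode offset of any given sequencing run are
#' run-specific, so all fields are configurable.
#'
#' @param upstream_anchor constant sequence immediately 5' of the barcode.
#' @param barcode_length barcode length in nucleotides (must equal the library
#'   sequence length at counting time).
#' @param max_mismatch_anchor substitutions tolerated when locating the anchor
#'   (default 2: tolerant location, strict barcode call).
#' @param max_mismatch_barcode substitutions tolerated in the barcode call.
#'   Default 0 (exact matching); 1 enables single-mismatch rescue where a read
#'   barcode matching two or more library barcodes equally well is discarded
#'   as ambiguous rather than assigned.
#' @param anchor_window the anchor must start within the first this-many
#'   nucleotides of the read.
#'
#' @return a list of class `read_structure`.
#' @export
read_structure <- function(upstream_anchor = "TGCTGCCGTCAACTAGAACA",
                           barcode_length = 21L,
                           max_mismatch_anchor = 2L,
                           max_mismatch_barcode = 0L,
                           anchor_window = 60L) {
  upstream_anchor <- toupper(upstream_anchor)
  stopifnot(
    nchar(upstream_anchor) > 0L, !grepl("[^ACGT]", upstream_anchor),
    barcode_length >= 1L, max_mismatch_anchor >= 0L,
    max_mismatch_barcode >= 0L, anchor_window >= 1L
  )
  if (max_mismatch_barcode > 1L) {
    stop("barcode mismatch rescue is supported up to 1 substitution",
         call. = FALSE)
  }
  structure(
    list(upstream_anchor = upstream_anchor,
         barcode_length = as.integer(barcode_length),
         max_mismatch_anchor = as.integer(max_mismatch_anchor),
         max_mismatch_barcode = as.integer(max_mismatch_barcode),
         anchor_window = as.integer(anchor_window)),
    class = "read_structure"
  )
}

#' Demultiplex amplicon reads and count barcodes
#'
#' Assigns each read to a sample by its index and to a barcode by locating the
#' constant anchor and matching the following window against the reference
#' library, producing a barcode x sample matrix of read counts at technical
#' replicate granularity. Every read is assigned to at most one
#' (sample, barcode) pair; reads failing index, anchor or barcode matching are
#' tallied per category, so assigned + discarded always equals the number of
#' input reads.
#'
#' @param fastq character vector of FASTQ paths (gzip transparent), or a
#'   `Biostrings::DNAStringSet` whose names carry the read headers.
#' @param sheet a sample sheet with an `index_sequence` column
#'   (see [as_sample_sheet()]).
#' @param library a [barcode_library()].
#' @param structure a [read_structure()]; its `barcode_length` must equal the
#'   library sequence length.
#' @param index_from where the sample index lives: `"header"` (default; the
#'   final colon-separated field of the read header, as written by Illumina
#'   pipelines) or `"sequence"` (the first `n` nucleotides of the read, where
#'   `n` is the sheet's index length; the anchor is then searched after the
#'   index).
#'
#' @return a list of class `barcode_counts`:
#'   \describe{
#'     \item{counts}{integer matrix, barcodes x samples.}
#'     \item{discards}{named integer vector with categories `unmatched_index`,
#'       `unmatched_anchor`, `unmatched_barcode`, `ambiguous`.}
#'     \item{assigned,total_reads}{read tallies.}
#'   }
#' @export
count_barcodes <- function(fastq, sheet, library,
                           structure = read_structure(),
                           index_from = c("header", "sequence")) {
  index_from <- match.arg(index_from)
  stopifnot(inherits(library, "barcode_library"))
  if (!"index_sequence" %in% names(sheet)) {
    stop("sample sheet needs an `index_sequence` column for demultiplexing",
         call. = FALSE)
  }
  if (nchar(library$sequence[1L]) != structure$barcode_length) {
    stop("structure$barcode_length (", structure$barcode_length,
         ") does not match the library sequence length (",
         nchar(library$sequence[1L]), ")", call. = FALSE)
  }

  if (inherits(fastq, "DNAStringSet")) {
    reads <- fastq
  } else {
    sets <- lapply(fastq, Biostrings::readDNAStringSet, format = "fastq",
                   with.qualities = FALSE)
    reads <- do.call(c, sets)
  }

  sample_ids <- sheet$sample_id
  counts <- matrix(0L, nrow = nrow(library), ncol = length(sample_ids),
                   dimnames = list(library$barcode_id, sample_ids))
  discards <- c(unmatched_index = 0L, unmatched_anchor = 0L,
                unmatched_barcode = 0L, ambiguous = 0L)
  total <- length(reads)
  if (total == 0L) {
    warning("empty read stream: returning an all-zero count table")
    return(new_barcode_counts(counts, discards, 0L, 0L))
  }

  seqs <- as.character(reads)
  index_len <- nchar(sheet$index_sequence[1L])
  offset <- 0L
  if (index_from == "header") {
    headers <- names(reads)
    if (is.null(headers)) {
      stop("reads carry no headers; cannot take the index from them",
           call. = FALSE)
    }
    idx <- sub("^.*:", "", headers)
    idx[!grepl(":", headers)] <- ""
  } else {
    if (any(nchar(seqs) < index_len)) {
      stop("reads shorter than the configured index length", call. = FALSE)
    }
    idx <- substr(seqs, 1L, index_len)
    offset <- index_len
  }
  sample_of <- match(idx, sheet$index_sequence)

  # anchor location: exact scan first, mismatch-tolerant rescue on the rest
  anchor <- structure$upstream_anchor
  alen <- nchar(anchor)
  window_end <- offset + structure$anchor_window + alen - 1L
  scan <- substr(seqs, offset + 1L, window_end)
  pos <- regexpr(anchor, scan, fixed = TRUE)
  pos <- ifelse(pos > 0L, pos + offset, NA_integer_)
  if (structure$max_mismatch_anchor > 0L && anyNA(pos)) {
    todo <- which(is.na(pos) & !is.na(sample_of))
    if (length(todo)) {
      hits <- Biostrings::vmatchPattern(
        anchor,
        Biostrings::DNAStringSet(substr(seqs[todo], offset + 1L, window_end)),
        max.mismatch = structure$max_mismatch_anchor
      )
      first <- vapply(Biostrings::startIndex(hits), function(s) {
        if (is.null(s) || length(s) == 0L) NA_integer_ else min(s)
      }, integer(1L))
      pos[todo] <- first + offset
    }
  }

  bc_start <- pos + alen
  bc <- substr(seqs, bc_start, bc_start + structure$barcode_length - 1L)
  bc_ok <- !is.na(pos) & nchar(bc) == structure$barcode_length
  hit <- rep(NA_integer_, total)
  hit[bc_ok] <- match(bc[bc_ok], library$sequence)

  ambiguous <- logical(total)
  if (structure$max_mismatch_barcode >= 1L) {
    todo <- which(bc_ok & is.na(hit))
    if (length(todo)) {
      res <- hamming1_lookup(bc[todo], library$sequence)
      hit[todo] <- ifelse(res > 0L, res, NA_integer_)
      ambiguous[todo] <- res == -1L
    }
  }

  no_index <- is.na(sample_of)
  no_anchor <- !no_index & is.na(pos)
  short_bc <- !no_index & !is.na(pos) & !bc_ok
  no_barcode <- (!no_index & bc_ok & is.na(hit) & !ambiguous) | short_bc
  amb <- !no_index & ambiguous
  keep <- !no_index & !is.na(hit) & !amb

  discards["unmatched_index"] <- sum(no_index)
  discards["unmatched_anchor"] <- sum(no_anchor)
  discards["unmatched_barcode"] <- sum(no_barcode)
  discards["ambiguous"] <- sum(amb)

  if (any(keep)) {
    tab <- table(factor(hit[keep], levels = seq_len(nrow(library))),
                 factor(sample_of[keep], levels = seq_along(sample_ids)))
    counts[] <- as.integer(tab)
  }
  new_barcode_counts(counts, discards, sum(keep), total)
}

new_barcode_counts <- function(counts, discards, assigned, total) {
  out <- list(counts = counts, discards = discards,
              assigned = as.integer(assigned), total_reads = as.integer(total))
  class(out) <- "barcode_counts"
  out
}

# Single-substitution barcode rescue. For each query, returns the library row
# matching at Hamming distance <= 1 if unique, -1 if two or more library
# barcodes tie at the best distance, 0 if none match.
hamming1_lookup <- function(queries, lib_seqs) {
  uq <- unique(queries)
  width <- nchar(lib_seqs[1L])
  n_hits <- integer(length(uq))
  best <- integer(length(uq))
  valid <- nchar(uq) == width & !grepl("[^ACGT]", uq)
  for (pos in seq_len(width)) {
    for (base in c("A", "C", "G", "T")) {
      variant <- uq
      substr(variant, pos, pos) <- base
      changed <- valid & variant != uq
      m <- match(variant[changed], lib_seqs)
      found <- !is.na(m)
      ii <- which(changed)[found]
      mm <- m[found]
      new_hit <- n_hits[ii] == 0L | best[ii] != mm
      n_hits[ii] <- n_hits[ii] + as.integer(new_hit)
      best[ii] <- mm
    }
  }
  res <- ifelse(n_hits == 1L, best, ifelse(n_hits >= 2L, -1L, 0L))
  res[match(queries, uq)]
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat(sprintf(
    "barcode counts: %d barcodes x %d samples; %d/%d reads assigned\n",
    nrow(x$counts), ncol(x$counts), x$assigned, x$total_reads))
  cat("discards:", paste(names(x$discards), x$discards, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Write a count matrix (and optional discard tally) to TSV
#'
#' @param counts integer matrix (barcodes x samples) or a `barcode_counts`
#'   object, in which case the discard tally is written to a `.discards.tsv`
#'   sidecar.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  if (inherits(counts, "barcode_counts")) {
    tally <- data.frame(category = names(counts$discards),
                        reads = as.integer(counts$discards))
    write.table(tally, sub("\\.tsv$", ".discards.tsv", path), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts <- counts$counts
  }
  df <- data.frame(barcode_id = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode x sample count matrix from TSV
#'
#' @param path TSV with a `barcode_id` first column and one column per sample.
#' @return numeric matrix with barcode rownames.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  validate_count_matrix(m)
  m
}
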