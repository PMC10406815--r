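# Shared in-code fixtures: a toy 2-replicate / 2-mouse design and small
# random count tables used by the property-style tests.

toy_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c("m1.p1.r1", "m1.p1.r2", "m1.p2.r1", "m1.p2.r2",
                  "m1.lung.r1", "m1.lung.r2",
                  "m2.p1.r1", "m2.p1.r2"),
    index_sequence = c("AAAA", "AAAC", "AAAG", "AAAT",
                       "AACA", "AACC", "AACG", "AACT"),
    mouse_id = c(rep("m1", 6), rep("m2", 2)),
    route = "IMFP",
    tissue = c(rep("tumour_piece", 4), "lung", "lung",
               "tumour_piece", "tumour_piece"),
    piece_id = c("p1", "p1", "p2", "p2", NA, NA, "p1", "p1"),
    replicate_id = rep(c("r1", "r2"), 4),
    batch = "b1",
    stringsAsFactors = FALSE
  ))
}

toy_counts <- function(sheet = toy_sheet(), barcodes = paste0("bc", 1:6),
                       fill = 0) {
  matrix(fill, nrow = length(barcodes), ncol = nrow(sheet),
         dimnames = list(barcodes, sheet$sample_id))
}

random_counts <- function(n_barcodes, sheet, lambda = 40) {
  m <- matrix(rpois(n_barcodes * nrow(sheet), lambda),
              nrow = n_barcodes,
              dimnames = list(sprintf("bc%03d", seq_len(n_barcodes)),
                              sheet$sample_id))
  storage.mode(m) <- "double"
  m
}

# random frequency profile over n barcodes (named, sums to 1)
random_profile <- function(n, ids = sprintf("bc%03d", seq_len(n))) {
  x <- rgamma(n, shape = 0.5)
  setNames(x / sum(x), ids)
}

# minimal 3-barcode library with 21-nt sequences
tiny_library <- function() {
  barcode_library(
    c("b1", "b2", "b3"),
    c("ACGTACGTACGTACGTACGTA",
      "TTTTGGGGCCCCAAAATTTTG",
      "GATTACAGATTACAGATTACA")
  )
}

# build a FASTQ file of synthetic reads for the tiny library
write_tiny_fastq <- function(path, records) {
  lines <- unlist(lapply(records, function(r) {
    c(paste0("@", r$header), r$seq, "+", strrep("I", nchar(r$seq)))
  }))
  writeLines(lines, path)
  path
}
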