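# Reads are built by hand around the default anchor so every branch of the
# demultiplexer (index, anchor, barcode, ambiguity) is exercised exactly.

anchor <- read_structure()$upstream_anchor

two_sample_sheet <- function() {
  as_sample_sheet(data.frame(
    sample_id = c("S1", "S2"),
    index_sequence = c("ACGTACGT", "TGCATGCA"),
    mouse_id = c("m1", "m1"), route = "IMFP",
    tissue = c("tumour_piece", "tumour_piece"),
    piece_id = c("p1", "p1"), replicate_id = c("r1", "r2"), batch = "b1",
    stringsAsFactors = FALSE
  ))
}

make_read <- function(barcode_seq, index = "ACGTACGT", n = 1L,
                      prefix = "", mutate_at = NA) {
  seq <- paste0(prefix, anchor, barcode_seq, "GATCGATC")
  if (!is.na(mutate_at)) {
    pos <- nchar(prefix) + nchar(anchor) + mutate_at
    old <- substr(seq, pos, pos)
    substr(seq, pos, pos) <- setdiff(c("A", "C", "G", "T"), old)[1L]
  }
  lapply(seq_len(n), function(i) {
    list(header = sprintf("r%d 1:N:0:%s", i, index), seq = seq)
  })
}

test_that("constructed reads are counted into the right cells", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  path <- withr::local_tempfile(fileext = ".fastq")
  write_tiny_fastq(path, make_read(lib$sequence[2L], n = 10L))
  res <- count_barcodes(path, sheet, lib)
  expect_equal(res$counts["b2", "S1"], 10L)
  expect_equal(sum(res$counts), 10L)
  expect_equal(res$assigned, 10L)
  expect_equal(sum(res$discards), 0L)
})

test_that("discard categories and read conservation hold", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  path <- withr::local_tempfile(fileext = ".fastq")
  records <- c(
    make_read(lib$sequence[1L], n = 3L),                      # assigned S1
    make_read(lib$sequence[3L], index = "TGCATGCA", n = 2L),  # assigned S2
    make_read(lib$sequence[1L], index = "GGGGGGGG", n = 2L),  # bad index
    make_read(lib$sequence[2L], n = 1L, mutate_at = 5L),      # bad barcode
    list(list(header = "x 1:N:0:ACGTACGT",
              seq = strrep("A", 60L)))                        # no anchor
  )
  write_tiny_fastq(path, records)
  res <- count_barcodes(path, sheet, lib)
  expect_equal(res$counts["b1", "S1"], 3L)
  expect_equal(res$counts["b3", "S2"], 2L)
  expect_equal(as.integer(res$discards["unmatched_index"]), 2L)
  expect_equal(as.integer(res$discards["unmatched_barcode"]), 1L)
  expect_equal(as.integer(res$discards["unmatched_anchor"]), 1L)
  # conservation: assigned + discarded = total input reads
  expect_equal(res$assigned + sum(res$discards), res$total_reads)
  expect_equal(res$total_reads, 9L)
})

test_that("single-mismatch reads are rescued only when allowed, and raising
           the allowance never decreases counts", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  path <- withr::local_tempfile(fileext = ".fastq")
  write_tiny_fastq(path, c(make_read(lib$sequence[2L], n = 4L),
                           make_read(lib$sequence[2L], n = 2L,
                                     mutate_at = 7L)))
  strict <- count_barcodes(path, sheet, lib,
                           read_structure(max_mismatch_barcode = 0L))
  lenient <- count_barcodes(path, sheet, lib,
                            read_structure(max_mismatch_barcode = 1L))
  expect_equal(strict$counts["b2", "S1"], 4L)
  expect_equal(as.integer(strict$discards["unmatched_barcode"]), 2L)
  expect_equal(lenient$counts["b2", "S1"], 6L)
  expect_true(all(lenient$counts >= strict$counts))
})

test_that("reads matching two barcodes equally well are discarded", {
  lib <- barcode_library(c("b1", "b2"), c("AAAAAA", "AAAATT"))
  sheet <- two_sample_sheet()
  rs <- read_structure(barcode_length = 6L, max_mismatch_barcode = 1L)
  path <- withr::local_tempfile(fileext = ".fastq")
  # AAAAAT is Hamming-1 from both library barcodes
  write_tiny_fastq(path, list(list(header = "r1 1:N:0:ACGTACGT",
                                   seq = paste0(anchor, "AAAAAT", "GG"))))
  res <- count_barcodes(path, sheet, lib, rs)
  expect_equal(sum(res$counts), 0L)
  expect_equal(as.integer(res$discards["ambiguous"]), 1L)
})

test_that("counting is invariant to read order", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  records <- c(make_read(lib$sequence[1L], n = 5L),
               make_read(lib$sequence[2L], index = "TGCATGCA", n = 3L),
               make_read(lib$sequence[3L], n = 2L, prefix = "TT"))
  p1 <- withr::local_tempfile(fileext = ".fastq")
  p2 <- withr::local_tempfile(fileext = ".fastq")
  write_tiny_fastq(p1, records)
  write_tiny_fastq(p2, rev(records))
  r1 <- count_barcodes(p1, sheet, lib)
  r2 <- count_barcodes(p2, sheet, lib)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$discards, r2$discards)
})

test_that("anchor is found despite stagger and tolerated mismatches", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  mut_anchor <- anchor
  substr(mut_anchor, 3L, 3L) <- setdiff(c("A", "C", "G", "T"),
                                        substr(anchor, 3L, 3L))[1L]
  path <- withr::local_tempfile(fileext = ".fastq")
  write_tiny_fastq(path, list(
    list(header = "a 1:N:0:ACGTACGT",
         seq = paste0("GGTT", anchor, lib$sequence[1L])),
    list(header = "b 1:N:0:ACGTACGT",
         seq = paste0(mut_anchor, lib$sequence[1L]))
  ))
  res <- count_barcodes(path, sheet, lib)
  expect_equal(res$counts["b1", "S1"], 2L)
})

test_that("an empty stream warns and returns an all-zero table", {
  lib <- tiny_library()
  sheet <- two_sample_sheet()
  path <- withr::local_tempfile(fileext = ".fastq")
  writeLines(character(0), path)
  expect_warning(res <- count_barcodes(path, sheet, lib), "empty")
  expect_equal(sum(res$counts), 0L)
  expect_equal(res$total_reads, 0L)
})

test_that("error-free synthetic FASTQ reproduces generator truth exactly", {
  cfg <- simulation_config(n_barcodes = 60, n_mice = 1, routes = "IMFP",
                           n_cells_injected = 2000, read_depth = 3000,
                           n_pieces = 2, seed = 19)
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  ex <- simulate_experiment(cfg, fastq = fq)
  res <- count_barcodes(fq, ex$sheet, ex$library,
                        read_structure(barcode_length = cfg$barcode_length))
  expect_identical(res$counts[rownames(ex$counts), colnames(ex$counts)],
                   ex$counts)
  expect_equal(sum(res$discards), 0L)
})
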