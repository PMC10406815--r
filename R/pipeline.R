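validate_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` needs barcode rownames and sample colnames", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative counts are not allowed", call. = FALSE)
  invisible(counts)
}

#' Zero out low-confidence barcode counts
#'
#' Cells at or below the read floor are set to zero; the study's rule sets
#' counts "below or equal to 10" to zero, so the floor is inclusive.
#'
#' @param counts barcode x sample count matrix (see [count_barcodes()]).
#' @param floor inclusive threshold; counts `<= floor` become 0. Default 10.
#' @return the floored count matrix.
#' @export
#' @examples
#' m <- matrix(c(10, 11), 2, 1, dimnames = list(c("b1", "b2"), "s1"))
#' apply_read_floor(m)  # b1 -> 0, b2 stays 11
apply_read_floor <- function(counts, floor = 10) {
  validate_count_matrix(counts)
  stopifnot(floor >= 0)
  counts[counts <= floor] <- 0
  counts
}

#' Filter barcodes by replicate concordance
#'
#' Within each replicate group (samples sharing mouse, tissue and piece), a
#' barcode detected (nonzero, after the read floor) in fewer than
#' `min_detections` replicates is considered unreliable and zeroed in all
#' replicates of that group. Groups with fewer replicates than
#' `min_detections` cannot support the filter and raise an error, unless
#' `allow_small_groups = TRUE`, in which case they pass through unfiltered
#' with a message.
#'
#' @param counts floored count matrix.
#' @param sheet sample sheet covering every column of `counts`.
#' @param min_detections minimum number of replicates a barcode must appear in
#'   (default 2, the study's rule).
#' @param allow_small_groups skip rather than fail groups smaller than
#'   `min_detections`.
#' @return the filtered count matrix.
#' @export
filter_replicates <- function(counts, sheet, min_detections = 2,
                              allow_small_groups = FALSE) {
  validate_count_matrix(counts)
  stopifnot(min_detections >= 1)
  grp <- replicate_groups(sheet)
  unknown <- setdiff(colnames(counts), grp$sample_id)
  if (length(unknown)) {
    stop("samples absent from the sheet: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  groups <- split(grp$sample_id, grp$group_id)
  groups <- lapply(groups, intersect, colnames(counts))
  groups <- groups[lengths(groups) > 0L]
  small <- names(groups)[lengths(groups) < min_detections]
  if (length(small) && !allow_small_groups) {
    stop("replicate groups smaller than min_detections (", min_detections,
         "): ", paste(small, collapse = ", "),
         "; set allow_small_groups = TRUE to pass them through unfiltered",
         call. = FALSE)
  }
  for (g in names(groups)) {
    cols <- groups[[g]]
    if (length(cols) < min_detections) {
      message("replicate group ", g, " has ", length(cols),
              " replicate(s); concordance filter skipped")
      next
    }
    detections <- rowSums(counts[, cols, drop = FALSE] > 0)
    drop <- detections > 0 & detections < min_detections
    if (any(drop)) counts[drop, cols] <- 0
  }
  counts
}

# sum matrix columns by a grouping factor, preserving group-first-seen order
pool_columns <- function(counts, key) {
  key <- factor(key, levels = unique(key))
  pooled <- vapply(levels(key), function(k) {
    rowSums(counts[, key == k, drop = FALSE])
  }, numeric(nrow(counts)))
  pooled <- matrix(pooled, nrow = nrow(counts),
                   dimnames = list(rownames(counts), levels(key)))
  pooled
}

#' Pool technical replicates by summing read counts
#'
#' Replicates of the same biological unit are pooled by adding their barcode
#' read counts, yielding one column per replicate group.
#'
#' @param counts filtered count matrix.
#' @param sheet sample sheet covering every column of `counts`.
#' @return a list: `counts` (barcodes x replicate groups) and `sheet` (one row
#'   per pooled unit, usable in downstream stages).
#' @export
pool_replicates <- function(counts, sheet) {
  validate_count_matrix(counts)
  grp <- replicate_groups(sheet)
  key <- grp$group_id[match(colnames(counts), grp$sample_id)]
  if (anyNA(key)) {
    stop("samples absent from the sheet: ",
         paste(colnames(counts)[is.na(key)], collapse = ", "), call. = FALSE)
  }
  pooled <- pool_columns(counts, key)
  gs <- group_sheet(sheet)
  list(counts = pooled, sheet = gs[match(colnames(pooled), gs$sample_id), ])
}

#' Pool tumour pieces into whole-tumour columns
#'
#' Reassembles dissected tumours: all `tumour_piece` columns of the same mouse
#' are combined into a single `tumour` column. The default mode sums raw read
#' counts across pieces before normalisation (reading the study's "added and
#' normalised" literally); `"mean_of_frequencies"` instead averages the
#' per-piece frequency vectors (weighting each piece equally regardless of
#' its read depth) and rescales to the summed depth.
#'
#' @param counts replicate-pooled count matrix.
#' @param sheet the pooled-unit sheet from [pool_replicates()].
#' @param mode `"sum_raw_counts"` (default) or `"mean_of_frequencies"`.
#' @return a list: `counts` and updated `sheet`, where each mouse's pieces are
#'   replaced by one `<mouse>.tumour` column.
#' @export
pool_pieces <- function(counts, sheet,
                        mode = c("sum_raw_counts", "mean_of_frequencies")) {
  mode <- match.arg(mode)
  validate_count_matrix(counts)
  info <- sheet[match(colnames(counts), sheet$sample_id), ]
  is_piece <- info$tissue == "tumour_piece"
  if (!any(is_piece)) return(list(counts = counts, sheet = sheet))
  key <- ifelse(is_piece, paste0(info$mouse_id, ".tumour"), info$sample_id)
  if (mode == "sum_raw_counts") {
    pooled <- pool_columns(counts, key)
  } else {
    totals <- colSums(counts)
    freq <- sweep(counts, 2L, ifelse(totals > 0, totals, 1), "/")
    keyf <- factor(key, levels = unique(key))
    pooled <- vapply(levels(keyf), function(k) {
      cols <- which(keyf == k)
      p <- rowMeans(freq[, cols, drop = FALSE])
      s <- sum(p)
      if (s > 0) p <- p / s
      p * sum(totals[cols])
    }, numeric(nrow(counts)))
    pooled <- matrix(pooled, nrow = nrow(counts),
                     dimnames = list(rownames(counts), levels(keyf)))
  }
  new_sheet <- info
  new_sheet$sample_id <- key
  new_sheet$tissue[is_piece] <- "tumour"
  new_sheet$piece_id[is_piece] <- NA_character_
  new_sheet <- new_sheet[!duplicated(new_sheet$sample_id), ]
  new_sheet <- new_sheet[match(colnames(pooled), new_sheet$sample_id), ]
  rownames(new_sheet) <- NULL
  list(counts = pooled, sheet = new_sheet)
}

#' Collapse co-integrated barcodes into virtual barcodes
#'
#' Barcodes that co-occur at a constant frequency ratio across samples likely
#' mark a single founder cell carrying multiple integrations; each such group
#' is replaced by one virtual barcode whose counts are the member sums. The
#' virtual row takes the position of the group's first member; other rows keep
#' their order.
#'
#' @param counts count matrix.
#' @param groups named list: `virtual_id = c(member barcode IDs)`. Groups must
#'   be disjoint. An empty list is the identity.
#' @return the collapsed count matrix.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30), 3, 1,
#'             dimnames = list(c("915", "1312", "1864"), "s1"))
#' collapse_virtual_barcodes(m, list(v1 = c("915", "1312", "1864")))
collapse_virtual_barcodes <- function(counts, groups) {
  validate_count_matrix(counts)
  if (length(groups) == 0L) return(counts)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("virtual groups must be a named list (virtual_id = members)",
         call. = FALSE)
  }
  members <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(members)) {
    stop("virtual groups overlap: ",
         paste(unique(members[duplicated(members)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(members, rownames(counts))
  if (length(missing)) {
    stop("virtual group members absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (vid in names(groups)) {
    mem <- groups[[vid]]
    first <- match(mem[1L], rownames(counts))
    vrow <- colSums(counts[mem, , drop = FALSE])
    counts[first, ] <- vrow
    rownames(counts)[first] <- vid
    rest <- setdiff(mem, mem[1L])
    if (length(rest)) counts <- counts[!rownames(counts) %in% rest, ,
                                       drop = FALSE]
  }
  counts
}

#' Flag candidate co-integrated barcode groups
#'
#' Barcode pairs detected together in at least `min_shared_samples` units
#' whose frequency ratio is near-constant (coefficient of variation of
#' f1/f2 across shared units at most `ratio_cv_max`) are linked; connected
#' components of linked pairs are returned as candidate virtual groups. The
#' output is advisory: inspect before passing to
#' [collapse_virtual_barcodes()].
#'
#' @param profiles a `clonal_profiles` object (see [normalize_counts()]) or a
#'   barcode x unit frequency matrix.
#' @param min_shared_samples minimum number of units in which both barcodes
#'   must be detected (default 3).
#' @param ratio_cv_max maximum coefficient of variation of the pairwise
#'   frequency ratio (default 0.2).
#' @return a named list of candidate groups (`virtual_1`, `virtual_2`, ...),
#'   each a character vector of member barcode IDs; empty list if none.
#' @export
detect_co_integration <- function(profiles, min_shared_samples = 3,
                                  ratio_cv_max = 0.2) {
  freq <- as_freq_matrix(profiles)
  present <- freq > 0
  candidates <- which(rowSums(present) >= min_shared_samples)
  if (length(candidates) < 2L) return(list())
  ids <- rownames(freq)[candidates]
  sub <- freq[candidates, , drop = FALSE]
  presence <- sub > 0
  pairs <- NULL
  n <- length(candidates)
  for (i in seq_len(n - 1L)) {
    shared_i <- presence[i, ]
    for (j in seq.int(i + 1L, n)) {
      shared <- shared_i & presence[j, ]
      if (sum(shared) < min_shared_samples) next
      ratio <- sub[i, shared] / sub[j, shared]
      cv <- sd(ratio) / mean(ratio)
      if (is.finite(cv) && cv <= ratio_cv_max) {
        pairs <- rbind(pairs, c(i, j))
      }
    }
  }
  if (is.null(pairs)) return(list())
  # connected components via union-find
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(pairs))) {
    a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  comp <- split(ids, roots)
  comp <- comp[lengths(comp) >= 2L]
  names(comp) <- paste0("virtual_", seq_along(comp))
  lapply(comp, unname)
}

#' Normalise counts to clonal frequency profiles
#'
#' Each column is divided by its total, giving per-unit barcode frequency
#' vectors that sum to 1. Zero-total columns are flagged empty (their
#' frequencies are all zero, never NaN).
#'
#' @param counts pooled count matrix.
#' @return an object of class `clonal_profiles`: a list with `freq`
#'   (barcodes x units frequency matrix), `total_reads` (named vector) and
#'   `empty` (named logical).
#' @export
normalize_counts <- function(counts) {
  validate_count_matrix(counts)
  totals <- colSums(counts)
  empty <- totals == 0
  if (any(empty)) {
    warning("empty profile(s) with zero total reads: ",
            paste(colnames(counts)[empty], collapse = ", "))
  }
  freq <- sweep(counts, 2L, ifelse(empty, 1, totals), "/")
  out <- list(freq = freq,
              total_reads = setNames(as.numeric(totals), colnames(counts)),
              empty = setNames(empty, colnames(counts)))
  class(out) <- "clonal_profiles"
  out
}

#' @export
print.clonal_profiles <- function(x, ...) {
  cat(sprintf("clonal profiles: %d barcodes x %d units (%d empty)\n",
              nrow(x$freq), ncol(x$freq), sum(x$empty)))
  invisible(x)
}

# Accept a clonal_profiles object, a frequency matrix, or a named vector
# (single profile), and return a barcodes x units matrix.
as_freq_matrix <- function(x) {
  if (inherits(x, "clonal_profiles")) return(x$freq)
  if (is.matrix(x)) return(x)
  if (is.numeric(x) && !is.null(names(x))) {
    return(matrix(x, ncol = 1L, dimnames = list(names(x), "profile")))
  }
  stop("expected clonal_profiles, a frequency matrix, or a named vector",
       call. = FALSE)
}

#' Export clonal profiles as long-format TSV
#'
#' One row per (unit, detected barcode): `unit_id`, `barcode_id`, `frequency`,
#' `total_reads`.
#'
#' @param profiles a `clonal_profiles` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  stopifnot(inherits(profiles, "clonal_profiles"))
  freq <- profiles$freq
  idx <- which(freq > 0, arr.ind = TRUE)
  df <- data.frame(
    unit_id = colnames(freq)[idx[, 2L]],
    barcode_id = rownames(freq)[idx[, 1L]],
    frequency = freq[idx],
    total_reads = profiles$total_reads[idx[, 2L]],
    stringsAsFactors = FALSE
  )
  df <- df[order(df$unit_id, -df$frequency, df$barcode_id), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
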