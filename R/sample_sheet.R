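ROUTE_LEVELS <- c("IMFP", "IMFPc", "SC", "ID", "IV", "in_vitro", "initial")
TISSUE_LEVELS <- c("tumour_piece", "lung", "liver", "blood", "flask",
                   "population")

#' Validate a sample sheet
#'
#' A sample sheet maps sequencing samples (technical replicates) to their
#' biological origin: mouse, injection route, tissue, tumour piece, replicate
#' and experiment batch. Replicates of the same `(mouse_id, tissue, piece_id)`
#' form a replicate group; the pipeline's concordance filter and pooling
#' operate on these groups.
#'
#' @param x a data frame with columns `sample_id`, `mouse_id`, `route`,
#'   `tissue`, `replicate_id`, `batch`, and optionally `index_sequence` and
#'   `piece_id`. `route` must be one of IMFP, IMFPc, SC, ID, IV, in_vitro,
#'   initial; `tissue` one of tumour_piece, lung, liver, blood, flask,
#'   population.
#' @param tumour_replicates if not `NULL`, require every tumour-piece replicate
#'   group to contain exactly this many replicates (the study design used
#'   duplicates).
#' @param organ_replicates if not `NULL`, require every blood/lung replicate
#'   group to contain exactly this many replicates (quintuplicates in the
#'   study's PDX arm).
#'
#' @return the validated data frame with class `sample_sheet`.
#' @export
as_sample_sheet <- function(x, tumour_replicates = NULL,
                            organ_replicates = NULL) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("sample_id", "mouse_id", "route", "tissue", "replicate_id",
                "batch")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"piece_id" %in% names(x)) x$piece_id <- NA_character_
  for (col in c("sample_id", "mouse_id", "route", "tissue", "replicate_id",
                "batch", "piece_id")) {
    x[[col]] <- as.character(x[[col]])
  }
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if ("index_sequence" %in% names(x)) {
    x$index_sequence <- toupper(as.character(x$index_sequence))
    if (anyDuplicated(x$index_sequence)) {
      stop("duplicate index_sequence in sample sheet", call. = FALSE)
    }
    if (length(unique(nchar(x$index_sequence))) > 1L) {
      stop("index sequences must have uniform length", call. = FALSE)
    }
  }
  bad_route <- setdiff(unique(x$route), ROUTE_LEVELS)
  if (length(bad_route)) {
    stop("unknown route(s): ", paste(bad_route, collapse = ", "),
         call. = FALSE)
  }
  bad_tissue <- setdiff(unique(x$tissue), TISSUE_LEVELS)
  if (length(bad_tissue)) {
    stop("unknown tissue(s): ", paste(bad_tissue, collapse = ", "),
         call. = FALSE)
  }
  grp <- replicate_groups(x)
  sizes <- table(grp$group_id)
  if (!is.null(tumour_replicates)) {
    tum <- unique(grp$group_id[x$tissue == "tumour_piece"])
    off <- tum[sizes[tum] != tumour_replicates]
    if (length(off)) {
      stop("tumour-piece groups without exactly ", tumour_replicates,
           " replicates: ", paste(off, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(organ_replicates)) {
    org <- unique(grp$group_id[x$tissue %in% c("blood", "lung")])
    off <- org[sizes[org] != organ_replicates]
    if (length(off)) {
      stop("blood/lung groups without exactly ", organ_replicates,
           " replicates: ", paste(off, collapse = ", "), call. = FALSE)
    }
  }
  class(x) <- c("sample_sheet", "data.frame")
  x
}

#' Read a sample sheet TSV
#'
#' @param path path to a TSV with the columns documented in
#'   [as_sample_sheet()].
#' @inheritParams as_sample_sheet
#' @return a `sample_sheet` data frame.
#' @export
read_sample_sheet <- function(path, tumour_replicates = NULL,
                              organ_replicates = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  as_sample_sheet(df, tumour_replicates, organ_replicates)
}

#' Replicate groups of a sample sheet
#'
#' Technical replicates share a `(mouse_id, tissue, piece_id)` key. The
#' returned `group_id` is the biological-unit identifier used as the column
#' name after replicate pooling.
#'
#' @param sheet a sample sheet (see [as_sample_sheet()]).
#' @return a data frame with one row per sample: `sample_id`, `group_id`,
#'   `mouse_id`, `route`, `tissue`, `piece_id`, `batch`.
#' @export
replicate_groups <- function(sheet) {
  piece <- ifelse(is.na(sheet$piece_id) | sheet$piece_id == "", "",
                  paste0(".", sheet$piece_id))
  data.frame(
    sample_id = sheet$sample_id,
    group_id = paste0(sheet$mouse_id, ".", sheet$tissue, piece),
    mouse_id = sheet$mouse_id,
    route = sheet$route,
    tissue = sheet$tissue,
    piece_id = sheet$piece_id,
    batch = sheet$batch,
    stringsAsFactors = FALSE
  )
}

# one row per replicate group, for the pooled stage's sheet
group_sheet <- function(sheet) {
  grp <- replicate_groups(sheet)
  grp <- grp[!duplicated(grp$group_id),
             c("group_id", "mouse_id", "route", "tissue", "piece_id", "batch")]
  names(grp)[1L] <- "sample_id"
  rownames(grp) <- NULL
  grp
}
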