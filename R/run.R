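#' Run the full clonal-tracking pipeline from one configuration
#'
#' Executes the stages in fixed order — count (when FASTQ input is given),
#' read floor, replicate concordance, replicate pooling, virtual-barcode
#' collapsing, piece pooling, normalisation, then diversity/correlation
#' statistics and (optionally) the neutral-appearance comparison — and writes
#' every result as TSV plus a JSON run manifest recording the configuration,
#' input digests, package version, seed and per-stage record counts. Any
#' stage failure aborts with the stage name.
#'
#' @param config a list, or the path to a YAML file, with entries:
#'   \describe{
#'     \item{counts / sample_sheet}{paths to a replicate-level count TSV and
#'       sample sheet TSV; alternatively in-memory objects.}
#'     \item{fastq / library}{FASTQ path(s) and barcode library path, used
#'       instead of `counts` for raw-read input (requires `index_sequence`
#'       in the sheet).}
#'     \item{read_floor}{inclusive count floor (default 10).}
#'     \item{min_replicate_detections}{concordance minimum (default 2).}
#'     \item{allow_small_groups}{pass groups smaller than the minimum through
#'       unfiltered instead of failing (default FALSE).}
#'     \item{piece_pooling}{`"sum_raw_counts"` (default) or
#'       `"mean_of_frequencies"`.}
#'     \item{virtual_groups}{named list of co-integrated barcode groups to
#'       collapse (default none).}
#'     \item{reference_route}{route for the richness log2 fold change
#'       (default `"IMFP"`, skipped when absent from the data).}
#'     \item{determinism}{optional list with `p0_unit` (the pooled unit
#'       holding the initial-population profile), `n_cells_injected`,
#'       and optionally `n_reps` (default 1000).}
#'     \item{seed}{RNG seed for the determinism stage (default 1).}
#'   }
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the pooled `profiles`, the `diversity`
#'   table, the `correlation` result, the `presence` table (or `NULL`) and
#'   the `manifest`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    package = "clonetrace",
    version = as.character(packageVersion("clonetrace")),
    seed = config$seed %||% 1L,
    config = config[setdiff(names(config), c("counts", "sample_sheet"))],
    inputs = list(),
    stages = list()
  )
  digest_input <- function(name, x) {
    if (is.character(x)) {
      manifest$inputs[[name]] <<- as.list(tools::md5sum(x))
    }
  }

  sheet <- stage("sample_sheet", {
    if (is.character(config$sample_sheet)) {
      digest_input("sample_sheet", config$sample_sheet)
      read_sample_sheet(config$sample_sheet)
    } else {
      as_sample_sheet(config$sample_sheet)
    }
  })

  counting <- NULL
  counts <- stage("count", {
    if (!is.null(config$fastq)) {
      digest_input("fastq", config$fastq)
      digest_input("library", config$library)
      lib <- if (is.character(config$library))
        read_barcode_library(config$library) else config$library
      rs <- do.call(read_structure, config$read_structure %||% list())
      counting <- count_barcodes(config$fastq, sheet, lib, rs)
      write_count_table(counting, file.path(out_dir, "counts_replicate.tsv"))
      manifest$stages$count <- list(
        total_reads = counting$total_reads, assigned = counting$assigned,
        discards = as.list(counting$discards))
      counting$counts
    } else if (is.character(config$counts)) {
      digest_input("counts", config$counts)
      read_count_table(config$counts)
    } else {
      validate_count_matrix(config$counts)
      config$counts
    }
  })
  global_richness <- function(m) sum(rowSums(m > 0) > 0)
  manifest$stages$input <- list(barcodes = nrow(counts),
                                samples = ncol(counts),
                                detected_barcodes = global_richness(counts))

  floor <- config$read_floor %||% 10
  counts <- stage("read_floor", apply_read_floor(counts, floor))
  manifest$stages$read_floor <- list(floor = floor,
                                     detected_barcodes =
                                       global_richness(counts))

  min_det <- config$min_replicate_detections %||% 2
  counts <- stage("replicate_concordance",
                  filter_replicates(counts, sheet, min_det,
                                    config$allow_small_groups %||% FALSE))
  manifest$stages$replicate_concordance <-
    list(min_detections = min_det,
         detected_barcodes = global_richness(counts))

  pooled <- stage("pool_replicates", pool_replicates(counts, sheet))
  vg <- config$virtual_groups %||% list()
  pooled$counts <- stage("collapse_virtual",
                         collapse_virtual_barcodes(pooled$counts, vg))
  pooled <- stage("pool_pieces",
                  pool_pieces(pooled$counts, pooled$sheet,
                              config$piece_pooling %||% "sum_raw_counts"))
  manifest$stages$pooled <- list(units = ncol(pooled$counts),
                                 detected_barcodes =
                                   global_richness(pooled$counts))
  write_count_table(pooled$counts, file.path(out_dir, "counts_pooled.tsv"))

  profiles <- stage("normalize", suppressWarnings(
    normalize_counts(pooled$counts)))
  write_profiles(profiles, file.path(out_dir, "profiles.tsv"))

  diversity <- stage("diversity", {
    d <- diversity_summary(profiles, pooled$sheet)
    ref <- config$reference_route %||% "IMFP"
    if (ref %in% d$route) d <- suppressWarnings(richness_log2fc(d, ref))
    d
  })
  write.table(diversity, file.path(out_dir, "diversity.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  correlation <- NULL
  keep <- !profiles$empty
  if (sum(keep) >= 2L) {
    correlation <- stage("correlation", suppressWarnings(
      pearson_matrix(profiles$freq[, keep, drop = FALSE])))
    write.table(
      data.frame(unit_id = rownames(correlation$r), correlation$r,
                 check.names = FALSE),
      file.path(out_dir, "correlation.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  presence <- NULL
  det_cfg <- config$determinism
  if (!is.null(det_cfg)) {
    presence <- stage("determinism", {
      p0_unit <- det_cfg$p0_unit
      if (!p0_unit %in% colnames(profiles$freq)) {
        stop("p0_unit '", p0_unit, "' not among pooled units")
      }
      tumour_units <- pooled$sheet$sample_id[pooled$sheet$tissue == "tumour"]
      if (length(tumour_units) == 0L) stop("no tumour units for determinism")
      pop <- initial_population(profiles$freq[, p0_unit],
                                det_cfg$n_cells_injected,
                                length(tumour_units))
      presence_summary(pop,
                       profiles$freq[, tumour_units, drop = FALSE],
                       n_reps = det_cfg$n_reps %||% 1000,
                       seed = config$seed %||% 1L)
    })
    write.table(presence, file.path(out_dir, "presence.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  manifest$stages$profiles <- list(units = ncol(profiles$freq),
                                   empty_units = sum(profiles$empty))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(profiles = profiles, sheet = pooled$sheet,
                 diversity = diversity, correlation = correlation,
                 presence = presence, manifest = manifest))
}
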