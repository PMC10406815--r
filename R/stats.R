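#' Shannon diversity index of clonal profiles
#'
#' Computes H = -sum(p_i log p_i) over strictly positive clone frequencies, in
#' nats (natural logarithm; the base only rescales H and never reorders
#' samples). H is 0 for a monoclonal profile and ln(richness) at uniformity.
#'
#' @param x a named frequency vector (one profile), a barcode x unit frequency
#'   matrix, or a `clonal_profiles` object. Each profile must sum to 1; empty
#'   (all-zero) profiles yield `NA` with a warning.
#' @return numeric vector of H values, one per unit.
#' @export
#' @examples
#' shannon_index(c(a = 0.5, b = 0.25, c = 0.25))  # 1.5 * log(2)
shannon_index <- function(x) {
  freq <- as_freq_matrix(x)
  sums <- colSums(freq)
  ok <- abs(sums - 1) <= 1e-6
  emptyish <- sums == 0
  if (any(!ok & !emptyish)) {
    stop("profile frequencies must sum to 1 (off: ",
         paste(colnames(freq)[!ok & !emptyish], collapse = ", "), ")",
         call. = FALSE)
  }
  h <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    if (length(p) == 0L) return(NA_real_)
    -sum(p * log(p))
  })
  if (any(emptyish)) {
    warning("empty profile(s), Shannon index undefined: ",
            paste(colnames(freq)[emptyish], collapse = ", "))
  }
  setNames(as.numeric(h), colnames(freq))
}

#' Clone richness of profiles
#'
#' Number of distinct barcodes with strictly positive frequency per unit.
#'
#' @inheritParams shannon_index
#' @return integer vector, one per unit.
#' @export
richness <- function(x) {
  freq <- as_freq_matrix(x)
  setNames(as.integer(colSums(freq > 0)), colnames(freq))
}

#' Per-unit diversity summary
#'
#' Convenience table of richness and Shannon diversity per unit, annotated
#' with route and batch from a unit sheet when given.
#'
#' @inheritParams shannon_index
#' @param sheet optional unit-level sheet (e.g. from [pool_pieces()]) with
#'   `sample_id`, `route`, `batch` columns.
#' @return data frame with `unit_id`, `richness`, `shannon`, and when
#'   available `route` and `batch`.
#' @export
diversity_summary <- function(x, sheet = NULL) {
  freq <- as_freq_matrix(x)
  out <- data.frame(unit_id = colnames(freq),
                    richness = as.integer(richness(freq)),
                    shannon = as.numeric(suppressWarnings(shannon_index(freq))),
                    stringsAsFactors = FALSE)
  if (!is.null(sheet)) {
    m <- match(out$unit_id, sheet$sample_id)
    out$route <- sheet$route[m]
    out$batch <- sheet$batch[m]
  }
  rownames(out) <- NULL
  out
}

#' Log2 fold change in clone number against a reference route
#'
#' For each unit, log2 of its richness over the arithmetic mean richness of
#' the reference-route units in the same experiment batch (routes are only
#' comparable within an experiment, since each batch may start from a
#' different barcoded population).
#'
#' @param summary a data frame as returned by [diversity_summary()], with
#'   `unit_id`, `richness`, `route` and `batch` columns.
#' @param reference_route the comparison route (default `"IMFP"`).
#' @return `summary` with a `log2fc_richness` column added. Zero richness
#'   yields `-Inf` with a warning.
#' @export
richness_log2fc <- function(summary, reference_route = "IMFP") {
  stopifnot(all(c("unit_id", "richness", "route", "batch") %in%
                  names(summary)))
  out <- summary
  out$log2fc_richness <- NA_real_
  for (b in unique(out$batch)) {
    in_batch <- out$batch == b
    ref <- out$richness[in_batch & out$route == reference_route]
    if (length(ref) == 0L) {
      stop("no ", reference_route, " units in batch ", b, call. = FALSE)
    }
    ref_mean <- mean(ref)
    if (ref_mean == 0) {
      stop("reference mean richness is zero in batch ", b, call. = FALSE)
    }
    out$log2fc_richness[in_batch] <- log2(out$richness[in_batch] / ref_mean)
  }
  if (any(is.infinite(out$log2fc_richness))) {
    warning("zero-richness unit(s) give -Inf log2 fold change")
  }
  out
}

#' Minimal dominant barcode set covering a frequency fraction
#'
#' Barcodes sorted by descending frequency (ties broken by barcode ID, so the
#' result is deterministic); returns the shortest prefix whose cumulative
#' frequency reaches `q`. With `q = 1` this is every detected barcode.
#'
#' @param profile a named frequency vector, or a one-column frequency matrix.
#' @param q target cumulative frequency, in (0, 1].
#' @return character vector of barcode IDs, ordered by descending frequency;
#'   empty for an empty profile.
#' @export
#' @examples
#' top_fraction_set(c(b1 = 0.6, b2 = 0.3, b3 = 0.08, b4 = 0.02), q = 0.95)
top_fraction_set <- function(profile, q = 0.95) {
  stopifnot(q > 0, q <= 1)
  freq <- as_freq_matrix(profile)
  if (ncol(freq) != 1L) {
    stop("top_fraction_set() takes a single profile", call. = FALSE)
  }
  p <- setNames(as.numeric(freq[, 1L]), rownames(freq))
  p <- p[p > 0]
  if (length(p) == 0L) return(character())
  ord <- order(-p, names(p))
  p <- p[ord]
  cum <- cumsum(p)
  # tolerance shields against frequencies that sum to 1 only within rounding
  k <- which(cum >= q - 1e-9)[1L]
  if (is.na(k)) k <- length(p)
  names(p)[seq_len(k)]
}

#' Biomass captured by a barcode set in target profiles
#'
#' For each target unit, the summed frequency over the barcodes of
#' `source_set`: the fraction of that unit's clonal biomass accounted for by
#' the set (e.g. how much of each primary tumour is explained by a flask's
#' top-95% dominant clones). The median across targets is the study's
#' headline summary.
#'
#' @param source_set character vector of barcode IDs.
#' @param targets target profiles: `clonal_profiles`, frequency matrix, or a
#'   named vector.
#' @return a list with `capture` (named per-unit proportions) and `median`.
#' @export
biomass_capture <- function(source_set, targets) {
  freq <- as_freq_matrix(targets)
  hit <- rownames(freq) %in% source_set
  capture <- colSums(freq[hit, , drop = FALSE])
  list(capture = setNames(as.numeric(capture), colnames(freq)),
       median = median(as.numeric(capture)))
}

#' Pairwise Pearson correlation of clonal profiles
#'
#' Profiles are aligned on the union of their barcodes (absent barcodes enter
#' as frequency 0) and correlated pairwise on untransformed frequencies; an
#' average-linkage dendrogram on the distance 1 - r accompanies the matrix.
#' Zero-variance profiles have undefined correlations, recorded as `NA`.
#'
#' @param profiles `clonal_profiles`, a frequency matrix, or a list of named
#'   frequency vectors (aligned on their barcode union).
#' @param log_transform correlate `log1p(freq)` instead of raw frequencies
#'   (off by default).
#' @param linkage hierarchical clustering linkage (default `"average"`).
#' @return a list of class `correlation_result`: `r` (symmetric matrix),
#'   `dendrogram` (an `hclust`, or `NULL` when undefined entries prevent
#'   clustering), `unit_ids`.
#' @export
pearson_matrix <- function(profiles, log_transform = FALSE,
                           linkage = "average") {
  if (is.list(profiles) && !inherits(profiles, "clonal_profiles")) {
    all_ids <- sort(unique(unlist(lapply(profiles, names))))
    freq <- vapply(profiles, function(p) {
      v <- setNames(numeric(length(all_ids)), all_ids)
      v[names(p)] <- p
      v
    }, numeric(length(all_ids)))
    freq <- matrix(freq, nrow = length(all_ids),
                   dimnames = list(all_ids,
                                   names(profiles) %||%
                                     paste0("unit", seq_along(profiles))))
  } else {
    freq <- as_freq_matrix(profiles)
  }
  if (ncol(freq) < 2L) stop("need at least two profiles", call. = FALSE)
  if (log_transform) freq <- log1p(freq)
  zero_var <- apply(freq, 2L, sd) == 0
  r <- suppressWarnings(cor(freq, method = "pearson"))
  if (any(zero_var)) {
    r[zero_var, ] <- NA_real_
    r[, zero_var] <- NA_real_
  }
  diag(r) <- 1
  dend <- NULL
  if (!anyNA(r)) {
    dend <- hclust(as.dist(1 - r), method = linkage)
  } else {
    warning("zero-variance profile(s): correlations recorded as NA, ",
            "dendrogram skipped")
  }
  out <- list(r = r, dendrogram = dend, unit_ids = colnames(freq))
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation over %d profiles\n", length(x$unit_ids)))
  print(round(x$r, 3))
  invisible(x)
}

#' Paired primary/distant frequency records for one mouse
#'
#' One record per barcode in the union of the two profiles, with its frequency
#' at the primary site and at the distant site and a flag for barcodes found
#' only in the primary tumour (the points that sit on the x-axis of a
#' primary-vs-metastasis scatter plot).
#'
#' @param primary,distant named frequency vectors (or one-column matrices)
#'   from the same mouse.
#' @return data frame with `barcode_id`, `freq_primary`, `freq_distant`,
#'   `unique_to_primary`.
#' @export
site_scatter <- function(primary, distant) {
  p <- as_freq_matrix(primary)[, 1L]
  d <- as_freq_matrix(distant)[, 1L]
  ids <- sort(union(names(p)[p > 0], names(d)[d > 0]))
  fp <- ifelse(ids %in% names(p), p[ids], 0)
  fd <- ifelse(ids %in% names(d), d[ids], 0)
  fp[is.na(fp)] <- 0
  fd[is.na(fd)] <- 0
  data.frame(barcode_id = ids,
             freq_primary = as.numeric(fp),
             freq_distant = as.numeric(fd),
             unique_to_primary = fp > 0 & fd == 0,
             stringsAsFactors = FALSE,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
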