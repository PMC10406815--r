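#' Probability a clone is sampled at least once
#'
#' Closed-form companion of the injection-sampling null: the probability that
#' a clone at frequency `f` in the initial population is drawn at least once
#' in `n` independent draws, `1 - (1 - f)^n`, evaluated stably for small `f`
#' via `expm1`/`log1p`.
#'
#' @param f clone frequency (vectorised), in `[0, 1]`.
#' @param n number of cells sampled (e.g. cells injected per mouse).
#' @return presence probability in `[0, 1]`.
#' @export
#' @examples
#' presence_probability(0.001, 1000)  # ~0.6323
presence_probability <- function(f, n) {
  stopifnot(all(f >= 0 & f <= 1), all(n >= 1))
  p <- -expm1(n * log1p(-f))
  p[f == 1] <- 1
  p
}

#' Construct an initial population for the sampling null
#'
#' @param frequencies named vector of P0 clone frequencies (must sum to 1
#'   within 1e-6).
#' @param n_cells_injected cells injected per mouse.
#' @param n_tumours number of tumours (mice) in the experiment.
#' @return a list of class `initial_population`.
#' @export
initial_population <- function(frequencies, n_cells_injected, n_tumours) {
  stopifnot(!is.null(names(frequencies)), all(frequencies >= 0),
            abs(sum(frequencies) - 1) <= 1e-6,
            n_cells_injected >= 1, n_tumours >= 1)
  out <- list(barcode_ids = names(frequencies),
              frequencies = as.numeric(frequencies),
              n_cells_injected = as.integer(n_cells_injected),
              n_tumours = as.integer(n_tumours))
  class(out) <- "initial_population"
  out
}

#' Expected clone appearance across tumours under neutral sampling
#'
#' Monte-Carlo estimate of how many tumours each clone should appear in if
#' tumour composition were pure multinomial sampling of `n_cells_injected`
#' cells from the P0 frequencies, independently per tumour. Two detection
#' models are offered:
#' \describe{
#'   \item{`"injection"` (default)}{a clone is present in a tumour if at least
#'     `detection_min_cells` of its cells are drawn at injection. This is the
#'     documented null.}
#'   \item{`"sequencing"`}{each simulated tumour is additionally passed
#'     through a neutral engraftment bottleneck (`n_founders`, when set),
#'     neutral lognormal growth noise, replicate sequencing at `depth`, the
#'     read floor, and the replicate-concordance rule, so that the null
#'     carries the same detection losses as the empirical pipeline while
#'     staying neutral (no clone has a fitness advantage).}
#' }
#'
#' @param pop an [initial_population()].
#' @param n_reps Monte-Carlo replicates of the whole experiment
#'   (default 10000).
#' @param seed RNG seed; identical `(pop, n_reps, seed)` give identical
#'   output.
#' @param detection `"injection"` or `"sequencing"`.
#' @param detection_min_cells cells required for presence under the
#'   injection model (default 1).
#' @param depth,read_floor,n_replicates,min_detections sequencing detection
#'   model parameters: reads per technical replicate, inclusive read floor,
#'   replicates per tumour, concordance minimum.
#' @param n_founders engraftment bottleneck of the sequencing detection
#'   model: founder cells sampled (with neutral lognormal noise) from the
#'   injected cells before growth; `NULL` (default) disables it.
#' @param growth_sd sd of per-tumour lognormal clone noise in the sequencing
#'   detection model, applied at engraftment and growth as in the generator
#'   (0 = none).
#' @param chunk internal chunking of replicates (memory control).
#' @return data frame, one row per barcode: `barcode_id`, `p0_frequency`,
#'   `expected` (mean tumours containing the clone), `mc_low`, `mc_high`
#'   (2.5/97.5 Monte-Carlo percentiles), `presence_probability` (closed form,
#'   injection model with `detection_min_cells = 1`).
#' @export
simulate_presence <- function(pop, n_reps = 10000, seed = 1,
                              detection = c("injection", "sequencing"),
                              detection_min_cells = 1,
                              depth = 1e5, read_floor = 10,
                              n_replicates = 2, min_detections = 2,
                              n_founders = NULL, growth_sd = 0,
                              chunk = 500L) {
  detection <- match.arg(detection)
  stopifnot(inherits(pop, "initial_population"), n_reps >= 1)
  set.seed(seed)
  B <- length(pop$frequencies)
  presence_counts <- matrix(0L, nrow = B, ncol = n_reps)
  done <- 0L
  while (done < n_reps) {
    m <- min(chunk, n_reps - done)
    for (r in seq_len(m)) {
      tumours <- rmultinom(pop$n_tumours, pop$n_cells_injected,
                           pop$frequencies)
      if (detection == "injection") {
        present <- tumours >= detection_min_cells
      } else {
        present <- matrix(FALSE, nrow = B, ncol = pop$n_tumours)
        noisy <- function(w) {
          nz <- w > 0
          if (growth_sd > 0 && any(nz)) {
            w[nz] <- w[nz] * exp(rnorm(sum(nz), 0, growth_sd))
          }
          w
        }
        for (tt in seq_len(pop$n_tumours)) {
          w <- noisy(tumours[, tt])
          if (!is.null(n_founders) && sum(w) > 0) {
            w <- noisy(rmultinom(1L, n_founders, w / sum(w))[, 1L])
          }
          if (sum(w) == 0) next
          p <- w / sum(w)
          det <- integer(B)
          for (rep_i in seq_len(n_replicates)) {
            reads <- rmultinom(1L, depth, p)[, 1L]
            det <- det + (reads > read_floor)
          }
          present[, tt] <- det >= min_detections
        }
      }
      presence_counts[, done + r] <- rowSums(present)
    }
    done <- done + m
  }
  qs <- apply(presence_counts, 1L, quantile, probs = c(0.025, 0.975),
              names = FALSE, type = 1L)
  data.frame(
    barcode_id = pop$barcode_ids,
    p0_frequency = pop$frequencies,
    expected = rowMeans(presence_counts),
    mc_low = qs[1L, ],
    mc_high = qs[2L, ],
    presence_probability = presence_probability(pop$frequencies,
                                                pop$n_cells_injected),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Observed number of tumours containing each barcode
#'
#' @param profiles final (post-filter) tumour profiles: `clonal_profiles` or
#'   a frequency matrix with one column per tumour.
#' @return named integer vector: per barcode, the number of tumours in which
#'   its frequency is strictly positive.
#' @export
observed_presence <- function(profiles) {
  freq <- as_freq_matrix(profiles)
  setNames(as.integer(rowSums(freq > 0)), rownames(freq))
}

#' Observed/expected appearance fold change
#'
#' @param observed observed tumour counts (vectorised).
#' @param expected expected tumour counts under the null.
#' @param eps threshold below which the expectation is treated as zero
#'   (default 1e-9 tumours).
#' @return `observed / expected`; `Inf` (flagged infinite enrichment) when
#'   the expectation is ~0 but the clone was observed; `NA` when both are ~0.
#' @export
appearance_fold_change <- function(observed, expected, eps = 1e-9) {
  stopifnot(all(expected >= 0))
  out <- observed / expected
  zero_exp <- expected < eps
  out[zero_exp & observed > 0] <- Inf
  out[zero_exp & observed == 0] <- NA_real_
  out
}

#' Observed vs expected clone appearance summary
#'
#' Joins the Monte-Carlo neutral expectation with the observed tumour counts
#' and the appearance fold change, ranked by P0 frequency — the table behind
#' the "how many tumours contain each clone" comparison.
#'
#' @param pop an [initial_population()] (its `n_tumours` must match the
#'   number of observed tumour profiles).
#' @param profiles final tumour profiles (see [observed_presence()]). Barcodes
#'   absent from the profiles count as observed in 0 tumours.
#' @param ... passed to [simulate_presence()].
#' @return data frame with `barcode_id`, `p0_frequency`, `p0_rank` (1 = most
#'   frequent at P0), `observed`, `expected`, `mc_low`, `mc_high`,
#'   `fold_change`, `exceeds_mc_high`.
#' @export
presence_summary <- function(pop, profiles, ...) {
  freq <- as_freq_matrix(profiles)
  if (ncol(freq) != pop$n_tumours) {
    stop("pop$n_tumours (", pop$n_tumours, ") does not match the number of ",
         "tumour profiles (", ncol(freq), ")", call. = FALSE)
  }
  exp_side <- simulate_presence(pop, ...)
  obs <- observed_presence(freq)
  exp_side$observed <- ifelse(pop$barcode_ids %in% names(obs),
                              obs[pop$barcode_ids], 0L)
  exp_side$observed[is.na(exp_side$observed)] <- 0L
  exp_side$p0_rank <- rank(-exp_side$p0_frequency, ties.method = "first")
  exp_side$fold_change <- appearance_fold_change(exp_side$observed,
                                                 exp_side$expected)
  exp_side$exceeds_mc_high <- exp_side$observed > exp_side$mc_high
  exp_side[, c("barcode_id", "p0_frequency", "p0_rank", "observed",
               "expected", "mc_low", "mc_high", "fold_change",
               "exceeds_mc_high")]
}
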