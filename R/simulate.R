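#' Configuration of a synthetic barcoding experiment
#'
#' Encodes the statistical structure of a clonal-tracking study: a reference
#' barcode library, a log-normal initial population (P0), a multinomial
#' injection bottleneck per mouse, clonal fitness with a deterministic
#' component shared across mice plus per-mouse noise, route-dependent organ
#' seeding (spontaneous assays seed organs from the primary tumour;
#' experimental tail-vein assays split circulating clones disjointly between
#' lung and liver), dissection into pieces with technical replicates, and
#' overdispersed sequencing counts. Ground truth is retained for every stage.
#'
#' @param n_barcodes library size (default 2500).
#' @param barcode_length barcode length in nt (default 21).
#' @param p0_sigma log-normal sigma of P0 clone abundances (default 1).
#' @param routes injection routes simulated, one cohort each. `IV` mice follow
#'   the experimental regime; all other routes are spontaneous.
#' @param n_mice mice per route (default 10).
#' @param n_cells_injected cells injected per mouse. The study's presets are
#'   5000 (PDX), 60000 and 200000 (cell line experiments); default 60000.
#' @param fraction_deterministic fraction of clones carrying a deterministic
#'   in-vivo fitness advantage shared across mice (default 0.02).
#' @param deterministic_advantage multiplicative fitness advantage of those
#'   clones (default 200).
#' @param stochastic_sd sd of the per-mouse lognormal clone fitness noise,
#'   applied independently at engraftment and during growth (default 1.5;
#'   together with the engraftment bottleneck this drives the observed
#'   dominance of tumours by a handful of clones).
#' @param engraftment_rate fraction of injected cells that engraft and found
#'   the tumour (default 0.01, within the 1/10-1/10000 range reported for
#'   fat-pad transplants). Engraftment is fitness-biased: founder cells are
#'   drawn with probability proportional to injected cells x exp(fitness).
#'   Set to 1 to disable the bottleneck (tumour = injected cells).
#' @param dominance_target documented design target: expected number of clones
#'   dominating a tumour (default 8, i.e. the ~5-10 band).
#' @param seeder_fraction fraction of clones able to colonise distant organs
#'   (default 0.25).
#' @param organ_bottleneck founder cells seeding each organ (default 2000).
#' @param organ_noise_sd sd of lognormal growth noise during organ expansion
#'   (default 1).
#' @param lung_trap_prob in the experimental regime, probability that a
#'   circulating clone is trapped in the lung rather than extravasating to
#'   the liver (default 0.5).
#' @param n_pieces tumour dissection pieces (default 4).
#' @param piece_concentration Dirichlet concentration of per-piece spatial
#'   heterogeneity around the whole-tumour composition (default 100; larger =
#'   more homogeneous pieces).
#' @param tumour_replicates technical replicates per tumour piece (default 2).
#' @param organ_replicates technical replicates per organ/blood sample
#'   (default 2; set 5 for quintuplicate designs).
#' @param read_depth reads per technical replicate (default 1e5).
#' @param overdispersion Dirichlet-multinomial overdispersion of sequencing
#'   counts; 0 = pure multinomial. The default 5e-4 keeps clones above ~0.1%
#'   frequency concordant between replicates at the default depth.
#' @param sequencing_error_rate per-base substitution rate applied when
#'   emitting FASTQ (default 0).
#' @param seed mandatory RNG seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_barcodes = 2500,
                              barcode_length = 21,
                              p0_sigma = 1,
                              routes = c("IMFP", "IV"),
                              n_mice = 10,
                              n_cells_injected = 60000,
                              fraction_deterministic = 0.02,
                              deterministic_advantage = 200,
                              stochastic_sd = 1.5,
                              engraftment_rate = 0.01,
                              dominance_target = 8,
                              seeder_fraction = 0.25,
                              organ_bottleneck = 2000,
                              organ_noise_sd = 1,
                              lung_trap_prob = 0.5,
                              n_pieces = 4,
                              piece_concentration = 100,
                              tumour_replicates = 2,
                              organ_replicates = 2,
                              read_depth = 1e5,
                              overdispersion = 5e-4,
                              sequencing_error_rate = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory for a simulation config", call. = FALSE)
  }
  cfg <- list(
    n_barcodes = as.integer(n_barcodes),
    barcode_length = as.integer(barcode_length),
    p0_sigma = p0_sigma,
    routes = routes,
    n_mice = as.integer(n_mice),
    n_cells_injected = as.integer(n_cells_injected),
    fraction_deterministic = fraction_deterministic,
    deterministic_advantage = deterministic_advantage,
    stochastic_sd = stochastic_sd,
    engraftment_rate = engraftment_rate,
    dominance_target = dominance_target,
    seeder_fraction = seeder_fraction,
    organ_bottleneck = as.integer(organ_bottleneck),
    organ_noise_sd = organ_noise_sd,
    lung_trap_prob = lung_trap_prob,
    n_pieces = as.integer(n_pieces),
    piece_concentration = piece_concentration,
    tumour_replicates = as.integer(tumour_replicates),
    organ_replicates = as.integer(organ_replicates),
    read_depth = as.integer(read_depth),
    overdispersion = overdispersion,
    sequencing_error_rate = sequencing_error_rate,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_barcodes >= 1, cfg$barcode_length >= 1, cfg$p0_sigma >= 0,
    cfg$n_mice >= 1, cfg$n_cells_injected >= 1,
    cfg$fraction_deterministic >= 0, cfg$fraction_deterministic <= 1,
    cfg$deterministic_advantage > 0, cfg$stochastic_sd >= 0,
    cfg$engraftment_rate > 0, cfg$engraftment_rate <= 1,
    cfg$seeder_fraction >= 0, cfg$seeder_fraction <= 1,
    cfg$organ_bottleneck >= 1, cfg$organ_noise_sd >= 0,
    cfg$lung_trap_prob >= 0, cfg$lung_trap_prob <= 1,
    cfg$n_pieces >= 1, cfg$piece_concentration > 0,
    cfg$tumour_replicates >= 1, cfg$organ_replicates >= 1,
    cfg$read_depth >= 1, cfg$overdispersion >= 0,
    cfg$sequencing_error_rate >= 0, cfg$sequencing_error_rate < 1,
    all(cfg$routes %in% c("IMFP", "IMFPc", "SC", "ID", "IV"))
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Generate a random barcode reference library
#'
#' Distinct uniform-random sequences with a minimum pairwise Hamming distance
#' enforced by rejection, so that exact barcode matching stays unambiguous
#' even in the presence of single sequencing errors.
#'
#' @param n number of barcodes.
#' @param length sequence length in nt (default 21).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @return a [barcode_library()] with IDs `bc0001`, `bc0002`, ...
#' @export
generate_barcode_library <- function(n, length = 21, min_hamming = 3) {
  if (n > 4^length / 2) {
    stop("cannot draw ", n, " distinct ", length,
         "-mers with the requested spacing", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  draw <- function(k) {
    chars <- matrix(sample(bases, k * length, replace = TRUE), nrow = k)
    do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
  }
  seqs <- draw(n)
  # pigeonhole: two sequences closer than Hamming 3 agree on one of three
  # disjoint segments, so only segment-sharing pairs need exact checking
  cuts <- round(seq(0, length, length.out = 4L))
  for (iter in seq_len(100L)) {
    bad <- rep(FALSE, n)
    for (s in 1:3) {
      seg <- substr(seqs, cuts[s] + 1L, cuts[s + 1L])
      for (grp in split(seq_len(n), seg)) {
        if (length(grp) < 2L) next
        for (i in seq_len(length(grp) - 1L)) {
          for (j in seq.int(i + 1L, length(grp))) {
            a <- grp[i]; b <- grp[j]
            if (bad[b]) next
            d <- sum(utf8ToInt(seqs[a]) != utf8ToInt(seqs[b]))
            if (d < min_hamming) bad[b] <- TRUE
          }
        }
      }
    }
    if (!any(bad)) break
    seqs[bad] <- draw(sum(bad))
    if (iter == 100L) {
      stop("failed to generate a library with the requested spacing",
           call. = FALSE)
    }
  }
  barcode_library(sprintf("bc%04d", seq_len(n)), seqs)
}

#' Generate the initial barcoded population
#'
#' Clone abundances are drawn log-normal(0, `p0_sigma`) and normalised to P0
#' frequencies; with `p0_sigma = 0` the population is uniform. Clone-intrinsic
#' properties are drawn here and retained as truth: the deterministic-fitness
#' flag (shared across mice) and the organ-seeding flag.
#'
#' @param config a [simulation_config()].
#' @param library optional pre-built [barcode_library()]; generated from the
#'   config when `NULL`.
#' @param seed RNG seed; defaults to `config$seed`. Pass `NULL` to use the
#'   current RNG state (as [simulate_experiment()] does internally).
#' @return a list of class `synthetic_population`: `library`, `p0` (named
#'   frequencies), `deterministic` and `seeder` (named logical flags).
#' @export
generate_population <- function(config, library = NULL, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(library)) {
    library <- generate_barcode_library(config$n_barcodes,
                                        config$barcode_length)
  }
  ids <- library$barcode_id
  B <- length(ids)
  abundance <- if (config$p0_sigma == 0) rep(1, B) else
    rlnorm(B, meanlog = 0, sdlog = config$p0_sigma)
  p0 <- setNames(abundance / sum(abundance), ids)
  n_det <- round(config$fraction_deterministic * B)
  det <- setNames(rep(FALSE, B), ids)
  if (n_det > 0) det[sample.int(B, n_det)] <- TRUE
  seeder <- setNames(rep(FALSE, B), ids)
  n_seed <- round(config$seeder_fraction * B)
  if (n_seed > 0) seeder[sample.int(B, n_seed)] <- TRUE
  out <- list(library = library, p0 = p0, deterministic = det,
              seeder = seeder)
  class(out) <- "synthetic_population"
  out
}

# Dirichlet draw around base frequencies with concentration `conc`
rdirichlet_around <- function(base, conc) {
  g <- rgamma(length(base), shape = conc * base)
  s <- sum(g)
  if (s == 0) base else g / s
}

# lognormal growth of injected cells; deterministic advantage for flagged
# clones plus per-context noise
grow <- function(cells, det, advantage, noise_sd) {
  w <- as.numeric(cells)
  nz <- w > 0
  if (!any(nz)) return(w)
  logw <- ifelse(det[nz], log(advantage), 0)
  if (noise_sd > 0) logw <- logw + rnorm(sum(nz), 0, noise_sd)
  w[nz] <- w[nz] * exp(logw)
  w / sum(w)
}

#' Simulate one mouse of a barcoding assay
#'
#' Spontaneous routes (IMFP/IMFPc/SC/ID): a multinomial injection bottleneck,
#' a fitness-biased engraftment bottleneck (founder cells drawn with
#' probability proportional to injected cells x exp(fitness), fitness being
#' the shared deterministic advantage of flagged clones plus per-mouse
#' lognormal noise), lognormal clone growth, dissection into pieces
#' (Dirichlet spatial heterogeneity), and organ/blood profiles seeded from
#' the tumour (seeder-restricted founder sampling followed by noisy
#' expansion, preserving the tumour's frequency ranking). Tumour frequencies
#' are proportional to injected count x exp(fitness) in expectation. The
#' experimental route (IV) forms no tumour: the circulating pool is split
#' disjointly at random into lung-trapped and liver-extravasating clone sets
#' before expansion, which decorrelates lung and liver repertoires.
#'
#' @param pop a `synthetic_population` (see [generate_population()]).
#' @param config a [simulation_config()].
#' @param route one of IMFP, IMFPc, SC, ID (spontaneous) or IV (experimental).
#' @param seed optional RNG seed (default `NULL`: use current RNG state).
#' @return a list of class `synthetic_mouse`: `route`, `sites` (named list of
#'   frequency vectors: `tumour`, `pieces` matrix, `lung`, `liver`, `blood`;
#'   IV mice have no tumour/pieces), and `truth` (`injected` cell counts and
#'   per-site fitness realisations).
#' @export
simulate_mouse <- function(pop, config, route, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(route %in% c("IMFP", "IMFPc", "SC", "ID", "IV"))
  ids <- names(pop$p0)
  B <- length(ids)
  injected <- rmultinom(1L, config$n_cells_injected, pop$p0)[, 1L]
  names(injected) <- ids
  adv <- config$deterministic_advantage
  sites <- list()
  if (route != "IV") {
    founders <- injected
    if (config$engraftment_rate < 1) {
      w_eng <- grow(injected, pop$deterministic, adv, config$stochastic_sd)
      n_found <- max(1L, round(config$engraftment_rate *
                                 config$n_cells_injected))
      founders <- rmultinom(1L, n_found, w_eng)[, 1L]
      names(founders) <- ids
    }
    tumour <- grow(founders, pop$deterministic, adv, config$stochastic_sd)
    names(tumour) <- ids
    pieces <- vapply(seq_len(config$n_pieces), function(i) {
      rdirichlet_around(tumour, config$piece_concentration)
    }, numeric(B))
    pieces <- matrix(pieces, nrow = B,
                     dimnames = list(ids, paste0("piece",
                                                 seq_len(config$n_pieces))))
    seed_organ <- function(restrict) {
      base <- tumour * (if (restrict) pop$seeder else TRUE)
      if (sum(base) == 0) return(setNames(numeric(B), ids))
      founders <- rmultinom(1L, config$organ_bottleneck,
                            base / sum(base))[, 1L]
      setNames(grow(founders, pop$deterministic, 1,
                    config$organ_noise_sd), ids)
    }
    sites <- list(tumour = tumour, pieces = pieces,
                  lung = seed_organ(TRUE), liver = seed_organ(TRUE),
                  blood = seed_organ(FALSE))
  } else {
    trapped <- runif(B) < config$lung_trap_prob
    lung_cells <- injected * trapped
    liver_cells <- injected * !trapped
    sites <- list(
      lung = setNames(grow(lung_cells, pop$deterministic, adv,
                           config$stochastic_sd), ids),
      liver = setNames(grow(liver_cells, pop$deterministic, adv,
                            config$stochastic_sd), ids),
      blood = setNames(if (sum(injected) > 0) injected / sum(injected)
                       else numeric(B), ids)
    )
  }
  out <- list(route = route, sites = sites,
              truth = list(injected = injected,
                           founders = if (route != "IV") founders else NULL,
                           trapped = if (route == "IV")
                             setNames(trapped, ids) else NULL))
  class(out) <- "synthetic_mouse"
  out
}

#' Simulate serial in vitro passaging
#'
#' Flasks are seeded from P0 with a multinomial bottleneck and grown under
#' clone-intrinsic in vitro fitness (drawn independently of the in vivo
#' fitness and shared across flasks) plus small per-passage noise. Growth to
#' confluency is deterministic expansion of the clone weights; the 1:10
#' split is the sampling bottleneck (a multinomial draw of the kept cells),
#' so with `split_fraction = 1` and no fitness variance the composition is
#' exactly constant. The recorded profile per passage is the composition of
#' the passaged aliquot, mirroring sequencing a fixed share of the cells at
#' every split.
#'
#' @param pop a `synthetic_population`.
#' @param config a [simulation_config()]; `n_cells_injected` is the flask
#'   seeding size.
#' @param n_passages number of passages (default 15).
#' @param n_flasks parallel flasks (default 4).
#' @param split_fraction fraction kept at each passage, in (0, 1]
#'   (default 0.1).
#' @param invitro_sd sd of the clone-intrinsic lognormal in vitro fitness
#'   (default 0.5); 0 disables selection.
#' @param passage_noise_sd sd of per-flask, per-passage growth noise
#'   (default 0.1).
#' @param seed optional RNG seed.
#' @return a list of class `synthetic_passaging`: `profiles` — per flask a
#'   barcodes x passages frequency matrix (columns `P1`..`Pn`) — and `truth`
#'   (the shared in vitro fitness).
#' @export
simulate_passaging <- function(pop, config, n_passages = 15, n_flasks = 4,
                               split_fraction = 0.1, invitro_sd = 0.5,
                               passage_noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(split_fraction > 0, split_fraction <= 1)
  ids <- names(pop$p0)
  B <- length(ids)
  n_seed <- config$n_cells_injected
  logw <- if (invitro_sd > 0) rnorm(B, 0, invitro_sd) else numeric(B)
  flasks <- lapply(seq_len(n_flasks), function(fl) {
    cells <- as.numeric(rmultinom(1L, n_seed, pop$p0)[, 1L])
    prof <- matrix(0, nrow = B, ncol = n_passages,
                   dimnames = list(ids, paste0("P", seq_len(n_passages))))
    for (p in seq_len(n_passages)) {
      w <- cells
      nz <- w > 0
      if (!any(nz)) break
      noise <- if (passage_noise_sd > 0)
        rnorm(sum(nz), 0, passage_noise_sd) else 0
      w[nz] <- w[nz] * exp(logw[nz] + noise)
      cells <- if (split_fraction == 1) w else
        as.numeric(rmultinom(1L, n_seed, w / sum(w))[, 1L])
      prof[, p] <- cells / sum(cells)
    }
    prof
  })
  names(flasks) <- paste0("flask", seq_len(n_flasks))
  out <- list(profiles = flasks,
              truth = list(invitro_fitness = setNames(logw, ids)))
  class(out) <- "synthetic_passaging"
  out
}

#' Draw sequencing read counts for one technical replicate
#'
#' Dirichlet-multinomial counts around the true clone frequencies; the
#' overdispersion parameter is the inverse Dirichlet concentration (0 = pure
#' multinomial). Totals equal `depth` exactly.
#'
#' @param frequencies true clone frequency vector (sums to 1).
#' @param depth total reads.
#' @param overdispersion inverse concentration (default 5e-4).
#' @param seed optional RNG seed.
#' @return integer count vector named like `frequencies`.
#' @export
sequence_sample <- function(frequencies, depth, overdispersion = 5e-4,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(depth >= 1, all(frequencies >= 0))
  s <- sum(frequencies)
  if (s == 0) return(setNames(integer(length(frequencies)),
                              names(frequencies)))
  p <- frequencies / s
  if (overdispersion > 0) {
    g <- rgamma(length(p), shape = p / overdispersion)
    if (sum(g) > 0) p <- g / sum(g)
  }
  setNames(rmultinom(1L, depth, p)[, 1L], names(frequencies))
}

#' Simulate a complete barcoding experiment
#'
#' Generates the population, simulates every mouse of every configured route,
#' sequences all technical replicates (including an initial-population P0
#' sample), and assembles the sample sheet, the replicate-level count matrix
#' and the full ground truth. Optionally emits the reads as FASTQ using the
#' amplicon read structure, for end-to-end validation of the counting step.
#'
#' @param config a [simulation_config()].
#' @param fastq path to write a (gzipped, if ending in `.gz`) FASTQ of all
#'   reads, or `NULL` (default) to skip FASTQ emission.
#' @param structure [read_structure()] used for FASTQ emission.
#' @return a list of class `synthetic_experiment`:
#'   \describe{
#'     \item{library}{the [barcode_library()].}
#'     \item{sheet}{replicate-level sample sheet (with index sequences).}
#'     \item{counts}{barcodes x replicates true read-count matrix.}
#'     \item{truth}{`p0`, clone flags, per-mouse site frequencies and
#'       injected cells.}
#'     \item{fastq}{FASTQ path, when emitted.}
#'   }
#' @export
simulate_experiment <- function(config, fastq = NULL,
                                structure = read_structure(
                                  barcode_length = config$barcode_length)) {
  set.seed(config$seed)
  pop <- generate_population(config, seed = NULL)
  ids <- pop$library$barcode_id
  samples <- list()
  sheet_rows <- list()
  mice <- list()
  add_sample <- function(freq, mouse, route, tissue, piece, rep_i, batch) {
    sid <- paste0(mouse, ".", tissue,
                  if (!is.na(piece)) paste0(".", piece) else "", ".r", rep_i)
    samples[[sid]] <<- sequence_sample(freq, config$read_depth,
                                       config$overdispersion)
    sheet_rows[[sid]] <<- data.frame(
      sample_id = sid, mouse_id = mouse, route = route, tissue = tissue,
      piece_id = if (is.na(piece)) NA_character_ else piece,
      replicate_id = paste0("r", rep_i), batch = batch,
      stringsAsFactors = FALSE)
  }
  # P0 reference sample of the injected population
  for (r in seq_len(config$tumour_replicates)) {
    add_sample(pop$p0, "P0", "initial", "population", NA, r, "batch1")
  }
  for (route in config$routes) {
    for (m in seq_len(config$n_mice)) {
      mouse_id <- paste0(route, "_m", m)
      mouse <- simulate_mouse(pop, config, route)
      mice[[mouse_id]] <- mouse
      if (route != "IV") {
        for (pc in seq_len(config$n_pieces)) {
          for (r in seq_len(config$tumour_replicates)) {
            add_sample(mouse$sites$pieces[, pc], mouse_id, route,
                       "tumour_piece", paste0("p", pc), r, "batch1")
          }
        }
      }
      for (tissue in c("lung", "liver", "blood")) {
        if (sum(mouse$sites[[tissue]]) == 0) next
        n_rep <- if (tissue == "liver") config$tumour_replicates else
          config$organ_replicates
        for (r in seq_len(n_rep)) {
          add_sample(mouse$sites[[tissue]], mouse_id, route, tissue, NA, r,
                     "batch1")
        }
      }
    }
  }
  counts <- matrix(0L, nrow = length(ids), ncol = length(samples),
                   dimnames = list(ids, names(samples)))
  for (s in names(samples)) counts[, s] <- samples[[s]]
  sheet <- do.call(rbind, sheet_rows)
  sheet$index_sequence <- generate_index_sequences(nrow(sheet))
  sheet <- as_sample_sheet(sheet)
  out <- list(library = pop$library, sheet = sheet, counts = counts,
              truth = list(p0 = pop$p0, deterministic = pop$deterministic,
                           seeder = pop$seeder, mice = mice),
              config = config)
  if (!is.null(fastq)) {
    emit_fastq(counts, pop$library, sheet, structure,
               error_rate = config$sequencing_error_rate, path = fastq)
    out$fastq <- fastq
  }
  class(out) <- "synthetic_experiment"
  out
}

# distinct random index sequences of the given length
generate_index_sequences <- function(n, length = 8L) {
  bases <- c("A", "C", "G", "T")
  repeat {
    chars <- matrix(sample(bases, n * length, replace = TRUE), nrow = n)
    idx <- do.call(paste0, as.data.frame(chars, stringsAsFactors = FALSE))
    if (!anyDuplicated(idx)) return(idx)
  }
}

#' Emit synthetic amplicon reads as FASTQ
#'
#' Each counted read becomes one FASTQ record: a random 0-3 nt stagger, the
#' upstream anchor, the barcode sequence and a downstream constant region,
#' with the sample's index written into the read header (Illumina style,
#' `... 1:N:0:INDEX`). Substitution errors are applied at `error_rate` per
#' base.
#'
#' @param counts barcodes x samples read-count matrix.
#' @param library the [barcode_library()].
#' @param sheet sample sheet with `index_sequence`.
#' @param structure a [read_structure()].
#' @param error_rate per-base substitution probability (default 0).
#' @param path output FASTQ path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
emit_fastq <- function(counts, library, sheet, structure = read_structure(),
                       error_rate = 0, path) {
  downstream <- "TAAGCGCCTGATTCGAGATC"  # reverse complement of BotLib
  bases <- c("A", "C", "G", "T")
  seq_of <- setNames(library$sequence, library$barcode_id)
  all_reads <- character(0)
  all_heads <- character(0)
  for (s in colnames(counts)) {
    cc <- counts[, s]
    nz <- cc > 0
    if (!any(nz)) next
    bc <- rep(seq_of[rownames(counts)[nz]], cc[nz])
    stagger_len <- sample(0:3, length(bc), replace = TRUE)
    pad <- matrix(sample(bases, 3L * length(bc), replace = TRUE),
                  ncol = 3L)
    stagger <- substr(paste0(pad[, 1L], pad[, 2L], pad[, 3L]),
                      1L, stagger_len)
    reads <- paste0(stagger, structure$upstream_anchor, bc, downstream)
    if (error_rate > 0) {
      n_err <- rbinom(length(reads), nchar(reads), error_rate)
      for (i in which(n_err > 0)) {
        pos <- sample.int(nchar(reads[i]), n_err[i])
        for (p in pos) {
          substr(reads[i], p, p) <- sample(setdiff(bases,
                                                   substr(reads[i], p, p)),
                                           1L)
        }
      }
    }
    index <- sheet$index_sequence[sheet$sample_id == s]
    heads <- sprintf("%s:%d 1:N:0:%s", s, seq_along(reads), index)
    all_reads <- c(all_reads, reads)
    all_heads <- c(all_heads, heads)
  }
  dna <- Biostrings::DNAStringSet(all_reads)
  names(dna) <- all_heads
  qual <- Biostrings::BStringSet(strrep("I", nchar(all_reads)))
  Biostrings::writeXStringSet(dna, filepath = path, format = "fastq",
                              qualities = qual,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
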