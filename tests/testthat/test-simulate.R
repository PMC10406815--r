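small_cfg <- function(...) {
  args <- modifyList(
    list(n_barcodes = 150, n_mice = 2, routes = "IMFP",
         n_cells_injected = 3000, read_depth = 20000,
         n_pieces = 2, seed = 1),
    list(...))
  do.call(simulation_config, args)
}

test_that("config validation rejects bad values and requires a seed", {
  expect_error(simulation_config(n_barcodes = 10), "seed")
  expect_error(simulation_config(seed = 1, seeder_fraction = 1.5))
  expect_error(simulation_config(seed = 1, routes = "oral"))
  expect_error(simulation_config(seed = 1, engraftment_rate = 0))
})

test_that("P0 frequencies sum to one and sigma = 0 gives uniformity", {
  cfg <- simulation_config(n_barcodes = 4, p0_sigma = 0, seed = 2)
  pop <- generate_population(cfg)
  expect_equal(unname(pop$p0), rep(0.25, 4))
  cfg2 <- small_cfg()
  pop2 <- generate_population(cfg2)
  expect_equal(sum(pop2$p0), 1)
  expect_equal(sum(pop2$deterministic), round(0.02 * 150))
})

test_that("P0 dispersion grows with sigma", {
  cvs <- vapply(c(0.3, 1, 2), function(sg) {
    cfg <- simulation_config(n_barcodes = 500, p0_sigma = sg, seed = 7)
    p <- generate_population(cfg)$p0
    sd(p) / mean(p)
  }, numeric(1))
  expect_true(all(diff(cvs) > 0))
})

test_that("neutral no-noise tumours reproduce injected-cell proportions", {
  cfg <- small_cfg(fraction_deterministic = 0, stochastic_sd = 0,
                   engraftment_rate = 1)
  pop <- generate_population(cfg)
  m <- simulate_mouse(pop, cfg, "IMFP")
  expect_equal(m$sites$tumour,
               m$truth$injected / sum(m$truth$injected))
})

test_that("universal seeders with no noise give lung proportional to
           tumour", {
  cfg <- small_cfg(seeder_fraction = 1, organ_noise_sd = 0,
                   organ_bottleneck = 200000)
  pop <- generate_population(cfg)
  m <- simulate_mouse(pop, cfg, "IMFP")
  expect_gt(cor(m$sites$tumour, m$sites$lung), 0.99)
})

test_that("spontaneous and experimental regimes separate as designed", {
  cfg <- simulation_config(n_barcodes = 500, n_cells_injected = 20000,
                           seed = 13)
  pop <- generate_population(cfg)
  set.seed(14)
  r_spont <- r_iv <- numeric(10)
  for (i in 1:10) {
    sm <- simulate_mouse(pop, cfg, "IMFP")
    r_spont[i] <- cor(sm$sites$tumour, sm$sites$lung)
    iv <- simulate_mouse(pop, cfg, "IV")
    r_iv[i] <- cor(iv$sites$lung, iv$sites$liver)
    # IV mice have no tumour and their lung/liver clone sets are disjoint
    expect_null(iv$sites$tumour)
    expect_equal(sum(iv$sites$lung > 0 & iv$sites$liver > 0), 0)
  }
  expect_gt(mean(r_spont), mean(r_iv))
})

test_that("passaging with no selection and no split is constant", {
  cfg <- small_cfg()
  pop <- generate_population(cfg)
  pas <- simulate_passaging(pop, cfg, n_passages = 4, n_flasks = 1,
                            split_fraction = 1, invitro_sd = 0,
                            passage_noise_sd = 0, seed = 3)
  prof <- pas$profiles$flask1
  expect_equal(prof[, "P1"], prof[, "P4"])
})

test_that("passaging erodes richness monotonically with an early drop", {
  cfg <- simulation_config(n_barcodes = 800, n_cells_injected = 20000,
                           seed = 23)
  pop <- generate_population(cfg)
  pas <- simulate_passaging(pop, cfg, n_passages = 10, n_flasks = 2,
                            seed = 24)
  for (fl in pas$profiles) {
    rich <- colSums(fl > 0)
    expect_true(all(diff(rich) <= 0))
    # the first half of the course loses more clones than the second
    expect_gt(rich[1] - rich[5], rich[6] - rich[10])
  }
})

test_that("flasks sharing in vitro fitness correlate more with each other
           than with tumours", {
  cfg <- simulation_config(n_barcodes = 600, n_cells_injected = 20000,
                           seed = 25)
  pop <- generate_population(cfg)
  pas <- simulate_passaging(pop, cfg, n_passages = 8, n_flasks = 2,
                            seed = 26)
  set.seed(27)
  tum <- simulate_mouse(pop, cfg, "IMFP")$sites$tumour
  f1 <- pas$profiles$flask1[, "P8"]
  f2 <- pas$profiles$flask2[, "P8"]
  expect_gt(cor(f1, f2), cor(f1, tum))
})

test_that("sequencing draws exact depth and converges to the input
           frequencies", {
  p <- random_profile(60)
  counts <- sequence_sample(p, depth = 50000, overdispersion = 0, seed = 4)
  expect_equal(sum(counts), 50000)
  expect_lt(max(abs(counts / 50000 - p)), 0.01)
  # overdispersion widens replicate scatter
  set.seed(5)
  reps_od <- replicate(40, {
    cc <- sequence_sample(p, 5000, overdispersion = 0.005)
    cc[[1]] / 5000
  })
  reps_mn <- replicate(40, {
    cc <- sequence_sample(p, 5000, overdispersion = 0)
    cc[[1]] / 5000
  })
  expect_gt(sd(reps_od), sd(reps_mn))
})

test_that("experiments are byte-identical under a fixed seed", {
  ex1 <- simulate_experiment(small_cfg())
  ex2 <- simulate_experiment(small_cfg())
  expect_identical(ex1$counts, ex2$counts)
  expect_identical(ex1$sheet, ex2$sheet)
  expect_identical(ex1$truth$p0, ex2$truth$p0)
})

test_that("experiment output is internally consistent", {
  cfg <- small_cfg(routes = c("IMFP", "IV"))
  ex <- simulate_experiment(cfg)
  expect_s3_class(ex$sheet, "sample_sheet")
  expect_equal(sort(colnames(ex$counts)), sort(ex$sheet$sample_id))
  expect_true(all(colSums(ex$counts) == cfg$read_depth))
  # IV mice contribute no tumour pieces
  iv_rows <- ex$sheet[startsWith(ex$sheet$mouse_id, "IV"), ]
  expect_false(any(iv_rows$tissue == "tumour_piece"))
  # expected richness after injection matches the closed form within MC error
  inj_rich <- vapply(ex$truth$mice[startsWith(names(ex$truth$mice), "IMFP")],
                     function(m) sum(m$truth$injected > 0), numeric(1))
  expected <- sum(presence_probability(ex$truth$p0, cfg$n_cells_injected))
  expect_lt(abs(mean(inj_rich) - expected), 4 * sqrt(expected))
})
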