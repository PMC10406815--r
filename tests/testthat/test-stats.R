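test_that("Shannon index matches closed forms and the entropy bounds", {
  expect_equal(unname(shannon_index(c(a = .25, b = .25, c = .25, d = .25))),
               log(4))
  expect_equal(unname(shannon_index(c(a = 1, b = 0))), 0)
  expect_equal(unname(shannon_index(c(a = .5, b = .25, c = .25))),
               1.5 * log(2))
  set.seed(3)
  for (i in 1:200) {
    p <- random_profile(sample(2:80, 1))
    h <- unname(shannon_index(p))
    expect_gte(h, 0)
    expect_lte(h, log(sum(p > 0)) + 1e-12)
  }
})

test_that("Shannon index agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:20) {
    p <- random_profile(50)
    expect_equal(unname(shannon_index(p)),
                 unname(vegan::diversity(p, index = "shannon")),
                 tolerance = 1e-12)
  }
})

test_that("richness log2 fold change is computed against the in-batch
           reference mean", {
  d <- data.frame(
    unit_id = paste0("t", 1:6),
    richness = c(90L, 110L, 50L, 200L, 100L, 25L),
    route = c("IMFP", "IMFP", "SC", "IMFP", "IMFP", "SC"),
    batch = c("e1", "e1", "e1", "e2", "e2", "e2"),
    shannon = 1
  )
  fc <- richness_log2fc(d, "IMFP")
  expect_equal(fc$log2fc_richness[3], log2(50 / 100))   # vs e1 mean 100
  expect_equal(fc$log2fc_richness[6], log2(25 / 150))   # vs e2 mean 150
  # reference units centre on ~0 against their own mean
  expect_equal(mean(fc$log2fc_richness[c(1, 2)]),
               mean(log2(c(90, 110) / 100)))
  # brute-force recomputation over random batches
  set.seed(9)
  for (i in 1:10) {
    rd <- data.frame(unit_id = paste0("u", 1:12),
                     richness = sample(10:300, 12),
                     route = sample(c("IMFP", "SC", "ID"), 12, TRUE),
                     batch = sample(c("b1", "b2"), 12, TRUE),
                     shannon = 0)
    rd$route[c(1, 7)] <- "IMFP"; rd$batch[c(1, 7)] <- c("b1", "b2")
    got <- richness_log2fc(rd, "IMFP")
    for (k in seq_len(nrow(rd))) {
      ref <- mean(rd$richness[rd$route == "IMFP" & rd$batch == rd$batch[k]])
      expect_equal(got$log2fc_richness[k], log2(rd$richness[k] / ref))
    }
  }
  expect_error(richness_log2fc(d[d$route != "IMFP", ], "IMFP"), "no IMFP")
})

test_that("top-fraction sets are covering and minimal", {
  p <- c(b1 = 0.6, b2 = 0.3, b3 = 0.08, b4 = 0.02)
  expect_equal(top_fraction_set(p, 0.95), c("b1", "b2", "b3"))
  expect_equal(top_fraction_set(p, 1), c("b1", "b2", "b3", "b4"))
  expect_equal(top_fraction_set(setNames(numeric(3), letters[1:3]), 0.9),
               character(0))
  # ties broken by barcode ID for determinism
  expect_equal(top_fraction_set(c(z = 0.5, a = 0.5), 0.4), "a")
  set.seed(13)
  for (i in 1:200) {
    p <- random_profile(sample(3:60, 1))
    q <- sample(c(0.5, 0.9, 0.95, 1), 1)
    s <- top_fraction_set(p, q)
    expect_gte(sum(p[s]), q - 1e-9)
    if (length(s) > 1L && q < 1) {
      expect_lt(sum(p[s[-length(s)]]), q)
    }
  }
})

test_that("biomass capture sums source-set frequencies in targets", {
  t1 <- c(a = 0.5, b = 0.3, c = 0.2)
  t2 <- c(a = 0, b = 0, c = 1)
  m <- cbind(t1 = t1, t2 = t2)
  full <- biomass_capture(c("a", "b", "c"), m)
  expect_equal(unname(full$capture), c(1, 1))
  none <- biomass_capture(c("x", "y"), m)
  expect_equal(unname(none$capture), c(0, 0))
  expect_equal(none$median, 0)
  part <- biomass_capture(c("a", "b"), m)
  expect_equal(unname(part$capture), c(0.8, 0))
  expect_equal(part$median, 0.4)
})

test_that("Pearson matrix matches direct covariance recomputation", {
  # disjoint dominant clones over a 3-barcode union: closed form r = -0.5
  r <- pearson_matrix(list(u1 = c(a = 1, b = 0, c = 0),
                           u2 = c(a = 0, b = 1, c = 0)))
  expect_equal(r$r["u1", "u2"], -0.5)
  expect_equal(diag(r$r), c(u1 = 1, u2 = 1))
  # self-correlation = 1, symmetry, bounds, brute-force agreement
  set.seed(17)
  ids <- sprintf("bc%03d", 1:40)
  freq <- sapply(1:6, function(i) random_profile(40, ids))
  colnames(freq) <- paste0("u", 1:6)
  res <- pearson_matrix(freq)
  expect_equal(res$r, t(res$r))
  expect_true(all(res$r >= -1 - 1e-12 & res$r <= 1 + 1e-12))
  for (i in 1:5) for (j in (i + 1):6) {
    x <- freq[, i]; y <- freq[, j]
    manual <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r[i, j], manual, tolerance = 1e-12)
  }
  expect_s3_class(res$dendrogram, "hclust")
})

test_that("zero-variance profiles yield NA correlations, not errors", {
  freq <- cbind(u1 = c(a = 0.7, b = 0.3), u2 = c(a = 0.7, b = 0.3),
                u3 = c(a = 0, b = 0))
  expect_warning(res <- pearson_matrix(freq), "zero-variance")
  expect_true(is.na(res$r["u1", "u3"]))
  expect_equal(res$r["u1", "u2"], 1)
  expect_equal(res$r["u3", "u3"], 1)  # diagonal stays 1 by definition
  expect_null(res$dendrogram)
})

test_that("site scatter pairs frequencies over the barcode union", {
  primary <- c(a = 0.7, b = 0.3)
  distant <- c(b = 0.9, c = 0.1)
  sc <- site_scatter(primary, distant)
  expect_equal(nrow(sc), 3L)  # record count = union richness
  expect_true(sc$unique_to_primary[sc$barcode_id == "a"])
  expect_equal(sc$freq_distant[sc$barcode_id == "a"], 0)
  expect_equal(sc$freq_primary[sc$barcode_id == "c"], 0)
  # identical profiles sit on the diagonal
  same <- site_scatter(primary, primary)
  expect_equal(same$freq_primary, same$freq_distant)
  set.seed(19)
  for (i in 1:20) {
    p <- random_profile(sample(5:30, 1))
    d <- random_profile(sample(5:30, 1))
    sc <- site_scatter(p, d)
    expect_equal(nrow(sc), length(union(names(p)[p > 0], names(d)[d > 0])))
  }
})
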