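test_that("degenerate homogeneous cohort has identical lifespans", {
  p <- cohort_params(n_individuals = 50, sigma_r = 1e-12,
                     lifespan_noise_sd = 1e-12, markers = c(m = 1),
                     n_genes = 10, n_orthogonal = 2, seed = 1)
  ind <- simulate_individuals(p)
  expect_equal(ind$lifespan, rep(p$base_lifespan, 50), tolerance = 1e-6)
  expect_equal(ind$r, rep(1, 50), tolerance = 1e-6)
})

test_that("noise-free biomarker predicts lifespan", {
  # linear regime: the biomarker is an affine readout of the aging rate
  p <- cohort_params(n_individuals = 10000, sigma_r = 0.1, w_q = 0,
                     sigma_b = 1e-12, lifespan_noise_sd = 1e-12,
                     markers = c(m = 1), n_genes = 10, n_orthogonal = 2,
                     seed = 11)
  ind <- simulate_individuals(p)
  expect_gt(cor(ind$b_m, ind$lifespan), 0.95)
  # at the default sigma_r the map lifespan = base/r is monotone in b,
  # so the rank correlation is exactly 1 even though Pearson is capped
  p2 <- cohort_params(n_individuals = 2000, w_q = 0, sigma_b = 1e-12,
                      lifespan_noise_sd = 1e-12, markers = c(m = 1),
                      n_genes = 10, n_orthogonal = 2, seed = 11)
  i2 <- simulate_individuals(p2)
  expect_equal(cor(i2$b_m, i2$lifespan, method = "spearman"), 1)
})

test_that("aging rate and latent factor are independent", {
  p <- cohort_params(n_individuals = 5000, n_genes = 10, n_orthogonal = 0,
                     seed = 12)
  ind <- simulate_individuals(p)
  expect_lt(abs(cor(ind$r, ind$q)), 0.05)
})

test_that("invalid parameters are rejected", {
  expect_error(cohort_params(sigma_r = 0), "sigma_r")
  expect_error(cohort_params(n_orthogonal = 5000), "n_orthogonal")
  expect_error(cohort_params(archetype_fractions = c(flat = 0.5, up = 0.6,
                                                     down = 0, early_peak = 0,
                                                     late_peak = 0,
                                                     mid_trough = 0)),
               "sum to 1")
})

test_that("expression_mean matches closed forms", {
  flat <- list(archetype = "flat", baseline = 50, amplitude = 0,
               orthogonal = FALSE, gamma = 0)
  expect_equal(expression_mean(flat, 7, q = 0), 50)
  up <- list(archetype = "up", baseline = 20, amplitude = 1.3,
             orthogonal = FALSE, gamma = 0)
  expect_equal(expression_mean(up, 12) / expression_mean(up, 2),
               exp(1.3))
  orth <- list(archetype = "flat", baseline = 10, amplitude = 0,
               orthogonal = TRUE, gamma = 0.5)
  expect_equal(expression_mean(orth, 5, q = 1) / expression_mean(orth, 5, q = 0),
               exp(0.5), tolerance = 1e-12)
  expect_error(expression_mean(flat, -1), "phys_age")
})

test_that("decile selection takes exactly the top tenth of the cohort", {
  p <- cohort_params(n_individuals = 100, markers = c(m = 1), n_genes = 20,
                     n_orthogonal = 2, pool_size = 10, seed = 3)
  ind <- simulate_individuals(p)
  genes <- simulate_gene_specs(p)
  draw <- sample_bulk_counts(ind, genes, 5, "top_decile", marker = "m",
                             pool_size = 10, seed = 7)
  top10 <- ind$id[order(ind$b_m, decreasing = TRUE)[1:10]]
  expect_length(draw$pool, 10)
  expect_setequal(draw$pool, top10)
  expect_error(sample_bulk_counts(ind, genes, 5, "top_decile", marker = "m",
                                  pool_size = 11, seed = 7),
               "pool_size")
})

test_that("a single r = 1 individual is sampled at its chronological age", {
  p <- cohort_params(n_individuals = 20, sigma_r = 1e-12, markers = c(m = 1),
                     n_genes = 30, n_orthogonal = 2, pool_size = 1, seed = 5)
  ind <- simulate_individuals(p)
  ind$q <- 0
  genes <- simulate_gene_specs(p)
  draw <- sample_bulk_counts(ind, genes, 5, "all", pool_size = 1, seed = 9)
  expected <- vapply(seq_len(nrow(genes)),
                     function(g) expression_mean(as.list(genes[g, ]), 5, 0),
                     0)
  expect_equal(unname(draw$mu), expected, tolerance = 1e-9)
})

test_that("near-Poisson counts match their expectation", {
  p <- cohort_params(n_individuals = 50, markers = c(m = 1), n_genes = 200,
                     n_orthogonal = 0, dispersion_range = c(1e-8, 1e-8),
                     pool_size = 20, seed = 21)
  ind <- simulate_individuals(p)
  genes <- simulate_gene_specs(p)
  draw <- sample_bulk_counts(ind, genes, 5, "all", pool_size = 20, seed = 31)
  z <- (draw$counts - draw$mu) / sqrt(draw$mu)
  expect_lt(abs(mean(z)), 3 / sqrt(200))
})

test_that("NB mean-variance relation holds across replicate draws", {
  p <- cohort_params(n_individuals = 40, markers = c(m = 1), n_genes = 6,
                     n_orthogonal = 0, dispersion_range = c(0.15, 0.15),
                     pool_size = 40, sigma_r = 1e-12, seed = 41)
  ind <- simulate_individuals(p)
  ind$q <- 0
  genes <- simulate_gene_specs(p)
  reps <- vapply(1:1000, function(i) {
    sample_bulk_counts(ind, genes, 5, "all", pool_size = 40,
                       seed = 10000 + i)$counts
  }, numeric(6))
  mu <- rowMeans(reps)
  v <- apply(reps, 1, var)
  expected_v <- mu + 0.15 * mu^2
  expect_true(all(abs(v / expected_v - 1) < 0.35))
})

test_that("generate_dataset is deterministic and structurally correct", {
  p <- small_params(seed = 8)
  ds1 <- generate_dataset(p)
  ds2 <- generate_dataset(p)
  expect_identical(ds1$counts, ds2$counts)
  expect_identical(ds1$survival, ds2$survival)
  # sample count: timepoints x reps + 2 x markers x reps
  expect_equal(nrow(ds1$meta),
               length(p$timepoints) * p$reps_timecourse +
                 2 * length(p$markers) * p$reps_sorted)
  expect_true(all(ds1$meta$marker_code %in% c(-1, 0, 1)))
  expect_true(all((ds1$meta$marker_code == 0) ==
                    (ds1$meta$group == "timecourse")))
  # every sorted sample's pool lies in the claimed decile
  for (i in which(ds1$meta$group != "timecourse")) {
    m <- ds1$meta$marker[i]
    b <- ds1$truth$individuals[[paste0("b_", m)]]
    k <- floor(length(b) / 10)
    members <- ds1$truth$sample_composition[[ds1$meta$sample_id[i]]]
    rows <- match(members, ds1$truth$individuals$id)
    if (ds1$meta$group[i] == "marker-high") {
      expect_true(all(b[rows] >= sort(b, decreasing = TRUE)[k]))
    } else {
      expect_true(all(b[rows] <= sort(b)[k]))
    }
  }
})

test_that("sorted groups separate by lifespan in the survival table", {
  ds <- generate_dataset(small_params(seed = 9))
  sv <- ds$survival
  # lin4 has sign +1: high fluorescence = predicted long-lived
  hi <- sv$day[sv$group == "lin4_high" & sv$event == "death"]
  lo <- sv$day[sv$group == "lin4_low" & sv$event == "death"]
  expect_gt(median(hi), median(lo))
})

test_that("biomarker predictivity grows with the rate loading", {
  rhos <- vapply(c(0.25, 1, 4), function(wr) {
    p <- cohort_params(n_individuals = 3000, w_r = wr, markers = c(m = 1),
                       n_genes = 10, n_orthogonal = 0, seed = 77)
    ind <- simulate_individuals(p)
    cor(ind$b_m, ind$lifespan, method = "spearman")
  }, 0)
  expect_true(all(diff(rhos) > 0))
  expect_true(all(rhos > 0))
})
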