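make_counts <- function(m) {
  dimnames(m) <- list(sprintf("g%03d", seq_len(nrow(m))),
                      sprintf("s%02d", seq_len(ncol(m))))
  m
}

test_that("detection filter applies the 5-counts-in-75%-of-samples rule", {
  m <- make_counts(rbind(c(5, 5, 5, 0),    # 3/4 detecting -> kept
                         c(4, 4, 4, 4),    # never reaches 5 -> dropped
                         c(5, 5, 0, 0)))   # 2/4 -> dropped
  out <- detection_filter(m)
  expect_identical(rownames(out), "g001")
  # planted fixture: 20 of 100 genes pass
  set.seed(10)
  big <- matrix(0, 100, 8)
  passing <- sample(100, 20)
  big[passing, ] <- 6
  big[-passing, sample(8, 2)] <- 6  # below the 6-of-8 threshold
  big <- make_counts(big)
  expect_equal(nrow(detection_filter(big)), 20)
  expect_identical(rownames(detection_filter(big)),
                   rownames(big)[sort(passing)])
})

test_that("size factors recover known library-depth ratios", {
  eq <- make_counts(matrix(c(10, 50, 10, 50), 2, 2))
  expect_equal(unname(size_factors(eq)), c(1, 1))
  m <- make_counts(matrix(c(10, 100, 20, 200), 2, 2))
  s <- size_factors(m)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # scaling invariance on the ratio scale
  expect_equal(size_factors(m * 3), size_factors(m), tolerance = 1e-12)
})

test_that("vst is zero at zero, monotone, and flattens NB variance", {
  m <- make_counts(matrix(c(0, 1, 5, 100, 0, 2, 7, 120), 4, 2))
  s <- setNames(c(1, 1), colnames(m))
  x <- vst_transform(m, s, 0.1)
  expect_equal(x[1, ], setNames(c(0, 0), colnames(m)))
  expect_true(all(diff(x[, 1]) > 0))
  # variance flattening across a mean grid at alpha = a1
  set.seed(3)
  a1 <- 0.1
  mus <- c(10, 100, 1000, 10000)
  sds <- vapply(mus, function(mu) {
    y <- matrix(rnbinom(2000, mu = mu, size = 1 / a1), ncol = 1)
    rownames(y) <- sprintf("g%04d", 1:2000)
    colnames(y) <- "s1"
    sd(vst_transform(y, c(s1 = 1), a1))
  }, 0)
  expect_lt(max(sds) / min(sds) - 1, 0.25)
  expect_warning(vst_transform(m, s, -1), "falling back")
})

test_that("batch removal restores an additively shifted matrix exactly", {
  set.seed(4)
  X0 <- matrix(rnorm(50 * 8), 50, 8,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  batch <- rep(c(1, 2), each = 4)
  # "no structure besides the shift": balance each gene across the split so
  # the batch shift is exactly identifiable
  for (b in c(1, 2)) {
    X0[, batch == b] <- X0[, batch == b] -
      rowMeans(X0[, batch == b, drop = FALSE])
  }
  delta <- 1.7
  X <- X0
  X[, batch == 2] <- X[, batch == 2] + delta
  corrected <- remove_batch(X, batch)
  expect_equal(corrected, X0, tolerance = 1e-8)
  # single batch: unchanged
  expect_identical(remove_batch(X, rep(1, 8)), X)
})

test_that("batch correction leaves an orthogonal age slope untouched", {
  set.seed(5)
  age <- rep(c(2, 4, 6, 8), times = 2)
  batch <- rep(c(1, 2), each = 4)       # orthogonal to age
  slope <- 0.5
  X <- matrix(rep(slope * age, each = 20), 20, 8) + rnorm(160, 0, 0.1)
  dimnames(X) <- list(sprintf("g%02d", 1:20), sprintf("s%d", 1:8))
  X_shift <- X
  X_shift[, batch == 2] <- X_shift[, batch == 2] + 2
  corrected <- remove_batch(X_shift, batch, protect = cbind(age = age))
  before <- coef(lm(X[1, ] ~ age))["age"]
  after <- coef(lm(corrected[1, ] ~ age))["age"]
  expect_equal(unname(after), unname(before), tolerance = 1e-6)
  # confounded batch errors
  expect_error(remove_batch(X, batch, protect = cbind(b = batch)),
               "confounded")
})

test_that("design matrix centers age, prunes degenerate columns, and codes markers", {
  tc <- data.frame(sample_id = sprintf("t%02d", 1:11), age_days = 2:12,
                   group = "timecourse", marker = "none", marker_code = 0,
                   batch = 1, stringsAsFactors = FALSE)
  expect_warning(d <- build_design(tc, "chronological", "pooled"),
                 "pruning")
  expect_false("marker" %in% colnames(d$matrix))
  expect_equal(mean(d$matrix[, "age1"]), 0, tolerance = 1e-12)
  expect_equal(sd(d$matrix[, "age1"]), 1, tolerance = 1e-12)
  # per-marker coding on the synthetic default: 4 marker columns
  ds <- default_dataset(1)
  dm <- build_design(ds$meta, "chronological", "per_marker")
  expect_length(grep("^marker_", colnames(dm$matrix)), 4L)
  # fluorescence-level coding: high = +1, low = -1, others 0
  hi <- ds$meta$group == "marker-high" & ds$meta$marker == "lin4"
  expect_true(all(dm$matrix[hi, "marker_lin4"] == 1))
  lo <- ds$meta$group == "marker-low" & ds$meta$marker == "lin4"
  expect_true(all(dm$matrix[lo, "marker_lin4"] == -1))
  expect_true(all(dm$matrix[ds$meta$marker != "lin4", "marker_lin4"] == 0))
  # physiological source requires full coverage
  expect_error(build_design(ds$meta, "physiological", "pooled",
                            phys_ages = c(x = 1)),
               "phys_ages")
})

test_that("dispersion estimation recovers simulated regimes", {
  set.seed(6)
  n <- 24
  X <- cbind(intercept = 1, group = rep(c(-1, 1), each = n / 2))
  s <- setNames(rep(1, n), sprintf("s%02d", 1:n))
  pois <- make_counts(matrix(rpois(400 * n, 150), 400, n))
  dp <- suppressWarnings(estimate_dispersions(pois, s, X))
  expect_lte(median(dp$alpha), 0.01)
  nb <- make_counts(matrix(rnbinom(400 * n, mu = 200, size = 5), 400, n))
  dn <- estimate_dispersions(nb, s, X)
  expect_gt(median(dn$alpha), 0.1)
  expect_lt(median(dn$alpha), 0.4)
  # constant gene clamps at the floor
  const <- make_counts(matrix(7, 5, n))
  expect_warning(dc <- estimate_dispersions(const, s, X), "Poisson fallback")
  expect_equal(unname(dc$alpha), rep(1e-8, 5))
})

test_that("NB GLM recovers exact small-sample solutions", {
  n <- 12
  s <- setNames(rep(1, n), sprintf("s%02d", 1:n))
  X1 <- matrix(1, n, 1, dimnames = list(names(s), "intercept"))
  # y = s: intercept-only fit is exactly zero
  fit <- fit_nb_glm(rep(1, n), X1, s, alpha = 0.1)
  expect_equal(unname(fit$beta), 0, tolerance = 1e-6)
  expect_true(fit$converged)
  # two groups with means 100 and 200 at alpha ~ 0: beta = log(2)
  X2 <- cbind(intercept = 1, group = rep(c(0, 1), each = n / 2))
  y <- rep(c(100, 200), each = n / 2)
  fit2 <- fit_nb_glm(y, X2, s, alpha = 1e-8)
  expect_equal(unname(fit2$beta["group"]), log(2), tolerance = 1e-3)
})

test_that("NB GLM marker effect is recovered within its standard error", {
  set.seed(7)
  n <- 36
  X <- cbind(intercept = 1,
             age = scale(rep(1:6, each = 6))[, 1],
             marker = rep(c(-1, 0, 1), times = 12))
  s <- setNames(exp(rnorm(n, 0, 0.1)), sprintf("s%02d", 1:n))
  beta_true <- c(log(150), 0.4, 0.5)
  hits <- vapply(1:200, function(i) {
    mu <- s * exp(drop(X %*% beta_true))
    y <- rnbinom(n, mu = mu, size = 1 / 0.05)
    fit <- fit_nb_glm(y, X, s, alpha = 0.05)
    abs(fit$beta["marker"] - 0.5) < 3 * fit$se["marker"]
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("Wald/BH behaves on edge cases and hand-checked p-vectors", {
  wb <- wald_bh(c(0, 1), c(1, 0.5))
  expect_equal(wb$p[1], 1)
  # q dominates p and is monotone in p
  set.seed(9)
  wb_r <- wald_bh(rnorm(50), runif(50, 0.5, 2))
  expect_true(all(wb_r$q >= wb_r$p))
  ord <- order(wb_r$p)
  expect_true(all(diff(wb_r$q[ord]) >= -1e-12))
  # zero/invalid SE excluded
  wb2 <- wald_bh(c(1, 2), c(0, 1))
  expect_true(is.na(wb2$p[1]) && is.na(wb2$q[1]))
  expect_false(is.na(wb2$p[2]))
})

test_that("dge_fit output is invariant to gene order", {
  set.seed(8)
  ds <- generate_dataset(small_params(seed = 2))
  cts <- detection_filter(ds$counts)[1:40, ]
  s <- size_factors(detection_filter(ds$counts))
  des <- build_design(ds$meta, "chronological", "pooled")
  disp <- estimate_dispersions(cts, s, des)
  dge <- dge_fit(cts, des, s, disp)
  perm <- sample(nrow(cts))
  dge_perm <- dge_fit(cts[perm, ], des, s,
                      structure(list(alpha = disp$alpha[perm],
                                     trend = disp$trend),
                                class = "dispersion_model"))
  reord <- dge_perm[match(dge$gene_id, dge_perm$gene_id), ]
  rownames(reord) <- NULL
  expect_equal(reord$beta_marker, dge$beta_marker, tolerance = 1e-12)
  expect_equal(reord$p_age1, dge$p_age1, tolerance = 1e-12)
})
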