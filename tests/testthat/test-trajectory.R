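test_that("timepoint averaging reproduces hand-computed means", {
  X <- rbind(gA = c(1, 3, 10, 20), gB = c(2, 2, 4, 8))
  colnames(X) <- c("t1", "t2", "t3", "t4")
  meta <- data.frame(sample_id = colnames(X), age_days = c(2, 2, 5, 5),
                     group = "timecourse", marker = "none", marker_code = 0,
                     batch = 1, stringsAsFactors = FALSE)
  tr <- average_by_timepoint(X, meta)
  expect_equal(unname(tr$values["gA", ]), c(2, 15))
  expect_equal(tr$ages, c(2, 5))
  # single replicate per day is the identity
  meta1 <- meta
  meta1$age_days <- c(2, 3, 4, 5)
  tr1 <- average_by_timepoint(X, meta1)
  expect_equal(unname(tr1$values), unname(X))
})

test_that("smoothing reproduces linear trends and standardizes rows", {
  ages <- 2:12
  lin <- outer(c(gA = 2, gB = -1), ages) + c(3, 5)
  tr <- structure(list(values = lin, ages = ages, standardized = FALSE),
                  class = "trajectory_matrix")
  sm <- smooth_standardize(tr, df = 5)
  expect_true(sm$standardized)
  expect_equal(unname(rowMeans(sm$values)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(sm$values, 1, sd)), c(1, 1), tolerance = 1e-9)
  # linear input smoothed exactly (up to standardization, shape is linear)
  expect_equal(cor(sm$values[1, ], ages), 1, tolerance = 1e-9)
  # constant genes flagged and zeroed
  cst <- structure(list(values = matrix(5, 1, 11,
                                        dimnames = list("gC", NULL)),
                        ages = ages, standardized = FALSE),
                   class = "trajectory_matrix")
  smc <- smooth_standardize(cst)
  expect_true(smc$constant[1])
  expect_equal(unname(smc$values[1, ]), rep(0, 11))
  expect_error(smooth_standardize(structure(list(values = lin[, 1:4],
                                                 ages = ages[1:4],
                                                 standardized = FALSE),
                                            class = "trajectory_matrix"),
                                  df = 5),
               "df")
})

test_that("spline smoothing denoises a known signal", {
  set.seed(11)
  ages <- 2:12
  signal <- sin((ages - 2) / 10 * 2 * pi)
  noisy <- signal + rnorm(11, 0, 0.3)
  tr <- structure(list(values = rbind(g = noisy), ages = ages,
                       standardized = FALSE),
                  class = "trajectory_matrix")
  sm <- smooth.spline(ages, noisy, df = 5, cv = FALSE)
  fitted <- predict(sm, ages)$y
  expect_lt(sum((fitted - signal)^2), sum((noisy - signal)^2))
})

test_that("dtw distance has metric-like basics and matches enumeration", {
  a <- c(0, 1, 0)
  b <- c(1, 0, 0)
  expect_equal(dtw_distance(a, a), 0)
  expect_equal(dtw_distance(a, b), dtw_distance(b, a))
  expect_equal(dtw_distance(a, b, window = 1), oracle_dtw(a, b, window = 1))
  expect_error(dtw_distance(1:5, 1:2, window = 1), "band")
})

test_that("dtw equals the exhaustive-path oracle on short series", {
  vals <- c(0, 0.5, 1)
  for (len in 2:4) {
    series <- as.matrix(expand.grid(rep(list(vals), len)))
    set.seed(len)
    idx <- expand.grid(i = seq_len(nrow(series)), j = seq_len(nrow(series)))
    # exhaustive for length 2-3; a fixed random subsample of pairs for 4
    if (len == 4) idx <- idx[sample(nrow(idx), 600), ]
    for (k in seq_len(nrow(idx))) {
      a <- series[idx$i[k], ]
      b <- series[idx$j[k], ]
      expect_equal(dtw_distance(a, b, window = 1),
                   oracle_dtw(a, b, window = 1), tolerance = 1e-12)
    }
  }
})

test_that("DBA centroids behave on degenerate sets and reduce the objective", {
  s1 <- c(0, 1, 2, 1, 0)
  expect_equal(as.numeric(dba_centroid(rbind(s1))), s1)
  two <- rbind(s1, s1)
  expect_equal(as.numeric(dba_centroid(two)), s1)
  set.seed(12)
  series <- t(replicate(12, sin(seq(0, pi, length.out = 9)) + rnorm(9, 0, 0.3)))
  cent <- dba_centroid(series, max_iter = 10)
  trace <- attr(cent, "objective")
  expect_true(all(diff(trace) <= 1e-9))           # non-increasing
  expect_lte(trace[length(trace)], trace[1])      # beats the medoid init
})

test_that("planted archetypes are recovered with semantic labels", {
  fx <- archetype_fixture(n_per = 12, noise_sd = 0.05, seed = 13)
  st <- smooth_standardize(fx$traj)
  fake_dge <- data.frame(gene_id = rownames(fx$traj$values),
                         q_age1 = 0, q_age2 = 1, q_age3 = 1)
  cl <- cluster_trajectories(st, fake_dge)
  expect_equal(unname(cl$labels), fx$labels)
  # permuting gene order leaves labels unchanged
  perm <- sample(nrow(st$values))
  st_p <- st
  st_p$values <- st$values[perm, ]
  cl_p <- cluster_trajectories(st_p, fake_dge)
  expect_equal(cl_p$labels[names(cl$labels)], cl$labels)
})

test_that("single noiseless gene per archetype lands on its own shape label", {
  fx <- archetype_fixture(n_per = 1, noise_sd = 0, seed = 1)
  st <- smooth_standardize(fx$traj)
  fake_dge <- data.frame(gene_id = rownames(fx$traj$values),
                         q_age1 = 0, q_age2 = 1, q_age3 = 1)
  cl <- cluster_trajectories(st, fake_dge)
  expect_equal(unname(cl$labels), 1:5)
})

test_that("cluster 0 membership is exactly the non-significant genes", {
  fx <- archetype_fixture(n_per = 4, noise_sd = 0.05, seed = 14)
  st <- smooth_standardize(fx$traj)
  q <- rep(c(0.5, 0.001), each = 10)  # first half non-significant
  dge <- data.frame(gene_id = rownames(fx$traj$values),
                    q_age1 = q, q_age2 = 1, q_age3 = 1)
  cl <- cluster_trajectories(st, dge, k = 3)
  expect_true(all(cl$labels[1:10] == 0))
  expect_true(all(cl$labels[11:20] != 0))
})
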