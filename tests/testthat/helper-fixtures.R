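# Scaled-down cohort parameters for fast unit tests. Acceptance tests use
# the full defaults; these only exercise mechanics.
small_params <- function(seed = 1, ...) {
  cohort_params(n_individuals = 200, n_genes = 300, n_orthogonal = 15,
                pool_size = 15, reps_timecourse = 2, reps_sorted = 2,
                seed = seed, ...)
}

# Archetype trajectory fixture: n_per genes per shape on the daily grid,
# gaussian noise of the given SD, plus truth labels 1..5.
archetype_fixture <- function(n_per = 40, noise_sd = 0.1, seed = 42,
                              ages = 2:12) {
  set.seed(seed)
  zstd <- function(v) (v - mean(v)) / sd(v)
  shapes <- list(up = zstd(ages), down = zstd(-ages),
                 early_peak = zstd(exp(-0.5 * ((ages - 4) / 1.8)^2)),
                 late_peak = zstd(exp(-0.5 * ((ages - 9) / 1.8)^2)),
                 mid_trough = zstd(-exp(-0.5 * ((ages - 7) / 1.8)^2)))
  vals <- do.call(rbind, lapply(shapes, function(sh) {
    t(replicate(n_per, sh + rnorm(length(ages), 0, noise_sd)))
  }))
  rownames(vals) <- sprintf("g%03d", seq_len(nrow(vals)))
  list(traj = structure(list(values = vals, ages = ages,
                             standardized = FALSE),
                        class = "trajectory_matrix"),
       labels = rep(1:5, each = n_per))
}

# Random small survival table with two groups.
random_survival_table <- function(seed, n_max = 20) {
  set.seed(seed)
  make_group <- function(g, rate) {
    n <- sample(5:n_max, 1)
    data.frame(individual_id = paste0(g, seq_len(n)),
               group = g,
               day = round(rexp(n, rate) + 1, 1),
               event = ifelse(runif(n) < 0.2, "censor", "death"),
               stringsAsFactors = FALSE)
  }
  tab <- rbind(make_group("A", 0.1), make_group("B", 0.15))
  # guarantee at least one death per group
  tab$event[match(c("A1", "B1"), tab$individual_id)] <- "death"
  tab
}
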