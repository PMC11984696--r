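#' Parameters for a synthetic aging cohort
#'
#' Defines the study conditions emulated by the generator: a synchronized
#' isogenic population whose individuals traverse a common transcriptional
#' aging trajectory at heterogeneous rates, carrying one or more
#' lifespan-predictive fluorescent biomarkers. Physiological age of
#' individual i at chronological day t is `r_i * t`, with
#' `r_i = exp(N(0, sigma_r^2))`. Each biomarker reads out a combination of
#' the aging rate and an independent latent factor `q_i`, so both an
#' age-aligned and an age-orthogonal expression signature exist in truth.
#'
#' @param n_individuals Cohort size.
#' @param sigma_r SD of log aging rate (dimensionless).
#' @param w_r,w_q Biomarker loadings on the (standardized) aging rate and on
#'   the latent factor q.
#' @param sigma_b Biomarker measurement-noise SD.
#' @param markers Named vector of marker signs (+1 = fluorescence correlates
#'   positively with lifespan). Defaults to the four markers of the assay
#'   design: lin-4p::GFP (+), mir-243p::GFP (+), mir-240/786p::GFP (-),
#'   autofluorescence (-).
#' @param base_lifespan Median lifespan (days) of an individual aging at the
#'   reference rate r = 1.
#' @param lifespan_noise_sd SD of lognormal lifespan noise.
#' @param n_genes Number of genes.
#' @param archetype_fractions Six non-negative fractions (flat, up, down,
#'   early_peak, late_peak, mid_trough) summing to 1.
#' @param n_orthogonal Number of flat genes carrying an age-orthogonal
#'   loading on q.
#' @param effect_size_orth Magnitude of the log-scale loading gamma of
#'   orthogonal genes on q.
#' @param baseline_meanlog,baseline_sdlog Lognormal parameters of per-gene
#'   baseline mean counts.
#' @param amplitude_range Range of per-gene log-fold amplitude over days
#'   2-12 for non-flat genes.
#' @param dispersion_range Range (alpha_min, alpha_max) of per-gene NB
#'   dispersions.
#' @param n_batches Number of sequencing batches.
#' @param batch_sd Log-scale SD of gene-by-batch multiplicative effects.
#' @param library_size_sd Log-scale SD of per-sample library size factors.
#' @param pool_size Individuals pooled per bulk library.
#' @param timepoints Chronological ages (days) of the time course.
#' @param reps_timecourse,reps_sorted Replicates per timepoint / per sorted
#'   group.
#' @param sort_day Chronological day of biomarker sorting.
#' @param censor_rate Probability that a sorted individual is censored
#'   during the survival assay.
#' @param seed Master seed (mandatory; all randomness flows from it through
#'   named substreams).
#' @return A `cohort_params` list, validated.
#' @export
cohort_params <- function(n_individuals = 500,
                          sigma_r = 0.25,
                          w_r = 1,
                          w_q = 1,
                          sigma_b = 0.5,
                          markers = c(lin4 = 1, mir243 = 1,
                                      mir240_786 = -1, autofl = -1),
                          base_lifespan = 14,
                          lifespan_noise_sd = 0.15,
                          n_genes = 3000,
                          archetype_fractions = c(flat = 0.20, up = 0.30,
                                                  down = 0.25,
                                                  early_peak = 0.10,
                                                  late_peak = 0.08,
                                                  mid_trough = 0.07),
                          n_orthogonal = 150,
                          effect_size_orth = 0.8,
                          baseline_meanlog = log(100),
                          baseline_sdlog = 1,
                          amplitude_range = c(0.5, 2.5),
                          dispersion_range = c(0.01, 0.2),
                          n_batches = 2,
                          batch_sd = 0.1,
                          library_size_sd = 0.15,
                          pool_size = 30,
                          timepoints = 2:12,
                          reps_timecourse = 3,
                          reps_sorted = 3,
                          sort_day = 5,
                          censor_rate = 0.05,
                          seed = 1) {
  p <- as.list(environment())
  validate_cohort_params(p)
  class(p) <- "cohort_params"
  p
}

validate_cohort_params <- function(p) {
  if (p$sigma_r <= 0) stop_physage("sigma_r must be > 0")
  if (p$n_individuals < 1 || p$n_genes < 1 || p$pool_size < 1)
    stop_physage("counts (n_individuals, n_genes, pool_size) must be positive")
  archetypes <- c("flat", "up", "down", "early_peak", "late_peak", "mid_trough")
  if (length(p$archetype_fractions) != 6L ||
      !setequal(names(p$archetype_fractions), archetypes))
    stop_physage("archetype_fractions must be named: %s",
                 paste(archetypes, collapse = ", "))
  if (any(p$archetype_fractions < 0) ||
      abs(sum(p$archetype_fractions) - 1) > 1e-12)
    stop_physage("archetype_fractions must be non-negative and sum to 1")
  if (p$n_orthogonal > p$n_genes)
    stop_physage("n_orthogonal must not exceed n_genes")
  if (p$dispersion_range[1L] <= 0 ||
      p$dispersion_range[2L] < p$dispersion_range[1L])
    stop_physage("dispersion_range must satisfy 0 < alpha_min <= alpha_max")
  if (is.null(names(p$markers)) || !all(p$markers %in% c(-1, 1)))
    stop_physage("markers must be a named vector of +1/-1 signs")
  if (is.null(p$seed)) stop_physage("seed is mandatory")
  invisible(p)
}

#' Simulate individuals with heterogeneous aging rates
#'
#' Draws, per individual: aging rate `r = exp(N(0, sigma_r^2))`, latent
#' factor `q ~ N(0,1)` independent of r, lifespan
#' `base_lifespan / r * exp(N(0, lifespan_noise_sd^2))`, and one biomarker
#' level per configured marker,
#' `b = sign * (-w_r (r-1)/sigma_r + w_q q) + N(0, sigma_b^2)`,
#' so markers with sign +1 correlate positively with lifespan.
#'
#' @param params A [cohort_params()] object.
#' @return data.frame with columns `id`, `r`, `q`, `lifespan`, and one
#'   `b_<marker>` column per marker.
#' @export
simulate_individuals <- function(params) {
  validate_cohort_params(params)
  set.seed(substream_seed(params$seed, "individuals"))
  n <- params$n_individuals
  r <- exp(rnorm(n, 0, params$sigma_r))
  q <- rnorm(n)
  lifespan <- params$base_lifespan / r * exp(rnorm(n, 0, params$lifespan_noise_sd))
  ind <- data.frame(id = sprintf("i%04d", seq_len(n)), r = r, q = q,
                    lifespan = lifespan, stringsAsFactors = FALSE)
  shared <- -params$w_r * (r - 1) / params$sigma_r + params$w_q * q
  for (m in names(params$markers)) {
    ind[[paste0("b_", m)]] <-
      params$markers[[m]] * shared + rnorm(n, 0, params$sigma_b)
  }
  ind
}

#' Simulate per-gene trajectory specifications
#'
#' Assigns archetypes by the configured fractions (largest-remainder
#' rounding), draws baselines, amplitudes and NB dispersions, and flags
#' `n_orthogonal` flat genes as age-orthogonal with loading `+-gamma` on q.
#'
#' @param params A [cohort_params()] object.
#' @return data.frame with columns `id`, `archetype`, `baseline`,
#'   `amplitude`, `orthogonal`, `gamma`, `dispersion`.
#' @export
simulate_gene_specs <- function(params) {
  validate_cohort_params(params)
  set.seed(substream_seed(params$seed, "genes"))
  n <- params$n_genes
  fr <- params$archetype_fractions
  counts <- floor(fr * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(fr * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  archetype <- rep(names(fr), counts)
  if (sum(archetype == "flat") < params$n_orthogonal)
    stop_physage("n_orthogonal exceeds the number of flat genes")
  genes <- data.frame(id = sprintf("g%05d", seq_len(n)),
                      archetype = archetype,
                      baseline = rlnorm(n, params$baseline_meanlog,
                                        params$baseline_sdlog),
                      amplitude = runif(n, params$amplitude_range[1L],
                                        params$amplitude_range[2L]),
                      stringsAsFactors = FALSE)
  genes$amplitude[genes$archetype == "flat"] <- 0
  genes$orthogonal <- FALSE
  flat_idx <- which(genes$archetype == "flat")
  orth_idx <- flat_idx[seq_len(params$n_orthogonal)]
  genes$orthogonal[orth_idx] <- TRUE
  genes$gamma <- 0
  genes$gamma[orth_idx] <- params$effect_size_orth *
    sample(c(-1, 1), params$n_orthogonal, replace = TRUE)
  genes$dispersion <- runif(n, params$dispersion_range[1L],
                            params$dispersion_range[2L])
  genes
}

# Archetype shape functions on physiological age (days). Ramps span days
# 2-12 normalized to [0,1]; bumps are Gaussian, centered at days 4
# (early peak), 9 (late peak) and 7 (mid trough, negated), width 1.8 days.
archetype_shape <- function(archetype, phys_age) {
  t <- phys_age
  ramp <- pmin(pmax((t - 2) / 10, 0), 1)
  bump <- function(center, width = 1.8) exp(-0.5 * ((t - center) / width)^2)
  switch(archetype,
         flat = rep(0, length(t)),
         up = ramp,
         down = 1 - ramp,
         early_peak = bump(4),
         late_peak = bump(9),
         mid_trough = -bump(7),
         stop_physage("unknown archetype '%s'", archetype))
}

#' Mean expression of a gene for an individual state
#'
#' `baseline * exp(f_archetype(phys_age) * amplitude + gamma * q)` where
#' the orthogonal loading gamma is zero for non-orthogonal genes.
#'
#' @param gene One row of a [simulate_gene_specs()] data.frame (or a list
#'   with the same fields).
#' @param phys_age Physiological age(s) in days (>= 0).
#' @param q Latent factor value(s).
#' @return Mean expression on the counts scale.
#' @export
expression_mean <- function(gene, phys_age, q = 0) {
  if (any(phys_age < 0)) stop_physage("phys_age must be >= 0")
  f <- archetype_shape(gene$archetype, phys_age)
  gamma <- if (isTRUE(gene$orthogonal)) gene$gamma else 0
  gene$baseline * exp(f * gene$amplitude + gamma * q)
}

# Vectorized pooled mean expression: genes data.frame x pool of individuals
# at chronological age t. Returns per-gene mean over individuals of
# expression_mean(g, r_i * t, q_i).
pooled_expression_means <- function(genes, r, q, chrono_age) {
  phys <- r * chrono_age
  archetypes <- unique(genes$archetype)
  shape_mat <- vapply(archetypes,
                      function(a) archetype_shape(a, phys),
                      numeric(length(phys)))
  if (is.null(dim(shape_mat))) shape_mat <- matrix(shape_mat, nrow = 1L)
  colnames(shape_mat) <- archetypes
  F <- t(shape_mat)[genes$archetype, , drop = FALSE]     # gene x individual
  logmu <- F * genes$amplitude +
    outer(ifelse(genes$orthogonal, genes$gamma, 0), q)
  genes$baseline * rowMeans(exp(logmu))
}

# Decile membership by nearest rank: the floor(n/10) individuals with the
# highest (top) or lowest (bottom) biomarker values.
decile_members <- function(b, which = c("top", "bottom")) {
  which <- match.arg(which)
  k <- floor(length(b) / 10)
  if (k < 1L) stop_physage("cohort too small for decile sorting")
  ord <- order(b, decreasing = (which == "top"))
  sort(ord[seq_len(k)])
}

#' Draw one bulk RNA-seq count vector from a pooled sample
#'
#' Pools `pool_size` individuals from the requested stratum (full cohort or
#' top/bottom biomarker decile), averages their per-gene mean expression at
#' the given chronological age, applies gene-wise batch factors and a
#' library size factor, and draws negative-binomial counts.
#'
#' @param individuals data.frame from [simulate_individuals()].
#' @param genes data.frame from [simulate_gene_specs()].
#' @param chrono_age Chronological age of the sample (days).
#' @param selection `all`, `top_decile` or `bottom_decile`.
#' @param marker Marker name whose biomarker column defines the deciles
#'   (required for decile selections).
#' @param pool_size Number of individuals pooled.
#' @param batch_factor Per-gene multiplicative batch factor (default 1).
#' @param lib_scale Library size scalar (default 1).
#' @param seed Integer seed for this draw.
#' @return List with `counts` (named integer vector), `mu` (expected
#'   counts), and `pool` (ids of pooled individuals).
#' @export
sample_bulk_counts <- function(individuals, genes, chrono_age,
                               selection = c("all", "top_decile", "bottom_decile"),
                               marker = NULL, pool_size,
                               batch_factor = 1, lib_scale = 1, seed) {
  selection <- match.arg(selection)
  stratum <- seq_len(nrow(individuals))
  if (selection != "all") {
    if (is.null(marker)) stop_physage("decile selection requires a marker name")
    bcol <- paste0("b_", marker)
    if (!bcol %in% colnames(individuals))
      stop_physage("unknown marker '%s'", marker)
    stratum <- decile_members(individuals[[bcol]],
                              if (selection == "top_decile") "top" else "bottom")
  }
  if (!length(stratum)) stop_physage("empty stratum for selection '%s'", selection)
  if (pool_size > length(stratum))
    stop_physage("pool_size (%d) exceeds stratum size (%d)",
                 pool_size, length(stratum))
  set.seed(seed)
  pool <- sample(stratum, pool_size)
  mu_gene <- pooled_expression_means(genes,
                                     individuals$r[pool],
                                     individuals$q[pool],
                                     chrono_age)
  mu <- batch_factor * lib_scale * mu_gene
  counts <- rnbinom(nrow(genes), mu = mu, size = 1 / genes$dispersion)
  names(counts) <- names(mu) <- genes$id
  list(counts = counts, mu = mu, pool = individuals$id[pool])
}

#' Generate a full synthetic aging-cohort dataset
#'
#' Emits a time course of pooled bulk samples at each configured timepoint
#' (marker code 0), plus biomarker-sorted high/low samples per marker at the
#' sort day (marker code +1 for predicted long-lived, -1 for predicted
#' short-lived), a post-sorting survival table for the sorted deciles, and
#' the complete ground truth.
#'
#' @param params A [cohort_params()] object.
#' @return List with `counts` (gene x sample matrix), `meta` (sample
#'   metadata data.frame), `survival` (per-individual survival table) and
#'   `truth` (individuals, genes, per-sample composition and true pooled
#'   physiological ages).
#' @export
generate_dataset <- function(params = cohort_params()) {
  validate_cohort_params(params)
  individuals <- simulate_individuals(params)
  genes <- simulate_gene_specs(params)

  set.seed(substream_seed(params$seed, "batch_factors"))
  batch_fac <- matrix(exp(rnorm(params$n_genes * params$n_batches,
                                0, params$batch_sd)),
                      nrow = params$n_genes)

  plan <- list()
  for (ti in seq_along(params$timepoints)) {
    for (rep in seq_len(params$reps_timecourse)) {
      plan[[length(plan) + 1L]] <- list(
        sample_id = sprintf("tc_d%02d_r%d", params$timepoints[ti], rep),
        age = params$timepoints[ti], selection = "all", marker = "none",
        marker_code = 0L, group = "timecourse",
        batch = (rep - 1L) %% params$n_batches + 1L)
    }
  }
  for (m in names(params$markers)) {
    sgn <- params$markers[[m]]
    for (level in c("high", "low")) {
      code <- if (level == "high") sgn else -sgn
      for (rep in seq_len(params$reps_sorted)) {
        plan[[length(plan) + 1L]] <- list(
          sample_id = sprintf("%s_%s_r%d", m, level, rep),
          age = params$sort_day,
          selection = if (level == "high") "top_decile" else "bottom_decile",
          marker = m, marker_code = code,
          group = paste0("marker-", level),
          batch = (rep - 1L) %% params$n_batches + 1L)
      }
    }
  }

  set.seed(substream_seed(params$seed, "lib_sizes"))
  lib_scale <- exp(rnorm(length(plan), 0, params$library_size_sd))

  counts <- matrix(0L, nrow = params$n_genes, ncol = length(plan),
                   dimnames = list(genes$id, vapply(plan, `[[`, "", "sample_id")))
  composition <- vector("list", length(plan))
  names(composition) <- colnames(counts)
  true_phys <- true_q <- numeric(length(plan))
  for (j in seq_along(plan)) {
    s <- plan[[j]]
    draw <- sample_bulk_counts(individuals, genes, s$age,
                               selection = s$selection,
                               marker = if (s$marker == "none") NULL else s$marker,
                               pool_size = params$pool_size,
                               batch_factor = batch_fac[, s$batch],
                               lib_scale = lib_scale[j],
                               seed = substream_seed(params$seed,
                                                     paste0("sample_", s$sample_id)))
    counts[, j] <- draw$counts
    composition[[j]] <- draw$pool
    pool_rows <- match(draw$pool, individuals$id)
    true_phys[j] <- mean(individuals$r[pool_rows]) * s$age
    true_q[j] <- mean(individuals$q[pool_rows])
  }

  meta <- data.frame(
    sample_id = colnames(counts),
    age_days = vapply(plan, `[[`, 0, "age"),
    group = vapply(plan, `[[`, "", "group"),
    marker = vapply(plan, `[[`, "", "marker"),
    marker_code = vapply(plan, function(s) as.numeric(s$marker_code), 0),
    batch = vapply(plan, function(s) as.integer(s$batch), 0L),
    stringsAsFactors = FALSE)

  survival_tab <- build_survival_table(individuals, params)

  truth <- list(
    individuals = individuals,
    genes = genes,
    sample_composition = composition,
    samples = data.frame(sample_id = colnames(counts),
                         true_phys_age = true_phys,
                         true_mean_q = true_q,
                         stringsAsFactors = FALSE),
    params = params)

  list(counts = counts, meta = meta, survival = survival_tab, truth = truth)
}

# Post-sorting survival records for every individual in each marker's top
# and bottom decile. Groups are named <marker>_high / <marker>_low
# (fluorescence level). A small fraction is right-censored uniformly
# between the sort day and death.
build_survival_table <- function(individuals, params) {
  set.seed(substream_seed(params$seed, "survival"))
  rows <- list()
  for (m in names(params$markers)) {
    b <- individuals[[paste0("b_", m)]]
    for (level in c("high", "low")) {
      idx <- decile_members(b, if (level == "high") "top" else "bottom")
      for (i in idx) {
        death <- max(individuals$lifespan[i], params$sort_day + 0.5)
        censored <- runif(1) < params$censor_rate
        day <- if (censored) runif(1, params$sort_day, death) else death
        rows[[length(rows) + 1L]] <- data.frame(
          individual_id = individuals$id[i],
          group = paste0(m, "_", level),
          day = day,
          event = if (censored) "censor" else "death",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
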