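#' Average expression by timepoint
#'
#' Collapses the time-course samples of an expression matrix to one column
#' per chronological age by averaging replicates, ages sorted ascending.
#'
#' @param X Gene-by-sample expression matrix (typically VST,
#'   batch-corrected).
#' @param meta Sample metadata; only `group == "timecourse"` samples are
#'   used.
#' @return A `trajectory_matrix` list: `values` (gene x timepoint), `ages`,
#'   `standardized = FALSE`.
#' @export
average_by_timepoint <- function(X, meta) {
  tc <- meta[meta$group == "timecourse", , drop = FALSE]
  if (!nrow(tc)) stop_physage("no timecourse samples in metadata")
  ages <- sort(unique(tc$age_days))
  if (length(ages) < 2L) stop_physage("need >= 2 timepoints")
  vals <- vapply(ages, function(a) {
    ids <- tc$sample_id[tc$age_days == a]
    if (!length(ids)) stop_physage("timepoint %s has zero samples", a)
    rowMeans(X[, ids, drop = FALSE])
  }, numeric(nrow(X)))
  dimnames(vals) <- list(rownames(X), paste0("d", ages))
  structure(list(values = vals, ages = ages, standardized = FALSE),
            class = "trajectory_matrix")
}

#' Smooth and standardize gene trajectories
#'
#' Per gene, fits a cubic smoothing spline with the given effective degrees
#' of freedom to the timepoint averages, evaluates it at the observed ages,
#' and z-standardizes the result (mean 0, SD 1). Genes constant across
#' timepoints map to all-zero rows and are flagged.
#'
#' @param traj A `trajectory_matrix` from [average_by_timepoint()].
#' @param df Spline degrees of freedom.
#' @return A standardized `trajectory_matrix` with a `constant` logical
#'   vector.
#' @export
smooth_standardize <- function(traj, df = 5) {
  ages <- traj$ages
  if (length(ages) < df + 1) stop_physage("need at least df + 1 timepoints")
  vals <- traj$values
  out <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  constant <- logical(nrow(vals))
  for (g in seq_len(nrow(vals))) {
    y <- vals[g, ]
    if (sd(y) == 0) {
      constant[g] <- TRUE
      next
    }
    sm <- smooth.spline(ages, y, df = df, cv = FALSE)
    f <- predict(sm, ages)$y
    s <- sd(f)
    if (s < 1e-12) {
      constant[g] <- TRUE
      next
    }
    out[g, ] <- (f - mean(f)) / s
  }
  structure(list(values = out, ages = ages, standardized = TRUE,
                 constant = constant),
            class = "trajectory_matrix")
}

#' Dynamic time warping distance
#'
#' Classic dynamic programming over a Sakoe-Chiba band of radius `window`
#' (index units; with daily sampling one index equals one day), squared
#' local cost, symmetric unit-weight steps; returns the square root of the
#' accumulated cost.
#'
#' @param a,b Numeric series on the same sampling grid.
#' @param window Band radius in index units.
#' @return DTW distance (scalar).
#' @export
dtw_distance <- function(a, b, window = 1) {
  if (abs(length(a) - length(b)) > window)
    stop_physage("length mismatch (%d vs %d) exceeds warping band radius %d",
                 length(a), length(b), window)
  sqrt(dtw_accum_cost(as.numeric(a), as.numeric(b), as.integer(window)))
}

#' Pairwise DTW distance matrix
#'
#' @param series Matrix with one series per row.
#' @param window Band radius.
#' @return Symmetric distance matrix.
#' @export
dtw_pairwise <- function(series, window = 1) {
  D <- dtw_pairwise_cpp(as.matrix(series), as.integer(window))
  dimnames(D) <- list(rownames(series), rownames(series))
  D
}

#' DTW barycenter averaging (DBA)
#'
#' Computes a centroid series for a set of equal-length series: initialized
#' at the medoid (minimum sum of squared DTW distances), then iteratively
#' re-averaged over the points aligned to each centroid position along the
#' optimal warping paths. The objective (sum of squared DTW distances to
#' the centroid) is non-increasing across iterations.
#'
#' @param series Matrix with one series per row (non-empty).
#' @param window DTW band radius.
#' @param max_iter Iteration cap.
#' @return Numeric centroid series with attribute `objective` (per-iteration
#'   trace, medoid objective first).
#' @export
dba_centroid <- function(series, window = 1, max_iter = 10) {
  series <- as.matrix(series)
  n <- nrow(series)
  if (n == 0L) stop_physage("dba_centroid needs a non-empty set")
  if (n == 1L) {
    cent <- series[1L, ]
    attr(cent, "objective") <- 0
    return(cent)
  }
  D <- dtw_pairwise(series, window)
  medoid <- which.min(rowSums(D^2))
  centroid <- series[medoid, ]
  objective <- function(cent) {
    sum(vapply(seq_len(n),
               function(i) dtw_accum_cost(cent, series[i, ], as.integer(window)),
               0))
  }
  trace <- objective(centroid)
  for (it in seq_len(max_iter)) {
    sums <- numeric(length(centroid))
    cnts <- numeric(length(centroid))
    for (i in seq_len(n)) {
      path <- dtw_path_cpp(centroid, series[i, ], as.integer(window))
      sums[path[, 1L]] <- sums[path[, 1L]] + series[i, path[, 2L]]
      cnts[path[, 1L]] <- cnts[path[, 1L]] + 1
    }
    new_centroid <- sums / cnts
    obj <- objective(new_centroid)
    if (obj > trace[length(trace)] - 1e-12) {
      if (obj <= trace[length(trace)]) {
        centroid <- new_centroid
        trace <- c(trace, obj)
      }
      break
    }
    centroid <- new_centroid
    trace <- c(trace, obj)
  }
  attr(centroid, "objective") <- trace
  centroid
}

# Standardized template shapes on an age grid, used to give cluster labels
# their semantics: 1 = monotone up, 2 = monotone down, 3 = early peak,
# 4 = late peak, 5 = mid trough.
shape_templates <- function(ages) {
  span <- diff(range(ages))
  zstd <- function(v) (v - mean(v)) / sd(v)
  bump <- function(frac) exp(-0.5 * ((ages - (min(ages) + frac * span)) /
                                       (0.18 * span))^2)
  list(`1` = zstd(ages),
       `2` = zstd(-ages),
       `3` = zstd(bump(0.2)),
       `4` = zstd(bump(0.7)),
       `5` = zstd(-bump(0.5)))
}

# Assign semantic labels to centroids by maximizing total Pearson
# correlation with the templates (exhaustive over permutations for k <= 6,
# greedy otherwise). Pure function of centroid shape.
relabel_by_shape <- function(centroids, ages) {
  templates <- shape_templates(ages)
  k <- nrow(centroids)
  cors <- matrix(-Inf, k, length(templates))
  for (i in seq_len(k)) {
    for (j in seq_along(templates)) {
      if (sd(centroids[i, ]) > 0)
        cors[i, j] <- cor(centroids[i, ], templates[[j]])
    }
  }
  labels <- integer(k)
  if (k <= length(templates)) {
    perms <- all_permutations(seq_along(templates), k)
    best <- -Inf
    for (p in perms) {
      score <- sum(cors[cbind(seq_len(k), p)])
      if (score > best) {
        best <- score
        labels <- p
      }
    }
  } else {
    labels <- apply(cors, 1L, which.max)
  }
  as.integer(labels)
}

# All ordered selections of `k` elements from `v` (k-permutations).
all_permutations <- function(v, k) {
  if (k == 0L) return(list(integer()))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i], k - 1L)) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

#' Cluster gene trajectories into cluster 0 plus shape clusters
#'
#' Genes with no age coefficient significant at the FDR threshold (none of
#' `q_age1`, `q_age2`, `q_age3` below `alpha0`) form cluster 0 (no
#' correlation with time). The remaining genes are clustered by
#' complete-linkage agglomeration on pairwise DTW distances of their
#' standardized trajectories, the tree is cut into `k` clusters, centroids
#' are computed by DTW barycenter averaging, and clusters are relabeled by
#' centroid shape: 1 = up, 2 = down, 3 = early peak, 4 = late peak,
#' 5 = mid trough.
#'
#' @param traj Standardized `trajectory_matrix`.
#' @param age_dge DGE table fitted on the chronological-age model (provides
#'   the q-values).
#' @param k Number of shape clusters.
#' @param alpha0 FDR threshold for the cluster-0 rule.
#' @param window DTW band radius.
#' @return List with `labels` (named integer vector, 0..k), `centroids`
#'   (label x timepoint matrix), `ages`, and the `hclust` object.
#' @export
cluster_trajectories <- function(traj, age_dge, k = 5, alpha0 = 0.01,
                                 window = 1) {
  if (!isTRUE(traj$standardized))
    stop_physage("cluster_trajectories requires a standardized trajectory matrix")
  vals <- traj$values
  genes <- rownames(vals)
  qcols <- intersect(c("q_age1", "q_age2", "q_age3"), colnames(age_dge))
  if (!length(qcols)) stop_physage("age_dge lacks q_age1..q_age3 columns")
  qm <- as.matrix(age_dge[match(genes, age_dge$gene_id), qcols, drop = FALSE])
  qmin <- suppressWarnings(apply(qm, 1L, min, na.rm = TRUE))
  qmin[!is.finite(qmin)] <- 1
  labels <- setNames(integer(length(genes)), genes)
  clusterable <- which(qmin < alpha0)
  if (length(clusterable) < k)
    stop_physage("only %d clusterable genes for k = %d clusters",
                 length(clusterable), k)
  sub <- vals[clusterable, , drop = FALSE]
  D <- dtw_pairwise(sub, window)
  hc <- hclust(as.dist(D), method = "complete")
  cl <- cutree(hc, k = k)
  cents <- t(vapply(seq_len(k), function(ci) {
    as.numeric(dba_centroid(sub[cl == ci, , drop = FALSE], window = window))
  }, numeric(ncol(sub))))
  new_lab <- relabel_by_shape(cents, traj$ages)
  labels[clusterable] <- new_lab[cl]
  centroids <- cents[order(new_lab), , drop = FALSE]
  rownames(centroids) <- sort(new_lab)
  colnames(centroids) <- colnames(vals)
  list(labels = labels, centroids = centroids, ages = traj$ages, hclust = hc)
}
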