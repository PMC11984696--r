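#' Detection filter for count matrices
#'
#' Keeps genes for which at least `min_fraction` of samples (rounded up)
#' show at least `min_count` counts; the default reproduces the standard
#' "5 counts in 75% of samples" detection rule.
#'
#' @param counts Gene-by-sample count matrix.
#' @param min_count Minimum count for a sample to count as detecting.
#' @param min_fraction Minimum fraction of detecting samples.
#' @return The filtered count matrix (row order preserved).
#' @export
detection_filter <- function(counts, min_count = 5, min_fraction = 0.75) {
  validate_counts(counts)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors: the median across reference genes of the
#' ratio of a sample's count to the gene's geometric mean, rescaled so the
#' factors have geometric mean 1. Reference genes are those with nonzero
#' counts in all samples; if none exist, genes nonzero in at least half the
#' samples are used (ratios taken over their positive entries) with a
#' warning.
#'
#' @param counts Gene-by-sample count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    sub <- counts[all_pos, , drop = FALSE]
    loggeo <- rowMeans(log(sub))
    logs <- apply(log(sub) - loggeo, 2L, median)
  } else {
    warn_physage("no gene has nonzero counts in all samples; using genes positive in >= half the samples")
    ok <- rowSums(counts > 0) >= ncol(counts) / 2
    if (!any(ok)) stop_physage("size factors undefined: counts too sparse")
    sub <- counts[ok, , drop = FALSE]
    lsub <- log(sub)
    lsub[!is.finite(lsub)] <- NA
    loggeo <- rowMeans(lsub, na.rm = TRUE)
    logs <- apply(lsub - loggeo, 2L, median, na.rm = TRUE)
  }
  s <- exp(logs - mean(logs))
  names(s) <- colnames(counts)
  s
}

#' Method-of-moments dispersion estimation with trend shrinkage
#'
#' Per gene, a raw NB dispersion is estimated as
#' `(var_hat - mu_bar) / mu_bar^2`, where `var_hat` is the design-residual
#' variance of the size-factor-normalized counts and `mu_bar` their mean.
#' A mean-dispersion trend `alpha(mu) = a0/mu + a1` is fitted by robust
#' regression over genes with positive raw estimates, and the final
#' per-gene dispersion is the geometric mean of the raw and trend values,
#' clamped to `[1e-8, 10]`.
#'
#' @param counts Gene-by-sample count matrix.
#' @param s Size factors.
#' @param design Design matrix from [build_design()] (used for residual
#'   degrees of freedom).
#' @return A `dispersion_model` list: `alpha` (per-gene), `trend`
#'   (`c(a0, a1)`), `mu` (per-gene mean normalized count), `alpha_raw`.
#' @export
estimate_dispersions <- function(counts, s, design) {
  X <- if (is.list(design)) design$matrix else design
  n <- ncol(counts)
  p <- ncol(X)
  if (n - p < 1) stop_physage("no residual degrees of freedom")
  q <- sweep(counts, 2L, s, "/")
  mu_bar <- rowMeans(q)
  qr_x <- qr(X)
  resid <- t(qr.resid(qr_x, t(q)))
  var_hat <- rowSums(resid^2) / (n - qr_x$rank)
  alpha_raw <- (var_hat - mu_bar) / mu_bar^2
  alpha_raw[!is.finite(alpha_raw)] <- 0

  pos <- which(alpha_raw > 0 & mu_bar > 0)
  if (!length(pos)) {
    warn_physage("all raw dispersion estimates <= 0; Poisson fallback (alpha = 1e-8)")
    alpha <- rep(1e-8, nrow(counts))
    names(alpha) <- rownames(counts)
    return(structure(list(alpha = alpha, trend = c(a0 = 0, a1 = 1e-8),
                          mu = mu_bar, alpha_raw = alpha_raw),
                     class = "dispersion_model"))
  }
  if (length(pos) >= 10L) {
    fit <- tryCatch(
      MASS::rlm(alpha_raw[pos] ~ I(1 / mu_bar[pos]), maxit = 50),
      error = function(e) NULL)
    cf <- if (!is.null(fit)) coef(fit) else
      coef(lm.fit(cbind(1, 1 / mu_bar[pos]), alpha_raw[pos]))
    a1 <- max(cf[[1L]], 1e-8)
    a0 <- max(cf[[2L]], 0)
  } else {
    a1 <- max(median(alpha_raw[pos]), 1e-8)
    a0 <- 0
  }
  alpha_trend <- pmax(a0 / pmax(mu_bar, 1e-8) + a1, 1e-8)
  w <- 0.5
  alpha <- exp(w * log(alpha_trend) + (1 - w) * log(pmax(alpha_raw, 1e-8)))
  alpha <- pmin(pmax(alpha, 1e-8), 10)
  names(alpha) <- rownames(counts)
  structure(list(alpha = alpha, trend = c(a0 = a0, a1 = a1),
                 mu = mu_bar, alpha_raw = alpha_raw),
            class = "dispersion_model")
}

#' Variance-stabilizing transformation for NB counts
#'
#' Closed-form stabilizer for the NB mean-variance relation with asymptotic
#' dispersion `a1`: `x = (2/sqrt(a1)) * asinh(sqrt(a1 * y / s))`. As
#' `a1 -> 0` this converges to `2 * sqrt(y/s)` (the Poisson stabilizer).
#' If `a1 <= 0` the transform falls back to `log2(y/s + 1)` with a warning.
#'
#' @param counts Gene-by-sample count matrix.
#' @param s Size factors.
#' @param dispersion A `dispersion_model`, or a single numeric `a1`.
#' @return Matrix of variance-stabilized expression values.
#' @export
vst_transform <- function(counts, s, dispersion) {
  a1 <- if (inherits(dispersion, "dispersion_model"))
    dispersion$trend[["a1"]] else as.numeric(dispersion)
  q <- sweep(counts, 2L, s, "/")
  if (is.na(a1) || a1 <= 0) {
    warn_physage("non-positive asymptotic dispersion; falling back to log2(y/s + 1)")
    return(log2(q + 1))
  }
  (2 / sqrt(a1)) * asinh(sqrt(a1 * q))
}

#' Remove additive batch effects from an expression matrix
#'
#' Per gene, fits ordinary least squares of expression on the protected
#' covariates plus batch indicator columns (reference batch dropped) and
#' subtracts only the fitted batch component, leaving protected signal
#' untouched. With a single batch the matrix is returned unchanged.
#'
#' @param X Gene-by-sample expression matrix.
#' @param batch Per-sample batch labels.
#' @param protect Optional sample-by-covariate matrix of signal to protect
#'   (an intercept is always included).
#' @return Batch-corrected expression matrix.
#' @export
remove_batch <- function(X, batch, protect = NULL) {
  batch <- factor(batch)
  if (nlevels(batch) < 2L) return(X)
  B <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
  colnames(B) <- paste0("batch_", levels(batch)[-1L])
  P <- cbind(intercept = rep(1, ncol(X)), protect)
  D <- cbind(P, B)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    drop_col <- colnames(D)[qr_d$pivot[(qr_d$rank + 1L):ncol(D)]]
    stop_physage("batch is confounded with protected covariate(s); rank-deficient column(s): %s",
                 paste(drop_col, collapse = ", "))
  }
  coefs <- qr.coef(qr_d, t(X))
  batch_cols <- (ncol(P) + 1L):ncol(D)
  X - t(B %*% coefs[batch_cols, , drop = FALSE])
}

#' Build a design matrix for NB differential expression
#'
#' Age (chronological or supplied physiological) is centered to mean 0 and
#' scaled to SD 1 once, then raised to powers 1-3 (`age1`, `age2`, `age3`),
#' implementing the third-degree polynomial age model. Marker coding is
#' either `pooled` (a single column of -1/0/+1 longevity codes; +1 =
#' predicted long-lived) or `per_marker` (one column per marker coding that
#' marker's fluorescence level: +1 high, -1 low, 0 elsewhere, so each
#' coefficient carries the biomarker's own sign convention). Batch enters as
#' one-hot indicators with the reference level dropped. Zero-variance
#' columns (other than the intercept) are pruned with a warning.
#'
#' @param meta Sample metadata (see [read_sample_meta()]).
#' @param age_source `chronological` or `physiological`.
#' @param marker_coding `pooled` or `per_marker`.
#' @param phys_ages Named vector of physiological ages (days), required for
#'   `age_source = "physiological"`; names must cover every sample.
#' @return List with `matrix` (sample x covariate), `age_center`,
#'   `age_scale`, `marker_coding`.
#' @export
build_design <- function(meta,
                         age_source = c("chronological", "physiological"),
                         marker_coding = c("pooled", "per_marker"),
                         phys_ages = NULL) {
  age_source <- match.arg(age_source)
  marker_coding <- match.arg(marker_coding)
  if (age_source == "physiological") {
    if (is.null(phys_ages) || !all(meta$sample_id %in% names(phys_ages)))
      stop_physage("physiological age_source requires phys_ages for every sample")
    age <- unname(phys_ages[meta$sample_id])
  } else {
    age <- meta$age_days
  }
  ctr <- mean(age)
  scl <- sd(age)
  if (scl == 0) stop_physage("age has zero variance; polynomial design undefined")
  z <- (age - ctr) / scl
  X <- cbind(intercept = 1, age1 = z, age2 = z^2, age3 = z^3)

  if (marker_coding == "pooled") {
    X <- cbind(X, marker = meta$marker_code)
  } else {
    markers <- setdiff(unique(meta$marker), "none")
    if (!length(markers)) stop_physage("per_marker coding requires marker samples")
    for (m in markers) {
      level <- ifelse(meta$group == "marker-high", 1, -1)
      X <- cbind(X, ifelse(meta$marker == m, level, 0))
      colnames(X)[ncol(X)] <- paste0("marker_", m)
    }
  }
  batch <- factor(meta$batch)
  if (nlevels(batch) > 1L) {
    B <- stats::model.matrix(~batch)[, -1L, drop = FALSE]
    colnames(B) <- paste0("batch_", levels(batch)[-1L])
    X <- cbind(X, B)
  }
  const <- apply(X[, -1L, drop = FALSE], 2L, function(col) all(col == col[1L]))
  if (any(const)) {
    warn_physage("pruning degenerate design column(s): %s",
                 paste(colnames(X)[-1L][const], collapse = ", "))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop_physage("design matrix is rank deficient; dependent column(s): %s",
                 paste(dep, collapse = ", "))
  }
  rownames(X) <- meta$sample_id
  list(matrix = X, age_center = ctr, age_scale = scl,
       marker_coding = marker_coding, age_source = age_source)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood with log link and offset `log(s)` by
#' iteratively reweighted least squares (Fisher scoring with working
#' weights `mu/(1 + alpha*mu)`), a ridge of 1e-6 on the normal equations,
#' and convergence when `max |delta beta| < tol`. Standard errors come from
#' the inverse observed information.
#'
#' @param y Count vector.
#' @param X Design matrix (samples x covariates).
#' @param s Size factors (offset `log(s)`).
#' @param alpha NB dispersion (Var = mu + alpha mu^2).
#' @param ridge Ridge added to the normal equations.
#' @param tol Convergence tolerance on coefficients.
#' @param max_iter Iteration cap.
#' @return List with `beta`, `se`, `converged`, `iterations`, `mu`.
#' @export
fit_nb_glm <- function(y, X, s, alpha, ridge = 1e-6, tol = 1e-8,
                       max_iter = 100) {
  if (length(y) != nrow(X)) stop_physage("length(y) must match nrow(X)")
  offset <- log(s)
  p <- ncol(X)
  # initialize from least squares on the log scale
  z0 <- log((y + 0.5) / s)
  beta <- qr.coef(qr(X), z0)
  beta[!is.finite(beta)] <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    A <- crossprod(X, X * w) + diag(ridge, p)
    b <- crossprod(X, w * z)
    beta_new <- drop(solve(A, b))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  eta <- drop(X %*% beta) + offset
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  w_obs <- mu * (1 + alpha * y) / (1 + alpha * mu)^2
  info <- crossprod(X, X * w_obs) + diag(ridge, p)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) {
    w_exp <- mu / (1 + alpha * mu)
    sqrt(diag(solve(crossprod(X, X * w_exp) + diag(ridge, p))))
  })
  names(beta) <- names(se) <- colnames(X)
  list(beta = beta, se = se, converged = converged, iterations = iter, mu = mu)
}

#' Wald test p-values with Benjamini-Hochberg adjustment
#'
#' Two-sided normal-reference Wald p-values `2 * pnorm(-|beta/se|)` and BH
#' q-values across genes. Entries with zero or non-finite SE get `NA`
#' p-values and are excluded from the BH adjustment.
#'
#' @param beta Coefficient estimates (one per gene).
#' @param se Standard errors.
#' @return List with `p` and `q` vectors.
#' @export
wald_bh <- function(beta, se) {
  p <- rep(NA_real_, length(beta))
  ok <- is.finite(se) & se > 0 & is.finite(beta)
  p[ok] <- 2 * pnorm(-abs(beta[ok] / se[ok]))
  q <- rep(NA_real_, length(beta))
  q[ok] <- p.adjust(p[ok], method = "BH")
  list(p = p, q = q)
}

#' Negative-binomial differential expression over all genes
#'
#' Fits [fit_nb_glm()] per gene against the supplied design and assembles a
#' coefficient table with per-coefficient Wald p and BH q values.
#'
#' @param counts Gene-by-sample count matrix.
#' @param design Output of [build_design()].
#' @param s Size factors.
#' @param dispersions A `dispersion_model` (or per-gene numeric vector).
#' @return data.frame (one row per gene): `gene_id`, `mean_norm_count`,
#'   `converged`, plus `beta_*`, `se_*`, `p_*`, `q_*` for every design
#'   column.
#' @export
dge_fit <- function(counts, design, s, dispersions) {
  X <- if (is.list(design)) design$matrix else design
  alpha <- if (inherits(dispersions, "dispersion_model"))
    dispersions$alpha else dispersions
  if (length(alpha) == 1L) alpha <- rep(alpha, nrow(counts))
  n_genes <- nrow(counts)
  p <- ncol(X)
  betas <- ses <- matrix(NA_real_, n_genes, p,
                         dimnames = list(rownames(counts), colnames(X)))
  conv <- logical(n_genes)
  for (g in seq_len(n_genes)) {
    fit <- fit_nb_glm(counts[g, ], X, s, alpha[g])
    betas[g, ] <- fit$beta
    ses[g, ] <- fit$se
    conv[g] <- fit$converged
  }
  out <- data.frame(gene_id = rownames(counts),
                    mean_norm_count = rowMeans(sweep(counts, 2L, s, "/")),
                    converged = conv,
                    stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    nm <- colnames(X)[j]
    wb <- wald_bh(betas[, j], ses[, j])
    out[[paste0("beta_", nm)]] <- betas[, j]
    out[[paste0("se_", nm)]] <- ses[, j]
    out[[paste0("p_", nm)]] <- wb$p
    out[[paste0("q_", nm)]] <- wb$q
  }
  attr(out, "design") <- if (is.list(design)) design[c("age_center", "age_scale", "marker_coding", "age_source")] else NULL
  out
}
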