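#' Principal component analysis of an expression matrix
#'
#' Column-centered (per gene), unscaled PCA of samples, with a
#' deterministic sign convention: within each component the
#' largest-magnitude gene loading is positive.
#'
#' @param X Gene-by-sample expression matrix (VST, batch-corrected).
#' @param n_components Number of components to retain.
#' @return List with `scores` (sample x component), `loadings`
#'   (gene x component), `var_fraction`, `center`.
#' @export
pca_model <- function(X, n_components = 3) {
  if (ncol(X) < n_components + 1)
    stop_physage("need more samples than components")
  sds <- apply(X, 1L, sd)
  if (all(sds == 0)) stop_physage("constant expression matrix; PCA undefined")
  pr <- prcomp(t(X), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    j <- which.max(abs(loadings[, c]))
    if (loadings[j, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  var_fraction <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = scores, loadings = loadings,
       var_fraction = var_fraction[seq_len(k)], center = pr$center)
}

# Project points (n x d) onto a polyline (vertices m x d with cumulative
# arc length). Vectorized over segments; ties go to the smaller arc
# position (first minimum).
project_polyline <- function(vertices, arc, points) {
  points <- matrix(points, ncol = ncol(vertices))
  m <- nrow(vertices)
  v0 <- vertices[-m, , drop = FALSE]
  dv <- vertices[-1L, , drop = FALSE] - v0
  seg_len2 <- pmax(rowSums(dv^2), 1e-300)
  n <- nrow(points)
  arc_pos <- dist2 <- numeric(n)
  closest <- matrix(0, n, ncol(vertices))
  for (i in seq_len(n)) {
    p <- points[i, ]
    diffs <- sweep(v0, 2L, p, "-")
    tt <- pmin(pmax(-rowSums(diffs * dv) / seg_len2, 0), 1)
    proj <- v0 + dv * tt
    d2 <- rowSums(sweep(proj, 2L, p, "-")^2)
    j <- which.min(d2)
    arc_pos[i] <- arc[j] + tt[j] * sqrt(seg_len2[j])
    dist2[i] <- d2[j]
    closest[i, ] <- proj[j, ]
  }
  list(arc = arc_pos, dist = sqrt(dist2), closest = closest)
}

#' Fit a principal curve through samples in PC space
#'
#' Hastie-Stuetzle iteration: the curve parameter is initialized by
#' projection onto the first PC axis; each iteration fits a cubic smoothing
#' spline of every coordinate against the parameter, resamples the curve
#' densely, reparameterizes by cumulative arc length, and re-projects the
#' points. Converges when the relative change in mean squared projection
#' distance drops below `tol`.
#'
#' @param scores Sample-by-component score matrix (time-series samples
#'   only).
#' @param df Spline degrees of freedom for each coordinate smoother.
#' @param tol Relative convergence tolerance on the mean squared projection
#'   distance.
#' @param max_iter Iteration cap.
#' @param n_points Number of dense resampling vertices.
#' @return A `principal_curve` list: `vertices` (n_points x d), `arc`
#'   (cumulative arc length), `lambda` (arc position per input sample),
#'   `mse`, `converged`, `n_iter`.
#' @export
fit_principal_curve <- function(scores, df = 4, tol = 1e-6, max_iter = 50,
                                n_points = 512) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2 * df) stop_physage("need at least 2*df samples to fit the curve")
  lambda <- scores[, 1L]
  prev_mse <- Inf
  converged <- FALSE
  vertices <- NULL
  arc <- NULL
  for (it in seq_len(max_iter)) {
    grid <- seq(min(lambda), max(lambda), length.out = n_points)
    vertices <- vapply(seq_len(ncol(scores)), function(j) {
      if (length(unique(lambda)) < 4)
        return(approx(lambda, scores[, j], xout = grid, rule = 2, ties = mean)$y)
      sm <- smooth.spline(lambda, scores[, j], df = df, cv = FALSE)
      predict(sm, grid)$y
    }, numeric(n_points))
    seg <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                           vertices[-n_points, , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    proj <- project_polyline(vertices, arc, scores)
    lambda <- proj$arc
    mse <- mean(proj$dist^2)
    if (is.finite(prev_mse) &&
        abs(prev_mse - mse) / max(mse, 1e-12) < tol) {
      converged <- TRUE
      break
    }
    prev_mse <- mse
  }
  if (!converged)
    warn_physage("principal curve did not converge in %d iterations", max_iter)
  structure(list(vertices = vertices, arc = arc, lambda = lambda,
                 mse = mse, converged = converged, n_iter = it, df = df),
            class = "principal_curve_fit")
}

#' Project points onto a fitted principal curve
#'
#' Each point is projected onto the nearest segment of the dense polyline;
#' ties break toward the smaller arc position. The signed residual is the
#' residual distance multiplied by the sign of the residual vector's
#' component along a reference axis (default the second PC).
#'
#' @param curve A `principal_curve_fit`.
#' @param points Point matrix (rows) in the same PC space.
#' @param ref_axis Column index of the reference axis for the residual
#'   sign.
#' @return data.frame with `arc`, `residual`, `signed_residual`.
#' @export
project_curve <- function(curve, points, ref_axis = 2) {
  points <- matrix(points, ncol = ncol(curve$vertices))
  proj <- project_polyline(curve$vertices, curve$arc, points)
  resvec <- points - proj$closest
  sgn <- sign(resvec[, min(ref_axis, ncol(points))])
  sgn[sgn == 0] <- 1
  data.frame(arc = proj$arc, residual = proj$dist,
             signed_residual = proj$dist * sgn)
}

#' Calibrate arc length to days and estimate physiological ages
#'
#' In `proportional` mode, physiological age is a linear map of arc length
#' anchored at the mean arc positions of the youngest and oldest
#' chronological days of the time course; extrapolation beyond the anchors
#' is linear. In `monotone` mode, an isotonic fit of day against mean arc
#' position per day is interpolated linearly (linear extrapolation at the
#' ends).
#'
#' @param curve A `principal_curve_fit` fitted on time-course scores.
#' @param meta Sample metadata.
#' @param scores Score matrix for all samples (rownames = sample ids).
#' @param mode `proportional` or `monotone`.
#' @param ref_axis Reference axis for the residual sign.
#' @return data.frame: `sample_id`, `arc`, `phys_age_days`, `residual`,
#'   `signed_residual`, `group`.
#' @export
calibrate_phys_age <- function(curve, meta, scores,
                               mode = c("proportional", "monotone"),
                               ref_axis = 2) {
  mode <- match.arg(mode)
  proj <- project_curve(curve, scores, ref_axis = ref_axis)
  proj$sample_id <- rownames(scores)
  tc <- meta[meta$group == "timecourse", , drop = FALSE]
  if (length(unique(tc$age_days)) < 2L)
    stop_physage("calibration needs >= 2 distinct time-course ages")
  arc_by_sample <- setNames(proj$arc, proj$sample_id)
  day_min <- min(tc$age_days)
  day_max <- max(tc$age_days)
  a_min <- mean(arc_by_sample[tc$sample_id[tc$age_days == day_min]])
  a_max <- mean(arc_by_sample[tc$sample_id[tc$age_days == day_max]])
  if (abs(a_max - a_min) < 1e-12)
    stop_physage("youngest and oldest anchor arc positions coincide")
  if (mode == "proportional") {
    phys <- day_min + (proj$arc - a_min) * (day_max - day_min) / (a_max - a_min)
  } else {
    days <- sort(unique(tc$age_days))
    mean_arc <- vapply(days, function(d) {
      mean(arc_by_sample[tc$sample_id[tc$age_days == d]])
    }, 0)
    flip <- a_max < a_min
    xs <- if (flip) -mean_arc else mean_arc
    iso <- isoreg(xs, days)
    xarc <- if (flip) -proj$arc else proj$arc
    ord <- order(iso$x)
    xk <- iso$x[ord]
    yk <- iso$yf[ord]
    phys <- approx(xk, yk, xout = xarc, rule = 2, ties = mean)$y
    # linear extrapolation beyond the anchors
    lo <- xarc < min(xk)
    hi <- xarc > max(xk)
    slope <- (yk[length(yk)] - yk[1L]) / max(xk[length(xk)] - xk[1L], 1e-12)
    phys[lo] <- yk[1L] + (xarc[lo] - xk[1L]) * slope
    phys[hi] <- yk[length(yk)] + (xarc[hi] - xk[length(xk)]) * slope
  }
  data.frame(sample_id = proj$sample_id,
             arc = proj$arc,
             phys_age_days = phys,
             residual = proj$residual,
             signed_residual = proj$signed_residual,
             group = meta$group[match(proj$sample_id, meta$sample_id)],
             stringsAsFactors = FALSE)
}

#' Estimate physiological age for every sample
#'
#' Convenience wrapper chaining [pca_model()], [fit_principal_curve()] (on
#' the time-course samples only) and [calibrate_phys_age()].
#'
#' @param X Gene-by-sample expression matrix (VST, batch-corrected).
#' @param meta Sample metadata.
#' @param n_components PCs used for the curve (default 3).
#' @param df Curve smoother degrees of freedom.
#' @param mode Calibration mode, see [calibrate_phys_age()].
#' @return List with `estimates` (data.frame), `curve`, `pca`.
#' @export
estimate_physiological_age <- function(X, meta, n_components = 3, df = 4,
                                       mode = "proportional") {
  pca <- pca_model(X, n_components = n_components)
  tc_ids <- meta$sample_id[meta$group == "timecourse"]
  curve <- fit_principal_curve(pca$scores[tc_ids, , drop = FALSE], df = df)
  est <- calibrate_phys_age(curve, meta, pca$scores, mode = mode)
  list(estimates = est, curve = curve, pca = pca)
}
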