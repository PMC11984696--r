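#' Pairwise Pearson correlation of differential-expression signatures
#'
#' Correlates, over genes, the age coefficient (`beta_age1`) with every
#' per-marker coefficient from the per-marker model (and the markers with
#' each other), using pairwise-complete genes.
#'
#' @param dge_markers DGE table fitted with `per_marker` coding (must also
#'   contain `beta_age1`).
#' @param extra Optional named list of additional coefficient vectors
#'   (aligned to `dge_markers$gene_id`).
#' @return Symmetric correlation matrix with signature labels.
#' @export
compare_signatures <- function(dge_markers, extra = NULL) {
  cols <- grep("^beta_(age1$|marker_)", colnames(dge_markers), value = TRUE)
  if (length(cols) < 2L)
    stop_physage("need beta_age1 plus marker coefficients to compare")
  M <- as.matrix(dge_markers[, cols, drop = FALSE])
  colnames(M) <- sub("^beta_", "", cols)
  if (!is.null(extra)) M <- cbind(M, do.call(cbind, extra))
  if (sum(stats::complete.cases(M)) < 3L)
    stop_physage("fewer than 3 genes shared across signatures")
  cor(M, use = "pairwise.complete.obs")
}

#' Classify genes into age-specific, marker-specific and intersection sets
#'
#' Using the physiological-age model's q-values at threshold `alpha`:
#' a gene is age-flagged if any of `q_age1..q_age3` is below `alpha` and
#' marker-flagged if `q_marker` is below `alpha`. Classes are
#' `age_specific` (age only), `marker_specific` (marker only),
#' `intersection` (both) and `neither`. When cluster labels are supplied,
#' marker-specific genes in cluster 0 (no average time trend) are flagged
#' as the age-orthogonal signature.
#'
#' @param dge_phys DGE table fitted with the physiological-age design
#'   (pooled marker coding).
#' @param alpha FDR threshold.
#' @param cluster_labels Optional named vector of trajectory cluster labels
#'   (0 = no time trend).
#' @return data.frame: `gene_id`, `class`, `age_flag`, `marker_flag`,
#'   `orthogonal`; attribute `counts` holds the Venn counts.
#' @export
classify_genes <- function(dge_phys, alpha = 1e-4, cluster_labels = NULL) {
  qcols <- c("q_age1", "q_age2", "q_age3", "q_marker")
  missing_cols <- setdiff(qcols, colnames(dge_phys))
  if (length(missing_cols))
    stop_physage("dge_phys lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  qa <- as.matrix(dge_phys[, c("q_age1", "q_age2", "q_age3")])
  age_flag <- apply(qa < alpha, 1L, any)
  age_flag[is.na(age_flag)] <- FALSE
  marker_flag <- dge_phys$q_marker < alpha
  marker_flag[is.na(marker_flag)] <- FALSE
  cls <- ifelse(age_flag & marker_flag, "intersection",
         ifelse(age_flag, "age_specific",
         ifelse(marker_flag, "marker_specific", "neither")))
  orth <- rep(FALSE, nrow(dge_phys))
  if (!is.null(cluster_labels)) {
    lab <- cluster_labels[dge_phys$gene_id]
    orth <- cls == "marker_specific" & !is.na(lab) & lab == 0
  }
  out <- data.frame(gene_id = dge_phys$gene_id, class = cls,
                    age_flag = age_flag, marker_flag = marker_flag,
                    orthogonal = orth, stringsAsFactors = FALSE)
  attr(out, "counts") <- c(age_specific = sum(cls == "age_specific"),
                           marker_specific = sum(cls == "marker_specific"),
                           intersection = sum(cls == "intersection"),
                           neither = sum(cls == "neither"))
  attr(out, "alpha") <- alpha
  out
}

#' Rank genes for enrichment analysis
#'
#' Score = `sign(beta) * (-log10 q)` with q floored at the smallest
#' representable double; descending order with deterministic gene-id
#' tie-break.
#'
#' @param dge DGE table.
#' @param coefficient Coefficient name (e.g. `"age1"`, `"marker"`).
#' @return data.frame `gene_id`, `score`, sorted by decreasing score.
#' @export
rank_genes <- function(dge, coefficient) {
  bcol <- paste0("beta_", coefficient)
  qcol <- paste0("q_", coefficient)
  if (!all(c(bcol, qcol) %in% colnames(dge)))
    stop_physage("coefficient '%s' not present in DGE table", coefficient)
  q <- pmax(dge[[qcol]], .Machine$double.xmin)
  score <- sign(dge[[bcol]]) * (-log10(q))
  score[is.na(score)] <- 0
  ord <- order(-score, dge$gene_id)
  data.frame(gene_id = dge$gene_id[ord], score = score[ord],
             stringsAsFactors = FALSE)
}

# Weighted KS enrichment score from hit positions in a ranked list.
# Extrema of the running sum occur only at hit boundaries, so the score is
# computed in O(k) from the sorted hit indices.
gsea_es_from_hits <- function(abs_scores_w, hit_idx, n_total) {
  k <- length(hit_idx)
  if (!k) return(0)
  hit_idx <- sort(hit_idx)
  w <- abs_scores_w[hit_idx]
  tot <- sum(w)
  if (tot == 0) w <- rep(1, k) else w <- w
  tot <- sum(w)
  miss_step <- 1 / (n_total - k)
  cum_hit <- cumsum(w) / tot
  after <- cum_hit - (hit_idx - seq_len(k)) * miss_step
  before <- c(0, cum_hit[-k]) - (hit_idx - 1 - (seq_len(k) - 1)) * miss_step
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Gene set enrichment analysis on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score: hit increments
#' proportional to `|score|^weight`, uniform miss decrements. The null is
#' size-matched random gene sampling (`n_perm` draws from the seeded
#' stream); `NES = ES / mean(|null ES| of the same sign)` and
#' `p = (1 + #{same-sign null |ES| >= |ES|}) / (n_same_sign + 1)`.
#'
#' @param ranked data.frame from [rank_genes()] (`gene_id`, `score`,
#'   descending).
#' @param gene_set Character vector of member gene ids.
#' @param weight KS weight exponent (1 = classic weighted, 0 = unweighted).
#' @param n_perm Number of null permutations.
#' @param seed Seed for the permutation stream.
#' @return List: `es`, `nes`, `p`, `n_hits`, `n_perm`.
#' @export
gsea <- function(ranked, gene_set, weight = 1, n_perm = 1000, seed = 1) {
  n <- nrow(ranked)
  hit_idx <- which(ranked$gene_id %in% gene_set)
  if (!length(hit_idx)) {
    warn_physage("gene set has no overlap with the ranked universe; skipped")
    return(list(es = NA_real_, nes = NA_real_, p = NA_real_,
                n_hits = 0L, n_perm = n_perm))
  }
  if (length(hit_idx) >= n)
    stop_physage("gene set covers the whole universe")
  aw <- abs(ranked$score)^weight
  es <- gsea_es_from_hits(aw, hit_idx, n)
  k <- length(hit_idx)
  set.seed(seed)
  null_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es_from_hits(aw, sample.int(n, k), n)
  }, 0)
  same <- null_es[sign(null_es) == sign(es)]
  if (!length(same)) {
    p <- 1 / (n_perm + 1)
    nes <- es
  } else {
    p <- (1 + sum(abs(same) >= abs(es))) / (length(same) + 1)
    nes <- es / mean(abs(same))
  }
  list(es = es, nes = nes, p = p, n_hits = k, n_perm = n_perm)
}

#' GSEA over a gene-set collection
#'
#' Runs [gsea()] for every set, adjusts permutation p-values by BH across
#' sets, and reports the signed score `sign(ES) * (-log10 q)` with q
#' floored at `1/(n_perm + 1)`.
#'
#' @param ranked Ranked list from [rank_genes()].
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param weight,n_perm,seed Passed to [gsea()]; each set gets a distinct
#'   substream seed.
#' @return data.frame: `set`, `size`, `es`, `nes`, `p`, `q`,
#'   `signed_score`.
#' @export
gsea_collection <- function(ranked, collection, weight = 1, n_perm = 1000,
                            seed = 1) {
  res <- lapply(names(collection), function(nm) {
    r <- gsea(ranked, collection[[nm]], weight = weight, n_perm = n_perm,
              seed = substream_seed(seed, paste0("gsea_", nm)))
    data.frame(set = nm, size = r$n_hits, es = r$es, nes = r$nes, p = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  qf <- pmax(out$q, 1 / (n_perm + 1))
  out$signed_score <- sign(out$es) * (-log10(qf))
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability of observing at least the realized overlap
#' between a hit list and an annotation set drawn from a common universe.
#'
#' @param hits Character vector of hit gene ids.
#' @param annotation Character vector of annotated gene ids.
#' @param universe Character vector of all considered gene ids.
#' @return Upper-tail p-value.
#' @export
hypergeom_overrep <- function(hits, annotation, universe) {
  if (!length(universe)) stop_physage("empty universe")
  hits <- intersect(hits, universe)
  annotation <- intersect(annotation, universe)
  ov <- length(intersect(hits, annotation))
  phyper(ov - 1, length(annotation),
         length(universe) - length(annotation),
         length(hits), lower.tail = FALSE)
}
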