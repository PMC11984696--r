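#' Default pipeline configuration
#'
#' Returns the full configuration list: cohort parameters (see
#' [cohort_params()]), analysis thresholds (`alpha_cluster = 0.01` for the
#' cluster-0 rule, `alpha_classify = 1e-4` for the signature
#' classification), curve settings, and enrichment settings. A user
#' configuration (list or YAML file) is merged over these defaults; the
#' master `seed` is mandatory for stochastic stages.
#'
#' @param config Optional named list or YAML file path to merge.
#' @return Configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(
    seed = NULL,
    cohort = as.list(unclass(cohort_params())),
    filter = list(min_count = 5, min_fraction = 0.75),
    cluster = list(k = 5, alpha = 0.01, df = 5, window = 1),
    physage = list(n_components = 3, df = 4, mode = "proportional"),
    classify = list(alpha = 1e-4),
    enrich = list(gmt = NULL, coefficient = "marker", weight = 1,
                  n_perm = 1000))
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    defaults <- modifyList(defaults, config)
  }
  defaults$cohort$markers <- unlist(defaults$cohort$markers)
  defaults
}

pipeline_stages <- c("simulate", "filter", "normalize", "dge_chrono",
                     "cluster", "physage", "dge_phys", "decompose",
                     "enrich", "survival")

log_stage <- function(outdir, stage, info) {
  entry <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  package_version = as.character(utils::packageVersion("physage"))),
             info)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE),
      file = file.path(outdir, "pipeline_log.jsonl"), sep = "\n", append = TRUE)
}

require_artifact <- function(outdir, file, stage, producer) {
  path <- file.path(outdir, file)
  if (!file.exists(path))
    stop_physage("stage '%s' requires artifact '%s' (produced by stage '%s'); run that stage first",
                 stage, file, producer)
  path
}

#' Run the analysis pipeline
#'
#' Executes the pipeline stages in order, writing each stage's artifact
#' tables under `outdir` and a JSON-lines log of parameters and seeds.
#' Stages are re-runnable from intermediates: any stage whose upstream
#' artifacts already exist on disk can be run on its own. Stage order:
#' `simulate` (synthetic cohort), `filter` (detection filter), `normalize`
#' (size factors, dispersion trend, VST, batch correction), `dge_chrono`
#' (chronological-age NB GLM, pooled and per-marker codings), `cluster`
#' (trajectory clustering), `physage` (principal-curve physiological age),
#' `dge_phys` (physiological-age NB GLM), `decompose` (signature
#' correlation + gene classification), `enrich` (GSEA, if a GMT file is
#' configured), `survival` (KM/log-rank of sorted groups).
#'
#' @param config Configuration list or YAML path (see [pipeline_config()]).
#' @param outdir Artifact directory (created if absent).
#' @param stages Character vector of stages, or `"all"`.
#' @return Invisibly, the artifact directory path.
#' @export
run_pipeline <- function(config = NULL, outdir, stages = "all") {
  cfg <- pipeline_config(config)
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad)) stop_physage("unknown stage(s): %s", paste(bad, collapse = ", "))
  stochastic <- c("simulate", "enrich")
  if (any(stages %in% stochastic) && is.null(cfg$seed))
    stop_physage("config must set a seed before running stochastic stages (%s)",
                 paste(intersect(stages, stochastic), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- pipeline_stages[pipeline_stages %in% stages]
  for (stage in stages) {
    switch(stage,
      simulate = stage_simulate(cfg, outdir),
      filter = stage_filter(cfg, outdir),
      normalize = stage_normalize(cfg, outdir),
      dge_chrono = stage_dge_chrono(cfg, outdir),
      cluster = stage_cluster(cfg, outdir),
      physage = stage_physage(cfg, outdir),
      dge_phys = stage_dge_phys(cfg, outdir),
      decompose = stage_decompose(cfg, outdir),
      enrich = stage_enrich(cfg, outdir),
      survival = stage_survival(cfg, outdir))
  }
  invisible(outdir)
}

stage_simulate <- function(cfg, outdir) {
  cohort_args <- cfg$cohort
  cohort_args$seed <- cfg$seed
  params <- do.call(cohort_params, cohort_args)
  ds <- generate_dataset(params)
  write_counts(ds$counts, file.path(outdir, "counts.tsv"))
  write_sample_meta(ds$meta, file.path(outdir, "meta.tsv"))
  write_survival(ds$survival, file.path(outdir, "survival.csv"))
  truth <- ds$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  log_stage(outdir, "simulate",
            list(seed = cfg$seed, n_genes = params$n_genes,
                 n_individuals = params$n_individuals))
}

load_counts_meta <- function(outdir, stage, file = "counts.tsv") {
  counts <- read_counts(require_artifact(outdir, file, stage, "simulate"))
  meta <- read_sample_meta(require_artifact(outdir, "meta.tsv", stage,
                                            "simulate"), counts)
  list(counts = counts, meta = meta)
}

stage_filter <- function(cfg, outdir) {
  cm <- load_counts_meta(outdir, "filter")
  filtered <- detection_filter(cm$counts, cfg$filter$min_count,
                               cfg$filter$min_fraction)
  write_counts(filtered, file.path(outdir, "counts_filtered.tsv"))
  log_stage(outdir, "filter",
            list(min_count = cfg$filter$min_count,
                 min_fraction = cfg$filter$min_fraction,
                 genes_in = nrow(cm$counts), genes_out = nrow(filtered)))
}

stage_normalize <- function(cfg, outdir) {
  cm <- load_counts_meta(outdir, "normalize", "counts_filtered.tsv")
  s <- size_factors(cm$counts)
  design <- build_design(cm$meta, "chronological", "pooled")
  disp <- estimate_dispersions(cm$counts, s, design)
  X <- vst_transform(cm$counts, s, disp)
  Xbc <- remove_batch(X, cm$meta$batch,
                      protect = design$matrix[, setdiff(colnames(design$matrix),
                                                        c("intercept",
                                                          grep("^batch_", colnames(design$matrix), value = TRUE))),
                                              drop = FALSE])
  write.table(data.frame(sample_id = names(s), size_factor = s),
              file.path(outdir, "size_factors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(disp$alpha), alpha = disp$alpha),
              file.path(outdir, "dispersions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_matrix_tsv(Xbc, file.path(outdir, "vst_bc.tsv"))
  log_stage(outdir, "normalize",
            list(trend_a0 = disp$trend[["a0"]], trend_a1 = disp$trend[["a1"]]))
}

write_matrix_tsv <- function(X, path) {
  df <- data.frame(gene_id = rownames(X), X, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

fit_dge_stage <- function(cfg, outdir, stage, age_source, coding,
                          phys_ages = NULL) {
  cm <- load_counts_meta(outdir, stage, "counts_filtered.tsv")
  s <- size_factors(cm$counts)
  design <- build_design(cm$meta, age_source, coding, phys_ages)
  disp <- estimate_dispersions(cm$counts, s, design)
  dge_fit(cm$counts, design, s, disp)
}

stage_dge_chrono <- function(cfg, outdir) {
  pooled <- fit_dge_stage(cfg, outdir, "dge_chrono", "chronological", "pooled")
  write.table(pooled, file.path(outdir, "dge_chrono_pooled.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  per_marker <- fit_dge_stage(cfg, outdir, "dge_chrono", "chronological",
                              "per_marker")
  write.table(per_marker, file.path(outdir, "dge_chrono_markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "dge_chrono", list(n_genes = nrow(pooled)))
}

stage_cluster <- function(cfg, outdir) {
  X <- read_matrix_tsv(require_artifact(outdir, "vst_bc.tsv", "cluster",
                                        "normalize"))
  meta <- read_sample_meta(require_artifact(outdir, "meta.tsv", "cluster",
                                            "simulate"))
  dge <- utils::read.table(require_artifact(outdir, "dge_chrono_pooled.tsv",
                                            "cluster", "dge_chrono"),
                           header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  traj <- smooth_standardize(average_by_timepoint(X, meta),
                             df = cfg$cluster$df)
  cl <- cluster_trajectories(traj, dge, k = cfg$cluster$k,
                             alpha0 = cfg$cluster$alpha,
                             window = cfg$cluster$window)
  write.table(data.frame(gene_id = names(cl$labels), cluster = cl$labels),
              file.path(outdir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cent <- data.frame(cluster = rep(rownames(cl$centroids),
                                   each = length(cl$ages)),
                     day = rep(cl$ages, nrow(cl$centroids)),
                     z = as.vector(t(cl$centroids)))
  write.table(cent, file.path(outdir, "centroids.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "cluster",
            list(k = cfg$cluster$k, alpha = cfg$cluster$alpha,
                 n_cluster0 = sum(cl$labels == 0)))
}

stage_physage <- function(cfg, outdir) {
  X <- read_matrix_tsv(require_artifact(outdir, "vst_bc.tsv", "physage",
                                        "normalize"))
  meta <- read_sample_meta(require_artifact(outdir, "meta.tsv", "physage",
                                            "simulate"))
  pa <- estimate_physiological_age(X, meta,
                                   n_components = cfg$physage$n_components,
                                   df = cfg$physage$df,
                                   mode = cfg$physage$mode)
  write.table(pa$estimates, file.path(outdir, "phys_age.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  curve_df <- data.frame(arc = pa$curve$arc, pa$curve$vertices)
  colnames(curve_df)[-1L] <- paste0("PC", seq_len(ncol(pa$curve$vertices)))
  write.table(curve_df, file.path(outdir, "curve.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "physage",
            list(n_components = cfg$physage$n_components, df = cfg$physage$df,
                 mode = cfg$physage$mode, curve_mse = pa$curve$mse))
}

stage_dge_phys <- function(cfg, outdir) {
  pa <- utils::read.table(require_artifact(outdir, "phys_age.tsv", "dge_phys",
                                           "physage"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  phys_ages <- setNames(pa$phys_age_days, pa$sample_id)
  dge <- fit_dge_stage(cfg, outdir, "dge_phys", "physiological", "pooled",
                       phys_ages = phys_ages)
  write.table(dge, file.path(outdir, "dge_phys.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "dge_phys", list(n_genes = nrow(dge)))
}

stage_decompose <- function(cfg, outdir) {
  dge_phys <- utils::read.table(require_artifact(outdir, "dge_phys.tsv",
                                                 "decompose", "dge_phys"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  dge_markers <- utils::read.table(
    require_artifact(outdir, "dge_chrono_markers.tsv", "decompose",
                     "dge_chrono"),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  clusters <- utils::read.table(require_artifact(outdir, "clusters.tsv",
                                                 "decompose", "cluster"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  labels <- setNames(clusters$cluster, clusters$gene_id)
  classification <- classify_genes(dge_phys, alpha = cfg$classify$alpha,
                                   cluster_labels = labels)
  write.table(classification, file.path(outdir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(attr(classification, "counts")),
                       file.path(outdir, "venn_counts.json"),
                       auto_unbox = TRUE, digits = NA)
  sig <- compare_signatures(dge_markers)
  write.table(data.frame(signature = rownames(sig), sig, check.names = FALSE),
              file.path(outdir, "signature_cor.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "decompose",
            list(alpha = cfg$classify$alpha,
                 counts = as.list(attr(classification, "counts"))))
}

stage_enrich <- function(cfg, outdir) {
  if (is.null(cfg$enrich$gmt)) {
    log_stage(outdir, "enrich", list(skipped = "no GMT file configured"))
    return(invisible(NULL))
  }
  dge_phys <- utils::read.table(require_artifact(outdir, "dge_phys.tsv",
                                                 "enrich", "dge_phys"),
                                header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  collection <- read_gmt(cfg$enrich$gmt)
  ranked <- rank_genes(dge_phys, cfg$enrich$coefficient)
  res <- gsea_collection(ranked, collection, weight = cfg$enrich$weight,
                         n_perm = cfg$enrich$n_perm,
                         seed = substream_seed(cfg$seed, "enrich"))
  write.table(res, file.path(outdir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "enrich",
            list(coefficient = cfg$enrich$coefficient,
                 n_perm = cfg$enrich$n_perm, n_sets = nrow(res)))
}

stage_survival <- function(cfg, outdir) {
  tab <- read_survival(require_artifact(outdir, "survival.csv", "survival",
                                        "simulate"))
  markers <- unlist(cfg$cohort$markers)
  summ <- survival_summary(tab, markers)
  jsonlite::write_json(summ, file.path(outdir, "survival_stats.json"),
                       digits = NA)
  curves <- do.call(rbind, lapply(unique(tab$group), function(g) {
    cv <- km_curve(tab, g)
    cv$group <- g
    cv
  }))
  write.table(curves, file.path(outdir, "km_curves.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(outdir, "survival", list(groups = length(unique(tab$group))))
}
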