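#' Read a gene-by-sample count matrix
#'
#' Reads a rectangular TSV or CSV table (delimiter sniffed from the header
#' line) whose first column holds gene identifiers and whose remaining
#' columns hold non-negative integer RNA-seq counts, one column per sample.
#'
#' @param path Path to the counts file.
#' @return Integer-valued numeric matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop_physage("counts file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  if (ncol(df) < 2L) stop_physage("counts table needs a gene-id column plus >=1 sample column")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    stop_physage("duplicate gene id in counts: %s",
                 gene_ids[duplicated(gene_ids)][1L])
  }
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop_physage("duplicate sample id in counts: %s",
                 sample_ids[duplicated(sample_ids)][1L])
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_physage("counts table contains non-numeric entries")
  bad <- which(!is_wholenumber(m) | m < 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop_physage("counts must be non-negative integers; offending entry %s at gene '%s', sample '%s'",
                 format(m[bad[1L]]), gene_ids[i[1L]], sample_ids[i[2L]])
  }
  m <- round(m)
  dimnames(m) <- list(gene_ids, sample_ids)
  m
}

#' Write a count matrix as TSV
#'
#' @param counts Gene-by-sample matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  validate_counts(counts)
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop_physage("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_physage("counts must carry gene ids (rownames) and sample ids (colnames)")
  if (any(counts < 0) || any(!is_wholenumber(counts)))
    stop_physage("counts must be non-negative integers")
  invisible(counts)
}

#' Read sample metadata
#'
#' Metadata columns: `sample_id`, `age_days` (chronological age),
#' `group` (`timecourse`, `marker-high`, `marker-low`), `marker`
#' (marker name or `none`), `marker_code` (-1/0/+1; +1 = predicted
#' long-lived), `batch`. When `counts` is supplied, cross-validates
#' that every count column has a metadata row and vice versa.
#'
#' @param path Metadata TSV/CSV path.
#' @param counts Optional count matrix to validate against.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path, counts = NULL) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_meta(meta, counts)
}

validate_sample_meta <- function(meta, counts = NULL) {
  need <- c("sample_id", "age_days", "group", "marker", "marker_code", "batch")
  missing_cols <- setdiff(need, colnames(meta))
  if (length(missing_cols))
    stop_physage("metadata lacks column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop_physage("duplicate sample_id in metadata")
  if (!all(meta$marker_code %in% c(-1, 0, 1)))
    stop_physage("marker_code must be -1, 0 or +1")
  if (!all((meta$marker_code == 0) == (meta$group == "timecourse")))
    stop_physage("marker_code must be 0 exactly for timecourse samples")
  if (!is.null(counts)) {
    missing_in_meta <- setdiff(colnames(counts), meta$sample_id)
    missing_in_counts <- setdiff(meta$sample_id, colnames(counts))
    if (length(missing_in_meta))
      stop_physage("sample(s) in counts but not metadata: %s",
                   paste(missing_in_meta, collapse = ", "))
    if (length(missing_in_counts))
      stop_physage("sample(s) in metadata but not counts: %s",
                   paste(missing_in_counts, collapse = ", "))
  }
  meta
}

#' @rdname read_sample_meta
#' @param meta Metadata data.frame.
#' @export
write_sample_meta <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then one field per member
#' gene. Blank lines are skipped, CRLF endings tolerated, and duplicate
#' members within a set are dropped with a message.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_physage("GMT file is empty: %s", path)
  sets <- list()
  descs <- character()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop_physage("GMT set '%s' has no members", fields[1L])
    name <- fields[1L]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members)) stop_physage("GMT set '%s' has no members", name)
    if (anyDuplicated(members)) {
      message(sprintf("GMT set '%s': dropping %d duplicate member(s)",
                      name, sum(duplicated(members))))
      members <- unique(members)
    }
    if (name %in% names(sets)) stop_physage("duplicate GMT set name '%s'", name)
    sets[[name]] <- members
    descs[name] <- fields[2L]
  }
  attr(sets, "description") <- descs
  sets
}

#' Read/write a per-individual survival table
#'
#' CSV columns: `individual_id`, `group`, `day` (positive time in days)
#' and `event` (`death` or `censor`).
#'
#' @param path CSV path.
#' @return data.frame survival table.
#' @export
read_survival <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_survival(tab)
}

validate_survival <- function(tab) {
  need <- c("individual_id", "group", "day", "event")
  if (!all(need %in% colnames(tab)))
    stop_physage("survival table needs columns: %s", paste(need, collapse = ", "))
  if (any(tab$day <= 0)) stop_physage("survival times must be positive")
  if (!all(tab$event %in% c("death", "censor")))
    stop_physage("survival event must be 'death' or 'censor'")
  if (!nrow(tab)) stop_physage("survival table is empty")
  tab
}

#' @rdname read_survival
#' @param tab Survival data.frame.
#' @export
write_survival <- function(tab, path) {
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
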