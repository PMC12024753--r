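# Readers and writers for the pipeline's plain-text interchange formats:
# gene x sample expression TSV, mutation and clinical tables, GMT gene sets.
# All readers reject duplicate identifiers and report the offending entries.

#' Read a gene-by-sample expression TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers.
#'
#' @param path file path.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    line <- which(duplicated(genes))[1L] + 1L  # +1 for header
    stop_input("duplicate gene identifier '", genes[duplicated(genes)][1L],
               "' at line ", line, " of ", path)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  check_ids(colnames(m), "sample")
  if (!is.numeric(m)) stop_input("non-numeric expression values in ", path)
  rownames(m) <- genes
  m
}

#' Write a gene-by-sample expression TSV
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path file path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_sample_table <- function(path, required) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_input(path, " lacks required column(s): ",
               paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) {
    line <- which(duplicated(df$sample_id))[1L] + 1L
    stop_input("duplicate sample identifier '",
               df$sample_id[duplicated(df$sample_id)][1L],
               "' at line ", line, " of ", path)
  }
  df
}

#' Read a per-sample mutation table
#'
#' Tab-separated with columns `sample_id`, `egfr_status`, `kras_status`,
#' `mutation_count` (statuses coded `mutated`/`WT`, as in cBioPortal-style
#' exports).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_mutation_tsv <- function(path) {
  df <- read_sample_table(path, c("sample_id", "egfr_status", "kras_status",
                                  "mutation_count"))
  if (any(df$mutation_count < 0, na.rm = TRUE))
    stop_input("negative mutation counts in ", path)
  df
}

#' Read a per-sample clinical table
#'
#' Tab-separated with columns `sample_id`, `os_months`, `os_event` plus any
#' optional covariates.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_clinical_tsv <- function(path) {
  read_sample_table(path, c("sample_id", "os_months", "os_event"))
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop_input("GMT line ", short[1L], " has fewer than 3 fields in ", path)
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm))
    stop_input("duplicate gene-set name '", nm[duplicated(nm)][1L],
               "' at line ", which(duplicated(nm))[1L], " of ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description description field (second GMT column), recycled.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
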