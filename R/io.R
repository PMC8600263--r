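## Readers/writers for the plain-text formats the pipeline touches:
## expression TSV (genes x samples), clinical TSV, and GMT gene sets.
## Loaders validate into the in-memory types used everywhere downstream:
##   expression  -> numeric matrix, genes in rows, samples in columns
##   survival    -> data.frame(sample_id, time, event, ...covariates)
##   gene sets   -> named list of character vectors, "description" attribute

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids
#' (the TCGA level-3 layout); set `transposed = TRUE` for samples-in-rows
#' exports. Duplicate gene rows are collapsed (mean by default), rows with
#' missing values are dropped or median-imputed, and any non-numeric cell is
#' reported by gene and sample.
#'
#' @param path TSV file path.
#' @param transposed logical; input has samples in rows.
#' @param duplicate_genes collapse rule for repeated gene ids, "mean" or "max".
#' @param missing "drop" rows containing NA (default) or "impute_median".
#' @return numeric matrix (genes x samples) with a `load_report` attribute
#'   (list: duplicates_collapsed, rows_dropped_missing, values_imputed).
#' @export
read_expression <- function(path, transposed = FALSE,
                            duplicate_genes = c("mean", "max"),
                            missing = c("drop", "impute_median")) {
  duplicate_genes <- match.arg(duplicate_genes)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("expression file not found: ", path)
  raw <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    stop("malformed expression file (need >= 1 gene row and >= 1 sample column): ",
         path)
  }
  gene_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  # blank cells are missing; anything else non-numeric is a format error
  blank <- !is.na(vals) & trimws(vals) == ""
  vals[blank] <- NA_character_
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric expression value '%s' at gene '%s', sample '%s'",
                 vals[bad[1, 1], bad[1, 2]], gene_ids[bad[1, 1]],
                 sample_ids[bad[1, 2]]))
  }
  mat <- num
  rownames(mat) <- gene_ids
  colnames(mat) <- sample_ids
  if (transposed) mat <- t(mat)

  report <- list(duplicates_collapsed = 0L, rows_dropped_missing = 0L,
                 values_imputed = 0L)
  if (anyDuplicated(rownames(mat))) {
    dup_ids <- unique(rownames(mat)[duplicated(rownames(mat))])
    report$duplicates_collapsed <- length(dup_ids)
    fun <- if (duplicate_genes == "mean") colMeans else
      function(m) apply(m, 2, max)
    keep_order <- unique(rownames(mat))
    mat <- do.call(rbind, lapply(keep_order, function(g) {
      rows <- mat[rownames(mat) == g, , drop = FALSE]
      if (nrow(rows) == 1) rows[1, ] else fun(rows)
    }))
    rownames(mat) <- keep_order
    warning(sprintf("collapsed %d duplicated gene id(s) by %s: %s",
                    length(dup_ids), duplicate_genes,
                    paste(head(dup_ids, 5), collapse = ", ")), call. = FALSE)
  }
  if (anyNA(mat)) {
    if (missing == "drop") {
      drop_rows <- apply(mat, 1, anyNA)
      report$rows_dropped_missing <- sum(drop_rows)
      mat <- mat[!drop_rows, , drop = FALSE]
      warning(sprintf("dropped %d gene row(s) with missing values",
                      report$rows_dropped_missing), call. = FALSE)
    } else {
      report$values_imputed <- sum(is.na(mat))
      mat <- t(apply(mat, 1, function(x) {
        x[is.na(x)] <- median(x, na.rm = TRUE)
        x
      }))
    }
  }
  validate_expression(mat)
  attr(mat, "load_report") <- report
  mat
}

#' Validate an in-memory expression matrix
#'
#' @param mat numeric matrix, genes x samples, unique dimnames, no NA.
#' @return the matrix, invisibly.
#' @export
validate_expression <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) stop("expression must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(mat))) stop("duplicated gene ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids")
  if (anyNA(mat)) stop("expression matrix contains missing values")
  if (nrow(mat) < 1) stop("expression matrix needs at least 1 gene")
  if (ncol(mat) < 2) stop("expression matrix needs at least 2 samples")
  invisible(mat)
}

#' Write an expression matrix as TSV (genes x samples)
#'
#' Values are written with 15 significant digits, so any value representable
#' at that decimal precision round-trips exactly through [read_expression()].
#'
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  validate_expression(mat)
  df <- data.frame(gene_id = rownames(mat),
                   format(mat, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical/survival table from TSV
#'
#' Requires columns `sample_id`, `time` (days, > 0) and `event` (1 = death
#' observed, 0 = censored); extra columns are kept as covariates. Rows with
#' missing time or event are dropped and counted in the `load_report`
#' attribute, mirroring the usual removal of samples without follow-up.
#'
#' @param path TSV file path.
#' @return data.frame with a `load_report` attribute (list: drops).
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0) {
    stop("survival table missing column(s): ", paste(miss, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  incomplete <- is.na(df$time) | is.na(df$event)
  drops <- sum(incomplete)
  if (drops > 0) {
    warning(sprintf("dropped %d sample(s) without complete survival data", drops),
            call. = FALSE)
    df <- df[!incomplete, , drop = FALSE]
  }
  rownames(df) <- NULL
  validate_survival(df)
  attr(df, "load_report") <- list(drops = drops)
  df
}

#' Validate a survival table
#' @param df data.frame with sample_id, time, event.
#' @return the data.frame, invisibly.
#' @export
validate_survival <- function(df) {
  if (anyDuplicated(df$sample_id)) stop("duplicated sample ids in survival table")
  if (!is.numeric(df$time) || any(df$time <= 0)) {
    stop("survival time must be positive for every sample")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  invisible(df)
}

#' Write a survival table as TSV
#' @param df survival data.frame.
#' @param path output path.
#' @export
write_survival <- function(df, path) {
  validate_survival(df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB gene...`.
#' Genes are deduplicated within each set; a line with fewer than three
#' fields is a parse error reported with its line number.
#'
#' @param path GMT file path.
#' @return named list of character vectors (one per set) with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    warning("empty GMT file: ", path, call. = FALSE)
    out <- list()
    attr(out, "description") <- character(0)
    return(out)
  }
  sets <- vector("list", length(keep))
  ids <- character(length(keep))
  desc <- character(length(keep))
  for (i in seq_along(keep)) {
    ln <- keep[i]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT parse error at line %d: expected >= 3 tab-separated fields",
                   ln))
    }
    ids[i] <- fields[1]
    desc[i] <- fields[2]
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      stop(sprintf("GMT parse error at line %d: gene set '%s' is empty",
                   ln, fields[1]))
    }
    sets[[i]] <- genes
  }
  if (anyDuplicated(ids)) {
    stop("duplicated pathway ids in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(sets) <- ids
  attr(sets, "description") <- setNames(desc, ids)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of character vectors; optional `description`
#'   attribute (named), defaulting to "na".
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  lines <- vapply(names(sets), function(id) {
    d <- if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "na"
    paste(c(id, d, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Align an expression matrix and survival table on shared samples
#'
#' Restricts both to the intersection of their sample ids, in the expression
#' matrix's column order. Idempotent; errors if no sample is shared.
#'
#' @param expr expression matrix (genes x samples).
#' @param surv survival data.frame.
#' @return list(expr, surv) over the common samples, same order.
#' @export
align_cohort <- function(expr, surv) {
  common <- intersect(colnames(expr), surv$sample_id)
  if (length(common) == 0) {
    stop("no samples shared between expression matrix and survival table")
  }
  expr2 <- expr[, common, drop = FALSE]
  surv2 <- surv[match(common, surv$sample_id), , drop = FALSE]
  rownames(surv2) <- NULL
  list(expr = expr2, surv = surv2)
}
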