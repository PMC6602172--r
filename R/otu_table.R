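#' Community abundance table
#'
#' A light container for a samples-by-taxa abundance matrix together with the
#' sample, taxon and replicate-group identifiers that the rest of the package
#' needs. Counts are non-negative integers straight off a rarefied OTU table;
#' after [standardize()] the same container carries z-scored reals and is
#' flagged with `standardized = TRUE` so that count-only operations (rarefying,
#' indicator analysis, abundance summaries) can refuse it.
#'
#' @param counts numeric matrix, samples in rows, taxa in columns.
#' @param sample_ids character vector of unique sample identifiers
#'   (default: rownames of `counts`).
#' @param taxon_ids character vector of taxon identifiers (default: colnames).
#' @param group_ids character vector assigning each sample to a replicate
#'   group (microcosms inoculated from the same source). If `NULL`, derived
#'   from `sample_ids` via [derive_groups()].
#' @param standardized logical flag; `TRUE` once the values are z-scores.
#'
#' @return An object of class `otu_table`: a list with elements `counts`
#'   (matrix with dimnames), `group_ids` and `standardized`.
#' @export
otu_table <- function(counts, sample_ids = rownames(counts),
                      taxon_ids = colnames(counts), group_ids = NULL,
                      standardized = FALSE) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("T", seq_len(ncol(counts)))
  sample_ids <- as.character(sample_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(sample_ids) != nrow(counts))
    stop("sample_ids length (", length(sample_ids),
         ") does not match number of rows (", nrow(counts), ")")
  if (length(taxon_ids) != ncol(counts))
    stop("taxon_ids length (", length(taxon_ids),
         ") does not match number of columns (", ncol(counts), ")")
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ids: ", paste(unique(dup), collapse = ", "))
  if (!is.numeric(counts))
    stop("counts must be numeric")
  if (!standardized && any(counts < 0, na.rm = TRUE))
    stop("negative counts in a non-standardized table")
  if (anyNA(counts))
    stop("counts contain missing values")
  if (is.null(group_ids)) {
    group_ids <- derive_groups(sample_ids)
  } else {
    group_ids <- as.character(group_ids)
    if (length(group_ids) != length(sample_ids))
      stop("group_ids length does not match number of samples")
  }
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(list(counts = counts, group_ids = group_ids,
                 standardized = standardized),
            class = "otu_table")
}

#' Derive replicate-group ids from sample ids
#'
#' Replicate microcosms are conventionally encoded as a shared prefix plus a
#' replicate token, e.g. `soil17_a`, `soil17_b`, `soil17_c`. The group id is
#' everything before the last delimiter-separated token; ids without the
#' delimiter form singleton groups.
#'
#' @param sample_ids character vector.
#' @param delim single-character delimiter (default `"_"`).
#' @return character vector of group ids, one per sample.
#' @export
derive_groups <- function(sample_ids, delim = "_") {
  pat <- paste0(gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", delim), "[^",
                gsub("([][^\\\\-])", "\\\\\\1", delim), "]*$")
  out <- sub(pat, "", sample_ids)
  out[out == ""] <- sample_ids[out == ""]
  out
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d taxa (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$standardized) "standardized" else "counts"))
  cat(sprintf("  groups: %d unique\n", length(unique(x$group_ids))))
  if (!x$standardized) {
    rs <- rowSums(x$counts)
    cat(sprintf("  sample depth: min %s, max %s\n",
                format(min(rs)), format(max(rs))))
    cat(sprintf("  zero cells: %.1f%%\n", 100 * mean(x$counts == 0)))
  }
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Read a community table (and optional target) from CSV/TSV
#'
#' Expected layout: one header row, first column `sample_id`, remaining
#' columns taxon counts, with optional `group_id` and target columns mixed in.
#' This is the "samples as rows and features as columns" dialect common for
#' deposited OTU tables.
#'
#' @param path file path.
#' @param target_col name of the target column inside the file, or `NULL` if
#'   the file has no target.
#' @param target_path optional separate CSV with columns `sample_id` and the
#'   target; overrides `target_col`.
#' @param group_col name of the replicate-group column, or `NULL` to derive
#'   groups from sample ids.
#' @param sep field separator; `","` (default) or `"\t"`.
#' @param id_col name of the sample-id column (default `"sample_id"`).
#' @return list with elements `table` (an [otu_table()]) and `target`
#'   (numeric vector, or `NULL` when no target was requested).
#' @export
read_otu_csv <- function(path, target_col = "target", target_path = NULL,
                         group_col = "group_id", sep = ",",
                         id_col = "sample_id") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path)
  if (!id_col %in% names(df))
    stop("missing sample-id column '", id_col, "' in ", path)
  sample_ids <- as.character(df[[id_col]])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(dup), collapse = ", "))

  group_ids <- NULL
  if (!is.null(group_col) && group_col %in% names(df)) {
    group_ids <- as.character(df[[group_col]])
  }

  target <- NULL
  if (!is.null(target_path)) {
    tdf <- utils::read.table(target_path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (!id_col %in% names(tdf) || ncol(tdf) < 2)
      stop("target file must have columns '", id_col, "' and a value column")
    vcol <- setdiff(names(tdf), id_col)[1]
    idx <- match(sample_ids, as.character(tdf[[id_col]]))
    if (anyNA(idx))
      stop("target file missing samples: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    target <- as.numeric(tdf[[vcol]][idx])
  } else if (!is.null(target_col)) {
    if (!target_col %in% names(df))
      stop("missing target column '", target_col, "' in ", path)
    target <- suppressWarnings(as.numeric(df[[target_col]]))
    if (anyNA(target))
      stop("non-numeric values in target column '", target_col, "'")
  }

  drop <- c(id_col, target_col, if (!is.null(group_ids)) group_col)
  keep <- setdiff(names(df), drop)
  mat <- df[keep]
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (anyNA(v))
      stop("non-numeric cell in column '", keep[j], "'")
    mat[[j]] <- v
  }
  mat <- as.matrix(mat)
  rownames(mat) <- sample_ids
  tab <- otu_table(mat, sample_ids = sample_ids, taxon_ids = keep,
                   group_ids = group_ids)
  if (!is.null(target) && any(!is.finite(target)))
    stop("non-finite target values")
  list(table = tab, target = target)
}

#' Write a community table (and optional target) to CSV/TSV
#'
#' Inverse of [read_otu_csv()]: emits `sample_id`, `group_id`, optional
#' `target`, then one column per taxon. Round-trips exactly for integer
#' counts.
#'
#' @param table an [otu_table()].
#' @param path output file path.
#' @param target optional numeric target vector aligned with the samples.
#' @param sep field separator.
#' @export
write_otu_csv <- function(table, path, target = NULL, sep = ",") {
  stopifnot(inherits(table, "otu_table"))
  df <- data.frame(sample_id = rownames(table$counts),
                   group_id = table$group_ids,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(target)) {
    if (length(target) != nrow(table$counts))
      stop("target length does not match number of samples")
    df$target <- target
  }
  df <- cbind(df, as.data.frame(table$counts, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Subset an otu_table by sample index
#' @param table an [otu_table()].
#' @param i integer or logical index over samples.
#' @return an [otu_table()] with the selected rows.
#' @export
subset_samples <- function(table, i) {
  otu_table(table$counts[i, , drop = FALSE],
            group_ids = table$group_ids[i],
            standardized = table$standardized)
}
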