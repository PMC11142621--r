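#' Read an expression matrix and split it into groups
#'
#' Reads a rectangular numeric table (rows = samples, columns = variables,
#' header row of variable names) and a two-column label table mapping each
#' sample to a group, and returns the per-group observation matrices.
#' Missing or non-numeric values are rejected rather than imputed.
#'
#' @param path CSV/TSV file of observations (samples x variables).  The
#'   delimiter is inferred from the extension (`.tsv` means tab).
#' @param labels_path CSV/TSV file whose first column is the sample
#'   identifier (matching row names of `path`, or row order when `path` has
#'   no identifier column) and whose `label_column` gives the group.
#' @param label_column Name or index of the group column in the label file;
#'   default 2.
#' @param transpose Logical; set `TRUE` when the input is variables x
#'   samples (e.g. genes in rows) so it is transposed after reading.
#' @return A `group_dataset` with groups in label-sorted order and a
#'   `group_labels` attribute.
#' @export
read_expression_matrix <- function(path, labels_path, label_column = 2L,
                                   transpose = FALSE) {
  sep_of <- function(f) if (grepl("\\.tsv$", f, ignore.case = TRUE)) "\t"
                        else ","
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (!file.exists(labels_path))
    stop("labels file not found: ", labels_path, call. = FALSE)
  tab <- read.csv(path, sep = sep_of(path), check.names = FALSE)
  # a leading non-numeric column holds the sample identifiers
  if (ncol(tab) > 1L && !is.numeric(tab[[1]])) {
    rownames(tab) <- tab[[1]]
    tab <- tab[-1]
  }
  X <- as.matrix(tab)
  if (!is.numeric(X)) {
    bad <- which(!vapply(tab, is.numeric, logical(1)))[1]
    stop("non-numeric column in expression matrix: ",
         colnames(tab)[bad], call. = FALSE)
  }
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at row %d, column %d", idx[1], idx[2]),
         call. = FALSE)
  }
  if (transpose) X <- t(X)
  labels <- read.csv(labels_path, sep = sep_of(labels_path),
                     check.names = FALSE)
  sample_ids <- as.character(labels[[1]])
  grp <- as.character(labels[[label_column]])
  if (!is.null(rownames(X)) && all(nzchar(rownames(X)))) {
    missing <- setdiff(sample_ids, rownames(X))
    if (length(missing))
      stop("labelled sample(s) absent from the matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- X[sample_ids, , drop = FALSE]
  } else if (length(sample_ids) != nrow(X)) {
    stop(sprintf("labels (%d) do not match matrix rows (%d)",
                 length(sample_ids), nrow(X)), call. = FALSE)
  }
  groups <- sort(unique(grp))
  obs <- lapply(groups, function(g) X[grp == g, , drop = FALSE])
  sizes <- vapply(obs, nrow, integer(1))
  if (any(sizes < 2))
    stop("every group needs at least 2 samples; group '",
         groups[which(sizes < 2)[1]], "' has ", min(sizes), call. = FALSE)
  structure(list(observations = obs, group_sizes = sizes,
                 dimension = ncol(X), group_labels = groups),
            class = "group_dataset")
}

#' Write test-result matrices and run metadata to a directory
#'
#' Writes `pvalues.csv`, `zscores.csv`, `statistic.csv`, `ci_lower.csv`,
#' `ci_upper.csv` (variable names as row/column headers) and a
#' `metadata.json` recording the contrast, level, variant, penalties,
#' group sizes and optional seed, sufficient to reproduce the run.
#'
#' @param result An `fgl_test_result`.
#' @param dir Output directory (created if absent).
#' @param variables Optional variable names for the headers.
#' @param penalty Optional `fgl_penalty` actually used (recorded in the
#'   metadata as the selected lambda/rho).
#' @param seed Optional seed to record.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(result, dir, variables = NULL, penalty = NULL,
                          seed = NULL) {
  stopifnot(inherits(result, "fgl_test_result"))
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory: ", dir, call. = FALSE)
  p <- nrow(result$statistic)
  if (is.null(variables)) variables <- paste0("V", seq_len(p))
  put <- function(M, name) {
    dimnames(M) <- list(variables, variables)
    f <- file.path(dir, name)
    write.csv(M, f, row.names = TRUE)
    f
  }
  files <- c(put(result$pvalues, "pvalues.csv"),
             put(result$zscores, "zscores.csv"),
             put(result$statistic, "statistic.csv"),
             put(result$ci_lower, "ci_lower.csv"),
             put(result$ci_upper, "ci_upper.csv"))
  meta <- list(contrast = result$contrast$coefficients,
               alpha = result$contrast$alpha, variant = result$variant,
               group_sizes = result$group_sizes,
               package_version = as.character(
                 utils::packageVersion("fglinfer")))
  if (!is.null(penalty))
    meta$penalty <- list(lasso = penalty$lasso, fusion = penalty$fusion)
  if (!is.null(seed)) meta$seed <- seed
  mf <- file.path(dir, "metadata.json")
  jsonlite::write_json(meta, mf, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mf))
}
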