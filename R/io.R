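#' Read numeric columns from a delimited table
#'
#' Reads a CSV or TSV file with a header row, selects columns, and drops
#' rows with missing values in the selection (complete-case analysis; the
#' number of dropped rows is reported via `message()`).
#'
#' @param path Path to the file.
#' @param delimiter Field delimiter; `NULL` (default) infers `"\t"` for
#'   `.tsv`/`.tab` files and `","` otherwise.
#' @param columns Character vector of column names (or `NULL` for all
#'   numeric columns).
#' @return Data frame of numeric columns with at least 8 complete rows.
#' @export
read_numeric_table <- function(path, delimiter = NULL, columns = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(columns)) {
    columns <- names(df)[vapply(df, is.numeric, logical(1))]
  } else {
    missing_cols <- setdiff(columns, names(df))
    if (length(missing_cols))
      stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
           call. = FALSE)
  }
  sel <- df[columns]
  bad <- vapply(sel, function(x) !is.numeric(x), logical(1))
  if (any(bad))
    stop("non-numeric column(s): ", paste(columns[bad], collapse = ", "),
         call. = FALSE)
  keep <- stats::complete.cases(sel)
  if (sum(!keep) > 0)
    message(sum(!keep), " row(s) with missing values dropped")
  sel <- sel[keep, , drop = FALSE]
  if (nrow(sel) < 8)
    stop("fewer than 8 complete rows", call. = FALSE)
  sel
}

#' Score every variable triple of a table
#'
#' With `target` given, every unordered pair of the remaining columns is
#' scored together with the target as the third (z) variable -- the typical
#' screen for pairs of factors jointly associated with an outcome.  Without
#' a target, all unordered triples are scored.  Axis roles follow input
#' column order (x, y, z) unless `symmetrize = TRUE`.
#'
#' Scores are rank-based, so the report is invariant to row order and to
#' monotone rescaling of individual columns.
#'
#' @param table Data frame of numeric columns (at least 3).
#' @param target Optional column name fixed as the third variable.
#' @param method,alpha,c,symmetrize Passed to [tic_score()].
#' @return Data frame with columns `var_a`, `var_b`, `var_c`, `method`,
#'   `score`, `best_x`, `best_y`, `best_z`, `n_used`, and the provenance
#'   columns `B`, `alpha`, `c`, sorted by descending score (lexicographic
#'   tiebreak).
#' @export
tic_scan <- function(table, target = NULL, method = "qotic", alpha = 0.75,
                     c = 10, symmetrize = FALSE) {
  num <- vapply(table, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric column(s): ", paste(names(table)[!num], collapse = ", "),
         call. = FALSE)
  vars <- names(table)
  if (length(vars) < 3) stop("need at least 3 numeric columns", call. = FALSE)
  if (!is.null(target)) {
    if (!target %in% vars) stop("target not found: ", target, call. = FALSE)
    others <- setdiff(vars, target)
    pairs <- utils::combn(sort(others), 2)
    triples <- rbind(pairs, rep(target, ncol(pairs)))
  } else {
    triples <- utils::combn(sort(vars), 3)
  }
  rows <- lapply(seq_len(ncol(triples)), function(i) {
    v <- triples[, i]
    cols <- table[v]
    keep <- stats::complete.cases(cols)
    s <- tic_score(tri_sample(cols[keep, 1], cols[keep, 2], cols[keep, 3]),
                   method = method, alpha = alpha, c = c,
                   symmetrize = symmetrize)
    data.frame(var_a = v[1], var_b = v[2], var_c = v[3], method = method,
               score = s$score, best_x = s$best_dims[1],
               best_y = s$best_dims[2], best_z = s$best_dims[3],
               n_used = sum(keep), B = s$B, alpha = alpha, c = as.integer(c),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$var_a, res$var_b, res$var_c), , drop = FALSE]
  rownames(res) <- NULL
  res
}
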