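#' Equitability sweep over noise levels
#'
#' For every combination of relationship and target R-squared, generates
#' `reps` seeded noisy samples and scores each with every requested method
#' (all methods score the same samples, so per-sample comparisons are
#' paired).  Deterministic given `seed`.
#'
#' @param methods Character vector of scoring methods (see [tic_score()]).
#' @param relationships Integer ids of the relationships to use.
#' @param r2_grid Numeric vector of target R-squared values in `(0, 1]`.
#' @param n Sample size per replicate.
#' @param reps Replicates per cell, at least 1.
#' @param seed Master seed; per-cell seeds are derived from it.
#' @param family Relationship family passed to [generate_relationship()].
#' @param alpha,c Coefficient parameters.
#' @return Tidy data frame with columns `method`, `relationship`, `r2`,
#'   `n`, `rep`, `score`.
#' @export
equitability_sweep <- function(methods = c("qotic", "single_opt", "teic"),
                               relationships = 1:12,
                               r2_grid = seq(0.1, 0.9, by = 0.1),
                               n = 500, reps = 10, seed = 1L,
                               family = "table1", alpha = 0.75, c = 10) {
  stopifnot(reps >= 1, all(r2_grid > 0 & r2_grid <= 1))
  methods <- match.arg(methods, tic_methods, several.ok = TRUE)
  out <- vector("list", length(relationships) * length(r2_grid) * reps)
  i <- 0L
  for (rel in relationships) for (r2 in r2_grid) for (rep in seq_len(reps)) {
    i <- i + 1L
    cell_seed <- (as.integer(seed) * 7919L + rel * 1009L +
                    round(r2 * 100) * 101L + rep) %% 2147483647L
    d <- generate_relationship(rel, family, n = n, r2 = r2, seed = cell_seed)
    sc <- vapply(methods, function(m)
      tic_score(d, method = m, alpha = alpha, c = c)$score, numeric(1))
    out[[i]] <- data.frame(method = methods, relationship = rel, r2 = r2,
                           n = n, rep = rep, score = unname(sc),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate a sweep into equitability curves
#'
#' @param sweep Output of [equitability_sweep()].
#' @return Data frame with one row per `(method, relationship, r2, n)` cell:
#'   `mean_score`, `sd_score`, `reps`.
#' @export
equitability_curves <- function(sweep) {
  key <- interaction(sweep$method, sweep$relationship, sweep$r2, sweep$n,
                     drop = TRUE)
  rows <- lapply(split(sweep, key), function(d)
    data.frame(method = d$method[1], relationship = d$relationship[1],
               r2 = d$r2[1], n = d$n[1],
               mean_score = mean(d$score),
               sd_score = if (nrow(d) > 1) stats::sd(d$score) else 0,
               reps = nrow(d), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  res <- res[order(res$method, res$relationship, res$r2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Bias and variance summary of an equitability sweep
#'
#' For an equitable statistic the score should track the noise level, so
#' per cell the bias is defined against the R-squared target:
#' `bias = |mean score - r2|`; the variance is the score variance across
#' replicates.  The summary reports min / mean / max of both over all
#' `(relationship, r2)` cells, per method.
#'
#' @param sweep Output of [equitability_sweep()] (or a compatible data
#'   frame); all methods must cover the same `(relationship, r2)` grid.
#' @return Data frame with one row per method: `bias_min`, `bias_mean`,
#'   `bias_max`, `var_min`, `var_mean`, `var_max`.
#' @export
bias_variance <- function(sweep) {
  curves <- equitability_curves(sweep)
  grids <- split(paste(curves$relationship, curves$r2), curves$method)
  ref <- sort(grids[[1]])
  if (!all(vapply(grids, function(g) identical(sort(g), ref), logical(1))))
    stop("methods do not cover a common (relationship, r2) grid",
         call. = FALSE)
  rows <- lapply(split(curves, curves$method), function(d) {
    bias <- abs(d$mean_score - d$r2)
    v <- d$sd_score^2
    data.frame(method = d$method[1],
               bias_min = min(bias), bias_mean = mean(bias),
               bias_max = max(bias),
               var_min = min(v), var_mean = mean(v), var_max = max(v),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
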