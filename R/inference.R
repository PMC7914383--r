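#' Build the condition-pair contingency table from a cluster solution
#'
#' Cross-classifies the electrodes of two conditions by cluster label. Rows
#' are the two conditions (each summing to the number of electrodes in the
#' set), columns are the cluster labels actually occurring among the involved
#' waveforms; labels with zero total are dropped.
#'
#' @param solution An `erp_clusters` with `meta` (from clustering an
#'   `erp_averages`).
#' @param pair Character vector of two condition names.
#' @return Integer matrix, 2 rows (the conditions) by up to `k` columns.
#' @export
build_contingency <- function(solution, pair) {
  stopifnot(inherits(solution, "erp_clusters"))
  if (is.null(solution$meta)) {
    stop("cluster solution carries no condition metadata", call. = FALSE)
  }
  if (length(pair) != 2L) stop("`pair` must name two conditions",
                               call. = FALSE)
  unknown <- setdiff(pair, unique(solution$meta$condition))
  if (length(unknown)) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  keep <- solution$meta$condition %in% pair
  tab <- table(factor(solution$meta$condition[keep], levels = pair),
               solution$assignments[keep])
  tab <- unclass(tab)[, colSums(tab) > 0, drop = FALSE]
  storage.mode(tab) <- "integer"
  names(dimnames(tab)) <- NULL
  tab
}

# enumerate all nonnegative integer tables with the given margins, calling
# fun(log-probability) for each; probabilities are multivariate hypergeometric
.enumerate_margin_tables <- function(rs, cs, fun) {
  r <- length(rs)
  logK <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
  row_loop <- function(i, cs_left, logacc) {
    if (i == r) {
      fun(logK + logacc - sum(lgamma(cs_left + 1)))
      return(invisible(NULL))
    }
    cells <- numeric(length(cs_left))
    cell_loop <- function(j, rem) {
      if (j == length(cs_left)) {
        if (rem > cs_left[j]) return(invisible(NULL))
        cells[j] <<- rem
        row_loop(i + 1L, cs_left - cells,
                 logacc - sum(lgamma(cells + 1)))
        return(invisible(NULL))
      }
      lo <- max(0L, rem - sum(cs_left[(j + 1L):length(cs_left)]))
      hi <- min(rem, cs_left[j])
      if (lo > hi) return(invisible(NULL))
      for (v in lo:hi) {
        cells[j] <<- v
        cell_loop(j + 1L, rem - v)
      }
    }
    if (length(cs_left) == 1L) {
      cells[1] <- rs[i]
      if (cells[1] > cs_left[1]) return(invisible(NULL))
      row_loop(i + 1L, cs_left - cells, logacc - lgamma(cells[1] + 1))
    } else {
      cell_loop(1L, rs[i])
    }
    invisible(NULL)
  }
  row_loop(1L, cs, 0)
}

#' Exact test of independence for an r x c contingency table
#'
#' Computes the exact two-sided p-value of the independence test with fixed
#' margins: the sum of the (multivariate hypergeometric) probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table. Implemented by full enumeration of the table space,
#' which is cheap at the sizes arising here (2 rows of 4 electrodes, up to 3
#' cluster labels). A relative tolerance guards float ties between table
#' probabilities.
#'
#' @param table Nonnegative integer matrix (rows and columns with zero totals
#'   are dropped first). A table with a single remaining row or column carries
#'   no evidence against independence and yields p = 1.
#' @param tol Relative tolerance for probability ties (default `1e-12`).
#' @return The exact p-value, in (0, 1]. The attribute `total_probability`
#'   holds the sum of all enumerated table probabilities (a self-check; it
#'   should be 1 up to rounding).
#' @export
fisher_exact <- function(table, tol = 1e-12) {
  tab <- as.matrix(table)
  if (!.is_wholenumber(tab) || any(tab < 0)) {
    stop("`table` must contain nonnegative integers", call. = FALSE)
  }
  tab <- round(tab)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) == 0L || ncol(tab) == 0L) {
    stop("table is empty after pruning zero margins", call. = FALSE)
  }
  if (nrow(tab) == 1L || ncol(tab) == 1L) {
    p <- 1
    attr(p, "total_probability") <- 1
    return(p)
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  logK <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(tab) + 1)
  logp_obs <- logK - sum(lgamma(tab + 1))
  acc <- new.env(parent = emptyenv())
  acc$psum <- 0
  acc$total <- 0
  .enumerate_margin_tables(rs, cs, function(lp) {
    pr <- exp(lp)
    acc$total <- acc$total + pr
    if (lp <= logp_obs + tol) acc$psum <- acc$psum + pr
  })
  p <- min(1, acc$psum)
  attr(p, "total_probability") <- acc$total
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (as in `stats::p.adjust`,
#' method `"BH"`): rejecting all adjusted values at or below `alpha`
#' reproduces the classic step-up rule on the raw p-values.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (!is.numeric(pvalues) || any(!is.finite(pvalues)) ||
      any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(pvalues, method = "BH")
}

#' Apply the rejection rule to comparison results
#'
#' Sets `rejected = adjusted p <= alpha` (boundary inclusive) on a data frame
#' of comparison results.
#'
#' @param results Data frame with a `p_adjusted` column.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @return `results` with a logical `rejected` column.
#' @export
decide <- function(results, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (!"p_adjusted" %in% names(results)) {
    stop("`results` must carry adjusted p-values", call. = FALSE)
  }
  results$rejected <- results$p_adjusted <= alpha
  results
}

#' Pairwise condition tests for one cluster solution
#'
#' Builds the contingency table of every condition pair, computes the exact
#' independence p-value, and (optionally) adjusts within this solution's
#' family of pairs.
#'
#' @param solution An `erp_clusters` with condition metadata.
#' @param conditions Conditions to compare pairwise (default: all in the
#'   solution, in order of appearance).
#' @param adjust If `TRUE`, Benjamini-Hochberg adjust across the pairs here;
#'   if `FALSE`, leave `p_adjusted` as `NA` for a caller-defined family.
#' @param alpha Level used for the rejection flag.
#' @return Data frame with one row per pair: `cond_a`, `cond_b`, flattened
#'   table cells, `p`, `p_adjusted`, `rejected`.
#' @export
test_condition_pairs <- function(solution, conditions = NULL, adjust = TRUE,
                                 alpha = 0.05) {
  stopifnot(inherits(solution, "erp_clusters"))
  conditions <- conditions %||% unique(solution$meta$condition)
  pairs <- utils::combn(conditions, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pr <- pairs[, j]
    tab <- build_contingency(solution, pr)
    p <- fisher_exact(tab)
    data.frame(cond_a = pr[1], cond_b = pr[2],
               table_cells = paste(apply(tab, 1, paste, collapse = ","),
                                   collapse = "|"),
               table_labels = paste(colnames(tab), collapse = ","),
               p = as.numeric(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust) bh_adjust(out$p) else NA_real_
  if (adjust) out <- decide(out, alpha) else out$rejected <- NA
  out
}
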