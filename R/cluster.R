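# k-means++ seeding on pre-transposed data (columns = points):
# returns column indices of the chosen centers
.kmeanspp_init <- function(Xt, k) {
  n <- ncol(Xt)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- colSums((Xt - Xt[, centers[1]])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      pool <- setdiff(seq_len(n), centers[seq_len(j - 1L)])
      centers[j] <- pool[sample.int(length(pool), 1L)]
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, colSums((Xt - Xt[, centers[j]])^2))
  }
  centers
}

# canonical labels: clusters renamed A, B, C... in order of first appearance
.canonical_assignment <- function(cl) {
  match(cl, unique(cl))
}

.inertia <- function(X, cl, centroids) {
  sum((X - centroids[cl, , drop = FALSE])^2)
}

#' Cluster averaged waveforms with k-means
#'
#' Partitions the 12 averaged waveforms of one electrode set into `k = 3`
#' clusters labelled A, B, C by best-of-`n_restarts` k-means under squared
#' Euclidean distance on the raw waveform vectors (no standardisation --
#' amplitude differences are the signal of interest). Each restart is seeded
#' with k-means++ centers; among restarts of equal inertia the
#' lexicographically smallest canonical assignment wins, making the result
#' reproducible. If the data contain fewer distinct waveforms than `k`, every
#' distinct waveform forms its own cluster, inertia is 0, and the solution is
#' flagged degenerate.
#'
#' @param x An `erp_averages` or a numeric matrix of waveforms in rows.
#' @param k Number of clusters (default 3).
#' @param n_restarts Number of k-means++ restarts (default 200).
#' @param seed Integer seed; the solution is deterministic given seed.
#' @return An object of class `erp_clusters` with `assignments` (factor with
#'   levels `A`, `B`, ..., named by waveform), `centroids`, `inertia`, `meta`
#'   (if available), `degenerate`, `n_restarts`, `seed`.
#' @export
cluster_waveforms <- function(x, k = 3L, n_restarts = 200L, seed = 1L) {
  if (inherits(x, "erp_averages")) {
    X <- x$waveforms
    meta <- x$meta
    set_name <- x$set_name
  } else {
    X <- as.matrix(x)
    meta <- NULL
    set_name <- NA_character_
  }
  if (!is.numeric(k) || k < 1) stop("`k` must be >= 1", call. = FALSE)
  k <- as.integer(k)
  n <- nrow(X)
  if (k > n) stop("`k` exceeds the number of waveforms", call. = FALSE)
  distinct <- unique(X)
  if (nrow(distinct) < k) {
    codes <- match(
      apply(X, 1, paste, collapse = "\r"),
      apply(distinct, 1, paste, collapse = "\r"))
    codes <- .canonical_assignment(codes)
    centroids <- X[!duplicated(codes), , drop = FALSE][order(unique(codes)), ,
                                                       drop = FALSE]
    sol <- list(codes = codes, centroids = centroids, inertia = 0,
                degenerate = TRUE)
  } else {
    # isometric reduction: n points span an <= n-dim subspace, and right-
    # multiplying by the orthonormal V of the SVD preserves all pairwise
    # distances, so k-means partitions and inertia are unchanged
    Xw <- if (ncol(X) > n) {
      sv <- svd(X, nu = n, nv = 0)
      sv$u %*% diag(sv$d, nrow = n)
    } else X
    Xwt <- t(Xw)
    sol <- withr::with_seed(as.integer(seed), {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        init <- .kmeanspp_init(Xwt, k)
        km <- tryCatch(
          suppressWarnings(stats::kmeans(Xw,
                                         centers = Xw[init, , drop = FALSE],
                                         iter.max = 100L)),
          error = function(e)
            suppressWarnings(stats::kmeans(Xw,
                                           centers = Xw[init, , drop = FALSE],
                                           iter.max = 100L,
                                           algorithm = "Lloyd")))
        codes <- .canonical_assignment(km$cluster)
        centroids <- matrix(0, nrow = max(codes), ncol = ncol(X))
        for (g in seq_len(max(codes))) {
          centroids[g, ] <- colMeans(X[codes == g, , drop = FALSE])
        }
        inert <- .inertia(X, codes, centroids)
        if (is.null(best) ||
            inert < best$inertia - 1e-9 * max(1, best$inertia) ||
            (abs(inert - best$inertia) <=
               1e-9 * max(1, best$inertia) &&
             .lex_less(codes, best$codes))) {
          best <- list(codes = codes, centroids = centroids, inertia = inert)
        }
        if (best$inertia <= 1e-12) break  # global optimum, unique partition
      }
      best
    })
    sol$degenerate <- FALSE
  }
  labels <- LETTERS[sol$codes]
  nm <- rownames(X) %||% paste0("w", seq_len(n))
  assignments <- factor(labels, levels = LETTERS[seq_len(k)])
  names(assignments) <- nm
  structure(
    list(assignments = assignments, centroids = sol$centroids,
         inertia = sol$inertia, meta = meta, set_name = set_name,
         k = k, n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         degenerate = sol$degenerate),
    class = "erp_clusters"
  )
}

# lexicographic strict comparison of integer vectors
.lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Exhaustive minimal-inertia partition (test oracle)
#'
#' Enumerates every assignment of up to 12 waveforms into at most `k` groups
#' (with the first waveform's label fixed, since inertia is invariant under
#' label permutation) and returns a partition of globally minimal
#' within-cluster sum of squares, with centroids equal to group means. Used as
#' an independent optimality check for [cluster_waveforms()].
#'
#' @param x Numeric matrix of waveforms in rows (at most 12 rows).
#' @param k Maximum number of groups.
#' @return List with `assignments` (canonical letters) and `inertia`.
#' @export
brute_force_partition <- function(x, k = 3L) {
  X <- as.matrix(x)
  n <- nrow(X)
  if (n > 12L) stop("too many waveforms for exhaustive enumeration",
                    call. = FALSE)
  k <- as.integer(k)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (n == 1L) {
    return(list(assignments = "A", inertia = 0))
  }
  A <- .assignment_matrix(n, k)
  G <- X %*% t(X)
  tot <- sum(X^2)
  explained <- numeric(nrow(A))
  for (g in seq_len(k)) {
    Ig <- (A == g) * 1
    ng <- rowSums(Ig)
    Sg <- rowSums((Ig %*% G) * Ig)
    explained <- explained + ifelse(ng > 0, Sg / pmax(ng, 1), 0)
  }
  inertia <- tot - explained
  best <- which.min(inertia)
  codes <- .canonical_assignment(A[best, ])
  list(assignments = LETTERS[codes], inertia = max(0, inertia[best]))
}

# all assignments of n items to k labels with item 1 fixed to label 1, cached
.bf_cache <- new.env(parent = emptyenv())
.assignment_matrix <- function(n, k) {
  key <- paste(n, k, sep = "_")
  if (!is.null(.bf_cache[[key]])) return(.bf_cache[[key]])
  rest <- as.matrix(expand.grid(rep(list(seq_len(k)), n - 1L),
                                KEEP.OUT.ATTRS = FALSE))
  A <- unname(cbind(1L, rest))
  .bf_cache[[key]] <- A
  A
}

#' @export
print.erp_clusters <- function(x, ...) {
  cat(sprintf("<erp_clusters> k=%d, inertia=%.4g%s\n", x$k, x$inertia,
              if (x$degenerate) " (degenerate)" else ""))
  print(x$assignments)
  invisible(x)
}

#' Plot cluster centroids
#'
#' @param x An `erp_clusters`.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.erp_clusters <- function(x, ...) {
  graphics::matplot(t(x$centroids), type = "l", lty = 1,
                    col = seq_len(nrow(x$centroids)) + 1L,
                    xlab = "sample", ylab = "amplitude (uV)",
                    main = sprintf("centroids (inertia %.3g)", x$inertia), ...)
  graphics::legend("bottomleft",
                   legend = LETTERS[seq_len(nrow(x$centroids))],
                   col = seq_len(nrow(x$centroids)) + 1L, lty = 1, bty = "n")
  invisible(x)
}
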