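#' Euclidean distance matrix between patient profiles
#'
#' Distances are computed over the given spot list on raw (unstandardized)
#' %Vol means. A spot missing from a patient's profile is imputed as 0 %Vol
#' by default — absence of a spot on a gel is read as true low abundance —
#' or handled pairwise-complete with rescaling when `missing = "pairwise"`.
#'
#' @param profiles List of `patient_profile` objects (or a numeric matrix,
#'   patients x spots).
#' @param spots Spot ids defining the feature space.
#' @param missing Either `"zero"` (default) or `"pairwise"`.
#' @return Symmetric distance matrix with patient ids as dimnames.
#' @export
euclidean_distance_matrix <- function(profiles, spots, missing = c("zero", "pairwise")) {
  missing <- match.arg(missing)
  m <- if (is.matrix(profiles)) profiles[, spots, drop = FALSE] else profiles_to_matrix(profiles, spots)
  if (nrow(m) < 2) stop("need at least 2 profiles", call. = FALSE)
  if (length(spots) < 1) stop("empty spot list", call. = FALSE)
  if (any(rowSums(!is.na(m)) == 0))
    stop("all-missing spot vector for patient(s): ",
         paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", "), call. = FALSE)
  if (missing == "zero") {
    m[is.na(m)] <- 0
    d <- as.matrix(stats::dist(m, method = "euclidean"))
  } else {
    n <- nrow(m)
    d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        if (!any(ok)) stop("no shared spots between ", rownames(m)[i],
                           " and ", rownames(m)[j], call. = FALSE)
        # rescale to the full spot count so sparsity does not shrink distances
        d[i, j] <- d[j, i] <- sqrt(sum((m[i, ok] - m[j, ok])^2) * length(spots) / sum(ok))
      }
    }
  }
  d
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Agglomerates the pair of clusters with minimal average inter-cluster
#' distance at each step; merged distances are size-weighted averages
#' (unweighted pair group method with arithmetic mean). Merge heights are
#' checked for the monotonicity UPGMA guarantees on a metric.
#'
#' @param dist_matrix Symmetric distance matrix (or `dist` object).
#' @return An object of class `upgma_dendrogram`: list with `merge`, `height`,
#'   `labels`, `order` (hclust encoding) and the underlying `hclust` object.
#' @export
upgma <- function(dist_matrix) {
  d <- stats::as.dist(dist_matrix)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  hc <- stats::hclust(d, method = "average")
  if (any(diff(hc$height) < -1e-8))
    stop("internal error: non-monotone UPGMA merge heights", call. = FALSE)
  out <- list(merge = hc$merge, height = hc$height,
              labels = hc$labels, order = hc$order, hclust = hc)
  class(out) <- "upgma_dendrogram"
  out
}

#' Extract main clusters and outliers from a dendrogram
#'
#' The tree is cut at successively finer levels; branches containing at most
#' `outlier_max_size` patients are labeled `OUTLIER` and set aside, and
#' cutting proceeds until exactly `k_main` non-outlier clusters remain (or
#' the leaves are exhausted, in which case fewer clusters are returned with a
#' warning). Main clusters are canonically labeled `C1`, `C2`, ... by
#' decreasing size, ties broken by the lexicographically smallest member, so
#' labels do not depend on patient input order.
#'
#' @param dendrogram An `upgma_dendrogram`.
#' @param k_main Number of main clusters to recover (default 2).
#' @param outlier_max_size Maximum size of a branch treated as outliers
#'   (default 1).
#' @return A `cluster_assignment` data frame with columns `patient_id`,
#'   `cluster` (`C1`, `C2`, ... or `OUTLIER`); attribute `k_cut` records the
#'   cut used.
#' @export
extract_clusters <- function(dendrogram, k_main = 2L, outlier_max_size = 1L) {
  stopifnot(inherits(dendrogram, "upgma_dendrogram"), k_main >= 1L)
  hc <- dendrogram$hclust
  n <- length(hc$labels)
  chosen <- NULL
  best <- NULL
  best_n_main <- -1L
  for (k in seq.int(min(k_main, n), n)) {
    ct <- stats::cutree(hc, k = k)
    sizes <- table(ct)
    main_groups <- as.integer(names(sizes)[sizes > outlier_max_size])
    if (length(main_groups) > best_n_main && length(main_groups) <= k_main) {
      best <- list(ct = ct, main = main_groups, k = k)
      best_n_main <- length(main_groups)
    }
    if (length(main_groups) == k_main) {
      chosen <- list(ct = ct, main = main_groups, k = k)
      break
    }
  }
  if (is.null(chosen)) {
    chosen <- best
    warning(sprintf("tree exhausted: only %d main cluster(s) of the requested %d",
                    best_n_main, k_main), call. = FALSE)
  }
  ct <- chosen$ct
  labels <- names(ct)
  cluster <- rep("OUTLIER", n)
  main <- chosen$main
  # canonical ordering: size desc, then smallest member id
  sizes <- vapply(main, function(g) sum(ct == g), integer(1))
  first_member <- vapply(main, function(g) min(labels[ct == g]), character(1))
  main <- main[order(-sizes, first_member)]
  for (i in seq_along(main)) cluster[ct == main[i]] <- paste0("C", i)
  out <- data.frame(patient_id = labels, cluster = cluster,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "k_cut") <- chosen$k
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels (same length).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
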