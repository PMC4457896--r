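#' Two-sided Mann-Whitney U test
#'
#' Uses the exact permutation null of the U statistic (via the Wilcoxon
#' count distribution) when `min(n_a, n_b) <= 10` and there are no ties;
#' otherwise a mid-rank normal approximation with tie correction (no
#' continuity correction). Two-sided throughout.
#'
#' @param group_a,group_b Numeric vectors of observations.
#' @return List with `p_value`, `u` (U statistic of group A) and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  n_a <- length(group_a)
  n_b <- length(group_b)
  if (n_a == 0 || n_b == 0) stop("mann_whitney: empty group", call. = FALSE)
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- any(duplicated(pooled))
  if (!ties && min(n_a, n_b) <= 10) {
    p <- 2 * min(stats::pwilcox(u, n_a, n_b),
                 stats::pwilcox(u - 1, n_a, n_b, lower.tail = FALSE))
    list(p_value = min(1, p), u = u, method = "exact")
  } else {
    n <- n_a + n_b
    tie_tab <- table(r)
    sigma2 <- n_a * n_b / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) return(list(p_value = 1, u = u, method = "normal"))
    z <- (u - n_a * n_b / 2) / sqrt(sigma2)
    list(p_value = min(1, 2 * stats::pnorm(-abs(z))), u = u, method = "normal")
  }
}

#' Fold change between two group means
#'
#' Reported as a ratio >= 1 with a direction: `up_in_b` when the second mean
#' is larger, `down_in_b` when smaller, `none` when equal. The 1-decimal
#' rounding used in human-readable tables is carried alongside the full
#' precision ratio. A single zero mean yields an infinite ratio (flagged by
#' direction); two zero means are an error.
#'
#' @param mean_a,mean_b Non-negative group means (%Vol).
#' @return List with `ratio`, `ratio_rounded`, `direction`.
#' @export
fold_change <- function(mean_a, mean_b) {
  stopifnot(mean_a >= 0, mean_b >= 0)
  if (mean_a == 0 && mean_b == 0) stop("fold_change: both means zero", call. = FALSE)
  if (mean_a == mean_b) {
    return(list(ratio = 1, ratio_rounded = 1, direction = "none"))
  }
  ratio <- max(mean_b / mean_a, mean_a / mean_b)
  list(ratio = ratio,
       ratio_rounded = round(ratio, 1),
       direction = if (mean_b > mean_a) "up_in_b" else "down_in_b")
}

#' Differential spot selection between two clusters
#'
#' For each spot, a two-sided Mann-Whitney test on the per-patient %Vol means
#' (the best-pair aggregated values, one number per patient) plus a fold
#' change of the cluster means. A spot is `selected` when it is significant
#' (`p < p_threshold`) OR passes the fold-change criterion
#' (`ratio >= fc_threshold`); both flags are reported separately so an
#' intersection rule is a filter away. No multiple-testing correction is
#' applied; the number of tests is attached as an attribute.
#'
#' @param profiles List of `patient_profile` objects.
#' @param assignment A `cluster_assignment`.
#' @param cluster_a,cluster_b The two cluster labels to compare (fold change
#'   reads B relative to A).
#' @param spots Spot ids to test (default: all spots present in any profile
#'   of the two clusters).
#' @param p_threshold,fc_threshold Selection thresholds (defaults 0.05, 1.5).
#' @return Data frame of per-spot results (`spot_id`, `mean_a`, `sd_a`,
#'   `mean_b`, `sd_b`, `p_value`, `fold_change`, `direction`, `significant`,
#'   `fc_pass`, `selected`), attribute `n_tests`.
#' @export
select_differential_spots <- function(profiles, assignment, cluster_a, cluster_b,
                                      spots = NULL, p_threshold = 0.05,
                                      fc_threshold = 1.5) {
  prof_ids <- vapply(profiles, function(p) p$patient_id, character(1))
  ids_a <- intersect(assignment$patient_id[assignment$cluster == cluster_a], prof_ids)
  ids_b <- intersect(assignment$patient_id[assignment$cluster == cluster_b], prof_ids)
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("select_differential_spots: each cluster needs >= 2 members", call. = FALSE)
  pa <- profiles[prof_ids %in% ids_a]
  pb <- profiles[prof_ids %in% ids_b]
  if (is.null(spots)) {
    spots <- sort(unique(unlist(lapply(c(pa, pb), function(p) p$spots$spot_id))))
  }
  ma <- profiles_to_matrix(pa, spots)
  mb <- profiles_to_matrix(pb, spots)
  res <- lapply(seq_along(spots), function(i) {
    va <- ma[, i][!is.na(ma[, i])]
    vb <- mb[, i][!is.na(mb[, i])]
    mean_a <- if (length(va)) mean(va) else NA_real_
    mean_b <- if (length(vb)) mean(vb) else NA_real_
    p <- if (length(va) >= 2 && length(vb) >= 2) mann_whitney(va, vb)$p_value else NA_real_
    fc <- if (!is.na(mean_a) && !is.na(mean_b) && (mean_a > 0 || mean_b > 0)) {
      fold_change(mean_a, mean_b)
    } else {
      list(ratio = NA_real_, direction = NA_character_)
    }
    data.frame(spot_id = spots[i],
               mean_a = mean_a, sd_a = if (length(va) >= 2) stats::sd(va) else NA_real_,
               mean_b = mean_b, sd_b = if (length(vb) >= 2) stats::sd(vb) else NA_real_,
               p_value = p, fold_change = fc$ratio, direction = fc$direction,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- !is.na(out$p_value) & out$p_value < p_threshold
  out$fc_pass <- !is.na(out$fold_change) & out$fold_change >= fc_threshold
  out$selected <- out$significant | out$fc_pass
  attr(out, "n_tests") <- sum(!is.na(out$p_value))
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-rank Spearman rho; the two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, `n >= 3`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman: need n >= 3 pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("spearman: zero variance in ranks", call. = FALSE)
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) return(list(rho = rho, p_value = 0, n = n))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(t_stat), df = n - 2), n = n)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic on the contingency table with asymptotic p-value:
#' no continuity correction and no small-count pooling. All-zero rows or
#' columns are dropped with a warning; a table degenerating to fewer than
#' two rows or columns returns NA statistics with a warning.
#'
#' @param contingency Numeric matrix of counts (e.g. clusters x classes).
#' @return List with `chi2`, `df`, `p_value`, and the `expected` matrix.
#' @export
chi_square_independence <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0) || sum(m) <= 0) stop("chi_square: invalid counts", call. = FALSE)
  zr <- rowSums(m) == 0
  zc <- colSums(m) == 0
  if (any(zr) || any(zc)) {
    warning("chi_square: dropping all-zero row(s)/column(s)", call. = FALSE)
    m <- m[!zr, !zc, drop = FALSE]
  }
  if (nrow(m) < 2 || ncol(m) < 2) {
    warning("chi_square: degenerate table, statistic undefined", call. = FALSE)
    return(list(chi2 = NA_real_, df = NA_integer_, p_value = NA_real_, expected = m))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  chi2 <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       expected = expected)
}

#' Phosphorylation call from stain intensity ratio
#'
#' The ratio of phospho-stain (ProQ Diamond) to total-protein stain (Sypro)
#' signal; a spot with `D/S < ds_threshold` is called not phosphorylated.
#'
#' @param proq_signal Phospho-stain intensity, `>= 0`.
#' @param sypro_signal Total-protein stain intensity, `> 0`.
#' @param ds_threshold Call threshold (default 0.08).
#' @return `"phosphorylated"` or `"not_phosphorylated"`.
#' @export
phospho_call <- function(proq_signal, sypro_signal, ds_threshold = 0.08) {
  stopifnot(proq_signal >= 0)
  if (sypro_signal <= 0) stop("phospho_call: Sypro signal must be > 0", call. = FALSE)
  if (proq_signal / sypro_signal < ds_threshold) "not_phosphorylated" else "phosphorylated"
}
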