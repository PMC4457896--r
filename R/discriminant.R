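#' Fit two-group linear discriminant classification functions
#'
#' Classification-function parameterization of two-group LDA: for group k,
#' `f_k(x) = mu_k' S^-1 x - 1/2 mu_k' S^-1 mu_k + log(prior_k)` with `S` the
#' pooled within-group covariance. A sample is assigned to the group with
#' the larger score; the decision is equivalent to thresholding the single
#' linear function `f_1 - f_2`.
#'
#' @param profiles List of `patient_profile` objects (or a numeric matrix,
#'   patients x spots, with rownames).
#' @param assignment A `cluster_assignment` giving the two groups.
#' @param feature_spots Spot ids used as features.
#' @param priors Named prior probabilities per group; default equal.
#' @return A `discriminant_model`: list with `groups`, `coefficients`
#'   (groups x features), `intercepts`, `features`, `provenance = "fitted"`.
#' @export
fit_discriminant <- function(profiles, assignment, feature_spots, priors = NULL) {
  groups <- setdiff(sort(unique(assignment$cluster)), "OUTLIER")
  if (length(groups) != 2) stop("fit_discriminant: exactly two groups required", call. = FALSE)
  m <- if (is.matrix(profiles)) profiles[, feature_spots, drop = FALSE] else profiles_to_matrix(profiles, feature_spots)
  if (anyNA(m)) stop("fit_discriminant: missing feature values", call. = FALSE)
  idx <- lapply(groups, function(g) {
    ids <- assignment$patient_id[assignment$cluster == g]
    which(rownames(m) %in% ids)
  })
  ns <- lengths(idx)
  p <- length(feature_spots)
  if (any(ns <= p))
    stop("fit_discriminant: each group needs more members than features", call. = FALSE)
  if (is.null(priors)) priors <- stats::setNames(rep(1 / 2, 2), groups)
  priors <- priors[groups] / sum(priors[groups])
  mus <- lapply(idx, function(ii) colMeans(m[ii, , drop = FALSE]))
  covs <- lapply(idx, function(ii) stats::cov(m[ii, , drop = FALSE]))
  S <- ((ns[1] - 1) * covs[[1]] + (ns[2] - 1) * covs[[2]]) / (sum(ns) - 2)
  kappa_s <- kappa(S, exact = TRUE)
  if (!is.finite(kappa_s) || kappa_s > 1e12)
    stop(sprintf("fit_discriminant: pooled covariance is singular (condition number %.3g)",
                 kappa_s), call. = FALSE)
  Sinv <- solve(S)
  coef <- t(vapply(mus, function(mu) as.numeric(Sinv %*% mu), numeric(p)))
  dimnames(coef) <- list(groups, feature_spots)
  intercepts <- vapply(seq_along(groups), function(k) {
    -0.5 * sum(mus[[k]] * (Sinv %*% mus[[k]])) + log(priors[k])
  }, numeric(1))
  names(intercepts) <- groups
  model <- list(groups = groups, coefficients = coef, intercepts = intercepts,
                features = feature_spots, provenance = "fitted")
  class(model) <- "discriminant_model"
  model
}

#' Bundled DBP-isoform discriminant functions
#'
#' The published pair of classification functions over the two vitamin D
#' binding protein isoform spots, carried as a frozen fixture (the per-patient
#' data behind the fit are not bundled):
#' `f1 = 33.813 * x288 + 48.942 * x289 - 7.155`,
#' `f2 = 103.508 * x288 + 42.871 * x289 - 15.248`,
#' with `x288`, `x289` the %Vol of spots "288" and "289". Which function
#' corresponds to which proteomic cluster is resolved at run time by
#' [map_discriminant_to_clusters()].
#'
#' @return A `discriminant_model` with `provenance = "fixture"`.
#' @export
dbp_discriminant_model <- function() {
  path <- system.file("extdata", "dbp_discriminant_functions.tsv",
                      package = "csfstrat", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  groups <- unique(df$group)
  features <- setdiff(unique(df$term), "(intercept)")
  coef <- matrix(NA_real_, length(groups), length(features),
                 dimnames = list(groups, features))
  intercepts <- stats::setNames(numeric(length(groups)), groups)
  for (i in seq_len(nrow(df))) {
    if (df$term[i] == "(intercept)") {
      intercepts[df$group[i]] <- df$value[i]
    } else {
      coef[df$group[i], df$term[i]] <- df$value[i]
    }
  }
  model <- list(groups = groups, coefficients = coef, intercepts = intercepts,
                features = features, provenance = "fixture")
  class(model) <- "discriminant_model"
  model
}

#' Evaluate discriminant classification functions
#'
#' @param model A `discriminant_model`.
#' @param x Named numeric vector of feature %Vol values; must cover every
#'   feature spot (a missing feature is an error, never silently zero).
#' @return Named numeric vector of per-group scores.
#' @export
evaluate_functions <- function(model, x) {
  stopifnot(inherits(model, "discriminant_model"))
  missing_feats <- setdiff(model$features, names(x))
  if (length(missing_feats) > 0)
    stop("evaluate_functions: missing feature spot(s): ",
         paste(missing_feats, collapse = ", "), call. = FALSE)
  xv <- as.numeric(x[model$features])
  if (anyNA(xv)) stop("evaluate_functions: NA feature value", call. = FALSE)
  drop(model$coefficients %*% xv) + model$intercepts
}

#' Classify a sample with a discriminant model
#'
#' Argmax of the classification-function scores; exact ties resolve
#' deterministically to the first-listed group.
#'
#' @inheritParams evaluate_functions
#' @return A group label.
#' @export
classify <- function(model, x) {
  scores <- evaluate_functions(model, x)
  model$groups[which.max(scores)]
}

#' Map discriminant functions onto proteomic clusters
#'
#' The published function pair does not state which function belongs to
#' which cluster. The mapping is resolved by the geometry of the
#' classification functions: each cluster centroid is scored and assigned
#' the function that maximizes it (falling back, for degenerate score ties,
#' to matching the larger spot-"288" coefficient with the higher
#' spot-"288" centroid).
#'
#' @param model A `discriminant_model`.
#' @param profiles List of `patient_profile` objects or a patients x spots
#'   matrix.
#' @param assignment A `cluster_assignment` with two non-outlier clusters.
#' @return Named character vector: `model group -> cluster label`.
#' @export
map_discriminant_to_clusters <- function(model, profiles, assignment) {
  clusters <- setdiff(sort(unique(assignment$cluster)), "OUTLIER")
  if (length(clusters) != 2) stop("need exactly two non-outlier clusters", call. = FALSE)
  m <- if (is.matrix(profiles)) profiles else profiles_to_matrix(profiles, model$features)
  centroids <- t(vapply(clusters, function(g) {
    ids <- assignment$patient_id[assignment$cluster == g]
    colMeans(m[rownames(m) %in% ids, model$features, drop = FALSE], na.rm = TRUE)
  }, numeric(length(model$features))))
  rownames(centroids) <- clusters
  assigned <- vapply(clusters, function(g) {
    classify(model, stats::setNames(centroids[g, ], model$features))
  }, character(1))
  if (length(unique(assigned)) == 2) {
    return(stats::setNames(clusters[match(model$groups, assigned)], model$groups))
  }
  # degenerate geometry: both centroids score the same function; fall back to
  # aligning the steeper first-feature coefficient with the higher centroid
  key <- model$features[1]
  hi_coef_group <- model$groups[which.max(model$coefficients[, key])]
  hi_centroid_cluster <- clusters[which.max(centroids[, key])]
  lo_coef_group <- setdiff(model$groups, hi_coef_group)
  lo_centroid_cluster <- setdiff(clusters, hi_centroid_cluster)
  stats::setNames(c(hi_centroid_cluster, lo_centroid_cluster),
                  c(hi_coef_group, lo_coef_group))[model$groups]
}
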