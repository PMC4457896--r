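#' Assign a clinical aggressiveness class from treatment history
#'
#' Classes are defined by the disease-modifying treatment (DMT) line in use
#' or proposed at the horizon: second-line therapy means a highly aggressive
#' course (`H`), first-line moderate (`M`), no therapy low (`L`); a benign
#' course (stable, untreated for over a decade; token `LB`) collapses into
#' `L` for association analyses. Primary progressive disease, death, loss to
#' follow-up and non-MS diagnoses are excluded tokens: they never enter the
#' cluster-vs-class tables but are accounted for with a reason.
#'
#' @param record One row of a `clinical_table` (data frame or list).
#' @param horizon `"2y"` or `"5y"`.
#' @return A single token: `"H"`, `"M"`, `"L"`, or one of the excluded
#'   tokens `"PP"`, `"death"`, `"lost"`, `"no_MS"`.
#' @export
assign_class <- function(record, horizon = c("5y", "2y")) {
  horizon <- match.arg(horizon)
  dmt <- as.character(record[[paste0("dmt_", horizon)]])
  cls <- as.character(record[[paste0("class_", horizon)]])
  if (cls %in% c("PP", "lost", "no_MS", "death")) return(cls)
  if (dmt %in% c("lost", "death", "no_MS")) return(dmt)
  switch(dmt,
         II = "H",
         I = "M",
         none = "L",  # includes the benign (LB) course
         stop("assign_class: unknown DMT token \"", dmt, "\"", call. = FALSE))
}

#' Assign classes for a whole clinical table
#'
#' @param clinical A `clinical_table`.
#' @param horizon `"2y"` or `"5y"`.
#' @return Data frame `patient_id`, `class`, `included` (TRUE for H/M/L),
#'   `reason` (the excluded token, or NA).
#' @export
assign_classes <- function(clinical, horizon = c("5y", "2y")) {
  horizon <- match.arg(horizon)
  cls <- vapply(seq_len(nrow(clinical)),
                function(i) assign_class(clinical[i, ], horizon), character(1))
  included <- cls %in% c("H", "M", "L")
  data.frame(patient_id = clinical$patient_id, class = cls,
             included = included,
             reason = ifelse(included, NA_character_, cls),
             stringsAsFactors = FALSE)
}

#' Cross-tabulate proteomic clusters against clinical classes
#'
#' Counts patients by (cluster, class) over those with an association class
#' (`H`/`M`/`L`) and a non-outlier cluster; reports column percentages
#' `P(cluster | class)`, within-cluster percentages `P(class | cluster)`,
#' and the Pearson chi-square association. Excluded patients (outliers,
#' `PP`, `death`, `lost`, `no_MS`) are listed with reasons, never silently
#' dropped: classified + excluded always equals the cohort size.
#'
#' @param assignment A `cluster_assignment`.
#' @param clinical A `clinical_table` (or the output of [assign_classes()]).
#' @param horizon `"2y"` or `"5y"`.
#' @param classes Class columns of the table, default `c("H", "L", "M")`.
#' @return A `crosstab`: list with `counts` (clusters x classes),
#'   `pct_given_class`, `pct_given_cluster`, `chi2`, `df`, `p_value`,
#'   `excluded` (data frame with reasons), `horizon`.
#' @export
cross_tabulate <- function(assignment, clinical, horizon = c("5y", "2y"),
                           classes = c("H", "L", "M")) {
  horizon <- match.arg(horizon)
  ac <- if (is.data.frame(clinical) && "included" %in% names(clinical)) clinical
        else assign_classes(clinical, horizon)
  merged <- merge(as.data.frame(assignment), ac, by = "patient_id", all = FALSE)
  if (nrow(merged) == 0) stop("cross_tabulate: no patients in common", call. = FALSE)
  excl_cluster <- merged$cluster == "OUTLIER"
  excl_class <- !merged$included
  keep <- !excl_cluster & !excl_class
  excluded <- data.frame(
    patient_id = merged$patient_id[!keep],
    reason = ifelse(excl_cluster[!keep], "cluster outlier",
                    paste0("class ", merged$class[!keep])),
    stringsAsFactors = FALSE)
  kept <- merged[keep, , drop = FALSE]
  if (nrow(kept) == 0) stop("cross_tabulate: empty after exclusions", call. = FALSE)
  clusters <- sort(unique(kept$cluster))
  counts <- table(factor(kept$cluster, levels = clusters),
                  factor(kept$class, levels = classes))
  counts <- unclass(counts)
  names(dimnames(counts)) <- NULL
  chi <- withCallingHandlers(
    chi_square_independence(counts),
    warning = function(w) invokeRestart("muffleWarning"))
  if (is.na(chi$p_value))
    warning("cross_tabulate: chi-square undefined for this table", call. = FALSE)
  col_tot <- colSums(counts)
  row_tot <- rowSums(counts)
  pct_class <- sweep(counts, 2, ifelse(col_tot > 0, col_tot, NA), "/") * 100
  pct_cluster <- sweep(counts, 1, ifelse(row_tot > 0, row_tot, NA), "/") * 100
  out <- list(counts = counts,
              pct_given_class = pct_class,
              pct_given_cluster = pct_cluster,
              chi2 = chi$chi2, df = chi$df, p_value = chi$p_value,
              excluded = excluded, horizon = horizon)
  class(out) <- "crosstab"
  out
}

#' Predictive values P(class | cluster)
#'
#' `within_cluster` (default) reads the probability of each clinical class
#' directly as its within-cluster proportion. `prevalence` applies Bayes'
#' rule to the per-class cluster rates `P(cluster | class)` weighted by a
#' class prevalence vector; with the observed prevalence the two modes
#' coincide exactly, and they also coincide for any table under a uniform
#' prevalence when the class totals are balanced.
#'
#' @param crosstab A `crosstab` from [cross_tabulate()].
#' @param mode `"within_cluster"` or `"prevalence"`.
#' @param prevalence Named class prevalence vector for `"prevalence"` mode;
#'   default the observed class frequencies.
#' @return Matrix (clusters x classes) of percentages; rows sum to 100.
#' @export
predictive_values <- function(crosstab, mode = c("within_cluster", "prevalence"),
                              prevalence = NULL) {
  mode <- match.arg(mode)
  counts <- crosstab$counts
  if (any(rowSums(counts) == 0))
    stop("predictive_values: empty cluster column", call. = FALSE)
  if (mode == "within_cluster") {
    return(sweep(counts, 1, rowSums(counts), "/") * 100)
  }
  if (is.null(prevalence)) {
    prevalence <- colSums(counts) / sum(counts)
  }
  prevalence <- prevalence[colnames(counts)] / sum(prevalence[colnames(counts)])
  lik <- crosstab$pct_given_class / 100  # P(cluster | class)
  post <- sweep(lik, 2, prevalence, "*")
  sweep(post, 1, rowSums(post), "/") * 100
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("Cross-tabulation (%s follow-up)\n", x$horizon))
  cat("Counts (cluster x class):\n")
  print(x$counts)
  cat("\nP(cluster | class), %:\n")
  print(round(x$pct_given_class, 2))
  cat("\nP(class | cluster), %:\n")
  print(round(x$pct_given_cluster, 2))
  if (!is.na(x$p_value)) {
    cat(sprintf("\nchi-square = %.3f, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  } else {
    cat("\nchi-square undefined for this table\n")
  }
  if (nrow(x$excluded) > 0)
    cat(sprintf("Excluded: %s\n",
                paste(sprintf("%s (%s)", x$excluded$patient_id, x$excluded$reason),
                      collapse = ", ")))
  invisible(x)
}
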