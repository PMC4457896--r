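#' Run the full stratification pipeline
#'
#' Executes the stages in order: `qc` (%Vol normalization, best-pair
#' replicate selection, profile aggregation), `cluster` (UPGMA over the
#' representative spots), `diff` (Mann-Whitney + fold-change differential
#' spots between the two main clusters), `discriminant` (marker-spot
#' two-spot and three-spot clusterings, LDA over the marker pair, Spearman
#' correlation of the marker spots), and `evaluate` (cluster vs clinical
#' class cross-tabulations and predictive values at both horizons).
#' Stage errors are re-signalled with the stage name.
#'
#' @param spot_table A `spot_replicate_table` (or `NULL` when starting from
#'   `evaluate` with a precomputed `clusters` table).
#' @param clinical A `clinical_table`, required for `evaluate`.
#' @param config A `run_config`.
#' @param stages Character vector of stages to run (a prefix of the stage
#'   order above; `evaluate` can also run alone from `clusters`).
#' @param marker_spots The DBP isoform spot pair (default `c("288", "289")`).
#' @param apoe_spot The ApoE spot (default `"469"`).
#' @param clusters Optional precomputed assignment data frame with columns
#'   `patient_id`, `cluster2`, `cluster3` (two- and three-spot cluster
#'   labels), used when `evaluate` runs without the upstream stages.
#' @param seed Seed echoed into the manifest (the pipeline itself is
#'   deterministic).
#' @param input_digests Optional named md5 digests of the input files.
#' @return A `stratification_report` list; see [write_report()].
#' @export
run_stratification <- function(spot_table = NULL, clinical = NULL,
                               config = run_config(),
                               stages = c("qc", "cluster", "diff",
                                          "discriminant", "evaluate"),
                               marker_spots = c("288", "289"),
                               apoe_spot = "469",
                               clusters = NULL,
                               seed = NA_integer_,
                               input_digests = list()) {
  all_stages <- c("qc", "cluster", "diff", "discriminant", "evaluate")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- all_stages[all_stages %in% stages]
  stage_err <- function(name, e) {
    stop(sprintf("stage %s: %s", name, conditionMessage(e)), call. = FALSE)
  }
  report <- list(config = config, seed = seed, input_digests = input_digests,
                 stage_counts = list(), crosstabs = list())
  profiles <- NULL
  marker_assign <- NULL
  threespot_assign <- NULL

  if ("qc" %in% stages) {
    tryCatch({
      if (is.null(spot_table)) stop("spot table required")
      pvols <- compute_percent_vol(spot_table)
      bp <- build_profiles(pvols, best_pair_max = config$best_pair_max)
      profiles <- bp$profiles
      report$profiles <- profiles
      report$qc <- bp$qc
      report$stage_counts$patients <- length(profiles)
    }, error = function(e) stage_err("qc", e))
  }

  if ("cluster" %in% stages) {
    tryCatch({
      if (is.null(profiles)) stop("qc stage must run first")
      rep_spots <- select_representative_spots(profiles, config$presence_fraction)
      if (length(rep_spots) < 1) stop("no representative spots")
      dend <- upgma(euclidean_distance_matrix(profiles, rep_spots))
      report$representative_spots <- rep_spots
      report$main_dendrogram <- dend
      report$main_assignment <- extract_clusters(dend, config$k_main_clusters,
                                                 config$outlier_max_size)
      report$stage_counts$representative_spots <- length(rep_spots)
      report$stage_counts$main_clusters <-
        length(setdiff(unique(report$main_assignment$cluster), "OUTLIER"))
    }, error = function(e) stage_err("cluster", e))
  }

  if ("diff" %in% stages) {
    tryCatch({
      diff_tab <- select_differential_spots(
        profiles, report$main_assignment, "C1", "C2",
        spots = report$representative_spots,
        p_threshold = config$p_threshold, fc_threshold = config$fc_threshold)
      report$differential <- diff_tab
      report$stage_counts$differential_selected <- sum(diff_tab$selected)
    }, error = function(e) stage_err("diff", e))
  }

  if ("discriminant" %in% stages) {
    tryCatch({
      marker_assign <- extract_clusters(
        upgma(euclidean_distance_matrix(profiles, marker_spots)),
        2L, config$outlier_max_size)
      threespot_assign <- extract_clusters(
        upgma(euclidean_distance_matrix(profiles, c(marker_spots, apoe_spot))),
        3L, config$outlier_max_size)
      report$marker_assignment <- marker_assign
      report$threespot_assignment <- threespot_assign
      m <- profiles_to_matrix(profiles, marker_spots)
      report$marker_spearman <- spearman(m[, 1], m[, 2])
      fit <- tryCatch(fit_discriminant(profiles, marker_assign, marker_spots),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        warning("discriminant fit skipped: ", conditionMessage(fit), call. = FALSE)
      } else {
        report$discriminant <- fit
      }
    }, error = function(e) stage_err("discriminant", e))
  }

  if ("evaluate" %in% stages) {
    tryCatch({
      if (is.null(clinical)) stop("clinical table required")
      if (is.null(marker_assign) && !is.null(clusters)) {
        marker_assign <- as_assignment(clusters, "cluster2")
        threespot_assign <- as_assignment(clusters, "cluster3")
        report$marker_assignment <- marker_assign
        report$threespot_assignment <- threespot_assign
      }
      if (is.null(marker_assign)) stop("no cluster assignment available")
      for (h in c("2y", "5y")) {
        report$crosstabs[[paste0("two_spot_", h)]] <-
          cross_tabulate(marker_assign, clinical, h)
        report$crosstabs[[paste0("three_spot_", h)]] <-
          cross_tabulate(threespot_assign, clinical, h)
      }
    }, error = function(e) stage_err("evaluate", e))
  }

  ct <- list()
  if (!is.null(report$main_assignment))
    ct$main <- data.frame(patient_id = report$main_assignment$patient_id,
                          clustering = "representative",
                          cluster = report$main_assignment$cluster)
  if (!is.null(report$marker_assignment))
    ct$two <- data.frame(patient_id = report$marker_assignment$patient_id,
                         clustering = "two_spot",
                         cluster = report$marker_assignment$cluster)
  if (!is.null(report$threespot_assignment))
    ct$three <- data.frame(patient_id = report$threespot_assignment$patient_id,
                           clustering = "three_spot",
                           cluster = report$threespot_assignment$cluster)
  if (length(ct) > 0)
    report$cluster_table <- do.call(rbind, c(ct, make.row.names = FALSE))
  report$stages_run <- stages
  class(report) <- "stratification_report"
  report
}

# coerce a patient_id + label column pair into a cluster_assignment
as_assignment <- function(df, column) {
  stopifnot(all(c("patient_id", column) %in% names(df)))
  out <- data.frame(patient_id = as.character(df$patient_id),
                    cluster = ifelse(df[[column]] %in% c("OUT", "OUTLIER"),
                                     "OUTLIER", as.character(df[[column]])),
                    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("Stratification report\n")
  cat("  stages run:", paste(x$stages_run, collapse = ", "), "\n")
  for (nm in names(x$stage_counts))
    cat(sprintf("  %s: %s\n", nm, x$stage_counts[[nm]]))
  if (!is.null(x$marker_spearman))
    cat(sprintf("  marker Spearman rho = %.3f (p = %.4g)\n",
                x$marker_spearman$rho, x$marker_spearman$p_value))
  for (nm in names(x$crosstabs)) {
    ctab <- x$crosstabs[[nm]]
    cat(sprintf("  %s: chi2 = %s, p = %s\n", nm,
                format(round(ctab$chi2, 3)), format(signif(ctab$p_value, 2))))
  }
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{simulate}{`--config FILE --out-dir DIR [--seed N]` — generate a
#'     synthetic cohort (spot table, clinical table, planted truth).}
#'   \item{run}{`--spots FILE --clinical FILE --out-dir DIR
#'     [--stages qc,cluster,diff,discriminant,evaluate] [--clusters FILE]
#'     [--marker-spots 288,289] [--apoe-spot 469] [--seed N]` — run the
#'     pipeline and write a report directory.}
#' }
#' An executable wrapper is installed at `exec/csfstrat` inside the package.
#'
#' @param args Character vector of arguments (default: the command line).
#' @return Invisibly, the result object of the subcommand.
#' @export
stratify_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) stop("usage: simulate|run ...", call. = FALSE)
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  switch(cmd,
         simulate = cli_simulate(opts),
         run = cli_run(opts),
         stop("unknown subcommand: ", cmd, call. = FALSE))
}

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1], "--"))
      stop("flag --", key, " needs a value", call. = FALSE)
    opts[[gsub("-", "_", key)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

need_opt <- function(opts, key) {
  if (is.null(opts[[key]]))
    stop("missing required flag --", gsub("_", "-", key), call. = FALSE)
  opts[[key]]
}

cli_simulate <- function(opts) {
  cfg <- read_cohort_config(need_opt(opts, "config"))
  if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
  out_dir <- need_opt(opts, "out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(cfg)
  paths <- file.path(out_dir, c("spots.tsv", "clinical.tsv", "truth.tsv"))
  write_spot_table(cohort$spots, paths[1])
  write_clinical_table(cohort$clinical, paths[2])
  write_truth(cohort$truth, paths[3])
  message(sprintf("simulate: %d patients, %d spot rows -> %s",
                  nrow(cohort$clinical), nrow(cohort$spots), out_dir))
  invisible(list(paths = paths, config = cfg))
}

cli_run <- function(opts) {
  stages <- if (is.null(opts$stages)) c("qc", "cluster", "diff", "discriminant", "evaluate")
            else strsplit(opts$stages, ",", fixed = TRUE)[[1]]
  spot_table <- NULL
  clinical <- NULL
  clusters <- NULL
  digests <- list()
  if (!is.null(opts$spots)) {
    spot_table <- read_spot_table(opts$spots)
    digests$spots <- unname(tools::md5sum(opts$spots))
  } else if (any(c("qc", "cluster", "diff", "discriminant") %in% stages)) {
    need_opt(opts, "spots")
  }
  if (!is.null(opts$clinical)) {
    clinical <- read_clinical_table(opts$clinical)
    digests$clinical <- unname(tools::md5sum(opts$clinical))
  }
  if (!is.null(opts$clusters)) {
    clusters <- utils::read.delim(opts$clusters, colClasses = "character")
    digests$clusters <- unname(tools::md5sum(opts$clusters))
  }
  marker_spots <- if (is.null(opts$marker_spots)) c("288", "289")
                  else strsplit(opts$marker_spots, ",", fixed = TRUE)[[1]]
  apoe_spot <- if (is.null(opts$apoe_spot)) "469" else opts$apoe_spot
  report <- run_stratification(
    spot_table = spot_table, clinical = clinical, config = run_config(),
    stages = stages, marker_spots = marker_spots, apoe_spot = apoe_spot,
    clusters = clusters,
    seed = if (is.null(opts$seed)) NA_integer_ else as.integer(opts$seed),
    input_digests = digests)
  out_dir <- need_opt(opts, "out_dir")
  write_report(report, out_dir)
  message(sprintf("run: stages [%s] -> %s",
                  paste(report$stages_run, collapse = ", "), out_dir))
  invisible(report)
}
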