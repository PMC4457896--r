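#' @details
#' All tables move through the package as plain tab-separated files (UTF-8,
#' header row, locale-independent decimal points). Spot quantifications are
#' kept in long (tidy) format so a spot that was not detected on a gel is
#' representable by absence rather than by a sentinel value.
#' @keywords internal
"_PACKAGE"

CLASS_TOKENS <- c("H", "M", "L", "LB", "PP", "lost", "no_MS", "death")
DMT_TOKENS <- c("none", "I", "II", "lost", "death", "no_MS")

#' Default thresholds for a stratification run
#'
#' Collects every tunable threshold used downstream, with the defaults used
#' throughout the package. The configuration is echoed verbatim into the run
#' summary so a report is always interpretable without the call that made it.
#'
#' @param sd_accept_max Replicate sets whose best-pair mean %SD exceeds this
#'   fraction are considered failed acquisitions (default 0.32).
#' @param best_pair_max Best replicate pairs above this mean %SD fraction are
#'   flagged `needs_new_replicate` (default 0.30).
#' @param presence_fraction Minimum fraction of patients in which a spot must
#'   be quantified to enter the representative set (default 1.0).
#' @param p_threshold Mann-Whitney two-sided significance threshold
#'   (default 0.05).
#' @param fc_threshold Fold-change selection threshold (default 1.5).
#' @param k_main_clusters Number of main clusters to extract (default 2).
#' @param outlier_max_size Branches of at most this many patients are labeled
#'   outliers when cutting the dendrogram (default 1).
#' @param phospho_ds_threshold Phospho/total stain ratio below which a spot is
#'   called not phosphorylated (default 0.08).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(sd_accept_max = 0.32,
                       best_pair_max = 0.30,
                       presence_fraction = 1.0,
                       p_threshold = 0.05,
                       fc_threshold = 1.5,
                       k_main_clusters = 2L,
                       outlier_max_size = 1L,
                       phospho_ds_threshold = 0.08) {
  cfg <- list(
    sd_accept_max = sd_accept_max,
    best_pair_max = best_pair_max,
    presence_fraction = presence_fraction,
    p_threshold = p_threshold,
    fc_threshold = fc_threshold,
    k_main_clusters = as.integer(k_main_clusters),
    outlier_max_size = as.integer(outlier_max_size),
    phospho_ds_threshold = phospho_ds_threshold
  )
  stopifnot(
    cfg$sd_accept_max > 0, cfg$best_pair_max > 0,
    cfg$presence_fraction >= 0, cfg$presence_fraction <= 1,
    cfg$p_threshold > 0, cfg$p_threshold <= 1,
    cfg$fc_threshold >= 1,
    cfg$k_main_clusters >= 1L, cfg$outlier_max_size >= 0L,
    cfg$phospho_ds_threshold > 0
  )
  class(cfg) <- "run_config"
  cfg
}

stop_io <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Validate a replicate-level spot volume table
#'
#' @param df Data frame with columns `patient_id`, `replicate_index`,
#'   `spot_id`, `raw_volume`.
#' @return The validated table, classed `spot_replicate_table`.
#' @export
as_spot_table <- function(df) {
  required <- c("patient_id", "replicate_index", "spot_id", "raw_volume")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_io("spot table: missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$patient_id <- as.character(df$patient_id)
  df$spot_id <- as.character(df$spot_id)
  if (anyNA(suppressWarnings(as.numeric(df$raw_volume))))
    stop_io("spot table: non-numeric raw_volume at line(s) %s",
            paste(which(is.na(suppressWarnings(as.numeric(df$raw_volume)))) + 1L, collapse = ", "))
  df$raw_volume <- as.numeric(df$raw_volume)
  ri <- suppressWarnings(as.integer(df$replicate_index))
  if (anyNA(ri) || any(ri < 0L))
    stop_io("spot table: replicate_index must be a 0-based integer")
  df$replicate_index <- ri
  bad <- which(!is.finite(df$raw_volume) | df$raw_volume <= 0)
  if (length(bad) > 0)
    stop_io("spot table: raw_volume must be > 0 (line %d: %s)",
            bad[1] + 1L, format(df$raw_volume[bad[1]]))
  key <- paste(df$patient_id, df$replicate_index, df$spot_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop_io("spot table: duplicate key (%s, %d, %s) at line %d",
            df$patient_id[dup[1]], df$replicate_index[dup[1]],
            df$spot_id[dup[1]], dup[1] + 1L)
  rownames(df) <- NULL
  class(df) <- c("spot_replicate_table", "data.frame")
  df
}

#' Read a replicate-level spot volume table
#'
#' Expects a TSV with header `patient_id`, `replicate_index` (0-based),
#' `spot_id`, `raw_volume` (arbitrary densitometry units, strictly positive).
#' Schema violations are reported with the offending 1-based file line.
#'
#' @param path Path to a TSV file.
#' @return A `spot_replicate_table` data frame.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop_io("spot table: no such file: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  as_spot_table(df)
}

#' Write a spot volume table
#' @param table A `spot_replicate_table`.
#' @param path Output TSV path.
#' @export
write_spot_table <- function(table, path) {
  write_tsv(as.data.frame(table), path)
}

#' Validate a clinical metadata table
#'
#' @param df Data frame with columns `patient_id`, `edss_at_lp`, `delta_edss`,
#'   `relapse_count`, `dmt_2y`, `dmt_5y`, `class_2y`, `class_5y`.
#' @return The validated table, classed `clinical_table`.
#' @export
as_clinical_table <- function(df) {
  required <- c("patient_id", "edss_at_lp", "delta_edss", "relapse_count",
                "dmt_2y", "dmt_5y", "class_2y", "class_5y")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop_io("clinical table: missing column(s): %s", paste(missing_cols, collapse = ", "))
  df <- df[required]
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop_io("clinical table: duplicate patient_id %s",
            df$patient_id[duplicated(df$patient_id)][1])
  num_or_na <- function(x) suppressWarnings(as.numeric(x))
  df$edss_at_lp <- num_or_na(df$edss_at_lp)
  df$delta_edss <- num_or_na(df$delta_edss)
  # unknown relapse counts ("?") are preserved as NA, never coerced to zero
  rc <- as.character(df$relapse_count)
  rc[rc %in% c("?", "", "NA", "lost", "no_MS")] <- NA
  df$relapse_count <- suppressWarnings(as.integer(rc))
  for (col in c("dmt_2y", "dmt_5y")) {
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), DMT_TOKENS)
    if (length(bad) > 0)
      stop_io("clinical table: unknown %s token \"%s\"", col, bad[1])
  }
  for (col in c("class_2y", "class_5y")) {
    df[[col]] <- as.character(df[[col]])
    bad <- setdiff(unique(df[[col]]), CLASS_TOKENS)
    if (length(bad) > 0)
      stop_io("clinical table: unknown %s token \"%s\"", col, bad[1])
  }
  # benign course is by definition untreated
  for (h in c("2y", "5y")) {
    cls <- df[[paste0("class_", h)]]
    dmt <- df[[paste0("dmt_", h)]]
    offending <- which(cls == "LB" & dmt != "none")
    if (length(offending) > 0)
      stop_io("clinical table: patient %s classed LB at %s but dmt is %s",
              df$patient_id[offending[1]], h, dmt[offending[1]])
  }
  rownames(df) <- NULL
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical metadata table
#'
#' One row per patient. Disease-modifying treatment (DMT) lines are `none`,
#' `I` (interferon beta / glatiramer acetate), `II` (natalizumab /
#' fingolimod), or the bookkeeping tokens `lost`, `death`, `no_MS`.
#' Clinical classes are `H`/`M`/`L`/`LB` plus the excluded tokens `PP`,
#' `lost`, `no_MS`, `death`. Unknown relapse counts (`?`) are kept as NA.
#'
#' @param path Path to a TSV file.
#' @return A `clinical_table` data frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop_io("clinical table: no such file: %s", path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  as_clinical_table(df)
}

#' Write a clinical metadata table
#' @param table A `clinical_table`.
#' @param path Output TSV path.
#' @export
write_clinical_table <- function(table, path) {
  df <- as.data.frame(table)
  df$relapse_count <- ifelse(is.na(df$relapse_count), "?", as.character(df$relapse_count))
  write_tsv(df, path)
}

# deterministic TSV writer: fixed column order, full double precision,
# "." decimal separator regardless of locale
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      x <- formatC(df[[col]], digits = 17, format = "g")
      x[is.na(df[[col]])] <- "NA"
      df[[col]] <- x
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a stratification report directory
#'
#' Writes four TSV result files (`differential.tsv`, `clusters.tsv`,
#' `crosstabs.tsv`, `predictive_values.tsv`) plus `summary.json` carrying the
#' configuration echo, package/R versions, seed, and md5 digests of inputs
#' and outputs. Output is deterministic: rerunning on identical inputs and
#' configuration yields byte-identical files (no timestamps).
#'
#' @param report A `stratification_report`, see [run_stratification()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "stratification_report"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_io("write_report: cannot create directory %s", dir)
  }
  paths <- file.path(dir, c("differential.tsv", "clusters.tsv",
                            "crosstabs.tsv", "predictive_values.tsv"))
  names(paths) <- c("differential", "clusters", "crosstabs", "predictive")

  diff_df <- report$differential
  if (is.null(diff_df)) {
    diff_df <- data.frame(spot_id = character(), mean_a = double(), sd_a = double(),
                          mean_b = double(), sd_b = double(), p_value = double(),
                          fold_change = double(), direction = character(),
                          significant = logical(), fc_pass = logical(),
                          selected = logical())
  }
  write_tsv(diff_df, paths["differential"])

  cl_df <- report$cluster_table
  if (is.null(cl_df)) {
    cl_df <- data.frame(patient_id = character(), clustering = character(),
                        cluster = character())
  }
  write_tsv(cl_df, paths["clusters"])

  write_tsv(crosstabs_long(report$crosstabs), paths["crosstabs"])
  write_tsv(predictive_long(report$crosstabs), paths["predictive"])

  summary_path <- file.path(dir, "summary.json")
  manifest <- list(
    package = "csfstrat",
    package_version = as.character(utils::packageVersion("csfstrat")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = report$seed,
    config = unclass(report$config),
    stage_counts = report$stage_counts,
    input_digests = report$input_digests,
    output_digests = as.list(tools::md5sum(paths))
  )
  names(manifest$output_digests) <- basename(paths)
  jsonlite::write_json(manifest, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(c(paths, summary = summary_path))
}

crosstabs_long <- function(crosstabs) {
  empty <- data.frame(horizon = character(), clustering = character(),
                      cluster = character(), class = character(),
                      count = integer(), pct_given_class = double(),
                      pct_given_cluster = double(), chi2 = double(),
                      df = integer(), p_value = double())
  if (is.null(crosstabs) || length(crosstabs) == 0) return(empty)
  out <- lapply(names(crosstabs), function(nm) {
    ct <- crosstabs[[nm]]
    counts <- ct$counts
    grid <- expand.grid(cluster = rownames(counts), class = colnames(counts),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(horizon = ct$horizon, clustering = nm, grid,
               count = as.integer(counts[as.matrix(grid)]),
               pct_given_class = ct$pct_given_class[as.matrix(grid)],
               pct_given_cluster = ct$pct_given_cluster[as.matrix(grid)],
               chi2 = ct$chi2, df = ct$df, p_value = ct$p_value)
  })
  do.call(rbind, out)
}

predictive_long <- function(crosstabs) {
  empty <- data.frame(horizon = character(), clustering = character(),
                      cluster = character(), class = character(),
                      predictive_value_pct = double())
  if (is.null(crosstabs) || length(crosstabs) == 0) return(empty)
  out <- lapply(names(crosstabs), function(nm) {
    ct <- crosstabs[[nm]]
    pv <- predictive_values(ct)
    grid <- expand.grid(cluster = rownames(pv), class = colnames(pv),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(horizon = ct$horizon, clustering = nm, grid,
               predictive_value_pct = pv[as.matrix(grid)])
  })
  do.call(rbind, out)
}
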