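#' Configure a synthetic 2-DE cohort
#'
#' Builds the configuration for [generate_cohort()]. Defaults emulate the
#' structure of a 24-patient CSF 2-DE study: triplicate technical replicates
#' with per-patient mean replicate variability (%SD) in the 17-32% range,
#' 236 class-independent background spots plus three marker spots — two
#' vitamin D binding protein (DBP) isoform spots ("288", "289") whose
#' abundances are anti-correlated across patients because they partition a
#' common total, and one apolipoprotein E (ApoE) spot ("469") shifted by
#' clinical class.
#'
#' The marker model draws, per patient, a total DBP abundance `T` (log-normal)
#' and a modified fraction `phi` (Beta, class-dependent mean); the latent
#' %Vol of spot "289" is `T * phi` and of spot "288" is `T * (1 - phi)`, so
#' aggressive-class patients (high `phi`) carry low 288 / high 289.
#'
#' @param class_counts Named integer vector of patients per clinical class.
#'   Recognized labels: `H`, `M`, `L`, `LB`, `PP`, `death`, `lost`, `no_MS`,
#'   `other` (`other` cycles through the four excluded fates).
#' @param n_background_spots Number of class-independent spots (default 236,
#'   so the default map carries 239 spots in total).
#' @param replicate_count Technical replicates per patient (default 3).
#' @param replicate_cv_range Range the per-patient target mean %SD (as a
#'   fraction) is drawn from, default `c(0.17, 0.32)`.
#' @param isoform_params List with `total_meanlog`, `total_sdlog` (log-normal
#'   of total DBP %Vol) and `phi_mean` (named per-class Beta means),
#'   `phi_concentration`.
#' @param apoe_params List with named per-class `meanlog` and scalar `sdlog`
#'   for the ApoE spot.
#' @param background_baseline_sdlog Spread of per-spot baseline abundances
#'   (log scale) across the background spots.
#' @param background_sdlog Patient-to-patient biological spread of each
#'   background spot (log scale).
#' @param dropout_background Per-gel probability that a background spot is
#'   not detected (default 0.05).
#' @param dropout_marker Per-gel dropout probability for the marker spots
#'   (default 0: markers are always detected).
#' @param gel_scale_meanlog,gel_scale_sdlog Log-normal total-volume scale of
#'   each gel (arbitrary densitometry units; cancels under %Vol).
#' @param marker_spots,apoe_spot Spot identifiers of the DBP pair and ApoE.
#' @param seed Integer seed; the generator derives one substream per patient
#'   so adding patients does not perturb earlier patients' draws.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(class_counts = c(H = 5L, M = 10L, L = 5L, other = 4L),
                          n_background_spots = 236L,
                          replicate_count = 3L,
                          replicate_cv_range = c(0.17, 0.32),
                          isoform_params = list(
                            total_meanlog = log(0.35),
                            total_sdlog = 0.20,
                            phi_mean = c(H = 0.70, M = 0.50, L = 0.30, other = 0.50),
                            phi_concentration = 12),
                          apoe_params = list(
                            meanlog = c(H = log(0.28), M = log(0.13),
                                        L = log(0.08), other = log(0.13)),
                            sdlog = 0.45),
                          background_baseline_sdlog = 1.0,
                          background_sdlog = 0.4,
                          dropout_background = 0.05,
                          dropout_marker = 0,
                          gel_scale_meanlog = log(1e6),
                          gel_scale_sdlog = 0.2,
                          marker_spots = c("288", "289"),
                          apoe_spot = "469",
                          seed = 1L) {
  known <- c("H", "M", "L", "LB", "PP", "death", "lost", "no_MS", "other")
  bad <- setdiff(names(class_counts), known)
  if (is.null(names(class_counts)) || length(bad) > 0)
    stop("invalid class label in class_counts: ",
         paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
         call. = FALSE)
  class_counts <- vapply(class_counts, as.integer, integer(1))
  if (any(class_counts < 0L) || sum(class_counts) < 1L)
    stop("class_counts must be non-negative and sum to at least 1", call. = FALSE)
  stopifnot(
    length(replicate_cv_range) == 2,
    replicate_cv_range[1] >= 0, replicate_cv_range[2] < 1,
    replicate_cv_range[1] <= replicate_cv_range[2],
    n_background_spots >= 0, replicate_count >= 1,
    dropout_background >= 0, dropout_background < 1,
    dropout_marker >= 0, dropout_marker < 1
  )
  cfg <- list(class_counts = class_counts,
              n_patients = sum(class_counts),
              n_background_spots = as.integer(n_background_spots),
              replicate_count = as.integer(replicate_count),
              replicate_cv_range = as.numeric(replicate_cv_range),
              isoform_params = isoform_params,
              apoe_params = apoe_params,
              background_baseline_sdlog = background_baseline_sdlog,
              background_sdlog = background_sdlog,
              dropout_background = dropout_background,
              dropout_marker = dropout_marker,
              gel_scale_meanlog = gel_scale_meanlog,
              gel_scale_sdlog = gel_scale_sdlog,
              marker_spots = as.character(marker_spots),
              apoe_spot = as.character(apoe_spot),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# map a clinical label onto the parameter class used for marker draws
param_class <- function(label) {
  switch(label, H = "H", M = "M", L = "L", LB = "L", "other")
}

# per-patient substream: patient i of base seed s always sees the same RNG
# state, independent of cohort size (i = 0 is the cohort-level stream)
substream_seed <- function(seed, i) {
  (abs(as.integer(seed)) %% 1000000L) * 2000L + as.integer(i)
}

# E[sample SD]/sigma for a normal sample of size n; used to unbias the
# replicate noise so the drawn target equals the expected observed mean %SD
c4_const <- function(n) {
  if (n < 2) return(NA_real_)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

#' Generate a synthetic replicate-level cohort
#'
#' Draws latent per-patient %Vol profiles (markers as described in
#' [cohort_config()], background spots log-normal and class-independent),
#' normalizes each profile to sum to 100, then emits `replicate_count` gels
#' per patient: each gel multiplies the profile by a log-normal total-volume
#' scale and by per-spot multiplicative log-normal noise whose magnitude is
#' calibrated so the expected mean %SD across replicates equals a per-patient
#' target drawn from `replicate_cv_range`. Background spots drop out of a gel
#' independently with probability `dropout_background`.
#'
#' The same configuration (including seed) always produces byte-identical
#' tables.
#'
#' @param config A `cohort_config`.
#' @return A list with `spots` (a `spot_replicate_table`), `clinical`
#'   (a `clinical_table`) and `truth` (a `planted_truth` data frame holding
#'   each patient's class, latent total DBP, modified fraction, ApoE level and
#'   expected marker %Vol values).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cc <- config$class_counts[config$class_counts > 0L]
  classes <- rep(names(cc), cc)
  n <- length(classes)
  ids <- sprintf("P%02d", seq_len(n))

  # cohort-level stream: background spot catalog
  set.seed(substream_seed(config$seed, 0L))
  reserved <- c(config$marker_spots, config$apoe_spot)
  candidates <- setdiff(as.character(seq_len(config$n_background_spots + length(reserved) + 50L)),
                        reserved)
  bg_ids <- candidates[seq_len(config$n_background_spots)]
  bg_baseline <- stats::rnorm(config$n_background_spots, 0, config$background_baseline_sdlog)

  iso <- config$isoform_params
  apo <- config$apoe_params
  nrep <- config$replicate_count
  c4 <- c4_const(max(nrep, 2L))
  other_cycle <- c("PP", "death", "lost", "no_MS")
  n_other_seen <- 0L

  spot_rows <- vector("list", n)
  clin_rows <- vector("list", n)
  truth_rows <- vector("list", n)

  for (i in seq_len(n)) {
    set.seed(substream_seed(config$seed, i))
    cls <- classes[i]
    if (cls == "other") {
      n_other_seen <- n_other_seen + 1L
      cls <- other_cycle[(n_other_seen - 1L) %% length(other_cycle) + 1L]
    }
    pc <- param_class(cls)

    total <- stats::rlnorm(1, iso$total_meanlog, iso$total_sdlog)
    mu <- iso$phi_mean[[pc]]
    k <- iso$phi_concentration
    phi <- stats::rbeta(1, mu * k, (1 - mu) * k)
    apoe <- stats::rlnorm(1, apo$meanlog[[pc]], apo$sdlog)

    bg <- stats::rlnorm(config$n_background_spots, bg_baseline, config$background_sdlog)
    bg <- bg * (100 - total - apoe) / sum(bg)
    latent <- c(total * (1 - phi), total * phi, apoe, bg)
    spot_ids <- c(config$marker_spots, config$apoe_spot, bg_ids)
    n_spots <- length(latent)

    cv_target <- stats::runif(1, config$replicate_cv_range[1], config$replicate_cv_range[2])
    sdlog_noise <- if (cv_target <= 0) 0 else sqrt(log1p((cv_target / c4)^2))

    drop_p <- c(rep(config$dropout_marker, 3L),
                rep(config$dropout_background, config$n_background_spots))
    keep_list <- vector("list", nrep)
    vol_list <- vector("list", nrep)
    for (r in seq_len(nrep)) {
      # fixed draw order per replicate keeps the stream layout documented:
      # gel scale, then per-spot noise, then per-spot dropout
      gscale <- stats::rlnorm(1, config$gel_scale_meanlog, config$gel_scale_sdlog)
      noise <- if (sdlog_noise > 0) stats::rlnorm(n_spots, 0, sdlog_noise) else rep(1, n_spots)
      keep <- stats::runif(n_spots) >= drop_p
      keep_list[[r]] <- keep
      vol_list[[r]] <- latent[keep] * noise[keep] * gscale
    }
    n_kept <- vapply(keep_list, sum, integer(1))
    spot_rows[[i]] <- data.frame(
      patient_id = ids[i],
      replicate_index = rep(seq_len(nrep) - 1L, n_kept),
      spot_id = unlist(lapply(keep_list, function(k) spot_ids[k])),
      raw_volume = unlist(vol_list),
      stringsAsFactors = FALSE)

    clin_rows[[i]] <- synth_clinical_row(ids[i], cls)
    truth_rows[[i]] <- data.frame(patient_id = ids[i], class = cls,
                                  total_dbp = total, phi = phi, apoe = apoe,
                                  spot288_expected = total * (1 - phi),
                                  spot289_expected = total * phi,
                                  spot469_expected = apoe,
                                  stringsAsFactors = FALSE)
  }

  spots <- as_spot_table(do.call(rbind, spot_rows))
  clinical <- as_clinical_table(do.call(rbind, clin_rows))
  truth <- do.call(rbind, truth_rows)
  class(truth) <- c("planted_truth", "data.frame")
  list(spots = spots, clinical = clinical, truth = truth)
}

# deterministic clinical record consistent with the class-assignment rules:
# second-line DMT for aggressive, first-line for moderate, none for low/benign
synth_clinical_row <- function(id, cls) {
  map <- switch(cls,
    H = list(dmt = c("II", "II"), cl = c("H", "H"), edss = c(0, 6), delta = c(0, 5), lam = 3),
    M = list(dmt = c("I", "I"), cl = c("M", "M"), edss = c(0, 4), delta = c(0, 1), lam = 1.5),
    L = list(dmt = c("none", "none"), cl = c("L", "L"), edss = c(0, 2), delta = c(0, 0), lam = 0.3),
    LB = list(dmt = c("none", "none"), cl = c("LB", "LB"), edss = c(0, 2), delta = c(0, 0), lam = 0.1),
    PP = list(dmt = c("none", "none"), cl = c("PP", "PP"), edss = c(3, 6), delta = c(0, 1), lam = 0),
    death = list(dmt = c("I", "death"), cl = c("M", "death"), edss = c(0, 4), delta = c(0, 1), lam = 1),
    lost = list(dmt = c("lost", "lost"), cl = c("lost", "lost"), edss = c(0, 4), delta = c(0, 0), lam = NA),
    no_MS = list(dmt = c("no_MS", "no_MS"), cl = c("no_MS", "no_MS"), edss = c(0, 1), delta = c(0, 0), lam = NA)
  )
  relapse <- if (is.na(map$lam)) NA_integer_ else stats::rpois(1, map$lam)
  data.frame(patient_id = id,
             edss_at_lp = round(stats::runif(1, map$edss[1], map$edss[2]) * 2) / 2,
             delta_edss = round(stats::runif(1, map$delta[1], map$delta[2]) * 2) / 2,
             relapse_count = relapse,
             dmt_2y = map$dmt[1], dmt_5y = map$dmt[2],
             class_2y = map$cl[1], class_5y = map$cl[2],
             stringsAsFactors = FALSE)
}

#' Write or read a planted-truth table
#'
#' TSVs round-trip losslessly (doubles written with 17 significant digits).
#'
#' @param truth A `planted_truth` data frame from [generate_cohort()].
#' @param path TSV path.
#' @return `write_truth` returns the path invisibly; `read_truth` the table.
#' @export
write_truth <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  write_tsv(as.data.frame(truth), path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_io("truth table: no such file: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character", class = "character"))
  class(df) <- c("planted_truth", "data.frame")
  df
}

#' Read a flat key:value cohort configuration file
#'
#' Accepts a minimal YAML-style file of `key: value` lines (`#` comments
#' allowed). Recognized keys: `seed`, `class_counts` (e.g. `H=5,M=10,L=5`),
#' `n_background_spots`, `replicate_count`, `replicate_cv_low`,
#' `replicate_cv_high`, `dropout_background`, `dropout_marker`. `seed` and
#' `class_counts` are required; unknown keys are an error.
#'
#' @param path Path to the config file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop_io("config: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) stop_io("config: unparseable line: %s", lines[bad[1]])
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  known <- c("seed", "class_counts", "n_background_spots", "replicate_count",
             "replicate_cv_low", "replicate_cv_high",
             "dropout_background", "dropout_marker")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) stop_io("config: unknown key: %s", unknown[1])
  for (req in c("seed", "class_counts")) {
    if (!req %in% keys) stop_io("config: missing config key: %s", req)
  }
  get <- function(k, default = NULL) if (k %in% keys) vals[match(k, keys)] else default
  parse_counts <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*([0-9]+)\\s*$", parts))
    if (any(lengths(m) != 3)) stop_io("config: unparseable class_counts: %s", s)
    stats::setNames(as.integer(vapply(m, `[`, "", 3L)), vapply(m, `[`, "", 2L))
  }
  defaults <- cohort_config()
  cohort_config(
    class_counts = parse_counts(get("class_counts")),
    n_background_spots = as.integer(get("n_background_spots", defaults$n_background_spots)),
    replicate_count = as.integer(get("replicate_count", defaults$replicate_count)),
    replicate_cv_range = c(as.numeric(get("replicate_cv_low", defaults$replicate_cv_range[1])),
                           as.numeric(get("replicate_cv_high", defaults$replicate_cv_range[2]))),
    dropout_background = as.numeric(get("dropout_background", defaults$dropout_background)),
    dropout_marker = as.numeric(get("dropout_marker", defaults$dropout_marker)),
    seed = as.integer(get("seed"))
  )
}
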