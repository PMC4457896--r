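#' Normalize raw spot volumes to %Vol
#'
#' Within each gel (patient x replicate), each spot volume is expressed as a
#' percentage of the total volume of all matched spots on that gel:
#' `%Vol_i = 100 * volume_i / sum_j volume_j`. This is the abundance unit of
#' the whole pipeline; it makes gels comparable regardless of loading and
#' staining intensity. The operation is idempotent up to the scale of 100.
#'
#' @param table A `spot_replicate_table`.
#' @return A long data frame (`percent_vol_map`) with columns `patient_id`,
#'   `replicate_index`, `spot_id`, `pct_vol`; each gel's `pct_vol` sums to 100.
#' @export
compute_percent_vol <- function(table) {
  stopifnot(inherits(table, "spot_replicate_table") || is.data.frame(table))
  if (nrow(table) == 0) stop("compute_percent_vol: empty table", call. = FALSE)
  gel <- interaction(table$patient_id, table$replicate_index, drop = TRUE)
  totals <- tapply(table$raw_volume, gel, sum)
  out <- data.frame(patient_id = table$patient_id,
                    replicate_index = table$replicate_index,
                    spot_id = table$spot_id,
                    pct_vol = 100 * table$raw_volume / as.numeric(totals[gel]),
                    stringsAsFactors = FALSE)
  class(out) <- c("percent_vol_map", "data.frame")
  out
}

# spots x replicates %Vol matrix for one patient (NA = not detected)
patient_pvol_matrix <- function(pvols, patient) {
  sub <- pvols[pvols$patient_id == patient, , drop = FALSE]
  if (nrow(sub) == 0) stop("no replicates for patient ", patient, call. = FALSE)
  reps <- sort(unique(sub$replicate_index))
  spots <- sort(unique(sub$spot_id))
  m <- matrix(NA_real_, length(spots), length(reps),
              dimnames = list(spots, as.character(reps)))
  m[cbind(match(sub$spot_id, spots), match(sub$replicate_index, reps))] <- sub$pct_vol
  m
}

# mean %SD (percent) over spots present in every column of m
mean_pct_sd <- function(m) {
  complete <- !is.na(rowSums(m))
  if (!any(complete)) return(NA_real_)
  mm <- m[complete, , drop = FALSE]
  n <- ncol(mm)
  means <- rowMeans(mm)
  # centered one-pass form; the uncentered sum-of-squares variant loses all
  # precision at near-zero variance
  vars <- rowSums((mm - means)^2) / (n - 1)
  mean(100 * sqrt(vars) / means)
}

#' Replicate variability (%SD) for a patient
#'
#' For every spot matched across all considered replicates, the sample
#' (n-1) standard deviation of its %Vol values is expressed as a percentage
#' of its mean (`%SD`); the per-set value is the mean of those per-spot %SDs.
#' Spots missing from any considered replicate are excluded (only matched
#' spots contribute).
#'
#' @param pvols A `percent_vol_map`.
#' @param patient Patient identifier.
#' @param replicates Optional integer vector of replicate indices to
#'   consider; default all replicates of the patient.
#' @return A list with `mean_pct_sd` (percent, over the full considered set),
#'   `per_pair` (data frame of every replicate pair and its mean %SD) and
#'   `n_matched_spots`.
#' @export
replicate_percent_sd <- function(pvols, patient, replicates = NULL) {
  m <- patient_pvol_matrix(pvols, patient)
  if (!is.null(replicates)) {
    keep <- colnames(m) %in% as.character(replicates)
    if (sum(keep) < 2) stop("fewer than 2 replicates selected", call. = FALSE)
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < 2) stop("replicate_percent_sd: need >= 2 replicates", call. = FALSE)
  pairs <- utils::combn(colnames(m), 2)
  per_pair <- data.frame(
    replicate_a = as.integer(pairs[1, ]),
    replicate_b = as.integer(pairs[2, ]),
    mean_pct_sd = apply(pairs, 2, function(p) mean_pct_sd(m[, p, drop = FALSE]))
  )
  list(mean_pct_sd = mean_pct_sd(m),
       per_pair = per_pair,
       n_matched_spots = sum(stats::complete.cases(m)))
}

#' Select the best replicate pair for a patient
#'
#' Evaluates every replicate pair by its mean %SD over shared spots and keeps
#' the minimizing pair (ties broken toward the lexicographically smallest
#' index pair). If even the best pair exceeds `best_pair_max` the patient is
#' flagged `needs_new_replicate` — flagged, not dropped, so the caller
#' decides; in the originating workflow such maps were re-acquired.
#'
#' @param pvols A `percent_vol_map`.
#' @param patient Patient identifier.
#' @param best_pair_max Acceptance threshold on the best pair's mean %SD,
#'   as a fraction (default 0.30 = 30%).
#' @return List with `pair` (two replicate indices), `mean_pct_sd` (percent),
#'   and logical `needs_new_replicate`.
#' @export
select_best_replicate_pair <- function(pvols, patient, best_pair_max = 0.30) {
  rs <- replicate_percent_sd(pvols, patient)
  pp <- rs$per_pair
  # order guarantees the deterministic lexicographic tie-break
  pp <- pp[order(pp$mean_pct_sd, pp$replicate_a, pp$replicate_b), , drop = FALSE]
  best <- pp[1, ]
  list(pair = c(best$replicate_a, best$replicate_b),
       mean_pct_sd = best$mean_pct_sd,
       needs_new_replicate = isTRUE(best$mean_pct_sd / 100 > best_pair_max))
}

#' Aggregate a patient profile over a replicate pair
#'
#' Per spot: the mean and sample SD of %Vol over the two selected replicates.
#' A spot detected in only one replicate of the pair carries that single
#' value with SD marked unavailable (NA).
#'
#' @param pvols A `percent_vol_map`.
#' @param patient Patient identifier.
#' @param pair Integer vector of the two selected replicate indices.
#' @return A `patient_profile`: list with `patient_id`, `spots` (data frame
#'   `spot_id`, `mean_pct_vol`, `sd_pct_vol`), `selected_replicates`, and
#'   `replicate_mean_sd_pct` (the pair's mean %SD, percent).
#' @export
aggregate_profile <- function(pvols, patient, pair) {
  m <- patient_pvol_matrix(pvols, patient)
  keep <- colnames(m) %in% as.character(pair)
  if (sum(keep) != 2) stop("selected pair not present for patient ", patient, call. = FALSE)
  mm <- m[, keep, drop = FALSE]
  present <- rowSums(!is.na(mm)) > 0
  mm <- mm[present, , drop = FALSE]
  both <- stats::complete.cases(mm)
  # sample SD of a pair reduces to |difference| / sqrt(2)
  spots <- data.frame(
    spot_id = rownames(mm),
    mean_pct_vol = rowMeans(mm, na.rm = TRUE),
    sd_pct_vol = ifelse(both, abs(mm[, 1] - mm[, 2]) / sqrt(2), NA_real_),
    stringsAsFactors = FALSE, row.names = NULL
  )
  spots <- spots[order(spots$spot_id), , drop = FALSE]
  rownames(spots) <- NULL
  profile <- list(patient_id = patient,
                  spots = spots,
                  selected_replicates = sort(as.integer(pair)),
                  replicate_mean_sd_pct = mean_pct_sd(m[, keep, drop = FALSE]))
  class(profile) <- "patient_profile"
  profile
}

#' Run replicate QC and profile aggregation for every patient
#'
#' @param pvols A `percent_vol_map`.
#' @param best_pair_max Passed to [select_best_replicate_pair()].
#' @return List with `profiles` (named list of `patient_profile`) and `qc`
#'   (per-patient data frame: selected pair, mean %SD, flag).
#' @export
build_profiles <- function(pvols, best_pair_max = 0.30) {
  patients <- sort(unique(pvols$patient_id))
  profiles <- vector("list", length(patients))
  names(profiles) <- patients
  qc <- vector("list", length(patients))
  for (i in seq_along(patients)) {
    sel <- select_best_replicate_pair(pvols, patients[i], best_pair_max)
    profiles[[i]] <- aggregate_profile(pvols, patients[i], sel$pair)
    qc[[i]] <- data.frame(patient_id = patients[i],
                          replicate_a = sel$pair[1], replicate_b = sel$pair[2],
                          mean_pct_sd = sel$mean_pct_sd,
                          needs_new_replicate = sel$needs_new_replicate,
                          stringsAsFactors = FALSE)
  }
  list(profiles = profiles, qc = do.call(rbind, qc))
}

#' Select representative spots across the cohort
#'
#' A spot is representative when it was quantified (non-missing profile mean)
#' in at least `presence_fraction` of the patients. The default of 1.0 keeps
#' spots present in the entire gel population.
#'
#' @param profiles List of `patient_profile` objects.
#' @param presence_fraction Minimum presence fraction in `[0, 1]`.
#' @return Character vector of spot ids, sorted.
#' @export
select_representative_spots <- function(profiles, presence_fraction = 1.0) {
  stopifnot(length(profiles) >= 1, presence_fraction >= 0, presence_fraction <= 1)
  all_spots <- sort(unique(unlist(lapply(profiles, function(p) p$spots$spot_id))))
  presence <- vapply(all_spots, function(s) {
    mean(vapply(profiles, function(p) s %in% p$spots$spot_id, logical(1)))
  }, numeric(1))
  sort(all_spots[presence >= presence_fraction])
}

#' Patient x spot matrix of profile means
#'
#' @param profiles List of `patient_profile` objects.
#' @param spots Spot ids to extract (columns).
#' @return Numeric matrix, patients as rows (NA where a spot is missing).
#' @export
profiles_to_matrix <- function(profiles, spots) {
  ids <- vapply(profiles, function(p) p$patient_id, character(1))
  m <- matrix(NA_real_, length(profiles), length(spots),
              dimnames = list(ids, spots))
  for (i in seq_along(profiles)) {
    sp <- profiles[[i]]$spots
    hit <- match(spots, sp$spot_id)
    m[i, ] <- sp$mean_pct_vol[hit]
  }
  m
}
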