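# Independent oracles and small fixture builders used across the suite.

# patient_profile with given spot means (structure mirrors aggregate_profile)
make_profile <- function(id, values, sds = NULL) {
  spots <- data.frame(spot_id = names(values),
                      mean_pct_vol = as.numeric(values),
                      sd_pct_vol = if (is.null(sds)) NA_real_ else as.numeric(sds),
                      stringsAsFactors = FALSE)
  spots <- spots[order(spots$spot_id), , drop = FALSE]
  rownames(spots) <- NULL
  structure(list(patient_id = id, spots = spots,
                 selected_replicates = c(0L, 1L),
                 replicate_mean_sd_pct = 0),
            class = "patient_profile")
}

make_assignment <- function(ids, clusters) {
  out <- data.frame(patient_id = ids, cluster = clusters, stringsAsFactors = FALSE)
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_assignment", "data.frame")
  out
}

# long spot table from a patients x spots matrix, replicated with no noise
table_from_matrix <- function(m, replicates = 1L) {
  rows <- expand.grid(patient_id = rownames(m),
                      replicate_index = seq_len(replicates) - 1L,
                      spot_id = colnames(m),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows$raw_volume <- m[cbind(rows$patient_id, rows$spot_id)]
  as_spot_table(rows)
}

# brute-force UPGMA: average of all original leaf-pair distances, per step
naive_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq.int(i + 1, length(clusters))) {
        avg <- mean(d[clusters[[i]], clusters[[j]]])
        if (avg < best_h - 1e-12) {
          best_h <- avg
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# full-enumeration two-sided Mann-Whitney p (tie-free data)
mw_enum_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  r <- rank(pooled)
  splits <- utils::combn(length(pooled), na)
  us <- apply(splits, 2, function(ii) sum(r[ii]) - na * (na + 1) / 2)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "csfstrat", mustWork = TRUE)
}

# published-study fixtures: clinical table and marker-clustering memberships
load_study_fixtures <- function() {
  clinical <- read_clinical_table(fixture_path("csf_cohort_clinical.tsv"))
  clusters <- utils::read.delim(fixture_path("marker_cluster_assignments.tsv"),
                                colClasses = "character")
  list(clinical = clinical,
       two_spot = csfstrat:::as_assignment(clusters, "cluster2"),
       three_spot = csfstrat:::as_assignment(clusters, "cluster3"))
}
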