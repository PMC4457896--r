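test_that("%Vol normalization does forced arithmetic and is idempotent", {
  m <- matrix(c(5), 1, 1, dimnames = list("p1", "s1"))
  pv <- compute_percent_vol(table_from_matrix(m))
  expect_equal(pv$pct_vol, 100)

  m4 <- matrix(rep(3, 4), 1, 4, dimnames = list("p1", paste0("s", 1:4)))
  expect_equal(compute_percent_vol(table_from_matrix(m4))$pct_vol, rep(25, 4))

  m3 <- matrix(c(2, 3, 5), 1, 3, dimnames = list("p1", paste0("s", 1:3)))
  pv3 <- compute_percent_vol(table_from_matrix(m3))
  expect_equal(pv3$pct_vol[order(pv3$spot_id)], c(20, 30, 50))

  # idempotence: feeding %Vol back in returns the same values
  set.seed(1)
  mr <- matrix(runif(12, 1, 10), 2, 6,
               dimnames = list(c("p1", "p2"), paste0("s", 1:6)))
  pv1 <- compute_percent_vol(table_from_matrix(mr))
  tab2 <- pv1
  names(tab2)[names(tab2) == "pct_vol"] <- "raw_volume"
  pv2 <- compute_percent_vol(as_spot_table(tab2))
  expect_equal(pv2$pct_vol, pv1$pct_vol, tolerance = 1e-12)

  # per-gel totals are 100
  gel_tot <- tapply(pv1$pct_vol, pv1$patient_id, sum)
  expect_equal(as.numeric(gel_tot), rep(100, 2), tolerance = 1e-9)
})

# one patient, two spots, three replicates; spot A %Vol = 10, 12, 14
toy_triplicate <- function() {
  rows <- data.frame(
    patient_id = "p1",
    replicate_index = rep(0:2, each = 2),
    spot_id = rep(c("A", "B"), 3),
    raw_volume = c(10, 90, 12, 88, 14, 86))
  compute_percent_vol(as_spot_table(rows))
}

test_that("replicate %SD matches the hand-computed value with sample SD", {
  pv <- toy_triplicate()
  rs <- replicate_percent_sd(pv, "p1")
  # spot A: mean 12, sample SD 2 -> 16.667%; spot B: mean 88, SD 2 -> 2.273%
  expect_equal(rs$n_matched_spots, 2L)
  per_spot_a <- 100 * 2 / 12
  per_spot_b <- 100 * 2 / 88
  expect_equal(rs$mean_pct_sd, mean(c(per_spot_a, per_spot_b)), tolerance = 1e-9)
  expect_equal(per_spot_a, 16.6667, tolerance = 1e-4)
  expect_error(replicate_percent_sd(pv, "p1", replicates = 0), "fewer than 2")
})

test_that("best-pair selection minimizes %SD, tie-breaks low, and flags bad sets", {
  # identical replicates: tie resolved to (0, 1)
  m <- matrix(rep(c(30, 70), 3), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("A", "B")))
  rows <- data.frame(patient_id = "p1", replicate_index = rep(0:2, 2),
                     spot_id = rep(c("A", "B"), each = 3),
                     raw_volume = c(m[, 1], m[, 2]))
  pv <- compute_percent_vol(as_spot_table(rows))
  sel <- select_best_replicate_pair(pv, "p1")
  expect_identical(sel$pair, c(0L, 1L))
  expect_equal(sel$mean_pct_sd, 0)
  expect_false(sel$needs_new_replicate)

  # replicate 1 is an outlier: brute force over the three pairs picks (0, 2)
  pv2 <- toy_triplicate()
  pv2$pct_vol[pv2$replicate_index == 1 & pv2$spot_id == "A"] <- 40
  pv2$pct_vol[pv2$replicate_index == 1 & pv2$spot_id == "B"] <- 60
  pairs <- replicate_percent_sd(pv2, "p1")$per_pair
  brute_best <- pairs[which.min(pairs$mean_pct_sd), ]
  sel2 <- select_best_replicate_pair(pv2, "p1")
  expect_identical(sel2$pair, c(brute_best$replicate_a, brute_best$replicate_b))
  expect_identical(sel2$pair, c(0L, 2L))

  # a best pair above the threshold is flagged, not dropped
  rows3 <- data.frame(patient_id = "p1", replicate_index = rep(0:1, 2),
                      spot_id = rep(c("A", "B"), each = 2),
                      raw_volume = c(10, 30, 90, 70))
  pv3 <- compute_percent_vol(as_spot_table(rows3))
  sel3 <- select_best_replicate_pair(pv3, "p1", best_pair_max = 0.30)
  expect_true(sel3$needs_new_replicate)
  expect_gt(sel3$mean_pct_sd / 100, 0.30)
})

test_that("adding a strictly noisier replicate never worsens the best pair", {
  pv <- toy_triplicate()
  base <- select_best_replicate_pair(pv, "p1")
  noisy <- data.frame(patient_id = "p1", replicate_index = 3L,
                      spot_id = c("A", "B"), raw_volume = c(45, 55))
  pv_plus <- rbind(pv, compute_percent_vol(as_spot_table(noisy)))
  class(pv_plus) <- class(pv)
  extended <- select_best_replicate_pair(pv_plus, "p1")
  expect_lte(extended$mean_pct_sd, base$mean_pct_sd + 1e-12)
})

test_that("profile aggregation takes the pair mean/SD and marks singletons NA", {
  rows <- data.frame(patient_id = "p1", replicate_index = c(0L, 1L, 0L),
                     spot_id = c("A", "A", "B"), raw_volume = c(10, 12, 90))
  pv <- rows
  names(pv)[4] <- "pct_vol"  # bypass normalization: treat values as %Vol
  class(pv) <- c("percent_vol_map", "data.frame")
  prof <- aggregate_profile(pv, "p1", c(0L, 1L))
  a <- prof$spots[prof$spots$spot_id == "A", ]
  expect_equal(a$mean_pct_vol, 11)
  expect_equal(a$sd_pct_vol, sqrt(2), tolerance = 1e-9)
  b <- prof$spots[prof$spots$spot_id == "B", ]
  expect_equal(b$mean_pct_vol, 90)
  expect_true(is.na(b$sd_pct_vol))
})

test_that("representative spot selection applies the presence threshold", {
  profs <- list(make_profile("p1", c(A = 1, B = 2)),
                make_profile("p2", c(A = 1, B = 3)),
                make_profile("p3", c(A = 1)))
  expect_identical(select_representative_spots(profs, 1.0), "A")
  expect_identical(select_representative_spots(profs, 0.6), c("A", "B"))
  expect_identical(select_representative_spots(profs, 0), c("A", "B"))
})
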