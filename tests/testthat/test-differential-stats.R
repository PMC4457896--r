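test_that("exact Mann-Whitney matches the known small-sample values", {
  res <- mann_whitney(1:4, 5:8)
  expect_identical(res$method, "exact")
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(mann_whitney(1:3, 4:6)$p_value, 0.1, tolerance = 1e-12)
  same <- c(1.2, 3.4, 5.6)
  expect_equal(mann_whitney(same, sample(same))$p_value, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty group")
})

test_that("exact Mann-Whitney equals full enumeration over random tie-free data", {
  set.seed(7)
  for (na in 2:6) {
    for (nb in na:6) {
      a <- rnorm(na)
      b <- rnorm(nb, 0.5)
      res <- mann_whitney(a, b)
      expect_equal(res$p_value, mw_enum_p(a, b), tolerance = 1e-12,
                   label = sprintf("n=(%d,%d)", na, nb))
      # exact p bounded below by the most extreme arrangement
      expect_gte(res$p_value, 2 / choose(na + nb, na) - 1e-12)
      expect_lte(res$p_value, 1)
    }
  }
})

test_that("the tie branch uses the mid-rank normal approximation", {
  a <- c(1, 2, 2, 3, 5, 5, 6, 7, 8, 8, 9)
  b <- c(2, 2, 3, 3, 4, 6, 6, 7, 9, 9, 10)
  res <- mann_whitney(a, b)
  expect_identical(res$method, "normal")
  ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("fold change reproduces the published cluster-mean examples", {
  fc97 <- fold_change(0.125, 0.210)
  expect_equal(fc97$ratio_rounded, 1.7)
  expect_identical(fc97$direction, "up_in_b")
  fc288 <- fold_change(0.224, 0.139)
  expect_equal(fc288$ratio_rounded, 1.6)
  expect_identical(fc288$direction, "down_in_b")
  expect_identical(fold_change(0.1, 0.1)$direction, "none")
  expect_equal(fold_change(0.1, 0.1)$ratio, 1)
  # symmetry: swapping groups preserves the ratio and flips direction
  f <- fold_change(0.04, 0.024)
  g <- fold_change(0.024, 0.04)
  expect_equal(f$ratio, g$ratio)
  expect_identical(sort(c(f$direction, g$direction)), c("down_in_b", "up_in_b"))
  expect_true(is.infinite(fold_change(0, 0.2)$ratio))
  expect_error(fold_change(0, 0), "both means zero")
})

test_that("differential selection honors its thresholds and finds planted spots", {
  set.seed(12)
  n <- 9
  mk <- function(i, shift) {
    vals <- c(planted = rlnorm(1, log(0.2) + shift, 0.15),
              setNames(rlnorm(6, log(0.1), 0.15), paste0("bg", 1:6)))
    make_profile(sprintf("p%02d", i), vals)
  }
  profs <- c(lapply(1:n, mk, shift = 0), lapply((n + 1):(2 * n), mk, shift = log(2)))
  assign <- make_assignment(sprintf("p%02d", 1:(2 * n)), rep(c("C1", "C2"), each = n))
  res <- select_differential_spots(profs, assign, "C1", "C2")
  expect_true(res$selected[res$spot_id == "planted"])
  expect_identical(res$direction[res$spot_id == "planted"], "up_in_b")
  expect_identical(attr(res, "n_tests"), 7L)
  # selection flags obey the union rule
  expect_identical(res$selected, res$significant | res$fc_pass)

  # degenerate thresholds: significance stays strict (p < threshold), and at
  # fc_threshold = 1 every quantified spot passes the fold-change criterion
  all_sel <- select_differential_spots(profs, assign, "C1", "C2",
                                       p_threshold = 1, fc_threshold = 1)
  expect_true(all(all_sel$selected))
  expect_identical(all_sel$significant, all_sel$p_value < 1)
  expect_true(all(all_sel$fc_pass))
  expect_error(select_differential_spots(profs[1:3], assign, "C1", "C2"),
               ">= 2 members")
})

test_that("identical clusters select nothing beyond the nominal rate", {
  set.seed(31)
  hits <- 0L
  tests <- 0L
  for (i in 1:40) {
    vals <- matrix(rlnorm(18 * 5, log(0.1), 0.3), 18, 5,
                   dimnames = list(sprintf("p%02d", 1:18), paste0("s", 1:5)))
    profs <- lapply(rownames(vals), function(p) make_profile(p, vals[p, ]))
    assign <- make_assignment(rownames(vals), rep(c("C1", "C2"), each = 9))
    res <- select_differential_spots(profs, assign, "C1", "C2", fc_threshold = Inf)
    hits <- hits + sum(res$significant)
    tests <- tests + nrow(res)
  }
  expect_lt(hits / tests, 0.12)
})

test_that("Spearman matches a naive mid-rank oracle and its t convention", {
  expect_equal(spearman(1:8, (1:8)^2)$rho, 1)
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(12)
    y <- rnorm(12) + 0.4 * x
    res <- spearman(x, y)
    rho_oracle <- cor(rank(x), rank(y))
    expect_equal(res$rho, rho_oracle, tolerance = 1e-12)
    t_stat <- rho_oracle * sqrt((12 - 2) / (1 - rho_oracle^2))
    expect_equal(res$p_value, 2 * pt(-abs(t_stat), 10), tolerance = 1e-12)
  }
  expect_error(spearman(rep(1, 5), 1:5), "zero variance")
  expect_error(spearman(1:2, 2:3), "n >= 3")
})

test_that("chi-square matches the closed-form 2x2 oracle and independence limit", {
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 4), 2, 2)
    res <- chi_square_independence(tab)
    a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
    n <- sum(tab)
    closed <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(res$chi2, closed, tolerance = 1e-10)
    expect_identical(res$df, 1L)
  }
  # outer product of margins: exact independence
  indep <- outer(c(2, 3), c(5, 10, 15))
  res0 <- chi_square_independence(indep)
  expect_equal(res0$chi2, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1)
  # dropping the all-zero row collapses the table, so both warnings fire
  expect_warning(
    expect_warning(chi_square_independence(matrix(c(4, 0, 6, 0), 2)), "all-zero"),
    "degenerate")
})

test_that("the phospho-stain ratio rule calls modification status", {
  expect_identical(phospho_call(0.05, 1), "not_phosphorylated")
  expect_identical(phospho_call(0, 3), "not_phosphorylated")
  expect_identical(phospho_call(2, 2), "phosphorylated")
  expect_identical(phospho_call(0.079, 1), "not_phosphorylated")
  expect_identical(phospho_call(0.08, 1), "phosphorylated")
  expect_error(phospho_call(1, 0), "Sypro")
})
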