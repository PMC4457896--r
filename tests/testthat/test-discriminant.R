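random_model <- function(seed) {
  set.seed(seed)
  structure(list(groups = c("g1", "g2"),
                 coefficients = matrix(rnorm(4), 2, 2,
                                       dimnames = list(c("g1", "g2"), c("a", "b"))),
                 intercepts = setNames(rnorm(2), c("g1", "g2")),
                 features = c("a", "b"), provenance = "fitted"),
            class = "discriminant_model")
}

two_group_profiles <- function(seed = 2, n = 8, sep = 4) {
  set.seed(seed)
  m1 <- cbind(rnorm(n, 0, 0.5), rnorm(n, 0, 0.5))
  m2 <- cbind(rnorm(n, sep, 0.5), rnorm(n, sep, 0.5))
  m <- rbind(m1, m2)
  dimnames(m) <- list(sprintf("p%02d", 1:(2 * n)), c("a", "b"))
  list(m = m,
       assignment = make_assignment(rownames(m), rep(c("C1", "C2"), each = n)))
}

test_that("fitting separable groups classifies every training point correctly", {
  tg <- two_group_profiles()
  model <- fit_discriminant(tg$m, tg$assignment, c("a", "b"))
  pred <- vapply(rownames(tg$m),
                 function(p) classify(model, tg$m[p, ]), character(1))
  expect_identical(unname(pred), tg$assignment$cluster[match(rownames(tg$m),
                                                             tg$assignment$patient_id)])
})

test_that("identical group means collapse the two functions (equal priors)", {
  set.seed(9)
  base <- cbind(rnorm(10), rnorm(10))
  m <- rbind(base, base)  # same points in both groups -> identical means
  dimnames(m) <- list(sprintf("p%02d", 1:20), c("a", "b"))
  assign <- make_assignment(rownames(m), rep(c("C1", "C2"), each = 10))
  model <- fit_discriminant(m, assign, c("a", "b"))
  expect_equal(model$coefficients["C1", ], model$coefficients["C2", ], tolerance = 1e-9)
  expect_equal(model$intercepts[["C1"]], model$intercepts[["C2"]], tolerance = 1e-9)
})

test_that("degenerate fits are rejected with informative errors", {
  tg <- two_group_profiles(n = 2)
  expect_error(fit_discriminant(tg$m, tg$assignment, c("a", "b")), "more members")
  # perfectly collinear features: singular pooled covariance
  tg2 <- two_group_profiles(n = 8)
  m <- tg2$m
  m[, "b"] <- 2 * m[, "a"]
  expect_error(fit_discriminant(m, tg2$assignment, c("a", "b")), "singular")
})

test_that("the bundled DBP discriminant fixture evaluates exactly", {
  model <- dbp_discriminant_model()
  expect_identical(model$provenance, "fixture")
  at0 <- evaluate_functions(model, c("288" = 0, "289" = 0))
  expect_equal(unname(at0), c(-7.155, -15.248))
  at22 <- evaluate_functions(model, c("288" = 0.2, "289" = 0.2))
  expect_equal(unname(at22), c(9.396, 14.0278), tolerance = 1e-9)
  expect_identical(classify(model, c("288" = 0.2, "289" = 0.2)), "f2")
  expect_identical(classify(model, c("288" = 0, "289" = 0)), "f1")
  expect_error(evaluate_functions(model, c("288" = 0.2)), "missing feature")
})

test_that("exact score ties resolve to the first-listed group", {
  model <- structure(list(groups = c("gA", "gB"),
                          coefficients = matrix(c(1, 1, 2, 2), 2, 2,
                                                dimnames = list(c("gA", "gB"), c("a", "b"))),
                          intercepts = c(gA = 0, gB = 0),
                          features = c("a", "b"), provenance = "fitted"),
                     class = "discriminant_model")
  expect_identical(classify(model, c(a = 1, b = 1)), "gA")
})

test_that("classification equals the sign of f1 - f2 on random models", {
  for (s in 1:25) {
    model <- random_model(s)
    x <- setNames(rnorm(2), c("a", "b"))
    scores <- evaluate_functions(model, x)
    expected <- if (scores[1] >= scores[2]) "g1" else "g2"
    expect_identical(classify(model, x), expected)
  }
})

test_that("group centroids score maximal under their own function", {
  for (s in 1:10) {
    tg <- two_group_profiles(seed = 100 + s, sep = runif(1, 1, 5))
    model <- fit_discriminant(tg$m, tg$assignment, c("a", "b"))
    for (g in c("C1", "C2")) {
      ids <- tg$assignment$patient_id[tg$assignment$cluster == g]
      centroid <- colMeans(tg$m[ids, ])
      scores <- evaluate_functions(model, centroid)
      expect_identical(names(which.max(scores)), g)
    }
  }
})

test_that("decisions are invariant to feature order and uniform rescaling", {
  tg <- two_group_profiles(seed = 42, sep = 2)
  m1 <- fit_discriminant(tg$m, tg$assignment, c("a", "b"))
  m2 <- fit_discriminant(tg$m, tg$assignment, c("b", "a"))
  m3 <- fit_discriminant(tg$m * 10, tg$assignment, c("a", "b"))
  set.seed(1)
  for (i in 1:20) {
    x <- setNames(runif(2, -1, 5), c("a", "b"))
    expect_identical(classify(m1, x), classify(m2, x))
    expect_identical(classify(m1, x), classify(m3, x * 10))
  }
})

test_that("refitting data generated around the fixture boundary recovers it", {
  model <- dbp_discriminant_model()
  w <- model$coefficients["f1", ] - model$coefficients["f2", ]
  b <- model$intercepts[["f1"]] - model$intercepts[["f2"]]
  w_hat <- w / sqrt(sum(w^2))
  # a point on the boundary: f1 = f2
  x289 <- 0.2
  x288 <- (b + w[2] * x289) / (-w[1])
  x0 <- setNames(c(x288, x289), c("288", "289"))
  expect_equal(sum(w * x0) + b, 0, tolerance = 1e-9)
  set.seed(77)
  n <- 40
  delta <- 0.05
  g1 <- sweep(matrix(rnorm(2 * n, 0, 0.02), n, 2), 2, x0 + delta * w_hat, "+")
  g2 <- sweep(matrix(rnorm(2 * n, 0, 0.02), n, 2), 2, x0 - delta * w_hat, "+")
  m <- rbind(g1, g2)
  dimnames(m) <- list(sprintf("p%02d", 1:(2 * n)), c("288", "289"))
  assign <- make_assignment(rownames(m), rep(c("C1", "C2"), each = n))
  refit <- fit_discriminant(m, assign, c("288", "289"))
  w_fit <- refit$coefficients["C1", ] - refit$coefficients["C2", ]
  cosine <- sum(w_fit * w_hat) / sqrt(sum(w_fit^2))
  expect_gt(abs(cosine), 0.95)
})

test_that("functions map onto clusters by centroid geometry", {
  model <- dbp_discriminant_model()
  # f2 has the steep spot-288 coefficient; the high-288 cluster must map to it
  profs <- list(make_profile("h1", c("288" = 0.35, "289" = 0.10)),
                make_profile("h2", c("288" = 0.30, "289" = 0.12)),
                make_profile("l1", c("288" = 0.05, "289" = 0.25)),
                make_profile("l2", c("288" = 0.08, "289" = 0.30)))
  assign <- make_assignment(c("h1", "h2", "l1", "l2"), c("G", "G", "Z", "Z"))
  mapping <- map_discriminant_to_clusters(model, profs, assign)
  expect_identical(mapping[["f2"]], "G")
  expect_identical(mapping[["f1"]], "Z")
})
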