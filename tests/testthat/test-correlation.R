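# Mixed-type correlation estimation and positive-definite repair.

test_that("measurement levels are detected from the data and overridable", {
  expect_equal(classify_level(rep(0:3, 10)), "ordinal")
  expect_equal(classify_level(c(4.69, 4.71, rep(1:5, 3))), "continuous")
  # integer sums with many distinct levels are continuous
  set.seed(3)
  sums <- rowSums(matrix(sample(0:3, 200 * 20, TRUE), 200, 20))
  expect_gt(length(unique(sums)), 7)
  expect_equal(classify_level(sums), "continuous")
  # overrides win
  spec <- variable_spec("x", "continuous")
  expect_equal(classify_level(rep(0:1, 10), spec), "continuous")
  expect_error(classify_level(c(1, 2, 3)), class = "supportnet_data_error")
  expect_error(classify_level(rep(2, 50)), class = "supportnet_data_error")
})

test_that("thresholds are normal quantiles of cumulative proportions", {
  th <- estimate_thresholds(rep(0:1, each = 50))
  expect_equal(th$tau, 0)
  th4 <- estimate_thresholds(rep(1:4, each = 25))
  expect_equal(th4$tau, qnorm(c(0.25, 0.5, 0.75)))
  expect_error(estimate_thresholds(rep(2, 30)), class = "supportnet_data_error")
})

test_that("bivariate normal CDF matches closed form and quadrature oracle", {
  # closed form at the origin: 1/4 + asin(rho)/(2*pi)
  for (r in c(-0.95, -0.5, 0, 0.3, 0.8, 0.999)) {
    expect_equal(pbvnorm(0, 0, r), 0.25 + asin(r) / (2 * pi), tolerance = 1e-9)
  }
  # independent 1-D quadrature oracle on general arguments
  cases <- expand.grid(h = c(-1.5, 0.3, 2), k = c(-0.7, 1.1), r = c(-0.85, 0.4, 0.97))
  for (i in seq_len(nrow(cases))) {
    expect_equal(pbvnorm(cases$h[i], cases$k[i], cases$r[i]),
                 bvn_quadrature(cases$h[i], cases$k[i], cases$r[i]),
                 tolerance = 1e-7)
  }
  # infinite bounds reduce to univariate margins
  expect_equal(pbvnorm(Inf, 1.2, 0.5), pnorm(1.2))
  expect_equal(pbvnorm(-Inf, 1.2, 0.5), 0)
})

test_that("polychoric recovers latent correlations from ordinalized data", {
  cut_at <- function(x, L) findInterval(x, qnorm(seq_len(L - 1) / L))
  # null: independent ordinals
  set.seed(11)
  expect_lt(abs(polychoric(sample(0:3, 4000, TRUE), sample(1:5, 4000, TRUE))),
            0.05)
  # recovery at rho = 0.5, 5x5 levels, n = 5000
  set.seed(42)
  z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, .5, .5, 1), 2))
  est <- polychoric(cut_at(z[, 1], 5), cut_at(z[, 2], 5))
  expect_lt(abs(est - 0.5), 0.05)
  # estimation error shrinks with n
  set.seed(43)
  z5 <- MASS::mvrnorm(500, c(0, 0), matrix(c(1, .5, .5, 1), 2))
  est_small <- polychoric(cut_at(z5[, 1], 5), cut_at(z5[, 2], 5))
  expect_lt(abs(est - 0.5), abs(est_small - 0.5) + 0.05)
  # perfect concordance clamps at the boundary
  x <- rep(0:1, each = 15)
  expect_warning(r <- polychoric(x, x), "boundary")
  expect_equal(r, 0.999)
})

test_that("polyserial recovers mixed latent correlations", {
  set.seed(7)
  z <- MASS::mvrnorm(5000, c(0, 0), matrix(c(1, .4, .4, 1), 2))
  y4 <- findInterval(z[, 2], qnorm((1:3) / 4))
  expect_lt(abs(polyserial(z[, 1], y4) - 0.4), 0.05)
  # null
  set.seed(8)
  expect_lt(abs(polyserial(rnorm(5000), sample(0:3, 5000, TRUE))), 0.05)
  # near-degenerate: binary median split of the continuous variable itself
  set.seed(9)
  x <- rnorm(2000)
  expect_gte(suppressWarnings(polyserial(x, as.numeric(x > median(x)))), 0.95)
})

test_that("mixed matrix reduces to Pearson on continuous data and is symmetric", {
  set.seed(15)
  X <- as.data.frame(MASS::mvrnorm(200, rep(0, 4),
                                   diag(4) * 0.5 + 0.5))
  names(X) <- letters[1:4]
  X$a[sample(200, 20)] <- NA   # pairwise deletion in play
  cr <- mixed_correlation_matrix(X)
  expect_true(all(cr$pair_method[upper.tri(cr$pair_method)] == "pearson"))
  expect_equal(unname(cr$matrix),
               unname(cor(X, use = "pairwise.complete.obs")))
  expect_identical(cr$matrix, t(cr$matrix))
  expect_equal(unname(diag(cr$matrix)), rep(1, 4))
  expect_true(all(abs(cr$matrix) <= 1))
  # per-pair n bounded by total n and varying under missingness
  expect_true(all(cr$pair_n <= 200))
  expect_gt(length(unique(cr$pair_n[upper.tri(cr$pair_n)])), 1)
})

test_that("the 7-node survey node table mixes polyserial and pearson pairs", {
  surv <- sample_survey(n = 150, seed = 33)
  nodes <- build_node_table(surv)
  cr <- mixed_correlation_matrix(nodes)
  meth <- cr$pair_method[upper.tri(cr$pair_method)]
  # the 0-3 composite risk is the lone ordinal node: 6 polyserial pairs
  expect_equal(sum(meth == "polyserial"), 6)
  expect_equal(sum(meth == "pearson"), 15)
  expect_equal(cr$levels[["risk"]], "ordinal")
})

test_that("pairs with too few complete cases are reported as errors", {
  set.seed(4)
  X <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
  X$a[1:18] <- NA   # 12 complete pairs with every other variable
  expect_error(mixed_correlation_matrix(X), "a-b",
               class = "supportnet_data_error")
})

test_that("positive-definite repair clips eigenvalues and keeps unit diagonal", {
  # identity and PD input pass through unchanged
  expect_equal(unname(nearest_pd(diag(3))), diag(3), ignore_attr = TRUE)
  pd <- matrix(c(1, .3, .3, 1), 2)
  expect_equal(unname(nearest_pd(pd)), pd, ignore_attr = TRUE)

  # indefinite input: all off-diagonals 0.9 except one -0.9
  bad <- matrix(0.9, 3, 3); bad[1, 2] <- bad[2, 1] <- -0.9; diag(bad) <- 1
  expect_lt(min(eigen(bad, only.values = TRUE)$values), 0)
  fixed <- nearest_pd(bad)
  expect_gte(min(eigen(fixed, only.values = TRUE)$values), 1e-8)
  expect_equal(unname(diag(fixed)), rep(1, 3))
  expect_identical(unname(fixed), unname(t(fixed)))
  # stays near the input and near the Higham projection
  higham <- as.matrix(Matrix::nearPD(bad, corr = TRUE)$mat)
  expect_lt(norm(fixed - bad, "F"), norm(higham - bad, "F") + 0.5)
})
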