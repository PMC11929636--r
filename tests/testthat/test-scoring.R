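# Scale scoring, composite risk, and internal consistency.

make_table <- function(df) survey_table(df)

test_that("score_scale handles complete, prorated and unscorable responses", {
  # maximum-score mean aggregation
  friend <- make_table(as.data.frame(matrix(7, 3, 4,
    dimnames = list(NULL, sprintf("friend_%d", 1:4)))))
  d_friend <- scale_definition("friend", sprintf("friend_%d", 1:4), "mean", c(1, 7))
  expect_equal(unname(score_scale(friend, d_friend)), rep(7, 3))

  # minimum-score sum aggregation
  cesd <- make_table(as.data.frame(matrix(0, 2, 20,
    dimnames = list(NULL, sprintf("cesd_%d", 1:20)))))
  d_cesd <- scale_definition("cesd", sprintf("cesd_%d", 1:20), "sum", c(0, 3))
  expect_equal(unname(score_scale(cesd, d_cesd)), c(0, 0))

  # prorated sum: 30 of 31 items answered, each 2 -> 2 * 31 = 62
  m <- matrix(2, 1, 31, dimnames = list(NULL, sprintf("stss_%d", 1:31)))
  m[1, 31] <- NA
  d_stss <- scale_definition("stss", sprintf("stss_%d", 1:31), "sum", c(1, 5),
                             min_prop_answered = 0.75)
  expect_equal(unname(score_scale(make_table(as.data.frame(m)), d_stss)), 62)

  # below the answered-fraction threshold -> missing
  m2 <- matrix(NA_real_, 1, 31, dimnames = list(NULL, sprintf("stss_%d", 1:31)))
  m2[1, 1:10] <- 3
  expect_true(is.na(score_scale(make_table(as.data.frame(m2)), d_stss)))
})

test_that("proration is the identity on complete responses and respects ranges", {
  set.seed(101)
  for (rep in 1:5) {
    k <- sample(5:20, 1)
    items <- matrix(sample(0:3, 50 * k, replace = TRUE), 50, k,
                    dimnames = list(NULL, sprintf("it_%d", 1:k)))
    d <- scale_definition("s", sprintf("it_%d", 1:k), "sum", c(0, 3))
    sc <- score_scale(make_table(as.data.frame(items)), d)
    expect_equal(unname(sc), rowSums(items))
    expect_true(all(sc >= 0 & sc <= 3 * k))
  }
})

test_that("score_scale rejects unknown items and out-of-range values", {
  tab <- make_table(data.frame(a_1 = c(1, 2), a_2 = c(2, 3)))
  expect_error(
    score_scale(tab, scale_definition("a", c("a_1", "a_9"), "sum", c(0, 3))),
    class = "supportnet_config_error")
  expect_error(
    score_scale(tab, scale_definition("a", c("a_1", "a_2"), "sum", c(0, 2.5))),
    class = "supportnet_data_error")
})

test_that("read_survey flags non-numeric cells by row and column", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y", "1,2", "oops,3"), f)
  expect_error(read_survey(f), "row 2, column 'x'",
               class = "supportnet_data_error")
})

test_that("composite risk counts criteria with a strict adherence cutoff", {
  expect_equal(score_composite_risk(0.75, TRUE, TRUE)$score, 3L)
  # exactly 80% adherence does NOT meet the '< 80%' criterion
  expect_equal(score_composite_risk(0.80, FALSE, FALSE)$score, 0L)
  expect_equal(score_composite_risk(0.95, FALSE, TRUE)$score, 1L)

  # a missing criterion contributes 0 but is flagged
  r <- score_composite_risk(NA, TRUE, NA)
  expect_equal(r$score, 1L)
  expect_equal(r$n_missing_criteria, 2)

  # all-missing respondent gets a missing score
  r2 <- score_composite_risk(NA, NA, NA)
  expect_true(is.na(r2$score))
  expect_equal(r2$n_missing_criteria, 3)
})

test_that("worsening any single criterion never decreases the composite score", {
  grid <- expand.grid(a = c(0.95, 0.75), v = c(FALSE, TRUE), m = c(FALSE, TRUE))
  sc <- score_composite_risk(grid$a, grid$v, grid$m)$score
  for (i in seq_len(nrow(grid))) {
    worse_a <- score_composite_risk(0.5, grid$v[i], grid$m[i])$score
    worse_v <- score_composite_risk(grid$a[i], TRUE, grid$m[i])$score
    worse_m <- score_composite_risk(grid$a[i], grid$v[i], TRUE)$score
    expect_gte(worse_a, sc[i])
    expect_gte(worse_v, sc[i])
    expect_gte(worse_m, sc[i])
  }
  expect_true(all(sc %in% 0:3))
})

test_that("cronbach_alpha matches the variance-decomposition formula", {
  # two identical items -> perfect consistency
  x <- c(1, 3, 2, 5, 4)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)

  # hand-computed case: item variances 11/12, 2/3, 11/12; total variance 6
  m <- rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3), c(1, 2, 3))
  expect_equal(cronbach_alpha(m), 1.5 * (1 - 2.5 / 6))
  expect_equal(cronbach_alpha(m), 0.875)

  # large-sample null: independent items -> alpha near 0
  set.seed(7)
  nullm <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(abs(cronbach_alpha(nullm)), 0.05)

  # invariance under adding a constant to every item
  set.seed(8)
  mm <- matrix(rnorm(300), 100, 3)
  expect_equal(cronbach_alpha(mm), cronbach_alpha(mm + 5))

  expect_error(cronbach_alpha(matrix(1, 5, 3)),
               class = "supportnet_data_error")
})

test_that("build_node_table yields the main and post-hoc node sets", {
  surv <- sample_survey(n = 60, seed = 21)
  main <- build_node_table(surv)
  expect_equal(names(main)[-1],
               c("cesd", "ptsd", "stss", "risk", "special", "family", "friend"))
  ph <- build_node_table(surv, network = "posthoc")
  expect_equal(ncol(ph) - 1L, 10L)
  expect_true(all(c("ext_self_perception", "care_self_sacrifice",
                    "silencing_self", "divided_self") %in% names(ph)))
  expect_false("stss" %in% names(ph))

  # STSS total equals the sum of its four subscales on complete data
  expect_equal(main$stss,
               ph$ext_self_perception + ph$care_self_sacrifice +
                 ph$silencing_self + ph$divided_self)

  # a respondent missing a whole scale keeps their row with a missing cell
  surv2 <- surv
  surv2[1, sprintf("cesd_%d", 1:20)] <- NA
  main2 <- build_node_table(survey_table(as.data.frame(surv2)))
  expect_true(is.na(main2$cesd[1]))
  expect_equal(nrow(main2), nrow(surv))

  expect_error(build_node_table(surv, defns = default_scale_definitions()["cesd"]),
               class = "supportnet_config_error")
})
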