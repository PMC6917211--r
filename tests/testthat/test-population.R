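test_that("generation is deterministic and handles the empty table", {
  a <- generate_population(n = 500, seed = 11)
  b <- generate_population(n = 500, seed = 11)
  expect_identical(a, b)
  c <- generate_population(n = 500, seed = 12)
  expect_false(identical(a, c))

  empty <- generate_population(n = 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("person_id", "sex", "age", "intake_sodium",
                    "sample_weight") %in% names(empty)))
})

test_that("invalid specs are rejected with the offending field named", {
  spec <- population_spec()
  spec$sex <- c(male = 0.6, female = 0.6)
  expect_error(generate_population(spec, 10), "sex")
  spec2 <- population_spec()
  spec2$intakes$sd[1] <- -1
  expect_error(generate_population(spec2, 10), "intakes")
  expect_error(generate_population(n = -1), "n must be")
})

test_that("intake marginals recover their configured moments and masses", {
  n <- 200000
  pop <- generate_population(n = n, seed = 3)
  spec <- population_spec()

  # SSB point mass at zero: binomial 3*SE around 48.1%
  p0 <- 0.481
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(pop$intake_ssb == 0) - p0), 3 * se)

  # sodium mean: 3*SE around 3,481.5 mg/day
  expect_lt(abs(mean(pop$intake_sodium) - 3481.5), 3 * 965.7 / sqrt(n))

  # nuts/seeds mean survives zero-inflation calibration
  expect_lt(abs(mean(pop$intake_nuts_seeds) - 12.5), 3 * 29.0 / sqrt(n))

  # ages live in the configured bands
  expect_true(all(pop$age >= 35 & pop$age <= 85))
  expect_true(all(pop$sample_weight >= 0))
  expect_true(all(dplyr::select(pop, dplyr::starts_with("intake_")) >= 0))
})

test_that("continuous marginals recover spec means across seeds", {
  spec <- population_spec()
  n <- 50000
  vars <- c("sbp", "total_chol")
  pass <- 0L
  trials <- 0L
  for (s in 1:20) {
    pop <- generate_population(spec, n = n, seed = s)
    for (v in vars) {
      row <- spec$continuous[spec$continuous$var == v, ]
      trials <- trials + 1L
      if (abs(mean(pop[[v]]) - row$mean) < 4 * row$sd / sqrt(n)) {
        pass <- pass + 1L
      }
    }
  }
  expect_gte(pass / trials, 0.95)
})

test_that("a Gaussian copula correlates intakes while preserving marginals", {
  spec <- population_spec()
  k <- nrow(spec$intakes)
  R <- diag(k)
  dimnames(R) <- list(spec$intakes$factor, spec$intakes$factor)
  R["fruits", "vegetables"] <- R["vegetables", "fruits"] <- 0.6
  spec$intake_corr <- R
  n <- 50000
  pop <- generate_population(spec, n = n, seed = 9)

  # dependence appears on the rank scale
  rho <- stats::cor(pop$intake_fruits, pop$intake_vegetables,
                    method = "spearman")
  expect_gt(rho, 0.45)

  # marginals unchanged: means and the SSB zero mass still calibrate
  expect_lt(abs(mean(pop$intake_fruits) - 120.6), 4 * 145.5 / sqrt(n))
  expect_lt(abs(mean(pop$intake_sodium) - 3481.5), 4 * 965.7 / sqrt(n))
  expect_lt(abs(mean(pop$intake_ssb == 0) - 0.481),
            4 * sqrt(0.481 * 0.519 / n))

  # malformed matrices are rejected
  bad <- spec
  bad$intake_corr <- R[-1, -1]
  expect_error(generate_population(bad, 10), "intake_corr")
  bad2 <- spec
  bad2$intake_corr["fruits", "vegetables"] <- 0.2 # asymmetric
  expect_error(generate_population(bad2, 10), "symmetric")
})

test_that("weighted resampling follows the weights", {
  # degenerate: one positive-weight record copied n times
  one <- toy_person(1)
  out <- resample_weighted(one, 5, seed = 1)
  expect_equal(nrow(out), 5)
  expect_true(all(out$sample_weight == 1))
  expect_true(all(out$age == one$age))

  # binomial closed form: weights 1 and 3 give the second record 75%
  two <- toy_person(2)
  two$sample_weight <- c(1, 3)
  two$age <- c(40, 60)
  n <- 100000
  res <- resample_weighted(two, n, seed = 2)
  share <- mean(res$age == 60)
  expect_lt(abs(share - 0.75), 3 * sqrt(0.75 * 0.25 / n))

  # equal weights: goodness-of-fit against uniform at alpha = 0.01
  k <- 5
  eq <- toy_person(k)
  eq$age <- 40 + seq_len(k)
  res2 <- resample_weighted(eq, 20000, seed = 3)
  tab <- table(factor(res2$age, levels = eq$age))
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)

  # errors
  zero <- toy_person(2); zero$sample_weight <- c(0, 0)
  expect_error(resample_weighted(zero, 5), "zero")
  neg <- toy_person(2); neg$sample_weight <- c(1, -1)
  expect_error(resample_weighted(neg, 5), "negative")
})

test_that("resampling preserves the weighted distribution", {
  pop <- generate_population(n = 2000, seed = 4)
  res <- resample_weighted(pop, 100000, seed = 5)
  w_mean <- sum(pop$sbp * pop$sample_weight) / sum(pop$sample_weight)
  se <- sd(res$sbp) / sqrt(nrow(res))
  expect_lt(abs(mean(res$sbp) - w_mean), 3 * se)
})

test_that("entrant cohorts grow by the configured rate and are aged 35", {
  expect_equal(entrant_size(1000, 0.01, 3), 1030L)
  expect_equal(entrant_size(1000, 0, 4), 1000L)
  expect_equal(nrow(make_entrant_cohort(size = 0, seed = 1)), 0)
  expect_error(make_entrant_cohort(size = -5, seed = 1), "size")

  ent <- make_entrant_cohort(size = 200, year = 2, growth = 0.01, seed = 9)
  expect_equal(nrow(ent), entrant_size(200, 0.01, 2))
  expect_true(all(ent$age == 35))
})

test_that("summaries report calibration quantities", {
  expect_error(summarize_population(generate_population(n = 0, seed = 1)),
               "empty")

  one <- generate_population(n = 1, seed = 6)
  s1 <- summarize_population(one)
  expect_equal(s1$continuous$sd, rep(0, nrow(s1$continuous)))
  expect_equal(s1$continuous$mean[s1$continuous$variable == "age"], one$age)

  pop <- generate_population(n = 50000, seed = 7)
  s <- summarize_population(pop)
  ins <- s$categorical[s$categorical$variable == "insurance", ]
  expect_equal(sum(ins$share), 1, tolerance = 1e-9)
  nuts <- s$intakes[s$intakes$factor == "nuts_seeds", ]
  expect_lt(abs(nuts$mean - 12.5), 4 * 29.0 / sqrt(50000))
  # zero-optimal factors: at-optimal share equals the configured point mass
  ssb <- s$intakes[s$intakes$factor == "ssb", ]
  expect_lt(abs(ssb$at_optimal - 0.481), 3 * sqrt(0.481 * 0.519 / 50000))
})
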