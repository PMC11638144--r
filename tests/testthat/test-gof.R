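test_that("m-array counts releases and next recaptures", {
  det <- rbind(c(1, 1, 0), c(1, 0, 0))
  m <- build_marray(det)
  expect_equal(m$m[1, 2], 1)
  expect_equal(m$releases, c(2L, 1L, 0L))
  expect_equal(m$never[1], 1)
  # no recaptures at all
  m0 <- build_marray(rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_true(all(m0$m == 0))
  expect_error(build_marray(matrix(1, 2, 1)), "two occasions")
})

test_that("first-diagonal m-array frequencies approach phi * p", {
  set.seed(31)
  det <- sim_cjs(3000, 6, phi = 0.8, p_aware = 0.5)
  m <- build_marray(det)
  frac <- diag(m$m[, -1]) / m$releases[-6]
  expected <- 0.8 * 0.5
  se <- sqrt(expected * (1 - expected) / m$releases[-6])
  expect_true(all(abs(frac - expected) < 3.5 * se))
})

test_that("trap-dependence chi-square matches the hand-computed 2x2 table", {
  # occasion 2 is the only informative table: 10 birds captured at 2 and
  # immediately recaptured, 10 birds missed at 2 whose next capture is late
  det <- rbind(
    matrix(rep(c(1, 1, 1, 0), 10), 10, 4, byrow = TRUE),
    matrix(rep(c(1, 0, 0, 1), 10), 10, 4, byrow = TRUE))
  res <- test_trap_dependence(det)
  expect_equal(res$df, 1)
  expect_equal(res$chi2, 20)     # Pearson chi-square of [[10,0],[0,10]]
  expect_gt(res$z, 0)            # trap-happiness direction
})

test_that("trap-dependence test holds its nominal size and detects trap-happiness", {
  set.seed(41)
  pvals <- replicate(150, {
    det <- sim_cjs(200, 8, phi = 0.8, p_aware = 0.45)
    test_trap_dependence(det)$p_value
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
  # strong trap-happiness: signed statistic positive, test rejects
  det <- sim_cjs(800, 10, phi = 0.85, p_aware = 0.8, p_unaware = 0.2)
  res <- test_trap_dependence(det)
  expect_gt(res$z, 2)
  expect_lt(res$p_value, 0.001)
})

test_that("transience test is null-calibrated and powered against a first-interval effect", {
  set.seed(51)
  pvals <- replicate(150, {
    det <- sim_cjs(200, 8, phi = 0.8, p_aware = 0.45)
    test_transience(det)$p_value
  })
  rate <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.11)
  det <- sim_cjs(2000, 10, phi = 0.85, p_aware = 0.5, delta = 0.3)
  res <- test_transience(det)
  expect_lt(res$p_value, 0.001)
  expect_gt(res$z, 0)
  # everyone reseen: no transience signal
  det_all <- rbind(c(1, 1, 1), c(0, 1, 1))
  expect_equal(test_transience(det_all)$chi2, 0)
})

test_that("qaicc follows the corrected quasi-likelihood formula", {
  expect_equal(qaicc(100, 5, 1.0, 1000), 100 + 10 + 60 / 994)
  expect_equal(qaicc(100, 5, 2.0, 1000), 50 + 10 + 60 / 994)
  # strictly increasing in np at fixed deviance, chat, n_eff
  q <- vapply(1:10, function(np) qaicc(100, np, 2, 500), numeric(1))
  expect_true(all(diff(q) > 0))
  expect_error(qaicc(100, 5, 0, 1000), "chat")
  expect_error(qaicc(100, 5, 1, 6), "n_eff")
})

test_that("akaike weights reproduce the ranking arithmetic", {
  w <- akaike_weights(c(4362.494, 4365.967, 4369.104, 4371.101))
  expect_equal(round(w, 3), c(0.815, 0.144, 0.030, 0.011))
  expect_equal(akaike_weights(rep(3, 4)), rep(0.25, 4))
  expect_equal(akaike_weights(c(0, 2 * log(9))), c(0.9, 0.1))
  # invariant to adding a constant
  expect_equal(akaike_weights(c(10, 12, 15)),
               akaike_weights(c(10, 12, 15) + 1000))
  expect_equal(sum(akaike_weights(runif(6, 100, 110))), 1, tolerance = 1e-10)
  expect_error(akaike_weights(numeric(0)), "non-empty")
})

test_that("model ranking prefers the generating structure", {
  specs <- list(
    constant = model_spec(survival = "constant", recapture = "trap",
                          rho = 147 / 182),
    area = model_spec(survival = "area", recapture = "trap", rho = 147 / 182))
  wins <- 0
  for (s in 1:5) {
    cfg <- simulation_config(
      n_individuals = 400, n_years = 10,
      params = parameter_set(phi = c(0.95, 0.45, 0.8, 0.9)),
      deployment = list(years = 2002:2006, prob = 0.4), seed = s)
    sim <- simulate_dataset(cfg)
    tab <- run_model_set(sim$data, specs, chat = 1, n_starts = 1)
    expect_equal(tab$delta_qaicc[1], 0)
    expect_equal(sum(tab$weight), 1, tolerance = 1e-10)
    if (tab$model[1] == "area") wins <- wins + 1
  }
  expect_gte(wins, 4)
  # single-model table has weight one
  tab1 <- run_model_set(sim_one <- simulate_dataset(
    simulation_config(150, 8, params = parameter_set(), seed = 77))$data,
    specs["constant"], chat = 1, n_starts = 1)
  expect_equal(tab1$weight, 1)
})
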