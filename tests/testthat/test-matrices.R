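test_that("transition rows sum to one and dead is absorbing for random parameters", {
  sp <- state_space()
  set.seed(11)
  for (rep in 1:20) {
    ps <- parameter_set(phi = runif(4, 0.2, 0.99), delta = runif(1, 0, 0.4),
                        p_aware = runif(1), p_unaware = runif(1),
                        change = runif(1, 0, 1 / 3),
                        pi = as.vector(prop.table(runif(4) + 0.1)),
                        rho = runif(1))
    M <- transition_matrix(sp, ps, deploy = rep %% 2 == 0,
                           first = rep %% 3 == 0)
    expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
    expect_identical(unname(M[sp$dead, ]),
                     c(rep(0, sp$n_states - 1), 1))
  }
})

test_that("degenerate parameters give the expected deterministic transitions", {
  sp <- state_space()
  # phi = 1, c = 0, p = 0: area and device preserved, bird becomes unaware
  ps <- parameter_set(phi = 1, change = 0, p_aware = 0, p_unaware = 0)
  M <- transition_matrix(sp, ps)
  for (a in 1:4) {
    for (w in 1:2) {
      expect_equal(unname(M[state_index(sp, a, 1, w),
                            state_index(sp, a, 1, 2)]), 1)
    }
  }
})

test_that("stay mass is 1 - 3c and survival mass equals phi", {
  sp <- state_space()
  ps <- parameter_set(phi = 1, change = 0.07)
  M <- transition_matrix(sp, ps)
  for (a in 1:4) {
    row <- M[state_index(sp, a, 1, 1), ]
    same_area <- state_index(sp, rep(a, 6), rep(1:3, 2), rep(1:2, each = 3))
    expect_equal(unname(sum(row[same_area])), 0.79)
  }
  # Equatorial survival mass 0.428 under the area-survival configuration
  ps2 <- parameter_set(phi = c(0.961, 0.428, 0.821, 0.903))
  M2 <- transition_matrix(sp, ps2)
  eq_row <- M2[state_index(sp, 2, 1, 1), ]
  expect_equal(unname(1 - eq_row[sp$dead]), 0.428)
  expect_equal(unname(sum(eq_row[-sp$dead])), 0.428, tolerance = 1e-12)
})

test_that("without climate slopes or first-interval effect the model is time-homogeneous", {
  sp <- state_space()
  ps <- parameter_set(phi = 0.85, delta = 0, change = 0.07)
  cov <- tibble::tibble(year = 2000:2005, soi = rnorm(6), wnao = rnorm(6))
  Ms <- lapply(2001:2005, function(y) {
    transition_matrix(sp, ps, year = y, covariates = cov)
  })
  for (M in Ms[-1]) expect_equal(M, Ms[[1]])
  # with a SOI slope the matrices differ across years
  ps2 <- parameter_set(phi = 0.85, soi_slope = 0.5)
  M1 <- transition_matrix(sp, ps2, year = 2001, covariates = cov)
  M2 <- transition_matrix(sp, ps2, year = 2002, covariates = cov)
  expect_gt(max(abs(M1 - M2)), 0)
})

test_that("infeasible change probabilities are rejected", {
  sp <- state_space()
  expect_error(parameter_set(change = 0.4), "infeasible")
  expect_error(winterCMR:::change_matrix(0.4, 4), "infeasible")
  expect_silent(winterCMR:::change_matrix(1 / 3, 4))
})

test_that("stay_probability follows the closed form", {
  expect_equal(stay_probability(0.07, 4), 0.79)
  expect_equal(stay_probability(0, 7), 1)
  expect_equal(stay_probability(1 / 3, 4), 0)
  expect_error(stay_probability(0.5, 4), "infeasible")
})

test_that("design resolution counts coefficients before fitting", {
  sp <- state_space()
  cov <- tibble::tibble(year = 2000:2009, soi = rnorm(10), wnao = rnorm(10))
  yrs <- 2000:2009
  np_of <- function(...) resolve_design(model_spec(...), sp, cov, yrs)$np
  # survival coefficient counts under the main hypothesis designs
  expect_equal(np_of(survival = "constant", recapture = "constant",
                     change = "constant", rho = "none"), 1 + 1 + 1)
  expect_equal(np_of(survival = "area", recapture = "constant",
                     change = "constant", rho = "none"), 4 + 1 + 1)
  expect_equal(np_of(survival = "area+soi", recapture = "constant",
                     change = "constant", rho = "none"), 5 + 1 + 1)
  expect_equal(np_of(survival = "area*soi", recapture = "constant",
                     change = "constant", rho = "none"), 8 + 1 + 1)
  expect_equal(np_of(survival = "constant", recapture = "trap",
                     change = "from_area", initial = "area",
                     first_encounter = "constant", rho = "estimate"),
               1 + 1 + 4 + 3 + 2 + 1)
  # realized parameters are valid probabilities
  des <- resolve_design(model_spec(survival = "area+soi", change = "wnao",
                                   initial = "canary_others"), sp, cov, yrs)
  r <- des$realize(des$start)
  expect_true(all(r$phi >= 0 & r$phi <= 1))
  expect_equal(sum(r$pi), 1)
  expect_lt(max(abs(apply(r$C, 3, rowSums) - 1)), 1e-12)
})
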