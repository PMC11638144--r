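make_data <- function(events, release = NULL, sp = state_space()) {
  encounter_data(events, release, space = sp)
}

test_that("closed-form histories match the forward likelihood", {
  sp <- state_space()
  # captured only at the final occasion: contributes exactly 0
  d <- make_data(matrix(c(0L, 0L, 1L), 1))
  ps <- parameter_set(phi = 0.7, change = 0.05, p_aware = 0.4, p_unaware = 0.2)
  expect_equal(dataset_loglik(d, params = ps), 0)

  # two occasions, captured twice, no movement: P = phi * p_aware
  d2 <- make_data(matrix(c(1L, 1L), 1))
  ps2 <- parameter_set(phi = 0.5, change = 0, p_aware = 0.5, p_unaware = 0.1)
  expect_equal(dataset_loglik(d2, params = ps2), log(0.25), tolerance = 1e-12)

  # captured, then missed: P = phi*(1-p) + (1-phi)
  d3 <- make_data(matrix(c(1L, 0L), 1))
  expect_equal(dataset_loglik(d3, params = ps2), log(0.5 * 0.5 + 0.5),
               tolerance = 1e-12)
})

test_that("forward likelihood equals exhaustive path enumeration on 3-occasion histories", {
  sp <- state_space()
  E <- emission_matrix(sp, "inter")
  init_cols <- state_index(sp, 1:4, 1, 1)
  set.seed(21)
  cases <- list(
    list(events = c(1L, 1L, 1L), release = c(1L, 1L, 0L)),
    list(events = c(1L, 0L, 1L), release = c(1L, 0L, 0L)),
    list(events = c(1L, 3L, 0L), release = c(2L, 1L, 0L)),  # deploy, reveal
    list(events = c(1L, 6L, 1L), release = c(2L, 1L, 0L)),  # deploy, failed
    list(events = c(1L, 0L, 5L), release = c(2L, 0L, 0L)),  # carry 2 winters
    list(events = c(0L, 1L, 0L), release = c(0L, 1L, 0L))
  )
  for (case in cases) {
    for (rep in 1:3) {
      ps <- parameter_set(phi = runif(4, 0.3, 0.95), delta = runif(1, 0, 0.3),
                          p_aware = runif(1, 0.2, 0.9),
                          p_unaware = runif(1, 0.1, 0.8),
                          change = runif(1, 0.01, 0.3),
                          pi = as.vector(prop.table(runif(4) + 0.2)),
                          rho = runif(1, 0.5, 0.99))
      d <- make_data(matrix(case$events, 1), matrix(case$release, 1))
      ll <- dataset_loglik(d, params = ps)
      # independent oracle: enumerate every hidden-state path
      first <- which(case$events > 0)[1]
      r <- winterCMR:::realize_params(ps, sp, d$covariates, d$years)
      Ts <- lapply(1:2, function(t) {
        fi <- first == t
        dep <- case$events[t] > 0 && case$release[t] == 2L
        key <- 1 + fi + 2 * dep
        winterCMR:::interval_matrices(
          sp, r, t, need = replace(rep(FALSE, 4), key, TRUE))[[key]]
      })
      init <- numeric(sp$n_states)
      init[init_cols] <- ps$pi
      oracle <- brute_force_loglik(case$events, Ts, E, init, first)
      expect_equal(ll, oracle, tolerance = 1e-10)
      # the exported single-history interface agrees too
      expect_equal(history_loglik(case$events, Ts, E, init, first), oracle,
                   tolerance = 1e-10)
    }
  }
})

test_that("dataset likelihood is additive and permutation invariant", {
  cfg <- simulation_config(n_individuals = 50, n_years = 8,
                           params = parameter_set(phi = 0.8, delta = 0.1),
                           deployment = list(years = c(2002, 2004), prob = 0.4),
                           seed = 5)
  sim <- simulate_dataset(cfg)
  d <- sim$data
  ps <- cfg$params
  total <- dataset_loglik(d, params = ps)
  by_ind <- dataset_loglik(d, params = ps, by_individual = TRUE)
  expect_equal(total, sum(by_ind), tolerance = 1e-9)
  perm <- sample(nrow(d$events))
  d2 <- encounter_data(d$events[perm, ], d$release[perm, ],
                       covariates = d$covariates, years = d$years,
                       ids = d$ids[perm], space = d$space)
  expect_equal(dataset_loglik(d2, params = ps), total, tolerance = 1e-9)
})

test_that("empty datasets and impossible histories are handled", {
  sp <- state_space()
  d0 <- encounter_data(matrix(1L, 0, 5), matrix(0L, 0, 5), space = sp)
  expect_equal(dataset_loglik(d0, params = parameter_set()), 0)
  # change = 0 pins the revealed area; a different reveal later is impossible
  ev <- matrix(c(1L, 2L, 0L, 3L), 1)
  rel <- matrix(c(2L, 2L, 0L, 0L), 1)
  d <- make_data(ev, rel)
  ps <- parameter_set(change = 0, p_aware = 0.5, p_unaware = 0.5, rho = 0.9)
  expect_error(dataset_loglik(d, params = ps), "impossible")
})

test_that("equal aware/unaware recapture collapses to the no-trap model", {
  cfg <- simulation_config(n_individuals = 120, n_years = 8,
                           params = parameter_set(p_aware = 0.5,
                                                  p_unaware = 0.5),
                           deployment = list(years = 2002:2004, prob = 0.3),
                           seed = 9)
  sim <- simulate_dataset(cfg)
  spec_trap <- model_spec(recapture = "trap", rho = 147 / 182)
  spec_const <- model_spec(recapture = "constant", rho = 147 / 182)
  des_t <- resolve_design(spec_trap, sim$data$space, sim$data$covariates,
                          sim$data$years)
  des_c <- resolve_design(spec_const, sim$data$space, sim$data$covariates,
                          sim$data$years)
  th_c <- des_c$start
  th_t <- des_t$start
  th_t[c("p:aware", "p:unaware")] <- th_c["p:(Intercept)"] <- 0.3
  expect_equal(dataset_loglik(sim$data, spec = spec_trap, theta = th_t),
               dataset_loglik(sim$data, spec = spec_const, theta = th_c),
               tolerance = 1e-9)
})

test_that("estimation error shrinks as sample size grows", {
  spec <- model_spec(survival = "constant", recapture = "trap", rho = "none")
  err <- function(n, seed) {
    cfg <- simulation_config(
      n_individuals = n, n_years = 10,
      params = parameter_set(phi = 0.841, pi = 1, change = 0),
      deployment = list(years = numeric(0), prob = 0), seed = seed)
    sim <- simulate_dataset(cfg)
    fit <- fit_model(sim$data, spec, n_starts = 1, se = FALSE)
    abs(fit$real$estimate[fit$real$term == "phi[Canary]"] - 0.841)
  }
  errors <- vapply(1:5, function(s) c(err(150, s), err(1200, s + 100)),
                   numeric(2))
  expect_lt(median(errors[2, ]), median(errors[1, ]))
})
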