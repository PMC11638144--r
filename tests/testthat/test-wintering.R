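# Assignment table reproducing the published tracking structure: individual
# cycle counts 34/15/11/4/7 (1-5 cycles), area totals 64/11/32/40 plus one
# excluded track.
study_assignments <- function() {
  cycles <- rep(c(1, 2, 3, 4, 5), c(34, 15, 11, 4, 7))
  ids <- sprintf("I%02d", seq_along(cycles))
  tb <- tibble::tibble(
    id = rep(ids, cycles),
    year = unlist(lapply(cycles, seq_len)) + 2008L)
  areas <- rep(c("Canary", "Equatorial", "Guinea", "Angola"),
               c(64, 11, 32, 40))
  tb$area <- c(areas, "excluded")   # 147 in-scheme tracks + 1 excluded
  tb
}

test_that("fidelity summary reproduces the printed track arithmetic", {
  fs <- fidelity_summary(study_assignments())
  expect_equal(fs$n_tracks, 148)
  expect_equal(fs$n_individuals, 71)
  expect_equal(fs$n_multi, 37)
  expect_equal(fs$cycles$n_individuals, c(34, 15, 11, 4, 7))
  ac <- fs$area_counts
  expect_equal(sum(ac$n), 147)      # the excluded track is not shared out
  expect_equal(ac$n[ac$area == "Canary"], 64)
  expect_equal(round(ac$pct[ac$area == "Canary"], 1), 43.5)
  expect_equal(round(ac$pct[ac$area == "Equatorial"], 1), 7.5)
  expect_equal(round(ac$pct[ac$area == "Guinea"], 1), 21.8)
  expect_equal(round(ac$pct[ac$area == "Angola"], 1), 27.2)
})

test_that("degenerate and invalid fidelity inputs are handled", {
  one <- tibble::tibble(id = "a", year = 2000, area = "Canary")
  fs <- fidelity_summary(one)
  expect_equal(fs$n_multi, 0)
  expect_true(is.na(fs$pct_consistent))
  dup <- tibble::tibble(id = c("a", "a"), year = c(2000, 2000),
                        area = c("Canary", "Guinea"))
  expect_error(fidelity_summary(dup), "duplicate")
})

test_that("alpha is 1 for perfect fidelity and matches the hand-computed micro-example", {
  perfect <- tibble::tibble(id = rep(c("a", "b", "c"), each = 3),
                            year = rep(2000:2002, 3),
                            area = rep(c("Canary", "Guinea", "Angola"), each = 3))
  expect_equal(krippendorff_alpha(perfect), 1)
  # 2 consistent + 2 discordant pairs over 2 areas with equal margins:
  # coincidence matrix o = [[2,2],[2,2]], D_o = 4, D_e = 32/7, alpha = 0.125
  micro <- tibble::tibble(
    id = rep(c("u1", "u2", "u3", "u4"), each = 2),
    year = rep(2000:2001, 4),
    area = c("A", "A", "B", "B", "A", "B", "B", "A"))
  expect_equal(krippendorff_alpha(micro), 0.125)
  expect_equal(brute_force_alpha(split(micro$area, micro$id)), 0.125)
})

test_that("alpha agrees with the independent pairwise oracle on random tables", {
  set.seed(61)
  for (rep in 1:10) {
    n_id <- sample(5:20, 1)
    tb <- tibble::tibble(
      id = rep(sprintf("i%02d", seq_len(n_id)),
               times = sample(2:5, n_id, replace = TRUE)))
    tb$year <- unlist(lapply(rle(tb$id)$lengths, seq_len))
    tb$area <- sample(c("Canary", "Equatorial", "Guinea", "Angola"),
                      nrow(tb), replace = TRUE)
    expect_equal(krippendorff_alpha(tb),
                 brute_force_alpha(split(tb$area, tb$id)),
                 tolerance = 1e-12)
  }
})

test_that("alpha is invariant to relabelling areas and near zero under shuffling", {
  set.seed(71)
  tb <- tibble::tibble(
    id = rep(sprintf("i%03d", 1:100), each = 3),
    year = rep(2000:2002, 100),
    area = unlist(lapply(1:100, function(i) {
      a <- sample(4, 1)
      ifelse(runif(3) < 0.79, c("Canary", "Equatorial", "Guinea", "Angola")[a],
             sample(c("Canary", "Equatorial", "Guinea", "Angola")[-a], 3,
                    replace = TRUE))
    })))
  a1 <- krippendorff_alpha(tb)
  relabel <- c(Canary = "Z4", Equatorial = "Z3", Guinea = "Z2", Angola = "Z1")
  tb2 <- dplyr::mutate(tb, area = unname(relabel[area]))
  expect_equal(krippendorff_alpha(tb2), a1)
  # permutation null
  alphas <- replicate(100, {
    tbs <- tb
    tbs$area <- sample(tbs$area)
    krippendorff_alpha(tbs)
  })
  expect_lt(abs(mean(alphas)), 0.05)
})

test_that("bootstrap interval is degenerate for perfect tables and seeded", {
  perfect <- tibble::tibble(id = rep(c("a", "b", "c", "d"), each = 3),
                            year = rep(2000:2002, 4),
                            area = rep(c("Canary", "Guinea", "Angola",
                                         "Canary"), each = 3))
  ci <- alpha_bootstrap_ci(perfect, n_boot = 200, seed = 1)
  expect_equal(ci$conf.low, 1)
  expect_equal(ci$conf.high, 1)
  tb <- study_assignments()
  ci1 <- alpha_bootstrap_ci(tb, n_boot = 300, seed = 42)
  ci2 <- alpha_bootstrap_ci(tb, n_boot = 300, seed = 42)
  expect_identical(ci1, ci2)
  expect_true(ci1$conf.low <= ci1$alpha && ci1$alpha <= ci1$conf.high)
  expect_warning(alpha_bootstrap_ci(tb, n_boot = 50, seed = 1), "100")
})

test_that("bootstrap intervals cover the long-run repeatability of the stay process", {
  set.seed(81)
  gen_table <- function(n_id, n_yr) {
    areas <- c("Canary", "Equatorial", "Guinea", "Angola")
    tibble::tibble(
      id = rep(sprintf("i%03d", seq_len(n_id)), each = n_yr),
      year = rep(seq_len(n_yr) + 1999, n_id),
      area = unlist(lapply(seq_len(n_id), function(i) {
        a <- sample(4, 1, prob = c(0.28, 0.24, 0.24, 0.24))
        out <- character(n_yr)
        for (t in seq_len(n_yr)) {
          out[t] <- areas[a]
          if (runif(1) > 0.79) a <- sample((1:4)[-a], 1)
        }
        out
      })))
  }
  alpha_ref <- krippendorff_alpha(gen_table(3000, 3))
  covered <- 0
  for (r in 1:15) {
    ci <- alpha_bootstrap_ci(gen_table(60, 3), n_boot = 250, seed = r)
    if (ci$conf.low <= alpha_ref && alpha_ref <= ci$conf.high) {
      covered <- covered + 1
    }
  }
  expect_gte(covered, 12)
})
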