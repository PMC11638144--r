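#' Fit a multievent model by maximum likelihood
#'
#' Maximises the conditional-on-first-release HMM likelihood over link-scale
#' coefficients with a quasi-Newton optimiser, from the best of `n_starts`
#' initialisations (a structured default start plus seeded uniform(-2, 2)
#' draws). Standard errors come from the observed information at the optimum;
#' real-parameter 95% intervals back-transform Wald intervals on the link
#' scale. Coefficients are box-constrained to |theta| <= 15 to avoid overflow
#' of the logistic link; estimates near that box are flagged as boundary.
#'
#' @param data An [encounter_data()].
#' @param spec A [model_spec()].
#' @param n_starts Number of optimisation starts.
#' @param seed Seed for the random starts.
#' @param tolerance Relative convergence tolerance passed to [stats::nlminb()].
#' @param start Optional explicit start vector (used as the first start).
#' @param se Compute the observed-information standard errors (set `FALSE`
#'   to skip the Hessian, e.g. inside simulation loops that only need point
#'   estimates).
#' @return An object of class `cmr_fit`: coefficients, log-likelihood,
#'   deviance, `np`, covariance matrix, a `real` tibble of back-transformed
#'   parameter estimates with 95% intervals, and convergence diagnostics.
#' @export
fit_model <- function(data, spec, n_starts = 10, seed = NULL,
                      tolerance = 1e-8, start = NULL, se = TRUE) {
  stopifnot(inherits(data, "encounter_data"), inherits(spec, "model_spec"))
  space <- data$space
  des <- resolve_design(spec, space, data$covariates, data$years)
  np <- des$np

  negll <- function(theta) {
    r <- des$realize(theta, strict = FALSE)
    if (!is.null(r$infeasible)) return(1e8 * (1 + r$infeasible))
    ll <- sum(forward_engine(data, r, space))
    if (!is.finite(ll)) return(1e9)
    -ll
  }

  if (!is.null(seed)) set.seed(seed)
  starts <- list(if (is.null(start)) des$start else start)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      starts[[i + 1]] <- stats::runif(np, -2, 2)
    }
  }

  best <- NULL
  n_ok <- 0
  for (s0 in starts) {
    opt <- tryCatch(
      stats::nlminb(s0, negll, lower = -15, upper = 15,
                    control = list(rel.tol = tolerance, iter.max = 1000,
                                   eval.max = 3000)),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$objective)) next
    if (opt$convergence == 0) n_ok <- n_ok + 1
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best) || best$objective >= 1e7) {
    stop("fit_model: no start converged to a feasible optimum", call. = FALSE)
  }
  theta <- stats::setNames(best$par, des$coef_names)
  ll <- -best$objective

  vcov <- se_vec <- NULL
  if (se) {
    H <- tryCatch(numDeriv::hessian(negll, theta), error = function(e) NULL)
    if (!is.null(H)) {
      vcov <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(vcov) && all(is.finite(diag(vcov))) &&
          all(diag(vcov) > 0)) {
        se_vec <- stats::setNames(sqrt(diag(vcov)), des$coef_names)
        dimnames(vcov) <- list(des$coef_names, des$coef_names)
      } else {
        vcov <- NULL
        warning("fit_model: singular observed information; SEs unavailable",
                call. = FALSE)
      }
    }
  }
  if (any(abs(theta) > 14)) {
    warning("fit_model: estimate at or near the link-scale boundary",
            call. = FALSE)
  }

  fit <- structure(
    list(spec = spec, design = des, coef = theta, se = se_vec, vcov = vcov,
         log_likelihood = ll, deviance = -2 * ll, np = np,
         n_releases = data$n_releases, n_individuals = nrow(data$events),
         converged = best$convergence == 0, n_starts = length(starts),
         n_converged = n_ok, space = space, years = data$years,
         real = NULL),
    class = "cmr_fit")
  fit$real <- real_parameter_table(fit)
  fit
}

## Delta-method Wald interval for f(theta), back-transformed on the logit
## scale of the probability f.
prob_ci <- function(f, theta, vcov, level = 0.95) {
  est <- unname(f(theta))
  if (is.null(vcov)) return(c(est, NA, NA))
  g <- tryCatch(numDeriv::grad(f, theta), error = function(e) NULL)
  if (is.null(g)) return(c(est, NA, NA))
  v <- drop(t(g) %*% vcov %*% g)
  if (!is.finite(v) || v < 0) return(c(est, NA, NA))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (est <= 0 || est >= 1) {
    half <- z * sqrt(v)
    return(c(est, max(0, est - half), min(1, est + half)))
  }
  se_link <- sqrt(v) / (est * (1 - est))
  eta <- logit(est)
  c(est, invlogit(eta - z * se_link), invlogit(eta + z * se_link))
}

## Build the real-parameter table of a fit (probability scale, 95% CI).
real_parameter_table <- function(fit) {
  des <- fit$design
  spec <- fit$spec
  k <- des$k
  space <- fit$space
  theta <- fit$coef
  items <- list()
  add <- function(term, f) items[[length(items) + 1]] <<- list(term = term, f = f)

  r0 <- function(theta) des$realize(theta, strict = FALSE)
  for (a in seq_len(k)) {
    local({
      a_ <- a
      add(paste0("phi[", space$areas[a_], "]"),
          function(th) {
            r <- r0(th); mean(r$phi[a_, 1, ])
          })
    })
  }
  if (spec$survival == "geo") {
    add("phi[tagged]", function(th) { r <- r0(th); mean(r$phi[1, 2, ]) })
  }
  if (spec$first_encounter == "constant") add("delta", function(th) r0(th)$delta)
  if (k > 1) {
    if (spec$change %in% c("from_area", "from_area+wnao")) {
      for (a in seq_len(k)) {
        local({
          a_ <- a
          add(paste0("c[from ", space$areas[a_], "]"),
              function(th) mean(r0(th)$C[a_, if (a_ == 1) 2 else 1, ]))
        })
      }
    } else if (spec$change == "to_area") {
      for (a in seq_len(k)) {
        local({
          a_ <- a
          add(paste0("stay[", space$areas[a_], "]"),
              function(th) mean(r0(th)$C[a_, a_, ]))
        })
      }
    } else {
      add("c", function(th) mean(r0(th)$C[1, 2, ]))
    }
    for (a in seq_len(k)) {
      local({
        a_ <- a
        add(paste0("pi[", space$areas[a_], "]"), function(th) r0(th)$pi[a_])
      })
    }
  }
  add("p[aware]", function(th) mean(r0(th)$p[1, ]))
  add("p[unaware]", function(th) mean(r0(th)$p[2, ]))
  if (identical(spec$rho, "estimate")) add("rho", function(th) r0(th)$rho)

  rows <- purrr::map(items, function(it) {
    ci <- prob_ci(it$f, theta, fit$vcov)
    tibble::tibble(term = it$term, estimate = ci[1],
                   conf.low = ci[2], conf.high = ci[3])
  })
  dplyr::bind_rows(rows)
}

#' @export
print.cmr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<cmr_fit> logLik %.3f deviance %.3f np %d%s\n",
              x$log_likelihood, x$deviance, x$np,
              if (x$converged) "" else " (NOT converged)"))
  print.data.frame(as.data.frame(
    dplyr::mutate(x$real, dplyr::across(dplyr::where(is.numeric),
                                        ~ round(.x, digits)))),
    row.names = FALSE)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the real-parameter estimates of a fitted multievent model
#'
#' @param x A `cmr_fit`.
#' @param link Return link-scale coefficients instead of the probability-scale
#'   real-parameter table.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`, `conf.high`
#'   (probability scale) or `term`, `estimate`, `std.error` (link scale).
#' @export
tidy.cmr_fit <- function(x, link = FALSE, ...) {
  if (link) {
    tibble::tibble(term = names(x$coef), estimate = unname(x$coef),
                   std.error = if (is.null(x$se)) NA_real_ else unname(x$se))
  } else {
    x$real
  }
}

#' One-row summary of a fitted multievent model
#'
#' @param x A `cmr_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `logLik`, `deviance`, `np`, `nobs` (number of
#'   releases), `n_individuals`, `converged`, `n_starts`.
#' @export
glance.cmr_fit <- function(x, ...) {
  tibble::tibble(logLik = x$log_likelihood, deviance = x$deviance, np = x$np,
                 nobs = x$n_releases, n_individuals = x$n_individuals,
                 converged = x$converged, n_starts = x$n_starts)
}

#' Derived parameters with delta-method intervals
#'
#' @param fit A converged `cmr_fit`.
#' @param target One of `"stay_probability"` (probability of keeping the
#'   wintering area between consecutive winters), `"area_survival"` (survival
#'   for `area` at a given `soi` value) or `"first_year_survival"`
#'   (`phi * (1 - delta)`).
#' @param area Area label or index for `"area_survival"`.
#' @param soi SOI value for `"area_survival"`.
#' @return A one-row tibble: `term`, `estimate`, `conf.low`, `conf.high`.
#' @export
derived_parameter <- function(fit, target = c("stay_probability",
                                              "area_survival",
                                              "first_year_survival"),
                              area = 1, soi = 0) {
  stopifnot(inherits(fit, "cmr_fit"))
  target <- match.arg(target)
  if (!fit$converged) warning("derived_parameter: fit did not converge")
  des <- fit$design
  k <- des$k
  if (is.character(area)) area <- match(area, fit$space$areas)
  f <- switch(target,
    stay_probability = function(th) {
      r <- des$realize(th, strict = FALSE)
      mean(r$C[1, 1, ])
    },
    area_survival = function(th) {
      r <- des$realize(th, strict = FALSE)
      # survival at the requested SOI: shift the linear predictor by the
      # difference between the requested and per-interval SOI values
      eta <- logit(r$phi[area, 1, ])
      if (grepl("soi", fit$spec$survival)) {
        slope_cols <- grepl("soi", des$coef_names)
        slope <- sum(th[slope_cols] *
                       (if (sum(slope_cols) > 1) tabulate(area, sum(slope_cols)) else 1))
        mean(invlogit(eta + slope * (soi - des$soi)))
      } else mean(invlogit(eta))
    },
    first_year_survival = function(th) {
      r <- des$realize(th, strict = FALSE)
      mean(r$phi[area, 1, ]) * (1 - r$delta)
    })
  ci <- prob_ci(f, fit$coef, fit$vcov)
  tibble::tibble(term = target, estimate = ci[1], conf.low = ci[2],
                 conf.high = ci[3])
}
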