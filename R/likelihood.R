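#' Forward-algorithm log-likelihood of a single encounter history
#'
#' Computes the probability of one individual's event sequence conditional on
#' its first capture and release, by the scaled forward algorithm of the
#' hidden Markov model. The initial state mixes the wintering area over `init`
#' (device and awareness are known at release); emissions are deterministic
#' given the state, so conditioning on an event masks the incompatible states.
#'
#' @param events Integer vector of inter event codes over all occasions.
#' @param transitions List of transition matrices; element `t` moves occasion
#'   `t` to `t + 1` (entries before the first capture may be `NULL`).
#' @param emission Inter emission matrix from [emission_matrix()].
#' @param init Initial state distribution at the first capture occasion
#'   (length `n_states`).
#' @param first First capture occasion (defaults to the first nonzero event).
#' @return The log-likelihood (<= 0).
#' @export
history_loglik <- function(events, transitions, emission, init,
                           first = which(events > 0)[1]) {
  T_ <- length(events)
  stopifnot(first >= 1, first <= T_, abs(sum(init) - 1) < 1e-9)
  alpha <- init
  ll <- 0
  if (first < T_) {
    for (t in (first + 1):T_) {
      alpha <- as.vector(alpha %*% transitions[[t - 1]])
      alpha <- alpha * emission[, events[t] + 1L]
      s <- sum(alpha)
      if (s <= 0) {
        stop(sprintf("history_loglik: event %d at occasion %d is impossible",
                     events[t], t), call. = FALSE)
      }
      ll <- ll + log(s)
      alpha <- alpha / s
    }
  }
  ll
}

## Realize probability-scale parameters from a parameter_set for a dataset.
realize_params <- function(params, space, covariates, years) {
  k <- space$n_areas
  n_int <- length(years) - 1L
  idx <- match(years[-1], covariates$year)
  soi <- covariates$soi[idx]
  wnao <- covariates$wnao[idx]
  phi_base <- rep(params$phi, length.out = k)
  phi <- array(0, dim = c(k, 2, n_int))
  for (t in seq_len(n_int)) {
    phi[, , t] <- invlogit(logit(phi_base) + params$soi_slope * soi[t])
  }
  C <- array(0, dim = c(k, k, n_int))
  for (t in seq_len(n_int)) {
    cc <- invlogit(logit(params$change) + params$wnao_slope * wnao[t])
    C[, , t] <- change_matrix(cc, k)
  }
  list(phi = phi, delta = params$delta, C = C, pi = params$pi,
       p = matrix(c(params$p_aware, params$p_unaware), 2, n_int),
       rho = params$rho, soi = soi, wnao = wnao)
}

## Transition matrices for one interval, keyed by variant
## 1 = plain, 2 = first interval, 3 = deploy, 4 = first + deploy.
interval_matrices <- function(space, r, t, need) {
  k <- space$n_areas
  grp <- ifelse(space$states$device[seq_len(space$n_alive)] == "none", 1L, 2L)
  a_of <- match(space$states$area[seq_len(space$n_alive)], space$areas)
  s <- r$phi[cbind(a_of, grp, t)]
  out <- vector("list", 4)
  for (v in which(need)) {
    first <- v %in% c(2L, 4L)
    deploy <- v %in% c(3L, 4L)
    sv <- if (first) s * (1 - r$delta) else s
    Cmat <- matrix(r$C[, , t], k, k)
    out[[v]] <- transition_kernel(space, sv, Cmat, r$p[1, t], r$p[2, t],
                                  rho = r$rho, deploy = deploy)
  }
  out
}

## Vectorised conditional-on-first-release forward algorithm over all
## individuals. Returns the vector of per-individual log-likelihoods.
forward_engine <- function(data, realized, space = data$space) {
  ev <- data$events
  rel <- data$release
  first <- data$first
  n <- nrow(ev); T_ <- ncol(ev); S <- space$n_states
  Emask <- t(emission_matrix(space, "inter"))  # events x states
  init_cols <- state_index(space, seq_len(space$n_areas), 1L, 1L)
  A <- matrix(0, n, S)
  ll <- numeric(n)
  w1 <- which(first == 1L)
  if (length(w1)) A[w1, init_cols] <- rep(realized$pi, each = length(w1))
  if (T_ < 2) return(ll)
  for (t in 2:T_) {
    # rows needing a non-plain transition (first interval and/or deployment)
    special <- which(first < t & (first == t - 1L | rel[, t - 1L] == 2L))
    keys <- integer(0)
    if (length(special)) {
      keys <- 1L + (first[special] == t - 1L) + 2L * (rel[special, t - 1L] == 2L)
    }
    need <- c(TRUE, tabulate(keys, 4L)[-1] > 0)
    Ms <- interval_matrices(space, realized, t - 1L, need)
    Aspec <- A[special, , drop = FALSE]
    A <- A %*% Ms[[1L]]
    for (key in unique(keys)) {
      rows <- keys == key
      A[special[rows], ] <- Aspec[rows, , drop = FALSE] %*% Ms[[key]]
    }
    newly <- which(first == t)
    if (length(newly)) A[newly, init_cols] <- rep(realized$pi, each = length(newly))
    A <- A * Emask[ev[, t] + 1L, , drop = FALSE]
    s <- .rowSums(A, n, S)
    act <- first <= t
    ll[act] <- ll[act] + log(s[act])
    A <- A / ifelse(s > 0, s, 1)
  }
  ll
}

#' Log-likelihood of an encounter dataset
#'
#' Sums the conditional-on-first-release forward log-likelihoods of all
#' individuals. Parameters can be given either as a probability-scale
#' [parameter_set()] (with optional climate slopes) or as link-scale
#' coefficients `theta` under a [model_spec()] design.
#'
#' @param data An [encounter_data()].
#' @param params A [parameter_set()], or `NULL` when using `spec` + `theta`.
#' @param spec A [model_spec()] (with `theta`).
#' @param theta Link-scale coefficient vector matching
#'   [resolve_design()]`$coef_names`.
#' @param by_individual Return the per-individual vector instead of the sum.
#' @return The total log-likelihood (or per-individual vector).
#' @export
dataset_loglik <- function(data, params = NULL, spec = NULL, theta = NULL,
                           by_individual = FALSE) {
  stopifnot(inherits(data, "encounter_data"))
  space <- data$space
  if (inherits(params, "parameter_set")) {
    realized <- realize_params(params, space, data$covariates, data$years)
  } else {
    stopifnot(inherits(spec, "model_spec"), is.numeric(theta))
    des <- resolve_design(spec, space, data$covariates, data$years)
    realized <- des$realize(theta)
  }
  ll <- forward_engine(data, realized, space)
  if (any(!is.finite(ll))) {
    bad <- which(!is.finite(ll))[1]
    stop(sprintf("dataset_loglik: impossible history for individual %s",
                 data$ids[bad]), call. = FALSE)
  }
  if (by_individual) ll else sum(ll)
}
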