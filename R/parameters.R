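#' Real-parameter set for the multievent model
#'
#' Collects the probability-scale parameters that drive the annual dynamics:
#' area-specific apparent survival, excess first-interval mortality, the
#' per-destination area-change probability, trap-dependent recapture
#' probabilities, the initial wintering-area distribution and the probability
#' that a deployed geolocator functions. Optional link-scale slopes attach the
#' climate covariates: `soi_slope` acts on logit survival, `wnao_slope` on the
#' logit per-destination change probability.
#'
#' @param phi Apparent annual survival; scalar or one value per area.
#' @param delta Excess mortality over the interval after first capture, in
#'   \[0,1\]; effective first-interval survival is `phi * (1 - delta)`.
#' @param p_aware,p_unaware Recapture probabilities for birds captured /
#'   missed at the previous occasion (trap-dependence).
#' @param change Per-destination annual probability of switching wintering
#'   area; scalar (symmetric) or one value per origin area.
#' @param pi Initial wintering-area distribution (sums to 1).
#' @param rho Probability a deployed geolocator records usable data.
#' @param soi_slope Slope of annual SOI on logit survival.
#' @param wnao_slope Slope of winter NAO on logit change probability.
#' @param n_areas Number of areas (defaults to `length(pi)`).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(phi = 0.841, delta = 0, p_aware = 0.6,
                          p_unaware = 0.35, change = 0.07,
                          pi = c(0.28, 0.24, 0.24, 0.24), rho = 147 / 182,
                          soi_slope = 0, wnao_slope = 0,
                          n_areas = length(pi)) {
  probs <- c(phi, delta, p_aware, p_unaware, change, pi, rho)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("parameter_set: all probability-scale values must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("parameter_set: pi must sum to 1", call. = FALSE)
  }
  if (length(pi) != n_areas) {
    stop("parameter_set: pi must have one entry per area", call. = FALSE)
  }
  if (!length(phi) %in% c(1L, n_areas)) {
    stop("parameter_set: phi must be scalar or per-area", call. = FALSE)
  }
  if (!length(change) %in% c(1L, n_areas)) {
    stop("parameter_set: change must be scalar or per-origin-area",
         call. = FALSE)
  }
  if (n_areas > 1 && any((n_areas - 1) * change > 1 + 1e-12)) {
    stop("parameter_set: infeasible change probability ((k-1)*c > 1)",
         call. = FALSE)
  }
  structure(list(phi = phi, delta = delta, p_aware = p_aware,
                 p_unaware = p_unaware, change = change, pi = pi, rho = rho,
                 soi_slope = soi_slope, wnao_slope = wnao_slope,
                 n_areas = n_areas),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  phi:", paste(signif(x$phi, 4), collapse = " "),
      if (x$delta > 0) sprintf("(first interval x %.3f)", 1 - x$delta) else "",
      "\n")
  cat("  change (per destination):", paste(signif(x$change, 4), collapse = " "), "\n")
  cat("  p (aware/unaware):", signif(x$p_aware, 4), "/", signif(x$p_unaware, 4), "\n")
  cat("  pi:", paste(signif(x$pi, 4), collapse = " "), " rho:", signif(x$rho, 4), "\n")
  invisible(x)
}

invlogit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

## Area-change matrix from per-origin, per-destination probability c.
change_matrix <- function(c_origin, n_areas) {
  c_origin <- rep(c_origin, length.out = n_areas)
  if (n_areas == 1) return(matrix(1, 1, 1))
  if (any((n_areas - 1) * c_origin > 1 + 1e-12)) {
    stop("change_matrix: infeasible change probability ((k-1)*c > 1)",
         call. = FALSE)
  }
  C <- matrix(rep(c_origin, n_areas), n_areas, n_areas)
  diag(C) <- 1 - (n_areas - 1) * c_origin
  C
}

## Core transition kernel between consecutive inter occasions.
## s: survival per alive state (length n_alive, (area, device, awareness)
## order); C: n_areas x n_areas area-change matrix; the device step depends on
## current awareness (captured birds have their device recovered and possibly
## a new one deployed; unseen birds keep what they carry); the awareness step
## is the stochastic detection at the next occasion.
transition_kernel <- function(space, s, C, p_aware, p_unaware, rho = 1,
                              deploy = FALSE) {
  k <- space$n_areas; nd <- space$n_device; nw <- space$n_awareness
  n <- space$n_states
  stopifnot(length(s) == space$n_alive, nrow(C) == k)
  if (any(abs(rowSums(C) - 1) > 1e-10)) {
    stop("transition_kernel: area-change matrix must be row-stochastic",
         call. = FALSE)
  }

  # device step conditional on current awareness
  D_unaware <- diag(nd)
  D_aware <- matrix(0, nd, nd)
  if (deploy) {
    if (nd >= 3) {
      D_aware[, 2] <- rho; D_aware[, 3] <- 1 - rho
    } else if (nd == 2) {
      if (rho < 1) stop("transition_kernel: failed devices need 3 statuses",
                        call. = FALSE)
      D_aware[, 2] <- 1
    } else stop("transition_kernel: cannot deploy with a single device status",
                call. = FALSE)
  } else {
    D_aware[, 1] <- 1
  }

  M <- matrix(0, n, n)
  p_by_w <- c(p_aware, p_unaware)[seq_len(nw)]
  for (w in seq_len(nw)) {
    D <- if (w == 1) D_aware else D_unaware
    # destination awareness distribution
    wdist <- if (nw == 1) 1 else c(p_by_w[w], 1 - p_by_w[w])
    blk <- kronecker(matrix(wdist, nrow = 1), kronecker(D, C))
    rows <- (w - 1) * k * nd + seq_len(k * nd)
    M[rows, seq_len(space$n_alive)] <- s[rows] * blk
    M[rows, space$dead] <- 1 - s[rows]
  }
  M[space$dead, space$dead] <- 1
  dimnames(M) <- list(space$states$label, space$states$label)
  M
}

#' Annual transition matrix between consecutive inter occasions
#'
#' Factorises the annual dynamics as survival, then wintering-area change,
#' then the device update (recovery at capture, deployment per the field
#' schedule, failure at deployment with probability `1 - rho`), then the
#' stochastic detection step that sets trap-awareness at the next occasion.
#' The dead state is absorbing. When `year` and `covariates` are supplied the
#' SOI and winter-NAO slopes of `params` modulate survival and change on the
#' logit scale.
#'
#' @param space A [state_space()].
#' @param params A [parameter_set()].
#' @param deploy Was a device deployed at this year's release (applies to
#'   birds captured this year)?
#' @param first Is this the individual's first interval after marking (excess
#'   mortality `delta` applies)?
#' @param year,covariates Optional calendar year and covariate tibble
#'   (columns `year`, `soi`, `wnao`) activating the climate slopes.
#' @return A row-stochastic `n_states` x `n_states` matrix.
#' @examples
#' sp <- state_space()
#' M <- transition_matrix(sp, parameter_set())
#' range(rowSums(M)) # 1 1
#' @export
transition_matrix <- function(space, params, deploy = FALSE, first = FALSE,
                              year = NULL, covariates = NULL) {
  stopifnot(inherits(space, "state_space"), inherits(params, "parameter_set"))
  if (params$n_areas != space$n_areas) {
    stop("transition_matrix: parameter_set and state_space disagree on areas",
         call. = FALSE)
  }
  soi <- wnao <- 0
  if (!is.null(year)) {
    if (is.null(covariates)) stop("transition_matrix: year given without covariates",
                                  call. = FALSE)
    i <- match(year, covariates$year)
    if (is.na(i)) stop(sprintf("transition_matrix: year %s missing from covariates", year),
                       call. = FALSE)
    soi <- covariates$soi[i]; wnao <- covariates$wnao[i]
  }
  phi <- invlogit(logit(rep(params$phi, length.out = space$n_areas)) +
                    params$soi_slope * soi)
  if (first) phi <- phi * (1 - params$delta)
  cc <- if (params$wnao_slope != 0 || !is.null(year)) {
    invlogit(logit(params$change) + params$wnao_slope * wnao)
  } else params$change
  C <- change_matrix(cc, space$n_areas)
  s <- rep(rep(phi, space$n_device), space$n_awareness)
  transition_kernel(space, s, C, params$p_aware, params$p_unaware,
                    rho = params$rho, deploy = deploy)
}

#' Probability of staying in the same wintering area
#'
#' For the symmetric change design with per-destination change probability
#' `c` and `k` areas, the stay probability is `1 - (k - 1) * c`.
#'
#' @param change_per_destination Per-destination change probability.
#' @param n_areas Number of areas.
#' @return The stay probability.
#' @examples
#' stay_probability(0.07, 4) # 0.79
#' @export
stay_probability <- function(change_per_destination, n_areas) {
  if (n_areas < 1 || any(change_per_destination < 0) ||
      any((n_areas - 1) * change_per_destination > 1)) {
    stop("stay_probability: infeasible change probability", call. = FALSE)
  }
  1 - (n_areas - 1) * change_per_destination
}
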