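#' Specify a model structure (the hypothesis grid)
#'
#' Each argument names one design from the hypothesis grid relating survival,
#' the first-encounter effect, wintering-area change, the initial area
#' distribution and recapture to areas and climate covariates.
#'
#' @param survival One of `"constant"`, `"area"`, `"canary_others"`,
#'   `"equatorial_others"`, `"soi"`, `"wnao"`, `"area+soi"`, `"area*soi"`,
#'   `"area+wnao"`, `"area*wnao"`, `"canary_others+soi"`,
#'   `"equatorial_others+soi"`, `"geo"` (device effect on survival).
#' @param first_encounter `"none"` or `"constant"` (a single excess-mortality
#'   parameter `delta`; first-interval survival is `phi * (1 - delta)`).
#' @param change `"constant"`, `"wnao"`, `"soi"`, `"from_area"`,
#'   `"from_area+wnao"` (per-destination logit designs) or `"to_area"`
#'   (destination-specific multinomial logit with "stay" as reference).
#' @param initial `"equal"`, `"canary_others"` or `"area"` (multinomial logit,
#'   first area as reference).
#' @param recapture `"constant"` (no trap effect), `"trap"` (separate
#'   recapture probabilities for birds captured / missed at the previous
#'   occasion) or `"trap_time"` (additive year effects plus a trap effect on
#'   the logit scale).
#' @param rho `"estimate"` to estimate the probability that a deployed
#'   geolocator functions, `"none"` when the data contain no deployments, or
#'   a number in (0, 1) to fix it.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(survival = "constant", first_encounter = "none",
                       change = "constant", initial = "equal",
                       recapture = "trap", rho = "estimate") {
  survival <- match.arg(survival, c(
    "constant", "area", "canary_others", "equatorial_others", "soi", "wnao",
    "area+soi", "area*soi", "area+wnao", "area*wnao", "canary_others+soi",
    "equatorial_others+soi", "geo"))
  first_encounter <- match.arg(first_encounter, c("none", "constant"))
  change <- match.arg(change, c("constant", "wnao", "soi", "from_area",
                                "from_area+wnao", "to_area"))
  initial <- match.arg(initial, c("equal", "canary_others", "area"))
  recapture <- match.arg(recapture, c("constant", "trap", "trap_time"))
  if (is.character(rho)) rho <- match.arg(rho, c("estimate", "none"))
  else stopifnot(is.numeric(rho), rho > 0, rho <= 1)
  structure(list(survival = survival, first_encounter = first_encounter,
                 change = change, initial = initial, recapture = recapture,
                 rho = rho),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> phi(%s) delta(%s) c(%s) pi(%s) p(%s) rho(%s)\n",
              x$survival, x$first_encounter, x$change, x$initial, x$recapture,
              if (is.numeric(x$rho)) paste("fixed", x$rho) else x$rho))
  invisible(x)
}

infeasible_error <- function(msg) {
  stop(structure(class = c("winterCMR_infeasible", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## Survival design matrix: rows = (area, device-group in {untagged, tagged},
## interval), columns = coefficients.
survival_design_matrix <- function(design, k, soi) {
  n_int <- length(soi)
  g <- expand.grid(area = seq_len(k), dev = 1:2, int = seq_len(n_int))
  x_soi <- soi[g$int]
  area_ind <- function() {
    X <- matrix(0, nrow(g), k,
                dimnames = list(NULL, paste0("phi:", seq_len(k))))
    X[cbind(seq_len(nrow(g)), g$area)] <- 1
    X
  }
  grp_ind <- function(focal, lab) {
    X <- cbind(as.numeric(g$area == focal), as.numeric(g$area != focal))
    colnames(X) <- paste0("phi:", c(lab, "others"))
    X
  }
  switch(design,
    constant = matrix(1, nrow(g), 1, dimnames = list(NULL, "phi:(Intercept)")),
    area = area_ind(),
    canary_others = grp_ind(1L, "canary"),
    equatorial_others = grp_ind(2L, "equatorial"),
    soi = cbind("phi:(Intercept)" = 1, "phi:soi" = x_soi),
    wnao = cbind("phi:(Intercept)" = 1, "phi:wnao" = x_soi * 0), # filled later
    "area+soi" = cbind(area_ind(), "phi:soi" = x_soi),
    "area*soi" = {
      A <- area_ind()
      S <- A * x_soi
      colnames(S) <- paste0("phi:soi.", seq_len(k))
      cbind(A, S)
    },
    "area+wnao" = cbind(area_ind(), "phi:wnao" = x_soi * 0),
    "area*wnao" = {
      A <- area_ind()
      S <- A * 0
      colnames(S) <- paste0("phi:wnao.", seq_len(k))
      cbind(A, S)
    },
    "canary_others+soi" = cbind(grp_ind(1L, "canary"), "phi:soi" = x_soi),
    "equatorial_others+soi" = cbind(grp_ind(2L, "equatorial"), "phi:soi" = x_soi),
    geo = cbind("phi:(Intercept)" = 1, "phi:geo" = as.numeric(g$dev == 2L))
  )
}

#' Resolve a model specification into its coefficient structure
#'
#' Expands a [model_spec()] against a state space and covariate series into
#' named coefficients, design matrices and a `realize()` function mapping a
#' link-scale coefficient vector to the real parameters used to build the
#' annual transition matrices. The coefficient count `np` is available before
#' any fitting.
#'
#' @param spec A [model_spec()].
#' @param space A [state_space()].
#' @param covariates Tibble with `year`, `soi`, `wnao`.
#' @param years Calendar years of the annual occasions.
#' @return A list with `coef_names`, `np`, `start` (a reasonable default
#'   start vector), and `realize(theta)` returning the per-interval real
#'   parameters (`phi` array area x device-group x interval, `delta`,
#'   `C` change-matrix array, `pi`, `p` matrix aware/unaware x interval,
#'   `rho`).
#' @export
resolve_design <- function(spec, space, covariates, years) {
  stopifnot(inherits(spec, "model_spec"), inherits(space, "state_space"))
  k <- space$n_areas
  T_ <- length(years)
  if (T_ < 2) stop("resolve_design: need at least two occasions", call. = FALSE)
  n_int <- T_ - 1L
  # interval t runs from occasion t to t+1; covariates are those of the
  # winter preceding arrival at t+1, indexed by the arrival year
  idx <- match(years[-1], covariates$year)
  if (any(is.na(idx))) {
    stop("resolve_design: covariate series does not cover the study years",
         call. = FALSE)
  }
  soi <- covariates$soi[idx]
  wnao <- covariates$wnao[idx]

  uses_wnao_phi <- grepl("wnao", spec$survival)
  Xphi <- survival_design_matrix(spec$survival, k,
                                 if (uses_wnao_phi) wnao else soi)
  if (uses_wnao_phi) { # covariate column(s) were placeholders
    g <- expand.grid(area = seq_len(k), dev = 1:2, int = seq_len(n_int))
    if (spec$survival %in% c("wnao", "area+wnao")) {
      Xphi[, ncol(Xphi)] <- wnao[g$int]
    } else if (spec$survival == "area*wnao") {
      for (a in seq_len(k)) {
        Xphi[, k + a] <- (g$area == a) * wnao[g$int]
      }
    }
  }
  phi_names <- colnames(Xphi)
  phi_start <- ifelse(grepl("soi|wnao|geo", phi_names), 0, logit(0.8))

  delta_names <- if (spec$first_encounter == "constant") "delta" else character()
  delta_start <- if (length(delta_names)) logit(0.1) else numeric()

  change_names <- if (k == 1) character() else switch(spec$change,
    constant = "c:(Intercept)",
    wnao = c("c:(Intercept)", "c:wnao"),
    soi = c("c:(Intercept)", "c:soi"),
    from_area = paste0("c:from.", seq_len(k)),
    "from_area+wnao" = c(paste0("c:from.", seq_len(k)), "c:wnao"),
    to_area = paste0("c:to.", seq_len(k)))
  change_start <- ifelse(grepl("wnao$|soi$", change_names), 0,
                         if (spec$change == "to_area") log(0.07 / 0.79)
                         else logit(0.08))

  pi_names <- if (k == 1) character() else switch(spec$initial,
    equal = character(),
    canary_others = "pi:canary",
    area = if (k > 1) paste0("pi:", 2:k) else character())
  pi_start <- rep(0, length(pi_names))

  p_names <- switch(spec$recapture,
    constant = "p:(Intercept)",
    trap = c("p:aware", "p:unaware"),
    trap_time = c(paste0("p:t", seq_len(n_int) + 1L), "p:trap"))
  p_start <- rep(0, length(p_names))

  rho_names <- if (identical(spec$rho, "estimate")) "rho" else character()
  rho_start <- if (length(rho_names)) logit(0.8) else numeric()

  coef_names <- c(phi_names, delta_names, change_names, pi_names, p_names,
                  rho_names)
  sizes <- c(length(phi_names), length(delta_names), length(change_names),
             length(pi_names), length(p_names), length(rho_names))
  off <- cumsum(c(0, sizes))

  realize <- function(theta, strict = TRUE) {
    stopifnot(length(theta) == length(coef_names))
    th <- function(j) theta[(off[j] + 1):off[j + 1]]
    phi <- array(invlogit(as.vector(Xphi %*% th(1))), dim = c(k, 2, n_int))
    delta <- if (sizes[2]) invlogit(th(2)) else 0

    gc_ <- if (sizes[3]) th(3) else numeric()
    C <- array(0, dim = c(k, k, n_int))
    if (k == 1) {
      C[1, 1, ] <- 1
    } else if (spec$change == "to_area") {
      w <- exp(gc_)
      for (a in seq_len(k)) {
        row <- numeric(k)
        row[-a] <- w[-a]
        row[a] <- 1
        C[a, , ] <- row / sum(row)
      }
    } else {
      eta <- switch(spec$change,
        constant = matrix(gc_[1], k, n_int),
        wnao = matrix(rep(gc_[1] + gc_[2] * wnao, each = k), k, n_int),
        soi = matrix(rep(gc_[1] + gc_[2] * soi, each = k), k, n_int),
        from_area = matrix(gc_[seq_len(k)], k, n_int),
        "from_area+wnao" = outer(gc_[seq_len(k)], gc_[k + 1] * wnao, `+`))
      cc <- invlogit(eta)
      if (any((k - 1) * cc > 1)) {
        if (strict) {
          infeasible_error("per-destination change probability exceeds 1/(k-1)")
        }
        return(list(infeasible = max((k - 1) * cc - 1)))
      }
      for (t in seq_len(n_int)) C[, , t] <- change_matrix(cc[, t], k)
    }

    pi <- if (k == 1) 1 else switch(spec$initial,
      equal = rep(1 / k, k),
      canary_others = {
        p1 <- invlogit(th(4))
        c(p1, rep((1 - p1) / (k - 1), k - 1))
      },
      area = {
        w <- c(1, exp(th(4)))
        w / sum(w)
      })

    pp <- th(5)
    p <- switch(spec$recapture,
      constant = matrix(invlogit(pp[1]), 2, n_int),
      trap = matrix(invlogit(pp), 2, n_int),
      trap_time = rbind(invlogit(pp[seq_len(n_int)] + pp[n_int + 1]),
                        invlogit(pp[seq_len(n_int)])))

    rho <- if (sizes[6]) invlogit(th(6)) else
      if (is.numeric(spec$rho)) spec$rho else 1

    list(phi = phi, delta = delta, C = C, pi = pi, p = p, rho = rho,
         soi = soi, wnao = wnao)
  }

  list(spec = spec, coef_names = coef_names, np = length(coef_names),
       start = stats::setNames(c(phi_start, delta_start, change_start,
                                 pi_start, p_start, rho_start), coef_names),
       realize = realize, Xphi = Xphi, soi = soi, wnao = wnao,
       n_int = n_int, k = k)
}
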