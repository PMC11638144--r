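#' Release-recapture m-array
#'
#' Classic summary supporting Cormack-Jolly-Seber goodness of fit: entry
#' `(i, j)` counts animals released at occasion `i` whose next recapture was
#' at occasion `j`.
#'
#' @param det A 0/1 detection matrix (individuals x occasions) or an
#'   [encounter_data()].
#' @return A list with `m` (releases x next-recapture counts, upper
#'   triangular), `releases` (animals released per occasion) and
#'   `never` (released and never recaptured).
#' @export
build_marray <- function(det) {
  det <- detection_matrix(det)
  T_ <- ncol(det)
  if (T_ < 2) stop("build_marray: need at least two occasions", call. = FALSE)
  m <- matrix(0L, T_, T_, dimnames = list(released = seq_len(T_),
                                          recaptured = seq_len(T_)))
  releases <- integer(T_)
  for (i in seq_len(nrow(det))) {
    seen <- which(det[i, ] == 1L)
    if (!length(seen)) next
    releases[seen] <- releases[seen] + 1L
    if (length(seen) > 1) {
      from <- seen[-length(seen)]
      to <- seen[-1]
      for (j in seq_along(from)) m[from[j], to[j]] <- m[from[j], to[j]] + 1L
    }
  }
  list(m = m, releases = releases,
       never = unname(releases - rowSums(m)))
}

## Pearson chi-square of a 2x2 table; informative when all margins positive
## and every expected cell is at least `min_expected` (smaller tables are the
## pooled-out cells of standard contingency practice).
chisq_2x2 <- function(tab, min_expected = 2) {
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NULL)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (min(E) < min_expected) return(NULL)
  chi2 <- sum((tab - E)^2 / E)
  # hypergeometric mean/variance of the (1,1) cell for the signed component
  n <- sum(tab)
  v <- prod(rowSums(tab)) * prod(colSums(tab)) / (n^2 * (n - 1))
  list(chi2 = chi2, oe = tab[1, 1] - E[1, 1], v = v)
}

#' Trap-dependence component of CJS goodness of fit
#'
#' For every interior occasion, animals known to be alive (seen later) are
#' cross-classified by capture at that occasion against the timing of their
#' next recapture (immediately vs later). Trap-happiness inflates immediate
#' recaptures of just-captured animals; the returned `z` is positive in that
#' direction. Component tables with any expected cell below 2 are dropped.
#'
#' @param det Detection matrix or [encounter_data()].
#' @return A list: `chi2`, `df`, `z` (signed), `p_value`, `n_tables`.
#' @export
test_trap_dependence <- function(det) {
  det <- detection_matrix(det)
  T_ <- ncol(det)
  if (T_ < 3) stop("test_trap_dependence: need at least 3 occasions",
                   call. = FALSE)
  first <- apply(det == 1L, 1, function(z) which(z)[1])
  chi2 <- 0; df <- 0L; oe <- 0; v <- 0
  for (t in 2:(T_ - 1)) {
    after <- if (t + 1 <= T_) det[, (t + 1):T_, drop = FALSE] else NULL
    seen_after <- rowSums(after) > 0
    next_at <- apply(after == 1L, 1, function(z) if (any(z)) which(z)[1] else NA)
    seen_t <- det[, t] == 1L
    known_alive <- !seen_t & first < t & seen_after
    use <- (seen_t & seen_after) | known_alive
    if (!any(use)) next
    tab <- table(factor(!seen_t[use], levels = c(FALSE, TRUE)),
                 factor(next_at[use] > 1, levels = c(FALSE, TRUE)))
    res <- chisq_2x2(tab)
    if (is.null(res)) next
    chi2 <- chi2 + res$chi2; df <- df + 1L; oe <- oe + res$oe; v <- v + res$v
  }
  z <- if (v > 0) oe / sqrt(v) else NA_real_
  list(chi2 = chi2, df = df, z = z,
       p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
       else NA_real_,
       n_tables = df)
}

#' Transience component of CJS goodness of fit
#'
#' For every interior occasion, animals captured there are cross-classified
#' as newly marked vs previously marked against ever reseen vs never reseen.
#' A deficit of reseen newly-marked animals signals transience (equivalently,
#' lower apparent survival over the interval after first capture).
#'
#' @param det Detection matrix or [encounter_data()].
#' @return A list: `chi2`, `df`, `z` (positive when newly-marked animals are
#'   reseen less), `p_value`, `n_tables`.
#' @export
test_transience <- function(det) {
  det <- detection_matrix(det)
  T_ <- ncol(det)
  if (T_ < 3) stop("test_transience: need at least 3 occasions", call. = FALSE)
  first <- apply(det == 1L, 1, function(z) which(z)[1])
  chi2 <- 0; df <- 0L; oe <- 0; v <- 0
  for (t in 2:(T_ - 1)) {
    seen_t <- det[, t] == 1L
    if (!any(seen_t)) next
    new_t <- first == t
    reseen <- rowSums(det[, (t + 1):T_, drop = FALSE]) > 0
    use <- seen_t
    tab <- table(factor(new_t[use], levels = c(TRUE, FALSE)),
                 factor(!reseen[use], levels = c(TRUE, FALSE)))
    res <- chisq_2x2(tab)
    if (is.null(res)) next
    chi2 <- chi2 + res$chi2; df <- df + 1L; oe <- oe + res$oe; v <- v + res$v
  }
  z <- if (v > 0) oe / sqrt(v) else NA_real_
  list(chi2 = chi2, df = df, z = z,
       p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
       else NA_real_,
       n_tables = df)
}

#' Goodness of fit of the CJS base model and overdispersion
#'
#' Combines the trap-dependence and transience components into a total
#' chi-square and the variance-inflation factor c-hat = chi2 / df. Because
#' trap-dependence is usually absorbed into the recapture model rather than
#' treated as overdispersion, `chat_excluding_trap` drops that component
#' before computing the inflation used for QAICc.
#'
#' @param det Detection matrix or [encounter_data()].
#' @return An object of class `cmr_gof`: `components` tibble (test, chi2, df,
#'   z, p_value), `total_chi2`, `total_df`, `chat`, `chat_excluding_trap`.
#' @export
gof_cjs <- function(det) {
  det <- detection_matrix(det)
  ct <- test_trap_dependence(det)
  sr <- test_transience(det)
  total_chi2 <- ct$chi2 + sr$chi2
  total_df <- ct$df + sr$df
  structure(
    list(components = tibble::tibble(
      test = c("trap_dependence", "transience"),
      chi2 = c(ct$chi2, sr$chi2), df = c(ct$df, sr$df),
      z = c(ct$z, sr$z), p_value = c(ct$p_value, sr$p_value)),
      total_chi2 = total_chi2, total_df = total_df,
      chat = if (total_df > 0) total_chi2 / total_df else NA_real_,
      chat_excluding_trap = if (sr$df > 0) sr$chi2 / sr$df else NA_real_),
    class = "cmr_gof")
}

#' @export
print.cmr_gof <- function(x, ...) {
  cat("<cmr_gof> CJS goodness of fit\n")
  print.data.frame(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("total chi2 %.3f on %d df; c-hat %.3f (excluding trap: %.3f)\n",
              x$total_chi2, x$total_df, x$chat, x$chat_excluding_trap))
  invisible(x)
}

#' Quasi-likelihood AIC with small-sample correction
#'
#' `QAICc = deviance / chat + 2 np + 2 np (np + 1) / (n_eff - np - 1)`.
#'
#' @param deviance Model deviance (-2 log-likelihood).
#' @param np Number of estimated coefficients.
#' @param chat Variance-inflation factor (> 0).
#' @param n_eff Effective sample size (total number of releases).
#' @return The QAICc value.
#' @examples
#' qaicc(100, 5, 1, 1000) # 110.060...
#' @export
qaicc <- function(deviance, np, chat, n_eff) {
  if (any(chat <= 0)) stop("qaicc: chat must be positive", call. = FALSE)
  if (any(n_eff <= np + 1)) {
    stop("qaicc: small-sample correction undefined (n_eff <= np + 1)",
         call. = FALSE)
  }
  deviance / chat + 2 * np + 2 * np * (np + 1) / (n_eff - np - 1)
}

#' Akaike weights from information-criterion values
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = qaicc_i - min(qaicc)`.
#'
#' @param qaicc_values Numeric vector of QAICc (or AICc) values.
#' @return Weights summing to 1.
#' @examples
#' round(akaike_weights(c(4362.494, 4365.967, 4369.104, 4371.101)), 3)
#' @export
akaike_weights <- function(qaicc_values) {
  if (!length(qaicc_values) || any(!is.finite(qaicc_values))) {
    stop("akaike_weights: need a non-empty vector of finite values",
         call. = FALSE)
  }
  delta <- qaicc_values - min(qaicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Fit a set of model specifications and rank them by QAICc
#'
#' @param data An [encounter_data()].
#' @param specs Named list of [model_spec()] objects.
#' @param chat Variance-inflation factor applied to all deviances.
#' @param n_starts,seed Passed to [fit_model()] (standard errors are skipped
#'   during the grid fits).
#' @return A `cmr_model_table`: a tibble with columns `model`, `np`,
#'   `deviance`, `qaicc`, `delta_qaicc`, `weight`, sorted by QAICc (ties
#'   broken by fewer parameters); the fitted objects are in
#'   `attr(, "fits")`.
#' @export
run_model_set <- function(data, specs, chat = 1, n_starts = 5, seed = NULL) {
  stopifnot(length(specs) >= 1)
  if (is.null(names(specs))) names(specs) <- paste0("M", seq_along(specs))
  fits <- purrr::imap(specs, function(sp, nm) {
    tryCatch(fit_model(data, sp, n_starts = n_starts, seed = seed, se = FALSE),
             error = function(e) {
               warning(sprintf("model %s failed to fit: %s", nm,
                               conditionMessage(e)), call. = FALSE)
               NULL
             })
  })
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    tibble::tibble(model = nm,
                   np = if (is.null(f)) NA_integer_ else f$np,
                   deviance = if (is.null(f)) NA_real_ else f$deviance)
  })
  tab$qaicc <- ifelse(is.na(tab$deviance), NA_real_,
                      qaicc(tab$deviance, tab$np, chat, data$n_releases))
  ok <- !is.na(tab$qaicc)
  tab$delta_qaicc <- tab$qaicc - min(tab$qaicc[ok])
  tab$weight <- NA_real_
  tab$weight[ok] <- akaike_weights(tab$qaicc[ok])
  tab <- dplyr::arrange(tab, dplyr::desc(!is.na(.data$qaicc)), .data$qaicc,
                        .data$np)
  structure(tab, fits = fits, chat = chat,
            class = c("cmr_model_table", class(tab)))
}
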