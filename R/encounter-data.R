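#' Encounter-history dataset
#'
#' Bundles individual encounter histories over annual occasions with the
#' climate covariate series. Events at arrival ("inter") occasions are coded
#' per [event_alphabet()]; the release record holds the departure ("intra")
#' action (0 not handled, 1 released without device, 2 released with device).
#'
#' @param events Integer matrix, individuals x years, of inter event codes.
#' @param release Integer matrix, individuals x years, of intra action codes
#'   (the last year's column is ignored; there is no departure occasion after
#'   the final arrival).
#' @param covariates Tibble with columns `year`, `soi`, `wnao` covering every
#'   study year.
#' @param years Calendar years of the annual occasions.
#' @param ids Optional individual identifiers.
#' @param space The [state_space()] the event codes refer to.
#' @return An object of class `encounter_data` with components `events`,
#'   `release`, `first` (first capture occasion per individual), `years`,
#'   `covariates`, `space`, `ids`, and `n_releases` (total captures, the
#'   effective sample size used by [qaicc()]).
#' @export
encounter_data <- function(events, release = NULL, covariates = NULL,
                           years = NULL, ids = NULL, space = state_space()) {
  events <- as.matrix(events)
  n <- nrow(events); T_ <- ncol(events)
  if (is.null(release)) release <- matrix(0L, n, T_)
  release <- as.matrix(release)
  stopifnot(dim(release)[1] == n, dim(release)[2] == T_)
  if (is.null(years)) years <- 2000L + seq_len(T_) - 1L
  if (is.null(ids)) ids <- sprintf("B%04d", seq_len(n))
  if (is.null(covariates)) {
    covariates <- tibble::tibble(year = years, soi = 0, wnao = 0)
  }
  if (!all(years %in% covariates$year)) {
    stop("encounter_data: covariates must cover every study year",
         call. = FALSE)
  }
  max_code <- space$n_areas + 2L
  if (any(is.na(events)) || any(events < 0) || any(events > max_code)) {
    stop("encounter_data: event codes out of range", call. = FALSE)
  }
  first <- if (n == 0) integer(0) else
    apply(events > 0, 1, function(z) if (any(z)) which(z)[1] else NA_integer_)
  if (any(is.na(first))) {
    stop("encounter_data: every individual needs at least one capture",
         call. = FALSE)
  }
  if (any(events[cbind(seq_len(n), first)] > 1L)) {
    stop("encounter_data: a device reveal cannot occur at first capture",
         call. = FALSE)
  }
  if (any(release[events == 0] != 0)) {
    stop("encounter_data: release action recorded without a capture",
         call. = FALSE)
  }
  validate_reveals(events, release)
  structure(
    list(events = events, release = release, first = as.integer(first),
         years = as.integer(years), covariates = covariates, space = space,
         ids = ids, n_releases = sum(events > 0)),
    class = "encounter_data"
  )
}

## Reveal (or failed-device) events require device carriage: a release-with-
## device at an earlier year with no intervening capture.
validate_reveals <- function(events, release) {
  n <- nrow(events); T_ <- ncol(events)
  for (i in seq_len(n)) {
    carrying <- FALSE
    for (t in seq_len(T_)) {
      e <- events[i, t]
      if (e > 1L && !carrying) {
        stop(sprintf(paste0("encounter_data: individual %d has a device event",
                            " at occasion %d without prior deployment"), i, t),
             call. = FALSE)
      }
      if (e > 0L) carrying <- FALSE                  # captured: device recovered
      if (t < T_ && e > 0L && release[i, t] == 2L) carrying <- TRUE
    }
  }
  invisible(TRUE)
}

#' @export
print.encounter_data <- function(x, ...) {
  cat(sprintf("<encounter_data> %d individuals, %d years (%d-%d), %d captures\n",
              nrow(x$events), length(x$years), min(x$years), max(x$years),
              x$n_releases))
  invisible(x)
}

#' @export
as_tibble.encounter_data <- function(x, ...) {
  tibble::tibble(
    id = x$ids,
    first_year = x$years[x$first],
    n_captures = rowSums(x$events > 0),
    history = vapply(seq_len(nrow(x$events)), function(i) {
      paste(history_tokens(x$events[i, ], x$release[i, ]), collapse = " ")
    }, character(1))
  )
}

history_tokens <- function(ev, rel) {
  tok <- character(length(ev))
  for (t in seq_along(ev)) {
    tok[t] <- if (ev[t] == 0L) "00" else
      paste0(ev[t], if (rel[t] == 2L) "1" else "0")
  }
  tok
}

#' Collapse an encounter dataset to a 0/1 detection matrix
#'
#' Goodness-of-fit tests for the Cormack-Jolly-Seber base model operate on
#' plain seen / not-seen histories at the arrival occasions.
#'
#' @param data An [encounter_data()] or an integer event matrix.
#' @return A 0/1 matrix, individuals x occasions.
#' @export
detection_matrix <- function(data) {
  ev <- if (inherits(data, "encounter_data")) data$events else as.matrix(data)
  (ev > 0) * 1L
}
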