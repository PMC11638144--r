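#' Write an encounter-history file
#'
#' Plain-text serialisation: two header comment lines carry the study years
#' and area labels; each record line is the individual id followed by one
#' two-character token per year. First character: `0` not captured, `1`
#' captured without device, `2`-`5` captured with a functioning device
#' revealing area 1-4, `6` captured with a failed device. Second character:
#' `1` released with a device, `0` otherwise.
#'
#' @param data An [encounter_data()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_encounter_file <- function(data, path) {
  stopifnot(inherits(data, "encounter_data"))
  lines <- c(
    sprintf("# years: %d-%d", min(data$years), max(data$years)),
    sprintf("# areas: %s", paste(data$space$areas, collapse = ",")),
    vapply(seq_len(nrow(data$events)), function(i) {
      paste(c(data$ids[i],
              history_tokens(data$events[i, ], data$release[i, ])),
            collapse = " ")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read an encounter-history file
#'
#' Parses the token grammar written by [write_encounter_file()] (a bare `0`
#' is accepted for a not-captured year) and validates it: unknown characters
#' or token counts raise a parse error with the line number, and a device
#' event without a prior release-with-device raises a semantic error.
#'
#' @param path Input file.
#' @param covariates Optional covariate tibble to attach.
#' @return An [encounter_data()] (empty files give a zero-row dataset with a
#'   warning).
#' @export
read_encounter_file <- function(path, covariates = NULL) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  yr <- stringr::str_match(header, "years:\\s*(\\d+)-(\\d+)")
  yr <- yr[!is.na(yr[, 1]), , drop = FALSE]
  if (!nrow(yr)) stop("read_encounter_file: missing '# years:' header",
                      call. = FALSE)
  years <- as.integer(yr[1, 2]):as.integer(yr[1, 3])
  ar <- stringr::str_match(header, "areas:\\s*(.+)$")
  ar <- ar[!is.na(ar[, 1]), , drop = FALSE]
  areas <- if (nrow(ar)) trimws(strsplit(ar[1, 2], ",")[[1]]) else
    c("Canary", "Equatorial", "Guinea", "Angola")
  space <- state_space(n_areas = length(areas), areas = areas)
  T_ <- length(years)
  if (!length(body_idx)) {
    warning("read_encounter_file: empty file, returning empty dataset")
    return(encounter_data(matrix(1L, 0, T_), matrix(0L, 0, T_),
                          covariates = covariates, years = years,
                          ids = character(0), space = space))
  }
  n <- length(body_idx)
  events <- matrix(0L, n, T_)
  release <- matrix(0L, n, T_)
  ids <- character(n)
  max_code <- space$n_areas + 2L
  for (r in seq_len(n)) {
    ln <- body_idx[r]
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(parts) != T_ + 1) {
      stop(sprintf("read_encounter_file: line %d has %d tokens, expected %d",
                   ln, length(parts) - 1, T_), call. = FALSE)
    }
    ids[r] <- parts[1]
    for (t in seq_len(T_)) {
      tok <- parts[t + 1]
      if (!grepl("^[0-9]{1,2}$", tok)) {
        stop(sprintf("read_encounter_file: bad token '%s' at line %d", tok, ln),
             call. = FALSE)
      }
      e <- as.integer(substr(tok, 1, 1))
      rel <- if (nchar(tok) == 2) as.integer(substr(tok, 2, 2)) else 0L
      if (e > max_code || rel > 1L) {
        stop(sprintf("read_encounter_file: bad token '%s' at line %d", tok, ln),
             call. = FALSE)
      }
      events[r, t] <- e
      # the final arrival has no departure occasion, so no release action
      release[r, t] <- if (e == 0L || t == T_) 0L else if (rel == 1L) 2L else 1L
    }
  }
  encounter_data(events, release, covariates = covariates, years = years,
                 ids = ids, space = space)
}

#' Read or write a covariate series
#'
#' Delimited table with one header row and columns `year`, `soi`, `wnao`.
#'
#' @param path File path.
#' @return A covariate tibble.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("year", "soi", "wnao")
  if (!all(need %in% names(cov))) {
    stop("read_covariates: need columns year, soi, wnao", call. = FALSE)
  }
  if (anyNA(cov[need])) {
    stop("read_covariates: missing values in covariate series", call. = FALSE)
  }
  tibble::as_tibble(cov[need])
}

#' @rdname read_covariates
#' @param covariates Covariate tibble to write.
#' @export
write_covariates <- function(covariates, path) {
  readr::write_csv(covariates, path)
  invisible(path)
}

#' Read or write an assignment table
#'
#' Delimited table with columns `id`, `year`, `area`.
#'
#' @param path File path.
#' @return An assignment tibble.
#' @export
read_assignments <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  assignment_table(tb)
}

#' @rdname read_assignments
#' @param table Assignment tibble to write.
#' @export
write_assignments <- function(table, path) {
  readr::write_csv(assignment_table(table), path)
  invisible(path)
}

#' Standardise covariates over the study years
#'
#' Climate indices arrive on arbitrary scales; z-scoring them over the study
#' window stabilises optimisation of the covariate slopes.
#'
#' @param covariates Tibble with `year`, `soi`, `wnao`.
#' @return The tibble with `soi` and `wnao` centred and scaled.
#' @export
standardise_covariates <- function(covariates) {
  dplyr::mutate(covariates,
                soi = as.vector(scale(.data$soi)),
                wnao = as.vector(scale(.data$wnao)))
}
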