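#' Build the hidden-state space of the multievent model
#'
#' Hidden states are the cross of wintering area, geolocator (device) status
#' and trap-awareness, plus a single absorbing dead state. With the standard
#' configuration of four wintering areas (Canary Current, pelagic Equatorial
#' Atlantic, Gulf of Guinea, Angola-Benguela Front), three device statuses
#' (none, functioning, failed) and two awareness levels (aware = captured at
#' the previous sampling occasion, unaware otherwise) this yields
#' 4 x 3 x 2 + 1 = 25 states.
#'
#' @param n_areas Number of wintering areas (>= 1).
#' @param n_device Number of device statuses (1 = untagged only, 2 adds a
#'   functioning device, 3 adds a failed device).
#' @param n_awareness Number of trap-awareness levels (1 or 2).
#' @param areas Optional character labels for the areas.
#' @return An object of class `state_space`: a list with the label vectors,
#'   `n_states`, a `states` tibble (one row per state: index, area, device,
#'   awareness, label) and the index of the dead state.
#' @examples
#' sp <- state_space()
#' sp$n_states # 25
#' @export
state_space <- function(n_areas = 4, n_device = 3, n_awareness = 2,
                        areas = NULL) {
  if (any(c(n_areas, n_device, n_awareness) < 1)) {
    stop("state_space: all dimension counts must be >= 1", call. = FALSE)
  }
  if (n_device > 3 || n_awareness > 2) {
    stop("state_space: at most 3 device statuses and 2 awareness levels",
         call. = FALSE)
  }
  default_areas <- c("Canary", "Equatorial", "Guinea", "Angola")
  if (is.null(areas)) {
    areas <- if (n_areas <= 4) default_areas[seq_len(n_areas)] else
      paste0("Area", seq_len(n_areas))
  }
  stopifnot(length(areas) == n_areas)
  devices <- c("none", "functioning", "failed")[seq_len(n_device)]
  awareness <- c("aware", "unaware")[seq_len(n_awareness)]

  grid <- expand.grid(area = seq_len(n_areas), device = seq_len(n_device),
                      awareness = seq_len(n_awareness))
  states <- tibble::tibble(
    index = seq_len(nrow(grid)),
    area = areas[grid$area],
    device = devices[grid$device],
    awareness = awareness[grid$awareness],
    label = paste(areas[grid$area], devices[grid$device],
                  awareness[grid$awareness], sep = ":")
  )
  states <- dplyr::bind_rows(
    states,
    tibble::tibble(index = nrow(grid) + 1L, area = NA_character_,
                   device = NA_character_, awareness = NA_character_,
                   label = "dead")
  )
  structure(
    list(areas = areas, devices = devices, awareness = awareness,
         n_areas = n_areas, n_device = n_device, n_awareness = n_awareness,
         n_alive = nrow(grid), n_states = nrow(grid) + 1L,
         dead = nrow(grid) + 1L, states = states),
    class = "state_space"
  )
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space> %d states = %d areas x %d device x %d awareness + dead\n",
              x$n_states, x$n_areas, x$n_device, x$n_awareness))
  invisible(x)
}

#' Index of a hidden state from its (area, device, awareness) tuple
#'
#' The enumeration runs area fastest, then device, then awareness; the dead
#' state takes the highest index.
#'
#' @param space A [state_space()].
#' @param area,device,awareness Integer coordinates (1-based); vectors recycle.
#' @return Integer state indices.
#' @export
state_index <- function(space, area, device = 1L, awareness = 1L) {
  stopifnot(inherits(space, "state_space"))
  ok <- area >= 1 & area <= space$n_areas &
    device >= 1 & device <= space$n_device &
    awareness >= 1 & awareness <= space$n_awareness
  if (!all(ok)) stop("state_index: coordinates out of range", call. = FALSE)
  as.integer((awareness - 1L) * space$n_areas * space$n_device +
               (device - 1L) * space$n_areas + area)
}

#' Event alphabet associated with a state space
#'
#' Events at "inter" (arrival) occasions code what the field team can see:
#' `0` not captured, `1` captured without device, `1 + a` captured carrying a
#' functioning geolocator revealing wintering area `a`, and `n_areas + 2`
#' captured carrying a device that failed to record. Events at "intra"
#' (departure) occasions code the release decision: `0` not handled,
#' `1` released without a device, `2` released with a device.
#'
#' @param space A [state_space()].
#' @return A list with tibbles `inter` and `intra` (columns `code`, `name`).
#' @export
event_alphabet <- function(space) {
  stopifnot(inherits(space, "state_space"))
  inter <- tibble::tibble(
    code = c(0L, 1L, seq_len(space$n_areas) + 1L, space$n_areas + 2L),
    name = c("not_captured", "captured_no_device",
             paste0("captured_reveals_", space$areas), "captured_device_failed")
  )
  intra <- tibble::tibble(
    code = 0:2,
    name = c("not_handled", "released_without_device", "released_with_device")
  )
  list(inter = inter, intra = intra)
}

#' Split annual occasions into coded inter/intra occasions
#'
#' Each study year contributes an arrival ("inter") occasion carrying the
#' biological state; every year except the last also contributes a departure
#' ("intra") occasion recording geolocator release, giving `2 * n_years - 1`
#' coded occasions (45 for a 23-year study).
#'
#' @param n_years Number of annual occasions (>= 1).
#' @param start_year Calendar year of the first occasion.
#' @return A tibble with one row per coded occasion: `coded` (1-based index),
#'   `year`, `kind` (`"inter"` or `"intra"`).
#' @export
encode_occasions <- function(n_years, start_year = 2000L) {
  if (length(n_years) != 1 || is.na(n_years) || n_years < 1) {
    stop("encode_occasions: n_years must be a single integer >= 1",
         call. = FALSE)
  }
  n_years <- as.integer(n_years)
  years <- rep(start_year + seq_len(n_years) - 1L, each = 2L)
  kind <- rep(c("inter", "intra"), times = n_years)
  tibble::tibble(coded = seq_len(2L * n_years - 1L),
                 year = years[seq_len(2L * n_years - 1L)],
                 kind = kind[seq_len(2L * n_years - 1L)])
}

#' Emission matrix (states by events)
#'
#' Emissions are deterministic given the hidden state: detection randomness
#' lives in the awareness step of the transition matrix, so aware states emit
#' their capture event with probability one and unaware or dead states emit
#' "not captured". At intra occasions the release decision is the field
#' team's, so the matrix is conditional on whether a device was deployed.
#'
#' @param space A [state_space()].
#' @param kind `"inter"` or `"intra"`.
#' @param deploy For `kind = "intra"`: was a device deployed at release?
#' @return A row-stochastic matrix, states in rows, event codes in columns
#'   (column `j` is event code `j - 1`).
#' @export
emission_matrix <- function(space, kind = c("inter", "intra"), deploy = FALSE) {
  stopifnot(inherits(space, "state_space"))
  kind <- match.arg(kind)
  st <- space$states
  if (kind == "inter") {
    n_ev <- space$n_areas + 3L
    E <- matrix(0, space$n_states, n_ev)
    for (i in seq_len(space$n_alive)) {
      if (!is.na(st$awareness[i]) && st$awareness[i] == "aware") {
        a <- match(st$area[i], space$areas)
        code <- switch(st$device[i],
                       none = 1L,
                       functioning = 1L + a,
                       failed = space$n_areas + 2L)
        E[i, code + 1L] <- 1
      } else {
        E[i, 1L] <- 1
      }
    }
    E[space$dead, 1L] <- 1
    colnames(E) <- event_alphabet(space)$inter$name
  } else {
    E <- matrix(0, space$n_states, 3L)
    handled <- if (deploy) 3L else 2L
    for (i in seq_len(space$n_alive)) {
      E[i, if (st$awareness[i] == "aware") handled else 1L] <- 1
    }
    E[space$dead, 1L] <- 1
    colnames(E) <- event_alphabet(space)$intra$name
  }
  rownames(E) <- st$label
  E
}

#' Export the state and event enumeration as a plain-text data dictionary
#'
#' @param space A [state_space()].
#' @param path File to write (tab-separated).
#' @return The dictionary tibble, invisibly.
#' @export
write_state_dictionary <- function(space, path) {
  ev <- event_alphabet(space)
  dict <- dplyr::bind_rows(
    dplyr::mutate(space$states, table = "state", .before = 1) |>
      dplyr::rename(code = "index"),
    dplyr::mutate(ev$inter, table = "event_inter", .before = 1,
                  area = NA, device = NA, awareness = NA, label = .data$name) |>
      dplyr::select(-"name"),
    dplyr::mutate(ev$intra, table = "event_intra", .before = 1,
                  area = NA, device = NA, awareness = NA, label = .data$name) |>
      dplyr::select(-"name")
  )
  readr::write_tsv(dict, path)
  invisible(dict)
}
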