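#' Validate an assignment table
#'
#' An assignment table records the wintering area revealed for an individual
#' in a given winter: one row per individual-winter with columns `id`,
#' `year`, `area`. The marker `"excluded"` flags tracks outside the area
#' scheme; they count as tracks but are dropped from area shares and from the
#' repeatability analysis.
#'
#' @param table A data frame with columns `id`, `year`, `area`.
#' @return The table as a tibble, invisibly checked.
#' @export
assignment_table <- function(table) {
  stopifnot(all(c("id", "year", "area") %in% names(table)))
  tb <- tibble::as_tibble(table)
  dup <- dplyr::count(tb, .data$id, .data$year) |> dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop(paste0("assignment_table: duplicate individual-year records: ",
                paste(paste(dup$id, dup$year), collapse = ", ")),
         call. = FALSE)
  }
  tb
}

#' Summarise wintering-site fidelity from tracked winters
#'
#' Counts tracks, tracked individuals, the distribution of migration cycles
#' per individual, consistency among individuals tracked more than once, and
#' per-area track counts with shares. Shares use the tracks assigned to a
#' wintering area as denominator (excluded tracks are counted in `n_tracks`
#' but not in shares); consistency uses the multi-tracked individuals as
#' denominator.
#'
#' @param table An assignment table (see [assignment_table()]).
#' @return An object of class `fidelity_summary`: `n_tracks`,
#'   `n_individuals`, `cycles` (tibble: n_cycles, n_individuals), `n_multi`,
#'   `n_consistent`, `n_changed`, `pct_consistent`, `area_counts` (tibble:
#'   area, n, pct).
#' @export
fidelity_summary <- function(table) {
  tb <- assignment_table(table)
  if (!nrow(tb)) stop("fidelity_summary: empty table", call. = FALSE)
  per_id <- tb |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(n_cycles = dplyr::n(),
                     n_areas_used = dplyr::n_distinct(
                       .data$area[.data$area != "excluded"]),
                     .groups = "drop")
  cycles <- dplyr::count(per_id, .data$n_cycles, name = "n_individuals")
  multi <- dplyr::filter(per_id, .data$n_cycles > 1)
  n_multi <- nrow(multi)
  n_consistent <- sum(multi$n_areas_used == 1)
  in_scheme <- dplyr::filter(tb, .data$area != "excluded")
  area_counts <- dplyr::count(in_scheme, .data$area, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
  structure(
    list(n_tracks = nrow(tb), n_individuals = nrow(per_id), cycles = cycles,
         n_multi = n_multi, n_consistent = n_consistent,
         n_changed = n_multi - n_consistent,
         pct_consistent = if (n_multi > 0) 100 * n_consistent / n_multi
         else NA_real_,
         area_counts = area_counts),
    class = "fidelity_summary")
}

#' @export
print.fidelity_summary <- function(x, ...) {
  cat(sprintf("<fidelity_summary> %d tracks from %d individuals\n",
              x$n_tracks, x$n_individuals))
  cat(sprintf("  tracked >1x: %d (consistent %d, changed %d; %.1f%% consistent)\n",
              x$n_multi, x$n_consistent, x$n_changed, x$pct_consistent))
  print.data.frame(as.data.frame(
    dplyr::mutate(x$area_counts, pct = round(.data$pct, 1))),
    row.names = FALSE)
  invisible(x)
}

## Coincidence matrix over pairable values within individuals: each ordered
## pair of values within a unit contributes 1/(m_u - 1).
coincidence_matrix <- function(values_by_unit, levels) {
  k <- length(levels)
  o <- matrix(0, k, k, dimnames = list(levels, levels))
  for (vals in values_by_unit) {
    m <- length(vals)
    if (m < 2) next
    idx <- match(vals, levels)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j) o[idx[i], idx[j]] <- o[idx[i], idx[j]] + 1 / (m - 1)
      }
    }
  }
  o
}

#' Krippendorff's alpha for nominal wintering-area repeatability
#'
#' Chance-corrected within-individual agreement of nominal wintering-area
#' assignments across years: `alpha = 1 - D_o / D_e`, with observed and
#' expected disagreement computed from the coincidence matrix over pairable
#' values (units are individuals; their assignments across winters are the
#' repeated observations; the difference function is nominal). Records with
#' area `"excluded"` are dropped first.
#'
#' @param table An assignment table (see [assignment_table()]).
#' @return Alpha in \[-1, 1\].
#' @export
krippendorff_alpha <- function(table) {
  tb <- assignment_table(table) |> dplyr::filter(.data$area != "excluded")
  units <- split(tb$area, tb$id)
  units <- units[lengths(units) >= 2]
  if (length(units) < 1) {
    stop("krippendorff_alpha: no individual has two or more pairable values",
         call. = FALSE)
  }
  levels <- sort(unique(unlist(units)))
  o <- coincidence_matrix(units, levels)
  n_c <- rowSums(o)
  n <- sum(n_c)
  if (n <= 1) stop("krippendorff_alpha: not enough pairable values",
                   call. = FALSE)
  d_o <- sum(o) - sum(diag(o))
  d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n - 1)
  if (d_e == 0) return(1)
  1 - d_o / d_e
}

#' Bootstrap percentile interval for Krippendorff's alpha
#'
#' Resamples individuals with replacement (the individual is the repeated-
#' measures unit, so its within-individual sequence is kept intact) and
#' returns the percentile interval of alpha over the resamples.
#'
#' @param table An assignment table.
#' @param n_boot Number of bootstrap iterations (default 10000; fewer than
#'   100 triggers a warning).
#' @param seed Seed for resampling.
#' @param conf Confidence level.
#' @return A tibble: `alpha`, `conf.low`, `conf.high`, `n_boot`.
#' @export
alpha_bootstrap_ci <- function(table, n_boot = 10000, seed = NULL,
                               conf = 0.95) {
  if (n_boot < 100) warning("alpha_bootstrap_ci: fewer than 100 iterations")
  tb <- assignment_table(table) |> dplyr::filter(.data$area != "excluded")
  units <- split(tb$area, tb$id)
  units <- units[lengths(units) >= 2]
  alpha <- krippendorff_alpha(tb)
  if (!is.null(seed)) set.seed(seed)
  levels_all <- sort(unique(unlist(units)))
  boot <- vapply(seq_len(n_boot), function(b) {
    take <- sample(length(units), replace = TRUE)
    o <- coincidence_matrix(units[take], levels_all)
    n_c <- rowSums(o)
    n <- sum(n_c)
    d_o <- sum(o) - sum(diag(o))
    d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n - 1)
    if (d_e == 0) 1 else 1 - d_o / d_e
  }, numeric(1))
  qs <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  tibble::tibble(alpha = alpha, conf.low = qs[1], conf.high = qs[2],
                 n_boot = n_boot)
}
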