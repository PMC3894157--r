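#' Multiplicative-null epistasis
#'
#' Deviation of the double-mutant relative fitness from the multiplicative
#' expectation of its two single mutants: `epsilon = w_ab - w_a * w_b`.
#' Negative values are aggravating (the double is worse than expected),
#' positive values alleviating. A lethal double (`w_ab = 0`) gives
#' `epsilon = -w_a * w_b`.
#'
#' @param w_a,w_b,w_ab Relative fitness of the two singles and the double
#'   (finite, >= 0; vectorised).
#' @return Numeric vector of epsilon values.
#' @export
#' @examples
#' epistasis_value(0.8, 0.9, 0.72)   # exactly multiplicative: 0
#' epistasis_value(1.0, 1.0, 0.7)    # aggravating: -0.3
epistasis_value <- function(w_a, w_b, w_ab) {
  if (any(!is.finite(c(w_a, w_b, w_ab)))) abort("fitness values must be finite")
  if (any(c(w_a, w_b, w_ab) < 0)) abort("fitness values must be >= 0")
  w_ab - w_a * w_b
}

#' Epistasis with replicate error
#'
#' Computes epsilon per biological replicate triple (replicates paired by
#' `bio_rep` label), then summarises each pair as mean, SEM (`sd/sqrt(n)`)
#' and a t-based 95% confidence interval over replicates.
#'
#' @param replicates Tibble with columns `gene_a`, `gene_b`, `bio_rep`,
#'   `w_a`, `w_b`, `w_ab` and optionally `parameter` (kept as a grouping
#'   column, e.g. `"rate"` / `"yield"`). Every pair needs at least two
#'   complete replicate triples; rows with unmatched replicate labels
#'   (missing fitness values) raise an error listing the offending labels.
#' @return A tibble of class `epistasis_fit`: grouping columns, `w_a`,
#'   `w_b`, `w_ab` (replicate means), `epsilon`, `sem`, `ci_lo`, `ci_hi`,
#'   `n_reps`.
#' @export
epistasis_with_error <- function(replicates) {
  replicates <- as_tibble(replicates)
  need <- c("gene_a", "gene_b", "bio_rep", "w_a", "w_b", "w_ab")
  stopifnot(all(need %in% names(replicates)))
  keys <- intersect(c("gene_a", "gene_b", "parameter"), names(replicates))

  incomplete <- replicates |>
    dplyr::filter(!stats::complete.cases(
      replicates[, c("w_a", "w_b", "w_ab")]))
  if (nrow(incomplete) > 0) {
    abort(paste0("unmatched replicate label(s): ",
                 paste(unique(paste0(incomplete$gene_a, ":", incomplete$gene_b,
                                     " bio_rep ", incomplete$bio_rep)),
                       collapse = ", ")))
  }
  dup <- replicates |>
    count(across(dplyr::all_of(c(keys, "bio_rep")))) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate replicate labels within a pair")

  out <- replicates |>
    mutate(eps = epistasis_value(.data$w_a, .data$w_b, .data$w_ab)) |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(w_a = mean(.data$w_a), w_b = mean(.data$w_b),
              w_ab = mean(.data$w_ab),
              epsilon = mean(.data$eps),
              sem = sd(.data$eps) / sqrt(dplyr::n()),
              n_reps = dplyr::n(), .groups = "drop")
  if (any(out$n_reps < 2)) {
    abort("each pair needs at least 2 complete replicate triples (SEM undefined)")
  }
  out <- out |>
    mutate(ci_lo = .data$epsilon - qt(0.975, .data$n_reps - 1) * .data$sem,
           ci_hi = .data$epsilon + qt(0.975, .data$n_reps - 1) * .data$sem) |>
    select(dplyr::all_of(keys), "w_a", "w_b", "w_ab", "epsilon", "sem",
           "ci_lo", "ci_hi", "n_reps")
  structure(out, class = c("epistasis_fit", class(out)))
}

#' Assemble replicate fitness triples from relative parameters
#'
#' Joins a relative-parameter table (from [normalize_to_wildtype()]) with a
#' pairs table naming each double-deletion strain, producing the replicate
#' triples [epistasis_with_error()] consumes, in long form over the two
#' growth parameters.
#'
#' @param rel_params Tibble `strain`, `condition`, `bio_rep`, `rel_rate`,
#'   `rel_yield` (one condition).
#' @param pairs Tibble `gene_a`, `gene_b`, `double_strain`.
#' @return Tibble `gene_a`, `gene_b`, `parameter`, `bio_rep`, `w_a`,
#'   `w_b`, `w_ab`.
#' @export
pair_fitness <- function(rel_params, pairs) {
  rel_params <- as_tibble(rel_params)
  if (dplyr::n_distinct(rel_params$condition) > 1) {
    abort("supply relative parameters from a single condition")
  }
  long <- rel_params |>
    tidyr::pivot_longer(c("rel_rate", "rel_yield"), names_to = "parameter",
                        values_to = "w") |>
    mutate(parameter = sub("^rel_", "", .data$parameter)) |>
    select("strain", "bio_rep", "parameter", "w")
  as_tibble(pairs) |>
    tidyr::expand_grid(parameter = c("rate", "yield"),
                       bio_rep = sort(unique(long$bio_rep))) |>
    left_join(rename(long, w_a = "w"),
              by = c(gene_a = "strain", "bio_rep", "parameter")) |>
    left_join(rename(long, w_b = "w"),
              by = c(gene_b = "strain", "bio_rep", "parameter")) |>
    left_join(rename(long, w_ab = "w"),
              by = c(double_strain = "strain", "bio_rep", "parameter")) |>
    select("gene_a", "gene_b", "parameter", "bio_rep", "w_a", "w_b", "w_ab")
}
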