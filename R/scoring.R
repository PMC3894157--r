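#' Build the wild-type reference distribution
#'
#' Summarises the empirical wild-type distribution of relative growth
#' parameters, pooled across the plates of each condition: sample mean
#' `mu_wt` and sample standard deviation `sd_wt` (n-1 denominator) per
#' (condition, parameter). Strain values are later projected onto this
#' distribution as sigma scores.
#'
#' @param wt_values Long tibble with columns `condition`, `parameter`
#'   (`"rate"`/`"yield"`) and `value` (relative values of individual
#'   wild-type replicates), e.g. from [wt_well_relatives()].
#' @return A tibble of class `wt_reference`: `condition`, `parameter`,
#'   `mu_wt`, `sd_wt`, `n_wt`. Errors if any cell has fewer than 3 values
#'   or zero spread.
#' @export
#' @examples
#' build_wt_reference(tibble::tibble(condition = "YPD", parameter = "yield",
#'                                   value = c(0.9, 1.0, 1.1)))
build_wt_reference <- function(wt_values) {
  wt_values <- as_tibble(wt_values)
  stopifnot(all(c("condition", "parameter", "value") %in% names(wt_values)))
  ref <- wt_values |>
    group_by(.data$condition, .data$parameter) |>
    summarise(mu_wt = mean(.data$value), sd_wt = sd(.data$value),
              n_wt = dplyr::n(), .groups = "drop")
  if (any(ref$n_wt < 3)) {
    abort("need at least 3 wild-type values per condition and parameter")
  }
  if (any(ref$sd_wt == 0)) abort("degenerate reference: zero wild-type spread")
  structure(ref, class = c("wt_reference", class(ref)))
}

#' Sigma-score strain values against the wild-type reference
#'
#' The sigma score of a strain is the number of wild-type standard
#' deviations its mean relative growth parameter lies from the wild-type
#' mean: `sigma = (x - mu_wt) / sd_wt`. Lethal and missing strains keep
#' their status and carry no score.
#'
#' @param values Tibble with columns `strain`, `condition`, `parameter`,
#'   `value` and optionally `status` (`"scored"`, `"lethal"`, `"missing"`;
#'   defaults to scored).
#' @param ref A [build_wt_reference()] table covering every (condition,
#'   parameter) present in `values`.
#' @return Tibble `strain`, `condition`, `parameter`, `sigma`, `status`;
#'   `sigma` is `NA` whenever `status != "scored"`.
#' @export
sigma_score <- function(values, ref) {
  stopifnot(inherits(ref, "wt_reference"))
  values <- as_tibble(values)
  if (!"status" %in% names(values)) values$status <- "scored"
  bad <- dplyr::anti_join(distinct(values, .data$condition, .data$parameter),
                          ref, by = c("condition", "parameter"))
  if (nrow(bad) > 0) {
    abort(paste0("no wild-type reference for ", bad$condition[1], "/",
                 bad$parameter[1]))
  }
  scored <- values$status == "scored"
  if (any(scored & !is.finite(values$value))) {
    abort("non-finite value for a scored strain")
  }
  values |>
    left_join(as_tibble(ref), by = c("condition", "parameter")) |>
    mutate(sigma = ifelse(.data$status == "scored",
                          (.data$value - .data$mu_wt) / .data$sd_wt,
                          NA_real_)) |>
    select("strain", "condition", "parameter", "sigma", "status")
}

#' Phenotype classes in sigma order
#' @export
phenotype_levels <- function() {
  c("highly_impaired", "impaired", "normal", "improved", "highly_improved")
}

#' Classify sigma scores into phenotype classes
#'
#' Any |sigma| above 2 is a non-normal phenotype and above 3 a strong one:
#' `sigma <= -3` highly impaired, `(-3, -2]` impaired, `(-2, 2)` normal,
#' `[2, 3)` improved, `>= 3` highly improved. Exact boundary values are
#' assigned to the more extreme class.
#'
#' @param sigma Numeric vector of sigma scores (`NA` allowed, returned as
#'   `NA`).
#' @return Ordered factor with levels [phenotype_levels()].
#' @export
#' @examples
#' classify_phenotype(c(-3.5, 0, 2.5))
classify_phenotype <- function(sigma) {
  cls <- ifelse(is.na(sigma), NA_character_,
         ifelse(sigma <= -3, "highly_impaired",
         ifelse(sigma <= -2, "impaired",
         ifelse(sigma < 2, "normal",
         ifelse(sigma < 3, "improved", "highly_improved")))))
  factor(cls, levels = phenotype_levels(), ordered = TRUE)
}

#' Assemble the strains x conditions phenotype matrix
#'
#' Combines sigma scores from all conditions into one long table covering
#' every (strain, condition, parameter) cell exactly once, preserving
#' lethal/missing statuses (cells never observed are filled as missing)
#' and attaching phenotype classes. Rows are ordered by amino acid, then
#' family, then gene when an annotation table is supplied.
#'
#' @param scores Sigma-score tibble from [sigma_score()] (may span several
#'   conditions).
#' @param annotation Optional tibble `strain`, `aa`, `family` used for row
#'   ordering.
#' @return A tibble of class `phenotype_matrix`: `strain`, `aa`, `family`,
#'   `condition`, `parameter`, `sigma`, `status`, `class`. Errors on
#'   conflicting duplicate scores for one cell.
#' @export
assemble_condition_matrix <- function(scores, annotation = NULL) {
  scores <- as_tibble(scores)
  dup <- scores |>
    count(.data$strain, .data$condition, .data$parameter) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    conflicts <- scores |>
      dplyr::semi_join(dup, by = c("strain", "condition", "parameter")) |>
      group_by(.data$strain, .data$condition, .data$parameter) |>
      summarise(ok = dplyr::n_distinct(round(.data$sigma, 10)) == 1 &&
                  dplyr::n_distinct(.data$status) == 1, .groups = "drop")
    if (any(!conflicts$ok)) {
      bad <- conflicts[!conflicts$ok, ][1, ]
      abort(paste0("conflicting duplicate scores for ", bad$strain, " / ",
                   bad$condition, " / ", bad$parameter))
    }
    scores <- distinct(scores, .data$strain, .data$condition, .data$parameter,
                       .keep_all = TRUE)
  }
  full <- tidyr::complete(scores, !!!rlang::syms(c("strain", "condition",
                                                   "parameter")),
                          fill = list(sigma = NA_real_, status = "missing"))
  if (!is.null(annotation)) {
    ann <- as_tibble(annotation)[, c("strain", "aa", "family")]
    full <- left_join(full, ann, by = "strain")
  } else {
    full$aa <- NA_character_
    full$family <- NA_character_
  }
  full <- full |>
    mutate(class = classify_phenotype(.data$sigma)) |>
    arrange(.data$aa, .data$family, .data$strain, .data$condition,
            .data$parameter) |>
    select("strain", "aa", "family", "condition", "parameter", "sigma",
           "status", "class")
  structure(full, class = c("phenotype_matrix", class(full)))
}

#' Per-condition phenotype fractions
#'
#' Percentages of scored strains (lethal and missing excluded from the
#' denominator) falling in the pooled impaired (`sigma <= -2`), improved
#' (`sigma >= 2`) and normal classes for one condition and parameter.
#'
#' @param matrix A [assemble_condition_matrix()] result.
#' @param condition,parameter Cell to summarise.
#' @return One-row tibble `condition`, `parameter`, `pct_impaired`,
#'   `pct_improved`, `pct_normal`, `n_scored`, `n_lethal`, `n_missing`.
#' @export
summarize_condition <- function(matrix, condition, parameter) {
  m <- as_tibble(matrix) |>
    dplyr::filter(.data$condition == !!condition,
                  .data$parameter == !!parameter)
  if (nrow(m) == 0) abort("no cells for that condition/parameter")
  scored <- dplyr::filter(m, .data$status == "scored")
  if (nrow(scored) == 0) abort("zero scored strains")
  n <- nrow(scored)
  tibble(
    condition = condition, parameter = parameter,
    pct_impaired = 100 * sum(scored$class %in%
                               c("impaired", "highly_impaired")) / n,
    pct_improved = 100 * sum(scored$class %in%
                               c("improved", "highly_improved")) / n,
    pct_normal = 100 * sum(scored$class == "normal") / n,
    n_scored = n,
    n_lethal = sum(m$status == "lethal"),
    n_missing = sum(m$status == "missing")
  )
}

#' Phenotype fractions for every condition and parameter
#'
#' @param matrix A [assemble_condition_matrix()] result.
#' @return Tibble with one [summarize_condition()] row per (condition,
#'   parameter) that has scored strains.
#' @export
summarize_phenotypes <- function(matrix) {
  cells <- distinct(as_tibble(matrix), .data$condition, .data$parameter)
  purrr::pmap(cells, function(condition, parameter) {
    summarize_condition(matrix, condition, parameter)
  }) |> bind_rows()
}

#' Correlation between sigma rate and sigma yield
#'
#' Pearson correlation across strains scored for both parameters in one
#' condition, with the two-sided t-distribution p-value; used to check
#' that rate and yield capture independent aspects of fitness.
#'
#' @param matrix A [assemble_condition_matrix()] result.
#' @param condition Condition to correlate.
#' @return One-row tibble `condition`, `pearson_r`, `p_value`, `n`.
#' @export
rate_yield_correlation <- function(matrix, condition) {
  m <- as_tibble(matrix) |>
    dplyr::filter(.data$condition == !!condition, .data$status == "scored") |>
    select("strain", "parameter", "sigma") |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "sigma") |>
    dplyr::filter(is.finite(.data$rate), is.finite(.data$yield))
  if (nrow(m) < 3) abort("need at least 3 strains scored for both parameters")
  ct <- cor.test(m$rate, m$yield, method = "pearson")
  tibble(condition = condition, pearson_r = unname(ct$estimate),
         p_value = ct$p.value, n = nrow(m))
}

#' Write / read a phenotype matrix as TSV
#'
#' Plain-text serialisation (`strain, aa, family, condition, parameter,
#' sigma, status, class`) that round-trips through [read_phenotype_matrix()]
#' unchanged.
#'
#' @param matrix A `phenotype_matrix`.
#' @param path TSV path.
#' @return `path` invisibly (writer); the `phenotype_matrix` (reader).
#' @export
write_phenotype_matrix <- function(matrix, path) {
  df <- as.data.frame(as_tibble(matrix))
  df$class <- as.character(df$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_phenotype_matrix
#' @export
read_phenotype_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  out <- as_tibble(df) |>
    mutate(class = factor(.data$class, levels = phenotype_levels(),
                          ordered = TRUE),
           aa = as.character(.data$aa), family = as.character(.data$family))
  structure(out, class = c("phenotype_matrix", class(out)))
}
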