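# broom-style tidy()/glance() methods for the package's result objects.

#' @export
tidy.wt_reference <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.wt_reference <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  tibble(n_conditions = dplyr::n_distinct(d$condition),
         n_parameters = dplyr::n_distinct(d$parameter),
         min_n_wt = min(d$n_wt),
         max_sd_wt = max(d$sd_wt))
}

#' @export
tidy.epistasis_fit <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  mutate(d, significant = .data$ci_lo > 0 | .data$ci_hi < 0)
}

#' @export
glance.epistasis_fit <- function(x, ...) {
  d <- tidy(x)
  tibble(n_pairs = nrow(d),
         n_aggravating = sum(d$epsilon < 0 & d$significant),
         n_alleviating = sum(d$epsilon > 0 & d$significant),
         mean_n_reps = mean(d$n_reps))
}

#' @export
tidy.motif_scan <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.motif_scan <- function(x, ...) {
  d <- dplyr::filter(as_tibble(unclass_result(x)), .data$available,
                     is.finite(.data$log10_e))
  best <- d[which.min(d$e_value), ]
  tibble(n_windows = nrow(as_tibble(unclass_result(x))),
         n_available = nrow(d),
         best_window_start = if (nrow(best)) best$window_start else NA_real_,
         best_motif = if (nrow(best)) best$best_motif else NA_character_,
         min_log10_e = if (nrow(best)) best$log10_e else NA_real_)
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @export
glance.phenotype_matrix <- function(x, ...) {
  d <- as_tibble(unclass_result(x))
  tibble(n_strains = dplyr::n_distinct(d$strain),
         n_conditions = dplyr::n_distinct(d$condition),
         pct_scored = 100 * mean(d$status == "scored"),
         pct_lethal = 100 * mean(d$status == "lethal"),
         pct_missing = 100 * mean(d$status == "missing"))
}

# drop the package's S3 class tag so tibble verbs behave plainly
unclass_result <- function(x) {
  class(x) <- setdiff(class(x), c("wt_reference", "epistasis_fit",
                                  "motif_scan", "enrichment_result",
                                  "phenotype_matrix"))
  x
}
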