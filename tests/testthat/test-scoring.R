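ref_of <- function(mu, sd, condition = "YPD", parameter = "yield") {
  build_wt_reference(tibble::tibble(
    condition = condition, parameter = parameter,
    value = mu + sd * c(-1, 0, 1)  # sample sd of {-c, 0, c} is exactly c
  ))
}

test_that("wild-type reference summarises the pooled distribution", {
  ref <- build_wt_reference(tibble::tibble(
    condition = "YPD", parameter = "yield", value = c(0.9, 1.0, 1.1)))
  expect_equal(ref$mu_wt, 1.0)
  expect_equal(ref$sd_wt, 0.1)
  expect_equal(ref$n_wt, 3L)

  expect_error(build_wt_reference(tibble::tibble(
    condition = "YPD", parameter = "yield", value = c(1, 1.1))), "at least 3")
  expect_error(build_wt_reference(tibble::tibble(
    condition = "YPD", parameter = "yield", value = rep(1, 5))), "degenerate")

  withr::with_seed(21, {
    big <- build_wt_reference(tibble::tibble(
      condition = "YPD", parameter = "rate", value = rnorm(1000, 1, 0.05)))
  })
  expect_true(big$mu_wt > 0.995 && big$mu_wt < 1.005)
  expect_true(big$sd_wt > 0.045 && big$sd_wt < 0.055)
})

test_that("sigma scores are standardised distances from the wild type", {
  ref <- ref_of(1, 0.05)
  vals <- tibble::tibble(strain = c("a", "b", "dead", "gone"),
                         condition = "YPD", parameter = "yield",
                         value = c(1.0, 0.9, NA, NA),
                         status = c("scored", "scored", "lethal", "missing"))
  sc <- sigma_score(vals, ref)
  expect_equal(sc$sigma[sc$strain == "a"], 0)
  expect_equal(sc$sigma[sc$strain == "b"], -2)
  expect_true(all(is.na(sc$sigma[sc$status != "scored"])))
  expect_equal(sc$status, vals$status)
})

test_that("null strains drawn from the wild-type distribution calibrate the tails", {
  ref <- ref_of(1, 0.05)
  withr::with_seed(77, {
    x <- rnorm(2000, ref$mu_wt, ref$sd_wt)
  })
  sc <- sigma_score(tibble::tibble(strain = sprintf("n%04d", 1:2000),
                                   condition = "YPD", parameter = "yield",
                                   value = x, status = "scored"), ref)
  called <- mean(abs(sc$sigma) > 2)
  p0 <- 2 * pnorm(-2)
  ci <- p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / 2000)
  expect_gt(called, ci[1])
  expect_lt(called, ci[2])
})

test_that("phenotype classes follow the sigma thresholds, extremes at boundaries", {
  expect_equal(as.character(classify_phenotype(-3.5)), "highly_impaired")
  expect_equal(as.character(classify_phenotype(0)), "normal")
  expect_equal(as.character(classify_phenotype(2.5)), "improved")
  expect_equal(as.character(classify_phenotype(c(-3, -2, 2, 3))),
               c("highly_impaired", "impaired", "improved", "highly_improved"))
  expect_true(is.na(classify_phenotype(NA)))
  # classify(sigma(x)) is monotone non-decreasing in x
  xs <- seq(0.5, 1.5, by = 0.01)
  cls <- classify_phenotype(sigma_score(
    tibble::tibble(strain = as.character(seq_along(xs)), condition = "YPD",
                   parameter = "yield", value = xs, status = "scored"),
    ref_of(1, 0.05))$sigma)
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("the condition matrix is complete, ordered and status-preserving", {
  scores <- tidyr::expand_grid(strain = c("s1", "s2", "s3"),
                               condition = c("YPD", "NaCl"),
                               parameter = c("rate", "yield")) |>
    dplyr::mutate(sigma = 0, status = "scored")
  scores$sigma[scores$strain == "s2"] <- NA
  scores$status[scores$strain == "s2"] <- "lethal"
  scores <- scores[-1, ]  # drop one cell -> should come back as missing
  ann <- tibble::tibble(strain = c("s1", "s2", "s3"), aa = c("L", "A", "L"),
                        family = c("L01", "A01", "L02"))
  mat <- assemble_condition_matrix(scores, annotation = ann)
  expect_s3_class(mat, "phenotype_matrix")
  expect_equal(nrow(mat), 3 * 2 * 2)
  expect_equal(sum(mat$status == "missing"), 1)
  expect_true(all(mat$status[mat$strain == "s2"] == "lethal"))
  expect_equal(unique(mat$strain), c("s2", "s1", "s3"))  # aa then family order

  dup <- dplyr::bind_rows(scores, dplyr::mutate(scores[1, ], sigma = 5))
  expect_error(assemble_condition_matrix(dup), "conflicting")
})

test_that("the phenotype matrix round-trips through TSV unchanged", {
  scores <- tidyr::expand_grid(strain = c("s1", "s2"),
                               condition = "YPD",
                               parameter = c("rate", "yield")) |>
    dplyr::mutate(sigma = c(-4, 2.5, 0, NA),
                  status = c("scored", "scored", "scored", "missing"))
  mat <- assemble_condition_matrix(scores)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotype_matrix(mat, path)
  back <- read_phenotype_matrix(path)
  expect_equal(as.data.frame(back), as.data.frame(mat))
})

test_that("condition summaries pool classes over scored strains only", {
  scores <- tibble::tibble(
    strain = sprintf("s%02d", 1:12), condition = "YPD", parameter = "yield",
    sigma = c(rep(0, 8), -2.5, -6, 2.2, NA),
    status = c(rep("scored", 11), "lethal"))
  mat <- assemble_condition_matrix(scores)
  sm <- summarize_condition(mat, "YPD", "yield")
  expect_equal(sm$n_scored, 11)
  expect_equal(sm$pct_impaired, 100 * 2 / 11)
  expect_equal(sm$pct_improved, 100 * 1 / 11)
  expect_equal(sm$pct_impaired + sm$pct_improved + sm$pct_normal, 100)
  expect_equal(sm$n_lethal, 1)

  all0 <- assemble_condition_matrix(tibble::tibble(
    strain = c("a", "b", "c"), condition = "YPD", parameter = "yield",
    sigma = 0, status = "scored"))
  expect_equal(summarize_condition(all0, "YPD", "yield")$pct_normal, 100)
})

test_that("planted impaired fractions are recovered in summaries", {
  withr::with_seed(5, {
    sig <- c(rnorm(180, 0, 1), rnorm(20, -5, 0.5))
  })
  mat <- assemble_condition_matrix(tibble::tibble(
    strain = sprintf("s%03d", 1:200), condition = "YPD", parameter = "yield",
    sigma = sig, status = "scored"))
  sm <- summarize_condition(mat, "YPD", "yield")
  expect_gt(sm$pct_impaired, 8)
  expect_lt(sm$pct_impaired, 14)
})

test_that("rate/yield correlation matches the direct covariance formula", {
  toy <- tibble::tibble(
    strain = sprintf("s%d", 1:5),
    rate = c(-1.2, 0.4, 2.0, -0.3, 0.8),
    yield = c(0.5, -0.7, 1.4, 0.1, -2.0))
  scores <- tidyr::pivot_longer(toy, c(rate, yield), names_to = "parameter",
                                values_to = "sigma") |>
    dplyr::mutate(condition = "YPD", status = "scored")
  mat <- assemble_condition_matrix(scores)
  ct <- rate_yield_correlation(mat, "YPD")
  r_direct <- sum((toy$rate - mean(toy$rate)) * (toy$yield - mean(toy$yield))) /
    sqrt(sum((toy$rate - mean(toy$rate))^2) * sum((toy$yield - mean(toy$yield))^2))
  expect_equal(ct$pearson_r, r_direct)
  expect_equal(ct$n, 5)

  # identical parameters -> r = 1
  same <- scores
  same$sigma <- rep(toy$rate, each = 2)
  expect_equal(rate_yield_correlation(assemble_condition_matrix(same),
                                      "YPD")$pearson_r, 1)

  # independently planted effects stay uncorrelated
  withr::with_seed(8, {
    ind <- tidyr::expand_grid(strain = sprintf("s%03d", 1:200),
                              parameter = c("rate", "yield")) |>
      dplyr::mutate(condition = "YPD", sigma = rnorm(400), status = "scored")
  })
  expect_lt(abs(rate_yield_correlation(assemble_condition_matrix(ind),
                                       "YPD")$pearson_r), 0.15)

  tiny <- assemble_condition_matrix(scores[1:4, ])
  expect_error(rate_yield_correlation(tiny, "YPD"), "at least 3")
})
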