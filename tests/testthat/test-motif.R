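test_that("flank FASTA round-trips with upstream coordinates intact", {
  fl <- simulate_flanks(c("g1", "g2"), flank_len = 200, seed = 2)$flanks
  path <- withr::local_tempfile(fileext = ".fa")
  write_flanks(fl, path)
  back <- read_flanks(path)
  expect_equal(back$gene, fl$gene)
  expect_equal(back$seq, fl$seq)
  # position -42 of a 200 bp flank is 0-based offset 158 (1-based 159)
  expect_equal(substr(back$seq[1], 159, 159),
               flank_window_seq_chr(back, -42))
})

test_that("flank reading validates identifiers and alphabet", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 upstream=-60..-1", strrep("ACGT", 15),
               ">g1 upstream=-60..-1", strrep("ACGT", 15)), path)
  expect_error(read_flanks(path), "duplicate")
  writeLines(c(">g1", paste0(strrep("ACGT", 14), "ACRT")), path)
  expect_error(read_flanks(path), "non-ACGT")
})

test_that("short flanks report unavailable positions instead of failing", {
  path <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">long", strrep("A", 100), ">short", strrep("A", 30)), path)
  fl <- read_flanks(path)
  el <- list(id = "trich", consensus = "TTTT", anchor = -53, tolerance = 2)
  hit <- match_element(fl, el)
  expect_false(hit$matched[hit$gene == "long"])   # covered, no match
  expect_true(is.na(hit$matched[hit$gene == "short"]))  # window not covered
})

test_that("anchored elements match within their tolerance window", {
  plan <- tibble::tibble(gene = "g1", element_id = "tata",
                         consensus = "TATAWA", anchor = -42)
  fl <- simulate_flanks(c("g1", "g2"), plan,
                        bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        flank_len = 120, seed = 6)$flanks
  el <- list(id = "tata", consensus = "TATAWA", anchor = -42, tolerance = 3)
  hit <- match_element(fl, el)
  expect_true(hit$matched[hit$gene == "g1"])
  expect_equal(hit$position[hit$gene == "g1"], -42)

  allg <- new_flank_set_for_test(tibble::tibble(
    gene = "gg", seq = strrep("G", 120), length = 120), 120)
  expect_false(match_element(allg, list(id = "t", consensus = "TTTT",
                                        anchor = -30, tolerance = 4))$matched)
})

test_that("element matching agrees with brute-force window enumeration", {
  fl <- simulate_flanks(sprintf("g%03d", 1:100),
                        bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                        flank_len = 80, seed = 13)$flanks
  el <- list(id = "tata", consensus = "TATAWA", anchor = -42, tolerance = 4)
  hits <- match_element(fl, el)
  # oracle: test every candidate start explicitly against IUPAC semantics
  brute <- vapply(fl$seq, function(s) {
    any(vapply(-46:-38, function(p) {
      sub <- substr(s, 80 + p + 1, 80 + p + 6)
      grepl("^TATA[AT]A$", sub)
    }, logical(1)))
  }, logical(1))
  expect_equal(hits$matched, unname(brute))
})

test_that("hypergeometric enrichment equals exhaustive draw enumeration", {
  # construct a flank universe with exactly K carriers, classify n genes,
  # k of them carriers, and compare against enumerating all C(N, n) draws
  for (cse in list(c(N = 10, K = 5, n = 5, k = 5),
                   c(N = 8, K = 3, n = 4, k = 2),
                   c(N = 12, K = 6, n = 5, k = 3),
                   c(N = 7, K = 7, n = 3, k = 3))) {
    res <- enrichment_case(cse["N"], cse["K"], cse["n"], cse["k"])
    expect_equal(res$p, enum_hyper_p(cse["N"], cse["K"], cse["n"], cse["k"]),
                 tolerance = 1e-12)
  }
  # N=10, K=5, n=5, k=5 -> 1/252 exactly
  expect_equal(enrichment_case(10, 5, 5, 5)$p, 1 / choose(10, 5))
  # everyone carries the element -> p = 1 for any class
  expect_equal(enrichment_case(9, 9, 4, 4)$p, 1)
})

test_that("enrichment p is monotone decreasing in the class carrier count", {
  ps <- vapply(0:4, function(k) enrichment_case(12, 6, 4, k)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("planted class-specific elements give strong enrichment", {
  genes <- sprintf("g%03d", 1:140)
  impaired <- genes[1:40]
  plan <- tibble::tibble(
    gene = c(impaired[1:36], genes[41:50]),  # 90% of class, 10% of the rest
    element_id = "tata", consensus = "TATAWA", anchor = -42)
  fl <- simulate_flanks(genes, plan, flank_len = 120, seed = 18)$flanks
  classes <- tibble::tibble(gene = genes,
                            class = ifelse(genes %in% impaired,
                                           "yield_impaired", "normal"))
  enr <- element_enrichment(fl, classes,
                            elements = tibble::tibble(
                              id = "tata", consensus = "TATAWA",
                              anchor = -42, tolerance = 4))
  p_imp <- enr$p[enr$gene_class == "yield_impaired"]
  expect_lt(p_imp, 1e-3)
  expect_equal(enr$neg_log10_p[enr$gene_class == "yield_impaired"],
               -log10(p_imp))
})

test_that("the windowed scan finds a planted 6-mer at its position", {
  genes_fg <- sprintf("f%03d", 1:40)
  genes_bg <- sprintf("b%03d", 1:99)
  fg <- simulate_flanks(genes_fg,
                        tibble::tibble(gene = genes_fg[1:32], element_id = "m",
                                       consensus = "GTATAA", anchor = -42),
                        flank_len = 120, seed = 23)$flanks
  bg <- simulate_flanks(genes_bg,
                        tibble::tibble(gene = genes_bg[1:5], element_id = "m",
                                       consensus = "GTATAA", anchor = -42),
                        flank_len = 120, seed = 24)$flanks
  sc <- windowed_kmer_scan(fg, bg, from = -60, to = -20)
  best <- glance(sc)
  expect_lt(best$min_log10_e, -3)
  expect_true(best$best_window_start >= -45 && best$best_window_start <= -42)
  expect_true(grepl(best$best_motif, "GTATAA", fixed = TRUE) ||
                grepl("GTATAA", best$best_motif, fixed = TRUE))
  # E-values always dominate their Fisher p; scan-level E dominates both
  ok <- !is.na(sc$p)
  expect_true(all(sc$e_value[ok] >= sc$p[ok]))
  expect_true(all(sc$e_value_scan[ok] >= sc$e_value[ok]))
  # deterministic: same inputs give identical results
  expect_identical(as.data.frame(sc),
                   as.data.frame(windowed_kmer_scan(fg, bg, from = -60,
                                                    to = -20)))
})

test_that("scan Fisher p-values match fisher.test on the contingency table", {
  fg <- new_flank_set_for_test(tibble::tibble(
    gene = sprintf("f%d", 1:6),
    seq = c(rep("AAATTTCCC", 4), rep("GGGGGGGGG", 2)),
    length = 9), 9)
  bg <- new_flank_set_for_test(tibble::tibble(
    gene = sprintf("b%d", 1:8),
    seq = c(rep("AAATTTCCC", 2), rep("CCCCCCCCC", 6)),
    length = 9), 9)
  sc <- windowed_kmer_scan(fg, bg, from = -9, to = -1)
  row <- sc[sc$available & !is.na(sc$p), ][1, ]
  ft <- stats::fisher.test(matrix(c(row$fg_hits, 6 - row$fg_hits,
                                    row$bg_hits, 8 - row$bg_hits), 2,
                                  byrow = TRUE),
                           alternative = "greater")
  expect_equal(row$p, ft$p.value, tolerance = 1e-10)
})

test_that("identical foreground and background sequences give p = 1 everywhere", {
  # every gene carries every candidate, so the upper tail is certain
  fg <- new_flank_set_for_test(tibble::tibble(
    gene = c("f1", "f2", "f3"), seq = rep("ACGTACGTA", 3), length = 9), 9)
  bg <- new_flank_set_for_test(tibble::tibble(
    gene = c("b1", "b2", "b3"), seq = rep("ACGTACGTA", 3), length = 9), 9)
  sc <- windowed_kmer_scan(fg, bg, from = -9, to = -1)
  expect_gt(sum(!is.na(sc$p)), 0)
  expect_true(all(sc$p[!is.na(sc$p)] == 1))
})
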