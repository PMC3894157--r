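# Independent oracles and small fixture builders used across the suite.

# closed-form lagged logistic, written out independently of the package
oracle_logistic <- function(t, K, r, lag, od0) {
  ifelse(t < lag, od0,
         K / (1 + ((K - od0) / od0) * exp(-r * (t - lag))))
}

# brute-force upper-tail hypergeometric by enumerating all C(N, n) draws
enum_hyper_p <- function(N, K, n, k) {
  carriers <- seq_len(K)  # genes 1..K carry the element
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(s) sum(s %in% carriers))
  mean(hits >= k)
}

# write a small plate reads + map CSV pair, returning the two paths
write_plate_fixture <- function(reads, map, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  rp <- file.path(dir, "reads.csv")
  mp <- file.path(dir, "map.csv")
  utils::write.csv(reads, rp, row.names = FALSE)
  utils::write.csv(map, mp, row.names = FALSE)
  list(reads = rp, map = mp)
}

# tiny single-plate assignment table: n strains + WT + blank wells
small_assignments <- function(strains, n_wt = 2, n_blank = 1) {
  tibble::tibble(
    well = well_seq(length(strains) + n_wt + n_blank),
    strain = c(rep("WT", n_wt), rep("BLANK", n_blank), strains),
    bio_rep = 1L
  )
}

well_seq <- function(n) {
  sprintf("%s%02d", rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(n)]
}

# thin wrappers over package internals used by the motif tests
new_flank_set_for_test <- function(tbl, flank_len) {
  growthscreen:::new_flank_set(tbl, flank_len)
}

flank_window_seq_chr <- function(flanks, pos) {
  growthscreen:::flank_window_seq(flanks, pos, pos)[1]
}

# deterministic enrichment universe: N genes, K carriers of a TTTT element
# at -30, a class of n genes containing k carriers; returns the class row
enrichment_case <- function(N, K, n, k) {
  stopifnot(k <= min(K, n), n < N, K <= N)
  carrier <- paste0(strrep("G", 30), "TTTT", strrep("G", 26))
  empty <- strrep("G", 60)
  genes <- sprintf("g%02d", seq_len(N))
  fl <- new_flank_set_for_test(tibble::tibble(
    gene = genes,
    seq = c(rep(carrier, K), rep(empty, N - K)),
    length = 60), 60)
  cls <- rep("out", N)
  cls[seq_len(k)] <- "in"                     # k carriers
  if (n - k > 0) cls[K + seq_len(n - k)] <- "in"  # n - k non-carriers
  enr <- element_enrichment(fl, tibble::tibble(gene = genes, class = cls),
                            elements = tibble::tibble(
                              id = "t", consensus = "TTTT",
                              anchor = -30, tolerance = 0))
  enr[enr$gene_class == "in", ]
}
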