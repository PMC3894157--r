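# Upstream flank handling and motif statistics.
#
# Coordinate convention: position 0 is the first base of the mature gene;
# upstream positions are negative and half-open at 0, so a flank of length
# L covers -L .. -1 and position -k of a gene with its own length `len`
# (right-aligned at -1) is 1-based sequence offset `len - k + 1`.

new_flank_set <- function(tbl, flank_len) {
  structure(tbl, flank_len = flank_len,
            class = c("flank_set", class(tbl)))
}

#' Read upstream flanking sequences from FASTA
#'
#' Sequences are right-aligned so their last base sits at position -1
#' (immediately upstream of the mature gene's first base at position 0).
#' Records shorter than `flank_len` are kept: their distal positions are
#' simply unavailable rather than padded. Gene identifiers are the first
#' whitespace-separated word of each header and must be unique; bases
#' other than A/C/G/T/N are an error.
#'
#' @param fasta_path FASTA path.
#' @param flank_len Nominal flank length (default: the longest record).
#' @return A `flank_set`: tibble `gene`, `seq`, `length` with a
#'   `flank_len` attribute.
#' @export
read_flanks <- function(fasta_path, flank_len = NULL) {
  set <- Biostrings::readDNAStringSet(fasta_path)
  genes <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1)
  if (anyDuplicated(genes)) {
    abort(paste0("duplicate gene id in FASTA: ",
                 genes[duplicated(genes)][1]))
  }
  seqs <- as.character(set)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0("non-ACGT/N base in record ", genes[bad][1]))
  }
  flank_len <- flank_len %||% max(nchar(seqs))
  new_flank_set(tibble(gene = unname(genes), seq = unname(seqs),
                       length = nchar(unname(seqs))),
                flank_len = flank_len)
}

# per-gene substring covering upstream positions from..to (negative,
# from <= to <= -1); NA where not fully covered
flank_window_seq <- function(flanks, from, to) {
  stopifnot(from <= to, to <= -1)
  len <- flanks$length
  start <- len + from + 1
  stop <- len + to + 1
  out <- rep(NA_character_, nrow(flanks))
  ok <- start >= 1
  out[ok] <- substr(flanks$seq[ok], start[ok], stop[ok])
  out
}

#' Default conserved upstream elements
#'
#' Positional consensus elements reported upstream of pol III-transcribed
#' genes: T-rich stretches near -53 and -30, a TATA-like element near -42
#' and a transcription start site element near -13 (positions relative to
#' the first base of the mature gene). Consensus strings are pragmatic
#' IUPAC stand-ins for the published profiles and are fully configurable.
#'
#' @return Tibble `id`, `consensus`, `anchor`, `tolerance`.
#' @export
conserved_elements <- function() {
  tibble(
    id = c("trich_m53", "tata_m42", "trich_m30", "tss_m13"),
    consensus = c("TTTT", "TATAWA", "TTTT", "YYCAA"),
    anchor = c(-53, -42, -30, -13),
    tolerance = c(4, 4, 4, 4)
  )
}

#' Match one anchored element against every flank
#'
#' An element matches a gene if its IUPAC consensus occurs with a start
#' position inside `anchor - tolerance` .. `anchor + tolerance` (and fully
#' upstream of position 0). Genes whose sequence does not cover the whole
#' search window are reported unavailable (`matched = NA`). The leftmost
#' (most upstream) match position is returned.
#'
#' @param flanks A `flank_set`.
#' @param element One-row tibble or list with `id`, `consensus`, `anchor`
#'   (negative), `tolerance` (>= 0).
#' @return Tibble `gene`, `element_id`, `matched` (logical, `NA` when
#'   unavailable), `position` (start of the leftmost match, `NA`
#'   otherwise).
#' @export
match_element <- function(flanks, element) {
  stopifnot(inherits(flanks, "flank_set"))
  element <- as.list(element)
  lc <- nchar(element$consensus)
  if (lc == 0) abort("empty consensus")
  if (element$anchor >= 0) abort("element anchor must be negative")
  if (element$tolerance < 0) abort("tolerance must be >= 0")
  from <- element$anchor - element$tolerance
  to <- min(element$anchor + element$tolerance + lc - 1, -1)
  if (from > to - lc + 1) abort("element does not fit upstream of position 0")
  pat <- iupac_regex(element$consensus)
  win <- flank_window_seq(flanks, from, to)
  hit <- regexpr(pat, win)
  matched <- ifelse(is.na(win), NA, hit > 0)
  # a match must *start* within the tolerance window
  start_pos <- from + as.integer(hit) - 1
  ok_start <- !is.na(matched) & matched &
    start_pos <= element$anchor + element$tolerance
  tibble(gene = flanks$gene,
         element_id = element$id,
         matched = ifelse(is.na(matched), NA, matched & ok_start),
         position = ifelse(ok_start, start_pos, NA_real_))
}

#' Match several elements
#'
#' @param flanks A `flank_set`.
#' @param elements Tibble of elements as in [conserved_elements()].
#' @return Row-bound [match_element()] results.
#' @export
match_elements <- function(flanks, elements) {
  purrr::map(seq_len(nrow(elements)),
             function(i) match_element(flanks, elements[i, ])) |>
    bind_rows()
}

#' Hypergeometric enrichment of elements in phenotype classes
#'
#' For every (element, gene class) pair, tests whether class members carry
#' the element more often than expected from the universe: upper-tail
#' hypergeometric `P(X >= k)` with universe size `N` (genes with a class
#' assignment and an available search window), `K` carriers in the
#' universe, class size `n` and `k` carriers in the class. p-values are
#' reported raw (as `-log10 p`), one test per cell.
#'
#' @param flanks A `flank_set`.
#' @param classes Tibble `gene`, `class` (one class per gene).
#' @param elements Element tibble (default [conserved_elements()]).
#' @return A tibble of class `enrichment_result`: `element_id`,
#'   `gene_class`, `N`, `K`, `n`, `k`, `p`, `neg_log10_p`.
#' @export
element_enrichment <- function(flanks, classes, elements = conserved_elements()) {
  classes <- as_tibble(classes)
  stopifnot(all(c("gene", "class") %in% names(classes)))
  if (anyDuplicated(classes$gene)) abort("a gene may carry only one class")
  hits <- match_elements(flanks, elements) |>
    inner_join(classes, by = "gene")
  out <- purrr::map(unique(elements$id), function(el) {
    h <- dplyr::filter(hits, .data$element_id == el, !is.na(.data$matched))
    if (nrow(h) == 0) abort(paste0("empty universe for element ", el))
    N <- nrow(h)
    K <- sum(h$matched)
    purrr::map(sort(unique(h$class)), function(cl) {
      inc <- h$class == cl
      n <- sum(inc)
      if (n == 0) abort("empty class")
      k <- sum(h$matched[inc])
      p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      tibble(element_id = el, gene_class = cl, N = N, K = K, n = n, k = k,
             p = p, neg_log10_p = -log10(p))
    }) |> bind_rows()
  }) |> bind_rows()
  structure(out, class = c("enrichment_result", class(out)))
}

# unique k-mers (kmin..kmax) of each sequence, counted once per sequence
kmer_presence_table <- function(seqs, kmin, kmax) {
  all <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    ks <- kmin:min(kmax, L)
    unique(unlist(lapply(ks, function(k) {
      substring(s, 1:(L - k + 1), k:L)
    })))
  }))
  if (length(all) == 0) {
    return(integer(0))
  }
  table(all)
}

#' Windowed k-mer over-representation scan
#'
#' Emulates a positionally constrained motif search: slides a window of
#' `window` bp across the upstream region, and within each window tests
#' every exact k-mer (`kmin`..`kmax` bp) present in at least `min_fg`
#' foreground window-sequences for over-representation in the foreground
#' versus background gene set (one-sided Fisher exact test on
#' presence/absence, computed as the hypergeometric upper tail). Each
#' window's E-value is its best Fisher p multiplied by the number of
#' k-mers tested in that window (Bonferroni-style inflation, mirroring a
#' motif-search E-value); the minimum-E motif per window is reported.
#' The scan is deterministic.
#'
#' Because many (heavily overlapping) windows are scanned, the per-window
#' E-value alone does not control the familywise error of the whole scan;
#' `e_value_scan` further multiplies each window's E by the number of
#' windows in which any motif was tested, and is the statistic to
#' threshold when asking whether the scan found anything at all.
#'
#' @param fg,bg Foreground and background `flank_set`s (non-overlapping
#'   gene sets).
#' @param window Window length in bp (default 9).
#' @param kmin,kmax Motif length range (defaults 4 and 8).
#' @param from,to Scan range in upstream coordinates (defaults -100 .. -1);
#'   window start positions run from `from` to `to - window + 1`.
#' @param min_fg Minimum foreground sequences a k-mer must occur in to be
#'   tested (default 2).
#' @return A tibble of class `motif_scan`, one row per window start:
#'   `window_start`, `window_len`, `n_fg`, `n_bg`, `best_motif`,
#'   `fg_hits`, `bg_hits`, `n_candidates`, `p`, `e_value`, `log10_e`,
#'   `e_value_scan`, `log10_e_scan`, `available`.
#' @export
windowed_kmer_scan <- function(fg, bg, window = 9, kmin = 4, kmax = 8,
                               from = -100, to = -1, min_fg = 2) {
  stopifnot(inherits(fg, "flank_set"), inherits(bg, "flank_set"))
  if (length(intersect(fg$gene, bg$gene)) > 0) {
    abort("foreground and background gene sets overlap")
  }
  if (kmin < 1 || kmax > window || kmin > kmax) {
    abort("need 1 <= kmin <= kmax <= window")
  }
  starts <- seq(from, to - window + 1)
  rows <- purrr::map(starts, function(s) {
    fg_seq <- flank_window_seq(fg, s, s + window - 1)
    bg_seq <- flank_window_seq(bg, s, s + window - 1)
    fg_seq <- fg_seq[!is.na(fg_seq)]
    bg_seq <- bg_seq[!is.na(bg_seq)]
    base <- tibble(window_start = s, window_len = window,
                   n_fg = length(fg_seq), n_bg = length(bg_seq),
                   best_motif = NA_character_, fg_hits = NA_integer_,
                   bg_hits = NA_integer_, n_candidates = 0L,
                   p = NA_real_, e_value = NA_real_, log10_e = NA_real_,
                   available = TRUE)
    if (length(fg_seq) == 0 && length(bg_seq) == 0) {
      base$available <- FALSE
      return(base)
    }
    if (length(fg_seq) < min_fg) {
      return(base)
    }
    fg_tab <- kmer_presence_table(fg_seq, kmin, kmax)
    cands <- names(fg_tab)[fg_tab >= min_fg]
    if (length(cands) == 0) {
      return(base)
    }
    bg_tab <- kmer_presence_table(bg_seq, kmin, kmax)
    fg_hits <- as.integer(fg_tab[cands])
    bg_hits <- as.integer(bg_tab[cands])
    bg_hits[is.na(bg_hits)] <- 0L
    m <- length(fg_seq)
    nb <- length(bg_seq)
    p <- phyper(fg_hits - 1, fg_hits + bg_hits, m + nb - fg_hits - bg_hits,
                m, lower.tail = FALSE)
    e <- p * length(cands)
    ord <- order(e, p, cands)
    i <- ord[1]
    base$best_motif <- cands[i]
    base$fg_hits <- fg_hits[i]
    base$bg_hits <- bg_hits[i]
    base$n_candidates <- length(cands)
    base$p <- p[i]
    base$e_value <- e[i]
    base$log10_e <- log10(e[i])
    base
  })
  out <- bind_rows(rows)
  n_tested <- sum(out$n_candidates > 0)
  out$e_value_scan <- out$e_value * max(n_tested, 1L)
  out$log10_e_scan <- log10(out$e_value_scan)
  structure(out, class = c("motif_scan", class(out)))
}
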