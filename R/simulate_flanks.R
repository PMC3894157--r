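#' Simulate upstream flanking sequences with planted elements
#'
#' Generates one upstream flank per gene: `flank_len` bases covering
#' positions `-flank_len` .. `-1`, where position 0 is the first base of
#' the mature gene (so position `-k` is sequence offset `flank_len - k`,
#' 0-based). Background bases are drawn i.i.d. from `bg`; each planted
#' element is instantiated from its IUPAC consensus (degenerate positions
#' sampled uniformly) and written at its anchored upstream position.
#'
#' @param genes Character vector of gene identifiers (unique).
#' @param element_plan Optional tibble with columns `gene`, `element_id`,
#'   `consensus` (IUPAC), `anchor` (negative upstream start position).
#'   An element anchored at `-k` occupies positions `-k` .. `-k + len - 1`
#'   and must fit upstream of position 0 and inside the flank.
#' @param bg Named background nucleotide probabilities (A, C, G, T);
#'   normalised internally.
#' @param flank_len Flank length in bp (default 200, minimum 60).
#' @param seed Integer seed; identical inputs and seed give identical
#'   sequences.
#'
#' @return A list with `flanks` (a `flank_set`, see [read_flanks()]) and
#'   `truth` (the realised `element_plan` with the instantiated `site`
#'   sequence per row).
#' @export
#' @examples
#' fl <- simulate_flanks(c("g1", "g2"),
#'   element_plan = tibble::tibble(gene = "g1", element_id = "tata",
#'                                 consensus = "TATAWA", anchor = -42),
#'   seed = 3)
simulate_flanks <- function(genes, element_plan = NULL,
                            bg = c(A = 0.31, C = 0.19, G = 0.19, T = 0.31),
                            flank_len = 200, seed = 1L) {
  if (anyDuplicated(genes)) abort("duplicate gene ids")
  if (flank_len < 60) abort("`flank_len` must be >= 60")
  bg <- bg[c("A", "C", "G", "T")]
  if (any(is.na(bg)) || any(bg < 0) || sum(bg) <= 0) {
    abort("`bg` must give non-negative A/C/G/T frequencies")
  }
  bg <- bg / sum(bg)

  plan <- if (is.null(element_plan)) {
    tibble(gene = character(), element_id = character(),
           consensus = character(), anchor = numeric())
  } else {
    as_tibble(element_plan)
  }
  if (nrow(plan) > 0) {
    len <- nchar(plan$consensus)
    if (any(plan$anchor >= 0)) abort("element anchors must be negative (upstream)")
    if (any(-plan$anchor > flank_len)) {
      abort("element anchored beyond the start of the flank")
    }
    if (any(len > -plan$anchor)) {
      abort("element longer than the distance from its anchor to position 0")
    }
    if (any(!plan$gene %in% genes)) abort("element_plan names an unknown gene")
  }

  withr::with_seed(as.integer(seed) %% 2147483647L, {
    seqs <- vapply(genes, function(g) {
      paste0(sample(names(bg), flank_len, replace = TRUE, prob = bg),
             collapse = "")
    }, character(1))
    sites <- character(nrow(plan))
    if (nrow(plan) > 0) {
      for (i in seq_len(nrow(plan))) {
        site <- instantiate_consensus(plan$consensus[i])
        sites[i] <- site
        start <- flank_len + plan$anchor[i] + 1  # 1-based offset of position anchor
        s <- seqs[[plan$gene[i]]]
        substr(s, start, start + nchar(site) - 1) <- site
        seqs[[plan$gene[i]]] <- s
      }
    }
  })
  plan$site <- if (nrow(plan) > 0) sites else character(0)

  flanks <- new_flank_set(tibble(gene = as.character(genes),
                                 seq = unname(seqs),
                                 length = nchar(unname(seqs))),
                          flank_len = flank_len)
  list(flanks = flanks, truth = plan)
}

#' Write a flank set to FASTA
#'
#' Headers follow `"<gene> upstream=-<len>..-1"` so coordinates survive a
#' round trip through [read_flanks()].
#'
#' @param flanks A `flank_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flanks <- function(flanks, path) {
  stopifnot(inherits(flanks, "flank_set"))
  set <- Biostrings::DNAStringSet(flanks$seq)
  names(set) <- paste0(flanks$gene, " upstream=-", flanks$length, "..-1")
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
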