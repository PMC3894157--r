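# Internal helpers shared across modules.

# Stable 32-bit string hash (polynomial rolling hash, mod 2^31 - 1).
# Used to derive per-plate RNG streams from a master seed so that plate
# simulation order never changes the draws.
hash_seed <- function(master, ...) {
  key <- paste(c(...), collapse = "\r")
  m <- 2147483647
  h <- as.numeric(master %% m)
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h)
}

# IUPAC nucleotide code -> regex character class.
iupac_regex <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0) {
    abort(paste0("invalid IUPAC code(s) in consensus: ", paste(bad, collapse = ", ")))
  }
  paste0(vapply(chars, function(ch) {
    bases <- map[[ch]]
    if (nchar(bases) == 1L) bases else paste0("[", bases, "]")
  }, character(1)), collapse = "")
}

# Draw one concrete instance of an IUPAC consensus (each degenerate position
# sampled uniformly among its allowed bases). Consumes RNG state.
instantiate_consensus <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(consensus), "")[[1]]
  paste0(vapply(chars, function(ch) {
    bases <- strsplit(map[[ch]], "")[[1]]
    if (length(bases) == 1L) bases else sample(bases, 1L)
  }, character(1)), collapse = "")
}

# Well labels A01..H12 for a 96-well plate (or as many rows as needed).
well_labels <- function(n) {
  rows <- LETTERS[1:8]
  cols <- sprintf("%02d", 1:12)
  labs <- as.vector(t(outer(rows, cols, paste0)))
  if (n > length(labs)) {
    # fall back to sequential labels for oversized virtual plates
    labs <- c(labs, sprintf("X%03d", seq_len(n - length(labs))))
  }
  labs[seq_len(n)]
}

# largest-remainder apportionment of n items to fractions summing to 1
apportion <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    take <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

assert_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(paste0("`", name, "` must be a finite number"))
  }
  if (positive && x <= 0) {
    abort(paste0("`", name, "` must be strictly positive"))
  }
  invisible(x)
}
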