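# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

is_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

#' @keywords internal
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# 1-based integer -> fixed-width base-4 DNA word (A=0, C=1, G=2, T=3)
int_to_dna <- function(i, len) {
  i <- as.integer(i) - 1L
  cols <- vector("list", len)
  for (j in len:1) {
    cols[[j]] <- DNA_BASES[i %% 4L + 1L]
    i <- i %/% 4L
  }
  do.call(paste0, cols)
}

# Hamming distance between each element of `a` and the single string `b`.
# All strings must have nchar(b) characters at the compared positions.
hamming_to <- function(a, b) {
  d <- integer(length(a))
  for (j in seq_len(nchar(b))) {
    d <- d + (substr(a, j, j) != substr(b, j, j))
  }
  d
}

min_pairwise_hamming <- function(barcodes) {
  n <- length(barcodes)
  if (n < 2L) return(Inf)
  dmin <- Inf
  for (i in seq_len(n - 1L)) {
    dmin <- min(dmin, min(hamming_to(barcodes[(i + 1L):n], barcodes[i])))
  }
  dmin
}

# Deterministic per-name RNG substream: results do not depend on the order
# in which cells are processed. Polynomial string hash mod 2^31 - 1.
stream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
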