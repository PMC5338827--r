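# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, restoring the previous
#' RNG state afterwards so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Uniform random DNA string(s) over ACGT.
random_dna <- function(n) {
  vapply(n, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Reverse complement of plain character sequences.
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute bases at a given per-base rate; transversions/transitions
# equally likely among the three alternatives.  Uses the current RNG stream.
inject_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  w <- nchar(reads)
  total <- sum(w)
  hits <- which(stats::runif(total) < rate)
  if (!length(hits)) return(reads)
  ends <- cumsum(w)
  starts <- ends - w + 1L
  ri <- findInterval(hits, starts)
  pos <- hits - starts[ri] + 1L
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hits)) {
    i <- ri[j]
    p <- pos[j]
    cur <- substr(reads[i], p, p)
    alt <- sample(setdiff(bases, cur), 1L)
    substr(reads[i], p, p) <- alt
  }
  reads
}

# Number of matching characters between two equal-length strings.
n_matching_bases <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (!nchar(a)) return(0L)
  sum(charToRaw(a) == charToRaw(b))
}

# Per-copy divergence: substitute a fixed fraction of positions.
diverge_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- round(rate * n)
  if (k == 0) return(seq)
  at <- sample.int(n, k)
  bases <- c("A", "C", "G", "T")
  for (p in at) {
    cur <- substr(seq, p, p)
    substr(seq, p, p) <- sample(setdiff(bases, cur), 1L)
  }
  seq
}
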