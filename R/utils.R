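# Internal helpers: validation, seeded evaluation, random sequence draws.

assert_dna <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) == 0L || anyNA(x)) {
    stop(what, " must be a non-missing character vector", call. = FALSE)
  }
  if (any(!nzchar(x))) {
    stop(what, " must be non-empty", call. = FALSE)
  }
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(what, " contains characters outside A/C/G/T (ambiguity codes are ",
         "not accepted): ", substr(x[bad][1L], 1L, 30L), call. = FALSE)
  }
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# n random DNA sequences of length len (uniform base composition).
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  chars <- sample(DNA_BASES, n * len, replace = TRUE)
  big <- paste(chars, collapse = "")
  starts <- (seq_len(n) - 1L) * len + 1L
  substring(big, starts, starts + len - 1L)
}

# Substitute each base independently with probability `rate` to a uniformly
# chosen different base. Sequences must share a common length.
mutate_bases <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  len <- unique(nchar(seqs))
  stopifnot(length(len) == 1L)
  chars <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    offs <- sample.int(3L, length(hit), replace = TRUE)
    idx <- (match(chars[hit], DNA_BASES) - 1L + offs) %% 4L + 1L
    chars[hit] <- DNA_BASES[idx]
  }
  apply(matrix(chars, nrow = len), 2L, paste, collapse = "")
}

# All linear k-windows of one sequence.
linear_kmers <- function(seq, k) {
  L <- nchar(seq)
  if (k > L) return(character(0))
  starts <- seq_len(L - k + 1L)
  substring(seq, starts, starts + k - 1L)
}
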