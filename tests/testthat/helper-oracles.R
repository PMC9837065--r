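# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: windows are built one at a time by character
# indexing and membership uses base %in%.

oracle_revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# circular k-mer at offset i of a monomer, built base by base
oracle_circular_kmers <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  m <- length(chars)
  out <- character(m)
  for (i in seq_len(m)) {
    idx <- ((i - 1 + seq_len(k) - 1) %% m) + 1
    out[i] <- paste(chars[idx], collapse = "")
  }
  sort(unique(out))
}

# fraction of a read's k-windows present in a signature set
oracle_coverage <- function(read, signature, k) {
  L <- nchar(read)
  if (L < k) return(NA_real_)
  hits <- 0L
  n <- L - k + 1L
  for (s in seq_len(n)) {
    if (substr(read, s, s + k - 1L) %in% signature) hits <- hits + 1L
  }
  hits / n
}

# explicit re-statement of the classification rule: max coverage over the
# declared family order, assigned when >= tau
oracle_classify <- function(read, models, tau) {
  covs <- vapply(models, function(m) {
    oracle_coverage(read, m$kmer_signature, m$k)
  }, numeric(1))
  if (anyNA(covs)) return(list(family = NA_character_, coverage = NA_real_))
  best <- which(covs == max(covs))[1]
  fam <- if (covs[best] >= tau) models[[best]]$family_name else NA_character_
  list(family = fam, coverage = covs[best])
}

# window-by-window k-mer tally across sequences
oracle_count_kmers <- function(seqs, k) {
  counts <- new.env(parent = emptyenv())
  total <- 0L
  for (s in seqs) {
    for (i in seq_len(nchar(s) - k + 1L)) {
      w <- substr(s, i, i + k - 1L)
      counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
      total <- total + 1L
    }
  }
  out <- unlist(as.list(counts))
  list(counts = out[order(names(out))], total_windows = total)
}

random_reads <- function(n, len, seed) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# read-length windows sampled from a divergent array of the given family
repeat_fragments <- function(n, len, family, divergence, seed, k = 12) {
  mono <- read_monomer_fasta(satscreen_extdata("satellite_monomers.fasta"))
  fams <- vapply(mono, `[[`, character(1), "family_name")
  arr <- expand_array(mono[[which(fams == family)[1]]],
                      n_units = ceiling(len * 20 / nchar(mono[[which(fams == family)[1]]]$sequence)),
                      divergence = divergence, seed = seed)
  set.seed(seed + 1)
  starts <- sample.int(nchar(arr$sequence) - len + 1L, n, replace = TRUE)
  substring(arr$sequence, starts, starts + len - 1L)
}
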