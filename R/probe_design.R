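# k-mer-frequency probe design: count k-mer frequencies across satellite
# arrays, rank them, and greedily merge the most frequent k-mers into a
# hybridization oligonucleotide. The published MaSat probe (derived with
# this strategy from WGS satellite arrays) and the DYZ1 probe are shipped
# as fixtures for validation.

#' Count k-mer frequencies across tandem arrays
#'
#' Slides a linear k-window over the forward strand of every array and
#' tallies occurrences. Counting is forward-strand only: a hybridization
#' probe is a single-stranded oligo, so strand closure belongs to the family
#' signature (see [build_family_model()]), not to the frequency table.
#'
#' @param arrays A `tandem_array`, a DNA string, or a list mixing either.
#' @param k Window length; must not exceed the length of any array.
#' @return Object of class `kmer_freq_table`: fields `k`, `counts` (named
#'   integer vector), `total_windows` (`sum(counts)` = sum of `L_i - k + 1`).
#' @examples
#' count_kmers("ATTCCATTCC", k = 5)
#' @export
count_kmers <- function(arrays, k) {
  if (!is.list(arrays) || inherits(arrays, "tandem_array")) arrays <- list(arrays)
  if (length(arrays) == 0L) stop("arrays must be non-empty", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1", call. = FALSE)
  seqs <- vapply(arrays, array_sequence, character(1L))
  lens <- nchar(seqs)
  if (any(lens < k)) {
    i <- which(lens < k)[1L]
    lab <- if (inherits(arrays[[i]], "tandem_array") && !is.na(arrays[[i]]$family_name)) {
      arrays[[i]]$family_name
    } else {
      paste0("#", i)
    }
    stop(sprintf("k = %d exceeds the length (%d) of array %s", k, lens[i], lab),
         call. = FALSE)
  }
  wins <- unlist(lapply(seqs, linear_kmers, k = k), use.names = FALSE)
  tab <- table(wins)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  structure(
    list(k = k, counts = counts, total_windows = sum(counts)),
    class = "kmer_freq_table"
  )
}

#' @export
print.kmer_freq_table <- function(x, ...) {
  cat(sprintf("<kmer_freq_table> k=%d, %d distinct k-mers over %d windows\n",
              x$k, length(x$counts), x$total_windows))
  invisible(x)
}

#' Most frequent k-mers of a frequency table
#'
#' Deterministic ranking: count descending, ties broken lexicographically
#' ascending. If `n` exceeds the number of distinct k-mers, all are returned
#' with a warning.
#'
#' @param table A `kmer_freq_table` from [count_kmers()].
#' @param n Number of top k-mers requested.
#' @return Character vector of k-mers in rank order.
#' @export
top_kmers <- function(table, n) {
  stopifnot(inherits(table, "kmer_freq_table"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be an integer >= 1", call. = FALSE)
  km <- names(table$counts)
  ord <- order(-table$counts, km, method = "radix")
  ranked <- km[ord]
  if (n > length(ranked)) {
    warning(sprintf("requested %d k-mers but only %d are distinct; returning all",
                    n, length(ranked)))
    n <- length(ranked)
  }
  ranked[seq_len(n)]
}

#' Export a k-mer frequency table as TSV
#'
#' Columns `kmer`, `count`, rows in [top_kmers()] order.
#'
#' @param table A `kmer_freq_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  ranked <- top_kmers(table, length(table$counts))
  df <- data.frame(kmer = ranked, count = as.integer(table$counts[ranked]),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_probe_sequence <- function(sequence, source_kmers, target_length) {
  structure(
    list(sequence = sequence, source_kmers = source_kmers,
         target_length = as.integer(target_length)),
    class = "probe_sequence"
  )
}

#' @export
print.probe_sequence <- function(x, ...) {
  cat(sprintf("<probe_sequence> %d nt (target %d, %d source k-mers): %s\n",
              nchar(x$sequence), x$target_length,
              length(x$source_kmers), x$sequence))
  invisible(x)
}

# largest o such that the last o bases of `probe` equal the first o of `kmer`
max_overlap <- function(probe, kmer) {
  kl <- nchar(kmer)
  pl <- nchar(probe)
  for (o in seq.int(min(kl, pl), 0L)) {
    if (o == 0L) return(0L)
    if (substr(probe, pl - o + 1L, pl) == substr(kmer, 1L, o)) return(o)
  }
  0L
}

#' Assemble ranked k-mers into a probe oligonucleotide
#'
#' Greedy maximal-overlap merge: start from the highest-ranked k-mer and
#' repeatedly append, among the remaining k-mers, the one whose prefix has
#' the largest overlap with the current probe suffix (ties favour the
#' higher-ranked k-mer), stopping as soon as the best append would exceed
#' `target_length`. Every merged k-mer is a substring of the result and the
#' first-ranked k-mer is its prefix.
#'
#' @param kmers Character vector of equal-length k-mers in rank order
#'   (e.g. from [top_kmers()]).
#' @param target_length Maximum probe length; default 25 nt, bracketing the
#'   23-nt published MaSat probe.
#' @return A `probe_sequence`.
#' @examples
#' assemble_probe(c("ATTCC", "TTCCA", "TCCAT"), target_length = 7)$sequence
#' @export
assemble_probe <- function(kmers, target_length = 25L) {
  assert_dna(kmers, "kmers")
  k <- unique(nchar(kmers))
  if (length(k) != 1L) stop("k-mers must share one length", call. = FALSE)
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < k) {
    stop(sprintf("target_length (%s) is below k = %d: no k-mer fits",
                 target_length, k), call. = FALSE)
  }
  probe <- kmers[1L]
  used <- kmers[1L]
  remaining <- kmers[-1L]
  while (length(remaining) > 0L) {
    ovl <- vapply(remaining, max_overlap, integer(1L), probe = probe)
    best <- which.max(ovl)  # first max = highest rank on ties
    ext <- k - ovl[best]
    if (nchar(probe) + ext > target_length) break
    probe <- paste0(probe, substr(remaining[best], ovl[best] + 1L, k))
    used <- c(used, remaining[best])
    remaining <- remaining[-best]
  }
  new_probe_sequence(probe, used, target_length)
}

#' Score a probe against a repeat-family signature
#'
#' Coverage is the fraction of the probe's k-length windows present in the
#' family k-mer signature; because the signature is closed under reverse
#' complement, either strand of the repeat is matched. The probe matches the
#' family when coverage reaches `min_fraction`.
#'
#' @param probe A `probe_sequence` or DNA string; must be at least `model$k`
#'   long.
#' @param model A `repeat_family_model`.
#' @param min_fraction Minimum coverage to call a match (default 0.8).
#' @return List with `matches` (logical) and `coverage` (numeric in
#'   `[0, 1]`).
#' @examples
#' mod <- build_family_model(repeat_monomer("attcc", "ATTCC", "HS2/HS3"), k = 5)
#' probe_matches_family(dyz1_probe(), mod)
#' @export
probe_matches_family <- function(probe, model, min_fraction = 0.8) {
  stopifnot(inherits(model, "repeat_family_model"))
  seq <- if (inherits(probe, "probe_sequence")) probe$sequence else {
    assert_dna(toupper(probe), "probe")
    toupper(probe)
  }
  if (nchar(seq) < model$k) {
    stop("probe is shorter than the model k-mer length", call. = FALSE)
  }
  wins <- linear_kmers(seq, model$k)
  coverage <- mean(wins %chin% model$kmer_signature)
  list(matches = coverage >= min_fraction, coverage = coverage)
}

read_probe_fasta <- function(path, id) {
  seqs <- Biostrings::readDNAStringSet(path)
  hit <- grepl(id, names(seqs), fixed = TRUE)
  if (!any(hit)) stop("probe '", id, "' not found in ", path, call. = FALSE)
  as.character(seqs[[which(hit)[1L]]])
}

#' Published satellite probes shipped as fixtures
#'
#' `dyz1_probe()` returns the 48-nt human DYZ1 oligonucleotide (tandem
#' ATTCC/TCCAT repeat, used as a pan-HS2/HS3 detection probe);
#' `masat_probe()` returns the 23-nt mouse MaSat oligonucleotide that was
#' originally derived by the 12-mer frequency strategy implemented in this
#' package. Both are stored verbatim in `extdata/probes.fasta` as regression
#' fixtures — the genomic arrays the MaSat probe was derived from are not
#' redistributed, so the probe is validated, not re-derived.
#'
#' @return A `probe_sequence`.
#' @export
dyz1_probe <- function() {
  s <- read_probe_fasta(satscreen_extdata("probes.fasta"), "DYZ1_probe")
  new_probe_sequence(s, character(0), nchar(s))
}

#' @rdname dyz1_probe
#' @export
masat_probe <- function() {
  s <- read_probe_fasta(satscreen_extdata("probes.fasta"), "MaSat_probe")
  new_probe_sequence(s, character(0), nchar(s))
}

#' Design a probe from satellite arrays
#'
#' Convenience composition of [count_kmers()], [top_kmers()] and
#' [assemble_probe()]: the full probe-design strategy in one call.
#'
#' @param arrays Arrays accepted by [count_kmers()].
#' @param k k-mer length (default 12).
#' @param top_n Number of ranked k-mers offered to the assembler (default 8).
#' @param target_length Maximum probe length (default 25).
#' @return A `probe_sequence`.
#' @export
design_probe <- function(arrays, k = 12L, top_n = 8L, target_length = 25L) {
  tab <- count_kmers(arrays, k)
  assemble_probe(top_kmers(tab, top_n), target_length)
}
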