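# Satellite repeat families: monomers, circular k-mer signatures, and
# synthetic tandem arrays. HS2/HS3 is built on the ATTCC pentamer; mouse
# major satellite (MaSat) is modelled from the canonical GAAAAATGA unit.

#' Create a satellite repeat monomer
#'
#' A monomer is one repeat unit of a satellite family, e.g. the ATTCC
#' pentamer underlying human satellites HS2/HS3 or the GAAAAATGA unit from
#' which mouse major-satellite (MaSat) oligonucleotides derive.
#'
#' @param monomer_id Short identifier for the monomer.
#' @param sequence DNA string over A/C/G/T (lower case is uppercased);
#'   length at least 5. Ambiguity codes are rejected.
#' @param family_name Satellite family the monomer belongs to, e.g.
#'   `"HS2/HS3"` or `"MaSat"`.
#' @return An object of class `repeat_monomer`.
#' @examples
#' repeat_monomer("attcc", "ATTCC", "HS2/HS3")
#' @export
repeat_monomer <- function(monomer_id, sequence, family_name) {
  stopifnot(is.character(monomer_id), length(monomer_id) == 1L, nzchar(monomer_id),
            is.character(family_name), length(family_name) == 1L, nzchar(family_name))
  sequence <- toupper(sequence)
  assert_dna(sequence, "monomer sequence")
  if (length(sequence) != 1L || nchar(sequence) < 5L) {
    stop("monomer sequence must be a single string of length >= 5", call. = FALSE)
  }
  structure(
    list(monomer_id = monomer_id, sequence = sequence, family_name = family_name),
    class = "repeat_monomer"
  )
}

#' @export
print.repeat_monomer <- function(x, ...) {
  cat(sprintf("<repeat_monomer> %s | %s (%d bp): %s\n",
              x$family_name, x$monomer_id, nchar(x$sequence), x$sequence))
  invisible(x)
}

monomer_sequence <- function(x) {
  if (inherits(x, "repeat_monomer")) x$sequence else {
    assert_dna(toupper(x), "monomer sequence")
    toupper(x)
  }
}

#' Read satellite monomers from a FASTA reference
#'
#' Headers must follow the `">family|monomer_id"` convention used by the
#' shipped reference (`satscreen_extdata("satellite_monomers.fasta")`).
#'
#' @param path Path to a FASTA file.
#' @return A list of [repeat_monomer] objects.
#' @export
read_monomer_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no records in ", path, call. = FALSE)
  heads <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(heads) != 2L)) {
    stop("FASTA headers must be '>family|monomer_id': ",
         names(seqs)[lengths(heads) != 2L][1L], call. = FALSE)
  }
  lapply(seq_along(seqs), function(i) {
    repeat_monomer(monomer_id = heads[[i]][2L],
                   sequence = as.character(seqs[[i]]),
                   family_name = heads[[i]][1L])
  })
}

#' Reverse complement of DNA sequences
#'
#' Strict Watson-Crick reverse complement over the A/C/G/T alphabet;
#' vectorised, and an involution on every valid input.
#'
#' @param seq Character vector of non-empty A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATTCC")  # "GGAAT"
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq, "seq")
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1L))
}

#' Circular k-mers of a repeat monomer
#'
#' Enumerates every k-length window of the monomer read circularly, i.e. the
#' k-mers that occur in an unbounded tandem concatenation of the monomer
#' (junction-spanning windows included). The monomer is wrapped as many times
#' as needed, so any `k >= 1` is valid even when `k` exceeds the monomer
#' length; a monomer of length `m` with no internal period yields exactly
#' `m` distinct k-mers.
#'
#' @param monomer A [repeat_monomer] or a plain DNA string.
#' @param k Window length, integer `>= 1`.
#' @return Sorted character vector of distinct k-mers.
#' @examples
#' circular_kmers("ATTCC", 5)
#' @export
circular_kmers <- function(monomer, k) {
  seq <- monomer_sequence(monomer)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1", call. = FALSE)
  m <- nchar(seq)
  reps <- ceiling((m + k - 1L) / m)
  ext <- substr(strrep(seq, reps), 1L, m + k - 1L)
  starts <- seq_len(m)
  sort(unique(substring(ext, starts, starts + k - 1L)))
}

#' Build a repeat-family k-mer signature model
#'
#' The signature is the union, over all monomers of the family, of the
#' circular k-mers and their reverse complements; it is therefore closed
#' under reverse complement, and membership of a read window in the
#' signature tests either strand of the repeat.
#'
#' @param monomers A [repeat_monomer], or a list of them sharing one
#'   `family_name`.
#' @param k k-mer length; default 12, the length used for satellite probe
#'   design. Any `k >= 1` is accepted (see [circular_kmers()]).
#' @return An object of class `repeat_family_model` with fields
#'   `family_name`, `monomers`, `k` and `kmer_signature`.
#' @examples
#' m <- repeat_monomer("attcc", "ATTCC", "HS2/HS3")
#' build_family_model(m, k = 5)
#' @export
build_family_model <- function(monomers, k = 12L) {
  if (inherits(monomers, "repeat_monomer")) monomers <- list(monomers)
  if (!is.list(monomers) || length(monomers) == 0L ||
      !all(vapply(monomers, inherits, logical(1L), "repeat_monomer"))) {
    stop("monomers must be a non-empty list of repeat_monomer objects",
         call. = FALSE)
  }
  fams <- unique(vapply(monomers, `[[`, character(1L), "family_name"))
  if (length(fams) != 1L) {
    stop("monomers belong to different families: ",
         paste(fams, collapse = ", "), call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be an integer >= 1", call. = FALSE)
  fwd <- unique(unlist(lapply(monomers, circular_kmers, k = k)))
  sig <- sort(unique(c(fwd, reverse_complement(fwd))))
  structure(
    list(family_name = fams, monomers = monomers, k = k, kmer_signature = sig),
    class = "repeat_family_model"
  )
}

#' @export
print.repeat_family_model <- function(x, ...) {
  cat(sprintf("<repeat_family_model> %s: %d monomer(s), k=%d, %d signature k-mers\n",
              x$family_name, length(x$monomers), x$k, length(x$kmer_signature)))
  invisible(x)
}

#' Default satellite family models (HS2/HS3 and MaSat)
#'
#' Builds the two shipped families from the packaged monomer FASTA: HS2/HS3
#' from the ATTCC pentamer and MaSat from the canonical GAAAAATGA unit. The
#' declared order (HS2/HS3 first) is also the classification tie-break order.
#'
#' @param k k-mer length for the signatures (default 12).
#' @param path Monomer FASTA; defaults to the shipped reference.
#' @return Named list of `repeat_family_model` objects, in declared order.
#' @export
default_family_models <- function(k = 12L,
                                  path = satscreen_extdata("satellite_monomers.fasta")) {
  monomers <- read_monomer_fasta(path)
  fams <- vapply(monomers, `[[`, character(1L), "family_name")
  out <- lapply(unique(fams), function(f) {
    build_family_model(monomers[fams == f], k = k)
  })
  names(out) <- unique(fams)
  out
}

#' Export a family signature as TSV
#'
#' One row per signature k-mer, columns `family_name`, `k`, `kmer`; intended
#' for inspection and for oracle tests against independent enumeration.
#'
#' @param model A `repeat_family_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_family_model_tsv <- function(model, path) {
  stopifnot(inherits(model, "repeat_family_model"))
  df <- data.frame(family_name = model$family_name, k = model$k,
                   kmer = model$kmer_signature, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expand a monomer into a divergent tandem array
#'
#' Concatenates the monomer `n_units` times and then substitutes each base
#' independently with probability `divergence` to a uniformly chosen
#' different base (no indels). Deterministic for a given `seed`. This is the
#' package's synthetic stand-in for genomic satellite arrays.
#'
#' @param monomer A [repeat_monomer] or DNA string.
#' @param n_units Number of tandem copies, `>= 1`.
#' @param divergence Per-base substitution rate in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return An object of class `tandem_array` with fields `family_name`,
#'   `sequence`, `n_units`, `divergence`, `seed`, `monomer_length`.
#' @examples
#' expand_array(repeat_monomer("attcc", "ATTCC", "HS2/HS3"), 3, 0)$sequence
#' @export
expand_array <- function(monomer, n_units, divergence = 0, seed = 1L) {
  seq <- monomer_sequence(monomer)
  fam <- if (inherits(monomer, "repeat_monomer")) monomer$family_name else NA_character_
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1L) stop("n_units must be >= 1", call. = FALSE)
  if (!is.numeric(divergence) || divergence < 0 || divergence >= 1) {
    stop("divergence must be in [0, 1)", call. = FALSE)
  }
  base_seq <- strrep(seq, n_units)
  if (divergence > 0) {
    base_seq <- with_seed(seed, mutate_bases(base_seq, divergence))
  }
  structure(
    list(family_name = fam, sequence = base_seq, n_units = n_units,
         divergence = divergence, seed = as.integer(seed),
         monomer_length = nchar(seq)),
    class = "tandem_array"
  )
}

#' @export
print.tandem_array <- function(x, ...) {
  cat(sprintf("<tandem_array> %s: %d x %d bp units, divergence %.3g (%d bp)\n",
              x$family_name, x$n_units, x$monomer_length, x$divergence,
              nchar(x$sequence)))
  invisible(x)
}

array_sequence <- function(x) {
  if (inherits(x, "tandem_array")) x$sequence else {
    assert_dna(toupper(x), "array sequence")
    toupper(x)
  }
}
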