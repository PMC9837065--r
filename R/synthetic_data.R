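# Deterministic synthetic inputs: barcoded FASTQ with known cluster
# structure, marker content and spiked satellite fractions, plus a
# ground-truth table, so every pipeline stage is testable without
# controlled-access data.

#' Cluster labels and marker gene names of the emulated study design
#'
#' `default_cluster_labels()` returns the nine labels the generator
#' emulates: seven lung-fibroblast clusters (cluster 1 = myCAF-like,
#' cluster 6 = normal lung fibroblasts) plus alveolar and cancer cells.
#' `default_marker_genes()` maps each label to its marker gene names; the
#' fibroblast lists are the published cluster markers (CTHRC1/VCAN/... for
#' cluster 1, GPC3/MFAP4/... for cluster 6, etc.). Cluster 3 had no
#' detectable marker in the source study, and the alveolar/cancer marker
#' lists were not printed, so those three get clearly synthetic placeholder
#' names (SYN3*, SYNALV*, SYNTUM*). Marker *sequences* are always synthetic
#' (see [cluster_marker_reference()]); only the names are reused as labels.
#'
#' @return A character vector of labels, or a named list of gene-name
#'   vectors.
#' @export
default_cluster_labels <- function() {
  c("cluster1_myCAF", "cluster2", "cluster3", "cluster4", "cluster5",
    "cluster6_normal", "cluster7", "alveolar", "cancer")
}

#' @rdname default_cluster_labels
#' @export
default_marker_genes <- function() {
  list(
    cluster1_myCAF = c("CTHRC1", "VCAN", "SULF1", "COL10A1", "POSTN",
                       "SFRP4", "HTRA3", "ASPN"),
    cluster2 = c("COX4I2", "HIGD1B", "RGS5", "GJA4", "NDUFA4L2", "PDGFRB",
                 "COL4A1", "PTP4A3", "COL4A2", "LHFP", "PPP1R14A", "EGFL6",
                 "NOTCH3", "PTN", "COL18A1", "ACTG2"),
    cluster3 = c("SYN3A", "SYN3B"),
    cluster4 = c("PLA2G2A", "SFRP2"),
    cluster5 = c("MMP3", "SERPINE2"),
    cluster6_normal = c("GPC3", "MFAP4", "A2M", "CYR61", "MACF1", "GPX3",
                        "TIMP3", "CFD", "FIGF", "LTBP4", "SEPP1", "ADH1B",
                        "CTGF", "PTGDS", "SCN7A", "PRELP", "MAMDC2", "FHL1",
                        "DST", "AOC3", "INMT", "NPNT", "ELN", "USP53",
                        "G0S2", "FMO2"),
    cluster7 = c("ALDH1A3", "C3", "CCL2", "SOD2", "TNFRSF12A", "SLC20A1",
                 "NFKBIA", "PTX3", "DKK1", "SERPINB2"),
    alveolar = c("SYNALV1", "SYNALV2"),
    cancer = c("SYNTUM1", "SYNTUM2")
  )
}

#' Build a synthetic cluster marker reference
#'
#' Assigns a seeded random transcript sequence to every marker gene name of
#' every requested cluster. Every cluster is guaranteed at least one
#' marker.
#'
#' @param clusters Cluster labels; default all nine emulated labels.
#' @param genes Named list, cluster -> marker gene names; default
#'   [default_marker_genes()].
#' @param transcript_length Length of each synthetic marker transcript in
#'   bases (default 500).
#' @param seed RNG seed.
#' @return Object of class `cluster_marker_reference`: field `clusters`, a
#'   named list mapping each cluster to a named character vector
#'   (gene -> sequence).
#' @export
cluster_marker_reference <- function(clusters = default_cluster_labels(),
                                     genes = default_marker_genes(),
                                     transcript_length = 500L, seed = 1L) {
  missing <- setdiff(clusters, names(genes))
  if (length(missing)) {
    stop("no marker genes declared for cluster: ", missing[1L], call. = FALSE)
  }
  if (any(lengths(genes[clusters]) == 0L)) {
    stop("every cluster needs at least one marker gene", call. = FALSE)
  }
  ref <- with_seed(seed, {
    out <- lapply(clusters, function(cl) {
      g <- genes[[cl]]
      stats::setNames(random_dna(length(g), transcript_length), g)
    })
    names(out) <- clusters
    out
  })
  structure(list(clusters = ref), class = "cluster_marker_reference")
}

#' @export
print.cluster_marker_reference <- function(x, ...) {
  cat(sprintf("<cluster_marker_reference> %d clusters, %d marker transcripts\n",
              length(x$clusters), sum(lengths(x$clusters))))
  invisible(x)
}

#' Read/write a marker reference as FASTA
#'
#' Headers follow the `">cluster|gene"` convention.
#'
#' @param ref A `cluster_marker_reference` (for writing).
#' @param path FASTA path.
#' @return `read_marker_fasta()` returns a `cluster_marker_reference`;
#'   `write_marker_fasta()` returns `path` invisibly.
#' @export
write_marker_fasta <- function(ref, path) {
  stopifnot(inherits(ref, "cluster_marker_reference"))
  seqs <- unlist(ref$clusters, use.names = FALSE)
  heads <- unlist(lapply(names(ref$clusters), function(cl) {
    paste(cl, names(ref$clusters[[cl]]), sep = "|")
  }), use.names = FALSE)
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- heads
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_marker_fasta
#' @export
read_marker_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  heads <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(heads) != 2L)) {
    stop("marker FASTA headers must be '>cluster|gene'", call. = FALSE)
  }
  cl <- vapply(heads, `[[`, character(1L), 1L)
  gene <- vapply(heads, `[[`, character(1L), 2L)
  out <- lapply(split(seq_along(seqs), cl), function(i) {
    stats::setNames(as.character(seqs[i]), gene[i])
  })
  structure(list(clusters = out), class = "cluster_marker_reference")
}

#' Configuration of the read simulator
#'
#' Defaults emulate the study contrast behind the per-cluster satellite TPM
#' comparison: five clusters of 10 cells x 200 reads, with satellite read
#' fractions spanning 0 (cancer cells) to 5% (myCAF-like fibroblasts) —
#' myCAFs transcribing satellites severalfold above other fibroblast
#' subpopulations and far above cancer cells.
#'
#' @param n_cells_per_cluster Named integer vector, cluster -> cell count.
#' @param reads_per_cell Reads per cell (default 200).
#' @param satellite_fraction Named numeric vector, cluster -> satellite read
#'   fraction in `[0, 1]`; names must match `n_cells_per_cluster`.
#' @param satellite_family Family spiked into satellite reads (default
#'   `"HS2/HS3"`; must exist in the monomer reference).
#' @param marker_fraction Fraction of reads drawn from the cluster's marker
#'   transcripts (default 0.1); `satellite_fraction + marker_fraction <= 1`.
#' @param background_n_transcripts Number of shared synthetic background
#'   transcripts (default 20).
#' @param background_length,marker_length Transcript lengths in bases
#'   (defaults 1000 and 500).
#' @param read_length cDNA read length (default 90 nt, giving 79
#'   twelve-mer windows per read).
#' @param bc_len,umi_len Barcode and UMI lengths (defaults 16 and 10).
#' @param error_rate Per-base sequencing substitution rate (default 0.005).
#' @param divergence Satellite array per-base divergence (default 0.02,
#'   placing the expected read window coverage
#'   `(1 - divergence - error_rate)^k` near 0.74 at `k = 12` — well inside
#'   the classifier's operating range at `tau = 0.5` while still producing
#'   strictly partial coverage).
#' @param low_quality_fraction Fraction of reads emitted with mean quality
#'   Q10 (below the pipeline's Q20 filter); default 0.
#' @param monomers Monomer FASTA path.
#' @param seed Master RNG seed (required for reproducibility).
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(
    n_cells_per_cluster = c(cluster1_myCAF = 10L, cluster2 = 10L,
                            cluster5 = 10L, cluster6_normal = 10L,
                            cancer = 10L),
    reads_per_cell = 200L,
    satellite_fraction = c(cluster1_myCAF = 0.05, cluster2 = 0.005,
                           cluster5 = 0.01, cluster6_normal = 0.02,
                           cancer = 0),
    satellite_family = "HS2/HS3",
    marker_fraction = 0.1,
    background_n_transcripts = 20L,
    background_length = 1000L,
    marker_length = 500L,
    read_length = 90L,
    bc_len = 16L,
    umi_len = 10L,
    error_rate = 0.005,
    divergence = 0.02,
    low_quality_fraction = 0,
    monomers = satscreen_extdata("satellite_monomers.fasta"),
    seed = 1L) {
  clusters <- names(n_cells_per_cluster)
  if (is.null(clusters) || any(!nzchar(clusters))) {
    stop("n_cells_per_cluster must be named by cluster", call. = FALSE)
  }
  if (!setequal(clusters, names(satellite_fraction))) {
    stop("satellite_fraction names must match n_cells_per_cluster",
         call. = FALSE)
  }
  satellite_fraction <- satellite_fraction[clusters]
  if (any(n_cells_per_cluster < 1L) || reads_per_cell < 1L ||
      background_n_transcripts < 1L) {
    stop("all counts must be positive", call. = FALSE)
  }
  if (any(satellite_fraction < 0 | satellite_fraction > 1) ||
      marker_fraction < 0 || marker_fraction > 1 ||
      low_quality_fraction < 0 || low_quality_fraction > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(satellite_fraction + marker_fraction > 1)) {
    stop("satellite_fraction + marker_fraction exceeds 1 for cluster: ",
         clusters[which(satellite_fraction + marker_fraction > 1)[1L]],
         call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1 || divergence < 0 || divergence >= 1) {
    stop("error_rate and divergence must lie in [0, 1)", call. = FALSE)
  }
  if (read_length < 1L || bc_len < 1L || umi_len < 1L) {
    stop("read_length, bc_len and umi_len must be positive", call. = FALSE)
  }
  if (read_length > marker_length || read_length > background_length) {
    stop("read_length must not exceed marker or background transcript length",
         call. = FALSE)
  }
  structure(
    list(n_cells_per_cluster = as.integer(n_cells_per_cluster) |>
           stats::setNames(clusters),
         reads_per_cell = as.integer(reads_per_cell),
         satellite_fraction = satellite_fraction,
         satellite_family = satellite_family,
         marker_fraction = marker_fraction,
         background_n_transcripts = as.integer(background_n_transcripts),
         background_length = as.integer(background_length),
         marker_length = as.integer(marker_length),
         read_length = as.integer(read_length),
         bc_len = as.integer(bc_len), umi_len = as.integer(umi_len),
         error_rate = error_rate, divergence = divergence,
         low_quality_fraction = low_quality_fraction,
         monomers = monomers, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

random_window <- function(seqs, pick, read_length) {
  starts <- floor(runif(length(pick)) * (nchar(seqs[pick]) - read_length)) + 1L
  substring(seqs[pick], starts, starts + read_length - 1L)
}

#' Simulate a barcoded single-cell satellite-screening run
#'
#' Draws, per cluster and cell, reads from a (satellite, marker,
#' background) mixture: satellite reads are random windows of a divergent
#' tandem array of the configured family, marker reads are windows of the
#' cluster's own synthetic marker transcripts, background reads are windows
#' of synthetic transcripts shared across clusters. Sequencing errors are
#' applied per base. Output is fully deterministic given `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param gzip Write gzipped FASTQ (default `FALSE`).
#' @return List of class `simulated_run`: file paths (`r1`, `r2`,
#'   `barcodes`, `markers_fasta`, `truth_reads`, `truth_summary`) plus the
#'   in-memory `truth_reads`/`truth_summary` data frames and the
#'   `cluster_marker_reference` used.
#' @export
simulate_reads <- function(config, out_dir, gzip = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  clusters <- names(config$n_cells_per_cluster)
  monomers <- read_monomer_fasta(config$monomers)
  fams <- vapply(monomers, `[[`, character(1L), "family_name")
  if (!config$satellite_family %in% fams) {
    stop("satellite_family not in monomer reference: ",
         config$satellite_family, call. = FALSE)
  }

  seeds <- derive_seeds(config$seed, 3L)
  genes <- default_marker_genes()
  novel <- setdiff(clusters, names(genes))
  genes[novel] <- lapply(novel, function(cl) {
    paste0("SYN_", toupper(gsub("[^A-Za-z0-9]", "", cl)), c("_M1", "_M2"))
  })
  markers <- cluster_marker_reference(
    clusters, genes = genes,
    transcript_length = config$marker_length, seed = seeds[1L])

  monomer <- monomers[[which(fams == config$satellite_family)[1L]]]
  n_units <- ceiling((config$read_length * 60L) / nchar(monomer$sequence))
  array <- expand_array(monomer, n_units, config$divergence, seed = seeds[2L])

  run <- with_seed(seeds[3L], {
    n_cells <- sum(config$n_cells_per_cluster)
    barcodes <- random_dna(n_cells, config$bc_len)
    while (anyDuplicated(barcodes)) {
      dup <- duplicated(barcodes)
      barcodes[dup] <- random_dna(sum(dup), config$bc_len)
    }
    cell_cluster <- rep(clusters, config$n_cells_per_cluster)

    bg <- random_dna(config$background_n_transcripts, config$background_length)
    bg_names <- sprintf("bg_%03d", seq_along(bg))

    n_reads <- n_cells * config$reads_per_cell
    read_cell <- rep(seq_len(n_cells), each = config$reads_per_cell)
    read_cluster <- cell_cluster[read_cell]

    f_sat <- config$satellite_fraction[read_cluster]
    u <- runif(n_reads)
    src <- ifelse(u < f_sat, "satellite",
                  ifelse(u < f_sat + config$marker_fraction, "marker",
                         "background"))

    cdna <- character(n_reads)
    source_label <- character(n_reads)

    is_sat <- src == "satellite"
    if (any(is_sat)) {
      pick <- rep(1L, sum(is_sat))
      cdna[is_sat] <- random_window(array$sequence, pick, config$read_length)
      source_label[is_sat] <- paste0("satellite:", config$satellite_family)
    }
    is_mk <- src == "marker"
    if (any(is_mk)) {
      idx <- which(is_mk)
      for (cl in clusters) {
        i <- idx[read_cluster[idx] == cl]
        if (!length(i)) next
        genes <- markers$clusters[[cl]]
        g <- sample.int(length(genes), length(i), replace = TRUE)
        cdna[i] <- random_window(unname(genes), g, config$read_length)
        source_label[i] <- paste0("marker:", names(genes)[g])
      }
    }
    is_bg <- src == "background"
    if (any(is_bg)) {
      t <- sample.int(length(bg), sum(is_bg), replace = TRUE)
      cdna[is_bg] <- random_window(bg, t, config$read_length)
      source_label[is_bg] <- BACKGROUND_FEATURE
    }
    if (config$error_rate > 0) cdna <- mutate_bases(cdna, config$error_rate)

    umi <- random_dna(n_reads, config$umi_len)
    lowq <- runif(n_reads) < config$low_quality_fraction
    read_id <- sprintf("read_%07d", seq_len(n_reads))

    list(barcodes = barcodes, cell_cluster = cell_cluster,
         read_cell = read_cell, read_cluster = read_cluster,
         cdna = cdna, source_label = source_label, umi = umi,
         lowq = lowq, read_id = read_id)
  })

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  paths <- list(r1 = file.path(out_dir, paste0("reads_R1", ext)),
                r2 = file.path(out_dir, paste0("reads_R2", ext)),
                barcodes = file.path(out_dir, "barcodes.tsv"),
                markers_fasta = file.path(out_dir, "markers.fasta"),
                truth_reads = file.path(out_dir, "truth_reads.tsv"),
                truth_summary = file.path(out_dir, "truth_summary.tsv"))

  bc_of_read <- run$barcodes[run$read_cell]
  r1_seq <- paste0(bc_of_read, run$umi)
  q_hi <- strrep("I", config$read_length)           # Q40
  q_lo <- strrep("+", config$read_length)           # Q10, below the Q20 gate
  r2_qual <- ifelse(run$lowq, q_lo, q_hi)
  r1_qual <- strrep("I", config$bc_len + config$umi_len)

  write_fastq <- function(seqs, quals, ids, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(Biostrings::BStringSet(quals)))
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path, compress = gzip)
  }
  write_fastq(r1_seq, rep(r1_qual, length(r1_seq)), run$read_id, paths$r1)
  write_fastq(run$cdna, r2_qual, run$read_id, paths$r2)

  bc_map <- data.frame(barcode = run$barcodes, cluster = run$cell_cluster,
                       stringsAsFactors = FALSE)
  write.table(bc_map, paths$barcodes, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_marker_fasta(markers, paths$markers_fasta)

  truth_reads <- data.frame(read_id = run$read_id, barcode = bc_of_read,
                            cluster = run$read_cluster,
                            source = run$source_label, umi = run$umi,
                            low_quality = run$lowq, stringsAsFactors = FALSE)
  agg <- as.data.table(truth_reads)[, list(
    n_reads = .N,
    n_satellite = sum(startsWith(source, "satellite:"))), by = "cluster"]
  agg[, "true_fraction" := agg$n_satellite / agg$n_reads]
  setorder(agg, cluster)
  truth_summary <- as.data.frame(agg)
  write.table(truth_reads, paths$truth_reads, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth_summary, paths$truth_summary, sep = "\t", quote = FALSE,
              row.names = FALSE)

  structure(
    c(paths, list(truth_reads_df = truth_reads,
                  truth_summary_df = truth_summary,
                  markers = markers, config = config)),
    class = "simulated_run"
  )
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf("<simulated_run> %d reads over %d clusters (seed %d)\n",
              nrow(x$truth_reads_df),
              length(unique(x$truth_summary_df$cluster)), x$config$seed))
  invisible(x)
}

#' Screen configuration matching a simulated run
#'
#' Points [screen_config()] at the files written by [simulate_reads()].
#'
#' @param run A `simulated_run`.
#' @param ... Overrides passed on to [screen_config()].
#' @return A `screen_config`.
#' @export
screen_config_for_run <- function(run, ...) {
  stopifnot(inherits(run, "simulated_run"))
  screen_config(r1 = run$r1, r2 = run$r2, barcodes = run$barcodes,
                monomers = run$config$monomers, markers = run$markers_fasta,
                umi_len = run$config$umi_len, ...)
}
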