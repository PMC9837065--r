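# The screening pipeline: demultiplex barcoded read pairs into annotated
# cell clusters, verify marker expression per cluster, classify cDNA reads
# against satellite family signatures by k-mer window coverage, collapse
# UMIs, and report per-cluster expression as TPM.

BACKGROUND_FEATURE <- "background"

#' Load a barcode-to-cluster map
#'
#' Reads a TSV with header `barcode<TAB>cluster`. All barcodes must share
#' one length; duplicate rows with the same label are deduplicated (with a
#' message), duplicates with conflicting labels are an error.
#'
#' @param path TSV path.
#' @param labels Optional declared label set; rows with labels outside it
#'   are an error.
#' @return Object of class `barcode_cluster_map`: `entries` (named character
#'   vector barcode -> cluster), `bc_len`, `clusters`.
#' @export
load_barcode_map <- function(path, labels = NULL) {
  lines <- readLines(path)
  if (length(lines) < 1L || !identical(strsplit(lines[1L], "\t")[[1L]],
                                       c("barcode", "cluster"))) {
    stop("expected header 'barcode<TAB>cluster' in ", path, call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L | vapply(parts, function(p) any(!nzchar(p)), logical(1L)))
  if (length(bad)) {
    stop(sprintf("malformed row at line %d of %s", bad[1L] + 1L, path), call. = FALSE)
  }
  bc <- vapply(parts, `[[`, character(1L), 1L)
  cl <- vapply(parts, `[[`, character(1L), 2L)
  if (length(unique(nchar(bc))) > 1L) {
    stop("barcodes have differing lengths", call. = FALSE)
  }
  dup <- duplicated(bc)
  if (any(dup)) {
    conflict <- tapply(cl, bc, function(x) length(unique(x)) > 1L)
    if (any(conflict)) {
      stop("duplicate barcode with conflicting labels: ",
           names(conflict)[conflict][1L], call. = FALSE)
    }
    message(sum(dup), " duplicate barcode row(s) deduplicated")
    cl <- cl[!dup]
    bc <- bc[!dup]
  }
  if (!is.null(labels) && !all(cl %in% labels)) {
    stop("cluster label outside declared set: ",
         setdiff(cl, labels)[1L], call. = FALSE)
  }
  entries <- cl
  names(entries) <- bc
  structure(
    list(entries = entries, bc_len = nchar(bc[1L]),
         clusters = sort(unique(cl))),
    class = "barcode_cluster_map"
  )
}

#' @export
print.barcode_cluster_map <- function(x, ...) {
  cat(sprintf("<barcode_cluster_map> %d barcodes (%d nt) over %d clusters\n",
              length(x$entries), x$bc_len, length(x$clusters)))
  invisible(x)
}

read_fastq <- function(path) {
  # QualityScaledDNAStringSet construction warns about dropping the (empty)
  # mcols of the freshly parsed set; that is cosmetic here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  q <- as(Biostrings::quality(x), "IntegerList")
  list(id = sub("\\s.*$", "", names(x)),
       seq = as.character(x),
       mean_quality = as.numeric(sum(q) / lengths(q)))
}

#' Demultiplex barcoded read pairs into clusters
#'
#' R1 carries the cell barcode (first `bc_len` bases) followed by the UMI
#' (next `umi_len` bases); R2 is the cDNA read. Each pair is assigned to the
#' cluster of its barcode or counted unassigned (`cluster = NA`); barcodes
#' absent from the whitelist are never rescued. Total pairs are conserved:
#' `assigned + unassigned == total`.
#'
#' @param fastq_r1,fastq_r2 Paths to the paired FASTQ files (records in the
#'   same order; gzipped files are accepted).
#' @param map A [load_barcode_map()] result.
#' @param bc_len,umi_len Barcode and UMI lengths; `bc_len` defaults to the
#'   map's barcode length, `umi_len` to 10.
#' @return `data.frame` of annotated reads (`read_id`, `barcode`, `umi`,
#'   `cluster`, `cdna`, `mean_quality`) with a `counts` attribute
#'   (`total`, `assigned`, `unassigned`).
#' @export
demultiplex <- function(fastq_r1, fastq_r2, map, bc_len = map$bc_len,
                        umi_len = 10L) {
  stopifnot(inherits(map, "barcode_cluster_map"))
  r1 <- read_fastq(fastq_r1)
  r2 <- read_fastq(fastq_r2)
  if (length(r1$seq) != length(r2$seq)) {
    stop(sprintf("R1/R2 record counts differ (%d vs %d)",
                 length(r1$seq), length(r2$seq)), call. = FALSE)
  }
  if (any(nchar(r1$seq) < bc_len + umi_len)) {
    stop("R1 record shorter than bc_len + umi_len", call. = FALSE)
  }
  if (any(!nzchar(r2$seq))) stop("empty cDNA read in R2", call. = FALSE)
  barcode <- substr(r1$seq, 1L, bc_len)
  umi <- substr(r1$seq, bc_len + 1L, bc_len + umi_len)
  cluster <- unname(map$entries[barcode])
  out <- data.frame(read_id = r2$id, barcode = barcode, umi = umi,
                    cluster = cluster, cdna = r2$seq,
                    mean_quality = r2$mean_quality,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(total = nrow(out),
                           assigned = sum(!is.na(cluster)),
                           unassigned = sum(is.na(cluster)))
  out
}

marker_kmer_sets <- function(markers, k) {
  lapply(markers$clusters, function(genes) {
    lapply(genes, function(s) unique(linear_kmers(s, k)))
  })
}

# per-read best marker gene (most shared k-mers, >= 1) among the genes of
# the read's own cluster; ties resolve to the lexicographically first gene
match_markers <- function(cdna, cluster, gene_sets) {
  k <- attr(gene_sets, "k")
  out <- rep(NA_character_, length(cdna))
  if (length(cdna) == 0L) return(out)
  for (cl in unique(cluster)) {
    sel <- which(cluster == cl)
    genes <- gene_sets[[cl]]
    if (is.null(genes) || length(genes) == 0L) next
    genes <- genes[order(names(genes))]
    w <- nchar(cdna[sel]) - k + 1L
    ok <- w >= 1L
    if (!any(ok)) next
    idx <- sel[ok]
    rd <- rep(seq_along(idx), w[ok])
    starts <- sequence(w[ok])
    wins <- substring(cdna[idx][rd], starts, starts + k - 1L)
    score <- matrix(0L, nrow = length(idx), ncol = length(genes))
    for (g in seq_along(genes)) {
      score[, g] <- tabulate(rd[wins %chin% genes[[g]]], nbins = length(idx))
    }
    best <- max.col(score, ties.method = "first")
    has <- score[cbind(seq_along(idx), best)] > 0L
    out[idx[has]] <- names(genes)[best[has]]
  }
  out
}

#' Verify marker-gene expression per cluster
#'
#' A read supports a marker when it shares at least one k-mer with that
#' marker's transcript (exact k-mer seed match against the cluster's own
#' markers). A cluster passes when at least `min_marker_reads` of its reads
#' support any of its markers.
#'
#' @param reads Annotated reads from [demultiplex()] (unassigned reads are
#'   ignored).
#' @param markers A [cluster_marker_reference()].
#' @param min_marker_reads Pass threshold (default 10 reads).
#' @param k Seed k-mer length (default 12, the classification k).
#' @param clusters Clusters to report on; defaults to those present in
#'   `reads`. A listed cluster with no reads fails with count 0.
#' @return List with `summary` (`cluster`, `n_marker_reads`, `pass`) and
#'   `report` (`cluster`, `marker`, `n_reads`).
#' @export
verify_cluster_markers <- function(reads, markers, min_marker_reads = 10L,
                                   k = 12L, clusters = NULL) {
  stopifnot(inherits(markers, "cluster_marker_reference"))
  assigned <- reads[!is.na(reads$cluster), , drop = FALSE]
  clusters <- sort(unique(c(assigned$cluster, clusters)))
  missing <- setdiff(clusters, names(markers$clusters))
  if (length(missing)) {
    stop("no markers declared for cluster: ", missing[1L], call. = FALSE)
  }
  gene_sets <- marker_kmer_sets(markers, k)
  attr(gene_sets, "k") <- as.integer(k)
  gene <- match_markers(assigned$cdna, assigned$cluster, gene_sets)
  report <- rbindlist(lapply(clusters, function(cl) {
    genes <- sort(names(markers$clusters[[cl]]))
    n <- vapply(genes, function(g) {
      sum(assigned$cluster == cl & !is.na(gene) & gene == g)
    }, integer(1L))
    data.table(cluster = cl, marker = genes, n_reads = n)
  }))
  summary <- report[, list(n_marker_reads = sum(n_reads)), by = "cluster"]
  summary[, "pass" := summary$n_marker_reads >= min_marker_reads]
  list(summary = as.data.frame(summary), report = as.data.frame(report))
}

#' Classify reads against satellite family signatures
#'
#' For each read and family, coverage is the fraction of the read's
#' k-length windows present in that family's k-mer signature (either
#' strand, via signature closure). The read is assigned to the family with
#' maximal coverage when that coverage reaches `tau`; exact coverage ties
#' are broken by the declared model order. Reads shorter than `k` are not
#' classified and are counted separately.
#'
#' @param reads Character vector of cDNA sequences, or a [demultiplex()]
#'   data frame (column `cdna`).
#' @param models List of `repeat_family_model`s sharing one `k`, in
#'   declared (tie-break) order.
#' @param tau Coverage threshold in `[0, 1]` (default 0.5).
#' @return `data.frame` (`read_idx`, `family`, `coverage`): one row per
#'   classified read; `family` is `NA` for reads below `tau`. Attribute
#'   `n_too_short` counts reads shorter than `k`.
#' @export
classify_reads <- function(reads, models, tau = 0.5) {
  if (is.data.frame(reads)) reads <- reads$cdna
  if (inherits(models, "repeat_family_model")) models <- list(models)
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1L), "repeat_family_model")))
  ks <- unique(vapply(models, `[[`, integer(1L), "k"))
  if (length(ks) != 1L) stop("models must share one k", call. = FALSE)
  k <- ks
  n <- length(reads)
  fams <- vapply(models, `[[`, character(1L), "family_name")
  out <- data.frame(read_idx = seq_len(n), family = NA_character_,
                    coverage = NA_real_, stringsAsFactors = FALSE)
  lens <- nchar(reads)
  ok <- lens >= k
  attr(out, "n_too_short") <- sum(!ok)
  if (!any(ok)) return(out)
  idx <- which(ok)
  w <- lens[idx] - k + 1L
  rd <- rep(seq_along(idx), w)
  starts <- sequence(w)
  wins <- substring(reads[idx][rd], starts, starts + k - 1L)
  cov <- matrix(0, nrow = length(idx), ncol = length(models))
  for (m in seq_along(models)) {
    hit <- wins %chin% models[[m]]$kmer_signature
    cov[, m] <- tabulate(rd[hit], nbins = length(idx)) / w
  }
  best <- max.col(cov, ties.method = "first")  # declared order on ties
  bestcov <- cov[cbind(seq_along(idx), best)]
  pass <- bestcov >= tau
  out$coverage[idx] <- bestcov
  out$family[idx[pass]] <- fams[best[pass]]
  out
}

#' Classify a single read
#'
#' Single-read wrapper around [classify_reads()].
#'
#' @inheritParams classify_reads
#' @param read One cDNA sequence.
#' @return A list (`family`, `coverage`) when the read reaches `tau`,
#'   otherwise `NULL`.
#' @export
classify_read <- function(read, models, tau = 0.5) {
  res <- classify_reads(read, models, tau)
  if (is.na(res$family[1L])) return(NULL)
  list(family = res$family[1L], coverage = res$coverage[1L])
}

#' Collapse UMIs into molecule counts
#'
#' Counts distinct `(barcode, umi)` pairs per `(cluster, feature)` —
#' exact-match UMI collapse, the droplet counting convention. With
#' `use_umi = FALSE` raw read counts are returned instead.
#'
#' @param assignments `data.frame` with columns `cluster`, `feature`,
#'   `barcode`, `umi`.
#' @param use_umi Collapse duplicates (default) or count reads.
#' @return `data.frame` (`cluster`, `feature`, `umi_count`).
#' @export
dedup_umis <- function(assignments, use_umi = TRUE) {
  stopifnot(all(c("cluster", "feature", "barcode", "umi") %in% names(assignments)))
  dt <- as.data.table(assignments)
  counts <- if (use_umi) {
    dt[, list(umi_count = uniqueN(paste(barcode, umi, sep = "\r"))),
       by = c("cluster", "feature")]
  } else {
    dt[, list(umi_count = .N), by = c("cluster", "feature")]
  }
  setorder(counts, cluster, feature)
  as.data.frame(counts)
}

#' Per-cluster TPM quantification
#'
#' Within each cluster, each feature's length-normalised rate is
#' `count / effective_length_kb`, and TPM is `1e6 * rate / sum(rates)` over
#' that cluster's features, so TPM sums to one million per non-empty
#' cluster. Features listed in `feature_universe` but never counted get
#' TPM 0; clusters with zero total counts get an all-zero row set and are
#' flagged in the `zero_clusters` attribute.
#'
#' @param umi_counts `data.frame` (`cluster`, `feature`, `umi_count`) from
#'   [dedup_umis()].
#' @param feature_lengths Named numeric vector of effective lengths in kb;
#'   every counted feature must be present.
#' @param feature_universe Optional named list, cluster -> character vector
#'   of features to report (zero-filled when uncounted).
#' @return `data.frame` of class `cluster_expression_table` with columns
#'   `cluster`, `feature`, `umi_count`, `effective_length_kb`, `tpm`.
#' @examples
#' quantify_tpm(data.frame(cluster = "c1", feature = c("a", "b"),
#'                         umi_count = c(10L, 10L)),
#'              c(a = 1, b = 2))
#' @export
quantify_tpm <- function(umi_counts, feature_lengths, feature_universe = NULL) {
  stopifnot(all(c("cluster", "feature", "umi_count") %in% names(umi_counts)))
  if (any(umi_counts$umi_count < 0)) stop("negative counts", call. = FALSE)
  dt <- as.data.table(umi_counts)[, c("cluster", "feature", "umi_count"), with = FALSE]
  if (!is.null(feature_universe)) {
    full <- rbindlist(lapply(names(feature_universe), function(cl) {
      data.table(cluster = cl, feature = feature_universe[[cl]])
    }))
    dt <- merge(full, dt, by = c("cluster", "feature"), all.x = TRUE)
    dt[is.na(dt$umi_count), "umi_count" := 0L]
  }
  miss <- setdiff(unique(dt$feature), names(feature_lengths))
  if (length(miss)) {
    stop("no effective length for feature: ", miss[1L], call. = FALSE)
  }
  if (any(feature_lengths[unique(dt$feature)] <= 0)) {
    stop("effective lengths must be > 0", call. = FALSE)
  }
  dt[, "effective_length_kb" := unname(feature_lengths[dt$feature])]
  dt[, "rate" := dt$umi_count / dt$effective_length_kb]
  dt[, "tpm" := {
    tot <- sum(rate)
    if (tot > 0) 1e6 * rate / tot else rep(0, .N)
  }, by = "cluster"]
  zero <- dt[, list(tot = sum(umi_count)), by = "cluster"]
  zero_clusters <- zero$cluster[zero$tot == 0L]
  dt[, "rate" := NULL]
  setorder(dt, cluster, feature)
  out <- as.data.frame(dt)
  attr(out, "zero_clusters") <- zero_clusters
  class(out) <- c("cluster_expression_table", class(out))
  out
}

#' Write an expression table as TSV
#'
#' @param table A `cluster_expression_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  write.table(format(as.data.frame(table), digits = 15, scientific = FALSE,
                     trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Configuration for the screening pipeline
#'
#' @param r1,r2 Paired FASTQ paths (R1 barcode+UMI, R2 cDNA).
#' @param barcodes Barcode map TSV.
#' @param monomers Monomer FASTA (`">family|monomer_id"`); defaults to the
#'   shipped satellite reference.
#' @param markers Marker FASTA (`">cluster|gene"`).
#' @param k Classification/marker k-mer length (default 12).
#' @param tau Satellite coverage threshold (default 0.5).
#' @param umi_len UMI length (default 10).
#' @param min_mean_quality Reads below this mean Phred quality are dropped
#'   before classification (default 20).
#' @param min_marker_reads Cluster marker-verification threshold
#'   (default 10).
#' @param satellite_length_kb Nominal effective transcript length for a
#'   satellite family, in kb (default 1; satellite transcripts have no
#'   defined gene model, and between-cluster TPM ratios are invariant to
#'   this constant when feature sets match).
#' @param background_length_kb Effective length of the pooled background
#'   feature (default 1).
#' @param use_umi Collapse UMIs (default) or count raw reads.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(r1, r2, barcodes,
                          monomers = satscreen_extdata("satellite_monomers.fasta"),
                          markers, k = 12L, tau = 0.5, umi_len = 10L,
                          min_mean_quality = 20, min_marker_reads = 10L,
                          satellite_length_kb = 1, background_length_kb = 1,
                          use_umi = TRUE) {
  stopifnot(tau >= 0, tau <= 1, satellite_length_kb > 0,
            background_length_kb > 0)
  structure(
    list(r1 = r1, r2 = r2, barcodes = barcodes, monomers = monomers,
         markers = markers, k = as.integer(k), tau = tau,
         umi_len = as.integer(umi_len), min_mean_quality = min_mean_quality,
         min_marker_reads = as.integer(min_marker_reads),
         satellite_length_kb = satellite_length_kb,
         background_length_kb = background_length_kb, use_umi = use_umi),
    class = "screen_config"
  )
}

#' Run the full satellite screening pipeline
#'
#' Composes [demultiplex()] (barcode demultiplexing), a mean-quality filter,
#' [verify_cluster_markers()] (clusters failing verification are excluded
#' from the expression table and listed in the report), [classify_reads()]
#' (satellite assignment), marker-gene assignment of the remaining reads,
#' [dedup_umis()] and [quantify_tpm()]. Reads matching neither a satellite
#' family nor a marker are pooled into a `"background"` feature so the TPM
#' denominator reflects the cluster's whole library.
#'
#' @param config A [screen_config()].
#' @return List of class `screen_result`: `expression`
#'   (`cluster_expression_table`), `marker_report`, `marker_summary`,
#'   `excluded_clusters`, and `log` (read-conservation counts and
#'   parameters).
#' @export
run_screen <- function(config) {
  stopifnot(inherits(config, "screen_config"))
  map <- load_barcode_map(config$barcodes)
  models <- default_family_models(k = config$k, path = config$monomers)
  markers <- read_marker_fasta(config$markers)

  reads <- demultiplex(config$r1, config$r2, map, umi_len = config$umi_len)
  counts <- attr(reads, "counts")
  assigned <- reads[!is.na(reads$cluster), , drop = FALSE]

  lowq <- assigned$mean_quality < config$min_mean_quality
  n_low_quality <- sum(lowq)
  assigned <- assigned[!lowq, , drop = FALSE]

  verif <- verify_cluster_markers(assigned, markers,
                                  min_marker_reads = config$min_marker_reads,
                                  k = config$k)
  excluded <- verif$summary$cluster[!verif$summary$pass]
  kept <- assigned[!(assigned$cluster %in% excluded), , drop = FALSE]

  cls <- classify_reads(kept$cdna, models, tau = config$tau)
  feature <- cls$family
  n_too_short <- attr(cls, "n_too_short")

  gene_sets <- marker_kmer_sets(markers, config$k)
  attr(gene_sets, "k") <- config$k
  rest <- is.na(feature) & nchar(kept$cdna) >= config$k
  if (any(rest)) {
    gene <- match_markers(kept$cdna[rest], kept$cluster[rest], gene_sets)
    feature[rest][!is.na(gene)] <- gene[!is.na(gene)]
  }
  feature[is.na(feature) & nchar(kept$cdna) >= config$k] <- BACKGROUND_FEATURE

  counted <- !is.na(feature)
  assignments <- data.frame(cluster = kept$cluster[counted],
                            feature = feature[counted],
                            barcode = kept$barcode[counted],
                            umi = kept$umi[counted],
                            stringsAsFactors = FALSE)
  umi_counts <- dedup_umis(assignments, use_umi = config$use_umi)

  fam_names <- names(models)
  marker_lengths <- unlist(lapply(markers$clusters, function(g)
    vapply(g, nchar, integer(1L)) / 1000), use.names = FALSE)
  names(marker_lengths) <- unlist(lapply(markers$clusters, names),
                                  use.names = FALSE)
  marker_lengths <- marker_lengths[!duplicated(names(marker_lengths))]
  feature_lengths <- c(
    stats::setNames(rep(config$satellite_length_kb, length(fam_names)), fam_names),
    marker_lengths,
    stats::setNames(config$background_length_kb, BACKGROUND_FEATURE)
  )
  present <- sort(unique(kept$cluster))
  feature_universe <- lapply(present, function(cl) {
    sort(unique(c(fam_names, names(markers$clusters[[cl]]), BACKGROUND_FEATURE)))
  })
  names(feature_universe) <- present

  expression <- quantify_tpm(umi_counts, feature_lengths, feature_universe)

  structure(
    list(expression = expression,
         marker_summary = verif$summary,
         marker_report = verif$report,
         excluded_clusters = excluded,
         log = list(total = unname(counts["total"]),
                    assigned = unname(counts["assigned"]),
                    unassigned = unname(counts["unassigned"]),
                    n_low_quality = n_low_quality,
                    n_too_short = n_too_short,
                    k = config$k, tau = config$tau,
                    use_umi = config$use_umi)),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d/%d reads assigned; %d cluster(s) excluded\n",
              x$log$assigned, x$log$total, length(x$excluded_clusters)))
  sat <- x$expression[x$expression$feature %in%
                        c("HS2/HS3", "MaSat"), , drop = FALSE]
  if (nrow(sat)) {
    cat("satellite TPM by cluster:\n")
    print(sat[, c("cluster", "feature", "umi_count", "tpm")], row.names = FALSE)
  }
  invisible(x)
}
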