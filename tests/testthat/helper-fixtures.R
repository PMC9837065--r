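# Fixture builders: tiny FASTQ/TSV files written with base R so that
# parsing tests do not share code with the package's Biostrings I/O.

write_raw_fastq <- function(path, ids, seqs, quals = strrep("I", nchar(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
}

write_raw_map <- function(path, barcodes, clusters) {
  writeLines(c("barcode\tcluster", paste(barcodes, clusters, sep = "\t")), path)
}

# small simulated run shared by screen tests (2 clusters, 5 cells, 20 reads)
small_sim_config <- function(seed = 42L, ...) {
  simulation_config(
    n_cells_per_cluster = c(cluster1_myCAF = 5L, cluster6_normal = 5L),
    reads_per_cell = 20L,
    satellite_fraction = c(cluster1_myCAF = 0.2, cluster6_normal = 0),
    marker_fraction = 0.2,
    seed = seed, ...)
}

attcc_model <- function(k = 5L) {
  build_family_model(repeat_monomer("attcc", "ATTCC", "HS2/HS3"), k = k)
}
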