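test_that("barcode maps load, deduplicate and reject conflicts", {
  path <- tempfile(fileext = ".tsv")
  write_raw_map(path, c("AAAA", "CCCC"), c("c1", "c2"))
  map <- load_barcode_map(path)
  expect_length(map$entries, 2L)
  expect_identical(map$bc_len, 4L)
  expect_identical(unname(map$entries["CCCC"]), "c2")

  write_raw_map(path, c("AAAA", "AAAA"), c("c1", "c1"))
  expect_message(map2 <- load_barcode_map(path), "deduplicated")
  expect_length(map2$entries, 1L)

  write_raw_map(path, c("AAAA", "AAAA"), c("c1", "c2"))
  expect_error(load_barcode_map(path), "conflicting labels")

  writeLines(c("barcode\tcluster", "AAAA\tc1", "broken_row"), path)
  expect_error(load_barcode_map(path), "line 3")
  writeLines(c("wrong\theader", "AAAA\tc1"), path)
  expect_error(load_barcode_map(path), "header")
  write_raw_map(path, c("AAAA", "CCCC"), c("c1", "weird"))
  expect_error(load_barcode_map(path, labels = c("c1", "c2")), "outside declared")
})

test_that("demultiplex assigns by whitelist and conserves every pair", {
  dir <- withr::local_tempdir()
  bc <- c(known = "AAAACCCC", other = "GGGGTTTT")
  map_path <- file.path(dir, "map.tsv")
  write_raw_map(map_path, bc, c("c1", "c2"))
  map <- load_barcode_map(map_path)

  # 10 pairs: 4 to c1, 3 to c2, 3 with unlisted barcodes
  barcodes <- c(rep(bc[1], 4), rep(bc[2], 3), rep("ACGTACGT", 3))
  umis <- random_reads(10, 4, seed = 2)
  r1 <- file.path(dir, "r1.fastq"); r2 <- file.path(dir, "r2.fastq")
  write_raw_fastq(r1, sprintf("rd%02d", 1:10), paste0(barcodes, umis))
  write_raw_fastq(r2, sprintf("rd%02d", 1:10), random_reads(10, 30, seed = 3))

  reads <- demultiplex(r1, r2, map, bc_len = 8, umi_len = 4)
  counts <- attr(reads, "counts")
  expect_identical(unname(counts["total"]), 10L)
  expect_identical(unname(counts["assigned"]), 7L)
  expect_identical(unname(counts["unassigned"]), 3L)
  expect_identical(unname(counts["assigned"] + counts["unassigned"]),
                   unname(counts["total"]))
  expect_identical(sum(reads$cluster == "c1", na.rm = TRUE), 4L)
  expect_identical(reads$umi, umis)

  # record-count mismatch between mates
  write_raw_fastq(r2, sprintf("rd%02d", 1:9), random_reads(9, 30, seed = 3))
  expect_error(demultiplex(r1, r2, map, bc_len = 8, umi_len = 4),
               "record counts differ")
})

test_that("demultiplexed per-cluster counts equal the generator truth table", {
  run <- simulate_reads(small_sim_config(seed = 42), withr::local_tempdir())
  map <- load_barcode_map(run$barcodes)
  reads <- demultiplex(run$r1, run$r2, map, umi_len = 10)
  got <- table(reads$cluster)
  truth <- run$truth_summary_df
  expect_identical(as.integer(got[truth$cluster]), truth$n_reads)
  expect_identical(attr(reads, "counts")[["unassigned"]], 0L)
})

test_that("classify_read detects pure satellite repeat reads", {
  mods <- default_family_models(k = 12)
  hit <- classify_read(strrep("ATTCC", 18), mods, tau = 0.8)
  expect_identical(hit$family, "HS2/HS3")
  expect_identical(hit$coverage, 1)
  # reads shorter than k are not classified and are counted separately
  res <- classify_reads(c("ATTCCATTCC", strrep("ATTCC", 18)), mods, tau = 0.8)
  expect_identical(attr(res, "n_too_short"), 1L)
  expect_true(is.na(res$family[1]))
  expect_null(classify_read("ATTCC", mods))
})

test_that("classification agrees exactly with the window-membership oracle", {
  mods <- default_family_models(k = 12)
  reads <- c(random_reads(300, 90, seed = 13),
             repeat_fragments(100, 90, "HS2/HS3", 0.05, seed = 14),
             repeat_fragments(100, 90, "MaSat", 0.05, seed = 15))
  for (tau in c(0.3, 0.8)) {
    got <- classify_reads(reads, mods, tau = tau)
    want <- lapply(reads, oracle_classify, models = mods, tau = tau)
    expect_identical(got$family, vapply(want, `[[`, character(1), "family"))
    expect_identical(got$coverage, vapply(want, `[[`, numeric(1), "coverage"))
  }
  # random 90-mers essentially never reach tau = 0.8
  rand <- classify_reads(random_reads(300, 90, seed = 13), mods, tau = 0.8)
  expect_identical(sum(!is.na(rand$family)), 0L)
})

test_that("divergent satellite fragments have strictly partial coverage", {
  mods <- default_family_models(k = 12)
  frags <- repeat_fragments(50, 90, "MaSat", 0.05, seed = 31)
  res <- classify_reads(frags, mods, tau = 0.5)
  expect_true(all(res$coverage > 0 & res$coverage < 1))
})

test_that("raising tau only removes hits (threshold coherence)", {
  mods <- default_family_models(k = 12)
  reads <- c(repeat_fragments(200, 90, "HS2/HS3", 0.04, seed = 8),
             random_reads(100, 90, seed = 9))
  hits <- lapply(c(0.3, 0.5, 0.8), function(tau) {
    res <- classify_reads(reads, mods, tau)
    which(!is.na(res$family))
  })
  expect_true(all(hits[[2]] %in% hits[[1]]))
  expect_true(all(hits[[3]] %in% hits[[2]]))
})

test_that("marker verification passes clusters with marker reads only", {
  ref <- cluster_marker_reference(c("cluster4", "cluster5"), seed = 6)
  mk <- ref$clusters$cluster4
  marker_reads <- substring(rep(unname(mk), each = 25), 1, 90)  # 50 marker reads
  bg_reads <- random_reads(50, 90, seed = 10)
  reads <- data.frame(
    read_id = sprintf("r%03d", 1:100),
    barcode = "B", umi = "U",
    cluster = rep(c("cluster4", "cluster5"), each = 50),
    cdna = c(marker_reads, bg_reads),
    mean_quality = 40, stringsAsFactors = FALSE)
  out <- verify_cluster_markers(reads, ref, min_marker_reads = 10, k = 12)
  expect_identical(out$summary$pass, c(TRUE, FALSE))
  expect_identical(out$summary$n_marker_reads[1], 50L)
  # per-marker counts split the 50 reads between the two cluster4 genes
  c4 <- out$report[out$report$cluster == "cluster4", ]
  expect_identical(sum(c4$n_reads), 50L)
  # an empty cluster fails with count 0
  out2 <- verify_cluster_markers(reads[0, ], ref, clusters = "cluster4")
  expect_identical(out2$summary$n_marker_reads, 0L)
  expect_false(out2$summary$pass)
  # a cluster without declared markers is an error
  reads$cluster[1] <- "mystery"
  expect_error(verify_cluster_markers(reads, ref), "mystery")
})

test_that("UMI collapse counts distinct barcode-UMI pairs per feature", {
  base <- data.frame(cluster = "c1", feature = "HS2/HS3",
                     barcode = "AAAA", umi = "TTTT", stringsAsFactors = FALSE)
  expect_identical(dedup_umis(base[rep(1, 5), ])$umi_count, 1L)
  five <- base[rep(1, 5), ]; five$umi <- paste0("UMI", 1:5)
  expect_identical(dedup_umis(five)$umi_count, 5L)
  expect_identical(dedup_umis(five, use_umi = FALSE)$umi_count, 5L)
  expect_identical(dedup_umis(base[rep(1, 5), ], use_umi = FALSE)$umi_count, 5L)
  # mixed case equals a brute-force set-size computation
  set.seed(77)
  mixed <- data.frame(
    cluster = sample(c("c1", "c2"), 200, TRUE),
    feature = sample(c("HS2/HS3", "bg"), 200, TRUE),
    barcode = sample(c("B1", "B2", "B3"), 200, TRUE),
    umi = sample(paste0("U", 1:20), 200, TRUE), stringsAsFactors = FALSE)
  got <- dedup_umis(mixed)
  for (i in seq_len(nrow(got))) {
    sub <- mixed[mixed$cluster == got$cluster[i] & mixed$feature == got$feature[i], ]
    expect_identical(got$umi_count[i], length(unique(paste(sub$barcode, sub$umi))))
  }
})

test_that("TPM normalisation follows the closed form and sums to one million", {
  one <- quantify_tpm(data.frame(cluster = "c", feature = "f", umi_count = 7L),
                      c(f = 1))
  expect_equal(one$tpm, 1e6)
  two <- quantify_tpm(data.frame(cluster = "c", feature = c("a", "b"),
                                 umi_count = c(10L, 10L)),
                      c(a = 1, b = 2))
  expect_equal(two$tpm[two$feature == "a"], 2e6 / 3, tolerance = 1e-12)
  expect_equal(two$tpm[two$feature == "b"], 1e6 / 3, tolerance = 1e-12)
  expect_equal(sum(two$tpm), 1e6, tolerance = 1e-9)
  expect_error(quantify_tpm(data.frame(cluster = "c", feature = "x",
                                       umi_count = 1L), c(f = 1)),
               "no effective length")
  # zero-count cluster: all-zero rows, flagged
  z <- quantify_tpm(data.frame(cluster = c("c1", "c2"), feature = "f",
                               umi_count = c(5L, 0L)), c(f = 1),
                    feature_universe = list(c1 = "f", c2 = "f"))
  expect_identical(attr(z, "zero_clusters"), "c2")
  expect_equal(z$tpm[z$cluster == "c2"], 0)
})

test_that("between-cluster satellite TPM ratios ignore the length constant", {
  counts <- data.frame(cluster = rep(c("c1", "c2"), each = 2),
                       feature = rep(c("HS2/HS3", "background"), 2),
                       umi_count = c(40L, 1960L, 20L, 1980L))
  ratio_for <- function(len) {
    tab <- quantify_tpm(counts, c("HS2/HS3" = len, background = len))
    sat <- tab[tab$feature == "HS2/HS3", ]
    sat$tpm[sat$cluster == "c1"] / sat$tpm[sat$cluster == "c2"]
  }
  expect_equal(ratio_for(1), ratio_for(3.7), tolerance = 1e-12)
})

test_that("run_screen composes the stages it is built from", {
  run <- simulate_reads(small_sim_config(seed = 42), withr::local_tempdir())
  cfg <- screen_config_for_run(run)
  res <- run_screen(cfg)

  # manual composition of the satellite arm of the pipeline
  map <- load_barcode_map(run$barcodes)
  reads <- demultiplex(run$r1, run$r2, map, umi_len = 10)
  keep <- !is.na(reads$cluster) & reads$mean_quality >= 20
  mods <- default_family_models(k = 12)
  cls <- classify_reads(reads$cdna[keep], mods, tau = 0.5)
  hits <- !is.na(cls$family)
  manual <- dedup_umis(data.frame(cluster = reads$cluster[keep][hits],
                                  feature = cls$family[hits],
                                  barcode = reads$barcode[keep][hits],
                                  umi = reads$umi[keep][hits]))
  sat <- res$expression[res$expression$feature == "HS2/HS3" &
                          res$expression$umi_count > 0, ]
  expect_identical(sat$umi_count,
                   manual$umi_count[manual$feature == "HS2/HS3"])
  # conservation bookkeeping
  expect_identical(res$log$assigned + res$log$unassigned, res$log$total)
  # per-cluster TPM sums to one million
  sums <- tapply(res$expression$tpm, res$expression$cluster, sum)
  expect_true(all(abs(sums - 1e6) < 1e6 * 1e-6))
})

test_that("zero spiked satellite reads yield zero satellite TPM everywhere", {
  cfg <- simulation_config(
    n_cells_per_cluster = c(cluster4 = 5L, cluster5 = 5L),
    reads_per_cell = 40L,
    satellite_fraction = c(cluster4 = 0, cluster5 = 0), seed = 7)
  run <- simulate_reads(cfg, withr::local_tempdir())
  res <- run_screen(screen_config_for_run(run))
  sat <- res$expression[res$expression$feature %in% c("HS2/HS3", "MaSat"), ]
  expect_true(all(sat$tpm == 0))
})

test_that("satellite TPM increases with the spiked fraction", {
  cfg <- simulation_config(
    n_cells_per_cluster = c(cluster2 = 10L, cluster5 = 10L, cluster7 = 10L),
    reads_per_cell = 100L,
    satellite_fraction = c(cluster2 = 0, cluster5 = 0.02, cluster7 = 0.10),
    seed = 11)
  run <- simulate_reads(cfg, withr::local_tempdir())
  res <- run_screen(screen_config_for_run(run))
  sat <- res$expression[res$expression$feature == "HS2/HS3", ]
  tpm <- setNames(sat$tpm, sat$cluster)
  expect_lt(tpm[["cluster2"]], tpm[["cluster5"]])
  expect_lt(tpm[["cluster5"]], tpm[["cluster7"]])
})

test_that("low-quality reads are dropped before classification", {
  cfg <- small_sim_config(seed = 5, low_quality_fraction = 0.3)
  run <- simulate_reads(cfg, withr::local_tempdir())
  res <- run_screen(screen_config_for_run(run))
  expect_identical(res$log$n_low_quality, sum(run$truth_reads_df$low_quality))
  expect_gt(res$log$n_low_quality, 0L)
})
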