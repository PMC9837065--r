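test_that("simulation_config validates fractions and counts upfront", {
  expect_error(simulation_config(
    n_cells_per_cluster = c(a = 5L), satellite_fraction = c(a = 0.95),
    marker_fraction = 0.1, seed = 1), "exceeds 1")
  expect_error(simulation_config(
    n_cells_per_cluster = c(5L, 5L),
    satellite_fraction = c(a = 0, b = 0), seed = 1), "named")
  expect_error(simulation_config(
    n_cells_per_cluster = c(a = 0L), satellite_fraction = c(a = 0), seed = 1),
    "positive")
  expect_error(simulation_config(
    n_cells_per_cluster = c(a = 5L), satellite_fraction = c(b = 0), seed = 1),
    "names must match")
  expect_error(simulation_config(
    n_cells_per_cluster = c(a = 5L), satellite_fraction = c(a = 0),
    read_length = 900L, seed = 1), "transcript length")
})

test_that("the generator writes the configured number of read pairs", {
  cfg <- simulation_config(
    n_cells_per_cluster = c(cluster4 = 10L, cluster5 = 10L),
    reads_per_cell = 100L,
    satellite_fraction = c(cluster4 = 0.02, cluster5 = 0), seed = 3)
  run <- simulate_reads(cfg, withr::local_tempdir())
  for (fq in c(run$r1, run$r2)) {
    expect_identical(length(readLines(fq)) / 4, 2000)
  }
  expect_identical(nrow(run$truth_reads_df), 2000L)
  # cluster with fraction 0 has no satellite reads in the truth
  t5 <- run$truth_summary_df[run$truth_summary_df$cluster == "cluster5", ]
  expect_identical(t5$n_satellite, 0L)
  expect_false(any(startsWith(
    run$truth_reads_df$source[run$truth_reads_df$cluster == "cluster5"],
    "satellite")))
})

test_that("ground truth summary equals the aggregation of per-read records", {
  run <- simulate_reads(small_sim_config(seed = 9), withr::local_tempdir())
  reads <- run$truth_reads_df
  agg_n <- table(reads$cluster)
  agg_sat <- tapply(startsWith(reads$source, "satellite:"), reads$cluster, sum)
  s <- run$truth_summary_df
  expect_identical(s$n_reads, as.integer(agg_n[s$cluster]))
  expect_identical(s$n_satellite, as.integer(agg_sat[s$cluster]))
  expect_equal(s$true_fraction, s$n_satellite / s$n_reads)
  # files mirror the in-memory truth
  on_disk <- read.delim(run$truth_summary, stringsAsFactors = FALSE)
  expect_equal(on_disk, run$truth_summary_df)
})

test_that("empirical satellite fractions sit in the binomial 99% interval", {
  cfg <- simulation_config(
    n_cells_per_cluster = c(cluster1_myCAF = 20L, cluster6_normal = 20L),
    reads_per_cell = 200L,
    satellite_fraction = c(cluster1_myCAF = 0.05, cluster6_normal = 0.01),
    seed = 17)
  run <- simulate_reads(cfg, withr::local_tempdir())
  s <- run$truth_summary_df
  for (i in seq_len(nrow(s))) {
    f <- cfg$satellite_fraction[[s$cluster[i]]]
    bounds <- qbinom(c(0.005, 0.995), s$n_reads[i], f)
    expect_gte(s$n_satellite[i], bounds[1])
    expect_lte(s$n_satellite[i], bounds[2])
  }
})

test_that("identical seeds give byte-identical simulated files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- simulate_reads(small_sim_config(seed = 123), d1)
  r2 <- simulate_reads(small_sim_config(seed = 123), d2)
  for (f in c("r1", "r2", "barcodes", "markers_fasta", "truth_reads",
              "truth_summary")) {
    expect_identical(unname(tools::md5sum(r1[[f]])),
                     unname(tools::md5sum(r2[[f]])),
                     info = f)
  }
  # and a different seed changes the reads
  r3 <- simulate_reads(small_sim_config(seed = 124), withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(r1$r2)),
                         unname(tools::md5sum(r3$r2))))
})

test_that("marker FASTA round-trips cluster|gene structure", {
  ref <- cluster_marker_reference(c("cluster1_myCAF", "cluster7"), seed = 2)
  path <- tempfile(fileext = ".fasta")
  write_marker_fasta(ref, path)
  back <- read_marker_fasta(path)
  expect_setequal(names(back$clusters), c("cluster1_myCAF", "cluster7"))
  expect_identical(sort(names(back$clusters$cluster7)),
                   sort(names(ref$clusters$cluster7)))
  expect_identical(back$clusters$cluster7[["CCL2"]],
                   ref$clusters$cluster7[["CCL2"]])
})

test_that("FISH field simulation paints exact per-nucleus pixel counts", {
  sim <- simulate_fish_image(width = 384, height = 384, n_nuclei = 3,
                             nuclear_signal_fraction = 0.1,
                             cytoplasmic_signal_fraction = 0.05, seed = 4)
  tr <- sim$truth_nuclei
  expect_identical(tr$signal_pixels, as.integer(round(0.1 * tr$area)))
  for (i in tr$nucleus) {
    painted <- sum(sim$fish[sim$labels == i] > 0.5)
    expect_identical(painted, tr$signal_pixels[i])
  }
  expect_identical(sim$truth_field$cytoplasmic_signal_pixels,
                   as.integer(round(0.05 * sim$truth_field$ring_area)))
  # extreme fractions
  none <- simulate_fish_image(n_nuclei = 2, nuclear_signal_fraction = 0, seed = 5)
  expect_identical(sum(none$fish[none$labels > 0] > 0), 0L)
  full <- simulate_fish_image(n_nuclei = 2, nuclear_signal_fraction = 1, seed = 6)
  expect_true(all(full$fish[full$labels > 0] > 0.5))
  # determinism
  again <- simulate_fish_image(width = 384, height = 384, n_nuclei = 3,
                               nuclear_signal_fraction = 0.1,
                               cytoplasmic_signal_fraction = 0.05, seed = 4)
  expect_identical(sim$fish, again$fish)
  expect_identical(sim$dapi, again$dapi)
})

test_that("impossible nucleus placement errors out instead of looping", {
  expect_error(simulate_fish_image(width = 128, height = 128, n_nuclei = 30,
                                   seed = 1, max_retries = 50),
               "placement failed")
})

test_that("written FISH fields read back with the same geometry", {
  sim <- simulate_fish_image(width = 256, height = 256, n_nuclei = 2,
                             nuclear_signal_fraction = 0.2, seed = 8)
  paths <- write_fish_field(sim, withr::local_tempdir(), "f1")
  dapi <- read_channel(paths$dapi)
  fish <- read_channel(paths$fish)
  expect_identical(dim(dapi), dim(sim$dapi))
  # 8-bit quantisation keeps foreground/background separation exact
  expect_identical(dapi > 0.5, sim$dapi > 0.5)
  expect_identical(fish > 0.5, sim$fish > 0.5)
})
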