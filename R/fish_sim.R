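# Synthetic two-channel FISH fields with exactly known signal geometry:
# a DAPI-analogue channel of filled nuclear ellipses and a FISH-analogue
# channel whose bright pixels cover a requested fraction of each nucleus
# and of a perinuclear cytoplasmic ring.

DAPI_INTENSITY <- 0.75
SIGNAL_INTENSITY <- 0.9
BACKGROUND_INTENSITY <- 0

# logical mask of a rotated filled ellipse on a height x width grid
ellipse_mask <- function(height, width, cy, cx, a, b, theta) {
  yy <- matrix(seq_len(height), nrow = height, ncol = width)
  xx <- matrix(seq_len(width), nrow = height, ncol = width, byrow = TRUE)
  dy <- yy - cy
  dx <- xx - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Simulate a two-channel FISH field with known signal fractions
#'
#' Places `n_nuclei` non-overlapping random ellipses (DAPI channel) and
#' paints FISH-channel signal covering exactly
#' `round(nuclear_signal_fraction * area)` pixels inside each nucleus and
#' `round(cytoplasmic_signal_fraction * ring_area)` pixels inside the
#' perinuclear cytoplasmic ring (a `ring_radius`-pixel dilation of the
#' nucleus minus the nucleus). The truth record stores the exact painted
#' pixel counts, making area-fraction recovery testable to integer
#' precision. Images are single-plane grayscale in `[0, 1]`; optional
#' Gaussian noise exercises thresholding behaviour.
#'
#' @param width,height Field size in pixels (defaults 512).
#' @param n_nuclei Number of nuclei (default 5).
#' @param nuclear_signal_fraction,cytoplasmic_signal_fraction Signal area
#'   fractions in `[0, 1]` (defaults 0.1 and 0).
#' @param ring_radius Cytoplasmic ring radius in pixels (default 15,
#'   matching the quantifier's default).
#' @param noise_sd Standard deviation of additive Gaussian noise on both
#'   channels (default 0 = noise-free).
#' @param seed RNG seed.
#' @param max_retries Nucleus placement retries before giving up with an
#'   error (default 2000).
#' @return List of class `fish_field_sim`: `dapi` and `fish` (numeric
#'   matrices), `labels` (true nucleus label matrix), `truth_nuclei`
#'   (per-nucleus `area`, `signal_pixels`, `percent`), `truth_field`
#'   (`nuclear_signal_pixels`, `cytoplasmic_signal_pixels`, `ring_area`).
#' @export
simulate_fish_image <- function(width = 512L, height = 512L, n_nuclei = 5L,
                                nuclear_signal_fraction = 0.1,
                                cytoplasmic_signal_fraction = 0,
                                ring_radius = 15L, noise_sd = 0, seed = 1L,
                                max_retries = 2000L) {
  stopifnot(nuclear_signal_fraction >= 0, nuclear_signal_fraction <= 1,
            cytoplasmic_signal_fraction >= 0, cytoplasmic_signal_fraction <= 1,
            n_nuclei >= 1L)
  with_seed(seed, {
    a_rng <- c(25, 40)
    b_rng <- c(18, 32)
    sep <- 2 * (max(a_rng) + ring_radius) + 3
    margin <- max(a_rng) + ring_radius + 2

    centers <- matrix(numeric(0), ncol = 2L)
    tries <- 0L
    while (nrow(centers) < n_nuclei) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("nucleus placement failed: field too crowded after ",
             max_retries, " retries", call. = FALSE)
      }
      cand <- c(runif(1, margin, height - margin),
                runif(1, margin, width - margin))
      if (nrow(centers) == 0L ||
          all(sqrt(rowSums(sweep(centers, 2L, cand)^2)) >= sep)) {
        centers <- rbind(centers, cand)
      }
    }

    labels <- matrix(0L, nrow = height, ncol = width)
    for (i in seq_len(n_nuclei)) {
      m <- ellipse_mask(height, width, centers[i, 1L], centers[i, 2L],
                        runif(1, a_rng[1L], a_rng[2L]),
                        runif(1, b_rng[1L], b_rng[2L]),
                        runif(1, 0, pi))
      labels[m] <- i
    }

    dapi <- matrix(BACKGROUND_INTENSITY, nrow = height, ncol = width)
    dapi[labels > 0L] <- DAPI_INTENSITY

    nuc_any <- labels > 0L
    ring <- as.logical(EBImage::dilate(
      EBImage::Image(nuc_any * 1), EBImage::makeBrush(2L * ring_radius + 1L, "disc"))
    ) & !nuc_any
    dim(ring) <- dim(labels)

    fish <- matrix(BACKGROUND_INTENSITY, nrow = height, ncol = width)
    areas <- tabulate(labels[labels > 0L], nbins = n_nuclei)
    signal_pixels <- integer(n_nuclei)
    for (i in seq_len(n_nuclei)) {
      px <- which(labels == i)
      n_sig <- as.integer(round(nuclear_signal_fraction * areas[i]))
      signal_pixels[i] <- n_sig
      if (n_sig > 0L) fish[sample(px, n_sig)] <- SIGNAL_INTENSITY
    }
    ring_px <- which(ring)
    n_cyt <- as.integer(round(cytoplasmic_signal_fraction * length(ring_px)))
    if (n_cyt > 0L) fish[sample(ring_px, n_cyt)] <- SIGNAL_INTENSITY

    if (noise_sd > 0) {
      dapi <- pmin(pmax(dapi + matrix(stats::rnorm(length(dapi), 0, noise_sd),
                                      nrow = height), 0), 1)
      fish <- pmin(pmax(fish + matrix(stats::rnorm(length(fish), 0, noise_sd),
                                      nrow = height), 0), 1)
    }

    structure(
      list(dapi = dapi, fish = fish, labels = labels,
           truth_nuclei = data.frame(
             nucleus = seq_len(n_nuclei), area = areas,
             signal_pixels = signal_pixels,
             percent = 100 * signal_pixels / areas),
           truth_field = data.frame(
             nuclear_signal_pixels = sum(signal_pixels),
             cytoplasmic_signal_pixels = n_cyt,
             ring_area = length(ring_px), n_nuclei = n_nuclei)),
      class = "fish_field_sim"
    )
  })
}

#' Write a simulated FISH field to disk
#'
#' Writes 8-bit grayscale TIFFs (`<field_id>_dapi.tif`,
#' `<field_id>_fish.tif`) and the truth tables as TSV.
#'
#' @param sim A [simulate_fish_image()] result.
#' @param dir Output directory (created if needed).
#' @param field_id Basename prefix for the files.
#' @return Named list of the written paths, invisibly.
#' @export
write_fish_field <- function(sim, dir, field_id = "field1") {
  stopifnot(inherits(sim, "fish_field_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    dapi = file.path(dir, paste0(field_id, "_dapi.tif")),
    fish = file.path(dir, paste0(field_id, "_fish.tif")),
    truth_nuclei = file.path(dir, paste0(field_id, "_truth_nuclei.tsv")),
    truth_field = file.path(dir, paste0(field_id, "_truth_field.tsv"))
  )
  EBImage::writeImage(EBImage::Image(sim$dapi), paths$dapi, type = "tiff",
                      bits.per.sample = 8L)
  EBImage::writeImage(EBImage::Image(sim$fish), paths$fish, type = "tiff",
                      bits.per.sample = 8L)
  write.table(sim$truth_nuclei, paths$truth_nuclei, sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth_field, paths$truth_field, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}
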