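# Quantification of FISH signal distribution in two-channel fields:
# nuclear segmentation from the DAPI channel, percent of nucleus area
# occupied by signal, and nuclear vs cytoplasmic signal pixel counts.

#' Read a grayscale microscopy channel
#'
#' Reads an 8- or 16-bit grayscale TIFF (or PNG) into a numeric matrix in
#' `[0, 1]`. Multi-channel images are split by `channel` index.
#'
#' @param path Image path.
#' @param channel Channel index for multi-channel files (default 1).
#' @return Numeric matrix.
#' @export
read_channel <- function(path, channel = 1L) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- img[, , channel]
  matrix(as.numeric(EBImage::imageData(img)), nrow = d[1L])
}

threshold_image <- function(img, method) {
  if (is.numeric(method)) return(img > method)
  if (!identical(method, "otsu")) {
    stop("threshold method must be 'otsu' or a numeric cut-off", call. = FALSE)
  }
  if (diff(range(img)) == 0) {
    # constant channel: nothing to separate, no foreground
    return(matrix(FALSE, nrow = nrow(img), ncol = ncol(img)))
  }
  thr <- EBImage::otsu(EBImage::Image(img), range = c(0, 1))
  img > thr
}

#' Segment nuclei from a DAPI channel
#'
#' Global Otsu threshold (default), hole filling, connected-component
#' labelling, and removal of components below `min_area`. Touching nuclei
#' are not split — they merge into one label. An all-background image
#' yields an empty mask (zero nuclei), not an error.
#'
#' @param dapi Numeric matrix in `[0, 1]` (see [read_channel()]).
#' @param min_area Minimum component area in pixels (default 100).
#' @param threshold_method `"otsu"` or a fixed numeric cut-off.
#' @return Object of class `nucleus_mask`: `labels` (integer matrix,
#'   0 = background, nuclei relabelled 1..n) and `areas` (integer vector).
#' @export
segment_nuclei <- function(dapi, min_area = 100L, threshold_method = "otsu") {
  stopifnot(is.matrix(dapi))
  fg <- threshold_image(dapi, threshold_method)
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(fg)))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow = nrow(dapi))
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(areas >= min_area)
    relabel <- integer(n)
    relabel[keep] <- seq_along(keep)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  structure(list(labels = lab, areas = areas), class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("<nucleus_mask> %d nuclei (areas %s px)\n", length(x$areas),
              if (length(x$areas)) paste(range(x$areas), collapse = "-") else "-"))
  invisible(x)
}

#' Quantify FISH signal within a segmented field
#'
#' Signal pixels are FISH-channel pixels above the threshold. Per nucleus,
#' the measurement is `100 * signal-in-nucleus / nucleus area` (the percent
#' of the nucleus area occupied by FISH signal); field totals are the
#' signal pixel counts inside nuclei and inside the cytoplasmic
#' compartment, operationalised as a `ring_radius`-pixel dilation ring
#' around the nuclei (signal outside both is reported separately).
#'
#' @param fish Numeric FISH-channel matrix, same shape as the mask.
#' @param mask A [segment_nuclei()] result (or the true label matrix from
#'   the simulator wrapped by it).
#' @param threshold_method `"otsu"` (default) or a fixed numeric cut-off.
#' @param ring_radius Cytoplasm ring radius in pixels (default 15).
#' @param field_id Identifier copied into the output (default `"field"`).
#' @return Object of class `fish_field_measurement`: `field_id`,
#'   `per_nucleus` (`nucleus`, `area`, `signal_pixels`, `percent`),
#'   `nuclear_signal_pixels`, `cytoplasmic_signal_pixels`,
#'   `outside_signal_pixels`, `total_signal_pixels`, `n_nuclei`.
#' @export
quantify_field <- function(fish, mask, threshold_method = "otsu",
                           ring_radius = 15L, field_id = "field") {
  stopifnot(inherits(mask, "nucleus_mask"))
  if (!identical(dim(fish), dim(mask$labels))) {
    stop("fish channel and nucleus mask shapes differ", call. = FALSE)
  }
  sig <- threshold_image(fish, threshold_method)
  n <- length(mask$areas)
  nuc_any <- mask$labels > 0L
  per_sig <- if (n > 0L) {
    tabulate(mask$labels[sig & nuc_any], nbins = n)
  } else {
    integer(0)
  }
  ring <- if (n > 0L) {
    r <- as.logical(EBImage::dilate(
      EBImage::Image(nuc_any * 1),
      EBImage::makeBrush(2L * ring_radius + 1L, "disc"))) & !nuc_any
    dim(r) <- dim(fish)
    r
  } else {
    matrix(FALSE, nrow = nrow(fish), ncol = ncol(fish))
  }
  nuclear <- sum(sig & nuc_any)
  cyto <- sum(sig & ring)
  total <- sum(sig)
  structure(
    list(field_id = field_id,
         per_nucleus = data.frame(
           nucleus = seq_len(n), area = mask$areas,
           signal_pixels = per_sig,
           percent = if (n > 0L) 100 * per_sig / mask$areas else numeric(0)),
         nuclear_signal_pixels = nuclear,
         cytoplasmic_signal_pixels = cyto,
         outside_signal_pixels = total - nuclear - cyto,
         total_signal_pixels = total,
         n_nuclei = n),
    class = "fish_field_measurement"
  )
}

#' @export
print.fish_field_measurement <- function(x, ...) {
  cat(sprintf(
    "<fish_field_measurement> %s: %d nuclei; signal px nuclear %d / cytoplasmic %d / outside %d\n",
    x$field_id, x$n_nuclei, x$nuclear_signal_pixels,
    x$cytoplasmic_signal_pixels, x$outside_signal_pixels))
  if (x$n_nuclei > 0L) {
    cat(sprintf("  mean percent of nucleus area occupied: %.2f\n",
                mean(x$per_nucleus$percent)))
  }
  invisible(x)
}

#' Summarise per-nucleus measurements across fields and groups
#'
#' Pools the per-nucleus percent-of-area values of each group's fields and
#' reports group mean and sample standard deviation, retaining the
#' individual values.
#'
#' @param measurements List of `fish_field_measurement`s.
#' @param groups Character vector of group labels, one per measurement.
#' @return List: `summary` (`group`, `n`, `mean_percent`, `sd_percent`) and
#'   `values` (`group`, `field_id`, `nucleus`, `percent`).
#' @export
summarize_fields <- function(measurements, groups) {
  stopifnot(length(measurements) == length(groups), length(groups) > 0L,
            all(vapply(measurements, inherits, logical(1L),
                       "fish_field_measurement")))
  values <- rbindlist(lapply(seq_along(measurements), function(i) {
    m <- measurements[[i]]
    if (m$n_nuclei == 0L) return(NULL)
    data.table(group = groups[i], field_id = m$field_id,
               nucleus = m$per_nucleus$nucleus,
               percent = m$per_nucleus$percent)
  }))
  empty <- setdiff(groups, values$group)
  if (length(empty)) {
    stop("group with no per-nucleus values: ", empty[1L], call. = FALSE)
  }
  summary <- values[, list(n = .N, mean_percent = mean(percent),
                           sd_percent = stats::sd(percent)), by = "group"]
  setorder(summary, group)
  list(summary = as.data.frame(summary), values = as.data.frame(values))
}
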