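#' Spot-detection parameters
#'
#' Defaults follow the convolution-and-threshold detector used for
#' interphase FISH copy-number counting: a sampled Gaussian kernel of
#' standard deviation 3 px and size 7x7, a fixed brightness threshold of
#' 15 on the 0-255 scale, a relative peak threshold of one standard
#' deviation above the image-wide mean brightness, and a minimum spot
#' area (in pixels) to suppress single-pixel noise.
#'
#' @param gaussian_sd Gaussian kernel standard deviation in pixels.
#' @param kernel_size Odd kernel side length in pixels.
#' @param fixed_threshold Post-convolution intensity threshold (0-255).
#' @param relative_sds Number of image standard deviations above the
#'   image mean that a spot's peak raw intensity must exceed.
#' @param min_area Minimum connected-component area in pixels.
#' @return A list of class `spot_call_params`.
#' @export
spot_call_params <- function(gaussian_sd = 3, kernel_size = 7,
                             fixed_threshold = 15, relative_sds = 1,
                             min_area = 4) {
  stopifnot(gaussian_sd > 0, kernel_size %% 2 == 1,
            fixed_threshold > 0, fixed_threshold < 255, min_area >= 1)
  structure(list(gaussian_sd = gaussian_sd, kernel_size = as.integer(kernel_size),
                 fixed_threshold = fixed_threshold, relative_sds = relative_sds,
                 min_area = min_area),
            class = "spot_call_params")
}

#' Normalize an image to the 0-255 intensity scale
#'
#' Images with a maximum above 255 (e.g. 16-bit TIFFs) are linearly
#' rescaled so the minimum maps to 0 and the maximum to 255; 8-bit
#' images pass through unchanged. A constant image passes through with a
#' warning (no spots can be found in it).
#'
#' @param image Numeric matrix (2-D grayscale).
#' @return Numeric matrix on the 0-255 scale.
#' @export
normalize_image <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warn("constant image: no spots will be found")
    return(image)
  }
  if (rng[2] <= 255) return(image)
  (image - rng[1]) / (rng[2] - rng[1]) * 255
}

# Sampled Gaussian kernel, normalized to sum 1.
gaussian_kernel <- function(size, sd) {
  r <- (size - 1) / 2
  d <- seq(-r, r)
  k <- outer(exp(-d^2 / (2 * sd^2)), exp(-d^2 / (2 * sd^2)))
  k / sum(k)
}

# 2-D convolution with reflective (symmetric) border handling,
# implemented as a shift-and-add over the kernel support.
convolve_reflect <- function(image, kernel) {
  k <- nrow(kernel)
  r <- (k - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  stopifnot(nr > r, nc > r)
  ri <- c(r:1, 1:nr, nr:(nr - r + 1L))
  ci <- c(r:1, 1:nc, nc:(nc - r + 1L))
  pad <- image[ri, ci]
  out <- matrix(0, nr, nc)
  for (di in seq_len(k)) {
    for (dj in seq_len(k)) {
      if (kernel[di, dj] == 0) next
      out <- out + kernel[di, dj] *
        pad[di:(di + nr - 1L), dj:(dj + nc - 1L)]
    }
  }
  out
}

# Connected-component labelling of a logical mask (8- or 4-connectivity)
# via graph components over adjacent foreground pixels.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(labels)
  compact <- integer(nr * nc)
  compact[idx] <- seq_along(idx)
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offsets <- c(offsets, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (off in offsets) {
    nrow_ok <- row + off[1] >= 1L & row + off[1] <= nr &
      col + off[2] >= 1L & col + off[2] <= nc
    nb <- idx + off[1] + off[2] * nr
    keep <- nrow_ok & mask[pmin(pmax(nb, 1L), nr * nc)] & nb >= 1L & nb <= nr * nc
    if (any(keep)) {
      edges[[length(edges) + 1L]] <- cbind(compact[idx[keep]], compact[nb[keep]])
    }
  }
  if (length(edges) > 0L) {
    em <- do.call(rbind, edges)
    g <- igraph::make_graph(t(em), n = length(idx), directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  labels[idx] <- igraph::components(g)$membership
  labels
}

#' Detect FISH spots in a grayscale image
#'
#' Implements the convolution-and-threshold detector: (1) convolve the
#' image with a sampled, sum-normalized Gaussian kernel (reflective
#' borders); (2) threshold the convolved image at `fixed_threshold`;
#' (3) keep 8-connected components whose peak *raw* intensity exceeds
#' the image-wide mean plus `relative_sds` standard deviations; (4)
#' discard components smaller than `min_area` pixels. Each surviving
#' component is one spot.
#'
#' @param image Numeric matrix on the 0-255 scale (see
#'   [normalize_image()]).
#' @param params A [spot_call_params()] object.
#' @return An object of class `spot_detection`: list with `spots`
#'   (tibble: `spot_id`, `row`, `col` centroid, `area`, `peak_raw`,
#'   `peak_smoothed`), `labels` (integer raster of surviving spots) and
#'   `params`.
#' @export
detect_spots <- function(image, params = spot_call_params()) {
  stopifnot(is.matrix(image))
  smoothed <- convolve_reflect(image,
                               gaussian_kernel(params$kernel_size,
                                               params$gaussian_sd))
  mask <- smoothed > params$fixed_threshold
  labels <- label_components(mask, connectivity = 8)
  n_comp <- max(labels)
  empty <- tibble(spot_id = integer(), row = numeric(), col = numeric(),
                  area = numeric(), peak_raw = numeric(),
                  peak_smoothed = numeric())
  if (n_comp == 0L) {
    return(structure(list(spots = empty, labels = labels, params = params),
                     class = "spot_detection"))
  }
  idx <- which(labels > 0L)
  lab <- labels[idx]
  row <- ((idx - 1L) %% nrow(image)) + 1L
  col <- ((idx - 1L) %/% nrow(image)) + 1L
  area <- tabulate(lab, nbins = n_comp)
  peak_raw <- as.numeric(tapply(image[idx], lab, max))
  peak_sm <- as.numeric(tapply(smoothed[idx], lab, max))
  cen_row <- as.numeric(tapply(row, lab, mean))
  cen_col <- as.numeric(tapply(col, lab, mean))
  rel_thresh <- mean(image) + params$relative_sds * sd(image)
  keep <- peak_raw > rel_thresh & area >= params$min_area
  if (!any(keep)) {
    return(structure(list(spots = empty,
                          labels = matrix(0L, nrow(image), ncol(image)),
                          params = params),
                     class = "spot_detection"))
  }
  relabel <- integer(n_comp)
  relabel[which(keep)] <- seq_len(sum(keep))
  out_labels <- matrix(0L, nrow(image), ncol(image))
  out_labels[idx] <- relabel[lab]
  spots <- tibble(spot_id = seq_len(sum(keep)),
                  row = cen_row[keep], col = cen_col[keep],
                  area = area[keep], peak_raw = peak_raw[keep],
                  peak_smoothed = peak_sm[keep])
  structure(list(spots = spots, labels = out_labels, params = params),
            class = "spot_detection")
}

#' Count spots per segmented cell
#'
#' Assigns each detected spot to the cell whose mask label contains the
#' spot's centroid pixel; spots whose centroid lies on background are
#' dropped. A cell is classified amplified when its spot count strictly
#' exceeds `amplified_threshold` (copy number greater than five at the
#' default).
#'
#' @param spots A [detect_spots()] result, or a tibble with `row` and
#'   `col` centroid columns.
#' @param mask Integer labelled raster, same shape as the image; 0 is
#'   background, positive labels are cells.
#' @param amplified_threshold Strict spot-count threshold for the
#'   amplified call.
#' @return A tibble with `cell_id`, `spot_count`, `amplified`, one row
#'   per cell label present in the mask (cells with no spots included).
#' @export
count_spots_per_cell <- function(spots, mask, amplified_threshold = 5) {
  if (inherits(spots, "spot_detection")) spots <- spots$spots
  cells <- sort(setdiff(unique(as.integer(mask)), 0L))
  if (length(cells) == 0L) {
    return(tibble(cell_id = integer(), spot_count = numeric(),
                  amplified = logical()))
  }
  counts <- setNames(rep(0, length(cells)), cells)
  if (nrow(spots) > 0L) {
    r <- pmin(pmax(round(spots$row), 1), nrow(mask))
    c_ <- pmin(pmax(round(spots$col), 1), ncol(mask))
    lab <- mask[cbind(r, c_)]
    tab <- table(lab[lab > 0])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  tibble(cell_id = cells, spot_count = as.numeric(counts),
         amplified = as.numeric(counts) > amplified_threshold)
}

#' Compare spot-count heterogeneity between samples and a reference
#'
#' For each sample, tests whether the per-cell spot-count distribution
#' has a different location than the reference (two-sided Mann-Whitney
#' rank-sum test, the independent-samples Wilcoxon test) and a different
#' scale (Levene's test centred on the group means), and reports the
#' fraction of amplified cells per group. ecDNA-bearing tumors are
#' expected to show greater mean and variance than a chromosomally
#' (HSR) amplified reference.
#'
#' @param sample_counts Named list of numeric spot-count vectors, or a
#'   long data frame with columns `sample` and `spot_count`.
#' @param reference Numeric vector of reference spot counts.
#' @param amplified_threshold Strict threshold for the amplified
#'   fraction.
#' @return An object of class `heterogeneity_report`: list with
#'   `summary` (per-group n, mean, variance, fraction amplified) and
#'   `tests` (per sample vs reference: rank-sum statistic and p, Levene
#'   statistic and p).
#' @export
compare_heterogeneity <- function(sample_counts, reference,
                                  amplified_threshold = 5) {
  if (is.data.frame(sample_counts)) {
    stopifnot(all(c("sample", "spot_count") %in% names(sample_counts)))
    sample_counts <- split(sample_counts$spot_count, sample_counts$sample)
  }
  stopifnot(length(sample_counts) > 0, !is.null(names(sample_counts)))
  if (length(reference) < 2L || any(lengths(sample_counts) < 2L)) {
    abort("each group needs at least 2 cells")
  }
  groups <- c(sample_counts, list(reference = reference))
  summary <- tibble(
    sample = names(groups),
    n_cells = unname(lengths(groups)),
    mean_count = unname(vapply(groups, mean, numeric(1))),
    var_count = unname(vapply(groups, var, numeric(1))),
    frac_amplified = unname(vapply(groups, function(x) {
      mean(x > amplified_threshold)
    }, numeric(1))))
  tests <- purrr::map_dfr(names(sample_counts), function(nm) {
    x <- sample_counts[[nm]]
    wt <- suppressWarnings(wilcox.test(x, reference, alternative = "two.sided",
                                       correct = TRUE))
    lt <- levene_test(list(x, reference), center = mean)
    tibble(sample = nm,
           ranksum_statistic = unname(wt$statistic),
           ranksum_p = wt$p.value,
           levene_statistic = lt$statistic,
           levene_p = lt$p.value)
  })
  structure(list(summary = summary, tests = tests,
                 amplified_threshold = amplified_threshold),
            class = "heterogeneity_report")
}

#' @export
tidy.heterogeneity_report <- function(x, ...) {
  left_join(x$summary, x$tests, by = "sample")
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group centre (the mean by default, Levene's original statistic; a
#' median centre gives the Brown-Forsythe variant). When the deviations
#' show no between-group spread at all, the statistic is 0 and the
#' p-value 1 (identical groups differ in scale by exactly nothing).
#'
#' @param groups List of numeric vectors, one per group.
#' @param center Function computing the group centre (`mean` or
#'   `median`).
#' @return A list with `statistic` (the F value), `df` (numerator,
#'   denominator) and `p.value`.
#' @export
levene_test <- function(groups, center = mean) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  dev <- lapply(groups, function(x) abs(x - center(x)))
  z <- unlist(dev)
  ni <- lengths(dev)
  k <- length(dev)
  n <- sum(ni)
  zbar_i <- vapply(dev, mean, numeric(1))
  zbar <- mean(z)
  ss_between <- sum(ni * (zbar_i - zbar)^2)
  ss_within <- sum(unlist(lapply(dev, function(d) (d - mean(d))^2)))
  if (ss_between == 0) {
    return(list(statistic = 0, df = c(k - 1, n - k), p.value = 1))
  }
  f <- (ss_between / (k - 1)) / (ss_within / (n - k))
  list(statistic = f, df = c(k - 1, n - k),
       p.value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Plot per-cell spot-count distributions by sample
#'
#' Box-and-jitter plot of FISH spot counts per cell with the amplified
#' threshold marked, the standard display for comparing copy-number
#' heterogeneity across tumors and control lines.
#'
#' @param counts Long data frame with columns `sample` and `spot_count`.
#' @param amplified_threshold Threshold line to draw (strict cutoff).
#' @return A ggplot object.
#' @export
plot_spot_counts <- function(counts, amplified_threshold = 5) {
  stopifnot(all(c("sample", "spot_count") %in% names(counts)))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$sample,
                                       y = .data$spot_count)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = amplified_threshold,
                        colour = "red", linetype = 2) +
    ggplot2::labs(x = NULL, y = "FISH spots per cell") +
    ggplot2::theme_minimal()
}

#' Fallback nucleus segmentation by global thresholding
#'
#' A simple segmenter for synthetic fixtures and smoke tests: Otsu
#' global threshold, hole filling, connected components and a minimum
#' nucleus area filter (default 500 px). Touching nuclei may merge into
#' one label; production use should supply masks from a dedicated
#' segmentation tool instead.
#'
#' @param image Numeric matrix (DAPI channel), any scale.
#' @param min_nucleus_area Minimum nucleus area in pixels.
#' @return Integer labelled mask, 0 = background.
#' @export
fallback_segment <- function(image, min_nucleus_area = 500) {
  stopifnot(is.matrix(image))
  rng <- range(image)
  if (rng[1] == rng[2]) return(matrix(0L, nrow(image), ncol(image)))
  img01 <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  bin <- img01 > thr
  filled <- EBImage::fillHull(EBImage::Image(bin * 1)) > 0
  filled <- matrix(as.logical(filled), nrow(image), ncol(image))
  labels <- label_components(filled, connectivity = 8)
  if (max(labels) == 0L) return(labels)
  area <- tabulate(labels[labels > 0L], nbins = max(labels))
  keep <- which(area >= min_nucleus_area)
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(image), ncol(image))
  pos <- labels > 0L
  out[pos] <- relabel[labels[pos]]
  out
}

#' Read a grayscale FISH image or labelled mask
#'
#' TIFFs are read with original integer values; PNGs are scaled from
#' \[0, 1\] to 0-255. Multi-channel images are reduced to their first
#' channel.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Numeric matrix.
#' @export
read_fish_image <- function(path) {
  img <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path) * 255
  } else {
    tiff::readTIFF(path, as.is = TRUE)
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  storage.mode(img) <- "double"
  img
}

#' Write a grayscale image or labelled mask as TIFF
#'
#' Images are written 8-bit (values 0-255); masks (`bits = 16`) keep
#' integer labels up to 65535.
#'
#' @param image Numeric matrix.
#' @param path Output path.
#' @param bits 8 for intensity images, 16 for labelled masks.
#' @return `path`, invisibly.
#' @export
write_fish_image <- function(image, path, bits = 8) {
  stopifnot(bits %in% c(8, 16))
  denom <- if (bits == 8) 255 else 65535
  tiff::writeTIFF(pmin(pmax(image / denom, 0), 1), path,
                  bits.per.sample = bits)
  invisible(path)
}
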