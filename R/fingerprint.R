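#' Variant allele fractions from allele counts
#'
#' @param counts A data frame with per-locus `ref_count` and `alt_count`
#'   columns (rows aligned to the SNP panel).
#' @param min_depth Minimum total depth (`ref + alt`) below which a
#'   locus is flagged missing.
#' @return A tibble with `vaf` (`alt / (ref + alt)`, `NA` when missing)
#'   and logical `missing`.
#' @export
vaf_vector <- function(counts, min_depth = 1) {
  stopifnot(all(c("ref_count", "alt_count") %in% names(counts)),
            all(counts$ref_count >= 0), all(counts$alt_count >= 0))
  depth <- counts$ref_count + counts$alt_count
  missing <- depth < min_depth
  vaf <- ifelse(missing, NA_real_, counts$alt_count / depth)
  tibble(vaf = vaf, missing = missing)
}

#' Pairwise sample fingerprinting from SNP-panel allele fractions
#'
#' Computes Pearson correlations of variant allele fractions between all
#' sample pairs over the loci observed (depth at least `min_depth`) in
#' both samples. Pairs with correlation above `threshold` are flagged as
#' originating from the same patient; pairs sharing fewer than
#' `min_shared` co-observed loci, or involving a sample with zero VAF
#' variance, are reported indeterminate rather than correlated.
#'
#' @param samples A long data frame with columns `sample_id`, `locus`
#'   (index or `chrom:pos` key), `ref_count`, `alt_count`; or a named
#'   list of per-sample count tibbles aligned to the same panel.
#' @param threshold Duplicate-call correlation threshold.
#' @param min_shared Minimum number of co-observed loci for a
#'   determinate correlation.
#' @param min_depth Per-locus depth floor (see [vaf_vector()]).
#' @return An object of class `fingerprint_result`: list with `pairs`
#'   (tibble: `sample_a`, `sample_b`, `r`, `n_shared`, `indeterminate`,
#'   `duplicate`), `correlation` (symmetric matrix) and the thresholds
#'   used.
#' @export
pairwise_fingerprint <- function(samples, threshold = 0.80,
                                 min_shared = 100, min_depth = 1) {
  if (is.data.frame(samples)) {
    stopifnot(all(c("sample_id", "locus", "ref_count", "alt_count") %in%
                    names(samples)))
    samples <- split(samples[, c("locus", "ref_count", "alt_count")],
                     samples$sample_id)
  }
  ids <- names(samples)
  if (length(ids) < 2L) abort("need at least 2 samples")
  loci <- sort(unique(unlist(lapply(samples, function(s) s$locus))))
  V <- matrix(NA_real_, nrow = length(loci), ncol = length(ids),
              dimnames = list(NULL, ids))
  for (id in ids) {
    s <- samples[[id]]
    v <- vaf_vector(s, min_depth = min_depth)
    V[match(s$locus, loci), id] <- v$vaf
  }
  cormat <- matrix(NA_real_, length(ids), length(ids),
                   dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j < i) next
      ok <- !is.na(V[, i]) & !is.na(V[, j])
      n_shared <- sum(ok)
      if (i == j) {
        cormat[i, j] <- if (n_shared > 0 && sd(V[ok, i]) > 0) 1 else NA_real_
        next
      }
      indeterminate <- n_shared < min_shared ||
        sd(V[ok, i]) == 0 || sd(V[ok, j]) == 0
      r <- if (n_shared >= 2 && !indeterminate) {
        cor(V[ok, i], V[ok, j])
      } else {
        NA_real_
      }
      cormat[i, j] <- cormat[j, i] <- r
      pairs[[length(pairs) + 1L]] <- tibble(
        sample_a = ids[[i]], sample_b = ids[[j]], r = r,
        n_shared = n_shared, indeterminate = indeterminate,
        duplicate = !indeterminate && !is.na(r) && r > threshold)
    }
  }
  structure(list(pairs = bind_rows(pairs), correlation = cormat,
                 threshold = threshold, min_shared = min_shared,
                 min_depth = min_depth),
            class = "fingerprint_result")
}

#' @export
tidy.fingerprint_result <- function(x, ...) x$pairs

#' @export
glance.fingerprint_result <- function(x, ...) {
  tibble(n_samples = nrow(x$correlation),
         n_pairs = nrow(x$pairs),
         n_duplicate = sum(x$pairs$duplicate),
         n_indeterminate = sum(x$pairs$indeterminate),
         threshold = x$threshold)
}

#' Write fingerprint results to disk
#'
#' @param result A [pairwise_fingerprint()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fingerprint_results <- function(result, dir) {
  stopifnot(inherits(result, "fingerprint_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- as.data.frame(result$correlation)
  cm <- cbind(sample_id = rownames(result$correlation), cm)
  readr::write_tsv(as_tibble(cm), file.path(dir, "correlation_matrix.tsv"))
  readr::write_tsv(dplyr::filter(result$pairs, .data$duplicate),
                   file.path(dir, "duplicate_pairs.tsv"))
  invisible(dir)
}
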