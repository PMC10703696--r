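#' Cell quality-control thresholds
#'
#' Default thresholds retain barcodes with an ATAC mitochondrial fraction
#' below 0.1, between 1,000 and 70,000 ATAC fragments and (when an RNA
#' modality is present) between 500 and 25,000 RNA counts.
#'
#' @param mito_frac_max Maximum mitochondrial fragment fraction (exclusive).
#' @param atac_min,atac_max Inclusive bounds on total ATAC fragments.
#' @param rna_min,rna_max Inclusive bounds on RNA counts; only applied to
#'   cells whose `rna_counts` is not `NA`.
#' @return A list of class `cell_qc_thresholds`.
#' @export
cell_qc_thresholds <- function(mito_frac_max = 0.1,
                               atac_min = 1000, atac_max = 70000,
                               rna_min = 500, rna_max = 25000) {
  stopifnot(mito_frac_max >= 0, mito_frac_max <= 1,
            atac_min < atac_max, rna_min < rna_max)
  structure(list(mito_frac_max = mito_frac_max,
                 atac_min = atac_min, atac_max = atac_max,
                 rna_min = rna_min, rna_max = rna_max),
            class = "cell_qc_thresholds")
}

#' Filter cell barcodes on quality-control statistics
#'
#' @param stats A data frame with columns `barcode`, `atac_fragments`,
#'   `mito_fragments` and optionally `rna_counts` (`NA` allowed when the
#'   RNA modality is absent for a cell).
#' @param thresholds A [cell_qc_thresholds()] object.
#' @return A tibble in input order with the input columns plus
#'   `mito_frac` and logical `retained`. Cells with zero ATAC fragments
#'   are rejected (not an error). Retained barcodes are
#'   `dplyr::filter(result, retained)$barcode`.
#' @export
apply_cell_qc <- function(stats, thresholds = cell_qc_thresholds()) {
  stopifnot(nrow(stats) > 0,
            all(c("barcode", "atac_fragments", "mito_fragments") %in% names(stats)))
  if (any(stats$mito_fragments > stats$atac_fragments, na.rm = TRUE)) {
    abort("mito_fragments cannot exceed atac_fragments")
  }
  out <- as_tibble(stats)
  if (!"rna_counts" %in% names(out)) out$rna_counts <- NA_real_
  out$mito_frac <- ifelse(out$atac_fragments > 0,
                          out$mito_fragments / out$atac_fragments, NA_real_)
  rna_ok <- is.na(out$rna_counts) |
    (out$rna_counts >= thresholds$rna_min & out$rna_counts <= thresholds$rna_max)
  out$retained <- out$atac_fragments > 0 &
    !is.na(out$mito_frac) & out$mito_frac < thresholds$mito_frac_max &
    out$atac_fragments >= thresholds$atac_min &
    out$atac_fragments <= thresholds$atac_max &
    rna_ok
  out
}

#' Monte Carlo permutation configuration
#'
#' @param n_permutations Number of random null regions per amplicon.
#' @param q_threshold Benjamini-Hochberg q-value below which a cell is
#'   called positive for an amplicon.
#' @param seed Integer seed controlling null-region placement.
#' @param region_length_mode How null regions are sized; currently only
#'   `"match_amplicon"` (each null region has the amplicon's total
#'   footprint length) is implemented.
#' @return A list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, q_threshold = 0.10,
                               seed = 1L,
                               region_length_mode = "match_amplicon") {
  stopifnot(is_count(n_permutations, min = 1),
            is_number(q_threshold), q_threshold > 0, q_threshold < 1)
  region_length_mode <- match.arg(region_length_mode, "match_amplicon")
  structure(list(n_permutations = as.integer(n_permutations),
                 q_threshold = q_threshold, seed = as.integer(seed),
                 region_length_mode = region_length_mode),
            class = "permutation_config")
}

#' Sample random contiguous null regions
#'
#' Draws `n` contiguous regions of a fixed length, uniformly over all
#' admissible placements in the genome: a placement is admissible when
#' the region lies fully on one chromosome and is disjoint from every
#' exclusion interval (centromeres, telomeres, known amplicons,
#' low-mappability regions, ...). Chromosomes are implicitly weighted by
#' their admissible start space, so sampling is uniform over placements
#' genome-wide.
#'
#' @param genome Genome tibble from [read_chrom_sizes()].
#' @param exclusions Intervals tibble (may have zero rows).
#' @param length Region length in bp.
#' @param n Number of regions to draw (with replacement across draws).
#' @param seed Integer seed; identical inputs and seed give identical
#'   regions.
#' @return A tibble of `n` intervals with columns `chrom`, `start`,
#'   `end`, `name`.
#' @export
sample_null_regions <- function(genome, exclusions, length, n, seed) {
  stopifnot(is_count(length, min = 1), is_count(n, min = 1))
  excl <- if (is.null(exclusions) || nrow(exclusions) == 0L) {
    tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    merge_intervals(validate_intervals(exclusions))
  }
  allowed <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[[i]]
    L <- genome$length[[i]]
    if (L < length) next
    # admissible integer starts: [0, L - length] minus, per exclusion
    # [a, b), the forbidden band [a - length + 1, b - 1]
    lo <- 0; hi <- L - length
    e <- excl[excl$chrom == chrom, , drop = FALSE]
    segs <- tibble(lo = lo, hi = hi)
    if (nrow(e) > 0L) {
      for (k in seq_len(nrow(e))) {
        flo <- e$start[[k]] - length + 1
        fhi <- e$end[[k]] - 1
        new <- list()
        for (s in seq_len(nrow(segs))) {
          slo <- segs$lo[[s]]; shi <- segs$hi[[s]]
          if (fhi < slo || flo > shi) {
            new[[length(new) + 1L]] <- c(slo, shi)
          } else {
            if (flo > slo) new[[length(new) + 1L]] <- c(slo, flo - 1)
            if (fhi < shi) new[[length(new) + 1L]] <- c(fhi + 1, shi)
          }
        }
        if (length(new) == 0L) { segs <- segs[0, ]; break }
        m <- do.call(rbind, new)
        segs <- tibble(lo = m[, 1], hi = m[, 2])
      }
    }
    if (nrow(segs) > 0L) {
      segs$chrom <- chrom
      allowed[[length(allowed) + 1L]] <- segs
    }
  }
  if (length(allowed) == 0L) {
    abort("genome exhausted: no admissible placement for the requested region length",
          class = "ecdnatools_genome_exhausted")
  }
  segs <- bind_rows(allowed)
  segs$w <- segs$hi - segs$lo + 1
  draw <- with_seed(seed, {
    pick <- sample.int(nrow(segs), n, replace = TRUE, prob = segs$w)
    list(chrom = segs$chrom[pick],
         start = segs$lo[pick] + floor(runif(n) * segs$w[pick]))
  })
  tibble(chrom = draw$chrom,
         start = draw$start,
         end = draw$start + length,
         name = sprintf("null_%d", seq_len(n)))
}

#' Per-cell scaled coverage of a region or multi-segment amplicon
#'
#' Counts, per cell barcode, the fragments overlapping the region (each
#' fragment once, any overlap of at least 1 bp, half-open semantics) and
#' divides by the total region length, giving fragments per bp.
#' Multi-segment amplicons pool counts over segments and divide by the
#' summed segment length.
#'
#' @param fragments Fragments tibble (see [read_fragments()]).
#' @param region Intervals tibble (one or more rows forming one region).
#' @param barcodes Optional character vector of barcodes to report
#'   (zero-coverage cells included); default all barcodes in `fragments`.
#' @return A tibble with columns `barcode`, `n_fragments`, `coverage`
#'   (fragments per bp).
#' @export
scaled_coverage <- function(fragments, region, barcodes = NULL) {
  validate_intervals(region)
  total_len <- sum(region$end - region$start)
  if (is.null(barcodes)) barcodes <- unique(fragments$barcode)
  hit <- rep(FALSE, nrow(fragments))
  for (i in seq_len(nrow(region))) {
    hit <- hit | (fragments$chrom == region$chrom[[i]] &
                    fragments$start < region$end[[i]] &
                    fragments$end > region$start[[i]])
  }
  counts <- table(factor(fragments$barcode[hit], levels = barcodes))
  tibble(barcode = barcodes,
         n_fragments = as.numeric(counts),
         coverage = as.numeric(counts) / total_len)
}

#' Empirical permutation p-value
#'
#' Computes \eqn{\hat{p} = (r + 1) / (n + 1)} where \eqn{r} is the number
#' of null statistics at least as large as the observed one (ties count
#' as exceeding, keeping the estimate conservative and bounded below by
#' \eqn{1/(n+1)}).
#'
#' @param observed Observed statistic (scaled coverage).
#' @param null_values Numeric vector of `n` null statistics.
#' @return A list with `r_exceed` and `p_emp`.
#' @export
empirical_pvalue <- function(observed, null_values) {
  if (length(null_values) < 1L) abort("null_values must be non-empty")
  r <- sum(null_values >= observed)
  list(r_exceed = r, p_emp = (r + 1) / (length(null_values) + 1))
}

#' Standardized coverage (z-score) against a permutation null
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of at least 2 null statistics.
#' @return `(observed - mean(null)) / sd(null)` (sample sd, denominator
#'   n-1), or `NA` with attribute `indeterminate = TRUE` when the null
#'   has zero variance.
#' @export
zscore <- function(observed, null_values) {
  if (length(null_values) < 2L) abort("need at least 2 null values")
  s <- sd(null_values)
  if (s == 0) {
    return(structure(NA_real_, indeterminate = TRUE))
  }
  (observed - mean(null_values)) / s
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment controlling the false discovery rate;
#' input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, `q >= p` elementwise.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Call ecDNA-containing cells from single-nucleus ATAC fragments
#'
#' For each declared amplicon, draws one shared set of
#' `config$n_permutations` random contiguous null regions (length-matched
#' to the amplicon's total footprint; the exclusion set always includes
#' all declared amplicons). Each cell's scaled coverage at the amplicon
#' is then compared to its own coverages at the shared null regions,
#' yielding a permutation p-value \eqn{(r+1)/(n+1)} and a z-score
#' against the null mean and standard deviation. Benjamini-Hochberg
#' adjustment is applied across cells separately per amplicon, and a
#' cell is called positive when `q < config$q_threshold`.
#'
#' @param fragments Fragments tibble, already restricted to QC-passing
#'   barcodes (see [apply_cell_qc()]); the mitochondrial contig may be
#'   present and is never sampled as a null region if excluded.
#' @param amplicons Intervals tibble with a `name` column; rows sharing a
#'   name form one (possibly multi-segment) amplicon.
#' @param exclusions Intervals tibble of regions never used as nulls
#'   (centromeres, telomeres, low-mappability, known ecDNA); may be empty.
#' @param genome Genome tibble.
#' @param config A [permutation_config()].
#' @param barcodes Optional explicit barcode universe; defaults to all
#'   barcodes present in `fragments`. Cells with zero fragments get
#'   `p_emp = 1` at every amplicon.
#' @return An object of class `cell_call_result`: a list with `calls`
#'   (tibble: `barcode`, `amplicon`, `observed`, `null_mean`, `null_sd`,
#'   `z`, `r_exceed`, `p_emp`, `q`, `called`, `indeterminate`),
#'   `cooccurrence` (tibble of cells per called-amplicon combination),
#'   `null_regions` (named list of tibbles) and `config`.
#' @export
call_cells <- function(fragments, amplicons, exclusions, genome,
                       config = permutation_config(), barcodes = NULL) {
  stopifnot(inherits(config, "permutation_config"))
  if (!"name" %in% names(amplicons) || any(is.na(amplicons$name))) {
    abort("amplicons need a 'name' column grouping segments")
  }
  validate_intervals(amplicons, genome)
  amp_names <- unique(amplicons$name)
  if (length(amp_names) == 0L) abort("no amplicons declared")
  user_excl <- if (is.null(exclusions) || nrow(exclusions) == 0L) {
    tibble(chrom = character(), start = numeric(), end = numeric())
  } else {
    validate_intervals(exclusions)
    as_tibble(exclusions[, c("chrom", "start", "end")])
  }
  # an amplicon overlapping a user exclusion is a configuration error
  for (i in seq_len(nrow(amplicons))) {
    ov <- user_excl$chrom == amplicons$chrom[[i]] &
      user_excl$start < amplicons$end[[i]] &
      user_excl$end > amplicons$start[[i]]
    if (any(ov)) {
      abort(sprintf("amplicon '%s' overlaps an exclusion region",
                    amplicons$name[[i]]))
    }
  }
  sampler_excl <- bind_rows(user_excl,
                            amplicons[, c("chrom", "start", "end")])

  if (is.null(barcodes)) barcodes <- unique(fragments$barcode)
  n_perm <- config$n_permutations

  # region table: amplicon segments plus per-amplicon null draws
  region_rows <- list()
  null_regions <- list()
  for (ai in seq_along(amp_names)) {
    a <- amp_names[[ai]]
    segs <- amplicons[amplicons$name == a, , drop = FALSE]
    len <- sum(segs$end - segs$start)
    nulls <- sample_null_regions(genome, sampler_excl, len, n_perm,
                                 seed = child_seed(config$seed, ai))
    null_regions[[a]] <- nulls
    region_rows[[length(region_rows) + 1L]] <- tibble(
      chrom = segs$chrom, start = segs$start, end = segs$end,
      amplicon = a, region_id = paste0("amp__", a), scale_len = len)
    region_rows[[length(region_rows) + 1L]] <- tibble(
      chrom = nulls$chrom, start = nulls$start, end = nulls$end,
      amplicon = a, region_id = paste0("null__", a, "__", seq_len(n_perm)),
      scale_len = len)
  }
  regions <- bind_rows(region_rows)

  counts <- count_fragment_region_overlaps(fragments, regions)

  calls <- list()
  for (ai in seq_along(amp_names)) {
    a <- amp_names[[ai]]
    len <- regions$scale_len[match(a, regions$amplicon)]
    amp_id <- paste0("amp__", a)
    null_ids <- paste0("null__", a, "__", seq_len(n_perm))
    sub <- counts[counts$amplicon == a, , drop = FALSE]
    # wide matrix: barcodes x (amp + null regions), zero-filled
    obs_n <- setNames(rep(0, length(barcodes)), barcodes)
    hit_amp <- sub[sub$region_id == amp_id, , drop = FALSE]
    obs_n[hit_amp$barcode] <- hit_amp$n
    nul <- sub[sub$region_id != amp_id, , drop = FALSE]
    M <- matrix(0, nrow = length(barcodes), ncol = n_perm,
                dimnames = list(barcodes, null_ids))
    if (nrow(nul) > 0L) {
      M[cbind(match(nul$barcode, barcodes), match(nul$region_id, null_ids))] <- nul$n
    }
    null_mean <- rowMeans(M)
    null_sd <- sqrt(pmax(0, (rowSums(M^2) - n_perm * null_mean^2) / (n_perm - 1)))
    r_exceed <- rowSums(M >= obs_n[barcodes])
    p_emp <- (r_exceed + 1) / (n_perm + 1)
    indeterminate <- null_sd == 0
    z <- ifelse(indeterminate, NA_real_,
                (obs_n[barcodes] - null_mean) / null_sd)
    q <- bh_adjust(p_emp)
    calls[[a]] <- tibble(
      barcode = barcodes, amplicon = a,
      observed = unname(obs_n[barcodes]) / len,
      null_mean = unname(null_mean) / len, null_sd = unname(null_sd) / len,
      z = unname(z), r_exceed = unname(r_exceed), p_emp = unname(p_emp),
      q = unname(q), called = unname(q < config$q_threshold),
      indeterminate = unname(indeterminate))
  }
  calls <- bind_rows(calls)
  structure(list(calls = calls,
                 cooccurrence = summarize_cooccurrence(calls),
                 null_regions = null_regions,
                 config = config),
            class = "cell_call_result")
}

# Fragment x region overlap counts via data.table::foverlaps.
# Half-open intervals are converted to closed by subtracting 1 from ends
# (all coordinates are integers). A fragment spanning two segments of
# the same amplicon is counted once for the pooled amplicon region.
# Only integer id pairs are materialized (which = TRUE) so that
# multi-million-fragment inputs stay within memory.
count_fragment_region_overlaps <- function(fragments, regions) {
  barcode_levels <- unique(fragments$barcode)
  frag <- data.table::data.table(
    chrom = fragments$chrom,
    start = as.integer(fragments$start),
    end = as.integer(fragments$end - 1),
    bc = match(fragments$barcode, barcode_levels))
  region_levels <- unique(regions$region_id)
  reg <- data.table::data.table(
    chrom = regions$chrom,
    start = as.integer(regions$start),
    end = as.integer(regions$end - 1),
    rid = match(regions$region_id, region_levels))
  data.table::setkey(reg, chrom, start, end)
  ov <- data.table::foverlaps(frag, reg, type = "any", which = TRUE,
                              nomatch = NULL)
  hits <- data.table::data.table(bc = frag$bc[ov$xid], rid = reg$rid[ov$yid],
                                 xid = ov$xid)
  rm(ov)
  hits <- unique(hits, by = c("xid", "rid"))
  out <- hits[, list(n = .N), by = list(bc, rid)]
  amp_of <- regions$amplicon[match(region_levels, regions$region_id)]
  tibble(barcode = barcode_levels[out$bc],
         amplicon = amp_of[out$rid],
         region_id = region_levels[out$rid],
         n = out$n)
}

#' Tabulate amplicon co-occurrence across called cells
#'
#' Partitions cells by the exact set of amplicons they were called
#' positive for ("none", each single amplicon, each pair, higher-order
#' combinations); every cell contributes to exactly one category.
#'
#' @param calls The `calls` tibble of a [call_cells()] result.
#' @return A tibble with `category`, `n_cells` and a `total_cells`
#'   attribute; category counts sum to the number of distinct barcodes.
#' @export
summarize_cooccurrence <- function(calls) {
  barcodes <- unique(calls$barcode)
  amp_names <- sort(unique(calls$amplicon))
  pos <- calls[calls$called, , drop = FALSE]
  sets <- split(pos$amplicon, pos$barcode)
  cat_of <- vapply(barcodes, function(b) {
    s <- sets[[b]]
    if (is.null(s) || length(s) == 0L) "none" else paste(sort(s), collapse = "+")
  }, character(1))
  tab <- table(cat_of)
  cats <- union(c("none", amp_names), names(tab))
  out <- tibble(category = cats,
                n_cells = as.numeric(tab[cats]))
  out$n_cells[is.na(out$n_cells)] <- 0
  attr(out, "total_cells") <- length(barcodes)
  out
}

#' Correlate per-cell z-scores with per-cell gene-set scores
#'
#' Pearson correlation (with the usual t-based two-sided p-value) over
#' the barcode intersection of a z-score table and an externally
#' computed per-cell activity score (for example a single-sample
#' gene-set enrichment score of ecDNA-borne genes).
#'
#' @param z_by_cell Data frame with columns `barcode` and `z`, or a named
#'   numeric vector.
#' @param score_by_cell Data frame with columns `barcode` and `score`, or
#'   a named numeric vector.
#' @return A tibble with `estimate` (Pearson r), `statistic`, `p.value`
#'   and `n` (shared cells).
#' @export
correlate_scores <- function(z_by_cell, score_by_cell) {
  z <- as_named_vector(z_by_cell, "z")
  s <- as_named_vector(score_by_cell, "score")
  shared <- intersect(names(z), names(s))
  if (length(shared) < 3L) abort("need at least 3 cells shared between mappings")
  zz <- z[shared]; ss <- s[shared]
  if (sd(zz) == 0 || sd(ss) == 0) abort("zero variance in z or score vector")
  ct <- cor.test(zz, ss, method = "pearson")
  tibble(estimate = unname(ct$estimate), statistic = unname(ct$statistic),
         p.value = ct$p.value, n = length(shared))
}

as_named_vector <- function(x, value_col) {
  if (is.data.frame(x)) {
    stopifnot(all(c("barcode", value_col) %in% names(x)))
    setNames(x[[value_col]], x$barcode)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Write per-cell call results to disk
#'
#' Writes the per-cell calls as TSV and the co-occurrence summary plus
#' configuration echo as JSON.
#'
#' @param result A [call_cells()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_call_results <- function(result, dir) {
  stopifnot(inherits(result, "cell_call_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$calls, file.path(dir, "cell_calls.tsv"))
  summary <- list(
    cooccurrence = as.list(setNames(result$cooccurrence$n_cells,
                                    result$cooccurrence$category)),
    total_cells = attr(result$cooccurrence, "total_cells"),
    config = unclass(result$config))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @export
tidy.cell_call_result <- function(x, ...) x$calls

#' @export
glance.cell_call_result <- function(x, ...) {
  tibble(n_cells = attr(x$cooccurrence, "total_cells"),
         n_amplicons = length(x$null_regions),
         n_called = length(unique(x$calls$barcode[x$calls$called])),
         n_permutations = x$config$n_permutations,
         q_threshold = x$config$q_threshold)
}

#' @export
autoplot.cell_call_result <- function(object, ...) {
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$amplicon, y = .data$z,
                               colour = .data$called)) +
    ggplot2::geom_jitter(width = 0.25, alpha = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "standardized read depth (z)",
                  colour = sprintf("q < %.2g", object$config$q_threshold)) +
    ggplot2::theme_minimal()
}
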