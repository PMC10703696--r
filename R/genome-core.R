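#' Read a chromosome sizes table
#'
#' Reads a two-column tab-separated file (chromosome name, length in bp)
#' such as a UCSC `chrom.sizes` file.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `chrom` (character) and `length`
#'   (integer bp), one row per chromosome, in file order.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr1\t1000", "chr2\t500"), tf)
#' read_chrom_sizes(tf)
read_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    abort(sprintf("%s: empty chromosome sizes file", path),
          class = "ecdnatools_format_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  chroms <- character(length(lines))
  lens <- numeric(length(lines))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 2L) stop_format(path, i, "expected two tab-separated columns")
    len <- suppressWarnings(as.numeric(p[[2L]]))
    if (is.na(len) || len != floor(len) || len <= 0) {
      stop_format(path, i, sprintf("chromosome length '%s' is not a positive integer", p[[2L]]))
    }
    if (p[[1L]] %in% chroms[seq_len(i - 1L)]) {
      stop_format(path, i, sprintf("duplicate chromosome name '%s'", p[[1L]]))
    }
    chroms[i] <- p[[1L]]
    lens[i] <- len
  }
  tibble(chrom = chroms, length = lens)
}

#' Read genomic intervals from a BED file
#'
#' Parses BED3+ records (0-based half-open coordinates). Columns beyond
#' the fourth (name) are ignored, as are `track`, `browser` and `#`
#' header lines.
#'
#' @param path Path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end` and `name`
#'   (`NA` when the file has no fourth column), in record order.
#' @export
read_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) &
    !grepl("^(track|browser|#)", lines)
  out <- list(chrom = character(), start = numeric(), end = numeric(),
              name = character())
  idx <- which(keep)
  chrom <- character(length(idx)); start <- numeric(length(idx))
  end <- numeric(length(idx)); name <- rep(NA_character_, length(idx))
  for (j in seq_along(idx)) {
    i <- idx[[j]]
    p <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(p) < 3L) stop_format(path, i, "expected at least 3 BED columns")
    s <- suppressWarnings(as.numeric(p[[2L]]))
    e <- suppressWarnings(as.numeric(p[[3L]]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      stop_format(path, i, "non-integer interval coordinates")
    }
    if (e <= s || s < 0) {
      stop_format(path, i, sprintf("invalid interval [%s, %s)", p[[2L]], p[[3L]]))
    }
    chrom[j] <- p[[1L]]; start[j] <- s; end[j] <- e
    if (length(p) >= 4L) name[j] <- p[[4L]]
  }
  tibble(chrom = chrom, start = start, end = end, name = name)
}

#' Write intervals to a BED file
#'
#' @param intervals A tibble with `chrom`, `start`, `end` and optionally
#'   `name` columns (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals) && !all(is.na(intervals$name))) {
    cols <- c(cols, "name")
  }
  df <- as.data.frame(intervals)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a single-nucleus ATAC fragments file
#'
#' Reads the 5-column `fragments.tsv` dialect (chrom, start, end, cell
#' barcode, duplicate-collapsed support count; 0-based half-open), plain
#' or gzip-compressed. Lines starting with `#` are skipped.
#'
#' @param path Path to a fragments TSV (`.gz` accepted).
#' @param genome Optional genome tibble (from [read_chrom_sizes()]); when
#'   supplied, fragments are checked to lie within chromosome bounds.
#' @return A tibble with columns `chrom`, `start`, `end`, `barcode`,
#'   `support`, in file order.
#' @export
read_fragments <- function(path, genome = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  barcode = character(), support = numeric()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5L)) {
    bad <- which(nf != 5L)[[1L]]
    stop_format(path, idx[[bad]],
                sprintf("expected 5 tab-separated columns, found %d", nf[[bad]]))
  }
  m <- matrix(unlist(parts), ncol = 5L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  support <- suppressWarnings(as.numeric(m[, 5L]))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | end <= start | start < 0)
  if (length(bad)) {
    stop_format(path, idx[[bad[[1L]]]], "invalid fragment coordinates")
  }
  bad <- which(is.na(support) | support < 1 | support != floor(support))
  if (length(bad)) {
    stop_format(path, idx[[bad[[1L]]]], "support count must be a positive integer")
  }
  frags <- tibble(chrom = m[, 1L], start = start, end = end,
                  barcode = m[, 4L], support = support)
  if (!is.null(genome)) {
    lens <- setNames(genome$length, genome$chrom)
    bad <- which(!(frags$chrom %in% genome$chrom) |
                   frags$end > lens[frags$chrom])
    if (length(bad)) {
      stop_format(path, idx[[bad[[1L]]]], "fragment outside chromosome bounds")
    }
  }
  frags
}

#' Write fragments to a TSV file
#'
#' @param fragments A fragments tibble (see [read_fragments()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(fragments, path) {
  stopifnot(all(c("chrom", "start", "end", "barcode", "support") %in%
                  names(fragments)))
  df <- as.data.frame(fragments)[, c("chrom", "start", "end", "barcode", "support")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  df$support <- format(df$support, scientific = FALSE, trim = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count fragments overlapping a region
#'
#' A fragment overlaps the region when the two half-open intervals share
#' at least 1 bp; each fragment counts once regardless of its `support`
#' column (support records collapsed PCR duplicates, not independent
#' molecules).
#'
#' @param fragments A fragments tibble.
#' @param region A one-row tibble or list with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return Integer number of overlapping fragments.
#' @export
overlap_count <- function(fragments, region) {
  stopifnot(region$end > region$start, region$start >= 0)
  sum(fragments$chrom == region$chrom &
        fragments$start < region$end &
        fragments$end > region$start)
}

# Validate an intervals tibble: half-open, non-negative, end > start.
validate_intervals <- function(intervals, genome = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(invisible(intervals))
  if (any(intervals$end <= intervals$start) || any(intervals$start < 0)) {
    abort("intervals must satisfy 0 <= start < end")
  }
  if (!is.null(genome)) {
    lens <- setNames(genome$length, genome$chrom)
    if (!all(intervals$chrom %in% genome$chrom)) {
      abort("interval chromosome absent from genome")
    }
    if (any(intervals$end > lens[intervals$chrom])) {
      abort("interval extends past chromosome end")
    }
  }
  invisible(intervals)
}

# Merge overlapping/adjacent intervals per chromosome; returns a tibble
# sorted by (chrom, start). Used by the null-region sampler.
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) return(intervals[, c("chrom", "start", "end")])
  dt <- data.table::as.data.table(intervals[, c("chrom", "start", "end")])
  data.table::setorder(dt, chrom, start)
  dt[, grp := cumsum(start > data.table::shift(cummax(end), fill = -Inf)),
     by = chrom]
  out <- dt[, list(start = min(start), end = max(end)), by = list(chrom, grp)]
  as_tibble(out[, list(chrom, start, end)])
}
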