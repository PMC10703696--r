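# Shared fixture builders; everything is generated in code at test time.

toy_genome <- function() {
  tibble::tibble(chrom = c("chr1", "chr2"), length = c(1e6, 5e5))
}

# A reduced fragment simulation for fast caller tests.
small_fragment_config <- function(seed = 1, n_cells = 120,
                                  background_mean = 1500, ...) {
  fragment_sim_config(
    n_cells = n_cells, background_mean = background_mean,
    genome = tibble::tibble(chrom = c("chr1", "chr2", "chrM"),
                            length = c(4e6, 4e6, 16569)),
    amplicons = tibble::tibble(chrom = "chr1", start = 1e6, end = 1.03e6,
                               name = "amp1"),
    exclusions = tibble::tibble(chrom = c("chr1", "chr2", "chrM"),
                                start = c(2e6, 2e6, 0),
                                end = c(2.1e6, 2.1e6, 16569)),
    seed = seed, ...)
}

run_small_caller <- function(seed = 1, n_perm = 200, ...) {
  sim <- gen_fragments(small_fragment_config(seed = seed, ...))
  qc <- apply_cell_qc(sim$qc)
  keep <- qc$barcode[qc$retained]
  res <- call_cells(dplyr::filter(sim$fragments, barcode %in% keep),
                    sim$amplicons, sim$exclusions, sim$genome,
                    permutation_config(n_permutations = n_perm,
                                       seed = seed + 100),
                    barcodes = keep)
  list(sim = sim, result = res, keep = keep)
}

# Render an image with Gaussian spots at given (row, col) centres.
render_spots <- function(centers, dim = c(120, 120), amplitude = 200,
                         sd = 2) {
  img <- matrix(0, dim[1], dim[2])
  for (cc in centers) {
    d2 <- outer((seq_len(dim[1]) - cc[1])^2, (seq_len(dim[2]) - cc[2])^2, "+")
    img <- img + amplitude * exp(-d2 / (2 * sd^2))
  }
  img
}

# Independent Benjamini-Hochberg step-up oracle, written directly from
# the step-up definition: q_(i) = min_{j >= i} m p_(j) / j, clipped at 1.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[ord[i]] / i)
    q_sorted[i] <- min(running, 1)
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher
# exact p-value.
fisher_enum_oracle <- function(m) {
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  k <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(k, c1, n - c1, r1)
  p0 <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}
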