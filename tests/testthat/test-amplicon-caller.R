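test_that("cell QC applies the documented thresholds and boundaries", {
  stats <- tibble::tibble(
    barcode = c("low", "ok", "mito_edge", "zero", "high", "rna_na", "rna_low"),
    atac_fragments = c(999, 5000, 5000, 0, 70001, 5000, 5000),
    mito_fragments = c(0, 499, 500, 0, 0, 10, 10),
    rna_counts = c(600, 600, 600, 600, 600, NA, 499))
  out <- apply_cell_qc(stats)
  expect_equal(out$barcode, stats$barcode)  # input order preserved
  expect_equal(out$retained,
               c(FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # mito fraction 499/5000 = 0.0998 < 0.1 retained; 0.1 is not < 0.1
  expect_true(out$retained[out$barcode == "ok"])
})

test_that("null regions are length-matched, in bounds, seeded and exclusion-disjoint", {
  g <- tibble::tibble(chrom = "chr1", length = 1000)
  none <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  r <- sample_null_regions(g, none, length = 100, n = 5, seed = 1)
  expect_equal(nrow(r), 5)
  expect_true(all(r$start >= 0 & r$start <= 900))
  expect_equal(r$end - r$start, rep(100, 5))
  expect_identical(r, sample_null_regions(g, none, 100, 5, seed = 1))

  full <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  expect_error(sample_null_regions(g, full, 100, 5, seed = 1), "exhausted")
  expect_error(sample_null_regions(g, none, 2000, 5, seed = 1), "exhausted")

  # property: regions stay disjoint from exclusions across seeds
  excl <- tibble::tibble(chrom = c("chr1", "chr1"), start = c(200, 700),
                         end = c(400, 750))
  for (s in 1:5) {
    r <- sample_null_regions(g, excl, 50, 50, seed = s)
    hits <- mapply(function(st, en) {
      any(excl$start < en & excl$end > st)
    }, r$start, r$end)
    expect_false(any(hits))
  }
})

test_that("scaled coverage divides pooled overlap counts by total footprint", {
  frags <- tibble::tibble(
    chrom = "chr1",
    start = c(100, 150, 200, 300, 400, 5000),
    end = c(140, 190, 260, 360, 440, 5100),
    barcode = "cellA", support = 1)
  region <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  cov <- scaled_coverage(frags, region)
  expect_equal(cov$coverage, 5 / 1000)
  cov0 <- scaled_coverage(frags, region, barcodes = c("cellA", "empty"))
  expect_equal(cov0$coverage[cov0$barcode == "empty"], 0)
  # two segments 600 + 400 bp with 3 + 2 overlapping fragments -> 5/1000
  segs <- tibble::tibble(chrom = "chr1", start = c(100, 5000),
                         end = c(700, 5400))
  frag2 <- tibble::tibble(
    chrom = "chr1",
    start = c(110, 120, 130, 5010, 5020),
    end = c(150, 160, 170, 5050, 5060),
    barcode = "cellA", support = 1)
  expect_equal(scaled_coverage(frag2, segs)$coverage, 5 / 1000)
})

test_that("empirical p-values follow (r+1)/(n+1) with ties counted as exceeding", {
  nulls <- runif(1000, 0.001, 0.01)
  top <- empirical_pvalue(max(nulls) + 1, nulls)
  expect_equal(top$r_exceed, 0)
  expect_equal(top$p_emp, 1 / 1001)
  bottom <- empirical_pvalue(min(nulls) - 1, nulls)
  expect_equal(bottom$p_emp, 1)
  # 490 strictly above, 10 tied, 500 below -> r = 500, p = 501/1001
  obs <- 0.5
  nulls <- c(runif(490, 0.6, 1), rep(0.5, 10), runif(500, 0, 0.4))
  e <- empirical_pvalue(obs, nulls)
  expect_equal(e$r_exceed, 500)
  expect_equal(e$p_emp, 501 / 1001)
  expect_error(empirical_pvalue(1, numeric()), "non-empty")
})

test_that("z-scores standardize against the null and flag degenerate nulls", {
  expect_equal(zscore(0.002, c(0, 0.002, 0.004)), 0)
  expect_equal(zscore(0.006, c(0, 0.002, 0.004)), 2)
  z <- zscore(5, c(1, 1, 1))
  expect_true(is.na(z))
  expect_true(attr(z, "indeterminate"))
  expect_error(zscore(1, 1), "at least 2")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), bh_stepup_oracle(p))
  }
})

test_that("the caller is deterministic and respects p/q invariants", {
  run1 <- run_small_caller(seed = 2)
  run2 <- run_small_caller(seed = 2)
  expect_identical(run1$result$calls, run2$result$calls)

  calls <- run1$result$calls
  n <- run1$result$config$n_permutations
  expect_true(all(calls$p_emp >= 1 / (n + 1) & calls$p_emp <= 1))
  expect_true(all(calls$q >= calls$p_emp))
  expect_true(all(calls$called == (calls$q < 0.10)))

  co <- run1$result$cooccurrence
  expect_equal(sum(co$n_cells), attr(co, "total_cells"))
})

test_that("a cell with zero fragments gets p_emp = 1 at every amplicon", {
  sim <- gen_fragments(small_fragment_config(seed = 3))
  keep <- head(unique(sim$fragments$barcode), 30)
  frags <- dplyr::filter(sim$fragments, barcode %in% keep)
  res <- call_cells(frags, sim$amplicons, sim$exclusions, sim$genome,
                    permutation_config(n_permutations = 100, seed = 5),
                    barcodes = c(keep, "ghost_cell"))
  ghost <- dplyr::filter(res$calls, barcode == "ghost_cell")
  expect_equal(ghost$p_emp, rep(1, nrow(ghost)))
  expect_false(any(ghost$called))
})

test_that("adding amplicon fragments to a cell never increases its p-value", {
  sim <- gen_fragments(small_fragment_config(seed = 4))
  keep <- head(unique(sim$fragments$barcode), 40)
  frags <- dplyr::filter(sim$fragments, barcode %in% keep)
  cfg <- permutation_config(n_permutations = 100, seed = 6)
  base <- call_cells(frags, sim$amplicons, sim$exclusions, sim$genome, cfg,
                     barcodes = keep)
  target <- keep[[1]]
  amp <- sim$amplicons[1, ]
  for (extra in c(2, 10, 40)) {
    add <- tibble::tibble(chrom = amp$chrom,
                          start = amp$start + seq_len(extra) * 7,
                          end = amp$start + seq_len(extra) * 7 + 150,
                          barcode = target, support = 1)
    res <- call_cells(dplyr::bind_rows(frags, add), sim$amplicons,
                      sim$exclusions, sim$genome, cfg, barcodes = keep)
    p_new <- res$calls$p_emp[res$calls$barcode == target &
                               res$calls$amplicon == "amp1"]
    p_old <- base$calls$p_emp[base$calls$barcode == target &
                                base$calls$amplicon == "amp1"]
    expect_lte(p_new, p_old)
  }
})

test_that("false discoveries among called cells stay near the q threshold", {
  fdrs <- c()
  for (s in 1:2) {
    run <- run_small_caller(seed = 10 + s, n_perm = 300)
    tr <- dplyr::inner_join(run$result$calls, run$sim$truth,
                            by = c("barcode", "amplicon"))
    called <- dplyr::filter(tr, called)
    if (nrow(called) > 0) fdrs <- c(fdrs, mean(called$copy_number == 2))
  }
  expect_true(all(fdrs <= 0.10 + 0.05))
})

test_that("an amplicon overlapping a user exclusion is a configuration error", {
  sim <- gen_fragments(small_fragment_config(seed = 5))
  bad_excl <- dplyr::bind_rows(sim$exclusions, sim$amplicons[1, 1:3])
  expect_error(
    call_cells(head(sim$fragments, 1000), sim$amplicons, bad_excl,
               sim$genome, permutation_config(n_permutations = 10, seed = 1)),
    "overlaps an exclusion")
})

test_that("call results write to TSV + JSON and reload consistently", {
  run <- run_small_caller(seed = 6, n_cells = 40, n_perm = 50)
  dir <- withr::local_tempdir()
  write_call_results(run$result, dir)
  reread <- readr::read_tsv(file.path(dir, "cell_calls.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(reread), nrow(run$result$calls))
  expect_equal(reread$p_emp, run$result$calls$p_emp)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$total_cells, attr(run$result$cooccurrence, "total_cells"))
  expect_equal(js$config$n_permutations, 50)
})

test_that("z-score / gene-set score correlation behaves at the extremes", {
  z <- tibble::tibble(barcode = letters[1:10], z = 1:10)
  s <- tibble::tibble(barcode = letters[1:10], score = 2 * (1:10) + 1)
  expect_equal(correlate_scores(z, s)$estimate, 1)
  s_rev <- tibble::tibble(barcode = letters[1:3], score = c(3, 2, 1))
  z3 <- tibble::tibble(barcode = letters[1:3], z = c(1, 2, 3))
  expect_equal(correlate_scores(z3, s_rev)$estimate, -1)
  expect_error(correlate_scores(z3[1:2, ], s_rev), "at least 3")
  s_const <- tibble::tibble(barcode = letters[1:5], score = rep(1, 5))
  expect_error(correlate_scores(z[1:5, ], s_const), "variance")
  # independent scores decorrelate in large samples
  set.seed(99)
  zz <- setNames(rnorm(1000), paste0("c", 1:1000))
  ss <- setNames(rnorm(1000), paste0("c", 1:1000))
  expect_lt(abs(correlate_scores(zz, ss)$estimate), 0.1)
})
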