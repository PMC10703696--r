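# Synthetic-data generators. Every generator is a pure function of its
# configuration and seed, emits ground truth alongside the data, and
# produces files/tables that parse cleanly through the package readers.

#' Toy genome used by the fragment simulator
#'
#' Three 10-Mbp autosomes plus a mitochondrial contig; small enough that
#' a full permutation-caller run finishes in minutes yet large enough
#' that 1,000 random 50-kb null regions sample a diverse background.
#'
#' @return A genome tibble (`chrom`, `length`).
#' @export
default_genome <- function() {
  tibble(chrom = c("chr1", "chr2", "chr3", "chrM"),
         length = c(1e7, 1e7, 1e7, 16569))
}

#' Default amplicon definitions for the fragment simulator
#'
#' Two focal amplifications: a contiguous 50-kb amplicon on chr1 and a
#' two-segment amplicon on chr2 (25 kb + 15 kb), mimicking an ecDNA
#' whose reference footprint is discontiguous.
#'
#' @return An intervals tibble with a `name` column.
#' @export
default_amplicons <- function() {
  tibble(chrom = c("chr1", "chr2", "chr2"),
         start = c(3.0e6, 6.0e6, 6.2e6),
         end = c(3.05e6, 6.025e6, 6.215e6),
         name = c("amp1", "amp2", "amp2"))
}

#' Default exclusion regions for the fragment simulator
#'
#' A 200-kb centromere-like band in the middle of each autosome,
#' standing in for the centromere/telomere/low-mappability exclusion
#' lists used with real genomes. The mitochondrial contig is excluded
#' entirely.
#'
#' @return An intervals tibble.
#' @export
default_exclusions <- function() {
  tibble(chrom = c("chr1", "chr2", "chr3", "chrM"),
         start = c(4.9e6, 4.9e6, 4.9e6, 0),
         end = c(5.1e6, 5.1e6, 5.1e6, 16569))
}

#' Configuration for the single-nucleus fragment simulator
#'
#' Defaults emulate a tumor in which 10% of cells carry each ecDNA
#' amplicon at a heterogeneous copy number (integer log-normal, median
#' 20, minimum 5), against a background of ~5,000 uniformly placed
#' fragments per cell and a small mitochondrial fraction.
#'
#' @param n_cells Number of cells.
#' @param frac_positive Fraction of cells positive for each amplicon
#'   (drawn independently per amplicon).
#' @param cn_meanlog,cn_sdlog,cn_min Copy-number distribution for
#'   positive cells: `pmax(cn_min, round(rlnorm(cn_meanlog, cn_sdlog)))`.
#' @param background_mean Poisson mean of background fragments per cell.
#' @param frag_len_range Fragment length range (uniform integer, bp).
#' @param mito_beta Two shape parameters of the Beta distribution of the
#'   per-cell mitochondrial fragment fraction.
#' @param rna_meanlog,rna_sdlog Log-normal parameters of the synthetic
#'   RNA counts reported in the QC table (independent of copy number).
#' @param genome,amplicons,exclusions Genome geometry (see
#'   [default_genome()], [default_amplicons()], [default_exclusions()]).
#' @param mito_chrom Name of the mitochondrial contig.
#' @param seed Integer seed.
#' @return A list of class `fragment_sim_config`.
#' @export
fragment_sim_config <- function(n_cells = 2000, frac_positive = 0.10,
                                cn_meanlog = log(20), cn_sdlog = 0.4,
                                cn_min = 5,
                                background_mean = 5000,
                                frag_len_range = c(100, 400),
                                mito_beta = c(4, 76),
                                rna_meanlog = log(5000), rna_sdlog = 0.3,
                                genome = default_genome(),
                                amplicons = default_amplicons(),
                                exclusions = default_exclusions(),
                                mito_chrom = "chrM",
                                seed = 1L) {
  stopifnot(is_count(n_cells, 1), frac_positive >= 0, frac_positive <= 1,
            background_mean > 0, cn_min >= 1)
  validate_intervals(amplicons, genome)
  structure(list(n_cells = n_cells, frac_positive = frac_positive,
                 cn_meanlog = cn_meanlog, cn_sdlog = cn_sdlog,
                 cn_min = cn_min, background_mean = background_mean,
                 frag_len_range = frag_len_range, mito_beta = mito_beta,
                 rna_meanlog = rna_meanlog, rna_sdlog = rna_sdlog,
                 genome = genome, amplicons = amplicons,
                 exclusions = exclusions, mito_chrom = mito_chrom,
                 seed = as.integer(seed)),
            class = "fragment_sim_config")
}

#' Simulate single-nucleus ATAC fragments with known copy-number truth
#'
#' Background fragments are placed uniformly over the autosomes with a
#' Poisson per-cell count. For a cell positive at an amplicon with copy
#' number k, additional amplicon-overlapping fragments are added so the
#' expected per-bp fragment rate there is `k/2` times the cell's
#' background rate (diploid background corresponds to k = 2).
#' Mitochondrial fragments are appended per the configured fraction.
#'
#' @param config A [fragment_sim_config()].
#' @return A list with `fragments` (tibble sorted by position), `qc`
#'   (per-cell QC statistics), `truth` (tibble: `barcode`, `amplicon`,
#'   `copy_number`, `is_positive`), and the geometry (`genome`,
#'   `amplicons`, `exclusions`, `config`).
#' @export
gen_fragments <- function(config = fragment_sim_config()) {
  stopifnot(inherits(config, "fragment_sim_config"))
  gn <- config$genome
  amp <- config$amplicons
  if (!all(amp$chrom %in% gn$chrom)) abort("amplicon outside genome")
  autos <- gn[gn$chrom != config$mito_chrom, , drop = FALSE]
  G <- sum(autos$length)
  n <- config$n_cells
  barcodes <- sprintf("cell_%05d", seq_len(n))
  amp_names <- unique(amp$name)

  with_seed(config$seed, {
    n_bg <- rpois(n, config$background_mean)

    # ground truth copy numbers
    truth <- purrr::map_dfr(amp_names, function(a) {
      pos <- runif(n) < config$frac_positive
      cn <- ifelse(pos,
                   pmax(config$cn_min,
                        round(rlnorm(n, config$cn_meanlog, config$cn_sdlog))),
                   2)
      tibble(barcode = barcodes, amplicon = a, copy_number = cn,
             is_positive = pos)
    })

    # background fragments, uniform over autosomes
    N <- sum(n_bg)
    ci <- sample.int(nrow(autos), N, replace = TRUE, prob = autos$length)
    len <- sample(config$frag_len_range[1]:config$frag_len_range[2], N,
                  replace = TRUE)
    start <- floor(runif(N) * (autos$length[ci] - len))
    bg <- data.table::data.table(
      chrom = autos$chrom[ci], start = start, end = start + len,
      barcode = rep(barcodes, n_bg))

    # amplicon excess for positive cells: rate x L x (k/2 - 1) extra
    extra_list <- list()
    rate <- n_bg / G
    segs_by_amp <- split(amp, amp$name)
    extra_per_cell <- numeric(n)
    for (a in amp_names) {
      segs <- segs_by_amp[[a]]
      L <- sum(segs$end - segs$start)
      tr <- truth[truth$amplicon == a, ]
      lambda <- rate * L * pmax(0, tr$copy_number / 2 - 1)
      n_extra <- rpois(n, lambda)
      extra_per_cell <- extra_per_cell + n_extra
      M <- sum(n_extra)
      if (M > 0) {
        si <- sample.int(nrow(segs), M, replace = TRUE,
                         prob = segs$end - segs$start)
        elen <- sample(config$frag_len_range[1]:config$frag_len_range[2], M,
                       replace = TRUE)
        estart <- segs$start[si] +
          floor(runif(M) * (segs$end[si] - segs$start[si]))
        extra_list[[a]] <- data.table::data.table(
          chrom = segs$chrom[si], start = estart, end = estart + elen,
          barcode = rep(barcodes, n_extra))
      }
    }

    # mitochondrial fragments per the configured fraction
    nuclear <- n_bg + extra_per_cell
    mito_frac <- stats::rbeta(n, config$mito_beta[1], config$mito_beta[2])
    n_mito <- round(mito_frac / (1 - mito_frac) * nuclear)
    Lm <- gn$length[gn$chrom == config$mito_chrom]
    mito <- NULL
    if (length(Lm) == 1 && sum(n_mito) > 0) {
      M <- sum(n_mito)
      mlen <- sample(config$frag_len_range[1]:config$frag_len_range[2], M,
                     replace = TRUE)
      mlen <- pmin(mlen, Lm - 1)
      mstart <- floor(runif(M) * (Lm - mlen))
      mito <- data.table::data.table(
        chrom = config$mito_chrom, start = mstart, end = mstart + mlen,
        barcode = rep(barcodes, n_mito))
    } else {
      n_mito <- rep(0, n)
    }

    frags <- data.table::rbindlist(c(list(bg), extra_list, list(mito)),
                                   use.names = TRUE)
    frags[, support := 1L + rpois(.N, 0.1)]
    data.table::setorder(frags, chrom, start, end, barcode)

    qc <- tibble(
      barcode = barcodes,
      atac_fragments = nuclear + n_mito,
      mito_fragments = n_mito,
      rna_counts = round(rlnorm(n, config$rna_meanlog, config$rna_sdlog)))

    list(fragments = as_tibble(frags), qc = qc, truth = truth,
         genome = gn, amplicons = amp, exclusions = config$exclusions,
         config = config)
  })
}

#' Write a fragment simulation to disk in the standard file dialects
#'
#' @param sim A [gen_fragments()] result.
#' @param dir Output directory (created if needed); writes
#'   `fragments.tsv.gz`, `qc.tsv`, `amplicons.bed`, `exclusions.bed`,
#'   `genome.chrom.sizes` and `truth/copy_number.tsv`.
#' @return `dir`, invisibly.
#' @export
write_fragment_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_fragments(sim$fragments, file.path(dir, "fragments.tsv.gz"))
  readr::write_tsv(sim$qc, file.path(dir, "qc.tsv"))
  write_bed(sim$amplicons, file.path(dir, "amplicons.bed"))
  write_bed(sim$exclusions, file.path(dir, "exclusions.bed"))
  utils::write.table(
    data.frame(sim$genome$chrom,
               format(sim$genome$length, scientific = FALSE, trim = TRUE)),
    file.path(dir, "genome.chrom.sizes"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth", "copy_number.tsv"))
  invisible(dir)
}

#' Configuration for the FISH image simulator
#'
#' Defaults draw disjoint circular nuclei on a dark canvas and render
#' per-nucleus FISH spots as Gaussian peaks. Per-cell spot counts follow
#' a mixture of a background Poisson (mean 2, non-amplified cells) and
#' an amplified Poisson (mean 20), matching the bimodal per-cell copy
#' number seen in ecDNA+ tumors. Spots are kept at least
#' `min_separation` pixels apart so that the sigma-3 detector can
#' resolve them; the amplitude is chosen to clear the fixed threshold
#' after smoothing while keeping neighbouring spots separable.
#'
#' @param canvas Image dimensions (rows, cols) in pixels.
#' @param n_nuclei Number of nuclei.
#' @param radius_range Nucleus radius range in pixels.
#' @param mix_fraction Fraction of amplified cells.
#' @param bg_mean,amp_mean Poisson means of per-cell spot counts for
#'   non-amplified and amplified cells.
#' @param spot_amplitude Peak spot intensity (0-255 scale).
#' @param spot_sd Spot Gaussian standard deviation in pixels.
#' @param min_separation Minimum pairwise distance between spot centres.
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param seed Integer seed.
#' @return A list of class `fish_sim_config`.
#' @export
fish_sim_config <- function(canvas = c(1000, 1000), n_nuclei = 10,
                            radius_range = c(36, 44), mix_fraction = 0.3,
                            bg_mean = 2, amp_mean = 20,
                            spot_amplitude = 40, spot_sd = 3,
                            min_separation = 16, noise_sd = 0,
                            seed = 1L) {
  stopifnot(spot_amplitude <= 255, spot_amplitude > 0,
            min_separation >= 4 * spot_sd, noise_sd >= 0)
  structure(list(canvas = canvas, n_nuclei = n_nuclei,
                 radius_range = radius_range, mix_fraction = mix_fraction,
                 bg_mean = bg_mean, amp_mean = amp_mean,
                 spot_amplitude = spot_amplitude, spot_sd = spot_sd,
                 min_separation = min_separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fish_sim_config")
}

#' Simulate a FISH image, segmentation mask and spot-count truth
#'
#' Nuclei are disjoint disks; per-nucleus spot counts are drawn from the
#' configured mixture and rendered as Gaussian peaks at random
#' in-nucleus positions with a global minimum pairwise separation. If a
#' spot cannot be placed after bounded retries the count is reduced and
#' the achieved count recorded in the truth table. Pixel noise is added
#' and the image clipped to 0-255 and rounded to 8-bit.
#'
#' @param config A [fish_sim_config()].
#' @return A list with `image` (numeric matrix), `mask` (integer
#'   labelled matrix), `truth` (tibble: `cell_id`, `spot_count`,
#'   `amplified_mixture`) and `config`.
#' @export
gen_fish_image <- function(config = fish_sim_config()) {
  stopifnot(inherits(config, "fish_sim_config"))
  nr <- config$canvas[1]; nc <- config$canvas[2]
  with_seed(config$seed, {
    rmax <- config$radius_range[2]
    centers <- matrix(numeric(0), ncol = 3)
    tries <- 0
    while (nrow(centers) < config$n_nuclei && tries < 20000) {
      tries <- tries + 1
      r <- runif(1, config$radius_range[1], config$radius_range[2])
      cy <- runif(1, r + 2, nr - r - 2)
      cx <- runif(1, r + 2, nc - r - 2)
      ok <- TRUE
      if (nrow(centers) > 0) {
        d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
        ok <- all(d >= centers[, 3] + r + 8)
      }
      if (ok) centers <- rbind(centers, c(cy, cx, r))
    }
    if (nrow(centers) < config$n_nuclei) {
      abort("could not place the requested number of disjoint nuclei")
    }

    mask <- matrix(0L, nr, nc)
    for (i in seq_len(nrow(centers))) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; r <- centers[i, 3]
      rows <- max(1, floor(cy - r)):min(nr, ceiling(cy + r))
      cols <- max(1, floor(cx - r)):min(nc, ceiling(cx + r))
      d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
      sel <- d2 <= r^2
      sub <- mask[rows, cols]
      sub[sel] <- i
      mask[rows, cols] <- sub
    }

    amplified <- runif(config$n_nuclei) < config$mix_fraction
    target <- rpois(config$n_nuclei,
                    ifelse(amplified, config$amp_mean, config$bg_mean))

    image <- matrix(0, nr, nc)
    sep2 <- config$min_separation^2
    placed_all <- matrix(numeric(0), ncol = 2)
    achieved <- integer(config$n_nuclei)
    rad <- ceiling(3 * config$spot_sd)
    for (i in seq_len(config$n_nuclei)) {
      cy <- centers[i, 1]; cx <- centers[i, 2]; r <- centers[i, 3]
      inner <- r - 2 * config$spot_sd
      for (s in seq_len(target[i])) {
        placed <- FALSE
        for (try in seq_len(200)) {
          ang <- runif(1, 0, 2 * pi)
          rr <- sqrt(runif(1)) * inner
          py <- cy + rr * sin(ang); px <- cx + rr * cos(ang)
          if (nrow(placed_all) > 0) {
            d2 <- (placed_all[, 1] - py)^2 + (placed_all[, 2] - px)^2
            if (any(d2 < sep2)) next
          }
          placed_all <- rbind(placed_all, c(py, px))
          placed <- TRUE
          break
        }
        if (!placed) break
        achieved[i] <- achieved[i] + 1
        rows <- max(1, floor(py - rad)):min(nr, ceiling(py + rad))
        cols <- max(1, floor(px - rad)):min(nc, ceiling(px + rad))
        d2 <- outer((rows - py)^2, (cols - px)^2, "+")
        image[rows, cols] <- image[rows, cols] +
          config$spot_amplitude * exp(-d2 / (2 * config$spot_sd^2))
      }
    }
    if (config$noise_sd > 0) {
      image <- image + rnorm(nr * nc, 0, config$noise_sd)
    }
    image <- round(pmin(pmax(image, 0), 255))
    truth <- tibble(cell_id = seq_len(config$n_nuclei),
                    spot_count = achieved,
                    amplified_mixture = amplified)
    list(image = image, mask = mask, truth = truth, config = config)
  })
}

#' Simulate SNP-panel allele counts for fingerprinting
#'
#' Fabricates a panel of `panel_size` common biallelic loci with
#' population allele frequencies uniform on (0.2, 0.8) — highly
#' variable sites, as used for fingerprinting panels, which keeps the
#' allele-frequency structure shared across unrelated patients from
#' inflating their correlation. Each patient receives a
#' Hardy-Weinberg genotype (VAF 0, 0.5 or 1) per locus; duplicate
#' samples share their patient's genotype. Observed alt counts are
#' binomial draws at Poisson-distributed depth with a symmetric
#' per-read error rate.
#'
#' @param n_patients Number of distinct patients.
#' @param n_duplicate_pairs Number of patients contributing two samples.
#' @param panel_size Number of SNP loci.
#' @param depth Mean sequencing depth per locus.
#' @param error_rate Per-read allele error rate.
#' @param seed Integer seed.
#' @return A list with `panel` (tibble: `locus`, `chrom`, `pos0`,
#'   `pos1`, `ref`, `alt`), `counts` (long tibble: `sample_id`, `locus`,
#'   `ref_count`, `alt_count`), `truth` (tibble: `sample_id`,
#'   `patient_id`) and the arguments as `config`.
#' @export
gen_fingerprints <- function(n_patients = 20, n_duplicate_pairs = 2,
                             panel_size = 1000, depth = 30,
                             error_rate = 0.01, seed = 1L) {
  stopifnot(depth >= 1, n_duplicate_pairs <= n_patients)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    panel <- tibble(
      locus = seq_len(panel_size),
      chrom = sample(paste0("chr", 1:22), panel_size, replace = TRUE),
      pos0 = sort(sample.int(2e8, panel_size)),
      ref = sample(bases, panel_size, replace = TRUE))
    panel$pos1 <- panel$pos0 + 1
    panel$alt <- vapply(panel$ref, function(r) sample(setdiff(bases, r), 1),
                        character(1))
    panel <- panel[, c("locus", "chrom", "pos0", "pos1", "ref", "alt")]
    af <- runif(panel_size, 0.2, 0.8)

    geno <- matrix(0, nrow = panel_size, ncol = n_patients)
    for (p in seq_len(n_patients)) {
      u <- runif(panel_size)
      g <- ifelse(u < (1 - af)^2, 0, ifelse(u < (1 - af)^2 + 2 * af * (1 - af),
                                            0.5, 1))
      geno[, p] <- g
    }

    patients <- sprintf("patient_%02d", seq_len(n_patients))
    sample_patient <- c(seq_len(n_patients),
                        seq_len(n_duplicate_pairs))
    dup_ids <- if (n_duplicate_pairs > 0) {
      paste0(patients[seq_len(n_duplicate_pairs)], "_b")
    } else {
      character(0)
    }
    sample_ids <- c(paste0(patients, "_a"), dup_ids)
    counts <- purrr::map_dfr(seq_along(sample_ids), function(si) {
      g <- geno[, sample_patient[[si]]]
      dp <- rpois(panel_size, depth)
      p_obs <- g + error_rate * (1 - 2 * g)
      alt <- rbinom(panel_size, dp, p_obs)
      tibble(sample_id = sample_ids[[si]], locus = panel$locus,
             ref_count = dp - alt, alt_count = alt)
    })
    truth <- tibble(sample_id = sample_ids,
                    patient_id = patients[sample_patient])
    list(panel = panel, counts = counts, truth = truth,
         config = list(n_patients = n_patients,
                       n_duplicate_pairs = n_duplicate_pairs,
                       panel_size = panel_size, depth = depth,
                       error_rate = error_rate, seed = seed))
  })
}

#' Configuration for the survival cohort simulator
#'
#' Generates cohorts from a log-normal accelerated failure time model
#' with a binary exposure (e.g. TP53 alteration) acting on survival
#' partly through a binary mediator (e.g. ecDNA presence):
#' `logit P(M = 1 | E) = a0 + a1 E` and
#' `log T = beta0 + beta_E E + beta_M M + sigma N(0,1)`, with uniform
#' right-censoring on `(0, censor_window)`. Default effect sizes give
#' mediator survival effects of the magnitude reported for ecDNA+
#' tumors (time ratio ~ 0.4, i.e. strongly adverse) and roughly 30%
#' censoring.
#'
#' @param n_patients Cohort size.
#' @param p_exposure Exposure prevalence.
#' @param a0,a1 Mediator-model logistic coefficients.
#' @param beta0 Baseline log survival time (log days).
#' @param beta_e Direct exposure effect on log time.
#' @param beta_m Mediator effect on log time.
#' @param sigma Log-time residual standard deviation.
#' @param censor_window Upper bound of the uniform censoring time (days).
#' @param seed Integer seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_patients = 500, p_exposure = 0.25,
                              a0 = -2, a1 = 3,
                              beta0 = 7.0, beta_e = -0.4, beta_m = -0.9,
                              sigma = 0.8, censor_window = 4000,
                              seed = 1L) {
  stopifnot(sigma > 0, p_exposure > 0, p_exposure < 1, censor_window > 0)
  structure(list(n_patients = n_patients, p_exposure = p_exposure,
                 a0 = a0, a1 = a1, beta0 = beta0, beta_e = beta_e,
                 beta_m = beta_m, sigma = sigma,
                 censor_window = censor_window, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate a survival cohort with a binary mediator
#'
#' @param config A [cohort_sim_config()].
#' @return A list with `cohort` (tibble: `sample_id`, `time`, `event`,
#'   `tp53` = exposure, `ecDNA` = mediator, plus decoy covariates
#'   `subgroup`, `age`, `sex` with no effect on survival) and `truth`
#'   (the generating parameters).
#' @export
gen_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  n <- config$n_patients
  with_seed(config$seed, {
    e <- rbinom(n, 1, config$p_exposure)
    pm <- 1 / (1 + exp(-(config$a0 + config$a1 * e)))
    m <- rbinom(n, 1, pm)
    log_t <- config$beta0 + config$beta_e * e + config$beta_m * m +
      config$sigma * rnorm(n)
    t_true <- exp(log_t)
    c_time <- runif(n, 0, config$censor_window)
    cohort <- tibble(
      sample_id = sprintf("pt_%04d", seq_len(n)),
      time = pmin(t_true, c_time),
      event = as.integer(t_true <= c_time),
      tp53 = e, ecDNA = m,
      subgroup = sample(c("SHH", "Group3", "Group4", "WNT"), n,
                        replace = TRUE, prob = c(0.30, 0.25, 0.40, 0.05)),
      age = round(runif(n, 1, 18), 1),
      sex = rbinom(n, 1, 0.5))
    list(cohort = cohort, truth = unclass(config))
  })
}

#' Simulate a proportional-hazards cohort with one binary covariate
#'
#' Exponential baseline hazard with a multiplicative effect
#' `hazard_ratio` for the exposed half of the cohort and uniform
#' censoring, used to validate Cox coefficient recovery.
#'
#' @param n Cohort size.
#' @param hazard_ratio True hazard ratio of the binary covariate.
#' @param baseline_rate Exponential baseline hazard (events per day).
#' @param censor_window Upper bound of uniform censoring (days); the
#'   default yields roughly 30% censoring.
#' @param seed Integer seed.
#' @return A tibble with `time`, `event` and binary `x`.
#' @export
gen_cohort_ph <- function(n = 500, hazard_ratio = 2.5,
                          baseline_rate = 0.001, censor_window = 2500,
                          seed = 1L) {
  with_seed(seed, {
    x <- rbinom(n, 1, 0.5)
    t_true <- stats::rexp(n, rate = baseline_rate * hazard_ratio^x)
    c_time <- runif(n, 0, censor_window)
    tibble(time = pmin(t_true, c_time),
           event = as.integer(t_true <= c_time),
           x = x)
  })
}

#' Bundled 2x2 contingency tables from the medulloblastoma cohort
#'
#' Returns the two published 2x2 tables used as fixed fixtures: ecDNA
#' presence in SHH-subgroup tumors versus the other subgroups (30/112
#' SHH vs 45/356 others), and TP53 alteration versus ecDNA status
#' within SHH tumors (12/23 ecDNA+ vs 2/69 ecDNA-).
#'
#' @return A named list of two labelled 2x2 matrices, `shh_vs_rest` and
#'   `tp53_vs_ecdna`.
#' @export
fixture_tables <- function() {
  shh <- matrix(c(30, 82, 45, 265), nrow = 2, byrow = TRUE,
                dimnames = list(subgroup = c("SHH", "other"),
                                ecDNA = c("positive", "negative")))
  tp53 <- matrix(c(12, 11, 2, 67), nrow = 2, byrow = TRUE,
                 dimnames = list(ecDNA = c("positive", "negative"),
                                 TP53 = c("altered", "wildtype")))
  list(shh_vs_rest = shh, tp53_vs_ecdna = tp53)
}
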