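# Cohort-level inference: Kaplan-Meier / log-rank, ridge-penalized Cox
# proportional hazards (Efron ties, Newton-Raphson) with cross-validated
# penalty, log-normal accelerated failure time regression, Baron-Kenny
# mediation, and 2x2 categorical association tests.

# Build a design matrix from named covariates. Character/factor columns
# are dummy coded against a reference level (default: the largest
# category). Rows with any missing value are dropped (no imputation).
build_design <- function(data, covariates, reference_levels = list()) {
  stopifnot(length(covariates) > 0, all(covariates %in% names(data)))
  df <- as.data.frame(data)[, covariates, drop = FALSE]
  keep <- complete.cases(df)
  df <- df[keep, , drop = FALSE]
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      x <- as.character(df[[v]])
      ref <- reference_levels[[v]]
      if (is.null(ref)) ref <- names(sort(table(x), decreasing = TRUE))[[1]]
      df[[v]] <- factor(x, levels = c(ref, setdiff(sort(unique(x)), ref)))
    }
  }
  X <- model.matrix(~ ., data = df)[, -1, drop = FALSE]
  list(X = X, keep = keep)
}

#' Efron partial log-likelihood of a Cox model
#'
#' The unpenalized log partial likelihood with Efron's approximation for
#' tied event times, exposed so that fits can be verified against
#' derivative-free optimizers or used as a cross-validation objective.
#'
#' @param beta Coefficient vector.
#' @param x Design matrix (rows = subjects).
#' @param time Follow-up times.
#' @param status Event indicators (1 = event, 0 = censored).
#' @return Scalar log partial likelihood.
#' @export
cox_partial_loglik <- function(beta, x, time, status) {
  efron_derivatives(beta, x, time, status, order = 0)$loglik
}

# Efron log partial likelihood with optional gradient and Hessian.
efron_derivatives <- function(beta, x, time, status, order = 2) {
  x <- as.matrix(x)
  p <- ncol(x)
  eta <- drop(x %*% beta)
  w <- exp(eta)
  ll <- 0
  grad <- numeric(p)
  hess <- matrix(0, p, p)
  for (t in sort(unique(time[status == 1]))) {
    R <- which(time >= t)
    D <- which(time == t & status == 1)
    d <- length(D)
    xR <- x[R, , drop = FALSE]; xD <- x[D, , drop = FALSE]
    S_R <- sum(w[R]); S_D <- sum(w[D])
    ll <- ll + sum(eta[D])
    if (order >= 1) {
      Z_R <- colSums(xR * w[R]); Z_D <- colSums(xD * w[D])
      grad <- grad + colSums(xD)
    }
    if (order >= 2) {
      Q_R <- crossprod(xR * sqrt(w[R])); Q_D <- crossprod(xD * sqrt(w[D]))
    }
    for (l in seq_len(d) - 1) {
      f <- l / d
      phi <- S_R - f * S_D
      ll <- ll - log(phi)
      if (order >= 1) {
        z <- (Z_R - f * Z_D) / phi
        grad <- grad - z
        if (order >= 2) {
          hess <- hess - ((Q_R - f * Q_D) / phi - tcrossprod(z))
        }
      }
    }
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Fit a (ridge-penalized) Cox proportional hazards model
#'
#' Maximizes the Efron-tie log partial likelihood minus
#' \eqn{(\lambda/2)\|\beta\|^2} by Newton-Raphson (convergence when the
#' penalized gradient norm falls below `tol`, at most `max_iter`
#' iterations). Confidence intervals come from the penalized
#' observed-information covariance. A ridge penalty (`lambda > 0`)
#' stabilizes estimation when covariates are collinear, e.g. ecDNA and
#' TP53 status.
#'
#' @param data Data frame of one record per patient.
#' @param covariates Character vector of covariate column names;
#'   character/factor columns are dummy coded (reference = largest
#'   category unless given in `reference_levels`). Records with missing
#'   covariates, time or event are dropped (no imputation).
#' @param time,event Column names of follow-up time (> 0) and event
#'   indicator (1 = event, 0 = right-censored).
#' @param lambda Ridge penalty (>= 0); the penalty never touches the
#'   baseline hazard.
#' @param reference_levels Named list of reference levels for
#'   categorical covariates.
#' @param tol,max_iter Newton convergence controls.
#' @return An object of class `cox_fit` with a `coefficients` tibble
#'   (`term`, `estimate`, `hazard_ratio`, `std.error`, `conf.low`,
#'   `conf.high` on the log-hazard scale), log likelihoods, `lambda`,
#'   `converged`, `n` and `n_events`.
#' @export
cox_fit <- function(data, covariates, time = "time", event = "event",
                    lambda = 0, reference_levels = list(),
                    tol = 1e-8, max_iter = 100) {
  stopifnot(lambda >= 0)
  des <- build_design(data, covariates, reference_levels)
  X <- des$X
  tt <- data[[time]][des$keep]
  ev <- data[[event]][des$keep]
  ok <- !is.na(tt) & !is.na(ev)
  X <- X[ok, , drop = FALSE]; tt <- tt[ok]; ev <- as.numeric(ev[ok])
  if (any(tt <= 0)) abort("follow-up times must be positive")
  if (sum(ev) < 1) abort("need at least one observed event")
  p <- ncol(X)
  beta <- numeric(p)
  converged <- FALSE
  iter <- 0
  pen_ll <- function(b) {
    cox_partial_loglik(b, X, tt, ev) - lambda / 2 * sum(b^2)
  }
  cur <- pen_ll(beta)
  while (iter < max_iter) {
    iter <- iter + 1
    der <- efron_derivatives(beta, X, tt, ev, order = 2)
    g <- der$gradient - lambda * beta
    info <- -der$hessian + diag(lambda, p)
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(info, g), error = function(e) NULL)
    if (is.null(step)) break
    # step halving to guarantee ascent of the penalized objective
    s <- 1
    repeat {
      cand <- beta + s * step
      val <- pen_ll(cand)
      if (is.finite(val) && val >= cur - 1e-12) break
      s <- s / 2
      if (s < 1e-8) break
    }
    beta <- beta + s * step
    cur <- pen_ll(beta)
  }
  der <- efron_derivatives(beta, X, tt, ev, order = 2)
  g <- der$gradient - lambda * beta
  if (max(abs(g)) < tol) converged <- TRUE
  info <- -der$hessian + diag(lambda, p)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  zcrit <- qnorm(0.975)
  beta <- unname(beta)
  se <- unname(se)
  coefs <- tibble(
    term = colnames(X), estimate = beta, hazard_ratio = exp(beta),
    std.error = se,
    conf.low = beta - zcrit * se, conf.high = beta + zcrit * se)
  structure(list(coefficients = coefs,
                 loglik = der$loglik,
                 penalized_loglik = der$loglik - lambda / 2 * sum(beta^2),
                 loglik_null = cox_partial_loglik(numeric(p), X, tt, ev),
                 lambda = lambda, converged = converged, iterations = iter,
                 n = nrow(X), n_events = sum(ev),
                 X = X, time = tt, status = ev),
            class = "cox_fit")
}

#' @export
tidy.cox_fit <- function(x, ...) x$coefficients

#' @export
glance.cox_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, lambda = x$lambda,
         loglik = x$loglik, penalized_loglik = x$penalized_loglik,
         loglik_null = x$loglik_null, converged = x$converged,
         iterations = x$iterations)
}

#' Select the Cox ridge penalty by cross-validation
#'
#' Grid search over `lambda_grid` on k-fold cross-validation: for each
#' fold, the model is fitted on the remaining folds and scored by the
#' *unpenalized* Efron log partial likelihood of the withheld fold.
#' The selected penalty maximizes the mean withheld log likelihood;
#' ties resolve to the smallest penalty. Folds without events are
#' skipped with a warning.
#'
#' @inheritParams cox_fit
#' @param lambda_grid Numeric vector of candidate penalties.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return A list with `lambda` (the selected value) and `cv` (tibble of
#'   mean withheld log likelihood per candidate).
#' @export
select_ridge_lambda <- function(data, covariates, time = "time",
                                event = "event",
                                lambda_grid = c(0, 0.01, 0.1, 1, 10, 100),
                                folds = 5, seed = 1L,
                                reference_levels = list()) {
  stopifnot(length(lambda_grid) > 0, nrow(data) >= folds)
  des <- build_design(data, covariates, reference_levels)
  X <- des$X
  tt <- data[[time]][des$keep]
  ev <- as.numeric(data[[event]][des$keep])
  n <- nrow(X)
  assign_fold <- with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  scores <- matrix(NA_real_, nrow = folds, ncol = length(lambda_grid))
  for (k in seq_len(folds)) {
    test <- assign_fold == k
    if (sum(ev[test]) < 1 || sum(ev[!test]) < 1) {
      warn(sprintf("fold %d has no events and was skipped", k))
      next
    }
    df_train <- data.frame(X[!test, , drop = FALSE],
                           .time = tt[!test], .event = ev[!test],
                           check.names = FALSE)
    for (li in seq_along(lambda_grid)) {
      fit <- cox_fit(df_train, covariates = colnames(X),
                     time = ".time", event = ".event",
                     lambda = lambda_grid[[li]])
      beta <- fit$coefficients$estimate
      scores[k, li] <- cox_partial_loglik(beta, X[test, , drop = FALSE],
                                          tt[test], ev[test])
    }
  }
  mean_score <- colMeans(scores, na.rm = TRUE)
  best <- which(mean_score == max(mean_score))
  lambda <- min(lambda_grid[best])
  list(lambda = lambda,
       cv = tibble(lambda = lambda_grid, mean_withheld_loglik = mean_score))
}

#' Fit a log-normal accelerated failure time model
#'
#' Maximum likelihood for \eqn{\log T = X\beta + \sigma\varepsilon} with
#' standard normal errors; right-censored records contribute
#' survival-function terms. Each coefficient is reported with its
#' percentage change in expected survival time,
#' \eqn{100\,(e^{\hat\beta_k} - 1)}.
#'
#' @inheritParams cox_fit
#' @return An object of class `aft_fit` with a `coefficients` tibble
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `percentage_change`), the scale `sigma`, `loglik`, `converged`,
#'   `n` and `n_events`.
#' @export
aft_fit <- function(data, covariates, time = "time", event = "event",
                    reference_levels = list()) {
  des <- build_design(data, covariates, reference_levels)
  X <- des$X
  tt <- data[[time]][des$keep]
  ev <- as.numeric(data[[event]][des$keep])
  ok <- !is.na(tt) & !is.na(ev)
  X <- X[ok, , drop = FALSE]; tt <- tt[ok]; ev <- ev[ok]
  if (sum(ev) < 1) abort("need at least one observed event")
  df <- data.frame(X, check.names = FALSE)
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::survreg(survival::Surv(tt, ev) ~ ., data = df,
                      dist = "lognormal"),
    warning = function(w) {
      if (grepl("iterations", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  est <- coef(fit)
  se <- sqrt(diag(fit$var))[seq_along(est)]
  stat <- est / se
  coefs <- tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = 2 * pnorm(-abs(unname(stat))),
    percentage_change = 100 * (exp(unname(est)) - 1))
  structure(list(coefficients = coefs, sigma = fit$scale,
                 loglik = fit$loglik[2], converged = converged,
                 n = nrow(X), n_events = sum(ev)),
            class = "aft_fit")
}

#' @export
tidy.aft_fit <- function(x, ...) x$coefficients

#' @export
glance.aft_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, sigma = x$sigma,
         loglik = x$loglik, converged = x$converged)
}

#' Baron-Kenny mediation analysis on survival
#'
#' Quantifies how much of a binary exposure's effect on survival (e.g.
#' TP53 alteration) is transmitted through a binary mediator (e.g. ecDNA
#' presence) by comparing log-normal AFT coefficients with and without
#' the mediator. Three models are fitted: (1) mediator ~ exposure
#' (logistic regression), (2) outcome ~ exposure (total effect), (3)
#' outcome ~ exposure + mediator (direct effect). Log-normal AFT
#' regression is used instead of Cox because hazard ratios are
#' non-collapsible and cannot be compared across nested models.
#'
#' @inheritParams cox_fit
#' @param exposure,mediator Column names of the binary exposure and
#'   mediator.
#' @param covariates Additional adjustment covariates (may be empty).
#' @return An object of class `mediation_result` with the three fitted
#'   models, the total, direct and mediator-path coefficients,
#'   `attenuation` (`1 - direct/total`) and percentage changes.
#' @export
mediation_baron_kenny <- function(data, exposure, mediator,
                                  covariates = character(),
                                  time = "time", event = "event") {
  m <- data[[mediator]]
  e <- data[[exposure]]
  if (length(unique(stats::na.omit(m))) < 2) {
    abort(sprintf("mediator '%s' is constant", mediator))
  }
  cc <- complete.cases(data.frame(m, e))
  if (all(m[cc] == e[cc])) {
    abort(sprintf("mediator '%s' is identical to exposure '%s' (perfect collinearity)",
                  mediator, exposure))
  }
  med_formula <- as.formula(paste(mediator, "~",
                                  paste(c(exposure, covariates), collapse = " + ")))
  mediator_model <- glm(med_formula, data = data, family = binomial())
  total_model <- aft_fit(data, covariates = c(exposure, covariates),
                         time = time, event = event)
  direct_model <- aft_fit(data, covariates = c(exposure, mediator, covariates),
                          time = time, event = event)
  coef_of <- function(fit, term) {
    i <- match(term, fit$coefficients$term)
    fit$coefficients$estimate[[i]]
  }
  total <- coef_of(total_model, exposure)
  direct <- coef_of(direct_model, exposure)
  med_path <- coef_of(direct_model, mediator)
  exposure_on_mediator <- coef(mediator_model)[[exposure]]
  structure(list(
    exposure = exposure, mediator = mediator,
    total_effect = total, direct_effect = direct,
    mediator_effect = med_path,
    exposure_on_mediator = exposure_on_mediator,
    attenuation = if (total != 0) 1 - direct / total else NA_real_,
    percentage_change_total = 100 * (exp(total) - 1),
    percentage_change_direct = 100 * (exp(direct) - 1),
    mediator_model = mediator_model,
    total_model = total_model, direct_model = direct_model),
    class = "mediation_result")
}

#' @export
tidy.mediation_result <- function(x, ...) {
  tibble(
    effect = c("total", "direct", "mediator", "exposure_on_mediator"),
    term = c(x$exposure, x$exposure, x$mediator, x$exposure),
    model = c("outcome ~ exposure", "outcome ~ exposure + mediator",
              "outcome ~ exposure + mediator", "mediator ~ exposure"),
    estimate = c(x$total_effect, x$direct_effect, x$mediator_effect,
                 x$exposure_on_mediator))
}

#' @export
glance.mediation_result <- function(x, ...) {
  tibble(total_effect = x$total_effect, direct_effect = x$direct_effect,
         attenuation = x$attenuation,
         loglik_total = x$total_model$loglik,
         loglik_direct = x$direct_model$loglik)
}

#' Kaplan-Meier estimate and log-rank test
#'
#' Product-limit survival estimates per group and (for two or more
#' groups) the log-rank chi-squared test of differential survival.
#'
#' @inheritParams cox_fit
#' @param group Column name of the grouping variable, or `NULL` for a
#'   single pooled curve.
#' @return An object of class `km_estimate`: list with `curves` (tibble:
#'   `group`, `time`, `n_risk`, `n_event`, `survival`) and `logrank`
#'   (`statistic`, `df`, `p.value`; `NA` for a single group).
#' @export
km_estimate <- function(data, group = NULL, time = "time", event = "event") {
  tt <- data[[time]]; ev <- as.numeric(data[[event]])
  g <- if (is.null(group)) factor(rep("all", length(tt))) else factor(data[[group]])
  sf <- survival::survfit(survival::Surv(tt, ev) ~ g)
  strata <- if (is.null(sf$strata)) {
    rep(levels(g)[1], length(sf$time))
  } else {
    rep(sub("^g=", "", names(sf$strata)), sf$strata)
  }
  curves <- tibble(group = strata, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, survival = sf$surv)
  logrank <- list(statistic = NA_real_, df = NA_integer_, p.value = NA_real_)
  if (nlevels(droplevels(g)) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    df <- length(sd_$n) - 1
    logrank <- list(statistic = sd_$chisq, df = df,
                    p.value = pchisq(sd_$chisq, df, lower.tail = FALSE))
  }
  structure(list(curves = curves, logrank = logrank), class = "km_estimate")
}

#' @export
tidy.km_estimate <- function(x, ...) x$curves

#' @export
glance.km_estimate <- function(x, ...) {
  tibble(statistic = x$logrank$statistic, df = x$logrank$df,
         p.value = x$logrank$p.value)
}

#' @export
autoplot.km_estimate <- function(object, ...) {
  start <- dplyr::distinct(object$curves, .data$group) |>
    mutate(time = 0, survival = 1)
  dat <- bind_rows(start,
                   object$curves[, c("group", "time", "survival")]) |>
    arrange(.data$group, .data$time)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Chi-squared test of independence for a 2x2 table
#'
#' Pearson chi-squared with 1 degree of freedom, Yates continuity
#' correction on by default (standard for 2x2 tables).
#'
#' @param table A 2x2 matrix of counts, or a length-4 vector
#'   `c(a, b, c, d)` filling the table by row.
#' @param yates Apply the Yates continuity correction.
#' @return A tibble with `statistic`, `p.value`, `df`.
#' @export
chi2_2x2 <- function(table, yates = TRUE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("2x2 table has a zero margin")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected <= 0)) abort("expected counts must be positive")
  ct <- suppressWarnings(chisq.test(m, correct = yates))
  tibble(statistic = unname(ct$statistic), p.value = ct$p.value, df = 1L)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value defined as the total probability of all tables with
#' the observed margins whose hypergeometric probability does not exceed
#' that of the observed table. The odds ratio is the sample odds ratio
#' `ad / bc` (`Inf` or `NaN` when a margin cell is zero). With
#' `midp = TRUE` the mid-p variant is returned instead: tables strictly
#' less probable than the observed one count fully and equally probable
#' tables (including the observed) count half, a less conservative
#' estimator sometimes encountered in published analyses.
#'
#' @inheritParams chi2_2x2
#' @param midp Return the mid-p variant of the two-sided p-value.
#' @return A tibble with `odds_ratio` and `p.value`.
#' @export
fisher_exact_2x2 <- function(table, midp = FALSE) {
  m <- as_2x2(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("2x2 table has a zero margin")
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  p <- if (midp) {
    a <- m[1, 1]
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    k <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(k, c1, n - c1, r1)
    p0 <- dhyper(a, c1, n - c1, r1)
    rel <- 1 + 1e-7
    sum(probs[probs < p0 / rel]) + 0.5 * sum(probs[probs >= p0 / rel &
                                                     probs <= p0 * rel])
  } else {
    fisher.test(m)$p.value
  }
  tibble(odds_ratio = or, p.value = p)
}

as_2x2 <- function(table) {
  m <- if (is.matrix(table)) table else matrix(as.numeric(table), 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2))) abort("expected a 2x2 table")
  if (any(m < 0) || any(m != floor(m))) abort("counts must be non-negative integers")
  if (sum(m) == 0) abort("table total must be positive")
  m
}
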