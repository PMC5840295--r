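#' Fit the background component from control captures
#'
#' Per-prey background mean = mean spectral count across control runs
#' (batch-adjusted, see below), floored at a small positive constant so
#' the negative-binomial likelihood stays defined for never-observed
#' preys. A single shared dispersion is estimated by method of moments
#' pooled over preys: phi = sum_i (s2_i - m_i) / sum_i m_i^2, clamped to
#' [1e-4, 10].
#'
#' When the run metadata carries a `batch` column, a multiplicative
#' per-batch depth factor is estimated from the control runs' column
#' totals (mean control total in the batch over the grand mean); control
#' counts are divided by their batch factor before the mean and
#' dispersion are computed, and scoring re-applies the factor of each
#' scored run's batch. Without batch adjustment the batch spread leaks
#' into the dispersion estimate and biases the per-run likelihoods.
#'
#' @param counts wide count tibble
#' @param run_meta run metadata (needs >= 2 control runs)
#' @param floor lower bound on background means (default 0.1)
#' @param prior prior probability pi of a true interaction (default 0.1)
#' @param batch_adjust estimate and use per-batch depth factors
#'   (default TRUE when `run_meta` has a `batch` column)
#' @return object of class `saint_bg`; see [tidy.saint_bg()] and
#'   [glance.saint_bg()]
#' @export
fit_background <- function(counts, run_meta, floor = 0.1, prior = 0.1,
                           batch_adjust = "batch" %in% names(run_meta)) {
  check_run_meta(counts, run_meta)
  if (prior <= 0 || prior >= 1) abort("`prior` must be in (0, 1).")
  ctrl <- run_meta$run_id[run_meta$construct == "control"]
  if (length(ctrl) < 2) abort("Background fitting needs >= 2 control runs.")
  m <- count_matrix(counts)[, ctrl, drop = FALSE]
  batch_factors <- NULL
  if (batch_adjust) {
    if (!"batch" %in% names(run_meta)) {
      abort("`batch_adjust = TRUE` needs a `batch` column in `run_meta`.")
    }
    ctrl_batch <- run_meta$batch[match(ctrl, run_meta$run_id)]
    tot <- colSums(m)
    per_batch <- tapply(tot, ctrl_batch, mean)
    batch_factors <- per_batch / mean(per_batch)
    missing_b <- setdiff(unique(run_meta$batch), names(batch_factors))
    if (length(missing_b)) {
      warn(paste0("No control runs in batch(es) ", paste(missing_b, collapse = ", "),
                  "; their depth factor is set to 1."))
      batch_factors <- c(batch_factors,
                         stats::setNames(rep(1, length(missing_b)), missing_b))
    }
    m <- sweep(m, 2, batch_factors[ctrl_batch], "/")
  }
  mu <- rowMeans(m)
  s2 <- apply(m, 1, stats::var)
  phi <- sum(s2 - mu) / sum(mu^2)
  phi <- min(max(phi, 1e-4), 10)
  structure(
    list(background = tibble(protein_id = rownames(m), mean = unname(pmax(mu, floor))),
         dispersion = phi, prior = prior, floor = floor, n_control = length(ctrl),
         batch_factors = batch_factors),
    class = "saint_bg"
  )
}

#' @describeIn fit_background per-prey background means as a tibble
#' @param x a `saint_bg` object
#' @param ... unused
#' @exportS3Method generics::tidy
tidy.saint_bg <- function(x, ...) x$background

#' @describeIn fit_background one-row model summary
#' @exportS3Method generics::glance
glance.saint_bg <- function(x, ...) {
  tibble(dispersion = x$dispersion, prior = x$prior,
         n_control = x$n_control, n_proteins = nrow(x$background))
}

#' @export
print.saint_bg <- function(x, ...) {
  cat("SAINT-style background model:", nrow(x$background), "preys,",
      x$n_control, "control runs\n")
  cat(sprintf("  shared dispersion %.4g, prior pi %.2f, mean floor %.2g\n",
              x$dispersion, x$prior, x$floor))
  invisible(x)
}

# Posterior that a single replicate count comes from the true-interaction
# component (mean mu*f) rather than background (mean mu). Vectorised.
mixture_posterior <- function(y, mu, dispersion, prior, factor) {
  l1 <- dnbinom_mu(y, mu * factor, dispersion, log = TRUE) + log(prior)
  l0 <- dnbinom_mu(y, mu, dispersion, log = TRUE) + log(1 - prior)
  1 / (1 + exp(l0 - l1))
}

# EM fit of one prey's true-component factor over its bait runs.
# E-step: responsibility of the true component from the full replicate
# likelihood under the current factor; M-step: maximise the weighted
# true-component log-likelihood over the factor within `bounds`.
# Deterministic (initialisation at `init`); returns the factor and
# whether it was clamped at a bound.
fit_true_factor <- function(y, mu, dispersion, prior,
                            bounds = c(2, 100), init = 4,
                            tol = 1e-6, max_iter = 500) {
  # mu may be a per-replicate background mean vector (batch-scaled)
  ll <- function(fc) sum(dnbinom_mu(y, mu * fc, dispersion, log = TRUE))
  l0 <- ll(1) + log(1 - prior)
  f <- init
  for (it in seq_len(max_iter)) {
    l1 <- ll(f) + log(prior)
    z <- 1 / (1 + exp(l0 - l1))
    opt <- stats::optimize(function(fc) z * ll(fc), interval = bounds,
                           maximum = TRUE, tol = tol / 10)
    f_new <- opt$maximum
    if (abs(f_new - f) < tol) { f <- f_new; break }
    f <- f_new
  }
  clamped <- f <= bounds[1] + 1e-3 || f >= bounds[2] - 1e-3
  if (clamped) f <- if (f <= bounds[1] + 1e-3) bounds[1] else bounds[2]
  list(factor = f, clamped = clamped)
}

#' SAINT-style posterior score for one prey
#'
#' Two-component negative-binomial mixture: per replicate, the posterior
#' probability that the count arises from the true-interaction component
#' (mean = background mean x `factor`) rather than background, under
#' prior `prior`; the score is the mean posterior across replicates.
#'
#' @param counts the prey's bait-replicate spectral counts
#' @param bg_mean the prey's background mean (floored positive); may be\n#'   a per-replicate vector, e.g. batch-scaled
#' @param dispersion shared NB dispersion
#' @param factor true-component mean multiplier, > 1
#' @param prior prior probability of a true interaction
#' @return score in \[0, 1\], with the per-replicate posteriors in
#'   attribute `"posteriors"`
#' @export
saint_score <- function(counts, bg_mean, dispersion, factor, prior = 0.1) {
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (factor <= 1) abort("`factor` must exceed 1.")
  post <- mixture_posterior(counts, bg_mean, dispersion, prior, factor)
  structure(mean(post), posteriors = post)
}

#' SAINT-style scores for every prey of a construct
#'
#' Fits (or takes) the shared true-component factor by EM over the
#' construct's runs, then scores each prey with [saint_score()]. The
#' averaging order is fixed: posteriors are averaged across replicates
#' within a prey; preys are never averaged.
#'
#' @param counts wide count tibble
#' @param run_meta run metadata
#' @param bg background model from [fit_background()]
#' @param construct construct whose runs to score (default "WT")
#' @param factor optional fixed true-component factor applied to every
#'   prey; NULL (default) fits a per-prey factor by EM over that prey's
#'   runs, bounded to \[2, 100\], deterministic initialisation at 4.
#'   Factors hitting a bound are clamped there (reported via a single
#'   warning naming how many preys were clamped).
#' @return tibble: `protein_id`, `score`, `factor`
#' @export
saint_scores <- function(counts, run_meta, bg, construct = "WT", factor = NULL) {
  stopifnot(inherits(bg, "saint_bg"))
  check_run_meta(counts, run_meta)
  m <- count_matrix(counts)
  runs <- run_meta$run_id[run_meta$construct == construct]
  if (!length(runs)) abort(paste0("No runs for construct ", construct, "."))
  bgm <- stats::setNames(bg$background$mean, bg$background$protein_id)
  if (!all(rownames(m) %in% names(bgm))) {
    abort("Background model does not cover every protein in the count table.")
  }
  bgm <- bgm[rownames(m)]
  bait <- m[, runs, drop = FALSE]
  run_f <- rep(1, length(runs))
  if (!is.null(bg$batch_factors)) {
    run_f <- unname(bg$batch_factors[run_meta$batch[match(runs, run_meta$run_id)]])
  }
  if (is.null(factor)) {
    fits <- lapply(seq_len(nrow(bait)), function(i) {
      fit_true_factor(bait[i, ], bgm[[i]] * run_f, bg$dispersion, bg$prior)
    })
    n_clamped <- sum(vapply(fits, `[[`, logical(1), "clamped"))
    if (n_clamped > 0) {
      warn(sprintf("True-component factor clamped at the [2, 100] bound for %d prey(s).",
                   n_clamped))
    }
    factor <- vapply(fits, `[[`, numeric(1), "factor")
  } else {
    factor <- rep_len(factor, nrow(bait))
  }
  score <- vapply(seq_len(nrow(bait)), function(i) {
    as.numeric(saint_score(bait[i, ], bgm[[i]] * run_f, bg$dispersion,
                           factor[[i]], bg$prior))
  }, numeric(1))
  tibble(protein_id = rownames(m), score = score, factor = factor) |>
    dplyr::arrange(.data$protein_id)
}
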