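#' Saturable readout model for synthetic densitometry-like data
#'
#' Describes how a downstream observable (e.g. a pERK/ERK densitometry
#' ratio) reports on the active-RAF fraction: a Hill-type saturable link
#' `v_max * a^hill / (a^hill + k_half^hill)` with multiplicative lognormal
#' noise.  Downstream phosphorylation readouts are monotone but typically
#' saturable in kinase activity, which compresses fold changes while leaving
#' baseline-crossing doses intact; this model makes that distortion
#' explicit and testable.
#'
#' @param v_max maximal readout (arbitrary units).
#' @param k_half active-RAF fraction giving half-maximal readout.  Values
#'   far above the curve's active range give an effectively linear readout.
#' @param hill Hill coefficient (dimensionless, > 0).
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   noise (>= 0); replicate blot ratios are positive and right-skewed,
#'   which the lognormal reproduces.
#' @param n_replicates replicates per dose (default 3, mirroring triplicate
#'   blot quantification).
#' @param seed integer seed; a fixed seed makes [generate_noisy()]
#'   reproducible.
#' @return Object of class `readout_model`.
#' @export
readout_model <- function(v_max = 1, k_half = 0.02, hill = 1,
                          noise_cv = 0.1, n_replicates = 3, seed = 42L) {
  if (v_max <= 0) stop("v_max must be positive", call. = FALSE)
  if (k_half <= 0) stop("k_half must be positive", call. = FALSE)
  if (hill <= 0) stop("hill must be positive", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(v_max = v_max, k_half = k_half, hill = hill,
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "readout_model")
}

#' @keywords internal
hill_link <- function(a, readout) {
  readout$v_max * a^readout$hill /
    (a^readout$hill + readout$k_half^readout$hill)
}

#' Generate synthetic noisy readout replicates from a model curve
#'
#' Passes the curve's active fractions through the saturable link of a
#' [readout_model()] and multiplies by lognormal noise with the stated CV
#' (unit mean).  Deterministic under the model's seed; the caller's RNG
#' state is left untouched.
#'
#' @param curve `dose_response` object.
#' @param readout `readout_model` object.
#' @return Object of class `noisy_dose_response`: a `data.frame` with
#'   columns `dose`, `replicate`, `readout`, carrying the generating curve
#'   and readout model as attributes.
#' @examples
#' curve <- dose_response(raf_params(), "CA", default_dose_grid(31),
#'                        mode = "free_drug", s_free = 0)
#' noisy <- generate_noisy(curve, readout_model(noise_cv = 0.1))
#' head(noisy)
#' @export
generate_noisy <- function(curve, readout) {
  stopifnot(inherits(curve, "dose_response"),
            inherits(readout, "readout_model"))
  mu <- hill_link(curve$active, readout)
  n_rep <- readout$n_replicates
  n <- nrow(curve) * n_rep
  noise <- if (readout$noise_cv == 0) rep(1, n) else {
    sdlog <- sqrt(log(1 + readout$noise_cv^2))
    with_preserved_rng(readout$seed,
                       stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  df <- data.frame(dose = rep(curve$dose, each = n_rep),
                   replicate = rep(seq_len(n_rep), times = nrow(curve)),
                   readout = rep(mu, each = n_rep) * noise)
  structure(df, class = c("noisy_dose_response", "data.frame"),
            curve = curve, readout_model = readout)
}

#' @keywords internal
#' Run expr with a fixed seed, restoring the caller's RNG state afterwards.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @keywords internal
#' Crossover (last mean above baseline, log-interpolated) from per-dose
#' means.  `doses` must start at 0 (the baseline dose).  Returns NA when no
#' positive dose exceeds baseline or the curve never comes back down.
crossover_from_means <- function(doses, means) {
  baseline <- means[1]
  above <- means > baseline
  above[1] <- FALSE
  if (!any(above)) return(NA_real_)
  j <- max(which(above))
  if (j == length(doses)) return(NA_real_)   # still above at the top dose
  # log-interpolate the crossing between dose j (above) and j+1 (below)
  frac <- (means[j] - baseline) / (means[j] - means[j + 1])
  10^(log10(doses[j]) + frac * (log10(doses[j + 1]) - log10(doses[j])))
}

#' Estimate PA metrics from noisy replicate readouts
#'
#' Point estimates and (optionally) bootstrap percentile intervals for the
#' PA observables from synthetic replicate data: the baseline (dose-0 mean),
#' per-dose above-baseline flags, the crossover dose (last dose whose mean
#' readout exceeds the baseline mean, log-interpolated to the crossing), and
#' the fold change of mean readouts.  The bootstrap resamples replicates
#' within each dose.
#'
#' Because the link is saturable, the estimated fold change understates the
#' fold change of the underlying active-RAF curve; the crossover dose, which
#' only needs a monotone link, is estimated without that compression.
#'
#' The bootstrap pools log-scale residuals across doses: with only a few
#' replicates per dose, within-dose resampling cannot represent the noise
#' distribution and its percentile intervals undercover badly, whereas the
#' multiplicative noise is independent and identically distributed across
#' doses, so the pooled residuals (replicates x doses of them) estimate it
#' well.  Each resample redraws all residuals with replacement onto the
#' per-dose geometric means and re-applies the full estimator.
#'
#' @param data `noisy_dose_response` from [generate_noisy()].
#' @param n_boot bootstrap resamples; 0 gives point estimates only.
#' @param seed integer seed for the bootstrap.
#' @return List with elements `baseline`, `fold_change`, `crossover_dose`,
#'   `above_baseline` (per-dose logical, positive doses), `n_replicates`,
#'   and when `n_boot > 0` the percentile intervals `fold_change_ci` and
#'   `crossover_ci` (95%, with `crossover_ci` computed over the resamples
#'   in which a crossover existed) plus `n_boot`.
#' @export
estimate_pa_from_noisy <- function(data, n_boot = 0, seed = 1L) {
  stopifnot(inherits(data, "noisy_dose_response"))
  doses <- sort(unique(data$dose))
  if (doses[1] != 0)
    stop("data must include the zero dose (baseline)", call. = FALSE)
  # replicate matrix: n_rep x n_doses, doses in column order
  reps <- split(data$readout, factor(data$dose, levels = doses))
  n_rep <- unique(lengths(reps))
  if (length(n_rep) != 1L)
    stop("replicate count must be uniform across doses", call. = FALSE)
  if (n_rep < 2L)
    stop("at least 2 replicates per dose are required", call. = FALSE)
  V <- matrix(unlist(reps), nrow = n_rep)
  if (any(colSums(V) == 0))
    stop("degenerate data: a dose with all-zero readouts", call. = FALSE)

  means <- colMeans(V)
  baseline <- means[1]
  est <- list(baseline = baseline,
              fold_change = max(means) / baseline,
              crossover_dose = crossover_from_means(doses, means),
              above_baseline = means[-1] > baseline,
              n_replicates = n_rep)
  if (n_boot > 0) {
    nd <- length(doses)
    gmean <- exp(colMeans(log(V)))
    res <- as.vector(sweep(log(V), 2, log(gmean)))  # pooled log residuals
    mu <- gmean[rep(seq_len(nd), each = n_rep)]
    boot <- with_preserved_rng(seed, {
      fold <- numeric(n_boot)
      cross <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        Vb <- matrix(mu * exp(sample(res, n_rep * nd, replace = TRUE)),
                     nrow = n_rep)
        bm <- colMeans(Vb)
        fold[b] <- max(bm) / bm[1]
        cross[b] <- crossover_from_means(doses, bm)
      }
      list(fold = fold, cross = cross)
    })
    est$fold_change_ci <- stats::quantile(boot$fold, c(0.025, 0.975),
                                          names = FALSE)
    cr <- boot$cross[!is.na(boot$cross)]
    est$crossover_ci <- if (length(cr))
      stats::quantile(cr, c(0.025, 0.975), names = FALSE)
    else c(NA_real_, NA_real_)
    est$n_boot <- n_boot
  }
  est
}
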