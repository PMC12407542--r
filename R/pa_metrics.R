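#' Default log-spaced dose grid
#'
#' 121 log-spaced drug concentrations over `1e-4 .. 1e2` uM, the grid used
#' for all descriptive dose-response figures.
#'
#' @param n number of grid points.
#' @param min,max grid end points (uM).
#' @return Numeric vector of strictly increasing doses.
#' @export
default_dose_grid <- function(n = 121, min = 1e-4, max = 1e2) {
  10^seq(log10(min), log10(max), length.out = n)
}

# Relative excess over baseline required before a dose counts as PA;
# guards floating-point equality where the curve is tangent to baseline.
pa_detect_tol <- 1e-9

#' @keywords internal
#' Build a scalar evaluator dose -> active fraction for a mode/engine combo.
#' In free_drug mode both free ligands are clamped (s_free fixed); in
#' total_drug mode each dose is a total drug concentration mapped through
#' the conservation solve of [solve_totals()], after which the analytic
#' engine evaluates the closed forms at the solved free concentrations.
make_active_evaluator <- function(params, variant, mode, engine, s_free) {
  force(params); force(variant); force(s_free)
  if (mode == "free_drug") {
    if (engine == "analytic") {
      function(dose) active_fraction(params, variant, dose, s_free)
    } else {
      function(dose) vapply(dose, function(d)
        active_raf(solve_free_clamped(params, variant, d, s_free)),
        numeric(1))
    }
  } else {
    function(dose) vapply(dose, function(D) {
      p <- params
      p$D_total <- D
      st <- solve_totals(p, variant)
      if (engine == "analytic")
        active_fraction(params, variant, st$d_free, st$s_free)
      else
        active_raf(st)
    }, numeric(1))
  }
}

#' Simulate a dose-response curve
#'
#' Computes the active-RAF fraction over a grid of drug doses.  In
#' `total_drug` mode (the default, matching how dose responses are plotted
#' against total inhibitor concentration) each dose is a total drug
#' concentration and the free concentrations are obtained from the
#' conservation solve; in `free_drug` mode the doses are clamped free-drug
#' concentrations and free 14-3-3 is clamped at `s_free`.  The `analytic`
#' engine evaluates the closed forms (at the conservation-solved free
#' concentrations in `total_drug` mode); the `oracle` engine sums species
#' of the mass-action solve.
#'
#' @param params `raf_params`.
#' @param variant one of [raf_variants()].
#' @param doses non-negative, strictly increasing drug concentrations (uM).
#'   A zero dose is prepended if absent, so the curve always carries its
#'   baseline.
#' @param mode `"total_drug"` or `"free_drug"`.
#' @param engine `"analytic"` or `"oracle"`.
#' @param s_free clamped free 14-3-3 (uM) for `free_drug` mode; defaults to
#'   `params$S_total` (the excess-14-3-3 clamp).  Ignored in `total_drug`
#'   mode, where 14-3-3 conservation determines the free level.
#' @return Object of class `dose_response`: a `data.frame` with columns
#'   `dose` and `active`, with attributes `baseline`, `variant`, `mode`,
#'   `engine`, `params`, `s_free` and the scalar `evaluator` used to extend
#'   the curve off-grid.
#' @examples
#' curve <- dose_response(raf_params(), "CA",
#'                        doses = default_dose_grid(31),
#'                        mode = "free_drug", s_free = 0)
#' head(curve)
#' @export
dose_response <- function(params, variant, doses = default_dose_grid(),
                          mode = c("total_drug", "free_drug"),
                          engine = c("analytic", "oracle"),
                          s_free = NULL) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (is.unsorted(doses, strictly = TRUE))
    stop("doses must be strictly increasing", call. = FALSE)
  if (doses[1] > 0) doses <- c(0, doses)
  if (mode == "free_drug") {
    if (is.null(s_free)) s_free <- params$S_total
    if (length(s_free) != 1L || s_free < 0)
      stop("s_free must be a single non-negative number", call. = FALSE)
  } else {
    if (!is.null(s_free))
      stop("s_free applies only to free_drug mode; in total_drug mode free ",
           "14-3-3 is set by conservation", call. = FALSE)
    s_free <- NA_real_
  }
  evaluator <- make_active_evaluator(params, variant, mode, engine, s_free)
  active <- evaluator(doses)
  structure(data.frame(dose = doses, active = active),
            class = c("dose_response", "data.frame"),
            baseline = active[1], variant = variant, mode = mode,
            engine = engine, params = params, s_free = s_free,
            evaluator = evaluator)
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response curve: variant %s, %s mode, %s engine\n",
              attr(x, "variant"), attr(x, "mode"), attr(x, "engine")))
  cat(sprintf("  %d doses in [%g, %g] uM, baseline active fraction %.4g\n",
              nrow(x), min(x$dose), max(x$dose), attr(x, "baseline")))
  NextMethod()
}

#' @keywords internal
#' Golden-section maximization of f over [lo, hi] in log10-dose.
golden_max <- function(f, lo, hi, tol = 1e-8) {
  phi <- (sqrt(5) - 1) / 2
  a <- log10(lo); b <- log10(hi)
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(10^x1); f2 <- f(10^x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(10^x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(10^x1)
    }
  }
  xm <- (a + b) / 2
  list(dose = 10^xm, value = f(10^xm))
}

#' @keywords internal
#' Refine the peak of a dose-response curve off-grid.
#' Returns list(dose, value); dose 0 with the baseline value when the curve
#' never rises above baseline.
refine_peak <- function(curve) {
  f <- attr(curve, "evaluator")
  baseline <- attr(curve, "baseline")
  i <- which.max(curve$active)
  if (curve$active[i] <= baseline * (1 + pa_detect_tol) || i == 1L)
    return(list(dose = 0, value = baseline))
  lo <- if (i > 2L) curve$dose[i - 1L] else curve$dose[i] / 10
  if (i < nrow(curve)) {
    hi <- curve$dose[i + 1L]
  } else {
    # peak beyond the grid: climb outward until the curve turns over
    hi <- curve$dose[i] * 10
    f_hi <- f(hi)
    for (k in 1:40) {
      f_next <- f(hi * 10)
      if (f_next <= f_hi) break
      lo <- hi
      hi <- hi * 10
      f_hi <- f_next
    }
    hi <- hi * 10
  }
  pk <- golden_max(f, lo, hi)
  if (pk$value < curve$active[i]) pk <- list(dose = curve$dose[i],
                                            value = curve$active[i])
  pk
}

#' PA fold change of a dose-response curve
#'
#' Peak active RAF across doses divided by the drug-free baseline.  The grid
#' argmax is refined by golden-section search in log-dose so the reported
#' maximum is grid-independent; a curve that never exceeds its baseline has
#' fold change 1.
#'
#' @param curve `dose_response` object (must include dose 0, which
#'   [dose_response()] guarantees).
#' @return Dimensionless fold change >= 1.
#' @export
pa_fold_change <- function(curve) {
  stopifnot(inherits(curve, "dose_response"))
  pk <- refine_peak(curve)
  baseline <- attr(curve, "baseline")
  if (baseline == 0) return(1)
  max(1, pk$value / baseline)
}

#' PA crossover dose (PA range)
#'
#' The largest drug concentration at which active RAF returns to its
#' drug-free baseline — the upper end of the PA window, reported as a scalar
#' because the lower end is 0+ whenever PA occurs.  Found by refining the
#' peak, expanding an upper bracket by factors of 10 until the curve falls
#' below baseline (at most 10 orders of magnitude beyond the peak), then
#' root finding in log-dose.  `NA` when the curve never exceeds baseline.
#'
#' @inheritParams dose_response
#' @param doses scan grid used to locate the peak.
#' @return Crossover dose (uM), or `NA_real_` when no PA.
#' @examples
#' pa_crossover_dose(raf_params(), "CA", mode = "free_drug", s_free = 0)
#' @export
pa_crossover_dose <- function(params, variant, doses = default_dose_grid(),
                              mode = c("total_drug", "free_drug"),
                              engine = c("analytic", "oracle"),
                              s_free = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  curve <- dose_response(params, variant, doses, mode, engine, s_free)
  pa_crossover(curve)
}

#' PA crossover dose of an existing dose-response curve
#'
#' Same quantity as [pa_crossover_dose()], computed from a curve already in
#' hand (reusing its evaluator to refine off-grid).
#'
#' @param curve `dose_response` object.
#' @return Crossover dose (uM), or `NA_real_` when no PA.
#' @export
pa_crossover <- function(curve) {
  stopifnot(inherits(curve, "dose_response"))
  f <- attr(curve, "evaluator")
  baseline <- attr(curve, "baseline")
  pk <- refine_peak(curve)
  if (pk$dose == 0) return(NA_real_)
  hi <- pk$dose
  for (i in 1:10) {
    hi <- hi * 10
    if (f(hi) < baseline) break
  }
  if (f(hi) >= baseline)
    stop("failed to bracket the PA crossover within 10 orders of magnitude ",
         "above the peak; this indicates a defect", call. = FALSE)
  root <- stats::uniroot(function(x) f(10^x) - baseline,
                         interval = c(log10(pk$dose), log10(hi)),
                         tol = 1e-10, maxiter = 1000L)$root
  10^root
}

#' Two-parameter sweep of a PA metric
#'
#' Evaluates one PA observable over the cross product of two swept
#' parameters.  Axes may be any [raf_params()] field or `"alpha"`, the
#' meta-parameter applied through [apply_alpha()].
#'
#' @inheritParams dose_response
#' @param axis1,axis2 lists `list(name =, values =)` naming the swept
#'   parameter and its (typically log-spaced) values.
#' @param metric one of `"baseline_pct"` (drug-free active RAF, percent of
#'   total), `"max_pct"` (peak active RAF across doses, percent of total),
#'   `"fold_change"`, `"crossover_dose"`.
#' @param doses dose grid used for the dose-dependent metrics.
#' @return Object of class `sweep_grid`: a long `data.frame` with columns
#'   `axis1`, `axis2`, `value`, and attributes `axis_names`, `metric`,
#'   `variant`, `mode`, `engine`, `params`.
#' @examples
#' sweep_grid(raf_params(), "CA",
#'            axis1 = list(name = "K_A", values = c(2, 10, 50)),
#'            axis2 = list(name = "R_total", values = c(0.01, 0.04)),
#'            metric = "baseline_pct", mode = "free_drug", s_free = 0)
#' @export
sweep_grid <- function(params, variant, axis1, axis2,
                       metric = c("baseline_pct", "max_pct", "fold_change",
                                  "crossover_dose"),
                       doses = default_dose_grid(),
                       mode = c("total_drug", "free_drug"),
                       engine = c("analytic", "oracle"),
                       s_free = NULL) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  metric <- match.arg(metric)
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  for (ax in list(axis1, axis2)) {
    if (!is.list(ax) || is.null(ax$name) || is.null(ax$values))
      stop("each axis must be list(name =, values =)", call. = FALSE)
    if (!(ax$name %in% c(raf_param_fields, "alpha")))
      stop("unknown axis name '", ax$name, "'", call. = FALSE)
  }
  set_axis <- function(p, name, value) {
    if (name == "alpha") apply_alpha(p, value)
    else { p[[name]] <- value; validate_raf_params(p); p }
  }
  grid <- expand.grid(axis1 = axis1$values, axis2 = axis2$values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$value <- vapply(seq_len(nrow(grid)), function(i) {
    p <- set_axis(params, axis1$name, grid$axis1[i])
    p <- set_axis(p, axis2$name, grid$axis2[i])
    sweep_metric(p, variant, metric, doses, mode, engine, s_free)
  }, numeric(1))
  structure(grid, class = c("sweep_grid", "data.frame"),
            axis_names = c(axis1$name, axis2$name), metric = metric,
            variant = variant, mode = mode, engine = engine, params = params)
}

#' @keywords internal
sweep_metric <- function(p, variant, metric, doses, mode, engine, s_free) {
  if (metric == "baseline_pct") {
    if (mode == "free_drug") {
      s <- if (is.null(s_free)) p$S_total else s_free
      return(100 * active_fraction(p, variant, 0, s))
    }
    return(100 * active_raf(solve_totals(p, variant)))
  }
  curve <- dose_response(p, variant, doses, mode, engine, s_free)
  switch(metric,
         max_pct = 100 * refine_peak(curve)$value,
         fold_change = pa_fold_change(curve),
         crossover_dose = pa_crossover(curve))
}

#' @export
print.sweep_grid <- function(x, ...) {
  ax <- attr(x, "axis_names")
  cat(sprintf("Sweep grid: %s over %s x %s (variant %s, %s mode)\n",
              attr(x, "metric"), ax[1], ax[2], attr(x, "variant"),
              attr(x, "mode")))
  NextMethod()
}
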