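#' @keywords internal
#' Effective CAS/DS dimensionless 14-3-3 terms for a variant.
#' `S_rel` (CAS coupling) can be computed from free or total 14-3-3; under
#' the excess-14-3-3 assumption the two coincide.  `s_rel` (DS coupling) is
#' defined from free 14-3-3.
variant_s_terms <- function(params, variant, s_free,
                            s_convention = c("free", "total")) {
  s_convention <- match.arg(s_convention)
  roles <- variant_roles(variant)
  s_cas <- if (s_convention == "free") s_free else params$S_total
  list(S_rel = if (roles$cas) s_cas / params$K_Smon else 0,
       s_rel = if (roles$ds) s_free / params$K_Sdim else 0)
}

#' Dimensionless abbreviations of the closed-form solutions
#'
#' The intermediates `E1`..`E10` that express the four variants' closed
#' forms in a common shape:
#' \describe{
#'   \item{E1}{`1 + K_A + d_rel` (monomer states, CA/DS)}
#'   \item{E2}{`8 * RAF_rel * (1 + d_rel)^2` (dimer states, CA/CAS)}
#'   \item{E3}{`8 * RAF_rel / (1 + K_A)^2` (CA baseline)}
#'   \item{E4}{`E1 + K_A * S_rel` (monomer states, CAS)}
#'   \item{E5}{`8 * RAF_rel / (1 + K_A + K_A*S_rel)^2` (CAS baseline)}
#'   \item{E6}{`E2 * (1 + s_rel)` (dimer states, DS)}
#'   \item{E7}{`E3 * (1 + s_rel)` (DS baseline)}
#'   \item{E8}{`E6` (dimer states, CAS+DS)}
#'   \item{E9}{`E1 + K_A * s_free / K_Smon` (monomer states, CAS+DS)}
#'   \item{E10}{`E5`-form with both 14-3-3 terms:
#'     `8 * RAF_rel * (1 + s_rel) / (1 + K_A + K_A*S_rel)^2`}
#' }
#' `S_rel` enters through the CAS coupling (`K_Smon`), `s_rel` through the
#' DS coupling (`K_Sdim`).
#'
#' @param params `raf_params`.
#' @param d_free free drug (uM), may be a vector.
#' @param s_free free 14-3-3 dimer (uM), scalar.
#' @param s_convention whether the CAS term `S_rel` uses free 14-3-3
#'   (default) or total 14-3-3; the two coincide when 14-3-3 is in excess
#'   over RAF.
#' @return Named list `E1`..`E10` plus the [dimensionless()] groups.
#' @export
analytic_intermediates <- function(params, d_free = 0, s_free = 0,
                                   s_convention = c("free", "total")) {
  s_convention <- match.arg(s_convention)
  g <- dimensionless(params, d_free, s_free)
  K_A <- params$K_A
  S_rel <- if (s_convention == "free") g$S_rel else
    params$S_total / params$K_Smon
  E1 <- 1 + K_A + g$d_rel
  E2 <- 8 * g$RAF_rel * (1 + g$d_rel)^2
  E3 <- 8 * g$RAF_rel / (1 + K_A)^2
  E4 <- E1 + K_A * S_rel
  E5 <- 8 * g$RAF_rel / (1 + K_A + K_A * S_rel)^2
  E6 <- E2 * (1 + g$s_rel)
  E7 <- E3 * (1 + g$s_rel)
  c(list(E1 = E1, E2 = E2, E3 = E3, E4 = E4, E5 = E5, E6 = E6, E7 = E7,
         E8 = E6, E9 = E4, E10 = E5 * (1 + g$s_rel)),
    g, list(S_rel_used = S_rel))
}

#' @keywords internal
#' Baseline family (sqrt(1+E)-1)^2/E in cancellation-free form E/(sqrt(1+E)+1)^2.
baseline_family <- function(E) {
  ifelse(E == 0, 0, E / (sqrt(1 + E) + 1)^2)
}

#' @keywords internal
#' Dosed family (sqrt(E^2+F)-E)^2/(F*(1+d_rel)) in the cancellation-free
#' form F/((sqrt(E^2+F)+E)^2*(1+d_rel)).
dosed_family <- function(E, F, d_rel) {
  ifelse(F == 0, 0, F / ((sqrt(E^2 + F) + E)^2 * (1 + d_rel)))
}

#' Closed-form baseline active RAF fraction (no drug)
#'
#' Evaluates the variant's closed-form steady-state active-RAF fraction at
#' zero drug, `(sqrt(1+E) - 1)^2 / E`, with `E` the variant's baseline
#' intermediate: `E3` (CA), `E5` (CAS), `E7` (DS) or `E10` (CAS+DS); see
#' [analytic_intermediates()].
#'
#' @inheritParams analytic_intermediates
#' @param variant one of [raf_variants()].
#' @param s_free free 14-3-3 dimer (uM); may be a vector.  Ignored by the
#'   CA variant.
#' @return Active fraction(s) in `[0, 1)`.
#' @examples
#' baseline_active_fraction(raf_params(), "CA")      # ~ 6.5e-3
#' @export
baseline_active_fraction <- function(params, variant, s_free = 0,
                                     s_convention = c("free", "total")) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  s_convention <- match.arg(s_convention)
  if (any(s_free < 0)) stop("s_free must be non-negative", call. = FALSE)
  RAF_rel <- params$R_total / params$K_dim
  E <- vapply(s_free, function(s) {
    st <- variant_s_terms(params, variant, s, s_convention)
    8 * RAF_rel * (1 + st$s_rel) / (1 + params$K_A * (1 + st$S_rel))^2
  }, numeric(1))
  baseline_family(E)
}

#' Closed-form active RAF fraction under drug
#'
#' Evaluates the variant's closed-form steady-state active-RAF fraction as a
#' function of free drug and free 14-3-3,
#' `(sqrt(E^2 + F) - E)^2 / (F * (1 + d_rel))`, where `E` is the variant's
#' monomer intermediate (`E1`, `E4`, `E1`, `E9` for CA, CAS, DS, CAS+DS) and
#' `F` its dimer intermediate (`E2`, `E2`, `E6`, `E8`).  At `d_free = 0`
#' this reduces to [baseline_active_fraction()].
#'
#' @inheritParams baseline_active_fraction
#' @param d_free free drug concentration (uM); may be a vector.
#' @param s_free free 14-3-3 dimer (uM), scalar.
#' @return Active fraction(s) in `[0, 1)`, one per element of `d_free`.
#' @examples
#' p <- raf_params()
#' active_fraction(p, "CA", d_free = c(0, 0.1, 1, 10))
#' @export
active_fraction <- function(params, variant, d_free, s_free = 0,
                            s_convention = c("free", "total")) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  s_convention <- match.arg(s_convention)
  if (any(d_free < 0)) stop("d_free must be non-negative", call. = FALSE)
  if (length(s_free) != 1L || s_free < 0)
    stop("s_free must be a single non-negative number", call. = FALSE)
  st <- variant_s_terms(params, variant, s_free, s_convention)
  g <- dimensionless(params, d_free, s_free)
  E <- 1 + params$K_A * (1 + st$S_rel) + g$d_rel
  F <- 8 * g$RAF_rel * (1 + g$d_rel)^2 * (1 + st$s_rel)
  dosed_family(E, F, g$d_rel)
}

#' Dimer complexes from the active fraction
#'
#' The dimer identity shared by all four variants: dimer complexes per total
#' RAF protomer equal `(1 + d_rel) / 2` times the active fraction.
#'
#' @param active active RAF fraction(s) in `[0, 1]`.
#' @param d_rel dimensionless free drug, `d_free / K_d`.
#' @return Dimer complexes per total RAF protomer.
#' @export
dimer_fraction <- function(active, d_rel) {
  if (any(active < 0 | active > 1)) stop("active must lie in [0, 1]",
                                         call. = FALSE)
  if (any(d_rel < 0)) stop("d_rel must be non-negative", call. = FALSE)
  (1 + d_rel) / 2 * active
}

#' Analytic condition for paradoxical activation
#'
#' Evaluates the variant's closed-form inequality deciding whether the
#' active-RAF dose response rises above its drug-free baseline at small
#' doses (free drug and free 14-3-3 clamped).  All four conditions are the
#' single re-derived criterion `(3*c0 - 2) * (c0 - 2) > f0`, with
#' `c0 = 1 + K_A * (1 + S_rel)` the drug-free monomer intermediate and
#' `f0 = 8 * RAF_rel * (1 + s_rel)` the drug-free dimer intermediate,
#' specialised per variant:
#' \describe{
#'   \item{CA}{`RAF_rel < (1 + 3*K_A) * (K_A - 1) / 8`}
#'   \item{CAS}{`RAF_rel < (K_A*S_rel + K_A - 1) * (3*K_A*S_rel + 3*K_A + 1) / 8`}
#'   \item{DS}{`RAF_rel < (1 + 3*K_A) * (K_A - 1) / (8 * (1 + s_rel))`}
#'   \item{CAS+DS}{`K_A > K_Smon / (3 * (K_Smon + s)) *
#'     (1 + 2 * sqrt(1 + 6 * RAF_rel * (K_Sdim + s) / K_Sdim))`}
#' }
#' The margin is signed so that a positive margin always predicts PA:
#' `bound - RAF_rel` for the RAF_rel-bounded variants and `K_A - bound` for
#' CAS+DS.
#'
#' @inheritParams baseline_active_fraction
#' @param s_free free 14-3-3 dimer (uM), scalar.
#' @return Object of class `pa_condition`: list with `variant`, `holds`
#'   (logical), `margin` (signed, dimensionless), `bound`, and `limit_note`
#'   naming the regime in which the printed inequality is exact.
#' @examples
#' pa_condition(raf_params(), "CA")      # bound 34.875 > RAF_rel 0.4
#' @export
pa_condition <- function(params, variant, s_free = 0,
                         s_convention = c("free", "total")) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  s_convention <- match.arg(s_convention)
  if (length(s_free) != 1L || s_free < 0)
    stop("s_free must be a single non-negative number", call. = FALSE)
  st <- variant_s_terms(params, variant, s_free, s_convention)
  K_A <- params$K_A
  RAF_rel <- params$R_total / params$K_dim
  s_cas <- if (s_convention == "free") s_free else params$S_total
  switch(variant,
    CA = {
      bound <- (1 + 3 * K_A) * (K_A - 1) / 8
      margin <- bound - RAF_rel
      note <- "exact (no 14-3-3; free drug and free 14-3-3 clamped)"
    },
    CAS = {
      bound <- (K_A * st$S_rel + K_A - 1) *
        (3 * K_A * st$S_rel + 3 * K_A + 1) / 8
      margin <- bound - RAF_rel
      note <- "limit: 14-3-3 available to bind RAF in excess of RAF"
    },
    DS = {
      bound <- (1 + 3 * K_A) * (K_A - 1) / (8 * (1 + st$s_rel))
      margin <- bound - RAF_rel
      note <- "limit: free 14-3-3 unchanged by the drug (ds/dd_rel -> 0)"
    },
    CAS_DS = {
      bound <- params$K_Smon / (3 * (params$K_Smon + s_cas)) *
        (1 + 2 * sqrt(1 + 6 * RAF_rel * (params$K_Sdim + s_free) /
                        params$K_Sdim))
      margin <- K_A - bound
      note <- "limit: total 14-3-3 in excess of total RAF"
    })
  structure(list(variant = variant, holds = margin > 0, margin = margin,
                 bound = bound, limit_note = note),
            class = "pa_condition")
}

#' @export
print.pa_condition <- function(x, ...) {
  cat(sprintf("PA condition [%s]: %s (margin %+.6g, bound %.6g)\n",
              x$variant, if (x$holds) "PA predicted" else "no PA predicted",
              x$margin, x$bound))
  cat("  ", x$limit_note, "\n", sep = "")
  invisible(x)
}

#' Cross-validate the closed forms against the mass-action oracle
#'
#' Draws random parameter sets (log-uniform over wide ranges) and compares
#' [active_fraction()] and [baseline_active_fraction()] against the
#' free-clamped oracle [solve_free_clamped()] for every variant.
#'
#' @param n number of random parameter sets.
#' @param seed integer seed for reproducibility.
#' @return List with `max_rel_error` (largest relative deviation observed),
#'   `n`, and the per-variant worst deviations `by_variant`.
#' @export
verify_analytic <- function(n = 500, seed = 1) {
  set.seed(seed)
  worst <- stats::setNames(numeric(length(raf_variants())), raf_variants())
  for (i in seq_len(n)) {
    p <- raf_params(K_A = 10^stats::runif(1, -1, 3),
                    K_d = 10^stats::runif(1, -3, 1),
                    K_dim = 10^stats::runif(1, -3, 1),
                    K_Smon = 10^stats::runif(1, -3, 1),
                    K_Sdim = 10^stats::runif(1, -3, 1),
                    R_total = 10^stats::runif(1, -3, 1))
    s <- stats::runif(1, 0, 100)
    d <- stats::runif(1, 0, 1000) * p$K_d
    for (v in raf_variants()) {
      base_o <- active_raf(solve_free_clamped(p, v, 0, s))
      dose_o <- active_raf(solve_free_clamped(p, v, d, s))
      base_a <- baseline_active_fraction(p, v, s)
      dose_a <- active_fraction(p, v, d, s)
      rel <- max(abs(base_a - base_o) / max(base_o, .Machine$double.xmin),
                 abs(dose_a - dose_o) / max(dose_o, .Machine$double.xmin))
      worst[v] <- max(worst[v], rel)
    }
  }
  list(max_rel_error = max(worst), n = n, by_variant = worst)
}
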