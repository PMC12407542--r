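#' @keywords internal
#' Effective free-ligand concentrations seen by the two 14-3-3 couplings.
#' Disabled couplings see zero 14-3-3.
variant_ligands <- function(variant, d_free, s_free) {
  roles <- variant_roles(variant)
  list(d = d_free,
       s_mon = if (roles$cas) s_free else 0,
       s_dim = if (roles$ds) s_free else 0)
}

#' @keywords internal
#' Assemble the full species state from the open-monomer concentration and
#' the clamped free ligands, using the mass-action equilibrium relations.
build_state <- function(params, variant, M, d_free, s_free, mode) {
  lig <- variant_ligands(variant, d_free, s_free)
  A <- params$K_A * M
  AS <- A * lig$s_mon / params$K_Smon
  Md <- M * lig$d / params$K_d
  D00 <- M^2 / params$K_dim
  D01 <- 2 * M * Md / params$K_dim
  D11 <- Md^2 / params$K_dim
  sdim <- lig$s_dim / params$K_Sdim
  state <- list(M = M, A = A, AS = AS, Md = Md,
                D00 = D00, D01 = D01, D11 = D11,
                D00S = D00 * sdim, D01S = D01 * sdim, D11S = D11 * sdim,
                d_free = d_free, s_free = s_free)
  structure(state, class = "raf_state",
            params = params, variant = variant, mode = mode)
}

#' Solve the equilibrium with free drug and free 14-3-3 clamped
#'
#' Brute-force mass-action solve of the species network at fixed (clamped)
#' free-ligand concentrations.  The open-monomer concentration `M` is found
#' by bracketed root finding on the RAF conservation residual
#' `M*b + a*M^2 - R_total` (monotone in `M`, bracketed on `[0, R_total]`),
#' where `b` collects the monomer states and `a` the dimer states; every
#' other species then follows from the equilibrium relations
#' `A = K_A*M`, `AS = A*s/K_Smon`, `Md = M*d/K_d`, `D00 = M^2/K_dim`,
#' `D01 = 2*M*Md/K_dim`, `D11 = Md^2/K_dim`, `DxyS = Dxy*s/K_Sdim`,
#' with the couplings disabled by `variant` zeroed out.
#'
#' This function is the package's ground-truth oracle: it never evaluates the
#' closed-form active-RAF expressions of [active_fraction()].
#'
#' @param params `raf_params` object (`D_total`/`S_total` are ignored here;
#'   the free concentrations are clamped instead).
#' @param variant one of [raf_variants()].
#' @param d_free clamped free drug concentration (uM).
#' @param s_free clamped free 14-3-3 dimer concentration (uM).
#' @return An object of class `raf_state`: species concentrations `M`, `A`,
#'   `AS`, `Md`, `D00`, `D01`, `D11` (dimers with 0/1/2 drug-bound
#'   protomers; `D01` counts both orientations), `D00S`, `D01S`, `D11S`
#'   (their 14-3-3-bound forms), plus `d_free` and `s_free`, all in uM.
#' @seealso [solve_totals()] for conservation of the ligand totals,
#'   [active_raf()], [dimer_count()].
#' @examples
#' st <- solve_free_clamped(raf_params(), "CA", d_free = 0, s_free = 0)
#' active_raf(st)
#' @export
solve_free_clamped <- function(params, variant, d_free = 0, s_free = 0) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  if (!is.numeric(d_free) || length(d_free) != 1L || !is.finite(d_free) ||
      d_free < 0)
    stop("d_free must be a single non-negative number", call. = FALSE)
  if (!is.numeric(s_free) || length(s_free) != 1L || !is.finite(s_free) ||
      s_free < 0)
    stop("s_free must be a single non-negative number", call. = FALSE)
  lig <- variant_ligands(variant, d_free, s_free)
  b <- 1 + params$K_A * (1 + lig$s_mon / params$K_Smon) + lig$d / params$K_d
  a <- (2 / params$K_dim) * (1 + lig$d / params$K_d)^2 *
    (1 + lig$s_dim / params$K_Sdim)
  # root finding on log(M) keeps full *relative* precision even when the
  # open monomer is many orders of magnitude below R_total
  M <- if (params$R_total == 0) 0 else {
    lhi <- log(params$R_total)
    x <- stats::uniroot(function(x) {
      M <- exp(x)
      a * M^2 + b * M - params$R_total
    }, interval = c(lhi - 80, lhi), tol = 1e-15, maxiter = 1000L)$root
    exp(x)
  }
  build_state(params, variant, M, d_free, s_free, mode = "free_clamped")
}

#' @keywords internal
#' Open-monomer concentration from RAF conservation, stable quadratic form.
monomer_closed_form <- function(params, variant, d_free, s_free) {
  lig <- variant_ligands(variant, d_free, s_free)
  b <- 1 + params$K_A * (1 + lig$s_mon / params$K_Smon) + lig$d / params$K_d
  a <- (2 / params$K_dim) * (1 + lig$d / params$K_d)^2 *
    (1 + lig$s_dim / params$K_Sdim)
  # positive root of a*M^2 + b*M - R = 0 in the cancellation-free form
  2 * params$R_total / (b + sqrt(b^2 + 4 * a * params$R_total))
}

#' @keywords internal
#' Total drug bound in RAF species at given free ligands.
drug_bound <- function(state) {
  state$Md + state$D01 + 2 * state$D11 + state$D01S + 2 * state$D11S
}

#' @keywords internal
#' Total 14-3-3 bound in RAF species at given free ligands.
s_bound <- function(state) {
  state$AS + state$D00S + state$D01S + state$D11S
}

#' Solve the equilibrium under full conservation of RAF, drug and 14-3-3
#'
#' Extends [solve_free_clamped()] by additionally imposing drug conservation
#' `D_total = d_free + Md + D01 + 2*D11 + D01S + 2*D11S` and 14-3-3
#' conservation `S_total = s_free + AS + D00S + D01S + D11S`.  Solved by
#' nested bracketed one-dimensional root finding: the outer solve brackets
#' `d_free` in `[0, D_total]`, the inner solve brackets `s_free` in
#' `[0, S_total]`, and the innermost open-monomer concentration is the
#' positive root of the RAF-conservation quadratic in closed (stable) form.
#' Each bound-species total is monotone in its free concentration, so the
#' brackets are safe.
#'
#' @param params `raf_params`; the totals are read from
#'   `params$D_total` and `params$S_total`.
#' @param variant one of [raf_variants()].
#' @param tol relative conservation tolerance checked on the returned state.
#' @return `raf_state` (see [solve_free_clamped()]) whose conservation
#'   residuals are below `tol` relative to each total (absolute floor
#'   `tol * R_total` when a total is zero); see [conservation_residuals()].
#' @examples
#' p <- raf_params(D_total = 1)
#' st <- solve_totals(p, "CAS_DS")
#' conservation_residuals(st)
#' @export
solve_totals <- function(params, variant, tol = 1e-10) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  roles <- variant_roles(variant)
  uses_s <- (roles$cas || roles$ds) && params$S_total > 0

  state_at <- function(d_free, s_free) {
    M <- monomer_closed_form(params, variant, d_free, s_free)
    build_state(params, variant, M, d_free, s_free, mode = "totals")
  }
  solve_s <- function(d_free) {
    # without an enabled 14-3-3 coupling all 14-3-3 stays unbound
    if (!uses_s) return(params$S_total)
    f <- function(s) s + s_bound(state_at(d_free, s)) - params$S_total
    stats::uniroot(f, interval = c(0, params$S_total),
                   tol = 1e-18, maxiter = 1000L)$root
  }
  solve_d <- function() {
    if (params$D_total == 0) return(0)
    f <- function(d) d + drug_bound(state_at(d, solve_s(d))) - params$D_total
    stats::uniroot(f, interval = c(0, params$D_total),
                   tol = 1e-18, maxiter = 1000L)$root
  }

  d_free <- solve_d()
  s_free <- solve_s(d_free)
  state <- state_at(d_free, s_free)

  res <- conservation_residuals(state)
  floor_abs <- tol * max(params$R_total, .Machine$double.xmin)
  lim <- function(total) if (total > 0) tol * total else floor_abs
  ok <- abs(res$r_RAF) <= lim(params$R_total) &&
    abs(res$r_drug) <= lim(params$D_total) &&
    abs(res$r_S) <= lim(params$S_total)
  if (!ok)
    stop(sprintf(paste0("conservation solve did not converge: residuals ",
                        "r_RAF=%.3e r_drug=%.3e r_S=%.3e (uM)"),
                 res$r_RAF, res$r_drug, res$r_S), call. = FALSE)
  state
}

#' Conservation residuals of a solved state
#'
#' Signed residuals (uM) of the three conservation equations, computed
#' against the totals in the state's parameters:
#' `r_RAF = R_total - (monomers + 2 * dimers)`,
#' `r_drug = D_total - (d_free + drug bound)`,
#' `r_S = S_total - (s_free + 14-3-3 bound)`.
#' For a state produced by [solve_free_clamped()] only `r_RAF` is
#' meaningful, since the ligand totals are not constrained there.
#'
#' @param state `raf_state`.
#' @return List with numeric elements `r_RAF`, `r_drug`, `r_S`.
#' @export
conservation_residuals <- function(state) {
  stopifnot(inherits(state, "raf_state"))
  p <- attr(state, "params")
  monomers <- state$M + state$A + state$AS + state$Md
  dimers <- state$D00 + state$D01 + state$D11 +
    state$D00S + state$D01S + state$D11S
  list(r_RAF = p$R_total - (monomers + 2 * dimers),
       r_drug = p$D_total - (state$d_free + drug_bound(state)),
       r_S = p$S_total - (state$s_free + s_bound(state)))
}

#' Active RAF fraction of a solved state
#'
#' Active RAF is the sum of all RAF protomers that are both within a RAF
#' dimer and not bound to drug: `(2*D00 + D01 + 2*D00S + D01S) / R_total`.
#' Protomers in 14-3-3-bound dimers count as active when drug-free.
#'
#' @param state `raf_state`.
#' @return Fraction of total RAF protomers, in `[0, 1]`.
#' @export
active_raf <- function(state) {
  stopifnot(inherits(state, "raf_state"))
  p <- attr(state, "params")
  if (p$R_total == 0) return(0)
  (2 * state$D00 + state$D01 + 2 * state$D00S + state$D01S) / p$R_total
}

#' Dimer complexes as a fraction of total RAF protomers
#'
#' Returns `(D00 + D01 + D11 + D00S + D01S + D11S) / R_total`.  Analytically
#' this equals `(1 + d_rel) / 2 *` [active_raf()] in every solved state.
#'
#' @param state `raf_state`.
#' @return Dimer complexes per total RAF protomer.
#' @export
dimer_count <- function(state) {
  stopifnot(inherits(state, "raf_state"))
  p <- attr(state, "params")
  if (p$R_total == 0) return(0)
  (state$D00 + state$D01 + state$D11 +
     state$D00S + state$D01S + state$D11S) / p$R_total
}

#' @export
print.raf_state <- function(x, digits = 6, ...) {
  p <- attr(x, "params")
  cat(sprintf("RAF equilibrium state (variant %s, %s solve)\n",
              attr(x, "variant"), attr(x, "mode")))
  sp <- unlist(x[c("M", "A", "AS", "Md", "D00", "D01", "D11",
                   "D00S", "D01S", "D11S", "d_free", "s_free")])
  print(signif(sp, digits))
  cat(sprintf("active RAF fraction: %.*g   dimers/protomer: %.*g\n",
              digits, active_raf(x), digits, dimer_count(x)))
  invisible(x)
}

#' Flatten a solved state to a one-row data frame
#'
#' One column per species (uM) plus the free ligands, the variant, and the
#' active-RAF and dimer summaries; suitable for writing to CSV.
#'
#' @param x `raf_state`.
#' @param row.names,optional,... passed on conventions of
#'   [base::as.data.frame()]; ignored.
#' @return One-row `data.frame`.
#' @export
as.data.frame.raf_state <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(variant = attr(x, "variant"),
             as.data.frame(unclass(x)),
             active_raf = active_raf(x),
             dimer_count = dimer_count(x))
}

#' Thermodynamic cycle products of the reaction network
#'
#' Enumerates the independent thermodynamic cycles of the species graph and
#' returns each cycle's equilibrium-constant product, formed as the product
#' of pairwise association constants along one path divided by the product
#' along the alternative path.  Detailed balance requires every product to
#' equal 1; any other value indicates an inconsistent set of equilibrium
#' relations.  The pairwise constants carry the statistical factors of the
#' two-site dimer (`M + Md -> D01` has association `2/K_dim`,
#' `D00 + d -> D01` has `2/K_d`, `D01 + d -> D11` has `1/(2*K_d)`).
#'
#' @param params `raf_params`.
#' @param variant one of [raf_variants()]; variants without the DS coupling
#'   have no 14-3-3 cycles (the CAS branch is a tree).
#' @param perturb optional named numeric vector multiplying individual edge
#'   constants, e.g. `c("D00+d=D01" = 1.1)`; used as a negative control to
#'   verify the check detects a broken relation.
#' @return `data.frame` with columns `cycle` and `product`.
#' @export
check_detailed_balance <- function(params, variant, perturb = NULL) {
  stopifnot(inherits(params, "raf_params"))
  variant <- match_variant(variant)
  roles <- variant_roles(variant)
  k <- c("M+d=Md"      = 1 / params$K_d,
         "M+M=D00"     = 1 / params$K_dim,
         "M+Md=D01"    = 2 / params$K_dim,
         "Md+Md=D11"   = 1 / params$K_dim,
         "D00+d=D01"   = 2 / params$K_d,
         "D01+d=D11"   = 1 / (2 * params$K_d),
         "D00+s=D00S"  = 1 / params$K_Sdim,
         "D01+s=D01S"  = 1 / params$K_Sdim,
         "D11+s=D11S"  = 1 / params$K_Sdim,
         "D00S+d=D01S" = 2 / params$K_d,
         "D01S+d=D11S" = 1 / (2 * params$K_d))
  if (!is.null(perturb)) {
    unknown <- setdiff(names(perturb), names(k))
    if (length(unknown))
      stop("unknown edge(s) in perturb: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    k[names(perturb)] <- k[names(perturb)] * perturb
  }
  cyc <- function(path_a, path_b) prod(k[path_a]) / prod(k[path_b])
  cycles <- list(
    "M>Md>D01 vs M>D00>D01" =
      cyc(c("M+d=Md", "M+Md=D01"), c("M+M=D00", "D00+d=D01")),
    "M>D00>D01>D11 vs M>Md>D11" =
      cyc(c("M+M=D00", "D00+d=D01", "D01+d=D11"),
          c("M+d=Md", "M+d=Md", "Md+Md=D11")),
    "Md>D01>D11 vs Md>Md2=D11" =
      cyc(c("M+Md=D01", "D01+d=D11"), c("M+d=Md", "Md+Md=D11")))
  if (roles$ds) {
    cycles <- c(cycles, list(
      "D00>D00S>D01S vs D00>D01>D01S" =
        cyc(c("D00+s=D00S", "D00S+d=D01S"), c("D00+d=D01", "D01+s=D01S")),
      "D01>D01S>D11S vs D01>D11>D11S" =
        cyc(c("D01+s=D01S", "D01S+d=D11S"), c("D01+d=D11", "D11+s=D11S"))))
  }
  data.frame(cycle = names(cycles), product = unlist(cycles, use.names = FALSE))
}
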