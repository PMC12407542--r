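# Shared fixtures and independent oracles for the test suite.

# Reference parameter set used throughout descriptive checks.
default_params <- function(...) raf_params(...)

# Log-uniform random parameter sets over the wide ranges used for
# oracle-equivalence checks: K_A in [1e-1, 1e3], dissociation constants in
# [1e-3, 1e1] uM, R_total in [1e-3, 1e1] uM.
random_params <- function() {
  raf_params(K_A = 10^runif(1, -1, 3),
             K_d = 10^runif(1, -3, 1),
             K_dim = 10^runif(1, -3, 1),
             K_Smon = 10^runif(1, -3, 1),
             K_Sdim = 10^runif(1, -3, 1),
             R_total = 10^runif(1, -3, 1),
             S_total = 10^runif(1, -3, 2),
             D_total = 10^runif(1, -3, 2))
}

# Independent brute-force active-fraction oracle: plain interval-halving
# bisection on the RAF conservation sum, then explicit summation of the
# drug-free dimer protomers.  Shares no code with the package solvers.
bisect_active <- function(p, variant, d, s, iters = 200) {
  cas <- variant %in% c("CAS", "CAS_DS")
  ds <- variant %in% c("DS", "CAS_DS")
  sm <- if (cas) s else 0
  sd <- if (ds) s else 0
  species <- function(M) {
    A <- p$K_A * M
    AS <- A * sm / p$K_Smon
    Md <- M * d / p$K_d
    D00 <- M^2 / p$K_dim
    D01 <- 2 * M * Md / p$K_dim
    D11 <- Md^2 / p$K_dim
    f <- sd / p$K_Sdim
    list(M = M, A = A, AS = AS, Md = Md, D00 = D00, D01 = D01, D11 = D11,
         D00S = D00 * f, D01S = D01 * f, D11S = D11 * f)
  }
  total_raf <- function(M) {
    sp <- species(M)
    sp$M + sp$A + sp$AS + sp$Md +
      2 * (sp$D00 + sp$D01 + sp$D11 + sp$D00S + sp$D01S + sp$D11S)
  }
  lo <- 0
  hi <- p$R_total
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (total_raf(mid) > p$R_total) hi <- mid else lo <- mid
  }
  sp <- species((lo + hi) / 2)
  (2 * sp$D00 + sp$D01 + 2 * sp$D00S + sp$D01S) / p$R_total
}

# Relative difference guarded against zero denominators.
rel_diff <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.xmin)

# Fresh per-test output directory under tempdir().
withr_like_tempdir <- function(tag) {
  d <- file.path(tempdir(), paste0("rafpa-", tag))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# Crossover of a curve already in hand.
pa_crossover_of_curve <- function(curve) pa_crossover(curve)

# One sweep metric at the parameter point itself (degenerate 1x1 sweep).
sweep_metric_value <- function(p, variant, metric, doses) {
  g <- sweep_grid(p, variant,
                  axis1 = list(name = "K_A", values = p$K_A),
                  axis2 = list(name = "K_d", values = p$K_d),
                  metric = metric, doses = doses)
  g$value
}
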