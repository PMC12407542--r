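#' Model variants
#'
#' The four equilibrium model variants differ in which 14-3-3 couplings are
#' enabled:
#'
#' * `"CA"` — conformational autoinhibition only; no 14-3-3 interactions.
#' * `"CAS"` — 14-3-3 binds (and stabilizes) the autoinhibited monomer.
#' * `"DS"` — 14-3-3 binds (and stabilizes) the RAF dimer.
#' * `"CAS_DS"` — both couplings enabled.
#'
#' @return Character vector of the four variant tags.
#' @export
raf_variants <- function() c("CA", "CAS", "DS", "CAS_DS")

#' @keywords internal
match_variant <- function(variant) {
  match.arg(variant, raf_variants())
}

#' Which 14-3-3 couplings a variant enables
#'
#' @param variant one of [raf_variants()].
#' @return List with logical elements `cas` (14-3-3 binds the autoinhibited
#'   monomer) and `ds` (14-3-3 binds the RAF dimer).
#' @export
variant_roles <- function(variant) {
  variant <- match_variant(variant)
  list(cas = variant %in% c("CAS", "CAS_DS"),
       ds  = variant %in% c("DS", "CAS_DS"))
}

raf_param_fields <- c("K_A", "K_d", "K_dim", "K_Smon", "K_Sdim",
                      "R_total", "S_total", "D_total")

#' Model parameters
#'
#' Container for the equilibrium constants and total concentrations that
#' define one model instance.  All concentrations are micromolar; 14-3-3 is
#' counted in dimer units.  The defaults are the reference parameter set used
#' for all descriptive simulations in the package.
#'
#' @param K_A dimensionless autoinhibition equilibrium constant, the ratio of
#'   autoinhibited to open monomer at equilibrium.  Larger `K_A` means
#'   stronger autoinhibition.  Must be >= 0 (`K_A = 0` disables
#'   autoinhibition).
#' @param K_d drug-protomer dissociation constant (uM).  A single `K_d`
#'   applies to the open monomer and to each dimer protomer independently
#'   (no binding cooperativity between the two dimer sites).
#' @param K_dim RAF dimerization dissociation constant (uM).
#' @param K_Smon dissociation constant of the 14-3-3 dimer binding the
#'   autoinhibited monomer (uM); used by the CAS coupling.
#' @param K_Sdim dissociation constant of the 14-3-3 dimer binding the RAF
#'   dimer (uM); used by the DS coupling.
#' @param R_total total RAF protomer concentration (uM).
#' @param S_total total 14-3-3 dimer concentration (uM).
#' @param D_total total drug concentration (uM).
#' @return An object of class `raf_params` (named list of the eight fields).
#' @examples
#' p <- raf_params()                  # reference parameter set
#' raf_params(K_A = 0)                # no-autoinhibition limit
#' @export
raf_params <- function(K_A = 10, K_d = 0.1, K_dim = 0.1,
                       K_Smon = 0.2, K_Sdim = 0.02,
                       R_total = 0.04, S_total = 1.0, D_total = 0) {
  p <- list(K_A = K_A, K_d = K_d, K_dim = K_dim,
            K_Smon = K_Smon, K_Sdim = K_Sdim,
            R_total = R_total, S_total = S_total, D_total = D_total)
  validate_raf_params(p)
  structure(p, class = "raf_params")
}

#' @keywords internal
validate_raf_params <- function(p) {
  for (f in raf_param_fields) {
    v <- p[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
  }
  for (f in c("K_d", "K_dim", "K_Smon", "K_Sdim")) {
    if (p[[f]] <= 0)
      stop("dissociation constant '", f, "' must be strictly positive (got ",
           p[[f]], ")", call. = FALSE)
  }
  for (f in c("K_A", "R_total", "S_total", "D_total")) {
    if (p[[f]] < 0)
      stop("parameter '", f, "' must be non-negative (got ", p[[f]], ")",
           call. = FALSE)
  }
  invisible(p)
}

#' Build parameters from a named list or vector
#'
#' Accepts any mapping whose names are the [raf_params()] field names.
#' Fields missing from `values` take the package defaults unless
#' `require_all = TRUE`.  Unknown names are an error.
#'
#' @param values named list or numeric vector.
#' @param require_all if `TRUE`, every field must be present.
#' @return `raf_params` object.
#' @export
as_raf_params <- function(values, require_all = FALSE) {
  values <- as.list(values)
  unknown <- setdiff(names(values), raf_param_fields)
  if (length(unknown))
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (require_all) {
    missing <- setdiff(raf_param_fields, names(values))
    if (length(missing))
      stop("missing parameter field(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  do.call(raf_params, values)
}

#' Read parameters from a flat config file
#'
#' Reads a flat key-value config in JSON (`.json`) or YAML (`.yml`/`.yaml`)
#' with exactly the [raf_params()] field names, then applies any overrides.
#'
#' @param path config file path.
#' @param overrides named list of fields overriding the file (e.g. from CLI
#'   flags).
#' @return `raf_params` object.
#' @export
read_raf_params <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  values <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read YAML configs",
             call. = FALSE)
      yaml::read_yaml(path)
    },
    stop("unsupported config extension '.", ext, "' (use .json or .yaml)",
         call. = FALSE))
  values[names(overrides)] <- overrides
  as_raf_params(values)
}

#' @export
print.raf_params <- function(x, ...) {
  cat("RAF equilibrium parameters (concentrations in uM)\n")
  cat(sprintf("  K_A = %g   K_d = %g   K_dim = %g\n", x$K_A, x$K_d, x$K_dim))
  cat(sprintf("  K_Smon = %g   K_Sdim = %g\n", x$K_Smon, x$K_Sdim))
  cat(sprintf("  R_total = %g   S_total = %g   D_total = %g\n",
              x$R_total, x$S_total, x$D_total))
  invisible(x)
}

#' Dimensionless groups
#'
#' The four dimensionless ratios that control the closed-form solutions:
#' `RAF_rel = R_total / K_dim`, `d_rel = d_free / K_d`,
#' `s_rel = s_free / K_Sdim` (DS coupling) and
#' `S_rel = s_free / K_Smon` (CAS coupling).
#'
#' @param params `raf_params` object.
#' @param d_free free (unbound) drug concentration, uM.  May be a vector.
#' @param s_free free (unbound) 14-3-3 dimer concentration, uM.  May be a
#'   vector (recycled against `d_free`).
#' @return List with numeric elements `RAF_rel`, `d_rel`, `s_rel`, `S_rel`.
#' @examples
#' dimensionless(raf_params(), d_free = 0, s_free = 1)
#' @export
dimensionless <- function(params, d_free = 0, s_free = 0) {
  stopifnot(inherits(params, "raf_params"))
  if (any(d_free < 0)) stop("d_free must be non-negative", call. = FALSE)
  if (any(s_free < 0)) stop("s_free must be non-negative", call. = FALSE)
  list(RAF_rel = params$R_total / params$K_dim,
       d_rel = d_free / params$K_d,
       s_rel = s_free / params$K_Sdim,
       S_rel = s_free / params$K_Smon)
}

#' Trade dimer-stabilization strength against autoinhibition stabilization
#'
#' Applies the meta-parameter `alpha` that tilts the balance between the two
#' 14-3-3 roles: `K_Sdim` is multiplied by `alpha` and `K_Smon` is divided by
#' `alpha`.  A small `alpha` favors strong DS and weak CAS; a large `alpha`
#' favors weak DS and strong CAS; `alpha = 1` is the identity.
#'
#' @param params `raf_params` object.
#' @param alpha strictly positive scalar.
#' @return New `raf_params` with `K_Sdim * alpha` and `K_Smon / alpha`; all
#'   other fields unchanged.
#' @examples
#' apply_alpha(raf_params(), 10)
#' @export
apply_alpha <- function(params, alpha) {
  stopifnot(inherits(params, "raf_params"))
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single strictly positive number", call. = FALSE)
  params$K_Sdim <- params$K_Sdim * alpha
  params$K_Smon <- params$K_Smon / alpha
  validate_raf_params(params)
  params
}
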