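#' @keywords internal
#' Write a JSON sidecar embedding the resolved configuration so every
#' artifact can be reproduced from its sidecar alone.
write_sidecar <- function(csv_path, config) {
  config$package <- "rafpa"
  config$version <- as.character(utils::packageVersion("rafpa"))
  path <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

#' @keywords internal
write_tidy_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' @keywords internal
check_outdir <- function(outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  outdir
}

#' Four-variant dose-response panel
#'
#' Computes dose-response curves for all four model variants at one
#' parameter set and writes them in both normalizations: relative to the
#' drug-free baseline and percent of total RAF.  Deterministic.
#'
#' @param outdir output directory (created if needed).
#' @param params `raf_params`; defaults to the reference set.
#' @param doses dose grid (total drug, uM).
#' @param mode,engine passed to [dose_response()].
#' @return Invisibly, a list with the tidy curve `data` (long format:
#'   `dose`, `variant`, `normalization`, `value`) and the paths written
#'   (`csv_relative`, `csv_percent`, sidecars).
#' @export
run_fig2b <- function(outdir, params = raf_params(),
                      doses = default_dose_grid(),
                      mode = "total_drug", engine = "analytic") {
  check_outdir(outdir)
  rows <- lapply(raf_variants(), function(v) {
    curve <- dose_response(params, v, doses, mode, engine)
    data.frame(dose = curve$dose, variant = v,
               relative = curve$active / attr(curve, "baseline"),
               percent = 100 * curve$active)
  })
  all <- do.call(rbind, rows)
  config <- list(driver = "fig2b", params = unclass(params), mode = mode,
                 engine = engine,
                 doses = list(min = min(doses[doses > 0]), max = max(doses),
                              n = length(doses)))
  rel <- all[, c("dose", "variant", "relative")]
  pct <- all[, c("dose", "variant", "percent")]
  f_rel <- write_tidy_csv(rel, file.path(outdir, "dose_response_relative.csv"))
  f_pct <- write_tidy_csv(pct, file.path(outdir, "dose_response_percent.csv"))
  s1 <- write_sidecar(f_rel, c(config, list(normalization = "relative")))
  s2 <- write_sidecar(f_pct, c(config, list(normalization = "percent")))
  invisible(list(data = all, csv_relative = f_rel, csv_percent = f_pct,
                 sidecars = c(s1, s2)))
}

#' PA-range contour grids
#'
#' Crossover-dose (PA range) grids over autoinhibition propensity crossed
#' with RAF abundance (`K_A` x `R_total`) and with 14-3-3 abundance
#' (`K_A` x `S_total`), for each requested variant.  Cells without PA hold
#' `NA`.  By default the grids are computed with the free-drug clamp
#' `s_free = S_total` (the excess-14-3-3 regime of the analytic
#' conditions); pass `mode = "total_drug"` for the full conservation solve.
#'
#' @inheritParams run_fig2b
#' @param variants variants to sweep.
#' @param K_A_values,R_total_values,S_total_values axis values.
#' @param mode,engine passed to [sweep_grid()].
#' @return Invisibly, list with the long `data` (`variant`, `grid`,
#'   `axis1`, `axis2`, `value`) and the written `csv` path.
#' @export
run_fig2c <- function(outdir, params = raf_params(),
                      variants = c("CAS", "DS", "CAS_DS"),
                      K_A_values = 10^seq(0, 2, length.out = 9),
                      R_total_values = 10^seq(-3, 0, length.out = 7),
                      S_total_values = 10^seq(-2, 2, length.out = 7),
                      doses = default_dose_grid(),
                      mode = "free_drug", engine = "analytic") {
  check_outdir(outdir)
  rows <- list()
  for (v in variants) {
    g1 <- sweep_grid(params, v,
                     axis1 = list(name = "K_A", values = K_A_values),
                     axis2 = list(name = "R_total", values = R_total_values),
                     metric = "crossover_dose", doses = doses,
                     mode = mode, engine = engine)
    g2 <- sweep_grid(params, v,
                     axis1 = list(name = "K_A", values = K_A_values),
                     axis2 = list(name = "S_total", values = S_total_values),
                     metric = "crossover_dose", doses = doses,
                     mode = mode, engine = engine)
    rows[[paste0(v, "_KA_RAF")]] <- data.frame(variant = v,
                                               grid = "K_A_x_R_total", g1)
    rows[[paste0(v, "_KA_S")]] <- data.frame(variant = v,
                                             grid = "K_A_x_S_total", g2)
  }
  all <- do.call(rbind, c(rows, make.row.names = FALSE))
  f <- write_tidy_csv(all, file.path(outdir, "pa_range_contours.csv"))
  write_sidecar(f, list(driver = "fig2c", params = unclass(params),
                        variants = variants, mode = mode, engine = engine,
                        K_A_values = K_A_values,
                        R_total_values = R_total_values,
                        S_total_values = S_total_values))
  invisible(list(data = all, csv = f))
}

#' 14-3-3 abundance x alpha sweep
#'
#' The CAS+DS model swept over total 14-3-3 crossed with the meta-parameter
#' `alpha` of [apply_alpha()] (small `alpha` = DS-dominant, large `alpha` =
#' CAS-dominant), for four metrics: baseline percent, maximal percent,
#' PA fold change and PA range.  Uses the full conservation solve by
#' default, making no assumption about the relative levels of 14-3-3 and
#' RAF.
#'
#' @inheritParams run_fig2b
#' @param S_total_values,alpha_values axis values.
#' @param metrics subset of the four sweep metrics.
#' @param mode,engine passed to [sweep_grid()].
#' @return Invisibly, list with long `data` (`metric`, `S_total`, `alpha`,
#'   `value`) and the written `csv` path.
#' @export
run_s2_alpha <- function(outdir, params = raf_params(),
                         S_total_values = 10^seq(-3, 2, length.out = 11),
                         alpha_values = 10^seq(-2, 2, length.out = 9),
                         metrics = c("baseline_pct", "max_pct",
                                     "fold_change", "crossover_dose"),
                         doses = default_dose_grid(),
                         mode = "total_drug", engine = "analytic") {
  check_outdir(outdir)
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(metrics, function(m) {
    g <- sweep_grid(params, "CAS_DS",
                    axis1 = list(name = "S_total", values = S_total_values),
                    axis2 = list(name = "alpha", values = alpha_values),
                    metric = m, doses = doses, mode = mode, engine = engine)
    data.frame(metric = m, S_total = g$axis1, alpha = g$axis2,
               value = g$value)
  })
  all <- do.call(rbind, rows)
  f <- write_tidy_csv(all, file.path(outdir, "s14_3_3_alpha_sweep.csv"))
  write_sidecar(f, list(driver = "s2alpha", params = unclass(params),
                        S_total_values = S_total_values,
                        alpha_values = alpha_values, metrics = metrics,
                        mode = mode, engine = engine))
  invisible(list(data = all, csv = f))
}
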