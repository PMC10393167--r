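#' Substrate-stiffness sweep of the multi-scale model
#'
#' Runs `replicates` Gillespie simulations of [run_multiscale()] at every
#' Young's modulus in `E_grid` and collects the per-replicate summaries in a
#' tidy data frame (one row per replicate x stiffness). This is the standard
#' rigidity-sensing experiment: traction rises with stiffness up to a plateau
#' around 10 kPa while the retrograde flow slows.
#'
#' @param config a [multiscale_config()]; its `E` is overridden by the grid.
#' @param E_grid Young's moduli (kPa); default 10 log-spaced values in
#'   0.1--100 kPa.
#' @param replicates Gillespie replicates per stiffness.
#' @param seed integer; replicate `r` at grid point `g` uses seed
#'   `seed + 1000 * (g - 1) + r` so every run is independently reproducible.
#' @return a data frame of class `sweep_result` with columns `E`, `replicate`,
#'   `seed` and the per-replicate summary columns of [run_multiscale()].
#' @export
stiffness_sweep <- function(config, E_grid = 10^seq(-1, 2, length.out = 10),
                            replicates = 10, seed = 1) {
  stopifnot(all(E_grid > 0), replicates >= 1)
  rows <- list()
  for (g in seq_along(E_grid)) {
    cfg <- config
    cfg$E <- E_grid[g]
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * (g - 1L) + r
      res <- run_multiscale(cfg, seed = s)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(E = E_grid[g], replicate = r, seed = s), res$summary)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Sensitivity scan over integrin bond parameters
#'
#' Full factorial scan of one bond parameter against substrate stiffness.
#' Scanned parameters: `k_ont` (linear scale), `k_off_slip` and `k_off_catch`
#' (exponential scale, to cover orders of magnitude), and `F_b` (linear),
#' which ties `F_b_slip = F_b_catch` as is conventional for this scan.
#' Default ranges span the preset value by one order of magnitude
#' (exponential parameters) or +/-50% (linear parameters).
#'
#' @param config a [multiscale_config()].
#' @param param one of `"k_ont"`, `"k_off_slip"`, `"k_off_catch"`, `"F_b"`.
#' @param values parameter values to scan; `NULL` for the default range.
#' @param n_values number of values in the default range.
#' @param E_grid Young's moduli (kPa).
#' @param replicates Gillespie replicates per cell.
#' @param seed integer seed (per-run offsets as in [stiffness_sweep()]).
#' @return a tidy data frame, one row per (value, E, replicate), with the
#'   scanned `param`, `value`, and summary columns.
#' @export
sensitivity_scan <- function(config,
                             param = c("k_ont", "k_off_slip", "k_off_catch",
                                       "F_b"),
                             values = NULL, n_values = 5,
                             E_grid = c(0.1, 1, 10, 100), replicates = 10,
                             seed = 1) {
  param <- match.arg(param)
  law <- config$integrin$law
  base <- switch(param,
                 k_ont = config$integrin$k_ont,
                 k_off_slip = law$k_off_slip,
                 k_off_catch = law$k_off_catch,
                 F_b = law$F_b_slip)
  if (is.null(values)) {
    values <- if (param %in% c("k_off_slip", "k_off_catch")) {
      10^seq(log10(base) - 1, log10(base) + 1, length.out = n_values)
    } else {
      seq(0.5 * base, 1.5 * base, length.out = n_values)
    }
  }
  stopifnot(all(values > 0))
  rows <- list()
  for (k in seq_along(values)) {
    cfg <- config
    v <- values[k]
    if (param == "k_ont") {
      cfg$integrin$k_ont <- v
    } else if (param == "F_b") {
      cfg$integrin$law$F_b_slip <- v
      cfg$integrin$law$F_b_catch <- v
    } else {
      cfg$integrin$law[[param]] <- v
    }
    sw <- stiffness_sweep(cfg, E_grid = E_grid, replicates = replicates,
                          seed = seed + 100000L * (k - 1L))
    rows[[length(rows) + 1]] <- cbind(data.frame(param = param, value = v),
                                      as.data.frame(sw))
  }
  do.call(rbind, rows)
}

#' Ligand-spacing experiment
#'
#' For each row of a user-supplied table of (stiffness, ligand spacing,
#' adhesion radius) -- typically adhesion sizes measured as a function of
#' substrate stiffness for different ligand spacings -- builds the ligand
#' layout from that row's geometry and runs the multi-scale engine. The
#' adhesion-size-versus-stiffness data themselves are an experimental input,
#' not something the model predicts.
#'
#' @param config a [multiscale_config()] (integrin preset, talin, motors).
#' @param table data frame with columns `E` (kPa), `d` (nm) and either `a`
#'   (nm) or `n_c`; `a` takes precedence.
#' @param replicates Gillespie replicates per row.
#' @param seed integer seed.
#' @return a tidy data frame, one row per (table row, replicate), with `E`,
#'   `d`, `a`, `n_c` and the summary columns.
#' @export
spacing_experiment <- function(config, table, replicates = 10, seed = 1) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop("the spacing experiment needs a non-empty (E, d, a) table", call. = FALSE)
  }
  if (!all(c("E", "d") %in% names(table)) ||
      !any(c("a", "n_c") %in% names(table))) {
    stop("table must have columns E, d and a (or n_c)", call. = FALSE)
  }
  rows <- list()
  for (k in seq_len(nrow(table))) {
    d <- table$d[k]
    a <- if ("a" %in% names(table) && !is.na(table$a[k])) {
      table$a[k]
    } else {
      # invert the count rule n_c = ceil(pi a^2 / d^2)
      sqrt(table$n_c[k] / pi) * d
    }
    layout <- make_ligand_layout(a, d)
    cfg <- config
    cfg$E <- table$E[k]
    cfg$layout <- layout
    cfg$motors <- motor_ensemble(n_m = layout$n_c,
                                 F_m = config$motors$F_m,
                                 v_u = config$motors$v_u)
    for (r in seq_len(replicates)) {
      s <- seed + 1000L * (k - 1L) + r
      res <- run_multiscale(cfg, seed = s)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(E = table$E[k], d = d, a = a, n_c = layout$n_c,
                   replicate = r, seed = s), res$summary)
    }
  }
  do.call(rbind, rows)
}

#' Deterministic miniature configurations for testing
#'
#' @param kind `"tiny_adhesion"` (a <= 5-ligand adhesion), `"single_chain"`,
#'   or `"two_clutch_oracle"` (2 ligands, talin frozen folded, near-rigid
#'   substrate: the regime where the Gillespie engine must match the
#'   classical Monte-Carlo model).
#' @param seed integer recorded in the fixture.
#' @return a list with a `config` ([multiscale_config()] or argument list)
#'   and `expect`, documented invariants of the fixture.
#' @export
fixture_generator <- function(kind = c("tiny_adhesion", "single_chain",
                                       "two_clutch_oracle"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "tiny_adhesion") {
    layout <- make_ligand_layout(a = 120, d = 100)  # ceil(pi*1.44) = 5
    cfg <- multiscale_config(integrin = "alpha5beta1", E = 10, layout = layout,
                             motors = motor_ensemble(n_m = layout$n_c),
                             t_f = 5)
    list(kind = kind, seed = seed, config = cfg,
         expect = list(n_c = 5L, count_rule = ceiling(pi * 120^2 / 100^2)))
  } else if (kind == "single_chain") {
    list(kind = kind, seed = seed,
         config = list(E = 100, motors = motor_ensemble(20), t_f = 8),
         expect = list(always_bound = TRUE, n_c = 1L))
  } else {
    frozen <- talin_default_params()
    frozen$k_unf0[] <- 0
    frozen$unfoldable[] <- FALSE
    # force-independent unbinding so the stationary bound fraction has the
    # analytic two-state value k_on / (k_on + k_off)
    custom <- list(name = "custom",
                   law = bond_law("slip", k_off = 1.2, F_b = 1e9),
                   k_ont = 1.5, cmr = FALSE)
    cfg <- multiscale_config(integrin = custom, E = 1e5,
                             layout = make_ligand_layout(a = 79, d = 100),
                             d_int0 = 1, talin = frozen, recruitment = "none",
                             motors = motor_ensemble(2), t_f = 50)
    list(kind = kind, seed = seed, config = cfg,
         expect = list(n_c = 2L, talin_frozen = TRUE,
                       p_bound = 1.5 / (1.5 + 1.2)))
  }
}

#' Write traces and summaries with a reproducibility manifest
#'
#' Writes tidy CSV files for a list of traces and/or a summary data frame,
#' plus a JSON manifest recording the configuration, seeds, package version
#' and the talin parameter checksum, so any output can be regenerated.
#'
#' @param traces list of `clutch_trace` objects (or `NULL`).
#' @param stats a data frame of summary rows (or `NULL`).
#' @param path output directory (created if needed).
#' @param seed the seed(s) used to produce the outputs.
#' @return invisibly, the manifest list.
#' @export
write_outputs <- function(traces = NULL, stats = NULL, path, seed = NA) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(traces)) {
    if (inherits(traces, "clutch_trace")) traces <- list(traces)
    for (k in seq_along(traces)) {
      f <- file.path(path, sprintf("trace_%03d.csv", k))
      utils::write.csv(traces[[k]]$trace, f, row.names = FALSE)
      files <- c(files, f)
    }
  }
  if (!is.null(stats)) {
    f <- file.path(path, "summary.csv")
    utils::write.csv(as.data.frame(stats), f, row.names = FALSE)
    files <- c(files, f)
  }
  cfg <- if (!is.null(traces) && length(traces) > 0) traces[[1]]$config else NULL
  manifest <- list(
    package = "clutchms",
    version = as.character(utils::packageVersion("clutchms")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    files = basename(files),
    config = .serialize_config(cfg))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

.serialize_config <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  list(
    integrin = cfg$integrin$name,
    law = unclass(cfg$integrin$law)[!vapply(unclass(cfg$integrin$law), is.null,
                                            logical(1))],
    E = cfg$E, a = cfg$layout$a, d = cfg$layout$d, n_c = cfg$layout$n_c,
    nu = cfg$nu, kappa_c = cfg$kappa_c, d_int0 = cfg$d_int0,
    int_add = cfg$int_add, m_r = cfg$m_r, recruitment = cfg$recruitment,
    k_onv = cfg$k_onv, kBT = cfg$kBT,
    motors = if (!is.null(cfg$motors)) unclass(cfg$motors) else NULL,
    t_f = cfg$t_f, record_dt = cfg$record_dt, tol = cfg$tol,
    talin = if (!is.null(cfg$talin)) as.data.frame(cfg$talin) else NULL)
}
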