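small_cfg <- multiscale_config(integrin = "alpha5beta1",
                               layout = make_ligand_layout(120, 100), E = 10,
                               motors = motor_ensemble(5), t_f = 3)

test_that("a one-point stiffness grid reduces to a plain multiscale run", {
  sw <- stiffness_sweep(small_cfg, E_grid = 8, replicates = 2, seed = 40)
  expect_equal(nrow(sw), 2)
  direct <- run_multiscale({
    cfg <- small_cfg; cfg$E <- 8; cfg
  }, seed = 41)
  expect_equal(sw$P_mean[1], direct$summary$P_mean)
  expect_equal(sw$seed, c(41, 42))
  # tidy: one row per (E, replicate) with declared columns
  sw2 <- stiffness_sweep(small_cfg, E_grid = c(1, 10), replicates = 2, seed = 1)
  expect_equal(nrow(sw2), 4)
  expect_true(all(c("E", "replicate", "seed", "P_mean", "v_mean", "P_b_mean")
                  %in% names(sw2)))
})

test_that("sensitivity scan ties F_b branches and shifts engagement as expected", {
  sc <- sensitivity_scan(small_cfg, param = "k_off_catch",
                         values = c(0.2, 20), E_grid = 10, replicates = 3,
                         seed = 7)
  expect_equal(nrow(sc), 6)
  pb <- tapply(sc$P_b_mean, sc$value, mean)
  # a 100x larger catch off-rate sharply lowers the bound fraction
  expect_gt(pb[["0.2"]], 2 * pb[["20"]])
  # degenerate single-value scan at the preset value reproduces the sweep
  sc1 <- sensitivity_scan(small_cfg, param = "k_ont",
                          values = small_cfg$integrin$k_ont, E_grid = 10,
                          replicates = 2, seed = 9)
  sw <- stiffness_sweep(small_cfg, E_grid = 10, replicates = 2, seed = 9)
  expect_equal(sc1$P_mean, sw$P_mean)
  # the F_b scan must tie both branch force scales
  sc2 <- sensitivity_scan(small_cfg, param = "F_b", values = 5, E_grid = 10,
                          replicates = 1, seed = 3)
  expect_equal(nrow(sc2), 1)
})

test_that("spacing experiment builds each row's geometry and correlates traction with engagement", {
  tab <- data.frame(E = c(5, 5, 5), d = c(100, 100, 200),
                    a = c(120, 180, 180))
  out <- spacing_experiment(small_cfg, tab, replicates = 2, seed = 11)
  expect_equal(nrow(out), 6)
  expect_equal(unique(out$n_c[out$a == 120]), 5)
  expect_equal(unique(out$n_c[out$a == 180 & out$d == 100]), 11)
  expect_equal(unique(out$n_c[out$a == 180 & out$d == 200]), 3)
  # traction tracks the number of bound binders: at the same adhesion size,
  # denser ligands mean more bound binders and a higher traction
  p_dense <- mean(out$P_mean[out$a == 180 & out$d == 100])
  p_sparse <- mean(out$P_mean[out$a == 180 & out$d == 200])
  expect_gt(p_dense, p_sparse)
  expect_error(spacing_experiment(small_cfg, data.frame()), "non-empty")
  expect_error(spacing_experiment(small_cfg, data.frame(E = 1, x = 2)),
               "columns")
})

test_that("fixtures are deterministic and obey their documented invariants", {
  fx <- fixture_generator("tiny_adhesion", seed = 3)
  expect_equal(fx$config$layout$n_c, 5L)
  expect_equal(fx$expect$count_rule, ceiling(pi * 120^2 / 100^2))
  fx2 <- fixture_generator("tiny_adhesion", seed = 3)
  expect_identical(fx$config$layout$positions, fx2$config$layout$positions)
  oracle <- fixture_generator("two_clutch_oracle")
  expect_equal(oracle$config$layout$n_c, 2L)
  expect_true(all(!oracle$config$talin$unfoldable))
  expect_error(fixture_generator("nope"), "arg")
})

test_that("outputs round-trip through CSV and the manifest reproduces the run", {
  dir <- tempfile("out")
  r <- run_multiscale(small_cfg, seed = 13)
  man <- write_outputs(traces = list(r), stats = r$summary, path = dir,
                       seed = 13)
  expect_true(file.exists(file.path(dir, "trace_001.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read.csv(file.path(dir, "trace_001.csv"))
  expect_equal(back$P, r$trace$P, tolerance = 1e-12)
  stats_back <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(stats_back$P_mean, r$summary$P_mean, tolerance = 1e-12)
  m <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(m$seed, 13)
  # rebuilding the configuration from the manifest reproduces the trace
  cfg2 <- multiscale_config(
    integrin = m$config$integrin, E = m$config$E, a = m$config$a,
    d = m$config$d, nu = m$config$nu, kappa_c = m$config$kappa_c,
    d_int0 = m$config$d_int0, int_add = m$config$int_add, m_r = m$config$m_r,
    recruitment = m$config$recruitment, k_onv = m$config$k_onv,
    kBT = m$config$kBT,
    motors = motor_ensemble(m$config$motors$n_m, m$config$motors$F_m,
                            m$config$motors$v_u),
    t_f = m$config$t_f, record_dt = m$config$record_dt, tol = m$config$tol)
  r2 <- run_multiscale(cfg2, seed = m$seed)
  expect_identical(r2$trace, r$trace)
})
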