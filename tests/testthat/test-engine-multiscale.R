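tiny_cfg <- function(...) {
  args <- utils::modifyList(
    list(integrin = "alpha5beta1", layout = make_ligand_layout(a = 120, d = 100),
         E = 10, motors = motor_ensemble(5), t_f = 5),
    list(...))
  do.call(multiscale_config, args)
}

test_that("equilibrate: no bound chains means no force and unloaded flow", {
  st <- adhesion_state(tiny_cfg())
  st <- equilibrate(st)
  expect_equal(st$F, numeric(5))
  expect_equal(st$F_sub, 0)
  expect_equal(st$v, 110)
  expect_equal(st$traction, 0)
})

test_that("equilibrate: one bound chain matches the linearised compliance oracle", {
  cfg <- tiny_cfg()
  st <- adhesion_state(cfg)
  st$bound[2] <- TRUE
  D <- 0.02
  st$D[2] <- D
  st <- equilibrate(st)
  # series compliance at zero force: folded FJC rod + integrin + substrate
  c_rod <- sum(cfg$talin$l0^2 / (3 * cfg$kBT))
  g_diag <- diag(st$G$G)[2]
  F_lin <- D / (c_rod + 1 / cfg$kappa_c + g_diag)
  expect_equal(st$F[2], F_lin, tolerance = 1e-3)
  expect_equal(st$F_sub, st$F[2])
  # residual of the compatibility equation
  rod <- talin_rod_state(params = cfg$talin)
  res <- rod_extension(st$F[2], rod, cfg$talin) + st$F[2] / cfg$kappa_c +
    (st$G$G %*% st$F)[2] - D
  expect_lt(abs(res), 1e-6)
})

test_that("equilibrate is invariant under chain relabelling", {
  cfg <- tiny_cfg()
  set.seed(21)
  st <- adhesion_state(cfg)
  st$bound <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  st$D <- c(25, 80, 0, 150, 0) * st$bound
  st$folded[2, c(3, 5)] <- FALSE
  st$folded[4, 3] <- FALSE
  st1 <- equilibrate(st)
  perm <- c(4, 2, 5, 1, 3)
  stp <- st
  stp$bound <- st$bound[perm]; stp$D <- st$D[perm]
  stp$folded <- st$folded[perm, ]; stp$F <- st$F[perm]
  stp$G$G <- st$G$G[perm, perm]
  st2 <- equilibrate(stp)
  expect_equal(st2$F, st1$F[perm], tolerance = 1e-9)
  expect_equal(st2$F_sub, st1$F_sub, tolerance = 1e-9)
})

test_that("force balance holds after every Gillespie step", {
  cfg <- tiny_cfg()
  set.seed(31)
  st <- equilibrate(adhesion_state(cfg))
  for (k in 1:120) {
    st <- gillespie_step(st)
    if (st$t >= cfg$t_f) break
    ib <- which(st$bound & st$F > 0)
    for (i in ib) {
      rod <- talin_rod_state(folded = st$folded[i, ], params = cfg$talin)
      res <- rod_extension(st$F[i], rod, cfg$talin) + st$F[i] / cfg$kappa_c +
        (st$G$G %*% st$F)[i] - st$D[i]
      expect_lt(abs(res), 1e-6)
    }
    expect_true(all(st$F >= 0))
    expect_equal(st$F_sub, sum(st$F))
    expect_equal(st$v, actin_velocity(st$F_sub, cfg$motors))
  }
})

test_that("schedules start with binding only and respect the catch well", {
  cfg <- multiscale_config(integrin = "alphaVbeta3",
                           layout = make_ligand_layout(120, 100), E = 10,
                           motors = motor_ensemble(5), t_f = 5)
  st <- equilibrate(adhesion_state(cfg))
  set.seed(8)
  sched <- build_schedule(st)
  expect_true(all(sched$kind %in% c("bind", "unfold")))
  binds <- sched[sched$kind == "bind", ]
  expect_equal(nrow(binds), 5)
  expect_equal(unique(binds$rate), 1e-4 * 300)
  # a bound chain deep in the catch well outlives one at zero force
  k0 <- off_rate(0, cfg$integrin$law)
  k_well <- off_rate(24, cfg$integrin$law)
  expect_lt(k_well, 0.6 * k0)
  # same seed, same schedule
  set.seed(9); s1 <- build_schedule(st)
  set.seed(9); s2 <- build_schedule(st)
  expect_identical(s1, s2)
})

test_that("events update the state consistently", {
  cfg <- tiny_cfg()
  st <- equilibrate(adhesion_state(cfg))
  # force a deterministic bind by handcrafted schedule
  sched <- data.frame(kind = "bind", chain = 3L, domain = NA_integer_,
                      rate = 1, time = 0.01)
  st <- gillespie_step(st, sched)
  expect_true(st$bound[3])
  expect_equal(st$D[3], 0)
  # let it load, then unfold R3 at fixed D: its force must drop
  st$D[3] <- 40
  st <- equilibrate(st)
  f_before <- st$F[3]
  expect_gt(f_before, 0)
  r3 <- which(cfg$talin$name == "R3")
  sched <- data.frame(kind = "unfold", chain = 3L, domain = r3,
                      rate = 1, time = st$t + 1e-9)
  st2 <- gillespie_step(st, sched)
  expect_false(st2$folded[3, r3])
  expect_lt(st2$F[3], f_before)
  # unbinding the only bound chain restores the unloaded flow
  sched <- data.frame(kind = "unbind", chain = 3L, domain = NA_integer_,
                      rate = 1, time = st2$t + 1e-9)
  st3 <- gillespie_step(st2, sched)
  expect_false(any(st3$bound))
  expect_equal(st3$v, 110)
  expect_equal(st3$F_sub, 0)
})

test_that("vinculin binding reinforces the density per the recruitment rule", {
  cfg <- tiny_cfg(recruitment = "event")
  st <- equilibrate(adhesion_state(cfg))
  st$bound[1] <- TRUE
  r3 <- which(cfg$talin$name == "R3")
  st$folded[1, r3] <- FALSE
  st <- equilibrate(st)
  sched <- data.frame(kind = "vinculin_bind", chain = 1L, domain = NA_integer_,
                      rate = 1e8, time = st$t + 1e-8)
  st2 <- gillespie_step(st, sched)
  expect_true(st2$vinculin[1])
  expect_equal(st2$pop$d_int, 324)
  # unbinding releases vinculin; with "event" recruitment density persists
  sched <- data.frame(kind = "unbind", chain = 1L, domain = NA_integer_,
                      rate = 1, time = st2$t + 1e-9)
  st3 <- gillespie_step(st2, sched)
  expect_false(st3$vinculin[1])
  expect_equal(st3$pop$d_int, 324)
})

test_that("the Gillespie engine matches the classical MC engine on the two-clutch oracle", {
  fx <- fixture_generator("two_clutch_oracle")
  p_exact <- fx$expect$p_bound
  set.seed(fx$seed)
  pb_g <- mean(vapply(1:6, function(s) {
    run_multiscale(fx$config, seed = s)$summary$P_b_mean
  }, numeric(1)))
  law <- fx$config$integrin$law
  set.seed(fx$seed)
  pb_mc <- mean(vapply(1:6, function(s) {
    set.seed(s + 100)
    r <- run_classic(E = 1e5, law = law, n_c = 2, kappa_c = 10,
                     k_ont = 1.5, d_int0 = 1, motors = motor_ensemble(2),
                     dt = 0.002, t_f = 50)
    mean(r$trace$P_b)
  }, numeric(1)))
  # both routes agree with each other and the analytic two-state value
  expect_equal(pb_g, pb_mc, tolerance = 0.08)
  expect_equal(pb_g, p_exact, tolerance = 0.08)
})

test_that("without binding the adhesion stays quiescent", {
  custom <- list(name = "custom", law = integrin_preset("alpha5beta1")$law,
                 k_ont = 0, cmr = FALSE)
  cfg <- multiscale_config(integrin = custom,
                           layout = make_ligand_layout(120, 100),
                           motors = motor_ensemble(5), E = 10, t_f = 2)
  r <- run_multiscale(cfg, seed = 1)
  expect_equal(r$summary$P_mean, 0)
  expect_equal(r$summary$v_mean, 110)
  expect_equal(r$summary$P_b_mean, 0)
})

test_that("run_multiscale is reproducible and satisfies its bookkeeping", {
  cfg <- tiny_cfg(t_f = 3)
  r1 <- run_multiscale(cfg, seed = 5)
  r2 <- run_multiscale(cfg, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_lt(r1$summary$worst_residual, cfg$tol * (1 + 1e-9))
  tr <- r1$trace
  expect_equal(tr$P, tr$F_sub / (pi * 120^2) * 1e6)
  expect_true(all(tr$n_bound >= 0 & tr$n_bound <= 5))
  expect_true(all(tr$v >= 0 & tr$v <= 110))
  # run maxima dominate the time-averaged maxima
  expect_gte(r1$summary$F_c_max, r1$summary$F_c_max_tavg)
  expect_gte(r1$summary$x_talin_max, r1$summary$x_talin_max_tavg)
})

test_that("the single always-bound chain loads the talin rod on stiff substrates", {
  r <- single_chain_run(E = 100, seed = 2)
  n <- nrow(r$trace)
  expect_equal(r$trace$n_bound, rep(1, n))
  # force grows into the talin mechanosensing range by 8 s
  expect_gt(r$trace$F[n], 10)
  expect_lt(r$trace$F[n], 40)
  # the substrate barely deforms on 100 kPa
  expect_lt(max(r$trace$x_sub), 25)
  r1 <- single_chain_run(E = 1, seed = 2)
  # soft substrate: fewer domains open on average than on glass-like stiffness
  expect_lt(sum(r1$domain_unfolded > 0.3), sum(r$domain_unfolded > 0.3))
  # determinism
  ra <- single_chain_run(E = 10, seed = 3)
  rb <- single_chain_run(E = 10, seed = 3)
  expect_identical(ra$trace, rb$trace)
})

test_that("summarize reduces replicates with exact degenerate behaviour", {
  cfg <- tiny_cfg(t_f = 2)
  r <- run_multiscale(cfg, seed = 3)
  s1 <- summarize(list(r, r, r))
  expect_equal(s1$stats$sd, rep(0, nrow(s1$stats)))
  expect_equal(s1$stats$mean[s1$stats$quantity == "P_mean"],
               r$summary$P_mean)
  # max statistics dominate mean statistics
  s <- summarize(lapply(1:3, function(k) run_multiscale(cfg, seed = k)))
  m <- setNames(s$stats$mean, s$stats$quantity)
  expect_gte(m["F_c_max"], m["F_c_max_tavg"])
  expect_error(summarize(list()), "no traces")
})
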