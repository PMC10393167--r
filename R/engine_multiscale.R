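#' Configuration of a multi-scale adhesion-complex simulation
#'
#' Assembles everything [run_multiscale()] needs: the ligand layout and
#' substrate Green operator, the integrin bond law and population, the talin
#' parameter set and the myosin motor ensemble. Defaults follow the reference
#' adhesion-complex geometry: a circular adhesion of radius 708 nm with
#' ligands spaced 100 nm (158 binders), integrin spring 10 pN/nm, one myosin
#' motor per ligand (2 pN stall each) and 110 nm/s unloaded actin flow.
#'
#' @param integrin an [integrin_preset()] name or result.
#' @param E substrate Young's modulus (kPa).
#' @param a adhesion radius (nm).
#' @param d ligand spacing (nm).
#' @param layout optionally a precomputed [make_ligand_layout()] (overrides
#'   `a`, `d`).
#' @param nu substrate Poisson ratio.
#' @param kappa_c integrin spring stiffness (pN/nm).
#' @param d_int0,int_add,m_r integrin density parameters (int/um^2).
#' @param recruitment integrin recruitment rule triggered by vinculin binding:
#'   `"tracked"` (default; the density excess above `d_int0` follows the
#'   number of currently bound vinculins, `int_add` per vinculin, capped at
#'   `m_r`), `"event"` (each vinculin-binding event adds `int_add`
#'   irreversibly up to `m_r`), or `"none"`.
#' @param k_onv vinculin binding rate to an exposed R3 site (1/s).
#' @param talin a `talin_params` data frame.
#' @param kBT thermal energy (pN nm).
#' @param motors a [motor_ensemble()]; default one motor per ligand.
#' @param t_f final time (s).
#' @param record_dt trace sampling interval (s).
#' @param rate_refresh_dt maximum interval between propensity refreshes (s):
#'   event rates are frozen at the current forces, so when no event fires
#'   within this window the engine advances the actin, re-balances forces and
#'   redraws (exact by memorylessness, with rates at most `rate_refresh_dt`
#'   stale).
#' @param tol force-balance residual tolerance (pN).
#' @return an object of class `multiscale_config`.
#' @export
multiscale_config <- function(integrin = "alpha5beta1", E = 10,
                              a = 708, d = 100, layout = NULL, nu = 0.5,
                              kappa_c = 10, d_int0 = 300, int_add = 24,
                              m_r = 15000,
                              recruitment = c("tracked", "event", "none"),
                              k_onv = 1e8, talin = talin_default_params(),
                              kBT = .kBT_default, motors = NULL, t_f = 100,
                              record_dt = 0.1, rate_refresh_dt = 0.005,
                              tol = 1e-6) {
  recruitment <- match.arg(recruitment)
  if (is.character(integrin)) integrin <- integrin_preset(integrin)
  if (is.null(layout)) layout <- make_ligand_layout(a, d)
  if (is.null(motors)) motors <- motor_ensemble(n_m = layout$n_c)
  if (length(unique(talin$A)) != 1) {
    stop("the engine requires a single persistence length shared by all unfolded domains",
         call. = FALSE)
  }
  structure(list(integrin = integrin, E = E, layout = layout, nu = nu,
                 kappa_c = kappa_c, d_int0 = d_int0, int_add = int_add,
                 m_r = m_r, recruitment = recruitment, k_onv = k_onv,
                 talin = talin, kBT = kBT, motors = motors, t_f = t_f,
                 record_dt = record_dt, rate_refresh_dt = rate_refresh_dt,
                 tol = tol),
            class = "multiscale_config")
}

.recruit_code <- function(recruitment) {
  match(recruitment, c("none", "event", "tracked")) - 1L
}

.law_pars <- function(law) {
  # generic 3-term parameterisation (k1,f1 slip; k2,f2 catch; k3,f3 CMR)
  if (law$mode == "slip") {
    c(law$k_off, law$F_b, 0, 1, 0, 1)
  } else {
    p <- c(law$k_off_slip, law$F_b_slip, law$k_off_catch, law$F_b_catch, 0, 1)
    if (law$mode == "catch_cmr") p[5:6] <- law$cmr_terms[3, ]
    p
  }
}

.law_mode_code <- function(law) {
  match(law$mode, c("slip", "catch_slip", "catch_cmr")) - 1L
}

#' Initial adhesion state for the step-wise interface
#'
#' Builds the explicit simulation state consumed by [equilibrate()],
#' [build_schedule()] and [gillespie_step()]. All chains start free, force-
#' free and fully folded.
#'
#' @param config a [multiscale_config()].
#' @return an object of class `adhesion_state`.
#' @export
adhesion_state <- function(config) {
  n <- config$layout$n_c
  G <- assemble_green_operator(config$layout, config$E, config$nu)
  structure(list(
    config = config, G = G,
    pop = integrin_population(config$integrin$k_ont, config$d_int0,
                              config$int_add, config$m_r),
    bound = rep(FALSE, n), D = numeric(n), F = numeric(n),
    folded = matrix(TRUE, n, nrow(config$talin)),
    vinculin = rep(FALSE, n),
    x_talin = numeric(n), x_int = numeric(n), x_sub_local = numeric(n),
    t = 0, v = config$motors$v_u, F_sub = 0, traction = 0),
    class = "adhesion_state")
}

#' Solve the coupled force balance of all bound chains
#'
#' For the current actin displacements `D` of the bound chains, solves the
#' nonlinear system
#' `rod_extension(F_b) + F_b / kappa_c + [G F]_b = D_b`, `F_b >= 0`
#' (chains at slack carry zero force) by a projected Newton iteration with an
#' analytic chain Jacobian, then updates forces, talin extensions, integrin
#' stretches, local substrate displacements, the total substrate force and
#' the actin velocity.
#'
#' @param state an [adhesion_state()].
#' @param tol residual infinity-norm tolerance (pN); defaults to the
#'   configured tolerance.
#' @return the equilibrated state; `attr(, "residual")` carries the achieved
#'   residual.
#' @export
equilibrate <- function(state, tol = NULL) {
  stopifnot(inherits(state, "adhesion_state"))
  cfg <- state$config
  if (is.null(tol)) tol <- cfg$tol
  tp <- cfg$talin
  r3 <- which(tp$name == "R3")
  sol <- ms_equilibrate_cpp(
    state$G$G, state$D, state$bound,
    matrix(as.integer(state$folded), nrow(state$folded)),
    tp$l0, tp$L0, tp$A[1], cfg$kBT, tp$unfoldable, tp$k_unf0, tp$dx_unf,
    tp$k_ref0, tp$dx_ref, r3, cfg$kappa_c, state$F, tol, 100L)
  if (sol$residual > tol) {
    stop(sprintf("force balance did not converge (residual %.3g pN > %.3g)",
                 sol$residual, tol), call. = FALSE)
  }
  state$F <- drop(sol$F)
  state$x_talin <- drop(sol$x_talin)
  state$x_int <- ifelse(state$bound, state$F / cfg$kappa_c, 0)
  state$x_sub_local <- substrate_displacements(state$G, state$F)
  state$F_sub <- sol$F_sub
  state$v <- actin_velocity(state$F_sub, cfg$motors)
  state$traction <- .pn_nm2_to_pa(state$F_sub / (pi * cfg$layout$a^2))
  attr(state, "residual") <- sol$residual
  state
}

#' Candidate event schedule of the Gillespie engine
#'
#' Draws, for every possible event at the current state, an exponential
#' candidate time `t_i = -ln(xi_i) / k_i` with the rate frozen at the current
#' forces: binding of each free ligand (`k_ont * d_int`), unbinding of each
#' bound chain (its bond law at its force), unfolding/refolding of each
#' eligible talin domain (zero force for unbound chains; R3 refolding blocked
#' while vinculin-bound), and vinculin binding to each exposed R3.
#'
#' @param state an equilibrated [adhesion_state()].
#' @return a data frame `kind, chain, domain, rate, time` (absolute times),
#'   sorted by time, zero-rate events omitted. Empty when no event is
#'   possible (quiescence).
#' @export
build_schedule <- function(state) {
  stopifnot(inherits(state, "adhesion_state"))
  cfg <- state$config
  tp <- cfg$talin
  r3 <- which(tp$name == "R3")
  n <- length(state$bound)
  nd <- nrow(tp)
  kind <- character(0); chain <- integer(0); domain <- integer(0)
  rate <- numeric(0)
  add <- function(k, ch, dom, ra) {
    kind <<- c(kind, k); chain <<- c(chain, ch)
    domain <<- c(domain, dom); rate <<- c(rate, ra)
  }
  kb <- binding_propensity(state$pop)
  for (i in which(!state$bound)) add("bind", i, NA_integer_, kb)
  for (i in which(state$bound)) {
    add("unbind", i, NA_integer_, off_rate(state$F[i], cfg$integrin$law))
  }
  for (i in seq_len(n)) {
    Fi <- if (state$bound[i]) state$F[i] else 0
    for (d in seq_len(nd)) {
      if (state$folded[i, d]) {
        if (tp$unfoldable[d]) add("unfold", i, d, unfold_rate(Fi, tp[d, ], cfg$kBT))
      } else if (!(d == r3 && state$vinculin[i])) {
        add("refold", i, d, refold_rate(Fi, tp[d, ], cfg$kBT))
      }
    }
  }
  for (i in which(state$bound & !state$folded[, r3] & !state$vinculin)) {
    add("vinculin_bind", i, NA_integer_, cfg$k_onv)
  }
  keep <- rate > 0
  sched <- data.frame(kind = kind[keep], chain = chain[keep],
                      domain = domain[keep], rate = rate[keep])
  sched$time <- state$t - log(stats::runif(nrow(sched))) / sched$rate
  sched[order(sched$time), , drop = FALSE]
}

#' Advance the adhesion state by one Gillespie event
#'
#' Chooses the earliest candidate event, moves the actin by `v * tau`
#' (incrementing every bound chain's accumulated displacement), applies the
#' event -- bind (attach force-free), unbind (release force and vinculin),
#' unfold/refold (toggle a talin domain), vinculin binding (set the flag and
#' reinforce the integrin density) -- and re-equilibrates.
#'
#' @param state an equilibrated [adhesion_state()].
#' @param schedule optionally a precomputed [build_schedule()] result.
#' @return the advanced state. If no event is possible the state advances to
#'   `config$t_f` unchanged.
#' @export
gillespie_step <- function(state, schedule = NULL) {
  stopifnot(inherits(state, "adhesion_state"))
  cfg <- state$config
  if (is.null(schedule)) schedule <- build_schedule(state)
  if (nrow(schedule) == 0) {
    state$t <- cfg$t_f
    return(state)
  }
  ev <- schedule[1, ]
  tau <- ev$time - state$t
  state$t <- ev$time
  state$D[state$bound] <- state$D[state$bound] + state$v * tau
  i <- ev$chain
  r3 <- which(cfg$talin$name == "R3")
  switch(ev$kind,
    bind = {
      state$bound[i] <- TRUE
      state$D[i] <- 0
      state$F[i] <- 0
    },
    unbind = {
      state$bound[i] <- FALSE
      state$D[i] <- 0
      state$F[i] <- 0
      if (state$vinculin[i]) {
        state$vinculin[i] <- FALSE
        if (cfg$recruitment == "tracked") state$pop <- release_density(state$pop)
      }
    },
    unfold = state$folded[i, ev$domain] <- FALSE,
    refold = state$folded[i, ev$domain] <- TRUE,
    vinculin_bind = {
      state$vinculin[i] <- TRUE
      if (cfg$recruitment != "none") state$pop <- reinforce_density(state$pop)
    })
  equilibrate(state)
}

#' Run the multi-scale Gillespie clutch simulation
#'
#' Simulates an adhesion complex of integrin--talin chains coupled through
#' the elastic half-space substrate, from the all-free state to `t_f`, in the
#' compiled engine. Every event re-solves the nonlinear force balance and
#' updates the actin velocity from the total substrate force.
#'
#' @param config a [multiscale_config()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return an object of class `clutch_trace`: list with
#'   * `trace`: data frame sampled every `record_dt` with columns `t`,
#'     `n_bound`, `F_sub` (pN), `P` (Pa), `v` (nm/s), `n_vinculin`, `d_int`,
#'     `F_c_max` (pN, instantaneous max over bound chains), `x_talin_max`
#'     (nm, idem);
#'   * `summary`: one-row data frame of time averages over the full trace
#'     (`P_mean`, `v_mean`, `P_b_mean`, `n_vinc_mean`, `d_int_mean`), run
#'     maxima (`F_c_max`, `x_talin_max`, `x_int_max`), event counts and the
#'     worst force-balance residual;
#'   * `domain_unfolded`: named per-domain time-averaged unfolded fraction
#'     among bound chains;
#'   * `config`.
#' @export
run_multiscale <- function(config, seed = NULL) {
  stopifnot(inherits(config, "multiscale_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  G <- assemble_green_operator(cfg$layout, cfg$E, cfg$nu)
  tp <- cfg$talin
  r3 <- which(tp$name == "R3")
  law <- cfg$integrin$law
  out <- ms_run_cpp(
    G$G, pi * cfg$layout$a^2, .law_mode_code(law), .law_pars(law),
    cfg$integrin$k_ont, cfg$d_int0, cfg$int_add, cfg$m_r,
    .recruit_code(cfg$recruitment), cfg$k_onv,
    tp$l0, tp$L0, tp$A[1], cfg$kBT, tp$unfoldable, tp$k_unf0, tp$dx_unf,
    tp$k_ref0, tp$dx_ref, r3, cfg$kappa_c, cfg$motors$F_stall,
    cfg$motors$v_u, cfg$t_f, cfg$record_dt, cfg$rate_refresh_dt, FALSE,
    cfg$tol, 100L, 5e7)
  .wrap_ms_result(out, cfg)
}

.wrap_ms_result <- function(out, cfg) {
  tr <- as.data.frame(out$trace)
  names(tr) <- c("t", "n_bound", "F_sub", "P", "v", "n_vinculin", "d_int",
                 "F_c_max", "x_talin_max")
  tr$P_b <- tr$n_bound / cfg$layout$n_c
  s <- out$summary
  summary <- data.frame(
    P_mean = s$P_mean, v_mean = s$v_mean, P_b_mean = s$P_b_mean,
    n_vinc_mean = s$n_vinc_mean, d_int_mean = s$d_int_mean,
    F_c_max = s$F_c_max, x_talin_max = s$x_talin_max, x_int_max = s$x_int_max,
    F_c_max_tavg = s$F_c_max_tavg, x_talin_max_tavg = s$x_talin_max_tavg,
    x_int_max_tavg = s$x_int_max_tavg,
    n_events = s$n_events, n_bind = s$n_bind, n_unbind = s$n_unbind,
    n_unfold = s$n_unfold, n_refold = s$n_refold,
    n_vinc_events = s$n_vinc_events, worst_residual = s$worst_residual,
    n_equil = s$n_equil, n_newton = s$n_newton, n_chol = s$n_chol,
    n_chol_reuse = s$n_chol_reuse)
  structure(list(trace = tr, summary = summary,
                 domain_unfolded = stats::setNames(drop(s$domain_unfolded_frac),
                                                   cfg$talin$name),
                 state = out$state, config = cfg),
            class = "clutch_trace")
}

#' Single always-bound adhesion chain on an elastic substrate
#'
#' The elementary building block of the multi-scale model: one talin rod
#' permanently coupling an actin filament to a single substrate ligand, with
#' no integrin element and binding/unbinding disabled. The substrate responds
#' through the Green's-function self term. Talin domains unfold and refold
#' stochastically while the motors load the chain; the run ends at `t_f`
#' (default 8 s, long enough for most unfoldable domains to open on a stiff
#' substrate).
#'
#' @param E substrate Young's modulus (kPa).
#' @param motors a [motor_ensemble()]; default 20 motors (40 pN stall), the
#'   contractility of the single actin filament pulling one chain.
#' @param t_f final time (s).
#' @param talin a `talin_params` data frame.
#' @param kBT thermal energy (pN nm).
#' @param nu substrate Poisson ratio.
#' @param self_offset Green's-function singularity offset (nm).
#' @param k_onv vinculin binding rate (1/s).
#' @param record_dt trace sampling interval (s).
#' @param rate_refresh_dt maximum staleness of the frozen folding rates (s).
#' @param tol force-balance tolerance (pN).
#' @param seed optional integer seed.
#' @return a `clutch_trace` (single chain: `n_bound` is identically 1; `P` is
#'   force per the nominal adhesion area of one ligand site and is mostly of
#'   diagnostic interest).
#' @export
single_chain_run <- function(E, motors = motor_ensemble(20), t_f = 8,
                             talin = talin_default_params(),
                             kBT = .kBT_default, nu = 0.5, self_offset = 5,
                             k_onv = 1e8, record_dt = 0.01,
                             rate_refresh_dt = 0.005, tol = 1e-6,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- E / (2 * (1 + nu))
  g_self <- greens_coefficient(c(self_offset, 0), c(1, 0), mu, nu)
  r3 <- which(talin$name == "R3")
  cfg <- list(layout = list(n_c = 1L, a = self_offset, d = NA),
              talin = talin, motors = motors, recruitment = "none",
              E = E, t_f = t_f, record_dt = record_dt, tol = tol)
  out <- ms_run_cpp(
    matrix(g_self, 1, 1), pi * self_offset^2, 0L, c(0, 1, 0, 1, 0, 1),
    0, 0, 0, 0, 0L, k_onv,
    talin$l0, talin$L0, talin$A[1], kBT, talin$unfoldable, talin$k_unf0,
    talin$dx_unf, talin$k_ref0, talin$dx_ref, r3,
    -1, motors$F_stall, motors$v_u, t_f, record_dt, rate_refresh_dt, TRUE,
    tol, 100L, 5e7)
  res <- .wrap_ms_result(out, cfg)
  names(res$trace)[names(res$trace) == "F_c_max"] <- "F"
  res$trace$x_sub <- res$trace$F * g_self
  res
}

#' Replicate summary statistics of multi-scale runs
#'
#' Reduces a list of `clutch_trace` objects to replicate mean and standard
#' deviation of the per-replicate time averages (traction, velocity, bound
#' fraction, vinculin-bound binder count) and per-replicate run maxima (chain
#' force, integrin stretch, talin extension), plus the per-domain unfolded
#' fractions.
#'
#' @param traces list of results from [run_multiscale()] /
#'   [single_chain_run()].
#' @return an object of class `summary_stats`: list with `stats` (data frame
#'   `quantity, mean, sd, n`) and `domain_unfolded` (matrix replicates x
#'   domains).
#' @export
summarize <- function(traces) {
  if (length(traces) == 0) stop("no traces to summarize", call. = FALSE)
  if (inherits(traces, "clutch_trace")) traces <- list(traces)
  per <- do.call(rbind, lapply(traces, function(tr) {
    s <- tr$summary
    data.frame(P_mean = s$P_mean, v_mean = s$v_mean, P_b_mean = s$P_b_mean,
               n_vinc_mean = s$n_vinc_mean, F_c_max = s$F_c_max,
               x_int_max = s$x_int_max, x_talin_max = s$x_talin_max,
               F_c_max_tavg = s$F_c_max_tavg,
               x_talin_max_tavg = s$x_talin_max_tavg,
               x_int_max_tavg = s$x_int_max_tavg)
  }))
  stats <- data.frame(
    quantity = names(per),
    mean = vapply(per, mean, numeric(1)),
    sd = vapply(per, function(x) if (length(x) > 1) stats::sd(x) else 0,
                numeric(1)),
    n = nrow(per), row.names = NULL)
  dom <- do.call(rbind, lapply(traces, function(tr) tr$domain_unfolded))
  structure(list(stats = stats, per_replicate = per, domain_unfolded = dom),
            class = "summary_stats")
}
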