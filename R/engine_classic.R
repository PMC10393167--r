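#' Force balance of the classical single-spring clutch model
#'
#' Solves the substrate displacement from the balance between the engaged
#' clutch springs and the lumped substrate spring:
#' `x_sub = kappa_c * sum(x_c[engaged]) / (kappa_sub + n_eng * kappa_c)`.
#'
#' @param x_c per-clutch displacements (nm).
#' @param engaged logical vector of engaged clutches.
#' @param kappa_c clutch spring stiffness (pN/nm).
#' @param kappa_sub substrate spring stiffness (pN/nm).
#' @return substrate displacement `x_sub` (nm).
#' @export
classic_force_balance <- function(x_c, engaged, kappa_c, kappa_sub) {
  stopifnot(length(x_c) == length(engaged), kappa_c > 0, kappa_sub >= 0)
  n_eng <- sum(engaged)
  if (n_eng == 0) return(0)
  kappa_c * sum(x_c[engaged]) / (kappa_sub + n_eng * kappa_c)
}

#' One fixed-time-step update of the classical clutch model
#'
#' Engaged clutches are advanced by the actin displacement `v dt`, the
#' substrate displacement is re-balanced, per-clutch forces are computed as
#' `kappa_c (x_c - x_sub)` (clamped at zero), binding and unbinding are drawn
#' with exact exponential probabilities `1 - exp(-k dt)` (important at the
#' ~900/s rates of the CMR law), clutches that unbind reset their stretch to
#' zero, and the actin velocity is updated from the substrate force.
#'
#' @param state list with `engaged` (logical), `x_c` (nm), `x_sub` (nm),
#'   `F_c` (pN), `v` (nm/s), `t` (s), optionally `d_int` (int/um^2).
#' @param dt time step (s).
#' @param law a [bond_law()] for unbinding.
#' @param k_on binding rate per free clutch (1/s).
#' @param motors a [motor_ensemble()].
#' @param kappa_c clutch stiffness (pN/nm).
#' @param kappa_sub substrate stiffness (pN/nm).
#' @return the updated state.
#' @export
classic_step <- function(state, dt, law, k_on, motors, kappa_c, kappa_sub) {
  if (dt <= 0) stop("time step must be positive", call. = FALSE)
  eng <- state$engaged
  x_c <- state$x_c
  x_c[eng] <- x_c[eng] + state$v * dt
  x_sub <- classic_force_balance(x_c, eng, kappa_c, kappa_sub)
  F_c <- pmax(0, kappa_c * (x_c - x_sub)) * eng
  # stochastic transitions at exact exponential probabilities
  u <- stats::runif(length(x_c))
  p_off <- 1 - exp(-off_rate(F_c, law) * dt)
  p_on <- 1 - exp(-k_on * dt)
  unbind <- eng & (u < p_off)
  bind <- !eng & (u < p_on)
  eng <- (eng & !unbind) | bind
  # disengaged clutches carry no stretch; newly bound start force-free
  x_c[unbind | bind] <- x_sub
  x_sub <- classic_force_balance(x_c, eng, kappa_c, kappa_sub)
  F_c <- pmax(0, kappa_c * (x_c - x_sub)) * eng
  F_sub <- kappa_sub * x_sub
  list(engaged = eng, x_c = x_c, x_sub = x_sub, F_c = F_c,
       v = actin_velocity(F_sub, motors), t = state$t + dt,
       d_int = state$d_int)
}

#' Run the classical Monte-Carlo clutch model
#'
#' Fixed-time-step simulation of `n_c` molecular clutches bound to a single
#' lumped substrate spring, pulled by a myosin motor ensemble. Supports slip,
#' catch-slip and catch+CMR unbinding laws, and an optional vinculin-free
#' density-reinforcement rule: whenever an engaged clutch's force exceeds
#' `reinforce_threshold`, the integrin density (and with it the binding rate
#' `k_ont * d_int`) is incremented by `int_add` up to `m_r`.
#'
#' @param E substrate Young's modulus (kPa).
#' @param law a [bond_law()].
#' @param n_c number of clutches.
#' @param a adhesion radius (nm), sets `kappa_sub` and the traction area.
#' @param kappa_c clutch stiffness (pN/nm).
#' @param k_ont association constant (um^2/s).
#' @param d_int0,int_add,m_r integrin density parameters (int/um^2).
#' @param motors a [motor_ensemble()]; default 40 motors of 2 pN at 110 nm/s.
#' @param dt time step (s).
#' @param t_f final time (s).
#' @param reinforce_threshold per-clutch force (pN) above which a density
#'   increment is triggered once per step, or `NULL` (default) to disable.
#' @param record_every store every k-th step in the trace (default 1).
#' @return an object of class `clutch_trace`: list with `trace` (data frame
#'   `t, n_eng, P_b, x_sub, F_sub, P, v, F_c_max, d_int`), `summary`, and the
#'   configuration. Traction `P` is in Pa.
#' @export
run_classic <- function(E, law, n_c = 158, a = 708, kappa_c = 10,
                        k_ont = 0.005, d_int0 = 300, int_add = 24, m_r = 15000,
                        motors = motor_ensemble(40), dt = 0.005, t_f = 100,
                        reinforce_threshold = NULL, record_every = 1L) {
  stopifnot(inherits(law, "bond_law"), dt > 0, t_f > 0)
  kappa_sub <- classic_substrate_stiffness(E, a)
  area <- pi * a^2
  pop <- integrin_population(k_ont, d_int0, int_add, m_r)
  state <- list(engaged = rep(FALSE, n_c), x_c = numeric(n_c), x_sub = 0,
                F_c = numeric(n_c), v = motors$v_u, t = 0, d_int = pop$d_int)
  n_steps <- ceiling(t_f / dt)
  keep <- seq(1, n_steps, by = record_every)
  tr <- matrix(NA_real_, length(keep), 9,
               dimnames = list(NULL, c("t", "n_eng", "P_b", "x_sub", "F_sub",
                                       "P", "v", "F_c_max", "d_int")))
  row <- 1
  for (s in seq_len(n_steps)) {
    k_on <- binding_propensity(pop)
    state <- classic_step(state, dt, law, k_on, motors, kappa_c, kappa_sub)
    if (!is.null(reinforce_threshold) && any(state$F_c > reinforce_threshold)) {
      for (i in seq_len(sum(state$F_c > reinforce_threshold))) {
        pop <- reinforce_density(pop)
      }
    }
    state$d_int <- pop$d_int
    if (s == keep[row]) {
      F_sub <- kappa_sub * state$x_sub
      tr[row, ] <- c(state$t, sum(state$engaged), mean(state$engaged),
                     state$x_sub, F_sub, .pn_nm2_to_pa(F_sub / area),
                     state$v, max(state$F_c), pop$d_int)
      row <- min(row + 1, length(keep))
    }
  }
  trace <- as.data.frame(tr)
  structure(list(
    trace = trace,
    summary = data.frame(P_mean = mean(trace$P), v_mean = mean(trace$v),
                         P_b_mean = mean(trace$P_b),
                         F_c_max = max(trace$F_c_max)),
    config = list(engine = "classic", E = E, law = law, n_c = n_c, a = a,
                  kappa_c = kappa_c, k_ont = k_ont, d_int0 = d_int0,
                  int_add = int_add, m_r = m_r, motors = motors, dt = dt,
                  t_f = t_f, reinforce_threshold = reinforce_threshold)),
    class = "clutch_trace")
}
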