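#' Default talin rod domain parameters
#'
#' Mechanical and kinetic parameters for the 13 elements of the talin rod
#' (R1--R12 plus the terminal R13-DD segment). Folded domains are modelled as
#' freely-jointed-chain (FJC) rigid bodies of size `l0`; unfolded domains as
#' worm-like chains (WLC) with persistence length `A` and contour length `L0`.
#' Unfolding follows Bell kinetics (`k_unf0`, `dx_unf`), refolding an
#' Arrhenius law (`k_ref0`, `dx_ref`). Two elements (R9, the mechanically most
#' stable bundle, and the terminal R13-DD actin anchor) are marked
#' non-unfolding, leaving 11 unfoldable domains.
#'
#' The shipped values are the package defaults, chosen to reproduce the
#' published mechanical phenotype of the full-length talin rod: folded rod
#' length ~65 nm, unfolded contour of the 11 unfoldable domains ~800 nm,
#' equilibrium unfolding forces 5--17 pN with R3 the weakest domain (~5 pN),
#' followed by R5, R6, R10 and R11, and all unfoldable domains opening within
#' a second above ~20 pN. See the methods vignette for the calibration.
#'
#' @param file path to a CSV with one row per domain and the columns shown
#'   above; defaults to the file shipped with the package.
#' @return a data frame of class `talin_params`, one row per rod element.
#' @export
talin_default_params <- function(file = system.file("extdata", "talin_domains.csv",
                                                    package = "clutchms")) {
  read_talin_params(file)
}

#' Read a talin parameter file
#'
#' @param file CSV path with columns `name, l0, L0, A, k_unf0, dx_unf,
#'   k_ref0, dx_ref, unfoldable` (units nm, nm, nm, 1/s, nm, 1/s, nm, logical).
#' @return a data frame of class `talin_params`.
#' @export
read_talin_params <- function(file) {
  p <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("name", "l0", "L0", "A", "k_unf0", "dx_unf", "k_ref0", "dx_ref",
           "unfoldable")
  if (!all(req %in% names(p))) {
    stop("talin parameter file must have columns: ", paste(req, collapse = ", "))
  }
  p$unfoldable <- as.logical(p$unfoldable)
  stopifnot(all(p$l0 < p$L0), all(p$A > 0),
            all(p$k_unf0 >= 0), all(p$k_ref0 >= 0),
            all(p$l0 > 0))
  class(p) <- c("talin_params", class(p))
  p
}

#' Freely-jointed-chain extension of a folded domain
#'
#' Mean end-to-end extension of a rigid body of size `l0` under force:
#' `x = l0 * coth(F l0 / kBT) - kBT / F`. Continuous at `F = 0` (series limit
#' `F l0^2 / (3 kBT)`), monotone increasing, saturating at `l0`.
#'
#' @param F force (pN), vectorised.
#' @param l0 rigid-body (Kuhn) size of the folded domain (nm).
#' @param kBT thermal energy (pN nm).
#' @return extension (nm).
#' @export
fjc_extension <- function(F, l0, kBT = .kBT_default) {
  .check_force(F)
  beta <- F * l0 / kBT
  small <- beta < 1e-4
  out <- numeric(length(beta))
  # series: coth(b) - 1/b = b/3 - b^3/45 + O(b^5)
  out[small] <- l0 * (beta[small] / 3 - beta[small]^3 / 45)
  b <- beta[!small]
  out[!small] <- l0 * (1 / tanh(b) - 1 / b)
  out
}

# derivative of fjc_extension w.r.t. force
fjc_compliance <- function(F, l0, kBT = .kBT_default) {
  beta <- F * l0 / kBT
  small <- beta < 1e-4
  out <- numeric(length(beta))
  out[small] <- l0^2 / (3 * kBT) * (1 - beta[small]^2 / 5)
  b <- beta[!small]
  out[!small] <- l0^2 / kBT * (1 / b^2 - 1 / sinh(b)^2)
  out
}

#' Worm-like-chain force of an unfolded domain
#'
#' Interpolated WLC law: `F A / kBT = 1/(4 (1 - x/L0)^2) - 1/4 + x/L0`.
#' Zero at zero extension, strictly increasing, diverging as `x -> L0`.
#'
#' @param x end-to-end extension (nm), `0 <= x < L0`; vectorised.
#' @param A persistence length (nm).
#' @param L0 contour length (nm).
#' @param kBT thermal energy (pN nm).
#' @return force (pN).
#' @export
wlc_force <- function(x, A, L0, kBT = .kBT_default) {
  if (any(x < 0) || any(x >= L0)) {
    stop("WLC extension must satisfy 0 <= x < L0", call. = FALSE)
  }
  q <- x / L0
  (kBT / A) * (1 / (4 * (1 - q)^2) - 1 / 4 + q)
}

# dimensionless WLC inversion: given f = F*A/kBT >= 0, return q = x/L0 solving
# f = 1/(4(1-q)^2) - 1/4 + q. With u = 1-q this is 4u^3 + (4f-3)u^2 - 1 = 0,
# which has exactly one root in (0, 1]. Safeguarded Newton, vectorised.
wlc_q <- function(f) {
  stopifnot(all(f >= 0))
  u <- pmin(1, pmax(0.05, 1 - f / (f + 1)))  # crude start
  lo <- rep(1e-12, length(f))
  hi <- rep(1, length(f))
  for (i in 1:100) {
    g <- 4 * u^3 + (4 * f - 3) * u^2 - 1
    hi[g > 0] <- u[g > 0]
    lo[g < 0] <- u[g < 0]
    dg <- 12 * u^2 + 2 * (4 * f - 3) * u
    step <- g / dg
    u_new <- u - step
    bad <- !is.finite(u_new) | u_new <= lo | u_new >= hi
    u_new[bad] <- (lo[bad] + hi[bad]) / 2
    done <- abs(u_new - u) < 1e-15 + 1e-14 * u_new
    u <- u_new
    if (all(done)) break
  }
  1 - u
}

#' Worm-like-chain extension at a given force
#'
#' Numerical inverse of [wlc_force()]: the unique `x` in `[0, L0)` with
#' `wlc_force(x) = F`, via a safeguarded Newton solve of the equivalent cubic.
#' Round-trip residuals are at machine-precision level.
#'
#' @param F force (pN), vectorised.
#' @inheritParams wlc_force
#' @return extension (nm).
#' @export
wlc_extension <- function(F, A, L0, kBT = .kBT_default) {
  .check_force(F)
  L0 * wlc_q(F * A / kBT)
}

#' Talin rod folding state
#'
#' @param folded logical vector, one flag per rod element (default all folded).
#' @param vinculin_bound is a vinculin bound to the (necessarily unfolded) R3
#'   domain?
#' @param params a `talin_params` data frame (defines element count and names).
#' @return an object of class `talin_rod_state` with fields `folded`,
#'   `vinculin_bound`, `extension` (nm) and `force` (pN); the last two are
#'   filled in by the engines.
#' @export
talin_rod_state <- function(folded = NULL, vinculin_bound = FALSE,
                            params = talin_default_params()) {
  n <- nrow(params)
  if (is.null(folded)) folded <- rep(TRUE, n)
  stopifnot(length(folded) == n, is.logical(folded))
  r3 <- which(params$name == "R3")
  if (vinculin_bound && folded[r3]) {
    stop("vinculin can only be bound while R3 is unfolded", call. = FALSE)
  }
  structure(list(folded = folded, vinculin_bound = vinculin_bound,
                 extension = 0, force = 0),
            class = "talin_rod_state")
}

#' Talin rod extension under force
#'
#' Sum of FJC extensions of the folded domains and WLC extensions of the
#' unfolded domains at a common force. Monotone in force and in the number of
#' unfolded domains.
#'
#' @param F force (pN); scalar or vector.
#' @param state a [talin_rod_state()].
#' @param params a `talin_params` data frame.
#' @param kBT thermal energy (pN nm).
#' @return extension (nm), same length as `F`.
#' @export
rod_extension <- function(F, state, params = talin_default_params(),
                          kBT = .kBT_default) {
  .check_force(F)
  vapply(F, function(f) {
    xf <- sum(fjc_extension(f, params$l0[state$folded], kBT))
    xu <- sum(wlc_extension(f, params$A[!state$folded],
                            params$L0[!state$folded], kBT))
    xf + xu
  }, numeric(1))
}

# d rod_extension / dF at scalar force
rod_compliance <- function(F, state, params, kBT = .kBT_default) {
  cf <- sum(fjc_compliance(F, params$l0[state$folded], kBT))
  unf <- !state$folded
  cu <- 0
  if (any(unf)) {
    f <- F * params$A[unf] / kBT
    q <- wlc_q(f)
    u <- 1 - q
    dfdq <- 1 / (2 * u^3) + 1
    cu <- sum(params$L0[unf] * (params$A[unf] / kBT) / dfdq)
  }
  cf + cu
}

# maximum extensible length of the current folding state
rod_max_length <- function(state, params) {
  sum(params$l0[state$folded]) + sum(params$L0[!state$folded])
}

#' Force in a talin rod held at a given extension
#'
#' Inverse of [rod_extension()]: the unique non-negative force at which the
#' rod's equilibrium extension equals `x_target`, found by a bracketed Newton
#' solve. The model is displacement-driven, so this inverse is what the
#' engines use. An `x_target` at or above the maximum extensible length of
#' the current folding state is impossible at finite force and errors.
#'
#' @param x_target extension (nm).
#' @inheritParams rod_extension
#' @return force (pN).
#' @export
rod_force <- function(x_target, state, params = talin_default_params(),
                      kBT = .kBT_default) {
  stopifnot(length(x_target) == 1, x_target >= 0)
  if (x_target == 0) return(0)
  xmax <- rod_max_length(state, params)
  if (x_target >= xmax) {
    stop(sprintf("target extension %.3g nm at/above the maximum extensible length %.3g nm of this folding state",
                 x_target, xmax), call. = FALSE)
  }
  # expand bracket
  hi <- 1
  while (rod_extension(hi, state, params, kBT) < x_target) {
    hi <- hi * 2
    if (hi > 1e8) stop("rod_force failed to bracket the solution", call. = FALSE)
  }
  lo <- 0
  F <- hi / 2
  for (i in 1:200) {
    r <- rod_extension(F, state, params, kBT) - x_target
    if (r > 0) hi <- F else lo <- F
    if (abs(r) < 1e-10 * max(1, x_target)) break
    Fn <- F - r / rod_compliance(F, state, params, kBT)
    if (!is.finite(Fn) || Fn <= lo || Fn >= hi) Fn <- (lo + hi) / 2
    F <- Fn
  }
  F
}

#' Bell unfolding rate of a folded talin domain
#'
#' `k_unf0 * exp(F * dx_unf / kBT)`.
#'
#' @param F force (pN).
#' @param dom one row of a `talin_params` data frame (list or data frame row).
#' @param kBT thermal energy (pN nm).
#' @return rate (1/s).
#' @export
unfold_rate <- function(F, dom, kBT = .kBT_default) {
  .check_force(F)
  # exponent capped to avoid overflow at the WLC divergence; rates this large
  # fire within any representable time step anyway
  dom$k_unf0 * exp(pmin(F * dom$dx_unf / kBT, 500))
}

#' Arrhenius refolding rate of an unfolded talin domain
#'
#' `k_ref0 * exp(-F * dx_ref / kBT)`: refolding slows under force. R3 with a
#' bound vinculin cannot refold; the engines set its propensity to zero.
#'
#' @inheritParams unfold_rate
#' @return rate (1/s).
#' @export
refold_rate <- function(F, dom, kBT = .kBT_default) {
  .check_force(F)
  dom$k_ref0 * exp(-F * dom$dx_ref / kBT)
}

#' Vinculin binding propensity of a talin rod
#'
#' Vinculin binds to the vinculin binding site exposed by the unfolded R3
#' domain, at rate `k_onv` when R3 is unfolded and unoccupied, zero otherwise.
#'
#' @param state a [talin_rod_state()].
#' @param k_onv vinculin binding rate (1/s).
#' @param params a `talin_params` data frame (locates R3).
#' @return rate (1/s).
#' @export
vinculin_propensity <- function(state, k_onv = 1e8,
                                params = talin_default_params()) {
  r3 <- which(params$name == "R3")
  if (!state$folded[r3] && !state$vinculin_bound) k_onv else 0
}

#' Stochastic pulling ramp on a single talin rod
#'
#' Pulls one talin rod at a constant rate, either displacement-driven
#' (`rate` in nm/s; forces drop at each unfolding event) or force-driven
#' (`rate` in pN/s; extension jumps at each unfolding event), with Gillespie
#' folding/unfolding kinetics refreshed at least every `dt_max`.
#'
#' @param rate pulling rate (nm/s for displacement mode, pN/s for force mode).
#' @param mode `"displacement"` or `"force"`.
#' @param params a `talin_params` data frame.
#' @param x_max final extension of a displacement ramp (nm); kept slightly
#'   below the fully unfolded contour.
#' @param F_max final force of a force ramp (pN).
#' @param kBT thermal energy (pN nm).
#' @param dt_max maximum interval between rate refreshes (s).
#' @return a data frame with columns `t`, `x`, `F`, `n_unfolded`, `event`
#'   (`"unfold"`, `"refold"` or `""` for rate-refresh ticks).
#' @export
ramp_experiment <- function(rate, mode = c("displacement", "force"),
                            params = talin_default_params(),
                            x_max = 700, F_max = 40,
                            kBT = .kBT_default, dt_max = 0.005) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0)
  state <- talin_rod_state(params = params)
  t <- 0
  cur <- function(t) {
    if (mode == "displacement") {
      x <- min(rate * t, rod_max_length(state, params) * 0.995)
      F <- if (x <= 0) 0 else rod_force(x, state, params, kBT)
      c(x = x, F = F)
    } else {
      F <- rate * t
      c(x = rod_extension(F, state, params, kBT), F = F)
    }
  }
  t_end <- if (rate == 0) 1 else if (mode == "displacement") x_max / rate else F_max / rate
  rows <- list()
  push <- function(t, ev) {
    v <- cur(t)
    rows[[length(rows) + 1]] <<- data.frame(
      t = t, x = v[["x"]], F = v[["F"]],
      n_unfolded = sum(!state$folded), event = ev)
  }
  push(0, "")
  while (t < t_end) {
    v <- cur(t)
    k_unf <- ifelse(state$folded & params$unfoldable,
                    unfold_rate(v[["F"]], params, kBT), 0)
    k_ref <- ifelse(!state$folded, refold_rate(v[["F"]], params, kBT), 0)
    ktot <- sum(k_unf) + sum(k_ref)
    tau <- if (ktot > 0) -log(stats::runif(1)) / ktot else Inf
    if (tau > dt_max) {
      t <- min(t + dt_max, t_end)
      push(t, "")
      next
    }
    t <- min(t + tau, t_end)
    rates <- c(k_unf, k_ref)
    j <- sample.int(2 * nrow(params), 1, prob = rates)
    if (j <= nrow(params)) {
      state$folded[j] <- FALSE
      push(t, "unfold")
    } else {
      state$folded[j - nrow(params)] <- TRUE
      push(t, "refold")
    }
  }
  do.call(rbind, rows)
}
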