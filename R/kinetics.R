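#' Integrin-ECM bond law
#'
#' Constructs the force-dependent unbinding law of an integrin-ligand bond.
#' Three laws are supported:
#'
#' * `"slip"`: Bell's model, `k_off * exp(F / F_b)`. Lifetime decreases
#'   monotonically with force.
#' * `"catch_slip"`: two-pathway law,
#'   `k_off_slip * exp(F / F_b_slip) + k_off_catch * exp(-F / F_b_catch)`.
#'   When the catch amplitude exceeds the slip amplitude the lifetime first
#'   increases with force (catch regime) before the slip pathway takes over.
#' * `"catch_cmr"`: catch-slip plus a fast-decaying third exponential active
#'   only below ~0.1 pN, modelling cyclic mechanical reinforcement (CMR):
#'   freshly engaged, unloaded bonds dissociate quickly until force builds.
#'
#' @param mode one of `"slip"`, `"catch_slip"`, `"catch_cmr"`.
#' @param k_off unloaded off-rate (1/s), slip mode.
#' @param F_b characteristic rupture force (pN), slip mode.
#' @param k_off_slip,F_b_slip slip-pathway constants (1/s, pN).
#' @param k_off_catch,F_b_catch catch-pathway constants (1/s, pN).
#' @param cmr_terms 3x2 matrix of (amplitude 1/s, force scale pN) rows for the
#'   CMR law; defaults to [cmr_default_terms()].
#' @return an object of class `bond_law`.
#' @seealso [off_rate()], [bond_lifetime()], [integrin_preset()]
#' @examples
#' law <- bond_law("slip", k_off = 0.1, F_b = 2)
#' off_rate(4, law)  # 0.1 * exp(2)
#' @export
bond_law <- function(mode = c("slip", "catch_slip", "catch_cmr"),
                     k_off = NULL, F_b = NULL,
                     k_off_slip = NULL, F_b_slip = NULL,
                     k_off_catch = NULL, F_b_catch = NULL,
                     cmr_terms = cmr_default_terms()) {
  mode <- match.arg(mode)
  law <- list(mode = mode, k_off = k_off, F_b = F_b,
              k_off_slip = k_off_slip, F_b_slip = F_b_slip,
              k_off_catch = k_off_catch, F_b_catch = F_b_catch,
              cmr_terms = cmr_terms)
  if (mode == "slip") {
    stopifnot(is.numeric(k_off), k_off >= 0, is.numeric(F_b), F_b > 0)
  } else {
    stopifnot(is.numeric(k_off_slip), k_off_slip >= 0, F_b_slip > 0,
              is.numeric(k_off_catch), k_off_catch >= 0, F_b_catch > 0)
  }
  if (mode == "catch_cmr") {
    stopifnot(is.matrix(cmr_terms), ncol(cmr_terms) == 2,
              all(cmr_terms[, 1] >= 0), all(cmr_terms[, 2] > 0))
  }
  structure(law, class = "bond_law")
}

#' Constants of the cyclic-mechanical-reinforcement off-rate law
#'
#' Amplitudes (1/s) and force scales (pN) of the three-term CMR unbinding law
#' `8.104 exp(F/8.16) + 10.14 exp(-F/6.24) + 900 exp(-F/0.01)`.
#'
#' @return a 3x2 matrix with columns `amplitude`, `force_scale`.
#' @export
cmr_default_terms <- function() {
  matrix(c(8.104, 8.16,
           10.14, 6.24,
           900,   0.01),
         ncol = 2, byrow = TRUE,
         dimnames = list(c("slip", "catch", "cmr"),
                         c("amplitude", "force_scale")))
}

.check_force <- function(F) {
  if (any(!is.finite(F)) || any(F < 0)) {
    stop("force must be finite and non-negative (pN)", call. = FALSE)
  }
}

#' Slip (Bell) unbinding rate
#'
#' `k_off * exp(F / F_b)`; strictly increasing in force.
#'
#' @param F force on the bond (pN); vectorised.
#' @param law a `"slip"`-mode [bond_law()].
#' @return unbinding rate (1/s).
#' @export
slip_off_rate <- function(F, law) {
  .check_force(F)
  stopifnot(inherits(law, "bond_law"), law$mode == "slip")
  law$k_off * exp(F / law$F_b)
}

#' Catch-slip unbinding rate
#'
#' Sum of an increasing (slip) and a decreasing (catch) exponential; tends to
#' the slip branch as force grows.
#'
#' @inheritParams slip_off_rate
#' @param law a `"catch_slip"`- or `"catch_cmr"`-mode [bond_law()]; the CMR
#'   terms are ignored here.
#' @return unbinding rate (1/s).
#' @export
catch_slip_off_rate <- function(F, law) {
  .check_force(F)
  stopifnot(inherits(law, "bond_law"), law$mode %in% c("catch_slip", "catch_cmr"))
  law$k_off_slip * exp(F / law$F_b_slip) +
    law$k_off_catch * exp(-F / law$F_b_catch)
}

#' Cyclic-mechanical-reinforcement unbinding rate
#'
#' Evaluates the three-term CMR law. The third term has a 0.01 pN force scale:
#' its exponent is clamped at -700 to avoid underflow warnings (mathematically
#' the term is zero beyond ~0.1 pN).
#'
#' @param F force on the bond (pN); vectorised.
#' @param terms 3x2 matrix of (amplitude, force scale) rows.
#' @return unbinding rate (1/s).
#' @examples
#' cmr_off_rate(0)  # 918.244 exactly
#' @export
cmr_off_rate <- function(F, terms = cmr_default_terms()) {
  .check_force(F)
  out <- numeric(length(F))
  signs <- c(1, -1, -1)  # slip grows, catch and CMR decay
  for (i in seq_len(nrow(terms))) {
    ex <- pmax(signs[i] * F / terms[i, 2], -700)
    out <- out + terms[i, 1] * exp(ex)
  }
  out
}

#' Force-dependent unbinding rate for any bond law
#'
#' Dispatches on `law$mode`.
#'
#' @inheritParams slip_off_rate
#' @param law a [bond_law()].
#' @return unbinding rate (1/s).
#' @export
off_rate <- function(F, law) {
  stopifnot(inherits(law, "bond_law"))
  switch(law$mode,
         slip = slip_off_rate(F, law),
         catch_slip = catch_slip_off_rate(F, law),
         catch_cmr = catch_slip_off_rate(F, law) +
           law$cmr_terms[3, 1] * exp(pmax(-F / law$cmr_terms[3, 2], -700)))
}

#' Mean bond lifetime under constant force
#'
#' Reciprocal of the unbinding rate. A zero rate yields `Inf`. For a
#' catch-slip law with catch amplitude above the slip amplitude the lifetime
#' has a single interior maximum.
#'
#' @inheritParams off_rate
#' @return lifetime (s).
#' @export
bond_lifetime <- function(F, law) {
  k <- off_rate(F, law)
  ifelse(k == 0, Inf, 1 / k)
}

#' Integrin population of an adhesion complex
#'
#' Book-keeping for the diffusive integrin density available for binding and
#' its vinculin-triggered reinforcement.
#'
#' @param k_ont association constant (um^2/s).
#' @param d_int0 initial integrin density (integrins/um^2).
#' @param int_add density increment per vinculin-binding event (int/um^2).
#' @param m_r maximum (saturating) density (int/um^2).
#' @return an object of class `integrin_population`.
#' @export
integrin_population <- function(k_ont, d_int0 = 300, int_add = 24, m_r = 15000) {
  stopifnot(k_ont >= 0, d_int0 >= 0, int_add >= 0, m_r >= d_int0)
  structure(list(k_ont = k_ont, d_int = d_int0, d_int0 = d_int0,
                 int_add = int_add, m_r = m_r),
            class = "integrin_population")
}

#' Binding propensity per free ligand
#'
#' `k_ont * d_int`: the association constant (um^2/s) times the current
#' integrin density (int/um^2), units cancelling to 1/s. This is the only
#' dimensionally consistent combination of the two quantities.
#'
#' @param pop an [integrin_population()].
#' @return binding rate per free ligand (1/s).
#' @export
binding_propensity <- function(pop) {
  stopifnot(inherits(pop, "integrin_population"))
  pop$k_ont * pop$d_int
}

#' Reinforce the integrin density after a vinculin-binding event
#'
#' Vinculin binding to an unfolded talin R3 domain signals integrin
#' recruitment: the available density increases by `int_add`, saturating at
#' `m_r`. Idempotent at the cap.
#'
#' @param pop an [integrin_population()].
#' @return the updated population.
#' @export
reinforce_density <- function(pop) {
  stopifnot(inherits(pop, "integrin_population"))
  pop$d_int <- min(pop$d_int + pop$int_add, pop$m_r)
  pop
}

# inverse of reinforce_density, used when recruitment is tied to the number of
# currently bound vinculins (never below the initial density)
release_density <- function(pop) {
  pop$d_int <- max(pop$d_int - pop$int_add, pop$d_int0)
  pop
}

#' Integrin parameter presets
#'
#' Catch-slip bond constants and association rates for the two integrin types
#' most commonly used in clutch models. The alpha5beta1 constants correspond to
#' the reinforced (2-fold lifetime) characterisation of the
#' alpha5beta1-fibronectin bond; alphaVbeta3 uses its own catch-slip fit.
#' CMR has only been demonstrated for alpha5beta1, so `cmr = TRUE` is accepted
#' but off by default for both presets (when on, the classical engine uses the
#' three-term CMR law instead of the catch-slip constants).
#'
#' @param name `"alpha5beta1"` or `"alphaVbeta3"`.
#' @param cmr use the CMR off-rate law in the classical engine.
#' @return list with elements `name`, `law` (a [bond_law()]), `k_ont`
#'   (um^2/s), and `cmr` (logical).
#' @examples
#' p <- integrin_preset("alphaVbeta3")
#' off_rate(0, p$law)  # 4.17e-4 + 0.4012
#' @export
integrin_preset <- function(name = c("alpha5beta1", "alphaVbeta3"), cmr = FALSE) {
  name <- match.arg(name)
  tab <- list(
    alpha5beta1 = list(k_ont = 0.005,
                       k_off_slip = 3.68e-4, F_b_slip = 7.168,
                       k_off_catch = 2, F_b_catch = 7.168),
    alphaVbeta3 = list(k_ont = 1e-4,
                       k_off_slip = 4.17e-4, F_b_slip = 5.4825,
                       k_off_catch = 0.4012, F_b_catch = 28.67))
  p <- tab[[name]]
  law <- if (cmr) {
    # the full printed CMR law: its first two terms are a catch-slip pair,
    # the third is the fast-decaying low-force reinforcement term
    terms <- cmr_default_terms()
    bond_law("catch_cmr",
             k_off_slip = terms[1, 1], F_b_slip = terms[1, 2],
             k_off_catch = terms[2, 1], F_b_catch = terms[2, 2],
             cmr_terms = terms)
  } else {
    bond_law("catch_slip",
             k_off_slip = p$k_off_slip, F_b_slip = p$F_b_slip,
             k_off_catch = p$k_off_catch, F_b_catch = p$F_b_catch)
  }
  list(name = name, law = law, k_ont = p$k_ont, cmr = cmr)
}
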