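# shared miniature objects for the suite

kBT <- 4.114

a5b1 <- integrin_preset("alpha5beta1")
aVb3 <- integrin_preset("alphaVbeta3")

talin_pars <- talin_default_params()

# a rod state with a chosen set of unfolded domains
rod_with_unfolded <- function(which_unfolded = integer(0), params = talin_pars) {
  folded <- rep(TRUE, nrow(params))
  folded[which_unfolded] <- FALSE
  talin_rod_state(folded = folded, params = params)
}

# brute-force argmax of a catch-slip lifetime on a fine force grid
lifetime_argmax_grid <- function(law, F_max = 60, by = 0.01) {
  F <- seq(0, F_max, by = by)
  F[which.max(bond_lifetime(F, law))]
}
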