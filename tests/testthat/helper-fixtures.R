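# Fixture molecules with hand-enumerated SSIP multisets, each assembled
# independently of the assignment code from the functional-group templates:
# every entry is a data frame of (role, value, count) rows whose expansion
# is the expected profile multiset.

fx <- function(...) {
  d <- data.frame(...)
  names(d) <- c("role", "value", "count")
  d
}

fixture_profiles <- list(
  methane = list(
    smiles = "C",
    ssips = fx(c("donor", "acceptor"), c(1.2, 0.6), c(4L, 4L))
  ),
  benzene = list(
    smiles = "c1ccccc1",
    ssips = fx(c("donor", "acceptor", "acceptor"),
               c(1.4, 0.7, 2.0), c(6L, 12L, 2L))
  ),
  toluene = list(
    smiles = "Cc1ccccc1",
    ssips = fx(c("donor", "donor", "acceptor", "acceptor", "acceptor",
                 "acceptor"),
               c(1.2, 1.4, 0.6, 0.7, 0.88, 2.2),
               c(3L, 5L, 3L, 10L, 2L, 2L))
  ),
  water = list(
    smiles = "O",
    ssips = fx(c("donor", "acceptor"), c(2.8, 4.5), c(2L, 2L))
  ),
  ethanol = list(
    smiles = "CCO",
    ssips = fx(c("donor", "donor", "acceptor", "acceptor", "acceptor"),
               c(1.2, 2.7, 0.6, 5.3, 3.98), c(5L, 1L, 5L, 1L, 1L))
  ),
  diethyl_ether = list(
    smiles = "CCOCC",
    ssips = fx(c("donor", "acceptor", "acceptor", "acceptor"),
               c(1.2, 0.6, 5.3, 3.98), c(10L, 10L, 1L, 1L))
  ),
  acetone = list(
    smiles = "CC(C)=O",
    ssips = fx(c("donor", "acceptor", "acceptor", "acceptor"),
               c(1.2, 0.6, 5.8, 3.8), c(6L, 8L, 1L, 1L))
  ),
  acetonitrile = list(
    smiles = "CC#N",
    ssips = fx(c("donor", "acceptor", "acceptor"),
               c(1.2, 0.6, 5.15), c(3L, 7L, 1L))
  ),
  t_butyl_chloride = list(
    smiles = "CC(C)(C)Cl",
    ssips = fx(c("donor", "acceptor", "acceptor"),
               c(1.2, 0.6, 2.3), c(11L, 11L, 1L))
  ),
  dichloromethane = list(
    smiles = "ClCCl",
    ssips = fx(c("donor", "donor", "acceptor", "acceptor"),
               c(1.2, 1.6, 0.6, 2.3), c(4L, 2L, 6L, 2L))
  ),
  chloroform = list(
    smiles = "ClC(Cl)Cl",
    ssips = fx(c("donor", "donor", "acceptor", "acceptor"),
               c(1.2, 1.6, 0.6, 2.3), c(6L, 1L, 7L, 3L))
  ),
  carbon_tetrachloride = list(
    smiles = "ClC(Cl)(Cl)Cl",
    ssips = fx(c("donor", "acceptor", "acceptor"),
               c(1.2, 0.6, 2.3), c(8L, 8L, 4L))
  )
)

# expand a (role, value, count) table into a sorted per-site multiset,
# for order-free comparison of profiles
expand_multiset <- function(ssips) {
  out <- data.frame(role = rep(ssips$role, ssips$count),
                    value = rep(ssips$value, ssips$count))
  out[order(out$role, out$value), , drop = FALSE]
}

profile_multiset <- function(profile) {
  expand_multiset(profile$ssips[, c("role", "value", "count")])
}

expect_profile_equal <- function(profile, expected_ssips) {
  got <- profile_multiset(profile)
  want <- expand_multiset(expected_ssips)
  expect_equal(unname(got$role), unname(want$role))
  expect_equal(unname(got$value), unname(want$value), tolerance = 1e-12)
}

# a synthetic single-site-pair solvent satisfying the reference closure
# C_alpha + C_beta = 6 - alpha_S * beta_S
make_closure_solvent <- function(alpha_s, beta_s, split = 0.5, c0 = 0) {
  total <- 6 - alpha_s * beta_s
  structure(list(name = "synthetic", alpha_s = alpha_s, beta_s = beta_s,
                 c_alpha = total * split, c_beta = total * (1 - split),
                 c0 = c0),
            class = "simple_solvent")
}

# a degenerate two-domain solvent whose two site types are identical, so
# every polar-solvent expression must collapse to the simple-solvent one
make_degenerate_polar <- function(alpha_s, c_alpha, beta_s, c_beta, c0 = 0,
                                  f_beta2 = 0.3, f_alpha2 = 0.4) {
  structure(list(class_name = "degenerate", member = "degenerate",
                 alpha_s1 = alpha_s, c_alpha1 = c_alpha,
                 beta_s1 = beta_s, c_beta1 = c_beta,
                 alpha_s2 = alpha_s, c_alpha2 = c_alpha,
                 beta_s2 = beta_s, c_beta2 = c_beta, c0 = c0,
                 f_alpha1 = 1 - f_alpha2, f_alpha2 = f_alpha2,
                 f_beta1 = 1 - f_beta2, f_beta2 = f_beta2),
            class = "two_domain_solvent")
}
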