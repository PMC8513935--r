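test_that("per-SSIP solvation energies reproduce the worked examples", {
  # alkane CH sites in water and in hexadecane
  expect_equal(round(dg_alpha_simple(1.20, "water"), 2), -3.40)
  expect_equal(round(dg_beta_simple(0.60, "water"), 2), -1.52)
  expect_equal(dg_alpha_simple(1.20, "hexadecane"), -3.36)
  expect_equal(dg_beta_simple(0.60, "hexadecane"), -3.36)

  # pure-function edge cases
  z <- structure(list(name = "z", alpha_s = 1, beta_s = 1, c_alpha = 0,
                      c_beta = 0, c0 = 0), class = "simple_solvent")
  expect_equal(dg_alpha_simple(0, z), 0)
  expect_equal(dg_beta_simple(0, z), 0)
})

test_that("donor solvation is strictly more favourable in more basic solvents", {
  betas <- seq(0.2, 5, by = 0.2)
  dg <- vapply(betas, function(bs) {
    s <- structure(list(name = "s", alpha_s = 1, beta_s = bs, c_alpha = 1,
                        c_beta = 1, c0 = 0), class = "simple_solvent")
    dg_alpha_simple(1.5, s)
  }, numeric(1))
  expect_true(all(diff(dg) < 0))
})

test_that("two-domain solvation matches an independent hand evaluation", {
  rt <- rt_kj(model_constants())

  # solute donor alpha = 2.7 in THF: ether constants, THF acceptor-site
  # fractions 8:2 (CH sites : oxygen lone pairs)
  k1 <- exp((2.7 * 0.60 + 2.98) / rt)
  k2 <- exp((2.7 * 5.30 - 3.65) / rt)
  oracle <- -rt * log(0.8 * k1 + 0.2 * k2)
  expect_equal(dg_alpha_polar(2.7, get_solvent("tetrahydrofuran")), oracle,
               tolerance = 1e-12)

  # solute acceptor beta = 5.3 in methanol: alcohol constants, donor-site
  # fractions 3:1 (CH donors : hydroxyl donor)
  j1 <- exp((1.20 * 5.3 + 2.75) / rt)
  j2 <- exp((3.50 * 5.3 - 6.02) / rt)
  oracle <- -rt * log(0.75 * j1 + 0.25 * j2)
  expect_equal(dg_beta_polar(5.3, get_solvent("methanol")), oracle,
               tolerance = 1e-12)
})

test_that("degenerate two-domain solvents collapse to the simple formulas", {
  simple_like <- list(c(1.2, 2.64, 0.6, 2.64), c(3.8, -0.76, 3.47, -0.76),
                      c(2.1, 1.78, 1.3, 2.11))
  alphas <- c(0, 0.5, 1.2, 2.8, 4.5)
  betas <- c(0, 0.6, 2.0, 4.5, 6.9)
  for (p in simple_like) {
    simple <- structure(list(name = "ref", alpha_s = p[1], c_alpha = p[2],
                             beta_s = p[3], c_beta = p[4], c0 = 0),
                        class = "simple_solvent")
    for (fr in c(0, 0.3, 1)) {
      degen <- make_degenerate_polar(p[1], p[2], p[3], p[4],
                                     f_beta2 = fr, f_alpha2 = fr)
      for (a in alphas) {
        expect_equal(dg_alpha_polar(a, degen), dg_alpha_simple(a, simple),
                     tolerance = 1e-9)
      }
      for (b in betas) {
        expect_equal(dg_beta_polar(b, degen), dg_beta_simple(b, simple),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("an all-polar two-domain solvent reduces to its polar site pair", {
  s <- make_degenerate_polar(1.2, 2.0, 0.6, 2.0, f_beta2 = 1, f_alpha2 = 1)
  s$beta_s2 <- 5.3; s$c_beta2 <- -3.65
  s$alpha_s2 <- 3.5; s$c_alpha2 <- -6.02
  expect_equal(dg_alpha_polar(2.0, s), -2.0 * 5.3 + 3.65, tolerance = 1e-9)
  expect_equal(dg_beta_polar(2.0, s), -3.5 * 2.0 + 6.02, tolerance = 1e-9)
})

test_that("whole-molecule solvation sums per-SSIP terms and applies C0 once", {
  p <- build_ssip_profile("C")
  bd <- solvation_free_energy(p, "water")
  expect_equal(bd$dg_total,
               4 * dg_alpha_simple(1.2, "water") +
                 4 * dg_beta_simple(0.6, "water"),
               tolerance = 1e-12)
  expect_equal(bd$sum_dg, sum(bd$per_site$dg_contribution))

  # positive C0 makes solvation more favourable by C0
  hex_no_c0 <- get_solvent("hexane")
  bd_hexane <- solvation_free_energy(p, "hexane")
  hex_no_c0$c0 <- 0
  bd_ref <- solvation_free_energy(p, hex_no_c0)
  expect_equal(bd_hexane$dg_total, bd_ref$dg_total - 1.38, tolerance = 1e-12)
})

test_that("transfer free energies: worked example, antisymmetry, zero diagonal", {
  # one CH pair, hexadecane -> water: +1.80 kJ/mol
  per_ch <- (dg_alpha_simple(1.2, "water") + dg_beta_simple(0.6, "water")) -
    (dg_alpha_simple(1.2, "hexadecane") + dg_beta_simple(0.6, "hexadecane"))
  expect_equal(round(per_ch, 2), 1.80)

  # n-heptane (16 CH bonds): 16 x per-CH
  hept <- transfer_free_energy("CCCCCCC", "hexadecane", "water")
  expect_equal(hept$dg_kjmol, 16 * per_ch, tolerance = 1e-12)
  expect_equal(hept$logp, -hept$dg_kjmol / (rt_kj(model_constants()) * log(10)),
               tolerance = 1e-12)

  solutes <- c("CCCCCCC", "CCO", "c1ccccc1", "ClCCl")
  solvents <- c("hexadecane", "water", "chloroform", "tetrahydrofuran",
                "ethanol", "acetone")
  for (smi in solutes) {
    p <- build_ssip_profile(smi)
    for (i in seq_along(solvents)) {
      expect_equal(transfer_free_energy(p, solvents[i], solvents[i])$dg_kjmol,
                   0, tolerance = 1e-12)
      for (j in seq_along(solvents)) {
        if (i >= j) next
        ij <- transfer_free_energy(p, solvents[i], solvents[j])$dg_kjmol
        ji <- transfer_free_energy(p, solvents[j], solvents[i])$dg_kjmol
        expect_equal(ij, -ji, tolerance = 1e-9)
      }
    }
  }
})

test_that("1:1 complexation matches the compact solvent-competition form", {
  r <- complexation_dg(2.80, 4.50, "carbon tetrachloride")
  # oracle: -(alpha - alpha_S)(beta - beta_S) + 6
  expect_equal(round(-(2.80 - 1.40) * (4.50 - 0.60) + 6, 2), 0.54)
  expect_equal(round(r$dg_kjmol, 2), 0.54)
  expect_equal(round(r$dg_eq_compact, 2), 0.54)
  expect_equal(r$k_assoc, exp(-r$dg_kjmol / rt_kj(model_constants())),
               tolerance = 1e-12)
  expect_gt(r$k_assoc, 0)

  # alpha = beta = 0: only the solvent-solvent constants remain
  r0 <- complexation_dg(0, 0, "carbon tetrachloride")
  expect_equal(r0$dg_kjmol, 2.58 + 2.58, tolerance = 1e-12)

  expect_error(complexation_dg(2.8, 4.5, "ethanol"), "non-polar")
})

test_that("both complexation forms agree on a grid when the closure holds", {
  grid <- expand.grid(alpha = seq(0, 6, by = 0.5), beta = seq(0, 6, by = 0.5))
  solvents <- list(get_solvent("hexadecane"),
                   get_solvent("carbon tetrachloride"),
                   make_closure_solvent(2.1, 1.3, split = 0.3),
                   make_closure_solvent(3.8, 3.47, split = 0.7))
  for (s in solvents) {
    expect_equal(s$c_alpha + s$c_beta, 6 - s$alpha_s * s$beta_s,
                 tolerance = 1e-12)
    for (k in seq_len(nrow(grid))) {
      r <- complexation_dg(grid$alpha[k], grid$beta[k], s)
      expect_equal(r$dg_kjmol, r$dg_eq_compact, tolerance = 1e-9)
    }
  }
})

test_that("RT ln[S.S] back-calculation reproduces the printed table", {
  printed <- c(hexadecane = 6.0, benzene = 6.4, toluene = 6.4, hexane = 6.0,
               cyclohexane = 5.9, "carbon tetrachloride" = 6.0,
               dichloromethane = 6.4, chloroform = 6.6,
               "1,2-dichloroethane" = 6.4, chlorobenzene = 6.2,
               perfluoroalkane = 5.5)
  for (name in names(printed)) {
    expect_equal(rt_ln_ss(name), printed[[name]], tolerance = 0.05,
                 label = name)
  }
  # the two solvating domains of alcohols
  alc <- get_solvent("ethanol")
  expect_equal(rt_ln_ss(alc, domain = 1), 6.4, tolerance = 0.05)
  expect_equal(rt_ln_ss(alc, domain = 2), 11.7, tolerance = 0.05)
  expect_error(rt_ln_ss(alc), "domain")
  expect_error(rt_ln_ss(get_solvent("tetrahydrofuran"), domain = 2),
               "no polar donor site")
})

test_that("the single-site closure recovers the printed solvent constants", {
  expect_equal(constants_from_ss(1.20, 0.60, rt_ln_ss_kj = 6),
               c(c_alpha = 2.64, c_beta = 2.64))
  expect_equal(constants_from_ss(1.40, 0.60, rt_ln_ss_kj = 6),
               c(c_alpha = 2.58, c_beta = 2.58))
  w <- constants_from_ss(2.80, 4.50, ss_concentration = 110)
  expect_equal(round(unname(w), 2), c(-0.47, -0.47))
  # closure and back-calculation are inverses
  s <- get_solvent("hexadecane")
  expect_equal(unname(constants_from_ss(s$alpha_s, s$beta_s,
                                        rt_ln_ss_kj = rt_ln_ss(s))[1]),
               s$c_alpha, tolerance = 1e-12)
  expect_error(constants_from_ss(1.2, 0.6), "positive")
})
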