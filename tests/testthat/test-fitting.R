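fit_solutes <- c(heptane = "CCCCCCC", pentane = "CCCCC", methane = "C",
                 isobutane = "CC(C)C", cyclohexane = "C1CCCCC1",
                 benzene = "c1ccccc1", toluene = "Cc1ccccc1",
                 ethanol = "CCO", acetone = "CC(C)=O",
                 acetonitrile = "CC#N", dcm = "ClCCl", water = "O")

test_that("rmsd is the root-mean-square deviation", {
  expect_equal(rmsd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsd(c(1, -1), c(0, 0)), 1.0)
  expect_equal(rmsd(c(3, 4), c(0, 0)), sqrt(12.5))
  expect_error(rmsd(1:3, 1:2), "equal non-zero length")
  expect_error(rmsd(numeric(0), numeric(0)), "equal non-zero length")
})

test_that("partition datasets reject duplicates and non-finite energies", {
  expect_error(
    partition_dataset(c("a", "a"), c("C", "C"), "water", "hexane", c(1, 2)),
    "duplicate")
  expect_error(
    partition_dataset("a", "C", "water", "hexane", NaN), "finite")
})

test_that("noise-free simulation agrees with the reference prediction route", {
  d <- simulate_partition_dataset(fit_solutes[1:6],
                                  c("hexadecane", "chloroform", "ethanol",
                                    "tetrahydrofuran"),
                                  noise_sd = 0, seed = 7)
  # independent route: per-record profile + breakdown summation
  ref <- vapply(seq_len(nrow(d)), function(k) {
    transfer_free_energy(build_ssip_profile(d$smiles[k]),
                         d$solvent_from[k], d$solvent_to[k])$dg_kjmol
  }, numeric(1))
  expect_equal(d$dg_kjmol, ref, tolerance = 1e-9)
  expect_equal(rmsd(d$dg_kjmol, ref), 0, tolerance = 1e-12)
})

test_that("simulation is reproducible for a fixed seed", {
  a <- simulate_partition_dataset(fit_solutes[1:4], "hexane",
                                  noise_sd = 1.0, seed = 42)
  b <- simulate_partition_dataset(fit_solutes[1:4], "hexane",
                                  noise_sd = 1.0, seed = 42)
  expect_identical(a, b)
  c2 <- simulate_partition_dataset(fit_solutes[1:4], "hexane",
                                   noise_sd = 1.0, seed = 43)
  expect_false(identical(a$dg_kjmol, c2$dg_kjmol))
})

test_that("an empty free set scores the shipped model without fitting", {
  d <- simulate_partition_dataset(fit_solutes[1:5], "hexadecane",
                                  noise_sd = 0.8, seed = 3)
  fit <- fit_parameters(d, fit_spec(free = character(0), seed = 3))
  expect_length(fit$par, 0)
  expect_equal(fit$rmsd_final, fit$rmsd_initial)
  expect_equal(fit$rmsd_final, rmsd(d$dg_kjmol - fit$residuals, d$dg_kjmol))
})

test_that("free and frozen sets must be disjoint; counts are never free", {
  expect_error(fit_spec(free = "solvent/hexane/c0",
                        frozen = "solvent/hexane/c0"), "overlap")
  expect_error(fit_spec(free = "group/[CX4H3]/count"), "integers")
})

test_that("noiseless synthetic data recovers simple-solvent constants", {
  truth <- c("solvent/hexane/c_alpha" = 2.85, "solvent/hexane/c_beta" = 2.40,
             "solvent/hexane/c0" = 0.95)
  pairs <- data.frame(from = c("water", "hexadecane", "benzene"),
                      to = "hexane")
  d <- simulate_partition_dataset(fit_solutes, pairs, noise_sd = 0,
                                  seed = 11, overrides = truth)
  fit <- fit_parameters(d, fit_spec(free = names(truth), seed = 11))
  expect_lt(fit$rmsd_final, 1e-6)
  expect_equal(unname(fit$par), unname(truth), tolerance = 1e-3)
})

test_that("noiseless synthetic data recovers two-domain solvent constants", {
  # ether class
  truth <- c("class/ethers/c_beta2" = -3.10, "class/ethers/c0" = 1.80)
  pairs <- data.frame(from = c("water", "hexadecane"),
                      to = c("tetrahydrofuran", "diethyl ether"))
  d <- simulate_partition_dataset(fit_solutes, pairs, noise_sd = 0,
                                  seed = 5, overrides = truth)
  fit <- fit_parameters(d, fit_spec(free = names(truth), seed = 5))
  expect_lt(fit$rmsd_final, 1e-6)
  expect_equal(unname(fit$par), unname(truth), tolerance = 1e-3)

  # alcohol class, including a polar donor-site constant
  truth <- c("class/alcohols/c_alpha2" = -5.50, "class/alcohols/c0" = 0.40)
  pairs <- data.frame(from = c("water", "hexadecane"),
                      to = c("ethanol", "methanol"))
  d <- simulate_partition_dataset(fit_solutes, pairs, noise_sd = 0,
                                  seed = 6, overrides = truth)
  fit <- fit_parameters(d, fit_spec(free = names(truth), seed = 6))
  expect_lt(fit$rmsd_final, 1e-6)
  expect_equal(unname(fit$par), unname(truth), tolerance = 1e-3)
})

test_that("the iteration trace never increases and fits are deterministic", {
  truth <- c("solvent/hexane/c_alpha" = 2.90, "solvent/hexane/c0" = 1.00)
  d <- simulate_partition_dataset(fit_solutes,
                                  data.frame(from = "water", to = "hexane"),
                                  noise_sd = 0.5, seed = 21,
                                  overrides = truth)
  spec <- fit_spec(free = names(truth), seed = 21)
  f1 <- fit_parameters(d, spec)
  f2 <- fit_parameters(d, spec)
  expect_identical(f1, f2)
  expect_true(all(diff(f1$trace) <= 1e-12))
  expect_lte(f1$rmsd_final, f1$rmsd_initial)
})

test_that("parameters the dataset cannot constrain are frozen with a warning", {
  d <- simulate_partition_dataset(fit_solutes[1:5],
                                  data.frame(from = "water", to = "hexane"),
                                  noise_sd = 0, seed = 2)
  expect_warning(
    fit <- fit_parameters(d, fit_spec(free = c("solvent/hexane/c0",
                                               "class/ketones/c_beta2"),
                                      seed = 2)),
    "zero sensitivity")
  expect_true("class/ketones/c_beta2" %in% fit$frozen)
  # the frozen parameter keeps its registry value
  expect_equal(unname(fit$par["class/ketones/c_beta2"]), -4.09)
})

test_that("fitting to noisy data approaches the noise floor", {
  targets <- c("hexadecane", "hexane", "cyclohexane", "chloroform",
               "dichloromethane", "benzene", "toluene",
               "carbon tetrachloride", "1,2-dichloroethane", "chlorobenzene",
               "perfluoroalkane", "tetrahydrofuran", "diethyl ether",
               "acetone", "acetonitrile", "ethanol", "methanol")
  d <- simulate_partition_dataset(fit_solutes, targets, noise_sd = 0.5,
                                  seed = 97)
  expect_gte(nrow(d), 200L)
  fit <- fit_parameters(d, fit_spec(free = c("solvent/hexane/c_alpha",
                                             "solvent/hexane/c_beta",
                                             "solvent/hexane/c0"),
                                    seed = 97))
  # generating values are the registry values; recovery within ~3 SE
  expect_lt(abs(fit$par[["solvent/hexane/c_alpha"]] - 2.62), 0.5)
  expect_lt(abs(fit$par[["solvent/hexane/c_beta"]] - 2.62), 0.5)
  expect_lt(abs(fit$par[["solvent/hexane/c0"]] - 1.38), 0.5)
  # the residual rms matches the injected noise level
  expect_lt(abs(fit$rmsd_final - 0.5), 0.1)
})
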