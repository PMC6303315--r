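test_that("scenarios are balanced and reproduce the stated scalings", {
  ctrl <- make_scenario("control")
  expect_silent(check_mass_balance(ctrl$network, ctrl$fluxes))
  expect_equal(ratios_from_fluxes(ctrl$network, ctrl$fluxes)[
    names(control_truth())], control_truth(), tolerance = 1e-10)

  inh <- make_scenario("phgdh_inhibited")
  expect_silent(check_mass_balance(inh$network, inh$fluxes))
  fc <- unclass(ctrl$fluxes); fi <- unclass(inh$fluxes)
  expect_equal(fi[["PPPOX"]] / fc[["PPPOX"]], 0.4, tolerance = 1e-10)
  expect_equal(fi[["PDH"]] / fc[["PDH"]], 0.4, tolerance = 1e-10)
  expect_equal(fi[["PC"]] / fc[["PC"]], 0.4, tolerance = 1e-10)
  expect_equal(fi[["SSP"]] / fc[["SSP"]], 0.5, tolerance = 1e-10)
  expect_equal(fi[["SHMT"]] / fc[["SHMT"]], 1.0, tolerance = 1e-10)

  # custom all-x1 overrides equal control
  same <- make_scenario("custom",
                        overrides = list(scales = list(ppp = 1, tca = 1)))
  expect_equal(stats::setNames(as.numeric(same$fluxes), names(same$fluxes)),
               stats::setNames(as.numeric(ctrl$fluxes), names(ctrl$fluxes)))

  # infeasible scaling (share pushed past 1) errors
  expect_error(make_scenario("custom",
                             overrides = list(scales = list(ppp = 3))),
               "infeasible")
})

test_that("MID datasets are reproducible and exact at zero noise", {
  sc0 <- make_scenario("control", overrides = list(noise_sd = 0,
                                                   n_replicates = 1))
  ds0 <- simulate_mid_dataset(sc0)
  truth <- simulate_network_mids(sc0$network, sc0$fluxes, tracer_spec(),
                                 targets = default_measured_metabolites())
  for (m in names(truth)) {
    expect_equal(get_mid(ds0, m, "control", 1), as.numeric(truth[[m]]),
                 tolerance = 1e-12)
  }

  sc <- make_scenario("control", seed = 33)
  a <- simulate_mid_dataset(sc)
  b <- simulate_mid_dataset(sc)
  expect_identical(a, b)
  c2 <- simulate_mid_dataset(sc, seed = 34)
  expect_false(identical(a, c2))
})

test_that("noisy datasets stay valid MIDs", {
  sc <- make_scenario("control", overrides = list(noise_sd = 0.05))
  ds <- simulate_mid_dataset(sc)
  for (m in unique(ds$metabolite)) {
    for (r in 1:3) {
      v <- get_mid(ds, m, "control", r)
      expect_true(all(v >= 0))
      expect_equal(sum(v), 1, tolerance = 1e-9)
    }
  }
})

test_that("time courses follow the first-order model and close the loop", {
  ctrl <- make_scenario("control")
  tc <- simulate_timecourse_dataset(ctrl, noise_sd = 0)
  expect_true(all(tc$fraction[tc$time_min == 0] == 0))
  # noise-free points lie exactly on the generating curve
  r5p <- tc[tc$metabolite == "R5P" & tc$replicate == 1, ]
  k_true <- emuflux:::production_flux(ctrl$network,
                                      unclass(ctrl$fluxes))[["R5P"]] /
    default_pool_sizes()[["R5P"]]
  expect_equal(r5p$fraction, 1 * (1 - exp(-k_true * r5p$time_min)),
               tolerance = 1e-12)

  # closure: fitted rate-constant ratio recovers the constructed TCA drop
  inh <- make_scenario("phgdh_inhibited")
  fits_c <- fit_timecourse_table(tc)
  fits_i <- fit_timecourse_table(simulate_timecourse_dataset(inh,
                                                             noise_sd = 0))
  for (met in c("AKG", "R5P")) {
    kc <- fits_c$k[fits_c$metabolite == met]
    ki <- fits_i$k[fits_i$metabolite == met]
    expect_equal(ki / kc, 0.4, tolerance = 1e-4)
  }

  expect_error(simulate_timecourse_dataset(ctrl, pools = c("3PG" = 0)),
               "positive")
  expect_identical(simulate_timecourse_dataset(ctrl),
                   simulate_timecourse_dataset(ctrl))
})

test_that("time-course tables round-trip through CSV", {
  tc <- simulate_timecourse_dataset(make_scenario("control"))
  path <- tempfile(fileext = ".csv")
  write_timecourse_table(tc, path, header = "synthetic time course")
  back <- read_timecourse_table(path)
  expect_equal(back$fraction, tc$fraction, tolerance = 1e-12)
  expect_error(read_timecourse_table(tempfile()), "not found")
})
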