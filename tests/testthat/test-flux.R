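# Independent oracle: the packaged network is small enough that the whole
# flux vector follows from the branch shares by backward chaining from the
# biomass demands. This closed-form route shares no code with the QR solve.
chain_solution <- function(r, b = c(SER = 0.4, GLY = 0.5, ASP = 0.35,
                                    IMP = 0.10, UMP = 0.08)) {
  v <- c(IMPS = r[["IMP"]] * b[["IMP"]],
         IMPSAL = (1 - r[["IMP"]]) * b[["IMP"]],
         UMPS = r[["UMP"]] * b[["UMP"]],
         UMPSAL = (1 - r[["UMP"]]) * b[["UMP"]])
  v["CPS"] <- v[["UMPS"]]
  gly_tot <- v[["IMPS"]] + b[["GLY"]]
  v["SHMT"] <- r[["GLY"]] * gly_tot
  v["GLYUP"] <- (1 - r[["GLY"]]) * gly_tot
  ser_tot <- v[["SHMT"]] + b[["SER"]]
  v["SSP"] <- r[["SER"]] * ser_tot
  v["SERUP"] <- (1 - r[["SER"]]) * ser_tot
  v["PPPOX"] <- v[["UMPS"]] + v[["IMPS"]]
  asp_tot <- v[["UMPS"]] + b[["ASP"]]
  v["ASPS"] <- r[["ASP"]] * asp_tot
  v["ASPUP"] <- (1 - r[["ASP"]]) * asp_tot
  v["PC"] <- v[["ASPS"]]
  v["TCA2"] <- v[["PC"]] * (1 - r[["OAA"]]) / r[["OAA"]]
  v["CS"] <- v[["TCA2"]]
  v["PDH"] <- v[["TCA2"]]
  v["PK"] <- v[["PDH"]] + v[["PC"]]
  v["GLYC"] <- (v[["SSP"]] + v[["PK"]]) / 2
  v["HK"] <- v[["PPPOX"]] + v[["GLYC"]]
  v
}

test_that("branch ratios are solved from reporter MIDs", {
  net <- build_phgdh_network()
  # de novo serine share = serine m+3 / 3PG m+3 with unlabeled uptake
  mids <- make_set(list(
    "3PG" = c(0.2, 0, 0, 0.8), SER = c(0.92, 0, 0, 0.08),
    GLY = c(0.96, 0, 0.04), R5P = c(0, 0, 0, 0, 0, 1),
    OAA = c(0, 0, 0, 0.6, 0.4), ASP = c(0.3, 0, 0, 0.42, 0.28),
    IMP = c(0.15, rep(0, 9), 0.85), UMP = c(0.2, rep(0, 8), 0.8)))
  ratios <- compute_branch_ratios(mids, net, tracer_spec(), "control", 1)
  names(ratios) <- vapply(ratios, `[[`, "", "pool")
  expect_equal(ratios$SER$shares[["SSP"]], 0.1)
  expect_equal(ratios$SER$shares[["SERUP"]], 0.9)
  expect_equal(ratios$GLY$shares[["SHMT"]], 0.04 / 0.08)
  expect_equal(ratios$OAA$shares[["PC"]], 0.6)
  expect_equal(ratios$ASP$shares[["ASPS"]], 0.7 / 1)
  expect_true(all(vapply(ratios, `[[`, TRUE, "identifiable")))

  # single-source limit: salvage unlabeled and absent -> de novo share 1
  expect_equal(ratios$IMP$shares[["IMPS"]], 0.85, tolerance = 1e-6)

  # all reporters unlabeled -> branch unidentifiable (denominator floor)
  dead <- make_set(list(
    "3PG" = c(1, 0, 0, 0), SER = c(1, 0, 0, 0), GLY = c(1, 0, 0),
    R5P = c(1, 0, 0, 0, 0, 0), OAA = c(1, 0, 0, 0, 0),
    ASP = c(1, 0, 0, 0, 0), IMP = c(1, rep(0, 10)),
    UMP = c(1, rep(0, 9))))
  dr <- compute_branch_ratios(dead, net, tracer_spec(), "control", 1)
  expect_false(dr[[1L]]$identifiable)

  # out-of-range share from noise is clipped with a warning
  noisy <- make_set(list(
    "3PG" = c(0.9, 0, 0, 0.1), SER = c(0.88, 0, 0, 0.12),
    GLY = c(1, 0, 0), R5P = c(0, 0, 0, 0, 0, 1),
    OAA = c(0, 0, 0, 0.6, 0.4), ASP = c(0.3, 0, 0, 0.42, 0.28),
    IMP = c(0.15, rep(0, 9), 0.85), UMP = c(0.2, rep(0, 8), 0.8)))
  expect_warning(
    nr <- compute_branch_ratios(noisy, net, tracer_spec(), "control", 1),
    "clipped")
  names(nr) <- vapply(nr, `[[`, "", "pool")
  expect_equal(nr$SER$shares[["SSP"]], 1)
  expect_true(nr$SER$clipped)
})

test_that("analytical solve reproduces the backward-chained solution", {
  net <- build_phgdh_network()
  for (r in list(control_truth(),
                 c(SER = 0.3, GLY = 0.7, ASP = 0.5, OAA = 0.4,
                   IMP = 0.6, UMP = 0.5))) {
    v <- solve_from_ratios(net, r)
    expected <- chain_solution(r)
    expect_equal(unclass(v)[names(expected)], expected, tolerance = 1e-10)
    expect_silent(check_mass_balance(net, v))
    # re-deriving the shares from the solved fluxes reproduces the inputs
    expect_equal(ratios_from_fluxes(net, v)[names(r)], r,
                 tolerance = 1e-8)
  }
})

test_that("solver fails informatively on bad constraint sets", {
  net <- build_phgdh_network()
  ratios <- emuflux:::ratio_constraints_from_values(net, control_truth())
  expect_error(solve_fluxes_analytical(ratios[-1L], net),
               "underdetermined")
  expect_error(solve_from_ratios(net, control_truth()[-2L]),
               "missing ratio")
  una <- ratios
  una[[1L]]$identifiable <- FALSE
  expect_error(solve_fluxes_analytical(una, net), "unidentifiable")
})

test_that("noise-free synthetic data gives exact flux recovery", {
  sc <- make_scenario("control", overrides = list(noise_sd = 0,
                                                  n_replicates = 3))
  ds <- simulate_mid_dataset(sc)
  est <- estimate_fluxes(ds, sc$network, tracer_spec(), "control")
  expect_equal(est$n, 3L)
  truth <- unclass(sc$fluxes)
  expect_lt(max(abs(est$mean - truth) / truth), 1e-6)
  # identical replicates: zero sd on every flux
  expect_true(all(est$sd == 0))
})

test_that("noisy replicates stay close to truth for non-tiny fluxes", {
  sc <- make_scenario("control", overrides = list(noise_sd = 0.01,
                                                  n_replicates = 3))
  est <- suppressWarnings(estimate_fluxes(simulate_mid_dataset(sc, seed = 4),
                                          sc$network, tracer_spec(),
                                          "control"))
  truth <- unclass(sc$fluxes)
  big <- truth >= 0.05
  expect_lt(max(abs(est$mean[big] - truth[big]) / truth[big]), 0.15)
})

test_that("condition comparison returns ratios and t statistics", {
  sc <- make_scenario("control", overrides = list(noise_sd = 0,
                                                  n_replicates = 3))
  ds <- simulate_mid_dataset(sc)
  est <- estimate_fluxes(ds, sc$network, tracer_spec(), "control")
  same <- compare_conditions(est, est)
  expect_true(all(same$ratio == 1))
  expect_true(all(same$p == 1))

  # zero-variance inputs with different means: p in the t -> Inf limit
  inh <- make_scenario("phgdh_inhibited",
                       overrides = list(noise_sd = 0, n_replicates = 3))
  est2 <- estimate_fluxes(simulate_mid_dataset(inh), inh$network,
                          tracer_spec(), "phgdh_inhibited")
  cmp <- compare_conditions(est, est2)
  expect_equal(cmp$p[cmp$flux == "PPPOX"], 0)
  expect_equal(cmp$ratio[cmp$flux == "PPPOX"], 0.4, tolerance = 1e-8)

  bad <- est2
  names(bad$mean)[1] <- "XX"
  expect_error(compare_conditions(est, bad), "flux names differ")
})
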