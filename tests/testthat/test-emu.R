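test_that("MID convolution follows the Cauchy product", {
  expect_equal(convolve_mids(c(1, 0), c(1, 0)), c(1, 0, 0))
  expect_equal(convolve_mids(c(0, 1), c(0, 1)), c(0, 0, 1))
  expect_equal(convolve_mids(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_error(convolve_mids(c(0.5, 0.2), c(1, 0)), "normalized")

  set.seed(11)
  for (i in 1:10) {
    a <- as_rand <- runif(4); a <- a / sum(a)
    b <- runif(3); b <- b / sum(b)
    cc <- runif(2); cc <- cc / sum(cc)
    expect_equal(convolve_mids(a, b), convolve_mids(b, a))
    expect_equal(convolve_mids(convolve_mids(a, b), cc),
                 convolve_mids(a, convolve_mids(b, cc)))
    expect_equal(convolve_mids(a, c(1, 0)), c(a, 0))
    expect_equal(sum(convolve_mids(a, b)), 1)
  }
})

test_that("simulated MIDs match simple transfer expectations", {
  net <- build_phgdh_network()
  fx <- make_scenario("control")$fluxes

  # fully unlabeled tracer: every pool stays at m+0
  sim <- simulate_network_mids(net, fx, tracer_spec("GLC", purity = 0))
  for (m in names(sim)) {
    expect_equal(sim[[m]][1L], 1, tolerance = 1e-12)
  }

  # pure [U-13C]glucose: R5P keeps five labeled carbons (m+5)
  sim <- simulate_network_mids(net, fx, tracer_spec(),
                               targets = c("R5P", "G6P", "3PG"))
  expect_equal(sim$R5P, c(0, 0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_equal(sim$G6P, c(0, 0, 0, 0, 0, 0, 1), tolerance = 1e-12)
  expect_equal(sim[["3PG"]], c(0, 0, 0, 1), tolerance = 1e-12)
})

test_that("a two-input pool mixes linearly: serine m+3 = f * p", {
  net <- convergence_net()
  f <- 0.3
  fx <- c(R1 = f, R2 = 1 - f, R3 = 1)
  tr <- tracer_spec("T", purity = 0.9)
  p <- 0.9^3
  sim <- simulate_network_mids(net, fx, tr)
  expect_equal(sim$P[4L], f * p, tolerance = 1e-12)
  bf <- enumerate_isotopomers_bruteforce(net, fx, tr, targets = "P")
  expect_equal(sim$P, bf$P, tolerance = 1e-10)
})

test_that("steady-state MIDs match independently derived closed forms", {
  # hand analysis of the packaged network under a pure glucose tracer:
  # positional enrichment balances give OAA carbons 1-3 fully labeled and
  # carbon 4 labeled with probability 1 - rho (rho = PC share of OAA
  # production), so OAA = (0,0,0,rho,1-rho); downstream pools follow by
  # linear mixing with their unlabeled uptake routes.
  r <- control_truth()
  rho <- r[["OAA"]]
  sc <- make_scenario("control")
  sim <- simulate_network_mids(sc$network, sc$fluxes, tracer_spec())

  expect_equal(sim$OAA, c(0, 0, 0, rho, 1 - rho), tolerance = 1e-10)
  expect_equal(sim$AKG, c(0, 0, 0, 0, rho, 1 - rho), tolerance = 1e-10)
  expect_equal(sim$SER, c(1 - r[["SER"]], 0, 0, r[["SER"]]),
               tolerance = 1e-10)
  expect_equal(sim$GLY, c(1 - r[["GLY"]] * r[["SER"]], 0,
                          r[["GLY"]] * r[["SER"]]), tolerance = 1e-10)
  asp <- r[["ASP"]]
  expect_equal(sim$ASP, c(1 - asp, 0, 0, asp * rho, asp * (1 - rho)),
               tolerance = 1e-10)
  # UMP: de novo = R5P(m5) x Asp[2..4] x CAP(m0); salvage unlabeled
  u <- r[["UMP"]]
  ump <- numeric(10)
  ump[1] <- 1 - u
  ump[6] <- u * (1 - asp)
  ump[8] <- u * asp * rho
  ump[9] <- u * asp * (1 - rho)
  expect_equal(sim$UMP, ump, tolerance = 1e-10)
})

test_that("EMU cascade agrees with the brute-force isotopomer oracle", {
  paths <- list_toy_networks()
  expect_gte(length(paths), 5L)
  for (p in paths) {
    net <- parse_network_file(p)
    src <- net$pools$id[net$pools$role == "source"]
    tr <- tracer_spec(src[1L], purity = 0.95, unlabeled_fraction = 0.08)
    for (seed in 1:3) {
      fx <- random_fluxes(net, seed)
      emu <- simulate_network_mids(net, fx, tr)
      bf <- enumerate_isotopomers_bruteforce(net, fx, tr,
                                             targets = names(emu))
      for (m in names(emu)) {
        expect_lt(max(abs(emu[[m]] - bf[[m]])), 1e-8)
      }
    }
  }
  # and on the full packaged network with an impure tracer
  net <- build_phgdh_network()
  fx <- make_scenario("control")$fluxes
  tr <- tracer_spec("GLC", purity = 0.99, unlabeled_fraction = 0.05)
  emu <- simulate_network_mids(net, fx, tr,
                               targets = default_measured_metabolites())
  bf <- enumerate_isotopomers_bruteforce(net, fx, tr, targets = names(emu))
  for (m in names(emu)) {
    expect_lt(max(abs(emu[[m]] - bf[[m]])), 1e-8)
  }
})

test_that("steady-state MIDs are invariant to rescaling all fluxes", {
  net <- build_phgdh_network()
  fx <- make_scenario("control")$fluxes
  sys <- emu_decompose(net, c("SER", "OAA", "IMP"))
  a <- simulate_mids(sys, fx, tracer_spec())
  b <- simulate_mids(sys, unclass(fx) * 7.3, tracer_spec())
  for (m in names(a)) expect_equal(a[[m]], b[[m]], tolerance = 1e-12)
})

test_that("simulated MIDs are normalized and non-negative", {
  net <- build_phgdh_network()
  for (seed in 1:5) {
    fx <- random_fluxes(net, seed + 100)
    sim <- simulate_network_mids(net, fx, tracer_spec(purity = 0.97))
    for (m in names(sim)) {
      expect_equal(sum(sim[[m]]), 1, tolerance = 1e-9)
      expect_true(all(sim[[m]] >= 0))
    }
  }
})

test_that("degenerate inputs fail loudly", {
  net <- build_phgdh_network()
  fx <- make_scenario("control")$fluxes
  bad <- unclass(fx); bad["SSP"] <- -0.1
  sys <- emu_decompose(net, "SER")
  expect_error(simulate_mids(sys, bad, tracer_spec()), "negative flux")
  expect_error(emu_decompose(net, "NOPE"), "unknown metabolite")

  orphan <- parse_lines("SOURCE A 2", "SINK B 2", "SINK C 2",
                        "R1: A (ab) -> B (ab)", "R2: C (ab) -> B (ab)")
  expect_error(emu_decompose(orphan, "C"), "unreachable|no producer")

  big <- parse_lines("SOURCE A 13", "SINK B 13",
                     paste0("R1: A (abcdefghijklm) -> B (abcdefghijklm)"))
  expect_error(enumerate_isotopomers_bruteforce(big, c(R1 = 1),
                                                tracer_spec("A")),
               "state space")
})
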