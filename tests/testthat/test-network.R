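test_that("reaction parsing recovers pools, carbon counts and atom maps", {
  net <- parse_lines("SOURCE GLC 6", "SINK G6P 6",
                     "HK: GLC (abcdef) -> G6P (abcdef)")
  expect_equal(length(net$reaction_ids), 1L)
  expect_equal(nrow(net$pools), 2L)
  expect_equal(sort(net$pools$n_carbons), c(6L, 6L))

  net <- parse_lines("SOURCE P3 3", "SINK GLY 2", "SINK C1 1",
                     "A: P3 (abc) -> SER (abc)",
                     "B: SER (abc) -> GLY (ab) + C1 (c)")
  # glycine carries serine carbons 1-2; the one-carbon unit carries carbon 3
  cleave <- net$variants[[2L]]
  expect_equal(cleave$products[[1L]]$map, c("a", "b"))
  expect_equal(cleave$products[[2L]]$map, "c")

  net <- parse_lines("SOURCE PYR 3", "SINK ACCOA 2", "SINK CO2 1",
                     "PDH: PYR (abc) -> ACCOA (bc) + CO2 (a)")
  expect_equal(net$variants[[1L]]$products[[2L]]$map, "a")
})

test_that("parse errors name the offending line", {
  expect_error(parse_lines("SOURCE A 2", "R1 A (ab) -> B (ab)"),
               "line 2")
  expect_error(parse_lines("SOURCE A 2", "R1: A (ab -> B (ab)"),
               "line 2")
  expect_error(parse_lines("SOURCE A 2"), "no reactions")
  expect_error(parse_network_file(tempfile()), "not found")
})

test_that("atom-balance validation catches carbon loss and map mismatches", {
  good <- parse_lines("SOURCE A 3", "SINK B 2", "SINK W 1",
                      "R1: A (abc) -> B (ab) + W (c)")
  expect_length(validate_atom_balance(good), 0L)

  # a 3-carbon substrate mapped into a 2-carbon product with no CO2 cannot
  # even parse as balanced; the validator reports it rather than raising
  net <- good
  net$variants[[1L]]$products <- net$variants[[1L]]$products[1L]
  expect_length(validate_atom_balance(net), 1L)
  expect_match(validate_atom_balance(net), "!=")

  # map length inconsistent with declared carbon count
  expect_error(parse_lines("SOURCE A 2", "SINK B 3",
                           "R1: A (abc) -> B (abc)"),
               "2 and 3 carbons|declared 2")
})

test_that("stoichiometric matrix encodes net balances with biomass column", {
  chain <- parse_lines("SOURCE A 2", "SINK C 2",
                       "R1: A (ab) -> B (ab)", "R2: B (ab) -> C (ab)")
  S <- stoichiometric_matrix(chain)
  expect_equal(rownames(S), "B")
  expect_equal(unname(S["B", ]), c(1, -1, 0))

  branch <- parse_lines("SOURCE S 2", "SINK B 2", "SINK C 2",
                        "RIN: S (ab) -> A (ab)",
                        "R1: A (ab) -> B (ab)", "R2: A (ab) -> C (ab)")
  S <- stoichiometric_matrix(branch)
  expect_equal(unname(S["A", c("R1", "R2")]), c(-1, -1))

  nosink <- parse_lines("SOURCE A 2", "SINK B 2", "R1: A (ab) -> B (ab)")
  expect_error(stoichiometric_matrix(nosink), "no balanced pool")
})

test_that("network writer round-trips losslessly", {
  net <- build_phgdh_network()
  path <- tempfile(fileext = ".txt")
  write_network_file(net, path)
  net2 <- parse_network_file(path)
  expect_equal(net2$pools, net$pools)
  expect_equal(net2$variants, net$variants)
  expect_equal(net2$biomass, net$biomass)
  expect_equal(lapply(net2$branches, `[[`, "text"),
               lapply(net$branches, `[[`, "text"))
  # writing the re-parsed network reproduces the file bit-exactly
  path2 <- tempfile(fileext = ".txt")
  write_network_file(net2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("packaged network has 19 reactions, 21 metabolites and balances", {
  net <- build_phgdh_network()
  expect_equal(length(net$reaction_ids), 19L)
  expect_equal(nrow(net$pools), 21L)
  expect_length(validate_atom_balance(net), 0L)
  # all twelve reported flux groups are present
  rep_tab <- reported_flux_table()
  expect_equal(nrow(rep_tab), 12L)
  expect_true(all(rep_tab$reaction %in% net$reaction_ids))
  expect_true(all(c("3PG->Ser", "G6P->R5P", "Pyr->AcCoA", "Pyr->OAA",
                    "IMP synthesis", "UMP salvage") %in% rep_tab$label))
})

test_that("balance rows plus branch constraints give a unique flux solution", {
  net <- build_phgdh_network()
  S <- stoichiometric_matrix(net)
  rids <- head(colnames(S), -1L)
  A <- S[, rids]
  for (b in net$branches) {
    prods <- emuflux:::producers_of(net, b$pool)
    row <- stats::setNames(numeric(length(rids)), rids)
    row[b$flux] <- 0.7
    row[setdiff(prods, b$flux)] <- -0.3
    A <- rbind(A, row)
  }
  expect_equal(qr(A)$rank, length(rids))
})
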