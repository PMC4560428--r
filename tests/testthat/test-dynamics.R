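test_that("state encoding is a bijection", {
  for (n in c(1, 3, 5)) {
    codes <- 0:(2^n - 1)
    expect_identical(vapply(codes, function(cc)
      encode_state(decode_state(cc, n)), numeric(1)), as.numeric(codes))
  }
  expect_error(encode_state(c(0, 2)), "0/1")
})

test_that("synchronous successor matches hand enumeration", {
  mn <- fixture_networks()$mutual_negation
  # A' = !B, B' = !A: (1,0) fixed; (1,1) -> (0,0)
  expect_identical(successor(mn, c(1L, 0L)), c(1L, 0L))
  expect_identical(successor(mn, c(1L, 1L)), c(0L, 0L))
  expect_identical(successor(mn, c(0L, 0L)), c(1L, 1L))

  idn <- fixture_networks()$identity1
  expect_equal(successor(idn, 1), 1)

  expect_error(successor(mn, c(1L, 0L, 1L)), "one bit per node")

  # clamped node ignores its rule
  mnc <- apply_mutation(mn, "A", 0)
  expect_identical(successor(mnc, c(1L, 1L)), c(0L, 0L))
  expect_identical(successor(mnc, c(0L, 0L)), c(0L, 1L))
})

test_that("attractor enumeration matches the brute-force oracle on fixtures", {
  nets <- fixture_networks()
  for (nm in names(nets)) {
    aset <- find_attractors(nets[[nm]])
    orc <- oracle_attractors(nets[[nm]])
    expect_identical(
      landscape_signature(attractor_cycles(aset),
                          vapply(aset$attractors, `[[`, numeric(1),
                                 "basin_size")),
      landscape_signature(orc$cycles, orc$basin),
      info = nm
    )
  }
  # hand-known structure: mutual negation
  aset <- find_attractors(nets$mutual_negation)
  periods <- sort(vapply(aset$attractors, `[[`, numeric(1), "period"))
  expect_identical(periods, c(1, 1, 2))
  # identity: 2^N fixed points
  expect_length(find_attractors(nets$identity1)$attractors, 2L)
  # constant: one fixed point, basin = whole state space
  ac <- find_attractors(nets$constant2)
  expect_length(ac$attractors, 1L)
  expect_equal(ac$attractors[[1]]$basin_size, 4)
})

test_that("oracle equivalence holds on random networks and basins conserve", {
  set.seed(42)
  cc <- load_cc_model()
  for (rep in 1:8) {
    rnet <- random_matched_network(
      boolean_network(c(A = "!C", B = "A & !B", C = "B | A"))
    )
    aset <- find_attractors(rnet)
    orc <- oracle_attractors(rnet)
    expect_identical(
      landscape_signature(attractor_cycles(aset),
                          vapply(aset$attractors, `[[`, numeric(1),
                                 "basin_size")),
      landscape_signature(orc$cycles, orc$basin)
    )
  }
  # conservation on 100 random 8-node networks: basins partition 2^N
  tmpl <- boolean_network(c(A = "B & !C", B = "!A", C = "A | D", D = "!C & A",
                            E = "A & !E", F = "E | !B", G = "F & C", H = "!G"))
  for (rep in 1:100) {
    rnet <- random_matched_network(tmpl)
    aset <- find_attractors(rnet)
    expect_identical(sum(vapply(aset$attractors, `[[`, numeric(1),
                                "basin_size")), 2^8)
  }
})

test_that("every state has exactly one successor (determinism)", {
  set.seed(7)
  tmpl <- boolean_network(c(A = "!B", B = "A & C", C = "!A | B"))
  for (rep in 1:20) {
    rnet <- random_matched_network(tmpl)
    tt <- transition_table(rnet)
    expect_length(tt, 2^3)
    expect_true(all(tt >= 0 & tt < 2^3))
  }
})

test_that("attractor identity is rotation invariant", {
  # period-6 cycle of the 3-node cyclic negation: engine canonicalizes
  cyc3 <- fixture_networks()$cyclic_negation3
  aset <- find_attractors(cyc3)
  for (a in aset$attractors) {
    expect_identical(a$cycle, canonicalize_cycle(a$cycle))
    # rotating and re-canonicalizing gives the same identity
    rot <- c(a$cycle[-1], a$cycle[1])
    expect_identical(canonicalize_cycle(rot), a$cycle)
  }
  # synchronous cyclic negation: two period-2 cycles and one period-6
  periods <- sort(vapply(aset$attractors, `[[`, numeric(1), "period"))
  orc <- oracle_attractors(cyc3)
  expect_identical(periods, sort(vapply(orc$cycles, length, numeric(1))))
})

test_that("sampled attractor search agrees with exhaustive on small nets", {
  mn <- fixture_networks()$mutual_negation
  aset <- find_attractors(mn, method = "sampled", n_samples = 200, seed = 3)
  keys <- vapply(attractor_cycles(aset), paste, character(1), collapse = ",")
  full <- vapply(attractor_cycles(find_attractors(mn)), paste, character(1),
                 collapse = ",")
  expect_true(all(keys %in% full))
  expect_identical(sum(vapply(aset$attractors, `[[`, numeric(1),
                              "basin_size")), 200)
})
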