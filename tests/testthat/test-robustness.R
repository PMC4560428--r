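test_that("function-flip enumeration covers sum(2^k) perturbations", {
  net <- boolean_network(c(A = "A", B = "A & !B"))
  flips <- enumerate_function_flips(net)
  expect_identical(nrow(flips), 2L + 4L)

  cc <- load_cc_model()
  flips_cc <- enumerate_function_flips(cc)
  expect_identical(nrow(flips_cc), as.integer(sum(2^in_degree_profile(cc))))

  # flipping twice restores the original network (involution)
  twice <- flip_table_bit(flip_table_bit(net, "B", 3), "B", 3)
  expect_identical(twice$rules[["B"]]$table, net$rules[["B"]]$table)
})

test_that("one-node identity network flips give constant rules, all altered", {
  idn <- fixture_networks()$identity1
  # flipped tables are [1,1] and [0,0]
  f1 <- flip_table_bit(idn, "A", 1)
  f2 <- flip_table_bit(idn, "A", 2)
  expect_identical(f1$rules[["A"]]$table, c(1L, 1L))
  expect_identical(f2$rules[["A"]]$table, c(0L, 0L))
  # identity has two fixed points; each flip collapses to one -> altered
  rs <- function_flip_robustness(idn, "exhaustive")
  expect_identical(unname(rs$counts["altered"]), 2L)
})

test_that("exhaustive classification matches a hand-built oracle on a toy", {
  mn <- fixture_networks()$mutual_negation
  rs <- function_flip_robustness(mn, "exhaustive")
  expect_identical(rs$n_perturbations, 4L)
  # oracle: reclassify each flip via the brute-force walker
  ref <- oracle_attractors(mn)
  ref_sig <- landscape_signature(ref$cycles, ref$basin)
  flips <- enumerate_function_flips(mn)
  want <- character(nrow(flips))
  key <- function(cyc) paste(cyc, collapse = ",")
  for (i in seq_len(nrow(flips))) {
    pert <- flip_table_bit(mn, flips$node[i], flips$row[i])
    orc <- oracle_attractors(pert)
    have <- vapply(orc$cycles, key, character(1))
    ref_keys <- vapply(ref$cycles, key, character(1))
    want[i] <- if (!all(ref_keys %in% have)) "altered"
      else if (length(have) == length(ref_keys)) "recovered_only"
      else "recovered_plus_new"
  }
  expect_identical(as.character(rs$outcomes$category), want)
  # fractions always partition
  expect_equal(sum(rs$fractions), 1)
})

test_that("sampled function flips converge to the exhaustive fractions", {
  net <- boolean_network(c(A = "!B", B = "A & C", C = "!A | B"))
  ex <- function_flip_robustness(net, "exhaustive")
  sa <- function_flip_robustness(net, "sampled", n = 2000, seed = 9)
  p <- ex$recovered_fraction
  phat <- sa$recovered_fraction
  # 99.9% binomial band
  expect_lt(abs(phat - p), 3.3 * sqrt(p * (1 - p) / 2000) + 1e-9)
  expect_error(function_flip_robustness(net, "sampled", n = 0), "positive")
})

test_that("transition flips behave sensibly on the mutual-negation toy", {
  mn <- fixture_networks()$mutual_negation
  ref <- find_attractors(mn)
  # flipping a transition ON the period-2 cycle never leaves the original
  # landscape intact as-is
  tr <- transition_flip_trial(mn, state = 0, node = "A", reference = ref)
  expect_true(as.character(tr$category) != "recovered_only" ||
              !identical(attractor_cycles(tr$perturbed_attractors),
                         attractor_cycles(ref)))
  # full enumeration: verify each (state, node) case against the oracle
  tt <- transition_table(mn)
  for (s in 0:3) for (i in 1:2) {
    tr <- transition_flip_trial(mn, s, i, reference = ref)
    tt2 <- tt
    tt2[s + 1] <- bitwXor(tt2[s + 1], bitwShiftL(1L, i - 1L))
    res <- cpp_attractors(tt2)
    expect_identical(
      length(tr$perturbed_attractors$attractors), length(res$cycles))
  }
})

test_that("transition-flip robustness is reproducible and summarized", {
  net <- boolean_network(c(A = "!B", B = "A & C", C = "!A | B"))
  r1 <- transition_flip_robustness(net, n_trials = 50, n_replicates = 4,
                                   seed = 123)
  r2 <- transition_flip_robustness(net, n_trials = 50, n_replicates = 4,
                                   seed = 123)
  expect_identical(r1$replicate_fractions, r2$replicate_fractions)
  expect_length(r1$replicate_fractions, 4L)
  expect_equal(r1$mean, mean(r1$replicate_fractions))
  # single trial gives a 0/1 fraction
  r3 <- transition_flip_robustness(net, n_trials = 1, seed = 5)
  expect_true(r3$replicate_fractions %in% c(0, 1))
  expect_error(transition_flip_robustness(net, n_trials = 0), ">= 1")
})
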