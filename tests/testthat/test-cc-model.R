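cc <- load_cc_model()

test_that("packaged cell-cycle model has the expected structure", {
  expect_identical(length(cc$nodes), 14L)
  expect_true(all(c("CYCD3;1", "CYCB1;1", "CYCA2;3", "CDKB1;1", "KRP1",
                    "RBR", "E2Fa", "E2Fb", "E2Fc", "E2Fe", "MYB77",
                    "MYB3R1/4", "SCF", "APC/C") %in% cc$nodes))
  # CDKA;1 is constitutive and therefore not a node
  expect_false("CDKA;1" %in% cc$nodes)
  # documented regulatory signs are visible in the interaction graph
  g <- interaction_graph(cc)
  edge_sign <- function(from, to)
    g$sign[g$from == from & g$to == to]
  expect_identical(edge_sign("RBR", "E2Fb"), "inhibiting")
  expect_identical(edge_sign("E2Fa", "E2Fb"), "activating")
  expect_identical(edge_sign("APC/C", "CYCB1;1"), "inhibiting")
  expect_identical(edge_sign("APC/C", "CYCA2;3"), "inhibiting")
  expect_identical(edge_sign("APC/C", "SCF"), "inhibiting")
  expect_identical(edge_sign("E2Fe", "APC/C"), "inhibiting")
  expect_identical(edge_sign("SCF", "CYCD3;1"), "inhibiting")
  expect_identical(edge_sign("MYB77", "MYB3R1/4"), "activating")
  # MYB3R1/4 self-input (autoregulation)
  expect_true(any(g$from == "MYB3R1/4" & g$to == "MYB3R1/4"))
})

test_that("wild type converges to a single period-11 attractor from all 16384 states", {
  aset <- find_attractors(cc)
  expect_identical(length(aset$attractors), 1L)
  att <- aset$attractors[[1]]
  expect_identical(att$period, 11L)
  expect_equal(att$basin_size, 2^14)
  expect_identical(att$basin_fraction, 1)
  # each cycle configuration maps to the next, closing after 11 steps
  for (j in seq_len(11)) {
    expect_identical(successor(cc, att$cycle[j]),
                     att$cycle[(j %% 11) + 1])
  }
})

test_that("phase annotation walks G1 through M-exit", {
  att <- find_attractors(cc)$attractors[[1]]
  ann <- suppressWarnings(annotate_phases(att, cc))
  expect_identical(ann$phase,
                   c("G1", "G1", "G1/S", "S", "S/G2", "S/G2", "G2", "G2/M",
                     "M", "M", "M-exit"))
  # anchored G1 configuration: mitotic cyclins absent and the
  # CYCD3;1-CDKA;1 complex absent or KRP1-inhibited
  first <- ann[1, ]
  expect_identical(first[["CYCB1;1"]], 0L)
  expect_identical(first[["CYCA2;3"]], 0L)
  expect_true(first[["CYCD3;1"]] == 0L || first$KRP1 == 1L)
  # the cycle is the same set of states in the same order, rotated
  expect_setequal(ann$state, att$cycle)
  # period mismatch errors
  toy <- find_attractors(fixture_networks()$mutual_negation)$attractors
  per2 <- toy[[which(vapply(toy, `[[`, numeric(1), "period") == 2)]]
  expect_error(annotate_phases(per2, fixture_networks()$mutual_negation),
               "period")
})

test_that("in-degree profile ties to the function-flip enumeration", {
  ks <- in_degree_profile(cc)
  expect_identical(nrow(enumerate_function_flips(cc)), as.integer(sum(2^ks)))
  g <- interaction_graph(cc)
  # interaction-graph in-degrees equal rule input counts
  for (nd in cc$nodes)
    expect_identical(sum(g$to == nd), unname(ks[nd]))
})
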