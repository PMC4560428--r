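cc <- load_cc_model()

test_that("clamping replaces the rule and leaves the original untouched", {
  mut <- apply_mutation(cc, "KRP1", 0)
  expect_identical(mut$clamps[["KRP1"]], 0L)
  expect_length(cc$clamps, 0L)
  expect_error(apply_mutation(cc, "NOSUCH", 0), "unknown node")
  expect_error(apply_mutation(cc, "KRP1", 2), "0 or 1")
  # clamped bit constant across every attractor configuration
  aset <- find_attractors(mut)
  for (a in aset$attractors) {
    conf <- attractor_configurations(a, mut)
    expect_true(all(conf["KRP1", ] == 0L))
  }
})

test_that("clamping a node whose value already matches leaves dynamics intact", {
  # KRP1 loss reproduces the wild-type cycle on the free nodes
  wt <- find_attractors(cc)$attractors[[1]]
  mut <- apply_mutation(cc, "KRP1", 0)
  aset <- find_attractors(mut)
  expect_identical(length(aset$attractors), 1L)
  expect_identical(aset$attractors[[1]]$period, 11L)
  expect_identical(aset$attractors[[1]]$basin_fraction, 1)
})

test_that("attractor classes follow the bit-pattern predicates", {
  wtref <- cc_reference_attractor()
  att <- find_attractors(cc)$attractors[[1]]
  expect_identical(classify_attractor(att, cc, wtref), "wild_type_like")
  # any period-1 attractor is an arrest
  rbr_gain <- apply_mutation(cc, "RBR", 1)
  fps <- find_attractors(rbr_gain)$attractors
  expect_true(all(vapply(fps, classify_attractor, character(1),
                         net = rbr_gain, reference = wtref)
                  == "fixed_point_arrest"))
  # APC/C gain: period-7 cycle without the mitosis-onset pattern
  apc_gain <- apply_mutation(cc, "APC/C", 1)
  endo <- find_attractors(apc_gain)$attractors[[1]]
  expect_identical(classify_attractor(endo, apc_gain, wtref),
                   "endocycle_like")
  conf <- attractor_configurations(endo, apc_gain)
  onset <- conf["CYCB1;1", ] == 1 & conf["KRP1", ] == 0 & conf["APC/C", ] == 0
  expect_false(any(onset))
  sphase <- conf["E2Fa", ] == 1 & conf["RBR", ] == 0
  expect_true(any(sphase))
})

test_that("mutant scan covers all 2N clamps with partitioning basins", {
  scan <- mutant_scan(cc)
  expect_identical(nrow(scan), 28L)
  row_of <- function(node, value)
    scan[scan$node == node & scan$value == value, ]
  # KRP1 loss leaves the wild-type cycle intact
  expect_identical(row_of("KRP1", 0)$periods, "11")
  expect_identical(row_of("KRP1", 0)$basin_pct, "100.00")
  # APC/C gain drives the endoreduplication-like short cycle
  expect_identical(row_of("APC/C", 1)$periods, "7")
  expect_true(grepl("endocycle", row_of("APC/C", 1)$classes))
  # basin fractions partition for every mutant
  for (i in seq_len(nrow(scan))) {
    b <- as.numeric(strsplit(scan$basin_pct[i], ";")[[1]])
    expect_equal(sum(b), 100, tolerance = 0.02)
  }
  # expectations table joins: every mutant has a grade and a match flag
  expect_false(any(is.na(scan$grade)))
  expect_type(scan$match, "logical")
  expect_true(all(scan$match[scan$node == "KRP1" & scan$value == 0]))
})

test_that("E2Fa gain-of-function basin split sums to 100", {
  aset <- find_attractors(apply_mutation(cc, "E2Fa", 1))
  fr <- vapply(aset$attractors, `[[`, numeric(1), "basin_fraction")
  expect_equal(sum(fr), 1)
})
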