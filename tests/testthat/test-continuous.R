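test_that("fuzzified rules agree with the Boolean table on corners", {
  cc <- load_cc_model()
  for (r in cc$rules) {
    k <- length(r$inputs)
    for (sem in c("minmax", "probabilistic")) {
      f <- fuzzify(r, sem)
      for (row in 0:(2^k - 1)) {
        x <- setNames(as.numeric(bitwAnd(bitwShiftR(row, seq_len(k) - 1L),
                                         1L)), r$inputs)
        expect_equal(f(x), r$table[row + 1], info = paste(r$target, sem))
      }
    }
  }
})

test_that("fuzzy semantics evaluate interior points as min/max and product", {
  r <- boolean_rule("E2Fb", "E2Fa & !RBR")
  x <- c(E2Fa = 0.8, RBR = 0.3)
  expect_equal(fuzzify(r, "minmax")(x), min(0.8, 0.7))
  expect_equal(fuzzify(r, "probabilistic")(x), 0.8 * 0.7)
  # corner agreement at (1, 0)
  x1 <- c(E2Fa = 1, RBR = 0)
  expect_equal(fuzzify(r, "minmax")(x1), 1)
  expect_equal(fuzzify(r, "probabilistic")(x1), 1)
})

test_that("production term matches its closed forms and is monotone", {
  for (h in c(1, 10, 50)) {
    a <- exp(0.5 * h)
    expect_equal(production_rate(0, h), 1 / (1 + a), tolerance = 1e-10)
    expect_equal(production_rate(1, h), (1 + a + a^2) / (a + a^2),
                 tolerance = 1e-10)
    expect_equal(production_rate(0.5, h), (1 + a) / (2 * a),
                 tolerance = 1e-10)
  }
  # closed forms vs direct (raw) evaluation of the defining expression
  for (h in c(1, 10, 50)) {
    w <- seq(0, 1, by = 0.05)
    raw <- (-exp(0.5 * h) + exp(-h * w)) /
      ((1 - exp(0.5 * h)) * (1 + exp(-h * (w - 0.5))))
    expect_equal(production_rate(w, h), raw, tolerance = 1e-10)
  }
  # increasing in omega, overflow-safe at large h (numerically the
  # curve saturates to a step for very large h, so strictness is only
  # checked where the values are away from the 0/1 plateaus)
  for (h in c(1, 10, 50, 100, 1000)) {
    p <- production_rate(seq(0, 1, by = 0.01), h)
    expect_true(all(is.finite(p)))
    expect_true(all(diff(p) >= 0))
    expect_gt(p[101], p[1])
  }
  for (h in c(1, 10, 50)) {
    p <- production_rate(seq(0, 1, by = 0.01), h)
    expect_true(all(diff(p) > 0))
  }
  expect_error(production_rate(0.5, 0), "h must be")
})

test_that("single-node constant model converges to its fixed point", {
  net <- boolean_network(c(A = "1"))
  model <- continuous_model(net, h = 50, gamma = 1)
  traj <- integrate_model(model, x0 = 0.1, t_end = 30)
  xstar <- production_rate(1, 50)
  expect_equal(unname(traj$x[nrow(traj$x), "A"]), xstar, tolerance = 1e-4)
  v <- detect_limit_cycle(traj)
  expect_false(v$is_cycle)
})

test_that("limit-cycle detector separates sinusoids from decaying signals", {
  tt <- seq(0, 100, by = 0.1)
  sin_traj <- structure(list(
    time = tt,
    x = cbind(A = 0.5 + 0.3 * sin(2 * pi * tt / 12),
              B = rep(0.2, length(tt)))
  ), class = "cc_trajectory")
  v <- detect_limit_cycle(sin_traj)
  expect_true(v$is_cycle)
  expect_equal(v$period, 12, tolerance = 0.05)

  dec_traj <- structure(list(
    time = tt,
    x = cbind(A = 0.5 + exp(-tt / 10) * sin(2 * pi * tt / 12))
  ), class = "cc_trajectory")
  expect_false(detect_limit_cycle(dec_traj)$is_cycle)

  expect_error(detect_limit_cycle(sin_traj, settle_fraction = 1),
               "settle_fraction")
})

test_that("cell-cycle continuous model sustains anti-phase cyclin oscillations", {
  cc <- load_cc_model()
  model <- continuous_model(cc, h = 50, gamma = 1)
  set.seed(11)
  traj <- integrate_model(model, runif(14), t_end = 150, dt = 0.1)
  v <- detect_limit_cycle(traj)
  expect_true(v$is_cycle)
  # CYCD3;1 and CYCB1;1 both oscillate with substantial amplitude
  expect_gt(v$amplitude[["CYCD3;1"]], 0.2)
  expect_gt(v$amplitude[["CYCB1;1"]], 0.2)
  # anti-phase: at CYCB1;1 peaks, CYCD3;1 is low (below its midrange)
  keep <- traj$time >= 75
  b <- traj$x[keep, "CYCB1;1"]; d <- traj$x[keep, "CYCD3;1"]
  pk <- which(b[2:(length(b) - 1)] > b[1:(length(b) - 2)] &
              b[2:(length(b) - 1)] >= b[3:length(b)]) + 1L
  pk <- pk[b[pk] > min(b) + 0.5 * diff(range(b))]
  expect_true(length(pk) >= 2)
  expect_true(all(d[pk] < mean(range(d))))
  # activities stay within the unit band throughout
  expect_true(all(traj$x > -1e-6 & traj$x < 1 + 1e-6))
  # both fuzzy semantics give a limit-cycle verdict
  model_p <- continuous_model(cc, h = 50, gamma = 1,
                              semantics = "probabilistic")
  traj_p <- integrate_model(model_p, traj$x0, t_end = 150, dt = 0.1)
  expect_true(detect_limit_cycle(traj_p)$is_cycle)
})

test_that("parameter sweep reports per-cell verdicts including degenerate h", {
  net <- boolean_network(c(A = "!B", B = "A"))
  sw <- parameter_sweep(net, h_values = c(0.01, 50), gamma_values = 1,
                        n_initial = 2, seed = 5, t_end = 60)
  expect_identical(nrow(sw$table), 2L)
  expect_true(all(sw$table$verdict %in% c("cycle", "mixed", "none")))
  expect_true(sw$fraction_cycle >= 0 && sw$fraction_cycle <= 1)
})
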