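# Continuous (fuzzy-logic ODE) approximation of a Boolean network:
# each node x_i follows dx_i/dt = p(omega_i(x), h) - gamma_i * x_i,
# where omega_i is a continuous extension of the node's logical rule
# and p is a sigmoid production term with steepness h.

#' Continuous (fuzzy) form of a Boolean rule
#'
#' Extends the rule to the unit hypercube. Under `"minmax"` semantics
#' AND is `min`, OR is `max`, NOT is `1 - x`; under `"probabilistic"`
#' semantics AND is the product, OR is `a + b - ab`, NOT is `1 - x`.
#' Both agree with the Boolean truth table on binary corner inputs.
#'
#' @param rule a [boolean_rule()].
#' @param semantics `"minmax"` or `"probabilistic"`.
#' @return function taking a named numeric vector (node activities in
#'   `[0,1]`) and returning omega in `[0,1]`.
#' @export
fuzzify <- function(rule, semantics = c("minmax", "probabilistic")) {
  semantics <- match.arg(semantics)
  ast <- rule$ast
  if (is.null(ast))
    stop("rule has no expression to fuzzify", call. = FALSE)
  eval_fuzzy <- function(a, x) {
    switch(a$op,
      var = x[[a$name]],
      const = as.numeric(a$value),
      not = 1 - eval_fuzzy(a$args[[1]], x),
      and = if (semantics == "minmax")
              pmin(eval_fuzzy(a$args[[1]], x), eval_fuzzy(a$args[[2]], x))
            else eval_fuzzy(a$args[[1]], x) * eval_fuzzy(a$args[[2]], x),
      or = if (semantics == "minmax")
             pmax(eval_fuzzy(a$args[[1]], x), eval_fuzzy(a$args[[2]], x))
           else {
             p <- eval_fuzzy(a$args[[1]], x); q <- eval_fuzzy(a$args[[2]], x)
             p + q - p * q
           }
    )
  }
  function(x) eval_fuzzy(ast, x)
}

#' Sigmoid production term
#'
#' Evaluates the production part of the node ODE,
#' \deqn{p(\omega, h) = \frac{-e^{0.5h} + e^{-h\omega}}
#'       {(1 - e^{0.5h})(1 + e^{-h(\omega - 0.5)})},}
#' strictly increasing in omega with p(0) = 1/(1+e^{0.5h}) and
#' p(1) = (1+a+a^2)/(a+a^2) for a = e^{0.5h}. When h tends to 0 the
#' curve flattens towards a straight line; near h = 100 it approximates
#' a step at omega = 0.5. Evaluated in an algebraically rearranged,
#' overflow-free form valid for large h.
#'
#' @param omega rule activity in `[0,1]` (vectorized).
#' @param h sigmoid steepness, > 0.
#' @return production rate.
#' @export
production_rate <- function(omega, h) {
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  # divide numerator and denominator by e^{0.5h}:
  #   p = (e^{-h(omega+0.5)} - 1) / ((e^{-0.5h} - 1) (1 + e^{-h(omega-0.5)}))
  # and for omega < 0.5 multiply through by e^{h(omega-0.5)} so that no
  # exponential argument is positive.
  num <- expm1(-h * (omega + 0.5))
  den1 <- expm1(-0.5 * h)
  z <- -h * (omega - 0.5)
  small <- z <= 0
  out <- numeric(length(omega))
  out[small] <- num[small] / (den1 * (1 + exp(z[small])))
  if (any(!small)) {
    # p = e^{-z} num / (den1 (e^{-z} + 1)) with e^{-z} <= 1
    enz <- exp(-z[!small])
    out[!small] <- enz * num[!small] / (den1 * (enz + 1))
  }
  out
}

# Compile an AST to the (op, arg) stack program cpp_eval_fuzzy expects.
compile_fuzzy_program <- function(ast, nodes) {
  rows <- list()
  emit <- function(op, arg = 0L) rows[[length(rows) + 1L]] <<- c(op, arg)
  walk <- function(a) {
    switch(a$op,
      var = emit(0L, match(a$name, nodes) - 1L),
      const = emit(1L, a$value),
      not = { walk(a$args[[1]]); emit(2L) },
      and = { walk(a$args[[1]]); walk(a$args[[2]]); emit(3L) },
      or = { walk(a$args[[1]]); walk(a$args[[2]]); emit(4L) }
    )
  }
  walk(ast)
  do.call(rbind, rows)
}

#' Build the continuous model of a Boolean network
#'
#' @param net a [boolean_network()]; clamped nodes are held constant at
#'   their clamp value during integration.
#' @param h sigmoid steepness (default 50: close to the step-function
#'   regime while numerically benign).
#' @param gamma per-node decay rates (recycled scalar or named vector),
#'   default 1.
#' @param semantics fuzzy-logic semantics, see [fuzzify()].
#' @return object of class `continuous_model`.
#' @export
continuous_model <- function(net, h = 50, gamma = 1,
                             semantics = c("minmax", "probabilistic")) {
  semantics <- match.arg(semantics)
  n <- n_nodes(net)
  if (length(gamma) == 1L) gamma <- rep(gamma, n)
  if (!is.null(names(gamma))) gamma <- gamma[net$nodes]
  if (length(gamma) != n || any(!is.finite(gamma)) || any(gamma <= 0))
    stop("gamma must be positive, one value per node", call. = FALSE)
  omega <- lapply(net$rules, fuzzify, semantics = semantics)
  programs <- lapply(net$rules, function(r) {
    if (is.null(r$ast))
      stop("continuous model requires rules with expressions", call. = FALSE)
    compile_fuzzy_program(r$ast, net$nodes)
  })
  structure(
    list(network = net, omega = omega, programs = unname(programs),
         h = h, gamma = setNames(as.numeric(gamma), net$nodes),
         semantics = semantics),
    class = "continuous_model"
  )
}

#' Integrate the continuous model
#'
#' Solves dx_i/dt = p(omega_i(x), h) - gamma_i x_i with `deSolve::ode`
#' (lsoda). Clamped nodes keep their clamp value with zero derivative.
#'
#' @param model a [continuous_model()].
#' @param x0 initial activities in `[0,1]` (named or in node order).
#' @param t_end end time (time unit: 1/gamma for gamma = 1).
#' @param dt output grid spacing.
#' @param rtol,atol solver tolerances.
#' @return object of class `cc_trajectory`: a list with `time`, `x`
#'   (matrix time x node) and solver metadata.
#' @export
integrate_model <- function(model, x0, t_end = 100, dt = 0.1,
                            rtol = 1e-8, atol = 1e-8) {
  net <- model$network
  n <- n_nodes(net)
  if (length(x0) != n) stop("x0 must have one entry per node", call. = FALSE)
  if (!is.null(names(x0))) x0 <- x0[net$nodes]
  x0 <- as.numeric(x0)
  if (any(x0 < 0 | x0 > 1)) stop("x0 must lie in [0,1]", call. = FALSE)
  clamped <- match(names(net$clamps), net$nodes)
  if (length(clamped)) x0[clamped] <- as.numeric(net$clamps)
  h <- model$h
  gamma <- model$gamma
  programs <- model$programs
  sem <- if (model$semantics == "minmax") 0L else 1L
  deriv <- function(t, x, parms) {
    w <- cpp_eval_fuzzy(programs, pmin(pmax(x, 0), 1), sem)
    dx <- production_rate(w, h) - gamma * x
    if (length(clamped)) dx[clamped] <- 0
    list(dx)
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = x0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed (t_end = ", t_end, ", rtol = ", rtol,
         ", atol = ", atol, ")", call. = FALSE)
  x <- sol[, -1, drop = FALSE]
  colnames(x) <- net$nodes
  structure(
    list(time = sol[, 1], x = x, x0 = x0,
         settings = list(h = h, gamma = gamma, semantics = model$semantics,
                         rtol = rtol, atol = atol)),
    class = "cc_trajectory"
  )
}

# indices of strict local maxima above a prominence floor
find_peaks <- function(y, min_height = NULL) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!is.null(min_height)) idx <- idx[y[idx] >= min_height]
  idx
}

#' Detect a sustained limit cycle in a trajectory
#'
#' After discarding a settling prefix, the trajectory is declared a limit
#' cycle if at least one node shows three or more successive oscillation
#' peaks whose heights and inter-peak intervals are constant within
#' `tolerance` (relative), and no oscillating node's amplitude decays
#' towards zero. The period estimate is the mean inter-peak interval of
#' the best node.
#'
#' @param traj a `cc_trajectory` from [integrate_model()].
#' @param settle_fraction fraction of the trajectory discarded as
#'   transient (default 0.5).
#' @param tolerance relative tolerance on peak-height and inter-peak
#'   interval constancy (default 0.05).
#' @param min_amplitude minimum peak-to-trough amplitude for a node to
#'   count as oscillating (default 0.05, activities live in [0,1]).
#' @return list with `is_cycle`, `period`, `amplitude` (per node) and
#'   `n_peaks` diagnostics.
#' @export
detect_limit_cycle <- function(traj, settle_fraction = 0.5,
                               tolerance = 0.05, min_amplitude = 0.05) {
  if (settle_fraction < 0 || settle_fraction >= 1)
    stop("settle_fraction must be in [0, 1)", call. = FALSE)
  keep <- traj$time >= settle_fraction * max(traj$time)
  if (sum(keep) < 10)
    stop("trajectory too short after discarding the settling prefix",
         call. = FALSE)
  tt <- traj$time[keep]
  xx <- traj$x[keep, , drop = FALSE]
  best <- NULL
  amplitude <- apply(xx, 2, function(y) diff(range(y)))
  n_peaks <- integer(ncol(xx))
  for (j in seq_len(ncol(xx))) {
    y <- xx[, j]
    if (amplitude[j] < min_amplitude) next
    pk <- find_peaks(y, min_height = min(y) + 0.5 * amplitude[j])
    n_peaks[j] <- length(pk)
    if (length(pk) < 3) next
    heights <- y[pk]
    intervals <- diff(tt[pk])
    h_ok <- diff(range(heights)) <= tolerance * max(abs(heights))
    i_ok <- diff(range(intervals)) <= tolerance * max(intervals)
    decaying <- all(diff(heights) < 0) &&
      (heights[length(heights)] < (1 - tolerance) * heights[1])
    if (h_ok && i_ok && !decaying) {
      cand <- list(node = colnames(xx)[j], period = mean(intervals))
      if (is.null(best)) best <- cand
    }
  }
  list(
    is_cycle = !is.null(best),
    period = if (!is.null(best)) best$period else NA_real_,
    node = if (!is.null(best)) best$node else NA_character_,
    amplitude = amplitude,
    n_peaks = setNames(n_peaks, colnames(xx))
  )
}

#' Sweep steepness and decay parameters for limit-cycle persistence
#'
#' For every (h, gamma) grid cell, integrates the continuous model from
#' `n_initial` random initial conditions and applies
#' [detect_limit_cycle()]; a cell's verdict is `"cycle"` if every start
#' reaches a sustained oscillation, `"none"` if none does, `"mixed"`
#' otherwise.
#'
#' @param net a [boolean_network()].
#' @param h_values steepness grid (default `c(1, 5, 10, 20, 50, 100)`).
#' @param gamma_values global decay-rate grid (default `c(0.5, 1, 2)`).
#' @param n_initial random initial conditions per cell.
#' @param seed RNG seed for the initial conditions.
#' @param t_end,dt integration window per run.
#' @param semantics fuzzy semantics.
#' @return list with `table` (data frame h, gamma, n_cycle, n_total,
#'   verdict) and `fraction_cycle` (fraction of cells whose verdict is
#'   `"cycle"`).
#' @export
parameter_sweep <- function(net, h_values = c(1, 5, 10, 20, 50, 100),
                            gamma_values = c(0.5, 1, 2),
                            n_initial = 5L, seed = 1L,
                            t_end = 120, dt = 0.1,
                            semantics = "minmax") {
  if (!length(h_values) || !length(gamma_values))
    stop("h_values and gamma_values must be non-empty", call. = FALSE)
  set.seed(seed)
  n <- n_nodes(net)
  starts <- matrix(runif(n_initial * n), nrow = n_initial)
  rows <- list()
  for (h in h_values) for (g in gamma_values) {
    model <- continuous_model(net, h = h, gamma = g, semantics = semantics)
    ncyc <- 0L
    for (r in seq_len(n_initial)) {
      traj <- integrate_model(model, starts[r, ], t_end = t_end, dt = dt)
      v <- detect_limit_cycle(traj)
      if (v$is_cycle) ncyc <- ncyc + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      h = h, gamma = g, n_cycle = ncyc, n_total = n_initial,
      verdict = if (ncyc == n_initial) "cycle"
                else if (ncyc == 0L) "none" else "mixed",
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       fraction_cycle = mean(tab$verdict == "cycle"))
}
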