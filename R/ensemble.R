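# Structure-matched random Boolean networks and ensemble robustness:
# the null model against which the cell-cycle network's perturbation
# tolerance is judged, plus small toy networks with hand-checked
# dynamics used throughout the test-suite.

#' Generate a random network matched to a template's in-degree profile
#'
#' Node i keeps its in-degree k_i from the template; its inputs are drawn
#' uniformly without replacement from all nodes (self-inputs allowed) and
#' its truth table uniformly from all 2^(2^k_i) tables (each output bit
#' is an independent fair coin). With `wiring = "matched"` the template's
#' wiring is kept and only the truth tables are randomized.
#'
#' @param template a [boolean_network()].
#' @param wiring `"random"` (default) or `"matched"`.
#' @return a [boolean_network()]-compatible object; rules carry truth
#'   tables without closed-form expressions.
#' @note Uses R's RNG stream; call `set.seed()` (or let the callers that
#'   take a `seed` argument do it) for reproducibility.
#' @export
random_matched_network <- function(template, wiring = c("random", "matched")) {
  wiring <- match.arg(wiring)
  n <- n_nodes(template)
  nodes <- template$nodes
  rules <- lapply(seq_len(n), function(i) {
    k <- length(template$rules[[i]]$inputs)
    inputs <- if (wiring == "random") {
      if (k > 0) nodes[sample.int(n, k)] else character(0)
    } else {
      template$rules[[i]]$inputs
    }
    tab <- as.integer(runif(2^k) < 0.5)
    structure(
      list(target = nodes[i], expression = NA_character_, ast = NULL,
           inputs = inputs, table = tab),
      class = "boolean_rule"
    )
  })
  names(rules) <- nodes
  structure(list(nodes = nodes, rules = rules, clamps = integer(0)),
            class = "boolean_network")
}

#' Ensemble robustness of structure-matched random networks
#'
#' Generates `n_networks` random networks with the template's in-degree
#' profile; for each one computes its own reference attractor set,
#' applies `n_perturb` random perturbations of the chosen kind, and
#' records the fraction of perturbations after which all of that
#' network's own attractors are recovered. Function-flip perturbations
#' pick one node uniformly, then flip one bit of its truth table (the
#' convention of the published protocol; `flip_weighting = "bit"` draws
#' uniformly over all bits instead); transition flips perturb one
#' successor bit in each of 1% of the states per copy (see
#' [transition_flip_robustness()]).
#'
#' @param template a [boolean_network()] (N <= 24).
#' @param n_networks ensemble size.
#' @param n_perturb perturbations per network.
#' @param kind `"functions"` or `"transitions"`.
#' @param seed RNG seed; the summary is a pure function of
#'   (template, arguments, seed).
#' @param wiring passed to [random_matched_network()].
#' @param flip_weighting sampling distribution for function flips.
#' @param include_template also compute the template network's own
#'   fraction under the same protocol (reported as `template_fraction`).
#' @return an `ensemble_summary`: per-network fractions, their median /
#'   mean / sd / 95% quantile, and the template's fraction.
#' @export
ensemble_robustness <- function(template, n_networks = 100L,
                                n_perturb = 100L,
                                kind = c("functions", "transitions"),
                                seed = 1L, wiring = c("random", "matched"),
                                include_template = TRUE,
                                flip_weighting = c("node", "bit")) {
  kind <- match.arg(kind)
  wiring <- match.arg(wiring)
  flip_weighting <- match.arg(flip_weighting)
  if (n_networks < 1) stop("n_networks must be >= 1", call. = FALSE)
  if (n_perturb < 1) stop("n_perturb must be >= 1", call. = FALSE)
  set.seed(seed)
  fractions <- vapply(seq_len(n_networks), function(i) {
    rnet <- random_matched_network(template, wiring)
    recovered_fraction_random(rnet, n_perturb, kind, flip_weighting)
  }, numeric(1))
  template_fraction <- if (include_template)
    recovered_fraction_random(template, n_perturb, kind, flip_weighting)
    else NA_real_
  structure(
    list(kind = kind, n_networks = n_networks, n_perturb = n_perturb,
         fractions = fractions,
         median = median(fractions), mean = mean(fractions),
         sd = sd(fractions),
         q95 = unname(quantile(fractions, 0.95)),
         template_fraction = template_fraction, seed = seed),
    class = "ensemble_summary"
  )
}

# fraction of n_perturb seeded random perturbations recovering all of
# net's own attractors (uses the current RNG stream)
recovered_fraction_random <- function(net, n_perturb, kind,
                                      flip_weighting = "node") {
  ref <- find_attractors(net)
  refCycles <- attractor_cycles(ref)
  n <- n_nodes(net)
  if (kind == "transitions") {
    tt <- transition_table(net)
    n_flips <- max(1L, as.integer(ceiling(0.01 * 2^n)))
    states <- integer(0)
    for (t in seq_len(n_perturb))
      states <- c(states, sample.int(2L^n, n_flips) - 1L)
    nodes <- sample.int(n, n_perturb * n_flips, replace = TRUE) - 1L
    cats <- cpp_transition_multiflip_trials(tt, n, states, nodes,
                                            n_flips, refCycles)
    return(mean(cats != 2L))
  }
  # functions: one flipped truth-table bit per perturbation
  sizes <- vapply(net$rules, function(r) length(r$table), integer(1))
  ends <- cumsum(sizes)
  ef <- engine_form(net)
  cats <- integer(n_perturb)
  for (t in seq_len(n_perturb)) {
    if (flip_weighting == "node") {
      i <- sample.int(n, 1L)
      row <- sample.int(sizes[i], 1L)
    } else {
      pick <- sample.int(ends[n], 1L)
      i <- which(pick <= ends)[1]
      row <- pick - c(0L, ends)[i]
    }
    ef2 <- ef
    ef2$tables[[i]][row] <- 1L - ef2$tables[[i]][row]
    res <- cpp_attractors(cpp_transition_table(ef2$inputs, ef2$tables, n))
    key <- function(cy) paste(cy, collapse = ",")
    have <- vapply(res$cycles, key, character(1))
    want <- vapply(refCycles, key, character(1))
    cats[t] <- if (!all(want %in% have)) 2L
               else if (length(have) == length(want)) 0L else 1L
  }
  mean(cats != 2L)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("Ensemble robustness (%s): %d networks x %d perturbations\n",
              x$kind, x$n_networks, x$n_perturb))
  cat(sprintf("  median %.2f%%  mean %.2f%% +/- %.2f  q95 %.2f%%\n",
              100 * x$median, 100 * x$mean, 100 * x$sd, 100 * x$q95))
  if (!is.na(x$template_fraction))
    cat(sprintf("  template network: %.2f%%\n", 100 * x$template_fraction))
  invisible(x)
}

#' Toy fixture networks with hand-verified dynamics
#'
#' Small networks whose synchronous attractor structure is known by
#' exhaustive hand enumeration: `identity1` (one self-copying node, two
#' fixed points), `mutual_negation` (fixed points 01 and 10 plus the
#' 00<->11 period-2 cycle), `cyclic_negation3` (A=!C, B=!A, C=!B: two
#' period-2 cycles and one period-6 cycle under synchronous update) and
#' `constant2` (both nodes constant, a single fixed point whose basin is
#' the whole state space).
#'
#' @return named list of [boolean_network()] objects.
#' @export
fixture_networks <- function() {
  list(
    identity1 = boolean_network(c(A = "A")),
    mutual_negation = boolean_network(c(A = "!B", B = "!A")),
    cyclic_negation3 = boolean_network(c(A = "!C", B = "!A", C = "!B")),
    constant2 = boolean_network(c(A = "1", B = "0"))
  )
}
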