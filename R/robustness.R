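# Perturbation robustness of the attractor landscape: systematic or
# sampled truth-table bit flips, and stochastic state-transition bit
# flips, each classified three ways against the unperturbed attractors.

outcome_levels <- c("recovered_only", "recovered_plus_new", "altered")

as_outcome <- function(code) factor(outcome_levels[code + 1L],
                                    levels = outcome_levels)

#' Enumerate all single truth-table bit flips of a network
#'
#' Each perturbation flips exactly one output bit of one node's rule
#' table, so a network with in-degrees k_i has `sum(2^k_i)` distinct
#' perturbations. The original network is never modified.
#'
#' @param net a [boolean_network()].
#' @return data frame with one row per perturbation: `node`, `row`
#'   (1-based truth-table row). Use [flip_table_bit()] to materialize a
#'   perturbed network.
#' @export
enumerate_function_flips <- function(net) {
  do.call(rbind, lapply(net$rules, function(r)
    data.frame(node = r$target, row = seq_along(r$table),
               stringsAsFactors = FALSE)))
}

#' Flip one truth-table output bit
#' @param net a [boolean_network()].
#' @param node node whose rule is perturbed.
#' @param row 1-based row of its truth table.
#' @return a new network with that single bit flipped (the expression is
#'   retained for reference but the table is authoritative).
#' @export
flip_table_bit <- function(net, node, row) {
  i <- match(node, net$nodes)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  r <- net$rules[[i]]
  if (row < 1 || row > length(r$table))
    stop("row out of range for rule of ", node, call. = FALSE)
  net$rules[[i]]$table[row] <- 1L - net$rules[[i]]$table[row]
  net$rules[[i]]$expression <- paste0("<", r$expression, " with bit ",
                                      row, " flipped>")
  net
}

# classification counts -> summary object
robustness_summary <- function(categories, descriptors, kind, seed = NULL,
                               replicates = NULL) {
  tab <- table(factor(outcome_levels[categories + 1L],
                      levels = outcome_levels))
  out <- list(
    kind = kind,
    n_perturbations = length(categories),
    counts = as.integer(tab),
    fractions = as.numeric(tab) / length(categories),
    recovered_fraction = sum(categories != 2L) / length(categories),
    outcomes = data.frame(descriptors,
                          category = as_outcome(categories)),
    seed = seed
  )
  names(out$counts) <- names(out$fractions) <- outcome_levels
  if (!is.null(replicates)) {
    out$replicate_fractions <- replicates
    out$mean <- mean(replicates)
    out$sd <- sd(replicates)
  }
  structure(out, class = "robustness_summary")
}

#' @export
print.robustness_summary <- function(x, ...) {
  cat("Robustness (", x$kind, "): ", x$n_perturbations,
      " perturbations\n", sep = "")
  for (lv in outcome_levels)
    cat(sprintf("  %-20s %6d  (%.2f%%)\n", lv, x$counts[lv],
                100 * x$fractions[lv]))
  if (!is.null(x$mean))
    cat(sprintf("  recovered per replicate: mean %.2f%%, sd %.2f%%\n",
                100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Truth-table bit-flip robustness
#'
#' Every single-bit rule perturbation (or a seeded uniform sample of
#' them) is applied in turn; the perturbed network's attractor set is
#' recomputed exhaustively and classified against the reference
#' attractors as `recovered_only` (the original attractor cycles are
#' exactly the perturbed network's attractors), `recovered_plus_new`
#' (all original cycles persist and new attractors appeared), or
#' `altered` (an original cycle was lost).
#'
#' @param net a [boolean_network()] (N <= 24).
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n number of sampled flips (sampled mode).
#' @param seed RNG seed (sampled mode).
#' @param weighting sampling distribution over flips: `"bit"` draws
#'   uniformly over individual table bits (nodes weighted by 2^k_i, the
#'   same population the exhaustive scan enumerates); `"node"` first
#'   draws a node uniformly, then one of its bits.
#' @param reference optionally a precomputed [find_attractors()] result.
#' @return a `robustness_summary` with per-perturbation outcomes,
#'   category counts and fractions.
#' @export
function_flip_robustness <- function(net,
                                     mode = c("exhaustive", "sampled"),
                                     n = 100L, seed = 1L,
                                     weighting = c("bit", "node"),
                                     reference = NULL) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  ref <- reference %||% find_attractors(net)
  refCycles <- attractor_cycles(ref)
  ef <- engine_form(net)
  if (mode == "exhaustive") {
    m <- cpp_function_flip_scan(ef$inputs, ef$tables, n_nodes(net),
                                refCycles)
    return(robustness_summary(
      m[, 3],
      data.frame(node = net$nodes[m[, 1] + 1L], row = m[, 2] + 1L),
      kind = "function flips (exhaustive)"
    ))
  }
  if (n <= 0) stop("n must be positive in sampled mode", call. = FALSE)
  set.seed(seed)
  flips <- enumerate_function_flips(net)
  idx <- if (weighting == "bit") {
    sample.int(nrow(flips), n, replace = TRUE)
  } else {
    nodes <- sample(net$nodes, n, replace = TRUE)
    vapply(nodes, function(nd) {
      rows <- which(flips$node == nd)
      rows[sample.int(length(rows), 1L)]
    }, integer(1))
  }
  cats <- integer(n)
  for (t in seq_len(n)) {
    pert <- flip_table_bit(net, flips$node[idx[t]], flips$row[idx[t]])
    cats[t] <- classify_against(find_attractors(pert), refCycles)
  }
  robustness_summary(cats, flips[idx, , drop = FALSE],
                     kind = sprintf("function flips (sampled, n=%d)", n),
                     seed = seed)
}

# 0/1/2 classification of an attractor_set against reference cycles
classify_against <- function(attractor_set, refCycles) {
  cycles <- attractor_cycles(attractor_set)
  key <- function(cy) paste(cy, collapse = ",")
  have <- vapply(cycles, key, character(1))
  want <- vapply(refCycles, key, character(1))
  if (!all(want %in% have)) return(2L)
  if (length(have) == length(want)) 0L else 1L
}

#' Single state-transition bit-flip trial
#'
#' One entry of the global transition table is perturbed: the successor
#' of state `state` has node `node`'s bit flipped (all other transitions
#' unchanged), the modified transition system's attractors are
#' recomputed, and the outcome is classified against the reference.
#'
#' @param net a [boolean_network()].
#' @param state state code in `[0, 2^N)` whose successor is perturbed.
#' @param node node name or index whose successor bit flips.
#' @param reference optional precomputed [find_attractors()] result.
#' @return list with `category` (factor) and `perturbed_attractors`.
#' @export
transition_flip_trial <- function(net, state, node, reference = NULL) {
  ref <- reference %||% find_attractors(net)
  tt <- transition_table(net)
  i <- if (is.character(node)) match(node, net$nodes) else as.integer(node)
  if (is.na(i) || i < 1 || i > n_nodes(net))
    stop("unknown node: ", node, call. = FALSE)
  tt[state + 1L] <- bitwXor(tt[state + 1L], bitwShiftL(1L, i - 1L))
  res <- cpp_attractors(tt)
  atts <- lapply(seq_along(res$cycles), function(j)
    new_attractor(res$cycles[[j]], res$basin[j], n_nodes(net)))
  pset <- structure(list(attractors = atts, n_nodes = n_nodes(net),
                         coverage = 2^n_nodes(net), method = "exhaustive"),
                    class = "attractor_set")
  list(category = as_outcome(classify_against(pset, attractor_cycles(ref))),
       perturbed_attractors = pset,
       descriptor = c(state = state, node = net$nodes[i]))
}

#' Stochastic state-transition bit-flip robustness
#'
#' Each trial produces one perturbed copy of the transition system in
#' which `n_flips` distinct states (drawn uniformly) each have one
#' uniformly chosen node's successor bit inverted; the copy's attractors
#' are recomputed and classified. `n_trials` copies form a replicate and
#' the per-replicate fraction of copies in which the original attractor
#' was reached again (categories `recovered_only` or
#' `recovered_plus_new`) is summarized across `n_replicates` replicates.
#' The default `n_flips` perturbs 1% of the state space (at least one
#' state), the conventional dose for transition-table perturbation;
#' `n_flips = 1` gives the minimal single-bit variant.
#'
#' @param net a [boolean_network()] (N <= 24).
#' @param n_trials perturbed copies per replicate.
#' @param n_replicates number of replicates.
#' @param seed RNG seed; results are a pure function of it.
#' @param n_flips perturbed states per copy.
#' @param reference optional precomputed [find_attractors()] result.
#' @return a `robustness_summary`; `replicate_fractions`, `mean` and
#'   `sd` describe the per-replicate recovered fractions.
#' @export
transition_flip_robustness <- function(net, n_trials = 100L,
                                       n_replicates = 1L, seed = 1L,
                                       n_flips = NULL,
                                       reference = NULL) {
  if (n_trials < 1 || n_replicates < 1)
    stop("n_trials and n_replicates must be >= 1", call. = FALSE)
  ref <- reference %||% find_attractors(net)
  refCycles <- attractor_cycles(ref)
  n <- n_nodes(net)
  if (is.null(n_flips)) n_flips <- max(1L, as.integer(ceiling(0.01 * 2^n)))
  if (n_flips < 1 || n_flips > 2^n)
    stop("n_flips must be in [1, 2^N]", call. = FALSE)
  tt <- transition_table(net)
  set.seed(seed)
  ntot <- n_trials * n_replicates
  states <- integer(0)
  for (t in seq_len(ntot))
    states <- c(states, sample.int(2L^n, n_flips) - 1L)
  nodes <- sample.int(n, ntot * n_flips, replace = TRUE) - 1L
  cats <- cpp_transition_multiflip_trials(tt, n, states, nodes,
                                          as.integer(n_flips), refCycles)
  recovered <- matrix(cats != 2L, nrow = n_trials)
  robustness_summary(
    cats,
    data.frame(replicate = rep(seq_len(n_replicates), each = n_trials),
               trial = rep(seq_len(n_trials), times = n_replicates),
               n_flips = n_flips),
    kind = sprintf("transition flips (%d x %d copies, %d flips each)",
                   n_replicates, n_trials, n_flips),
    seed = seed,
    replicates = colMeans(recovered)
  )
}
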