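# Synchronous state-transition dynamics: successor computation, exhaustive
# attractor enumeration with basin sizes, and phase annotation.

#' Encode / decode network states
#'
#' A state of an N-node network is a length-N 0/1 vector; its integer
#' code packs node i into bit i-1 (node 1 = low bit), giving a bijection
#' between states and codes in `[0, 2^N)`.
#'
#' @param bits 0/1 vector of node states.
#' @param code integer state code.
#' @param n number of nodes.
#' @return `encode_state` returns the integer code; `decode_state` the
#'   0/1 vector.
#' @export
encode_state <- function(bits) {
  bits <- as.integer(bits)
  if (any(is.na(bits)) || any(!bits %in% 0:1))
    stop("state bits must be 0/1", call. = FALSE)
  if (length(bits) > 30) # keep codes in integer range
    return(sum(bits * 2^(seq_along(bits) - 1)))
  as.integer(sum(bits * 2^(seq_along(bits) - 1)))
}

#' @rdname encode_state
#' @export
decode_state <- function(code, n) {
  bitwAnd(bitwShiftR(as.integer(code), seq_len(n) - 1L), 1L)
}

# Per-node input indices (0-based) and truth tables, with clamps applied
# as constant rules, in the form the C++ engine expects.
engine_form <- function(net) {
  inputs <- lapply(net$rules, function(r)
    match(r$inputs, net$nodes) - 1L)
  tables <- lapply(net$rules, function(r) r$table)
  if (length(net$clamps)) {
    for (nd in names(net$clamps)) {
      i <- match(nd, net$nodes)
      inputs[[i]] <- integer(0)
      tables[[i]] <- net$clamps[[nd]]
    }
  }
  list(inputs = unname(inputs), tables = unname(tables))
}

#' Full synchronous transition table
#'
#' @param net a [boolean_network()] with at most 24 nodes.
#' @return integer vector `succ` of length `2^N`: `succ[s + 1]` is the
#'   state code of the synchronous successor of state code `s`.
#' @export
transition_table <- function(net) {
  n <- n_nodes(net)
  if (n > 24)
    stop("exhaustive transition table limited to 24 nodes; ",
         "use sampled attractor search for larger networks", call. = FALSE)
  ef <- engine_form(net)
  cpp_transition_table(ef$inputs, ef$tables, n)
}

#' Synchronous successor of a state
#'
#' All nodes are updated simultaneously: node i's next value is its rule
#' applied to the current values of its inputs. Clamped nodes ignore
#' their rule and keep the clamp value. Every state has exactly one
#' successor.
#'
#' @param net a [boolean_network()].
#' @param state 0/1 vector of length N, or a single integer state code.
#' @return the successor in the same representation as the input.
#' @export
successor <- function(net, state) {
  n <- n_nodes(net)
  if (length(state) == n && all(state %in% 0:1)) {
    code <- encode_state(as.integer(state))
    as_code <- FALSE
  } else if (length(state) == 1L) {
    code <- as.integer(state)
    if (is.na(code) || code < 0 || code >= 2^n)
      stop("state code out of range [0, 2^N)", call. = FALSE)
    as_code <- TRUE
  } else {
    stop("state must have one bit per node (", n, " expected, got ",
         length(state), ")", call. = FALSE)
  }
  bits <- decode_state(code, n)
  out <- vapply(net$rules, function(r) {
    k <- length(r$inputs)
    row <- if (k == 0) 0L else {
      inb <- bits[match(r$inputs, net$nodes)]
      sum(inb * 2^(seq_len(k) - 1))
    }
    r$table[row + 1L]
  }, integer(1))
  if (length(net$clamps)) out[names(net$clamps)] <- net$clamps
  if (as_code) encode_state(out) else unname(out)
}

# ---- attractors --------------------------------------------------------

new_attractor <- function(cycle, basin_size, n) {
  structure(
    list(cycle = cycle, period = length(cycle),
         basin_size = basin_size, basin_fraction = basin_size / 2^n),
    class = "cc_attractor"
  )
}

#' Find all attractors of a synchronous Boolean network
#'
#' Exhaustive enumeration over the full state space (every state's
#' trajectory is followed to its cycle), yielding all attractors with
#' their configuration cycles, periods and basin sizes. Cycles are
#' canonicalized to start at their minimal state code, making attractor
#' identity invariant under rotation. For networks above the exhaustive
#' limit a seeded sampling mode explores trajectories from random
#' initial states; sampled basin sizes then count sampled states only.
#'
#' @param net a [boolean_network()].
#' @param method `"exhaustive"` (requires `N <= 24`) or `"sampled"`.
#' @param n_samples number of random initial states for sampled mode.
#' @param seed RNG seed for sampled mode.
#' @return an object of class `attractor_set`: a list with `attractors`
#'   (list of attractors: `cycle` of state codes, `period`, `basin_size`,
#'   `basin_fraction`), `n_nodes`, `coverage` (states analyzed) and
#'   `method`.
#' @examples
#' net <- boolean_network(c(A = "!B", B = "!A"))
#' find_attractors(net)
#' @export
find_attractors <- function(net, method = c("exhaustive", "sampled"),
                            n_samples = 1000L, seed = 1L) {
  method <- match.arg(method)
  n <- n_nodes(net)
  if (method == "exhaustive") {
    if (n > 24)
      stop("network has ", n, " nodes; exhaustive enumeration supports ",
           "at most 24. Use method = \"sampled\" with n_samples/seed.",
           call. = FALSE)
    res <- cpp_attractors(transition_table(net))
    atts <- lapply(seq_along(res$cycles), function(i)
      new_attractor(res$cycles[[i]], res$basin[i], n))
    coverage <- 2^n
  } else {
    if (n_samples <= 0) stop("n_samples must be positive", call. = FALSE)
    atts <- sampled_attractors(net, n_samples, seed)
    coverage <- n_samples
  }
  structure(
    list(attractors = atts, n_nodes = n, coverage = coverage,
         method = method),
    class = "attractor_set"
  )
}

# Trajectory walking from sampled initial conditions (for N > 24 the
# state space cannot be tabulated; codes are kept as doubles).
sampled_attractors <- function(net, n_samples, seed) {
  n <- n_nodes(net)
  set.seed(seed)
  found <- list()
  basins <- integer(0)
  for (rep in seq_len(n_samples)) {
    bits <- as.integer(runif(n) < 0.5)
    seen <- new.env(hash = TRUE)
    path <- character(0)
    repeat {
      key <- paste(bits, collapse = "")
      if (!is.null(seen[[key]])) {
        start <- seen[[key]]
        cyc_keys <- path[start:length(path)]
        cyc <- vapply(cyc_keys, function(kk)
          encode_state(as.integer(strsplit(kk, "")[[1]])), numeric(1))
        mi <- which.min(cyc)
        cyc <- c(cyc[mi:length(cyc)], cyc[seq_len(mi - 1L)])
        id <- paste(cyc, collapse = ",")
        if (is.null(found[[id]])) {
          found[[id]] <- cyc
          basins[id] <- 0L
        }
        basins[id] <- basins[id] + 1L
        break
      }
      seen[[key]] <- length(path) + 1L
      path <- c(path, key)
      bits <- successor(net, bits)
    }
  }
  lapply(names(found), function(id) {
    a <- new_attractor(found[[id]], basins[[id]], n)
    a$basin_fraction <- basins[[id]] / n_samples
    a
  })
}

#' @export
print.attractor_set <- function(x, ...) {
  cat("Attractor set:", length(x$attractors), "attractor(s) over",
      x$coverage, "states (", x$method, ")\n")
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("  #%d period %d, basin %d (%.2f%%)\n", i, a$period,
                a$basin_size, 100 * a$basin_fraction))
  }
  invisible(x)
}

#' Configuration matrix of an attractor cycle
#' @param attractor an attractor from [find_attractors()].
#' @param net the network it came from.
#' @return 0/1 matrix, nodes in rows, cycle positions in columns.
#' @export
attractor_configurations <- function(attractor, net) {
  m <- vapply(attractor$cycle, decode_state, integer(n_nodes(net)),
              n = n_nodes(net))
  m <- matrix(m, nrow = n_nodes(net),
              dimnames = list(net$nodes, seq_along(attractor$cycle)))
  m
}

# canonical rotation (minimal code first); cycles from the engine are
# already canonical, this is for cycles built elsewhere
canonicalize_cycle <- function(cycle) {
  mi <- which.min(cycle)
  c(cycle[mi:length(cycle)], cycle[seq_len(mi - 1L)])
}

attractor_cycles <- function(attractor_set) {
  lapply(attractor_set$attractors, function(a) a$cycle)
}

# ---- phase annotation --------------------------------------------------

#' Default cell-cycle phase scheme for the packaged model
#'
#' Eleven phase labels for the wild-type cycle (positions 1-2 G1, 3 G1/S,
#' 4 S, 5-6 S/G2, 7 G2, 8 G2/M, 9-10 M, 11 M-exit) plus the G1 anchor
#' pattern used to rotate a cycle into phase register: in the anchoring
#' configuration the CYCD3;1-CDKA;1 complex is absent or KRP1-inhibited,
#' APC/C and hypo-phosphorylated RBR are present, and the mitotic cyclins
#' CYCB1;1 and CYCA2;3 are absent.
#'
#' @return list with `labels` (character) and `anchor` (named 0/1
#'   requirements interpreted by [annotate_phases()]).
#' @export
cc_phase_scheme <- function() {
  list(
    labels = c("G1", "G1", "G1/S", "S", "S/G2", "S/G2", "G2", "G2/M",
               "M", "M", "M-exit"),
    anchor = list(
      complex_off = c("CYCD3;1", "KRP1"), # complex off: CYCD3;1 absent or KRP1 present
      on = c("APC/C", "RBR"),
      off = c("CYCB1;1", "CYCA2;3")
    )
  )
}

matches_anchor <- function(bits, nodes, anchor) {
  v <- setNames(bits, nodes)
  complex_active <- v[anchor$complex_off[1]] == 1L &&
    v[anchor$complex_off[2]] == 0L
  !complex_active && all(v[anchor$on] == 1L) && all(v[anchor$off] == 0L)
}

matches_anchor_relaxed <- function(bits, nodes, anchor) {
  v <- setNames(bits, nodes)
  complex_active <- v[anchor$complex_off[1]] == 1L &&
    v[anchor$complex_off[2]] == 0L
  !complex_active && all(v[anchor$off] == 0L)
}

#' Annotate an attractor cycle with cell-cycle phases
#'
#' The cycle is rotated so that the first configuration matching the
#' scheme's G1 anchor pattern (and whose predecessor does not match it,
#' i.e. the start of the G1 run) comes first, then labeled position by
#' position. If no configuration carries the full anchor marker set, a
#' relaxed anchor (CDK-cyclin complex inactive and mitotic cyclins
#' absent, dropping the RBR/APC-presence markers) is tried with a
#' warning; if that fails too, annotation errors rather than guessing.
#'
#' @param attractor an attractor whose period equals the scheme length.
#' @param net the network (for node names).
#' @param scheme a phase scheme, default [cc_phase_scheme()].
#' @return data frame with columns `position`, `phase`, `state` plus one
#'   0/1 column per node.
#' @export
annotate_phases <- function(attractor, net, scheme = cc_phase_scheme()) {
  p <- attractor$period
  if (p != length(scheme$labels))
    stop("attractor period (", p, ") does not match phase scheme length (",
         length(scheme$labels), ")", call. = FALSE)
  conf <- attractor_configurations(attractor, net)
  ok <- vapply(seq_len(p), function(j)
    matches_anchor(conf[, j], net$nodes, scheme$anchor), logical(1))
  if (!any(ok)) {
    ok <- vapply(seq_len(p), function(j)
      matches_anchor_relaxed(conf[, j], net$nodes, scheme$anchor),
      logical(1))
    if (any(ok))
      warning("no configuration carries the full G1 marker set; ",
              "anchored on the relaxed pattern (complex inactive, ",
              "mitotic cyclins absent)", call. = FALSE)
  }
  if (!any(ok))
    stop("no cycle configuration matches the G1 anchor pattern; ",
         "phase annotation unavailable for this attractor", call. = FALSE)
  starts <- which(ok & !ok[c(p, seq_len(p - 1L))])
  start <- if (length(starts)) starts[1] else which(ok)[1]
  ord <- ((start - 1L + seq_len(p) - 1L) %% p) + 1L
  out <- data.frame(
    position = seq_len(p),
    phase = scheme$labels,
    state = attractor$cycle[ord]
  )
  cbind(out, as.data.frame(t(conf[, ord, drop = FALSE]), row.names = FALSE))
}
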