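# In-silico loss- and gain-of-function mutants: clamp one node to 0/1,
# recompute the attractor landscape, and classify each attractor by its
# dynamical character (normal cycle, endocycle, arrest).

#' Clamp a node to simulate a mutant
#'
#' Loss of function fixes the node at 0, gain of function at 1: the
#' node's logical rule is skipped and the clamp value used at every
#' update, from the initial condition onwards. The original network is
#' not modified.
#'
#' @param net a [boolean_network()].
#' @param node node identifier.
#' @param value 0 (loss of function) or 1 (gain of function).
#' @return the clamped network.
#' @examples
#' cc <- load_cc_model()
#' krp1_null <- apply_mutation(cc, "KRP1", 0)
#' @export
apply_mutation <- function(net, node, value) {
  if (!node %in% net$nodes) stop("unknown node: ", node, call. = FALSE)
  if (!value %in% 0:1) stop("clamp value must be 0 or 1", call. = FALSE)
  clamps <- net$clamps
  clamps[node] <- as.integer(value)
  set_clamps(net, clamps)
}

# mitosis-onset configuration: CYCB1;1 present while KRP1 and APC/C are
# absent (the pattern of wild-type cycle positions 9-10); S-phase
# configuration: E2Fa present with RBR absent.
has_pattern <- function(conf, on, off) {
  any(apply(conf, 2, function(v) all(v[on] == 1L) && all(v[off] == 0L)))
}

#' Classify an attractor of the cell-cycle model
#'
#' Classes: `wild_type_like` (the attractor equals the unperturbed
#' 11-configuration cycle on all unclamped nodes), `fixed_point_arrest`
#' (period 1), `endocycle_like` (period > 1, no configuration shows the
#' mitosis-onset pattern CYCB1;1 on / KRP1 off / APC/C off, and at least
#' one configuration shows the S-phase pattern E2Fa on / RBR off), and
#' `other_cycle`.
#'
#' @param attractor an attractor from [find_attractors()].
#' @param net the (possibly clamped) network it was computed on.
#' @param reference the wild-type attractor (from the unclamped model);
#'   default: computed from [load_cc_model()].
#' @return character class label.
#' @export
classify_attractor <- function(attractor, net,
                               reference = cc_reference_attractor()) {
  needed <- c("CYCB1;1", "KRP1", "APC/C", "E2Fa", "RBR")
  if (!all(needed %in% net$nodes)) return("other_cycle")
  if (attractor$period == 1L) return("fixed_point_arrest")
  free <- setdiff(net$nodes, names(net$clamps))
  free_idx <- match(free, net$nodes)
  project <- function(cycle) {
    m <- vapply(cycle, function(code)
      decode_state(code, length(net$nodes))[free_idx],
      integer(length(free_idx)))
    proj <- apply(matrix(m, nrow = length(free_idx)), 2, function(v)
      sum(v * 2^(seq_along(v) - 1)))
    paste(canonicalize_cycle(proj), collapse = ",")
  }
  if (!is.null(reference) && identical(free_idx, match(free, reference$nodes)) &&
      project(attractor$cycle) == project(reference$cycle))
    return("wild_type_like")
  conf <- attractor_configurations(attractor, net)
  mitosis <- has_pattern(conf, "CYCB1;1", c("KRP1", "APC/C"))
  sphase <- has_pattern(conf, "E2Fa", "RBR")
  if (!mitosis && sphase) "endocycle_like" else "other_cycle"
}

# wild-type reference cycle for classification: cached per session
cc_ref_env <- new.env(parent = emptyenv())

#' Wild-type reference attractor of the packaged cell-cycle model
#' @return list with `cycle` (state codes of the period-11 attractor)
#'   and `nodes` (node order it is encoded over).
#' @export
cc_reference_attractor <- function() {
  if (is.null(cc_ref_env$ref)) {
    cc <- load_cc_model()
    att <- find_attractors(cc)$attractors[[1]]
    cc_ref_env$ref <- list(cycle = att$cycle, nodes = cc$nodes)
  }
  cc_ref_env$ref
}

#' Published mutant expectations for the cell-cycle model
#'
#' The phenotype table the mutant scan is compared against: for each
#' single-node clamp, the expected number of attractors and (where
#' printed) expected periods and basin percentages, plus the reported
#' agreement grade with experimental data (A = agrees, PA = partial,
#' NR = not recovered, "-" = no data). Qualitative entries have NA in
#' the numeric columns and are reported, not asserted.
#'
#' @return data frame with columns `node`, `value`, `n_attractors`,
#'   `periods`, `basin_pct`, `grade`, `description`.
#' @export
cc_mutant_expectations <- function() {
  path <- system.file("extdata", "cc_mutant_expectations.csv",
                      package = "ccgrn")
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

parse_num_list <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
}

#' Scan all single-node mutants
#'
#' Runs every loss- and gain-of-function clamp (2N mutants), computes
#' each clamped network's attractors over all 2^N initial conditions,
#' classifies them, and—when `expectations` are supplied—flags agreement
#' with the expected periods and basin percentages.
#'
#' @param net a [boolean_network()]; default the packaged model.
#' @param expectations a data frame as from [cc_mutant_expectations()],
#'   or NULL to skip the comparison.
#' @return data frame with one row per mutant: `node`, `value`,
#'   `n_attractors`, `periods`, `basin_pct`, `classes`, and (with
#'   expectations) `expected_periods`, `expected_basin_pct`, `grade`,
#'   `match` (TRUE when every printed expected number is reproduced).
#' @export
mutant_scan <- function(net = load_cc_model(),
                        expectations = cc_mutant_expectations()) {
  reference <- {
    att <- find_attractors(net)$attractors[[1]]
    list(cycle = att$cycle, nodes = net$nodes)
  }
  rows <- list()
  for (node in net$nodes) for (value in 0:1) {
    mut <- apply_mutation(net, node, value)
    aset <- find_attractors(mut)
    periods <- vapply(aset$attractors, function(a) a$period, numeric(1))
    basins <- vapply(aset$attractors, function(a)
      100 * a$basin_fraction, numeric(1))
    ord <- order(-basins)
    classes <- vapply(aset$attractors, classify_attractor, character(1),
                      net = mut, reference = reference)
    rows[[length(rows) + 1L]] <- data.frame(
      node = node, value = value,
      n_attractors = length(periods),
      periods = paste(periods[ord], collapse = ";"),
      basin_pct = paste(sprintf("%.2f", basins[ord]), collapse = ";"),
      classes = paste(classes[ord], collapse = ";"),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (!is.null(expectations)) {
    key <- paste(out$node, out$value)
    ekey <- paste(expectations$node, expectations$value)
    m <- match(key, ekey)
    out$expected_periods <- expectations$periods[m]
    out$expected_basin_pct <- expectations$basin_pct[m]
    out$grade <- expectations$grade[m]
    out$match <- vapply(seq_len(nrow(out)), function(i) {
      if (is.na(m[i])) return(NA)
      ep <- parse_num_list(out$expected_periods[i])
      eb <- parse_num_list(out$expected_basin_pct[i])
      en <- expectations$n_attractors[m[i]]
      got_p <- parse_num_list(out$periods[i])
      got_b <- parse_num_list(out$basin_pct[i])
      ok <- TRUE
      if (!is.na(en)) ok <- ok && en == out$n_attractors[i]
      if (length(ep)) ok <- ok && all(ep %in% got_p)
      if (length(eb))
        ok <- ok && all(vapply(eb, function(b)
          any(abs(got_b - b) < 0.005), logical(1)))
      ok
    }, logical(1))
  }
  out
}
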