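# raise testthat abort threshold so every file reports in full
options(testthat.progress.max_fails = 10000L)

# Brute-force attractor oracle: walks the trajectory of every state with
# plain R, independent of the C++ engine's decomposition.
oracle_attractors <- function(net) {
  n <- length(net$nodes)
  M <- 2^n
  succ <- vapply(0:(M - 1), function(s) successor(net, s), numeric(1))
  assign_id <- rep(NA_integer_, M)
  cycles <- list()
  basin <- integer(0)
  for (s0 in 0:(M - 1)) {
    if (!is.na(assign_id[s0 + 1])) next
    path <- integer(0)
    seen <- integer(0)
    cur <- s0
    while (is.na(assign_id[cur + 1]) && !(cur %in% path)) {
      path <- c(path, cur)
      cur <- succ[cur + 1]
    }
    if (!is.na(assign_id[cur + 1])) {
      id <- assign_id[cur + 1]
    } else {
      pos <- which(path == cur)
      cyc <- path[pos:length(path)]
      mi <- which.min(cyc)
      cyc <- c(cyc[mi:length(cyc)], cyc[seq_len(mi - 1)])
      id <- length(cycles) + 1L
      cycles[[id]] <- cyc
      basin[id] <- 0L
    }
    assign_id[path + 1] <- id
  }
  for (s in 0:(M - 1)) basin[assign_id[s + 1]] <- basin[assign_id[s + 1]] + 1L
  list(cycles = cycles, basin = basin)
}

# canonical multiset signature of an attractor landscape, for comparing
# the engine against the oracle
landscape_signature <- function(cycles, basins) {
  sig <- vapply(seq_along(cycles), function(i)
    paste0(paste(cycles[[i]], collapse = ","), "|", basins[i]), character(1))
  sort(sig)
}
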