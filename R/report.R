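# Reporting and command-line entry point: machine-readable exports of
# attractors, robustness and mutant results, figure-style plots, and a
# small subcommand dispatcher usable from Rscript.

#' Write an attractor report
#'
#' CSV layout: one row per cycle position with `position`, `phase` (if a
#' scheme of matching length applies, otherwise NA), `state`, then one
#' 0/1 column per node in network order.
#'
#' @param attractor_set from [find_attractors()].
#' @param net the network.
#' @param path output CSV path; a JSON summary (periods, basins) is
#'   written alongside with extension `.json`.
#' @return invisibly, the paths written.
#' @export
write_attractor_report <- function(attractor_set, net, path) {
  rows <- list()
  for (i in seq_along(attractor_set$attractors)) {
    a <- attractor_set$attractors[[i]]
    lab <- tryCatch(suppressWarnings(annotate_phases(a, net)$phase),
                    error = function(e) rep(NA_character_, a$period))
    conf <- attractor_configurations(a, net)
    rows[[i]] <- cbind(
      data.frame(attractor = i, position = seq_len(a$period),
                 phase = lab, state = a$cycle),
      as.data.frame(t(conf), row.names = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  write.csv(out, path, row.names = FALSE)
  jpath <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(
      n_attractors = length(attractor_set$attractors),
      periods = vapply(attractor_set$attractors, `[[`, numeric(1), "period"),
      basin_sizes = vapply(attractor_set$attractors, `[[`, numeric(1),
                           "basin_size"),
      basin_fractions = vapply(attractor_set$attractors, `[[`, numeric(1),
                               "basin_fraction"),
      coverage = attractor_set$coverage
    ),
    jpath, auto_unbox = TRUE, digits = NA
  )
  invisible(c(path, jpath))
}

#' Raster plot of an attractor cycle
#'
#' Nodes in rows, cycle positions in columns, filled cells for ON
#' states, mirroring the usual presentation of logical-model attractors.
#'
#' @param attractor an attractor.
#' @param net the network.
#' @param main plot title.
#' @export
plot_attractor_raster <- function(attractor, net, main = "Attractor") {
  if (attractor$period < 1) stop("empty attractor cycle", call. = FALSE)
  conf <- attractor_configurations(attractor, net)
  image(
    x = seq_len(ncol(conf)), y = seq_len(nrow(conf)),
    z = t(conf[rev(seq_len(nrow(conf))), , drop = FALSE]),
    col = c("firebrick", "forestgreen"), axes = FALSE,
    xlab = "cycle position", ylab = "", main = main, zlim = c(0, 1)
  )
  axis(1, at = seq_len(ncol(conf)))
  axis(2, at = seq_len(nrow(conf)), labels = rev(rownames(conf)),
       las = 2, cex.axis = 0.7)
  box()
}

#' Histogram of ensemble robustness with reference lines
#'
#' @param ensemble an `ensemble_summary`.
#' @param main plot title.
#' @export
plot_ensemble_histogram <- function(ensemble, main = NULL) {
  if (is.null(main))
    main <- sprintf("Random-network robustness (%s)", ensemble$kind)
  hist(100 * ensemble$fractions, breaks = 20,
       xlim = c(0, 100), col = "grey80",
       xlab = "% perturbations recovering the network's own attractors",
       main = main)
  abline(v = 100 * ensemble$q95, col = "blue", lwd = 2)
  if (!is.na(ensemble$template_fraction))
    abline(v = 100 * ensemble$template_fraction, col = "red", lwd = 2)
}

#' Plot continuous trajectories
#' @param traj a `cc_trajectory`.
#' @param nodes nodes to draw (default all).
#' @export
plot_trajectory <- function(traj, nodes = colnames(traj$x)) {
  matplot(traj$time, traj$x[, nodes, drop = FALSE], type = "l", lty = 1,
          xlab = "time", ylab = "activity", ylim = c(0, 1))
  legend("topright", legend = nodes, col = seq_along(nodes), lty = 1,
         cex = 0.6, bg = "white")
}

#' @importFrom graphics abline axis box hist image legend matplot
NULL

#' Command-line dispatcher
#'
#' Thin entry point for Rscript use:
#' `Rscript -e 'ccgrn::run_ccgrn()' attractors --out dir` etc.
#' Subcommands: `attractors`, `robustness`, `mutant`, `ensemble`,
#' `continuous`. Every run writes a JSON manifest (command, arguments,
#' seed, package version) next to its outputs.
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
run_ccgrn <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) stop("usage: <attractors|robustness|mutant|ensemble|continuous> [options]")
    cmd <- args[1]
    opts <- parse_cli_options(args[-1])
    out_dir <- opts[["out"]] %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    seed <- as.integer(opts[["seed"]] %||% "1")
    net <- if (is.null(opts[["model"]]) || opts[["model"]] == "cc")
      load_cc_model() else read_network(opts[["model"]])
    result <- switch(cmd,
      attractors = {
        aset <- find_attractors(net)
        write_attractor_report(aset, net, file.path(out_dir, "attractors.csv"))
        list(n_attractors = length(aset$attractors))
      },
      robustness = {
        kind <- opts[["kind"]] %||% "functions"
        summ <- if (kind == "functions") {
          if (!is.null(opts[["sample"]]))
            function_flip_robustness(net, "sampled",
                                     n = as.integer(opts[["sample"]]),
                                     seed = seed)
          else function_flip_robustness(net, "exhaustive")
        } else {
          transition_flip_robustness(
            net,
            n_trials = as.integer(opts[["trials"]] %||% "100"),
            n_replicates = as.integer(opts[["replicates"]] %||% "1"),
            seed = seed)
        }
        utils::write.table(summ$outcomes,
                           file.path(out_dir, "robustness.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        as.list(summ$fractions)
      },
      mutant = {
        if (!is.null(opts[["node"]])) {
          mut <- apply_mutation(net, opts[["node"]],
                                as.integer(opts[["value"]] %||% "0"))
          aset <- find_attractors(mut)
          write_attractor_report(aset, mut,
                                 file.path(out_dir, "mutant_attractors.csv"))
          list(n_attractors = length(aset$attractors))
        } else {
          scan <- mutant_scan(net)
          utils::write.table(scan, file.path(out_dir, "mutant_scan.tsv"),
                             sep = "\t", row.names = FALSE, quote = FALSE)
          list(n_mutants = nrow(scan))
        }
      },
      ensemble = {
        summ <- ensemble_robustness(
          net,
          n_networks = as.integer(opts[["n-networks"]] %||% "100"),
          n_perturb = as.integer(opts[["n-perturb"]] %||% "100"),
          kind = opts[["kind"]] %||% "functions",
          seed = seed)
        jsonlite::write_json(
          summ[c("kind", "median", "mean", "sd", "q95",
                 "template_fraction")],
          file.path(out_dir, "ensemble.json"), auto_unbox = TRUE,
          digits = NA)
        list(median = summ$median)
      },
      continuous = {
        model <- continuous_model(
          net, h = as.numeric(opts[["h"]] %||% "50"),
          gamma = as.numeric(opts[["gamma"]] %||% "1"),
          semantics = opts[["semantics"]] %||% "minmax")
        set.seed(seed)
        traj <- integrate_model(model, runif(n_nodes(net)),
                                t_end = as.numeric(opts[["t-end"]] %||% "120"))
        df <- data.frame(time = traj$time, traj$x, check.names = FALSE)
        write.csv(df, file.path(out_dir, "trajectory.csv"),
                  row.names = FALSE)
        detect_limit_cycle(traj)[c("is_cycle", "period")]
      },
      stop("unknown subcommand: ", cmd)
    )
    manifest <- list(command = cmd, options = opts, seed = seed,
                     package_version = as.character(utils::packageVersion("ccgrn")),
                     result = result)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_options <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- substring(args[i], 3L)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]
        i <- i + 2L
      } else {
        opts[[key]] <- "true"
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", args[i], call. = FALSE)
    }
  }
  opts
}
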