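# Plain-text readers/writers and a declarative pipeline runner.

.fmt <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)

#' Write an EMG dataset to a directory of delimited text files
#'
#' One CSV per participant in long format (`trial, muscle, timepoint,
#' value`), one CSV per task variable, and a `manifest.json` naming
#' muscles, dimensions and task kinds. Floating-point values are written
#' with 17 significant digits so the round trip is exact.
#'
#' @param dataset an [emg_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_emg_csv <- function(dataset, dir) {
  stopifnot(inherits(dataset, "emg_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_len(dataset$n_participants)) {
    e <- dataset$emg[[p]]
    d <- dim(e)
    df <- data.frame(
      trial = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
      muscle = rep(rep(dataset$muscle_names, each = d[1L]), times = d[3L]),
      timepoint = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
      value = .fmt(as.vector(e)))
    utils::write.csv(df, file.path(dir, sprintf("emg_p%02d.csv", p)),
                     row.names = FALSE, quote = FALSE)
  }
  for (tv in dataset$tasks) {
    rows <- lapply(seq_along(tv$values), function(p) {
      v <- tv$values[[p]]
      if (tv$kind == "discrete") {
        data.frame(participant = p, trial = seq_along(v), timepoint = NA,
                   value = as.character(v))
      } else {
        data.frame(participant = p,
                   trial = rep(seq_len(nrow(v)), ncol(v)),
                   timepoint = rep(seq_len(ncol(v)), each = nrow(v)),
                   value = .fmt(as.vector(v)))
      }
    })
    utils::write.csv(do.call(rbind, rows),
                     file.path(dir, sprintf("task_%s.csv", tv$name)),
                     row.names = FALSE, quote = FALSE)
  }
  manifest <- list(
    n_participants = dataset$n_participants,
    n_muscles = dataset$n_muscles,
    n_timepoints = dataset$n_timepoints,
    n_trials = vapply(dataset$emg, function(e) dim(e)[1L], 0L),
    muscles = dataset$muscle_names,
    tasks = lapply(dataset$tasks, function(tv)
      list(name = tv$name, kind = tv$kind)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read an EMG dataset written by [write_emg_csv()]
#'
#' @param dir directory containing the CSV files and `manifest.json`.
#' @return an [emg_dataset()].
#' @export
read_emg_csv <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop("missing manifest: ", mf_path,
                                  call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  emg <- lapply(seq_len(mf$n_participants), function(p) {
    path <- file.path(dir, sprintf("emg_p%02d.csv", p))
    if (!file.exists(path)) stop("missing EMG file: ", path, call. = FALSE)
    df <- utils::read.csv(path)
    nt <- mf$n_trials[p]
    if (nrow(df) != nt * mf$n_muscles * mf$n_timepoints) {
      stop("EMG file ", path, " does not match the manifest dimensions",
           call. = FALSE)
    }
    array(as.numeric(df$value),
          dim = c(nt, mf$n_muscles, mf$n_timepoints),
          dimnames = list(NULL, mf$muscles, NULL))
  })
  tasks <- lapply(seq_len(nrow(as.data.frame(mf$tasks))), function(ti) {
    tinfo <- as.data.frame(mf$tasks)[ti, ]
    df <- utils::read.csv(file.path(dir, sprintf("task_%s.csv", tinfo$name)))
    vals <- lapply(seq_len(mf$n_participants), function(p) {
      sub <- df[df$participant == p, ]
      if (tinfo$kind == "discrete") {
        factor(sub$value[order(sub$trial)])
      } else {
        m <- matrix(NA_real_, mf$n_trials[p], mf$n_timepoints)
        m[cbind(sub$trial, sub$timepoint)] <- as.numeric(sub$value)
        m
      }
    })
    task_variable(tinfo$name, vals, kind = tinfo$kind)
  })
  emg_dataset(emg, tasks, muscle_names = mf$muscles)
}

#' Export a muscle network as GraphML
#'
#' @param adj symmetric adjacency matrix.
#' @param path output file.
#' @param node_names optional node labels.
#' @param membership optional community ids stored as a node attribute.
#' @return invisibly, the path.
#' @export
write_network_graphml <- function(adj, path, node_names = NULL,
                                  membership = NULL) {
  g <- igraph::graph_from_adjacency_matrix(as.matrix(adj), mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (!is.null(node_names)) igraph::V(g)$name <- node_names
  if (!is.null(membership)) igraph::V(g)$community <- membership
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Run the full pipeline from a declarative configuration
#'
#' The configuration is a list (or path to a JSON file) with entries
#' `input` (directory for [read_emg_csv()]) or `synthetic` (arguments to
#' [synthetic_spec()]), optional `spatial_rank`/`temporal_rank`,
#' `sparsify`, `n_random`, and a global `seed` from which all stage seeds
#' are derived. Artifacts (factor tables as CSV, summary and provenance as
#' JSON, per-factor spatial networks as GraphML) are written to `out_dir`.
#'
#' @param config list or path to a JSON config file.
#' @param out_dir artifact directory (created if needed).
#' @return the fitted `nif` object, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("missing config file: ", config,
                                   call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(config$input)) {
    dataset <- read_emg_csv(config$input)
  } else if (!is.null(config$synthetic)) {
    args <- config$synthetic
    if (is.null(args$seed)) args$seed <- config$seed
    dataset <- generate(do.call(synthetic_spec, args))$dataset
  } else {
    stop("config must name an 'input' directory or a 'synthetic' spec",
         call. = FALSE)
  }
  fit <- nif(dataset,
             spatial_rank = config$spatial_rank,
             temporal_rank = config$temporal_rank,
             sparsify = !isFALSE(config$sparsify),
             n_random = if (is.null(config$n_random)) 100
                        else config$n_random,
             seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cls in fit$interactions) {
    f <- fit$fits[[cls]]
    if (isTRUE(f$empty)) next
    dec <- f$decomposition
    utils::write.csv(data.frame(factor = seq_len(nrow(dec$V)),
                                apply(dec$V, 2L, .fmt)),
                     file.path(out_dir, sprintf("%s_spatial.csv", cls)),
                     row.names = FALSE)
    utils::write.csv(data.frame(factor = seq_len(nrow(dec$W)),
                                apply(dec$W, 2L, .fmt)),
                     file.path(out_dir, sprintf("%s_temporal.csv", cls)),
                     row.names = FALSE)
    for (j in seq_along(f$networks)) {
      net <- f$networks[[j]]
      if (sum(net$adj) == 0) next
      write_network_graphml(
        net$pruned, file.path(out_dir, sprintf("%s_S%d.graphml", cls, j)),
        node_names = fit$muscle_names,
        membership = if (!is.null(net$submodules))
          net$submodules$membership else NULL)
    }
  }
  s <- summary(fit)
  jsonlite::write_json(
    list(summary = s$table,
         provenance = list(config = config, seed = config$seed,
                           package_version =
                             as.character(utils::packageVersion("taskspace")),
                           r_version = R.version.string)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(fit)
}
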