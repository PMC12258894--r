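#' Read TI datasets from CSV
#'
#' Long-format CSV with columns \code{residue, state, voltage, q, lambda,
#' mean_force} and optional \code{block_id, block_value} pairs for error
#' bars. Rows are grouped into one \code{\link{ti_dataset}} per
#' (residue, state, voltage).
#'
#' @param path CSV path.
#' @param units energy units of the mean forces.
#' @return list of \code{ti_dataset} objects.
#' @export
read_ti_csv <- function(path, units = "kcal/mol") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue", "state", "voltage", "q", "lambda", "mean_force")
  if (!all(need %in% names(df)))
    stop("TI CSV must have columns: ", paste(need, collapse = ", "))
  key <- paste(df$residue, df$state, df$voltage, sep = "|")
  lapply(split(df, key), function(g) {
    g <- g[order(g$lambda), ]
    blocks <- NULL
    if (all(c("block_id", "block_value") %in% names(df)) &&
        any(!is.na(g$block_id))) {
      lam <- unique(g$lambda)
      blocks <- lapply(lam, function(l) g$block_value[g$lambda == l])
      g <- g[!duplicated(g$lambda), ]
      g$mean_force <- vapply(blocks, mean, numeric(1))
    }
    ti_dataset(g$lambda, g$mean_force, residue_id = g$residue[1],
               state = g$state[1], voltage = g$voltage[1], q = g$q[1],
               units = units, blocks = blocks)
  })
}

#' Write TI datasets to CSV
#'
#' @param datasets list of \code{\link{ti_dataset}} objects.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ti_csv <- function(datasets, path) {
  rows <- lapply(datasets, function(d) {
    if (is.null(d$blocks)) {
      data.frame(residue = d$residue_id, state = d$state,
                 voltage = d$voltage, q = d$q, lambda = d$lambdas,
                 mean_force = d$mean_forces, stringsAsFactors = FALSE)
    } else {
      do.call(rbind, lapply(seq_along(d$lambdas), function(i)
        data.frame(residue = d$residue_id, state = d$state,
                   voltage = d$voltage, q = d$q, lambda = d$lambdas[i],
                   mean_force = d$mean_forces[i],
                   block_id = seq_along(d$blocks[[i]]),
                   block_value = d$blocks[[i]],
                   stringsAsFactors = FALSE)))
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

.read_matrix_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Run one analysis stage from a configuration
#'
#' Config-driven front end tying the stages together. \code{config} is a
#' named list or the path to a YAML file; every stage writes its outputs
#' plus a \code{manifest.json} (parameters, seed, input checksums,
#' output files) into \code{output_dir}, so a run is reproducible from
#' its archived config and inputs. Nothing is written when validation
#' fails.
#'
#' Stages and their main config keys:
#' \describe{
#'   \item{simulate-fixtures}{\code{seed}; writes a tilted helix-bundle
#'     PDB, a slab TI CSV and an ion-track CSV.}
#'   \item{descriptors}{\code{structure} (PDB), \code{trajectory} (DCD),
#'     \code{helices} (list of name/first/last), optional
#'     \code{proxy_residues}; writes tilt and displacement CSVs.}
#'   \item{gating-charge}{\code{ti_csv}; writes the gating-charge table
#'     CSV.}
#'   \item{potential-map}{\code{structure}, \code{box}, optional
#'     \code{voltage}, \code{beta}, \code{spacing}; writes an OpenDX map
#'     in mV.}
#'   \item{network}{\code{structure}, \code{trajectory}, optional
#'     \code{cutoff}, \code{occupancy}, \code{source}/\code{sink}
#'     labels; writes edge, community and path CSVs.}
#'   \item{flow}{\code{contact_csv}, \code{mi_csv} (square matrices),
#'     \code{source}, \code{sinks}; writes the per-node flow CSV.}
#' }
#'
#' @param subcommand one of the stages above.
#' @param config named list or YAML file path.
#' @param output_dir directory for outputs (created if needed).
#' @return (invisibly) a list with the manifest and the stage's main
#'   result object.
#' @export
run_stage <- function(subcommand, config, output_dir) {
  subcommand <- match.arg(subcommand,
                          c("simulate-fixtures", "descriptors",
                            "gating-charge", "potential-map", "network",
                            "flow"))
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  # validate inputs before creating anything
  inputs <- intersect(names(config),
                      c("structure", "trajectory", "ti_csv", "contact_csv",
                        "mi_csv"))
  for (key in inputs)
    if (!file.exists(config[[key]]))
      stop("config field '", key, "': no such file: ", config[[key]])
  seed <- config$seed %||% 1L
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  result <- switch(subcommand,
    "simulate-fixtures" = {
      bundle <- make_helix_bundle(n_helices = 4,
                                  tilt_deg = c(0, 10, 20, 30), seed = seed)
      p_pdb <- file.path(output_dir, "helix_bundle.pdb")
      write_structure(bundle, p_pdb)
      slab <- make_slab_coupling_system(
        depths_closed = c(0.35, 0.5), depths_open = c(0.6, 0.5),
        charges = c(1, -1), seed = seed)
      p_ti <- file.path(output_dir, "slab_ti.csv")
      write_ti_csv(slab$datasets, p_ti)
      tracks <- make_ion_tracks(n_events_up = 3, seed = seed)
      p_ion <- emit(data.frame(time_ns = tracks$time_ns, tracks$z),
                    "ion_tracks.csv")
      outputs <- c(outputs, p_pdb, p_ti)
      list(bundle = bundle, slab = slab, tracks = tracks)
    },
    "descriptors" = {
      st <- load_structure(config$structure)
      traj <- load_trajectory(config$trajectory, st$atoms)
      res <- list()
      if (!is.null(config$helices)) {
        tilts <- lapply(config$helices, function(h) {
          idx <- select_atoms(st$atoms, resid = h$first:h$last,
                              name = "CA")
          helix_tilt(traj, idx)
        })
        names(tilts) <- vapply(config$helices, `[[`, character(1), "name")
        emit(data.frame(frame = seq_len(n_frames(traj)),
                        as.data.frame(tilts)), "helix_tilt.csv")
        res$tilts <- tilts
      }
      if (!is.null(config$proxy_residues)) {
        px <- charge_group_proxies(st$atoms,
                                   as.integer(config$proxy_residues))
        zd <- charge_z_displacement(traj, px)
        emit(data.frame(frame = seq_len(n_frames(traj)), zd),
             "charge_z_displacement.csv")
        res$z_displacement <- zd
      }
      res
    },
    "gating-charge" = {
      datasets <- read_ti_csv(config$ti_csv)
      tab <- gating_charge_from_ti(datasets)
      df <- as.data.frame(tab)
      df_total <- rbind(df, data.frame(
        residue_id = NA, label = "total", q = NA, f_closed = NA,
        f_open = NA, dq = attr(tab, "dQ"), error = attr(tab, "dQ_error")))
      emit(df_total, "gating_charge.csv")
      tab
    },
    "potential-map" = {
      st <- load_structure(config$structure)
      box <- as.numeric(config$box)
      dens <- smear_charges(st$coords, st$atoms$charge, box = box,
                            beta = config$beta %||% 0.25,
                            spacing = config$spacing %||% 1.0)
      phi <- solve_poisson(dens)
      if (!is.null(config$voltage))
        phi <- add_external_field(phi, config$voltage)
      p <- file.path(output_dir, "potential_mV.dx")
      export_potential_dx(phi, p)
      outputs <- c(outputs, p)
      phi
    },
    "network" = {
      st <- load_structure(config$structure)
      traj <- load_trajectory(config$trajectory, st$atoms)
      nodes <- residue_nodes(st$atoms)
      cm <- contact_map(traj, nodes, cutoff = config$cutoff %||% 5,
                        occupancy = config$occupancy %||% 0.75,
                        neighbor_exclusion =
                          config$neighbor_exclusion %||% 1)
      C <- correlation_matrix(traj, nodes$ca_idx)
      net <- build_network(cm, C, labels = nodes$labels)
      emit(net$edges, "network_edges.csv")
      part <- communities(net)
      emit(data.frame(node = nodes$labels,
                      community = part$membership), "communities.csv")
      res <- list(network = net, communities = part)
      if (!is.null(config$source) && !is.null(config$sink)) {
        ps <- suboptimal_paths(net, config$source, config$sink,
                               tolerance = config$tolerance %||% 0.5)
        emit(data.frame(
          rank = seq_along(ps$suboptimal),
          length = vapply(ps$suboptimal, `[[`, numeric(1), "length"),
          path = vapply(ps$suboptimal, function(p)
            paste(nodes$labels[p$nodes], collapse = "|"), character(1))),
          "paths.csv")
        res$paths <- ps
      }
      res
    },
    "flow" = {
      contacts <- .read_matrix_csv(config$contact_csv) > 0
      M <- .read_matrix_csv(config$mi_csv)
      fn <- flow_network(contacts, M)
      fr <- information_flow(fn, as.integer(config$source),
                             as.integer(config$sinks))
      emit(data.frame(node = seq_len(fn$n), potential = fr$P,
                      flow = fr$f), "flow.csv")
      fr
    })
  manifest <- list(
    subcommand = subcommand,
    seed = seed,
    parameters = config[setdiff(names(config), inputs)],
    inputs = lapply(config[inputs], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = basename(outputs),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, result = result))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
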