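# Declared float format for all text exports: 9 significant digits.
fmt_num <- function(x) {
  if (is.double(x)) formatC(x, digits = 9, format = "g") else as.character(x)
}

write_table_9g <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  utils::write.table(out, path, quote = FALSE, sep = ",", row.names = FALSE)
  invisible(path)
}

#' Export run artifacts as plain text
#'
#' Spike rasters as two-column CSV (`neuron_id`, `time_ms`); neuron state
#' snapshots as CSV (`id`, `kind`, `x`, `y`, `v`, `u`, `ca`); element-pool
#' snapshots as CSV (`neuron_id`, `class`, `z`, `n_total`, `n_bound`,
#' `n_vacant`); connectivity as a directed weighted edge list
#' (`pre_id`, `post_id`, `n_synapses`); the per-update log as JSON lines.
#' Floats are written with 9 significant digits, and every CSV re-parses to
#' the same values.
#'
#' @param raster,network,log The object to export.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_raster <- function(raster, path) write_table_9g(raster, path)

#' @rdname export_raster
#' @export
export_states <- function(network, path) {
  write_table_9g(data.frame(
    id = seq_len(network$n), kind = network$kind,
    x = network$pos[, 1], y = network$pos[, 2],
    v = network$v, u = network$u, ca = network$ca), path)
}

#' @rdname export_raster
#' @export
export_pools <- function(network, path) {
  rows <- lapply(ELEMENT_CLASSES, function(cls) {
    k <- cls_key(cls)
    bound <- vapply(network[[paste0("prt_", k)]],
                    function(p) sum(p > 0), integer(1))
    total <- lengths(network[[paste0("ids_", k)]])
    data.frame(neuron_id = seq_len(network$n), class = cls,
               z = network[[paste0("z_", k)]], n_total = total,
               n_bound = bound, n_vacant = total - bound)
  })
  write_table_9g(do.call(rbind, rows), path)
}

#' @rdname export_raster
#' @export
export_edges <- function(network, path) {
  nz <- which(network$omega > 0, arr.ind = TRUE)
  df <- data.frame(pre_id = nz[, 1], post_id = nz[, 2],
                   n_synapses = network$omega[nz])
  write_table_9g(df[order(df$pre_id, df$post_id), , drop = FALSE], path)
}

#' @rdname export_raster
#' @export
export_update_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  invisible(path)
}

# --- scenario config files -------------------------------------------------

curve_to_list <- function(cv) list(nu = cv$nu, eta = cv$eta, eps = cv$eps)

scenario_to_list <- function(cfg) {
  list(
    name = cfg$name,
    geometry = list(exc_dims = cfg$geometry$exc_dims,
                    spacing = cfg$geometry$spacing,
                    jitter_sd = cfg$geometry$jitter_sd),
    curves = lapply(cfg$curves, curve_to_list),
    lesion = if (is.null(cfg$lesion)) NULL else unclass(cfg$lesion),
    peri_factor = cfg$peri_factor,
    membrane = unclass(cfg$membrane), input = unclass(cfg$input),
    calcium = unclass(cfg$calcium), kernel = unclass(cfg$kernel),
    vac = list(tau_vac = if (is.finite(cfg$vac$tau_vac))
      cfg$vac$tau_vac else "Inf"),
    pre_updates = cfg$pre_updates, post_updates = cfg$post_updates,
    snapshot_every = cfg$snapshot_every,
    update_interval_ms = cfg$update_interval_ms)
}

#' Write a scenario configuration file
#'
#' @param cfg A [scenario_config()].
#' @param path Output path (JSON).
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(jsonlite::toJSON(scenario_to_list(cfg), auto_unbox = TRUE,
                              digits = NA, pretty = TRUE, null = "null"),
             path)
  invisible(path)
}

#' Load and validate a scenario configuration file
#'
#' Reads a JSON scenario description, fills every omitted field with the
#' defaults of the named scenario (an empty file yields the full default
#' physiological standard scenario), rejects unknown keys, and checks all
#' ordering constraints via [validate_scenario()].
#'
#' @param path Path to a JSON config file.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  raw <- if (!length(txt) || !nzchar(trimws(paste(txt, collapse = ""))))
    list() else jsonlite::fromJSON(paste(txt, collapse = "\n"),
                                   simplifyVector = TRUE)
  allowed <- c("name", "geometry", "curves", "lesion", "peri_factor",
               "membrane", "input", "calcium", "kernel", "vac",
               "pre_updates", "post_updates", "snapshot_every",
               "update_interval_ms")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  name <- if (!is.null(raw$name)) raw$name else "physiological"
  geometry <- if (!is.null(raw$geometry)) {
    gkeys <- setdiff(names(raw$geometry), c("exc_dims", "spacing", "jitter_sd"))
    if (length(gkeys)) stop("unknown geometry keys: ",
                            paste(gkeys, collapse = ", "))
    do.call(network_geometry, raw$geometry)
  } else NULL
  args <- list(name = name, geometry = geometry)
  for (f in c("pre_updates", "post_updates", "snapshot_every",
              "update_interval_ms", "peri_factor"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$curves)) {
    ckeys <- setdiff(names(raw$curves), ELEMENT_CLASSES)
    if (length(ckeys)) stop("unknown curve classes: ",
                            paste(ckeys, collapse = ", "))
    cur <- scenario_config(name, geometry = geometry)$curves
    for (cls in names(raw$curves))
      cur[[cls]] <- do.call(growth_curve, as.list(raw$curves[[cls]]))
    args$curves <- cur
  }
  if (!is.null(raw$lesion))
    args$lesion <- do.call(lesion_spec, as.list(raw$lesion))
  for (f in c("membrane", "input", "calcium", "kernel"))
    if (!is.null(raw[[f]]))
      args[[f]] <- do.call(paste0(if (f == "kernel") "kernel_params"
                                  else paste0(f, if (f == "input") "_config"
                                              else "_params")),
                           as.list(raw[[f]]))
  if (!is.null(raw$vac)) {
    tv <- raw$vac$tau_vac
    args$vac <- vacancy_decay_params(if (identical(tv, "Inf")) Inf else tv)
  }
  do.call(scenario_config, args)
}

# --- run manifests and replay ----------------------------------------------

#' Save run outputs with a manifest
#'
#' Writes the scenario config, final neuron states, element pools,
#' connectivity edge list and per-update log to a directory, together with a
#' manifest recording the master seed, the derived stream seeds, the config
#' checksum and a checksum of every output file. The manifest is what
#' [replay()] verifies against.
#'
#' @param run A [run_protocol()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
save_run_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_config(run$scenario, file.path(dir, "config.json"))
  export_states(run$network, file.path(dir, "states.csv"))
  export_pools(run$network, file.path(dir, "pools.csv"))
  export_edges(run$network, file.path(dir, "edges.csv"))
  export_update_log(run$log, file.path(dir, "updates.jsonl"))
  files <- c("states.csv", "pools.csv", "edges.csv", "updates.jsonl")
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("homeoplast")),
    seed = run$seed, control = run$control,
    stream_seeds = as.list(run$stream_seeds),
    config_md5 = unname(tools::md5sum(file.path(dir, "config.json"))),
    files = as.list(sums))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Replay a saved run and verify reproducibility
#'
#' Re-executes the run described by a manifest (refusing if the stored
#' config file no longer matches its recorded checksum), regenerates every
#' output in a temporary directory and compares checksums bit for bit.
#'
#' @param dir Directory holding `manifest.json` and the run outputs.
#' @param seed Optionally override the seed (a different seed is expected
#'   to be reported as a mismatch, not silently accepted).
#' @return List with `ok` (all checksums match) and `mismatches`
#'   (file names whose regenerated content differs).
#' @export
replay <- function(dir, seed = NULL) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  cfg_path <- file.path(dir, "config.json")
  if (unname(tools::md5sum(cfg_path)) != manifest$config_md5)
    stop("config file does not match manifest checksum; refusing to replay")
  cfg <- load_config(cfg_path)
  if (is.null(seed)) seed <- manifest$seed
  run <- run_protocol(cfg, seed, control = isTRUE(manifest$control))
  tmp <- tempfile("replay")
  save_run_outputs(run, tmp)
  files <- names(manifest$files)
  new <- tools::md5sum(file.path(tmp, files))
  old <- unlist(manifest$files)
  mismatches <- files[unname(new) != unname(old[files])]
  unlink(tmp, recursive = TRUE)
  list(ok = length(mismatches) == 0, mismatches = mismatches)
}
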