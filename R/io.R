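# Plain-text persistence: trajectories and event logs as TSV with a
# commented header block, configs as YAML.

.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config), tf)
  unname(tools::md5sum(tf))
}

#' Write a trajectory to a directory of TSV files
#'
#' Writes `phases.tsv` (per-phase records), `events.tsv` (the transfer
#' attempt log) and `geometry.tsv`, each with a `#` header block recording
#' the seed, run length, burn-in, transfer range and a hash of the full
#' configuration. Fixed numeric formatting makes equal runs byte-identical.
#'
#' @param traj An `fo_trajectory`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trajectory <- function(traj, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(
    sprintf("# seed=%d", traj$config$seed),
    sprintf("# n_phases=%d", traj$config$n_phases),
    sprintf("# burn_in=%d", traj$config$burn_in),
    sprintf("# r_max=%.10g", traj$config$mc$r_max),
    sprintf("# config_hash=%s", .config_hash(traj$config)))
  write_tsv <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    is_num <- vapply(df, is.double, logical(1))
    df[is_num] <- lapply(df[is_num], function(x) sprintf("%.10g", x))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df) > 0) {
      writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
    }
  }
  write_tsv(traj$phases, file.path(dir, "phases.tsv"))
  write_tsv(traj$events, file.path(dir, "events.tsv"))
  write_geometry(traj$geom, file.path(dir, "geometry.tsv"))
  invisible(dir)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the phase records, event log and geometry; the embedded header
#' fields (seed, burn-in, transfer range) are enough for every analysis
#' function in the package.
#'
#' @param dir Directory written by [write_trajectory()].
#' @return An `fo_trajectory` (config restored as a plain list).
#' @export
read_trajectory <- function(dir) {
  read_tsv <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    body <- lines[!grepl("^#", lines)]
    get <- function(key) sub(paste0("^# ", key, "="), "",
                             grep(paste0("^# ", key, "="), hdr, value = TRUE)[1])
    df <- read.table(text = body, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, colClasses = "character")
    for (nm in names(df)) {
      if (nm != "h") df[[nm]] <- utils::type.convert(df[[nm]], as.is = TRUE)
    }
    list(df = df, seed = as.integer(get("seed")),
         n_phases = as.integer(get("n_phases")),
         burn_in = as.integer(get("burn_in")),
         r_max = as.numeric(get("r_max")),
         hash = get("config_hash"))
  }
  ph <- read_tsv(file.path(dir, "phases.tsv"))
  ev <- read_tsv(file.path(dir, "events.tsv"))
  phases <- ph$df
  if (nrow(phases) > 0) phases$h <- as.character(phases$h)
  structure(list(
    phases = phases, events = ev$df,
    geom = read_geometry(file.path(dir, "geometry.tsv")),
    config = list(seed = ph$seed, n_phases = ph$n_phases,
                  burn_in = ph$burn_in, mc = list(r_max = ph$r_max),
                  config_hash = ph$hash)
  ), class = "fo_trajectory")
}

#' Write a simulation configuration as YAML
#'
#' Doubles are stored with the maximum precision the YAML writer offers
#' (about 15 significant digits); parameters representable at that
#' precision round-trip exactly through [read_sim_config()].
#'
#' @param config A [sim_config()] (with a synthetic-geometry argument list,
#'   not a prebuilt geometry).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  if (inherits(config$geometry, "fo_geometry")) {
    stop("write_sim_config stores synthetic-geometry arguments; ",
         "export prebuilt geometries with write_geometry()")
  }
  as_plain <- function(x) {
    x <- unclass(x)
    x[!vapply(x, is.null, logical(1))]
  }
  out <- list(
    geometry = as_plain(config$geometry),
    energy = as_plain(config$energy),
    mc = as_plain(config$mc),
    dyn = as_plain(config$dyn),
    n_phases = config$n_phases,
    burn_in = config$burn_in,
    seed = config$seed,
    mutations = lapply(config$mutations, as_plain))
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Read a configuration written by [write_sim_config()]
#'
#' @param path YAML path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) do.call(ctor, if (is.null(args)) list() else args)
  muts <- lapply(y$mutations, function(m) do.call(mutation_spec, m))
  sim_config(
    geometry = if (is.null(y$geometry)) list() else y$geometry,
    energy = build(energy_params, y$energy),
    mc = build(mc_params, y$mc),
    dyn = build(dyn_params, y$dyn),
    n_phases = y$n_phases, burn_in = y$burn_in,
    mutations = muts, seed = y$seed)
}
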