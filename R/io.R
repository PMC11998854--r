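# File I/O: mesh snapshots (ASCII OFF and PLY), trajectory tables (CSV),
# run configurations (YAML) and reproducibility manifests.

#' Write a mesh as ASCII OFF
#' @param mesh a `trimesh`.
#' @param path output file.
#' @export
write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @inheritParams write_off
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.12g %.12g %.12g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read a mesh snapshot (ASCII OFF or PLY, auto-detected)
#' @param path input file.
#' @return a `trimesh`.
#' @export
read_mesh <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^OFF", first)) read_off_file(path) else read_ply_file(path)
}

read_off_file <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  stopifnot(grepl("^OFF", ln[1]))
  counts <- as.integer(strsplit(trimws(ln[2]), "\\s+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  v <- do.call(rbind, lapply(ln[3:(2 + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  f <- do.call(rbind, lapply(ln[(3 + nv):(2 + nv + nf)], function(s) {
    x <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  trimesh(v, f)
}

read_ply_file <- function(path) {
  ln <- readLines(path)
  stopifnot(ln[1] == "ply")
  hend <- which(ln == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "", ln[grepl("^element vertex", ln)]))
  nf <- as.integer(sub("element face ", "", ln[grepl("^element face", ln)]))
  v <- do.call(rbind, lapply(ln[(hend + 1):(hend + nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][1:3])))
  f <- do.call(rbind, lapply(ln[(hend + nv + 1):(hend + nv + nf)], function(s) {
    x <- as.integer(strsplit(trimws(s), "\\s+")[[1]])
    if (x[1] != 3L) stop("only triangle faces are supported")
    x[2:4] + 1L
  }))
  trimesh(v, f)
}

#' Write / read a trajectory ensemble as CSV
#'
#' Columns: sample, t, N, V, A, R, E_bend, E_area, E_tether, Phi and the
#' per-kind attempt/acceptance counts; the drive (delta_mu, dp, mu_eq, tau)
#' is stored in a commented header line.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param path CSV file path.
#' @export
write_trajectory_csv <- function(ensemble, path) {
  hdr <- sprintf("# vesiclegrowth trajectory v1 mu_eq=%.10g delta_mu=%.10g dp=%.10g tau=%d",
                 ensemble$mu_eq %||% NA, ensemble$delta_mu, ensemble$dp,
                 ensemble$tau)
  writeLines(hdr, path)
  data.table::fwrite(ensemble$records, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  get_num <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[-0-9.eE+]+"), hdr))
    if (length(m) == 0) NA_real_ else as.numeric(sub(paste0(key, "="), "", m))
  }
  rec <- data.table::fread(path, skip = 1L)
  structure(list(records = rec, mu_eq = get_num("mu_eq"),
                 delta_mu = get_num("delta_mu"), dp = get_num("dp"),
                 tau = as.integer(get_num("tau")), final_meshes = list(),
                 params = NULL, failed = 0L),
            class = "trajectory_ensemble")
}

config_schema_version <- "1"

config_known_keys <- c(
  "schema_version", "kappa", "tether_min", "tether_max", "k_a", "a0",
  "mu", "dp", "kT", "step_size", "pflip", "pexchange", "insert_halfwidth",
  "min_vertices", "max_vertices", "nequil", "nsim", "checkpoint_every",
  "nsamples", "seed", "subdivisions", "delta_mu", "lmax", "out")

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the package
#' defaults. The resolved configuration (all defaults filled in) is
#' attached so it can be logged for provenance.
#'
#' @param path YAML file.
#' @return list with `params` (a [sim_params()]), `subdivisions`,
#'   `delta_mu`, `lmax`, `resolved` (full resolved key-value list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), config_known_keys)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$schema_version) &&
      as.character(cfg$schema_version) != config_schema_version)
    stop("unsupported config schema version: ", cfg$schema_version)
  edef <- energy_params()
  ep <- energy_params(
    kappa = cfg$kappa %||% edef$kappa,
    tether_min = cfg$tether_min %||% edef$tether_min,
    tether_max = cfg$tether_max %||% edef$tether_max,
    k_a = cfg$k_a %||% edef$k_a,
    a0 = cfg$a0 %||% edef$a0)
  pdef <- sim_params(energy = ep)
  p <- sim_params(
    energy = ep,
    mu = cfg$mu %||% pdef$mu, dp = cfg$dp %||% pdef$dp,
    kT = cfg$kT %||% pdef$kT,
    step_size = cfg$step_size %||% pdef$step_size,
    pflip = cfg$pflip %||% pdef$pflip,
    pexchange = cfg$pexchange %||% pdef$pexchange,
    insert_halfwidth = cfg$insert_halfwidth %||% pdef$insert_halfwidth,
    min_vertices = cfg$min_vertices %||% pdef$min_vertices,
    max_vertices = cfg$max_vertices %||% pdef$max_vertices,
    nequil = cfg$nequil %||% pdef$nequil,
    nsim = cfg$nsim %||% pdef$nsim,
    checkpoint_every = cfg$checkpoint_every %||% pdef$checkpoint_every,
    nsamples = cfg$nsamples %||% pdef$nsamples,
    seed = cfg$seed %||% pdef$seed)
  resolved <- c(list(schema_version = config_schema_version),
                p$energy[c("kappa", "tether_min", "tether_max", "k_a", "a0")],
                p[setdiff(names(p), "energy")],
                list(subdivisions = cfg$subdivisions %||% 3L,
                     delta_mu = cfg$delta_mu %||% 0,
                     lmax = cfg$lmax))
  list(params = p, subdivisions = cfg$subdivisions %||% 3L,
       delta_mu = cfg$delta_mu %||% 0, lmax = cfg$lmax, resolved = resolved)
}

#' Write a run configuration (resolved defaults) to YAML
#' @param config a list as returned by `read_run_config()$resolved`, or a
#'   [sim_params()] object.
#' @param path output YAML path.
#' @export
write_run_config <- function(config, path) {
  if (inherits(config, "sim_params")) {
    config <- c(list(schema_version = config_schema_version),
                config$energy[c("kappa", "tether_min", "tether_max", "k_a", "a0")],
                config[setdiff(names(config), "energy")])
  }
  config <- config[!vapply(config, is.null, logical(1))]
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Reproducibility manifest for a run
#'
#' Records the package version, the resolved configuration and its MD5
#' hash, and the master seed: enough to reproduce the run bit for bit.
#'
#' @param resolved resolved configuration list.
#' @param seed master seed used.
#' @return list with `package_version`, `config_hash`, `seed`, `config`.
#' @export
run_manifest <- function(resolved, seed) {
  tf <- tempfile(fileext = ".yml")
  on.exit(unlink(tf))
  yaml::write_yaml(resolved, tf)
  list(package_version = as.character(utils::packageVersion("vesiclegrowth")),
       config_hash = unname(tools::md5sum(tf)),
       seed = seed, config = resolved)
}
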