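#' Write / read triangle meshes (ascii PLY, OFF, legacy VTK)
#'
#' Vertex order is stable across write/read; coordinates round-trip at
#' full double precision (17 significant digits).
#'
#' @param mesh a `trimesh`.
#' @param path output file; format chosen by extension (.ply, .off, .vtk)
#'   unless `format` is given.
#' @param format one of `"ply"`, `"off"`, `"vtk"`.
#' @return `write_mesh`: the path, invisibly. `read_mesh`: a `trimesh`.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  v <- mesh$x; f <- mesh$tri - 1L
  con <- file(path, "w")
  on.exit(close(con))
  fmt3 <- function(m) apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0", "comment phagosim trimesh",
                 sprintf("element vertex %d", nrow(v)),
                 "property double x", "property double y", "property double z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(fmt3(v), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "off") {
    writeLines("OFF", con)
    writeLines(sprintf("%d %d 0", nrow(v), nrow(f)), con)
    writeLines(fmt3(v), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  } else if (format == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "phagosim trimesh", "ASCII",
                 "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(v))), con)
    writeLines(fmt3(v), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4L * nrow(f)), con)
    writeLines(paste(3, f[, 1], f[, 2], f[, 3]), con)
  } else stop("unknown mesh format: ", format)
  invisible(path)
}

#' @rdname write_mesh
#' @export
read_mesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  ln <- readLines(path)
  if (format == "ply") {
    stopifnot(ln[1] == "ply")
    hdr_end <- which(ln == "end_header")[1]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", ln, value = TRUE)[1]))
    nf <- as.integer(sub("element face ", "", grep("^element face", ln, value = TRUE)[1]))
    v <- matrix(scan(text = ln[(hdr_end + 1):(hdr_end + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
    fr <- matrix(scan(text = ln[(hdr_end + nv + 1):(hdr_end + nv + nf)], quiet = TRUE), nf, 4, byrow = TRUE)
  } else if (format == "off") {
    stopifnot(ln[1] == "OFF")
    cnt <- scan(text = ln[2], quiet = TRUE)
    nv <- cnt[1]; nf <- cnt[2]
    v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
    fr <- matrix(scan(text = ln[(3 + nv):(2 + nv + nf)], quiet = TRUE), nf, 4, byrow = TRUE)
  } else if (format == "vtk") {
    ip <- grep("^POINTS", ln)[1]
    nv <- as.integer(strsplit(ln[ip], " +")[[1]][2])
    v <- matrix(scan(text = ln[(ip + 1):(ip + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
    ipol <- grep("^POLYGONS", ln)[1]
    nf <- as.integer(strsplit(ln[ipol], " +")[[1]][2])
    fr <- matrix(scan(text = ln[(ipol + 1):(ipol + nf)], quiet = TRUE), nf, 4, byrow = TRUE)
  } else stop("unknown mesh format: ", format)
  if (any(fr[, 1] != 3)) stop("non-triangular face in ", path)
  trimesh(v, fr[, 2:4] + 1L)
}

#' Write / read a trajectory directory
#'
#' A trajectory is a directory of PLY frames (`frame_000001.ply`, ...),
#' optional chain coordinate files (`chains_000001.tsv`), an observables
#' table `observables.tsv`, and a `meta.yaml` holding the seed, stride,
#' configuration echo and a content hash for integrity checking.
#'
#' @param frames list of `trimesh` (or `mc_run`) objects.
#' @param path directory to create.
#' @param obs optional observables data.frame.
#' @param chains optional list (per frame) of chain lists.
#' @param meta named list stored in `meta.yaml` (seed, config, ...).
#' @return `write_trajectory`: path invisibly; `read_trajectory`: list with
#'   `frames`, `chains`, `obs`, `meta`.
#' @export
write_trajectory <- function(frames, path, obs = NULL, chains = NULL,
                             meta = list()) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    m <- if (inherits(fr, "mc_run")) fr$mesh else fr
    write_mesh(m, file.path(path, sprintf("frame_%06d.ply", i)))
    ch <- if (!is.null(chains)) chains[[i]]
          else if (inherits(fr, "mc_run")) fr$chains
    if (!is.null(ch)) {
      xx <- do.call(rbind, lapply(seq_along(ch), function(k)
        cbind(chain = k, bead = seq_len(nrow(ch[[k]]$x)), ch[[k]]$x)))
      write.table(xx, file.path(path, sprintf("chains_%06d.tsv", i)),
                  sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  if (!is.null(obs))
    write.table(obs, file.path(path, "observables.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  meta$n_frames <- length(frames)
  meta$format_version <- 1L
  meta$hash <- trajectory_hash(path)
  writeLines(yaml::as.yaml(meta), file.path(path, "meta.yaml"))
  invisible(path)
}

trajectory_hash <- function(path) {
  files <- sort(list.files(path, pattern = "^(frame|chains|observables)", full.names = TRUE))
  unname(substr(paste(vapply(files, function(f) tools::md5sum(f), character(1)),
                      collapse = ""), 1, 32))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  metaf <- file.path(path, "meta.yaml")
  if (!file.exists(metaf)) stop("not a trajectory directory (missing meta.yaml)")
  meta <- yaml::read_yaml(metaf)
  if (is.null(meta$format_version) || meta$format_version != 1L)
    stop("trajectory format version mismatch")
  plys <- sort(list.files(path, pattern = "^frame_.*\\.ply$", full.names = TRUE))
  if (length(plys) != meta$n_frames)
    stop("trajectory corrupted: expected ", meta$n_frames, " frames, found ",
         length(plys))
  frames <- lapply(plys, read_mesh)
  chf <- sort(list.files(path, pattern = "^chains_.*\\.tsv$", full.names = TRUE))
  chains <- if (length(chf)) lapply(chf, function(f) {
    d <- read.table(f, header = TRUE, sep = "\t")
    lapply(split(d, d$chain), function(g) list(x = unname(as.matrix(g[, 3:5]))))
  }) else NULL
  obsf <- file.path(path, "observables.tsv")
  obs <- if (file.exists(obsf)) read.table(obsf, header = TRUE, sep = "\t") else NULL
  list(frames = frames, chains = chains, obs = obs, meta = meta)
}

default_config <- function() {
  list(
    kappa = 20, K_A = 1e6, K_V = 1e6, K_da = 5e6,
    u = 0, d0 = 0.5, d1_over_l = 1,
    K_bond = 1e4, K_ang = 1e3, K_dih = 500,
    subdivision = 3L, n_dimers = 6L, shape = "s",
    arc_radius = 1 / (2 * sin(pi / 30)),
    neck_radius_fraction = 0.1,
    v_target = 1 / sqrt(3), da_target = NA,
    n_sweeps = 10000L, sa_scale = 5e-3, n_repeats = 10L,
    tether_ratio = sqrt(3),
    stride = 100L, seed = 1L,
    scenario = NA)
}

scenario_presets <- function() {
  list(
    free_vesicle   = list(u = 0, n_dimers = 0L),
    fused3_s6      = list(v_target = 1 / sqrt(3), n_dimers = 6L, shape = "s",
                          kappa = 10, K_A = 2e5, K_V = 5e5, K_da = 0, u = 0.12),
    fused4_s6      = list(v_target = 0.5, n_dimers = 6L, shape = "s",
                          kappa = 10, K_A = 2e5, K_V = 5e5, K_da = 0, u = 0.1),
    fused3_straight6 = list(v_target = 1 / sqrt(3), n_dimers = 6L,
                            shape = "straight", kappa = 10, K_A = 2e5,
                            K_V = 5e5, K_da = 0, u = 0.1))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, fills defaults (bending rigidity 20 k_B T
#' for free vesicles; protein-run presets switch to 10 k_B T with
#' `K_A = 2e5`, `K_V = 5e5`), expands a `scenario` preset if named, and
#' validates fields. Unknown keys are rejected with field-level messages.
#'
#' @param path YAML file (an empty file gives the full defaults).
#' @return named list of validated configuration values.
#' @export
load_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else as.list(path)
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  out <- modifyList(def, cfg)
  if (!is.na(out$scenario)) {
    pre <- scenario_presets()[[out$scenario]]
    if (is.null(pre)) stop("unknown scenario: ", out$scenario)
    # explicit keys in the file override the preset
    pre <- pre[setdiff(names(pre), names(cfg))]
    out <- modifyList(out, pre)
  }
  chk <- function(cond, msg) if (!cond) stop("config: ", msg)
  chk(out$kappa > 0, "kappa must be positive")
  chk(out$u >= 0, "binding strength u must be non-negative")
  chk(out$K_A >= 0 && out$K_V >= 0 && out$K_da >= 0,
      "constraint stiffnesses must be non-negative")
  chk(out$d1_over_l > out$d0, "d1 must exceed d0")
  chk(out$v_target > 0 && out$v_target <= 1, "v_target must be in (0, 1]")
  chk(out$subdivision >= 0, "subdivision must be non-negative")
  chk(out$n_dimers >= 0, "n_dimers must be non-negative")
  chk(out$shape %in% c("s", "straight"), "shape must be 's' or 'straight'")
  chk(out$tether_ratio > 1, "tether_ratio must exceed 1")
  out
}

#' Write an observable table as TSV
#' @param obs data.frame of per-frame observables.
#' @param path output file.
#' @return path, invisibly.
#' @export
write_observables <- function(obs, path) {
  write.table(obs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
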