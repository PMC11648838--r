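# Self-describing text formats for DOS estimates and snapshot sets, and the
# run configuration with documented defaults.

.fmt_g <- function(x) sprintf("%.17g", x)

#' Save / load a density-of-states estimate
#'
#' One record per level (backbone count, sidechain count, energy, log-DOS,
#' visits, initial log-DOS) plus a header carrying the schedule state; the
#' round trip is lossless at full double precision.
#'
#' @param dos a `dos_estimate`
#' @param path file path
#' @return `load_dos` returns a `dos_estimate`
#' @export
save_dos <- function(dos, path) {
  stopifnot(inherits(dos, "dos_estimate"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# prime20samc DOS v1",
    paste0("# t=", .fmt_g(dos$t)),
    paste0("# gamma=", .fmt_g(dos$gamma)),
    paste0("# gamma_sum=", .fmt_g(dos$gamma_sum)),
    paste0("# gamma0=", .fmt_g(dos$gamma0)),
    paste0("# t0=", .fmt_g(dos$t0)),
    paste0("# gamma_min=", .fmt_g(dos$gamma_min)),
    paste0("# w_bb=", .fmt_g(dos$w_bb)),
    paste0("# w_sc=", .fmt_g(dos$w_sc)),
    paste0("# converged=", if (isTRUE(dos$converged)) 1 else 0),
    paste0("# config_hash=", attr(dos, "config_hash") %||% 0),
    "# n_backbone n_sidechain energy log_dos visits init_log_dos"), con)
  lv <- dos$levels
  writeLines(sprintf("%d %d %s %s %s %s", lv$n_backbone, lv$n_sidechain,
                     .fmt_g(lv$energy), .fmt_g(lv$log_dos), .fmt_g(lv$visits),
                     .fmt_g(lv$init_log_dos)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.header_value <- function(lines, key) {
  hit <- grep(paste0("^# ", key, "="), lines, value = TRUE)
  if (!length(hit)) stop("missing header field: ", key)
  as.numeric(sub(paste0("^# ", key, "="), "", hit[1]))
}

#' @rdname save_dos
#' @export
load_dos <- function(path) {
  if (!file.exists(path)) stop("DOS file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# prime20samc DOS"))
    stop("not a DOS file (line 1): ", path)
  hdr <- list(t = .header_value(lines, "t"),
              gamma = .header_value(lines, "gamma"),
              gamma_sum = .header_value(lines, "gamma_sum"),
              gamma0 = .header_value(lines, "gamma0"),
              t0 = .header_value(lines, "t0"),
              gamma_min = .header_value(lines, "gamma_min"),
              w_bb = .header_value(lines, "w_bb"),
              w_sc = .header_value(lines, "w_sc"),
              converged = .header_value(lines, "converged"))
  data_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  seen <- character(0)
  rows <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    ln <- data_idx[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) != 6)
      stop(sprintf("malformed DOS record at line %d of %s", ln, path))
    key <- paste(f[1], f[2])
    if (key %in% seen)
      stop(sprintf("duplicate level key (%s) at line %d of %s", key, ln, path))
    seen <- c(seen, key)
    rows[[k]] <- as.numeric(f)
    if (any(!is.finite(rows[[k]][c(1, 2, 4, 5, 6)])))
      stop(sprintf("malformed DOS record at line %d of %s", ln, path))
  }
  m <- if (length(rows)) do.call(rbind, rows) else matrix(0, 0, 6)
  levels <- data.frame(n_backbone = as.integer(m[, 1]),
                       n_sidechain = as.integer(m[, 2]),
                       log_dos = m[, 4], visits = m[, 5],
                       init_log_dos = m[, 6])
  cfg <- samc_config(gamma0 = hdr$gamma0, t0 = hdr$t0,
                     gamma_min = hdr$gamma_min)
  prm <- list(w_bb = hdr$w_bb, w_sc = hdr$w_sc)
  dos <- new_dos_estimate(levels, hdr$t, hdr$gamma, hdr$gamma_sum, cfg, prm,
                          hdr$converged == 1)
  dos
}

#' Save / load snapshot records
#'
#' Text format: a header with the model weights and sequences, then one
#' SNAPSHOT block per record (step, counts, energy, run id) followed by the
#' bead table (chain, residue, kind, x, y, z in Angstrom). The loader
#' re-verifies that each stored energy equals the model energy of the stored
#' counts and errors on any tampered record.
#'
#' @param records list of `snapshot_record`s (as from [run_production()])
#' @param path file path
#' @return `load_snapshots` returns the list of records
#' @export
save_snapshots <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# prime20samc snapshots v1", con)
  if (length(records)) {
    r1 <- records[[1]]
    writeLines(c(paste0("# sequences=", paste(r1$sequences, collapse = ",")),
                 paste0("# box_length=", .fmt_g(r1$box_length))), con)
  }
  for (r in records) {
    writeLines(sprintf("SNAPSHOT %s %d %d %s %s", .fmt_g(r$step),
                       r$counts$n_backbone, r$counts$n_sidechain,
                       .fmt_g(r$e_p20), r$run_id), con)
    co <- r$coords
    n <- nrow(co)
    kind <- rep(BEAD_KINDS, n / 4)
    writeLines(sprintf("%s %s %s", kind, .fmt_g(co[, 1]),
                       paste(.fmt_g(co[, 2]), .fmt_g(co[, 3]))), con)
  }
  invisible(path)
}

#' @rdname save_snapshots
#' @param params a [p20_params()] supplying the weights for the consistency
#'   check
#' @export
load_snapshots <- function(path, params = default_params()) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# prime20samc snapshots"))
    stop("not a snapshot file: ", path)
  seqs <- character(0)
  box <- NA_real_
  hit <- grep("^# sequences=", lines, value = TRUE)
  if (length(hit)) seqs <- strsplit(sub("^# sequences=", "", hit[1]), ",")[[1]]
  hit <- grep("^# box_length=", lines, value = TRUE)
  if (length(hit)) box <- as.numeric(sub("^# box_length=", "", hit[1]))
  starts <- which(startsWith(lines, "SNAPSHOT"))
  records <- vector("list", length(starts))
  nbead <- sum(nchar(seqs)) * 4
  for (k in seq_along(starts)) {
    ln <- starts[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) < 6) stop(sprintf("malformed SNAPSHOT header at line %d", ln))
    step <- as.numeric(f[2])
    nbb <- as.integer(f[3]); nsc <- as.integer(f[4])
    e <- as.numeric(f[5]); run_id <- f[6]
    counts <- structure(list(n_backbone = nbb, n_sidechain = nsc),
                        class = "interaction_count")
    e_expect <- p20_energy(counts, params)
    if (abs(e - e_expect) > 1e-9)
      stop(sprintf(paste0("inconsistent snapshot record at line %d: stored ",
                          "energy %.6g does not match counts (%d, %d) -> %.6g"),
                   ln, e, nbb, nsc, e_expect))
    rows <- lines[(ln + 1):(ln + nbead)]
    m <- do.call(rbind, strsplit(trimws(rows), "\\s+"))
    coords <- cbind(as.numeric(m[, 2]), as.numeric(m[, 3]), as.numeric(m[, 4]))
    records[[k]] <- structure(list(step = step, counts = counts, e_p20 = e,
                                   coords = coords, run_id = run_id,
                                   sequences = seqs, box_length = box),
                              class = "snapshot_record")
  }
  records
}

# ---------------------------------------------------------------------------
# run configuration

#' Default run configuration
#'
#' Nested configuration covering the model parameters, sampler settings,
#' backmapping geometry and statistics defaults, plus a global seed from
#' which per-stage seeds are derived (see [derive_seed()]). Every field has
#' a documented default; unknown keys are rejected by [load_config()].
#'
#' @return a `run_config` list
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    out_dir = ".",
    verbosity = "info",
    model = list(w_bb = 1.0, w_sc = 0.08, bb_well = c(3.65, 4.50),
                 scsc_well = c(4.50, 6.00), scbb_well = c(4.25, 5.75),
                 bond_tol = 0.02375, min_sep = 3L),
    sampler = list(gamma0 = 1.0, t0 = 1e4, gamma_min = 1e-7,
                   move_mix = c(0.25, 0.25, 0.25, 0.25),
                   max_displacement = 0.02, max_pivot_angle = pi,
                   max_chain_translation = 1.0, max_chain_rotation = pi,
                   snapshot_stride = 1000L, level_quota = 10L,
                   max_steps = 5e6),
    backmap = list(torsion_samples = 36L, clash_fraction = 0.6),
    stats = list(correlation_time = 10)
  ), class = "run_config")
}

#' Load a run configuration
#'
#' Reads a JSON configuration and merges it over the documented defaults.
#' Unknown keys (at any level) and constraint violations are reported by
#' name. An empty file yields the defaults.
#'
#' @param path JSON file path
#' @return a `run_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path), collapse = "\n")
  user <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  base <- unclass(default_config())
  merged <- .merge_config(base, user, "")
  # constraint validation via the constructors
  do.call(samc_config, c(merged$sampler[setdiff(names(merged$sampler),
                                                character(0))],
                         list(seed = merged$seed)))
  p20_params(w_bb = merged$model$w_bb, w_sc = merged$model$w_sc,
             bb_well = merged$model$bb_well, scsc_well = merged$model$scsc_well,
             scbb_well = merged$model$scbb_well,
             bond_tol = merged$model$bond_tol, min_sep = merged$model$min_sep)
  if (!merged$verbosity %in% c("quiet", "info", "debug"))
    stop("invalid value for key 'verbosity': ", merged$verbosity)
  structure(merged, class = "run_config")
}

.merge_config <- function(base, user, prefix) {
  if (!length(user)) return(base)
  for (key in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
    if (!key %in% names(base)) stop("unknown config key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("type mismatch for key '", full, "': expected a section")
      base[[key]] <- .merge_config(base[[key]], user[[key]], full)
    } else {
      v <- user[[key]]
      if (is.numeric(base[[key]]) && !is.numeric(v))
        stop("type mismatch for key '", full, "': expected numeric")
      if (is.character(base[[key]]) && !is.character(v))
        stop("type mismatch for key '", full, "': expected character")
      if (length(base[[key]]) > 1 && length(v) != length(base[[key]]))
        stop("wrong length for key '", full, "'")
      base[[key]] <- if (is.integer(base[[key]])) as.integer(v)
                     else if (is.numeric(base[[key]])) as.numeric(v) else v
    }
  }
  base
}

#' Hash of a resolved configuration
#'
#' Stable 32-bit hash of the serialized configuration, recorded in run
#' manifests so reruns can be checked for configuration drift.
#'
#' @param config a `run_config` (or any serializable list)
#' @return integer-valued numeric hash
#' @export
config_hash <- function(config) {
  fnv1a(paste(deparse(unclass(config)), collapse = ""))
}

# sampler/model objects from a run_config
.config_samc <- function(config, seed = NULL) {
  s <- config$sampler
  samc_config(gamma0 = s$gamma0, t0 = s$t0, gamma_min = s$gamma_min,
              move_mix = s$move_mix, max_displacement = s$max_displacement,
              max_pivot_angle = s$max_pivot_angle,
              max_chain_translation = s$max_chain_translation,
              max_chain_rotation = s$max_chain_rotation,
              seed = seed %||% config$seed,
              snapshot_stride = s$snapshot_stride,
              level_quota = s$level_quota, max_steps = s$max_steps)
}

.config_params <- function(config) {
  m <- config$model
  p20_params(w_bb = m$w_bb, w_sc = m$w_sc, bb_well = m$bb_well,
             scsc_well = m$scsc_well, scbb_well = m$scbb_well,
             bond_tol = m$bond_tol, min_sep = m$min_sep)
}
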