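# Configuration files, columnar table output with provenance, trajectory
# export.

#' Read a run configuration file
#'
#' Flat key-value YAML; keys match the arguments of [sim_config()] (and a
#' `synth:` block may carry [synth_track_params()] arguments). Unknown keys
#' are rejected so typos cannot silently change a run.
#'
#' @param path YAML file.
#' @return A list with `sim` (a [sim_config()]) and `synth`
#'   (a [synth_track_params()]), each built from the file's values over the
#'   defaults.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  synth_raw <- raw$synth
  raw$synth <- NULL
  bad <- setdiff(names(raw), names(formals(sim_config)))
  if (length(bad) > 0)
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  if (!is.null(synth_raw)) {
    bad <- setdiff(names(synth_raw), names(formals(synth_track_params)))
    if (length(bad) > 0)
      stop("unknown synth key(s): ", paste(bad, collapse = ", "))
  }
  list(sim = do.call(sim_config, raw),
       synth = do.call(synth_track_params, as.list(synth_raw)))
}

#' Write a provenance record
#'
#' Every artifact-producing run writes a YAML sidecar naming the
#' configuration, seed and package version, from which the artifact is
#' regenerable.
#'
#' @param path output file.
#' @param config the configuration object (a list).
#' @param seed the run seed.
#' @param extra optional named list of extra fields.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  rec <- c(list(package = "oriseg",
                version = as.character(packageVersion("oriseg")),
                seed = seed,
                config = unclass(config)),
           extra)
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' Write a columnar metrics table with a metadata header
#'
#' Plain CSV preceded by `#`-prefixed header lines naming the config and
#' seeds, so the table is self-describing.
#'
#' @param df data frame.
#' @param path output file.
#' @param meta named list written as `# key: value` lines.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]]), collapse = " ")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path file path.
#' @return The data frame, with attribute `meta` (character vector of header
#'   lines).
#' @export
read_metrics_table <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  df <- read.csv(text = paste(lines[!hdr], collapse = "\n"))
  attr(df, "meta") <- sub("^# ", "", lines[hdr])
  df
}

#' Per-frame, per-bead trajectory table
#'
#' Requires the run to have been made with `store_frames = TRUE`.
#'
#' @param traj a `sim_trajectory`.
#' @return Data frame `frame`, `time_s`, `bead`, `chromosome`, `x`, `y`,
#'   `z` (d_b units), `radius`.
#' @export
trajectory_table <- function(traj) {
  if (is.null(traj$full_frames))
    stop("trajectory was run without store_frames = TRUE")
  fr <- traj$frames
  out <- lapply(seq_along(traj$full_frames), function(i) {
    f <- traj$full_frames[[i]]
    n <- nrow(f$pos)
    data.frame(frame = i, time_s = fr$time_s[i], bead = seq_len(n),
               chromosome = f$chromosome, x = f$pos[, 1], y = f$pos[, 2],
               z = f$pos[, 3], radius = f$radii)
  })
  do.call(rbind, out)
}

#' Minimal XYZ export for molecular viewers
#'
#' One XYZ block per sampled frame; element symbols encode the chromosome
#' (C = template, N = daughter).
#'
#' @param traj a `sim_trajectory` run with `store_frames = TRUE`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_xyz <- function(traj, path) {
  if (is.null(traj$full_frames))
    stop("trajectory was run without store_frames = TRUE")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$full_frames)) {
    f <- traj$full_frames[[i]]
    n <- nrow(f$pos)
    writeLines(as.character(n), con)
    writeLines(sprintf("frame %d t=%.1fs", i, traj$frames$time_s[i]), con)
    el <- ifelse(f$chromosome == 1L, "C", "N")
    writeLines(sprintf("%s %.6f %.6f %.6f", el, f$pos[, 1], f$pos[, 2],
                       f$pos[, 3]), con)
  }
  invisible(path)
}
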