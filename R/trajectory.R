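# Trajectory persistence and interchange.  The primary container is R
# native serialization of the `cg_trajectory` object (positions, image
# flags, topology, box, run log); a plain-text extended-XYZ export/import
# is provided for interchange with other MD tooling.

#' Write / read a trajectory container
#'
#' Round-trips the full `cg_trajectory` object (wrapped positions, image
#' flags, species and molecule ids, run log, final velocities) bit-exactly.
#'
#' @param traj a `cg_trajectory`.
#' @param path file path.
#' @return `read_trajectory` returns the `cg_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cg_trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  if (!inherits(traj, "cg_trajectory"))
    stop("not a condensr trajectory file: ", path)
  traj
}

#' Write one frame in extended-XYZ format
#'
#' Format: atom count; a comment line `step=<s> time_fs=<t> box=<L>`; then
#' one line per particle: `species x y z ix iy iz mol`.  Coordinates are
#' printed with 17 significant digits so doubles round-trip bit-exactly.
#'
#' @param con open writable connection.
#' @param config a `cg_configuration`.
#' @param topology a `cg_topology` (species names and molecule ids).
#' @export
write_frame <- function(con, config, topology) {
  n <- nrow(config$pos)
  writeLines(as.character(n), con)
  writeLines(sprintf("step=%d time_fs=%.17g box=%.17g", config$step,
                     config$time_fs, config$box), con)
  sp <- topology$species_names[topology$type]
  writeLines(sprintf("%s %.17g %.17g %.17g %d %d %d %d", sp,
                     config$pos[, 1], config$pos[, 2], config$pos[, 3],
                     config$img[, 1], config$img[, 2], config$img[, 3],
                     topology$molecule), con)
  invisible(con)
}

#' Read one extended-XYZ frame
#'
#' @param con open readable connection.
#' @return list with `config` fields and `species`, `molecule`; `NULL` at
#'   end of file.  A truncated frame raises an error.
#' @export
read_frame <- function(con) {
  hdr <- readLines(con, n = 1)
  if (!length(hdr)) return(NULL)
  n <- as.integer(hdr)
  if (is.na(n)) stop("corrupt XYZ frame header: ", hdr)
  meta <- readLines(con, n = 1)
  body <- readLines(con, n = n)
  if (length(body) < n)
    stop("truncated XYZ frame: expected ", n, " particle lines, got ",
         length(body))
  kv <- regmatches(meta, gregexpr("[a-z_]+=[^ ]+", meta))[[1]]
  vals <- setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  parts <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
  list(species = parts[, 1],
       pos = matrix(as.numeric(parts[, 2:4]), n, 3),
       img = matrix(as.integer(parts[, 5:7]), n, 3),
       molecule = as.integer(parts[, 8]),
       step = as.integer(vals[["step"]]),
       time_fs = as.numeric(vals[["time_fs"]]),
       box = as.numeric(vals[["box"]]))
}

#' Export a trajectory to extended XYZ
#' @param traj a `cg_trajectory`.
#' @param path output file path.
#' @export
export_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(traj)))
    write_frame(con, get_frame(traj, i), traj$topology)
  invisible(path)
}

#' Import an extended-XYZ trajectory
#'
#' Rebuilds a `cg_trajectory` (without bonded topology, which XYZ does not
#' carry) from a file written by [export_xyz()].
#'
#' @param path XYZ file path.
#' @param species_names species labels, in type order.
#' @return a `cg_trajectory`.
#' @export
import_xyz <- function(path, species_names = c("P", "D")) {
  con <- file(path, "r")
  on.exit(close(con))
  frames <- list()
  first <- NULL
  repeat {
    fr <- read_frame(con)
    if (is.null(fr)) break
    if (is.null(first)) first <- fr
    frames[[length(frames) + 1L]] <-
      list(step = fr$step, time_fs = fr$time_fs, pos = fr$pos,
           img = fr$img)
  }
  if (!length(frames)) {
    traj <- new_trajectory(topology(integer(0), integer(0),
                                    species_names = species_names),
                           NULL, NULL, box = 1)
    return(traj)
  }
  type <- match(first$species, species_names)
  if (anyNA(type)) stop("unknown species labels in XYZ file")
  topo <- topology(type, first$molecule, species_names = species_names)
  traj <- new_trajectory(topo, NULL, NULL, box = first$box)
  traj$frames <- frames
  traj$final_step <- frames[[length(frames)]]$step
  traj
}
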