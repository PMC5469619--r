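# Trajectory container: time series of species densities (and mediator
# concentrations) with dilution-event markers.

new_trajectory <- function(times, species, mediators = NULL,
                           dilution_times = numeric(0), meta = list()) {
  stopifnot(is.matrix(species), length(times) == nrow(species))
  structure(list(times = times, species = species, mediators = mediators,
                 dilution_times = dilution_times, meta = meta),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, t in [",
      signif(min(x$times), 4), ", ", signif(max(x$times), 4), "] h\n",
      sep = "")
  cat("  species:  ", paste(colnames(x$species), collapse = ", "), "\n")
  if (!is.null(x$mediators))
    cat("  mediators:", paste(colnames(x$mediators), collapse = ", "), "\n")
  cat("  dilutions:", length(x$dilution_times), "\n")
  invisible(x)
}

#' Interpolate species densities of a trajectory at given times
#'
#' Linear interpolation of each species' density series.
#'
#' @param traj A trajectory.
#' @param times Times (hours) within the trajectory's range.
#' @return Matrix `length(times)` x n_species.
#' @export
trajectory_at <- function(traj, times) {
  if (min(times) < min(traj$times) - 1e-9 ||
      max(times) > max(traj$times) + 1e-9)
    stop("requested times fall outside the trajectory")
  out <- vapply(seq_len(ncol(traj$species)), function(j)
    approx(traj$times, traj$species[, j], xout = times, rule = 2)$y,
    numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  colnames(out) <- colnames(traj$species)
  out
}

#' Extract the state of a trajectory at a time point
#'
#' @param traj A trajectory.
#' @param time Time (hours).
#' @return Named vector of species densities (mediators appended when
#'   present, prefixed by their ids).
#' @export
trajectory_state <- function(traj, time) {
  sp <- drop(trajectory_at(traj, time))
  names(sp) <- colnames(traj$species)
  if (!is.null(traj$mediators)) {
    md <- vapply(seq_len(ncol(traj$mediators)), function(j)
      approx(traj$times, traj$mediators[, j], xout = time, rule = 2)$y, 0)
    names(md) <- colnames(traj$mediators)
    sp <- c(sp, md)
  }
  sp
}

#' Write / read a trajectory as tidy text files
#'
#' The time series is written as a CSV with one row per time point and one
#' column per state variable, plus a JSON sidecar (`<path>.meta.json`)
#' holding dilution-event times and provenance metadata.
#'
#' @param traj A trajectory.
#' @param path CSV file path.
#' @return `path` (write) or a trajectory (read).
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$species, check.names = FALSE)
  if (!is.null(traj$mediators))
    df <- cbind(df, as.data.frame(traj$mediators))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(species = colnames(traj$species),
               mediators = if (!is.null(traj$mediators))
                 colnames(traj$mediators),
               dilution_times = traj$dilution_times,
               meta = traj$meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  side <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  sp <- as.matrix(df[, side$species, drop = FALSE])
  md <- if (!is.null(side$mediators) && length(side$mediators))
    as.matrix(df[, side$mediators, drop = FALSE])
  new_trajectory(df$time, sp, md,
                 dilution_times = as.numeric(side$dilution_times),
                 meta = as.list(side$meta))
}

#' Species fractions of a trajectory
#'
#' @param traj A trajectory.
#' @return Matrix of per-time-point species fractions.
#' @export
species_fractions <- function(traj) {
  tot <- rowSums(traj$species)
  sweep(traj$species, 1, pmax(tot, .Machine$double.xmin), "/")
}
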