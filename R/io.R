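#' Persist and reload trajectories
#'
#' A trajectory container is a directory holding `header.json` (model
#' provenance, distribution specs, seeds, integration settings — everything
#' needed to rebuild the run) and `trajectory.rds` (the sampled `x`/`a`
#' matrices). `export_trajectory_csv()` writes selected neurons in long CSV
#' form for plotting outside R.
#'
#' @param traj A [trajectory][integrate_network].
#' @param path Directory to create/read.
#' @param model Optional [network_model][build_network] whose metadata is
#'   embedded in the header.
#' @return `write_trajectory()`: `path`, invisibly. `read_trajectory()`: the
#'   trajectory with a `header` attribute.
#' @export
write_trajectory <- function(traj, path, model = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  header <- list(
    t0 = traj$t0, dt = traj$dt, steps = nrow(traj$x), N = ncol(traj$x),
    has_a = !is.null(traj$a), has_u = !is.null(traj$u),
    model_ref = traj$model_ref,
    model_metadata = if (!is.null(model)) model$metadata else NULL
  )
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(traj, file.path(path, "trajectory.rds"))
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(file.path(path, "trajectory.rds"))
  attr(traj, "header") <- jsonlite::read_json(file.path(path, "header.json"))
  traj
}

#' @rdname write_trajectory
#' @param file CSV file path.
#' @param neurons Neuron indices to export.
#' @export
export_trajectory_csv <- function(traj, file, neurons = seq_len(ncol(traj$x))) {
  utils::write.csv(as_tibble.trajectory(traj, neurons = neurons), file,
                   row.names = FALSE)
  invisible(file)
}
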