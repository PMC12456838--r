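#' Run a named experiment from a config
#'
#' The experiment driver behind the command-line interface. A config is a
#' JSON-compatible list with at least `experiment` and `seed`; each
#' experiment reads its own fields (see Details). Every run writes its
#' artifacts plus the fully resolved config (`config.json`) into `outdir`,
#' so any artifact is reproducible from what sits next to it.
#'
#' Experiments and their main outputs:
#' * `simulate` — integrate a network (or single neuron); trajectory
#'   container + `trajectory.csv` of selected neurons.
#' * `gc` — analytic critical coupling for a distribution spec; `gc.json`
#'   with `gc`, `omega_star`, `method`. Grids over a parameter are emitted
#'   as `gc_grid.csv`.
#' * `phase-diagram` — [phase_diagram()]; `phase_diagram.csv`.
#' * `eigen` — [eigenspectrum()]; `eigenvalues.csv` (columns `re`, `im`).
#' * `lyapunov` — [lyapunov_curve()]; `lyapunov.csv`.
#' * `memory-capacity` — [capacity_curve()] (or a single
#'   [run_memory_capacity()] when `g` is scalar); `memory_capacity.csv`.
#' * `impulse` — [impulse_response_experiment()]; `impulse.csv`.
#' * `fixtures` — [fixture_suite()]; one trajectory container per fixture.
#'
#' @param config A named list, or a path to a JSON file containing one.
#' @param outdir Output directory (default `config$outdir`, else tempdir).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of the result objects keyed by artifact name.
#' @export
run_experiment <- function(config, outdir = NULL, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$experiment)) {
    abort_param("config must name an `experiment`.")
  }
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(outdir)) outdir <- config$outdir %||% tempfile("hetnetdyn_run_")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config$outdir <- outdir
  say <- function(...) if (!quiet) message(sprintf(...))
  say("[hetnetdyn] experiment=%s seed=%s outdir=%s",
      config$experiment, config$seed, outdir)

  dists <- function() list(
    gamma_dist = dist_from_list(config$gamma_dist),
    beta_dist = dist_from_list(config$beta_dist)
  )
  results <- switch(config$experiment,
    "simulate" = {
      d <- dists()
      model <- build_network(d$gamma_dist, d$beta_dist, N = config$N,
                             g = config$g, seed = config$seed)
      input <- config_input(config)
      x0 <- if (isTRUE(config$random_init)) {
        with_rng(sub_seed(config$seed, "init"), stats::rnorm(config$N))
      } else NULL
      tr <- integrate_network(model, input, x0 = x0,
                              dt = config$dt %||% 0.02,
                              T_total = config$T_total,
                              seed = sub_seed(config$seed, "input"))
      write_trajectory(tr, file.path(outdir, "trajectory"), model = model)
      sel <- config$export_neurons %||% seq_len(min(10, config$N))
      export_trajectory_csv(tr, file.path(outdir, "trajectory.csv"),
                            neurons = sel)
      list(trajectory = tr)
    },
    "gc" = {
      d <- dists()
      cc <- critical_coupling(d$gamma_dist, d$beta_dist)
      jsonlite::write_json(
        list(gc = cc$gc, omega_star = cc$omega_star, method = cc$method),
        file.path(outdir, "gc.json"), auto_unbox = TRUE, digits = NA
      )
      list(gc = cc)
    },
    "phase-diagram" = {
      spec_fn <- config_spec_fn(config)
      pd <- phase_diagram(config$het, config$g, spec_fn,
                          N = config$N %||% 500, seed = config$seed,
                          T_run = config$T_run %||% 200,
                          T_trans = config$T_trans %||% 50,
                          dt = config$dt %||% 0.02)
      utils::write.csv(pd, file.path(outdir, "phase_diagram.csv"),
                       row.names = FALSE)
      list(phase_diagram = pd)
    },
    "eigen" = {
      d <- dists()
      model <- build_network(d$gamma_dist, d$beta_dist, N = config$N,
                             g = config$g, seed = config$seed)
      es <- eigenspectrum(model)
      utils::write.csv(as_tibble.eigen_spectrum(es),
                       file.path(outdir, "eigenvalues.csv"), row.names = FALSE)
      list(eigen = es)
    },
    "lyapunov" = {
      d <- dists()
      cv <- lyapunov_curve(config$g, d$gamma_dist, d$beta_dist,
                           N = config$N %||% 500, seed = config$seed,
                           dt = config$dt %||% 0.02,
                           T_trans = config$T_trans %||% 50,
                           T_measure = config$T_measure %||% 200,
                           n_init = config$n_init %||% 10)
      utils::write.csv(cv, file.path(outdir, "lyapunov.csv"),
                       row.names = FALSE)
      list(lyapunov = cv)
    },
    "memory-capacity" = {
      d <- dists()
      cv <- capacity_curve(config$g, d$gamma_dist, d$beta_dist,
                           N = config$N %||% 300, seed = config$seed,
                           sigma_in = config$sigma_in %||% 0.1,
                           dt = config$dt %||% 0.02,
                           T = config$T %||% 400)
      utils::write.csv(cv, file.path(outdir, "memory_capacity.csv"),
                       row.names = FALSE)
      list(memory_capacity = cv)
    },
    "impulse" = {
      d <- dists()
      model <- build_network(d$gamma_dist, d$beta_dist, N = config$N,
                             g = config$g, seed = config$seed)
      pr <- impulse_response_experiment(
        model, amplitude = config$amplitude %||% 1,
        t_on = config$t_on %||% 5, duration = config$duration %||% 0.5,
        dt = config$dt %||% 0.02
      )
      utils::write.csv(pr, file.path(outdir, "impulse.csv"),
                       row.names = FALSE)
      list(impulse = pr)
    },
    "fixtures" = {
      fx <- fixture_suite(config$seed)
      for (nm in names(fx$trajectories)) {
        write_trajectory(fx$trajectories[[nm]], file.path(outdir, nm))
      }
      list(fixtures = fx)
    },
    abort_param(sprintf("unknown experiment '%s'", config$experiment))
  )
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("[hetnetdyn] done: %s", paste(names(results), collapse = ", "))
  invisible(results)
}

config_input <- function(config) {
  inp <- config$input
  if (is.null(inp)) return(input_none())
  switch(inp$kind %||% "none",
    none = input_none(),
    pulse_train = input_pulse_train(as.data.frame(inp$events),
                                    inp$targets %||% "all"),
    shared_white_noise = input_white_noise(inp$sigma_in %||% 0.1,
                                           inp$weights %||% 1),
    abort_param("unknown input kind in config.")
  )
}

# Heterogeneity-axis spec builder for phase-diagram configs: the config
# names which distribution parameter the axis drives.
config_spec_fn <- function(config) {
  axis <- config$axis %||% "p"
  base_gamma <- config$gamma_dist
  base_beta <- config$beta_dist
  function(h) {
    gd <- base_gamma
    bd <- base_beta
    if (axis == "p") gd$p <- h
    if (axis == "sigma_beta") {
      bd$sigma <- h
      bd$lo <- bd$mu - 4 * max(h, 1e-6)
    }
    list(gamma_dist = dist_from_list(gd), beta_dist = dist_from_list(bd))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canned small fixtures for tests and documentation
#'
#' Deterministically regenerates, from one seed: the two single-neuron pulse
#' demonstrations (`fig_gpa`, a graded-persistent neuron with `gamma = 0.51,
#' beta = 0.5` whose plateau steps up with depolarizing and down with
#' hyperpolarizing pulses; `fig_normal`, a normal neuron with `gamma = 10`),
#' an uncoupled linear-oracle network, and a small two-point network below
#' and above its critical coupling.
#'
#' @param seed Integer seed.
#' @return A list with `models`, `trajectories` and `pulse_protocol`.
#' @export
fixture_suite <- function(seed = 1) {
  pulses <- data.frame(
    t_start = c(10, 30, 50, 70, 90),
    t_end = c(12, 32, 52, 72, 92),
    amplitude = c(1, 1, 1, -1, -1)
  )
  fig_gpa <- single_neuron_pulse_response(0.51, 0.5, pulses, T_total = 110)
  fig_normal <- single_neuron_pulse_response(10, 0.5, pulses, T_total = 110)
  linear_net <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
                              N = 20, g = 0, seed = sub_seed(seed, "linear"),
                              activation = "linear")
  gc <- critical_coupling_two_point(0.5, 1, 10, 0.5)$gc
  below <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
                         N = 100, g = 0.5 * gc, seed = sub_seed(seed, "below"))
  above <- build_network(dist_two_point(0.5, 1, 10), dist_constant(0.5),
                         N = 100, g = 1.5 * gc, seed = sub_seed(seed, "above"))
  list(
    models = list(
      fig_gpa = list(gamma = 0.51, beta = 0.5),
      fig_normal = list(gamma = 10, beta = 0.5),
      linear_oracle = linear_net,
      two_point_below = below, two_point_above = above
    ),
    trajectories = list(fig_gpa = fig_gpa, fig_normal = fig_normal),
    pulse_protocol = pulses
  )
}
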