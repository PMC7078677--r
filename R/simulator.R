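#' Move the membrane for one time interval
#'
#' Integrates the overdamped equation of motion
#' \deqn{dx^k/dt = \zeta\,(F_{mem}(x^k) + F_{fil}(x^k))}
#' over `dt` with the classical Runge-Kutta scheme.  The membrane force is
#' re-evaluated at every Runge-Kutta stage while the actin force field
#' `ffil` is held constant over the whole interval.  Fixed vertices do not
#' move.  If any free vertex would travel farther than `d_tol` within an
#' interval, the interval is halved recursively (up to `max_depth` halvings)
#' and both halves are integrated.
#'
#' @param mesh A `spine_mesh` object.
#' @param ffil Actin force field: `n x 2` matrix, held constant (use zeros
#'   for pure membrane relaxation).
#' @param params A [spine_params()] object.
#' @param dt Interval length (s); defaults to `params$dt`.
#' @param max_depth Maximum number of recursive halvings (default 25).
#' @return The moved `spine_mesh`.
#' @export
move_membrane <- function(mesh, ffil, params, dt = params$dt,
                          max_depth = 25L) {
  assert_mesh(mesh)
  stopifnot(is.matrix(ffil), nrow(ffil) == nrow(mesh$positions),
            ncol(ffil) == 2)
  pos <- rk4_move_cpp(mesh$positions, mesh$fixed, ffil, params$P, params$tau,
                      params$kappa, params$zeta, dt, params$d_tol,
                      as.integer(max_depth))
  new_spine_mesh(pos, mesh$fixed, h_PSD = mesh$h_PSD, h_neck = mesh$h_neck,
                 delta_s = mesh$delta_s)
}

#' Create a simulation state
#'
#' Bundles mesh, foci table, clock and parameters into the mutable state
#' advanced by [simulation_step()].
#'
#' @param mesh A `spine_mesh` object (typically the relaxed resting shape).
#' @param params A [spine_params()] object.
#' @param foci A foci data frame; defaults to none.
#' @param t Simulation time (s).
#' @return An object of class `spine_state`.
#' @export
spine_state <- function(mesh, params, foci = empty_foci(), t = 0) {
  assert_mesh(mesh)
  structure(list(mesh = mesh, foci = foci, t = t, params = params,
                 next_id = if (nrow(foci)) max(foci$id) + 1L else 1L,
                 lifetimes = data.frame(id = integer(), birth = numeric(),
                                        death = numeric(),
                                        lifetime = numeric())),
            class = "spine_state")
}

#' Advance the coupled simulation by one time-step
#'
#' One tick of length `dt`: (1) evaluate the membrane force field; (2) update
#' every focus with the stochastic event sweep, using the membrane force
#' magnitude at its centre vertex as the Brownian-ratchet load; (3) remove
#' foci that reached zero barbed ends, logging their lifetimes; (4) with
#' probability `dt * gamma_f` attempt to nucleate one new focus; (5) evaluate
#' the actin force field; (6) move the membrane ([move_membrane()]); (7)
#' remesh and re-map focus centres to the nearest surviving vertices; (8)
#' advance the clock.
#'
#' @param state A `spine_state` object.
#' @return The updated `spine_state`.
#' @export
simulation_step <- function(state) {
  stopifnot(inherits(state, "spine_state"))
  p <- state$params
  mesh <- state$mesh
  foci <- state$foci

  fmem <- membrane_force(mesh, p)

  if (nrow(foci) > 0L) {
    load <- sqrt(fmem[foci$center, 1]^2 + fmem[foci$center, 2]^2)
    gamma0 <- p$phi * p$k_on * p$delta * p$a
    for (i in seq_len(nrow(foci))) {
      out <- step_focus_cpp(foci$m_c[i], foci$m_u[i], load[i], p$dt, gamma0,
                            p$delta, p$kBT, p$gamma_cap, p$gamma_uncap,
                            p$gamma_sever)
      foci$m_c[i] <- out[1]
      foci$m_u[i] <- out[2]
    }
    dead <- (foci$m_c + foci$m_u) == 0L
    if (any(dead)) {
      death_t <- state$t + p$dt
      state$lifetimes <- rbind(state$lifetimes, data.frame(
        id = foci$id[dead], birth = foci$birth[dead], death = death_t,
        lifetime = death_t - foci$birth[dead]))
      foci <- foci[!dead, , drop = FALSE]
    }
  }

  if (p$gamma_f > 0 && stats::runif(1) < p$dt * p$gamma_f) {
    nf <- nucleate_focus(mesh, p, t = state$t, id = state$next_id)
    if (!is.null(nf)) {
      foci <- rbind(foci, nf)
      state$next_id <- state$next_id + 1L
    }
  }

  ffil <- actin_force_field(mesh, foci, p)
  moved <- move_membrane(mesh, ffil, p)
  remeshed <- remesh(moved, p)
  foci <- remap_focus_centers(foci, moved$positions, remeshed)

  state$mesh <- remeshed
  state$foci <- foci
  state$t <- state$t + p$dt
  state
}

#' Run a full spine simulation
#'
#' Relaxes the initial mesh to the resting shape, inserts `n_f0` initial
#' polymerization foci with the standard nucleation rule, then advances the
#' coupled actin-membrane dynamics for `duration` seconds, recording the
#' enclosed area, number of active foci and mean barbed-end count at every
#' step, plus periodic mesh snapshots.
#'
#' @param params A [spine_params()] object.
#' @param duration Simulated time after initialization (s).
#' @param seed Integer seed; `set.seed(seed)` is called when non-`NULL`.
#' @param snapshot_interval Interval between mesh snapshots (s); `Inf`
#'   disables all but the initial snapshot.
#' @param mesh Optional pre-relaxed `spine_mesh` to reuse (with attribute or
#'   argument `A_s`); when `NULL` the mesh is built and relaxed internally.
#' @param A_s Resting area matching `mesh` when supplied.
#' @param progress_every Emit a progress message every this many steps
#'   (`Inf` = silent).
#' @return An object of class `spine_trace`: a list with per-record vectors
#'   `time`, `area`, `n_f`, `mean_B` (the first record is the state after
#'   focus insertion, before any step), the focus `lifetimes` log, `snapshots`
#'   (named list of meshes, names = time in seconds), `A_s`, `params`,
#'   `seed`, and the `final_state`.
#' @export
run_simulation <- function(params, duration, seed = NULL,
                           snapshot_interval = 15, mesh = NULL, A_s = NULL,
                           progress_every = Inf) {
  stopifnot(duration >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mesh)) {
    rest <- relax_to_rest(init_spine_mesh(params), params)
    mesh <- rest$mesh
    A_s <- rest$A_s
  } else {
    assert_mesh(mesh)
    if (is.null(A_s)) A_s <- compute_geometry(mesh)$area_enclosed
  }

  foci <- empty_foci()
  for (i in seq_len(params$n_f0)) {
    nf <- nucleate_focus(mesh, params, t = 0, id = i)
    if (!is.null(nf)) foci <- rbind(foci, nf)
  }
  state <- spine_state(mesh, params, foci = foci, t = 0)
  state$next_id <- params$n_f0 + 1L

  n_steps <- round(duration / params$dt)
  time <- area <- mean_b <- numeric(n_steps + 1L)
  n_f <- integer(n_steps + 1L)
  snapshots <- list()
  record <- function(idx) {
    time[idx] <<- state$t
    area[idx] <<- geom_report_cpp(state$mesh$positions)$area
    n_f[idx] <<- nrow(state$foci)
    mean_b[idx] <<- if (nrow(state$foci))
      mean(state$foci$m_c + state$foci$m_u) else NA_real_
  }
  record(1L)
  snapshots[["0"]] <- state$mesh
  next_snap <- snapshot_interval

  for (s in seq_len(n_steps)) {
    state <- simulation_step(state)
    record(s + 1L)
    if (state$t >= next_snap - 1e-9) {
      snapshots[[format(next_snap)]] <- state$mesh
      next_snap <- next_snap + snapshot_interval
    }
    if (is.finite(progress_every) && s %% progress_every == 0) {
      message(sprintf("step %d/%d  t=%.1f s  area=%.4f  n_f=%d", s, n_steps,
                      state$t, area[s + 1L], n_f[s + 1L]))
    }
  }

  structure(list(time = time, area = area, n_f = n_f, mean_B = mean_b,
                 lifetimes = state$lifetimes, snapshots = snapshots,
                 A_s = A_s, params = params, seed = seed,
                 final_state = state),
            class = "spine_trace")
}

#' @export
print.spine_trace <- function(x, ...) {
  cat(sprintf(
    "<spine_trace> %d records over %.1f s; area %.4f-%.4f um^2 (A_s = %.4f); %d foci died\n",
    length(x$time), max(x$time), min(x$area), max(x$area), x$A_s,
    nrow(x$lifetimes)))
  invisible(x)
}

#' Write a simulation trace as CSV
#'
#' Columns `t`, `area`, `n_f`, `mean_B`; one row per record.
#'
#' @param trace A `spine_trace` object.
#' @param path Output file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$time, area = trace$area,
                              n_f = trace$n_f, mean_B = trace$mean_B),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV file with columns `t`, `area`, `n_f`, `mean_B`.
#' @return A bare `spine_trace` (no snapshots, lifetimes or final state).
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  structure(list(time = df$t, area = df$area, n_f = df$n_f,
                 mean_B = df$mean_B, lifetimes = NULL, snapshots = list(),
                 A_s = NA_real_, params = NULL, seed = NULL,
                 final_state = NULL),
            class = "spine_trace")
}

#' Parameter sweep with replicate simulations
#'
#' For each value of one model parameter, runs `n_replicates` independent
#' simulations (distinct seeds, fresh initial foci) and summarises each run
#' by its mean area, area standard deviation, mean focus lifetime and mean
#' number of active foci.  Used to map how fluctuation statistics respond to
#' the branching amplitude, nucleation rate and location, kernel width, and
#' the other tunable parameters.
#'
#' @param base A [spine_params()] object supplying all other parameters.
#' @param param_name Name of the parameter to vary.
#' @param values Vector of values to assign to `param_name`.
#' @param n_replicates Replicates per value.
#' @param replicate_duration Duration of each replicate (s).
#' @param seeds Integer vector of seeds, one per run
#'   (`length(values) * n_replicates`); defaults to `1:n_runs`.
#' @param snapshot_interval Passed to [run_simulation()] (`Inf` keeps sweeps
#'   light).
#' @return A data frame with one row per run: `param`, `value`, `replicate`,
#'   `seed`, `mean_area`, `sd_area`, `mean_lifetime`, `mean_n_f`.
#' @export
run_sweep <- function(base, param_name, values, n_replicates = 15,
                      replicate_duration = 15 * 60, seeds = NULL,
                      snapshot_interval = Inf) {
  stopifnot(param_name %in% names(base))
  n_runs <- length(values) * n_replicates
  if (is.null(seeds)) seeds <- seq_len(n_runs)
  stopifnot(length(seeds) == n_runs)
  # the resting shape depends only on the membrane-mechanics parameters, so
  # it can be relaxed once and shared whenever the varied parameter does not
  # touch them
  mech <- c("delta_s", "r_s", "r_neck", "r_PSD", "P", "tau", "kappa",
            "zeta", "dt", "d_tol", "d_min", "d_max")
  shared_rest <- if (param_name %in% mech) NULL else
    relax_to_rest(init_spine_mesh(base), base)
  rows <- vector("list", n_runs)
  i <- 0L
  for (v in values) {
    args <- unclass(base)
    args[[param_name]] <- v
    if (param_name == "delta_s") {
      # let the remeshing bounds follow the new target edge length
      args$d_min <- NULL
      args$d_max <- NULL
    }
    args <- args[names(args) %in% names(formals(spine_params))]
    p <- do.call(spine_params, args)
    rest_v <- if (is.null(shared_rest)) relax_to_rest(init_spine_mesh(p), p)
              else shared_rest
    for (r in seq_len(n_replicates)) {
      i <- i + 1L
      tr <- run_simulation(p, replicate_duration, seed = seeds[i],
                           snapshot_interval = snapshot_interval,
                           mesh = rest_v$mesh, A_s = rest_v$A_s)
      rows[[i]] <- data.frame(
        param = param_name, value = v, replicate = r, seed = seeds[i],
        mean_area = mean(tr$area), sd_area = stats::sd(tr$area),
        mean_lifetime = if (nrow(tr$lifetimes))
          mean(tr$lifetimes$lifetime) else NA_real_,
        mean_n_f = mean(tr$n_f))
    }
  }
  do.call(rbind, rows)
}
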