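#' Per-filament branching rate under membrane load
#'
#' Brownian-ratchet attenuated branching rate of a single filament in a focus
#' with `B` uncapped barbed ends facing a membrane load of magnitude
#' `F_norm`:
#' \deqn{\gamma_{branch} = \phi k_{on} \delta a \,
#'   e^{-F \delta / (k_B T \, B)} / B.}
#' The free treadmilling velocity \eqn{\phi k_{on} \delta a} is shared by the
#' `B` barbed ends of the focus (the `1/B` factor), and the load is likewise
#' distributed over them inside the exponential.  The per-step branching
#' probability of one filament is `dt * rate`, clamped to `[0, 1]`.
#'
#' @param F_norm Magnitude of the membrane force at the focus centre (pN).
#' @param B Number of uncapped barbed ends in the focus (>= 1).
#' @param params A [spine_params()] object.
#' @return Branching rate per filament (1/s).
#' @examples
#' branching_rate(0, 1, spine_params())   # 7.2732
#' @export
branching_rate <- function(F_norm, B, params) {
  if (any(B < 1)) stop("branching rate undefined for a dead focus (B = 0)",
                       call. = FALSE)
  if (any(F_norm < 0)) stop("'F_norm' must be non-negative", call. = FALSE)
  gamma0 <- params$phi * params$k_on * params$delta * params$a
  gamma0 * exp(-F_norm * params$delta / (params$kBT * B)) / B
}

#' Advance a focus state by one time-step
#'
#' Performs the stochastic per-filament event sweep for one time-step of
#' length `dt`.  Every filament present at the start of the step is visited
#' once; events are drawn in the order: (1) branch (daughter filament added
#' with Arp2/3-capped minus end, not visited this step), (2) barbed-end
#' capping (filament eliminated, later events skipped), (3) minus-end
#' uncapping, (4) severing of an uncapped minus end (filament removed).  The
#' branching probability uses the barbed-end count `B` frozen at the start of
#' the step.  A focus with `B = 0` is dead and must not be stepped.
#'
#' @param state A list or named vector with integer counts `m_c` (minus end
#'   capped) and `m_u` (minus end uncapped).
#' @param F_norm Magnitude of the membrane force at the focus centre (pN).
#' @param params A [spine_params()] object.
#' @return A list with updated `m_c`, `m_u` and their sum `B`.
#' @export
step_focus_state <- function(state, F_norm, params) {
  m_c <- as.integer(state[["m_c"]])
  m_u <- as.integer(state[["m_u"]])
  if (m_c + m_u < 1L)
    stop("cannot step a dead focus (B = 0); remove it first", call. = FALSE)
  gamma0 <- params$phi * params$k_on * params$delta * params$a
  out <- step_focus_cpp(m_c, m_u, F_norm, params$dt, gamma0, params$delta,
                        params$kBT, params$gamma_cap, params$gamma_uncap,
                        params$gamma_sever)
  list(m_c = out[1], m_u = out[2], B = out[1] + out[2])
}

#' Deterministic steady state of the barbed-end count
#'
#' Rate-equation twin of the stochastic focus model, with `B` treated as
#' continuous.  At stationarity
#' \deqn{m_c^* = \hat\gamma(B^*) / (\gamma_{uncap} + \gamma_{cap}), \quad
#'   m_u^* = \gamma_{uncap} m_c^* / (\gamma_{sever} + \gamma_{cap}),}
#' with the total per-focus branching rate
#' \eqn{\hat\gamma(B) = \phi k_{on} \delta a\, e^{-F\delta/(k_B T B)}}, and
#' `B* = m_c* + m_u*` solved by root finding.  The largest positive root is
#' returned (the stable fixed point); when no positive root exists the
#' function returns 0 with attribute `root_found = FALSE`.
#'
#' @param F_norm Magnitude of the opposing membrane force (pN).
#' @param params A [spine_params()] object.
#' @return The stationary barbed-end count `B*` (continuous), with attribute
#'   `root_found`.
#' @examples
#' steady_state_barbed_ends(0, spine_params())  # ~7.156
#' @export
steady_state_barbed_ends <- function(F_norm, params) {
  stopifnot(F_norm >= 0)
  gamma0 <- params$phi * params$k_on * params$delta * params$a
  # multiplier from m_c* to B*
  mult <- (1 + params$gamma_uncap / (params$gamma_sever + params$gamma_cap)) /
    (params$gamma_uncap + params$gamma_cap)
  c0 <- gamma0 * mult
  q <- F_norm * params$delta / params$kBT
  if (q == 0) {
    return(structure(c0, root_found = TRUE))
  }
  g <- function(B) c0 * exp(-q / B) - B
  # g < 0 near 0+ and for large B; a positive root requires max(g) > 0
  upper <- c0 + 1
  opt <- stats::optimize(g, interval = c(1e-8, upper), maximum = TRUE)
  if (opt$objective <= 0) {
    return(structure(0, root_found = FALSE))
  }
  root <- stats::uniroot(g, lower = opt$maximum, upper = upper,
                         tol = 1e-12)$root
  structure(root, root_found = TRUE)
}

#' Simulate a single polymerization focus to extinction
#'
#' Runs the stochastic focus model at a fixed membrane load until all barbed
#' ends have vanished (or `max_steps` is reached).  The focus starts with all
#' `initial_B` filaments in the minus-capped class, the nascent state of
#' Arp2/3-branched filaments.
#'
#' @param initial_B Initial number of barbed ends (>= 1).
#' @param F_norm Constant opposing membrane force (pN).
#' @param params A [spine_params()] object.
#' @param max_steps Step cap; runs still alive at the cap are censored.
#' @param record_trace Record the barbed-end count after every step?
#' @return A list with `lifetime` (s), `died` (logical; `FALSE` = censored),
#'   `mean_B` (mean barbed ends over the steps before extinction), and
#'   `trace` (integer vector, or `NULL` when not recorded).
#' @export
simulate_focus <- function(initial_B, F_norm, params, max_steps = 2e6,
                           record_trace = FALSE) {
  stopifnot(initial_B >= 1, F_norm >= 0)
  gamma0 <- params$phi * params$k_on * params$delta * params$a
  simulate_focus_cpp(as.integer(initial_B), F_norm, params$dt, gamma0,
                     params$delta, params$kBT, params$gamma_cap,
                     params$gamma_uncap, params$gamma_sever,
                     as.integer(max_steps), record_trace)
}

#' Single-focus Monte Carlo ensemble
#'
#' Repeats [simulate_focus()] over a grid of membrane forces and returns a
#' per-run table of lifetimes and mean barbed-end counts, the raw material of
#' force-vs-lifetime and force-vs-B curves.
#'
#' @param F_values Membrane force magnitudes to simulate (pN).
#' @param n_runs Runs per force value.
#' @param initial_B Initial barbed ends per run.
#' @param params A [spine_params()] object.
#' @param max_steps Per-run step cap.
#' @return A data frame with columns `F_norm`, `run`, `lifetime`, `mean_B`,
#'   `died`.
#' @export
focus_ensemble <- function(F_values, n_runs = 50, initial_B = 1,
                           params = spine_params(), max_steps = 2e6) {
  grid <- expand.grid(run = seq_len(n_runs), F_norm = F_values)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- simulate_focus(initial_B, grid$F_norm[i], params,
                        max_steps = max_steps)
    data.frame(F_norm = grid$F_norm[i], run = grid$run[i],
               lifetime = r$lifetime, mean_B = r$mean_B, died = r$died)
  })
  do.call(rbind, res)
}
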