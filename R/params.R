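#' Model parameters for the spine-shape simulator
#'
#' Constructs the full parameter set of the mechanochemical spine model.
#' Defaults are the reference parameterisation of the 2D model; every value
#' can be overridden by name.  Derived remeshing bounds default to
#' `d_min = (3/5) delta_s` and `d_max = (4/3) delta_s`.
#'
#' @param dt Time-step length (s).
#' @param delta_s Target mesh edge length (um).
#' @param r_s Initial spine radius (um).
#' @param r_neck Neck radius (um); vertices below the matching chord are fixed.
#' @param r_PSD Post-synaptic density radius (um); vertices above the matching
#'   chord are fixed.
#' @param n_f0 Number of polymerization foci inserted after relaxation.
#' @param gamma_cap Barbed-end capping rate (1/s); a capped filament is
#'   eliminated.
#' @param gamma_uncap Minus-end uncapping rate (1/s).
#' @param gamma_sever Severing rate of uncapped minus ends (1/s).
#' @param gamma_f Nucleation rate of new polymerization foci (1/s).
#' @param a Profilin-ATP-actin concentration (uM), constant over a run.
#' @param phi Branching-rate amplitude (1/um^2).
#' @param k_on Barbed-end monomer assembly rate constant (1/(uM s)).
#' @param delta Length of an actin monomer (um).
#' @param kBT Thermal energy (pN um).
#' @param P Pressure difference across the membrane (pN/um^2).
#' @param tau Line tension (pN/um in 2D).
#' @param kappa Bending modulus (pN um).
#' @param alpha Amplitude of the actin force kernel (pN).
#' @param sigma Width of the actin force kernel.
#' @param zeta Mobility converting net force to velocity (um^2/(s pN)).
#' @param lam Length scale of the PSD-distance weighting of nucleation (um).
#' @param nucleation_shell Membrane/PSD proximity radius for nucleation (um).
#' @param d_tol Displacement tolerance per integration interval (um).
#' @param d_min Remeshing lower edge bound (um); default `(3/5) delta_s`.
#' @param d_max Remeshing upper edge bound (um); default `(4/3) delta_s`.
#'
#' @return An object of class `spine_params`: a named list of validated
#'   parameters.
#' @examples
#' p <- spine_params()
#' p$d_max / p$delta_s  # 4/3
#' @export
spine_params <- function(dt = 1 / 8,
                         delta_s = 0.03,
                         r_s = 0.5,
                         r_neck = 0.0995,
                         r_PSD = 0.3571,
                         n_f0 = 4L,
                         gamma_cap = 1,
                         gamma_uncap = 1 / 30,
                         gamma_sever = 1,
                         gamma_f = 0.1,
                         a = 3.8,
                         phi = 75,
                         k_on = 11.6,
                         delta = 0.0022,
                         kBT = 0.0041,
                         P = 85.7143,
                         tau = 15,
                         kappa = 0.18,
                         alpha = 3.8,
                         sigma = 0.3,
                         zeta = 0.002,
                         lam = 0.025,
                         nucleation_shell = 0.1,
                         d_tol = 0.0001,
                         d_min = NULL,
                         d_max = NULL) {
  p <- list(dt = dt, delta_s = delta_s, r_s = r_s, r_neck = r_neck,
            r_PSD = r_PSD, n_f0 = as.integer(n_f0), gamma_cap = gamma_cap,
            gamma_uncap = gamma_uncap, gamma_sever = gamma_sever,
            gamma_f = gamma_f, a = a, phi = phi, k_on = k_on, delta = delta,
            kBT = kBT, P = P, tau = tau, kappa = kappa, alpha = alpha,
            sigma = sigma, zeta = zeta, lam = lam,
            nucleation_shell = nucleation_shell, d_tol = d_tol,
            d_min = if (is.null(d_min)) (3 / 5) * delta_s else d_min,
            d_max = if (is.null(d_max)) (4 / 3) * delta_s else d_max)
  validate_spine_params(p)
  structure(p, class = "spine_params")
}

validate_spine_params <- function(p) {
  pos <- c("dt", "delta_s", "r_s", "a", "k_on", "delta", "kBT", "zeta",
           "lam", "nucleation_shell", "d_tol", "d_min", "d_max")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop(sprintf("parameter '%s' must be a single positive number", nm),
           call. = FALSE)
    }
  }
  nonneg <- c("r_neck", "r_PSD", "gamma_cap", "gamma_uncap", "gamma_sever",
              "gamma_f", "phi", "P", "tau", "kappa", "alpha", "sigma")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] < 0) {
      stop(sprintf("parameter '%s' must be a single non-negative number", nm),
           call. = FALSE)
    }
  }
  if (p$n_f0 < 0L) stop("'n_f0' must be non-negative", call. = FALSE)
  if (p$r_PSD >= p$r_s)
    stop("'r_PSD' must be smaller than the spine radius 'r_s'", call. = FALSE)
  if (p$r_neck >= p$r_s)
    stop("'r_neck' must be smaller than the spine radius 'r_s'", call. = FALSE)
  if (p$d_min >= p$d_max)
    stop("'d_min' must be smaller than 'd_max'", call. = FALSE)
  invisible(p)
}

#' @export
print.spine_params <- function(x, ...) {
  cat("<spine_params>\n")
  nm <- names(x)
  for (i in seq_along(x)) {
    cat(sprintf("  %-18s %s\n", nm[i], format(x[[i]])))
  }
  invisible(x)
}

#' Read model parameters from a key=value configuration file
#'
#' Parses a flat plain-text file with one `name = value` pair per line
#' (`#` starts a comment) whose names mirror the arguments of
#' [spine_params()].  Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A `spine_params` object.
#' @export
read_spine_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(spine_params())
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    stop("malformed configuration line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  known <- names(formals(spine_params))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0L) {
    stop("unknown parameter(s) in configuration: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(spine_params, as.list(stats::setNames(vals, keys)))
}
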