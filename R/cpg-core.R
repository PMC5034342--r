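#' Parameters of the two-neuron Matsuoka oscillator
#'
#' Constructs and validates the parameter set of the mutually inhibitive
#' two-neuron central-pattern-generator (CPG) oscillator. The model is
#' \deqn{\tau_1 \dot x_i = -x_i - \beta v_i - \mu_{ji} y_j + c, \qquad
#'       \tau_2 \dot v_i = -v_i + y_i, \qquad y_i = \max(0, x_i),}
#' with oscillator output \eqn{y_{out} = y_1 - y_2}. Neuron 1 plays the role
#' of the extensor half-center and neuron 2 the flexor; the rectified outputs
#' alternate once the mutual inhibition destabilises the symmetric
#' equilibrium.
#'
#' The defaults are the reference parameter set used throughout the package
#' examples.
#'
#' @param tau1 Membrane time constant (seconds), > 0.
#' @param tau2 Adaptation time constant (seconds), > 0.
#' @param beta Gain of the adaptive self-inhibition, >= 0.
#' @param mu21 Inhibitory weight from neuron 2 onto neuron 1, >= 0.
#' @param mu12 Inhibitory weight from neuron 1 onto neuron 2, >= 0.
#' @param c Tonic external drive shared by both neurons, >= 0. Scales the
#'   oscillation amplitude; the cycle period is invariant to it.
#' @return An object of class `cpg_params` (a named list).
#' @examples
#' p <- cpg_params()
#' tr <- cpg_simulate(p, duration = 4)
#' estimate_frequency(tr, discard = 2)
#' @export
cpg_params <- function(tau1 = 0.10, tau2 = 0.20, beta = 8.44,
                       mu21 = 4.94, mu12 = 6.00, c = 50.6) {
  p <- list(tau1 = tau1, tau2 = tau2, beta = beta,
            mu21 = mu21, mu12 = mu12, c = c)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cpg_params: '", nm, "' must be a single finite number")
  }
  if (tau1 <= 0) stop("cpg_params: tau1 must be > 0")
  if (tau2 <= 0) stop("cpg_params: tau2 must be > 0")
  if (beta < 0 || mu21 < 0 || mu12 < 0 || c < 0)
    stop("cpg_params: beta, mu21, mu12 and c must be >= 0")
  structure(p, class = "cpg_params")
}

#' @export
print.cpg_params <- function(x, ...) {
  cat("Matsuoka CPG parameters:\n")
  cat(sprintf("  tau1 = %g s, tau2 = %g s, beta = %g\n",
              x$tau1, x$tau2, x$beta))
  cat(sprintf("  mu21 = %g, mu12 = %g, c = %g\n", x$mu21, x$mu12, x$c))
  invisible(x)
}

#' Instantaneous state of the CPG oscillator
#'
#' @param x1,x2 Membrane potentials of the two neurons (dimensionless).
#' @param v1,v2 Adaptation (membrane-current) variables.
#' @param t Simulation time in seconds.
#' @return An object of class `cpg_state`.
#' @export
cpg_state <- function(x1 = 0, v1 = 0, x2 = 0, v2 = 0, t = 0) {
  s <- c(x1 = x1, v1 = v1, x2 = x2, v2 = v2, t = t)
  if (!all(is.finite(s))) stop("cpg_state: all components must be finite")
  structure(as.list(s), class = "cpg_state")
}

as_state_vector <- function(state) {
  c(state$x1, state$v1, state$x2, state$v2)
}

cpg_derivatives <- function(s, params) {
  y1 <- max(0, s[1]); y2 <- max(0, s[3])
  c((-s[1] - params$beta * s[2] - params$mu21 * y2 + params$c) / params$tau1,
    (-s[2] + y1) / params$tau2,
    (-s[3] - params$beta * s[4] - params$mu12 * y1 + params$c) / params$tau1,
    (-s[4] + y2) / params$tau2)
}

#' Advance the CPG oscillator by one RK4 step
#'
#' Single fixed step of the classical fourth-order Runge-Kutta scheme.
#' Deterministic: identical inputs give bit-identical output.
#'
#' @param state A [cpg_state()].
#' @param params A [cpg_params()].
#' @param dt Step size in seconds; must satisfy `dt <= tau1 / 10` so the
#'   fastest time constant is resolved.
#' @return The advanced `cpg_state` (time incremented by `dt`).
#' @export
cpg_step <- function(state, params, dt) {
  stopifnot(inherits(state, "cpg_state"), inherits(params, "cpg_params"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("cpg_step: dt must be a single positive number")
  if (dt > params$tau1 / 10)
    stop("cpg_step: dt must be <= tau1/10 (= ", params$tau1 / 10,
         " s) to resolve the membrane dynamics")
  s <- as_state_vector(state)
  if (!all(is.finite(s)))
    stop("cpg_step: non-finite state; the integration has blown up ",
         "(dt too large?)")
  k1 <- cpg_derivatives(s, params)
  k2 <- cpg_derivatives(s + dt / 2 * k1, params)
  k3 <- cpg_derivatives(s + dt / 2 * k2, params)
  k4 <- cpg_derivatives(s + dt * k3, params)
  s2 <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  if (!all(is.finite(s2)))
    stop("cpg_step: state became non-finite; integration blew up ",
         "(dt too large?)")
  cpg_state(s2[1], s2[2], s2[3], s2[4], state$t + dt)
}

#' Simulate the CPG oscillator
#'
#' Integrates the two-neuron oscillator on a uniform time grid with
#' fixed-step RK4 and returns the full trace. If the initial state is
#' exactly symmetric (`x1 == x2` and `v1 == v2`) the symmetric equilibrium
#' would be preserved forever, so a one-off asymmetric perturbation of
#' magnitude `perturbation` is added to `x1` at t = 0 (recorded in the
#' trace attributes).
#'
#' @param params A [cpg_params()].
#' @param duration Total simulated time in seconds (>= 2).
#' @param dt Integration step in seconds (default 1 ms).
#' @param init Optional [cpg_state()] initial condition; default is the
#'   origin (which is then perturbed).
#' @param perturbation Magnitude of the symmetry-breaking perturbation.
#' @return A `cpg_trace`: a data frame with columns `t, x1, v1, x2, v2,
#'   y1, y2, y_out` and attributes `params`, `dt`, `init`, `perturbed`.
#' @export
cpg_simulate <- function(params, duration = 10, dt = 0.001, init = NULL,
                         perturbation = 0.01) {
  stopifnot(inherits(params, "cpg_params"))
  if (duration < 2) stop("cpg_simulate: duration must be >= 2 s")
  if (dt <= 0 || dt > params$tau1 / 10)
    stop("cpg_simulate: dt must be in (0, tau1/10]")
  if (is.null(init)) init <- cpg_state()
  stopifnot(inherits(init, "cpg_state"))
  s0 <- as_state_vector(init)
  if (!all(is.finite(s0))) stop("cpg_simulate: init must be finite")
  perturbed <- FALSE
  if (s0[1] == s0[3] && s0[2] == s0[4]) {
    s0[1] <- s0[1] + perturbation
    perturbed <- TRUE
  }
  n_steps <- round(duration / dt)
  m <- cpg_integrate_cpp(s0, params$tau1, params$tau2, params$beta,
                         params$mu12, params$mu21, params$c, dt, n_steps)
  y1 <- pmax(0, m[, 1]); y2 <- pmax(0, m[, 3])
  tr <- data.frame(t = seq(0, by = dt, length.out = n_steps + 1L),
                   x1 = m[, 1], v1 = m[, 2], x2 = m[, 3], v2 = m[, 4],
                   y1 = y1, y2 = y2, y_out = y1 - y2)
  attr(tr, "params") <- params
  attr(tr, "dt") <- dt
  attr(tr, "init") <- s0
  attr(tr, "perturbed") <- perturbed
  class(tr) <- c("cpg_trace", "data.frame")
  tr
}

#' @rdname cpg_simulate
#' @param object A `cpg_params` object (for the [stats::simulate()] generic).
#' @param nsim,seed Ignored; the oscillator is deterministic.
#' @param ... Passed on to [cpg_simulate()].
#' @export
simulate.cpg_params <- function(object, nsim = 1, seed = NULL, ...) {
  cpg_simulate(object, ...)
}

#' @export
print.cpg_trace <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("CPG trace: %d samples, dt = %g s, duration = %g s\n",
              nrow(x), attr(x, "dt"), x$t[nrow(x)]))
  cat(sprintf("  peak-to-peak y_out (last half): %.4g\n",
              diff(range(x$y_out[x$t >= x$t[nrow(x)] / 2]))))
  print(p)
  invisible(x)
}

#' @export
plot.cpg_trace <- function(x, ...) {
  plot(x$t, x$y_out, type = "l", xlab = "time (s)",
       ylab = expression(y[out]), main = "CPG oscillator output", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Estimate the oscillation frequency of a CPG trace
#'
#' Frequency from the mean interval between rising zero crossings of
#' `y_out` after discarding an initial transient. Crossing times are
#' refined by linear interpolation between the bracketing samples, giving
#' sub-step resolution.
#'
#' @param trace A `cpg_trace`, or any data frame with columns `t` and
#'   `y_out` on a uniform grid.
#' @param discard Transient to drop from the start, in seconds.
#' @return Frequency in Hz; 0 if fewer than 2 rising crossings remain.
#' @export
estimate_frequency <- function(trace, discard = 2) {
  if (!all(c("t", "y_out") %in% names(trace)))
    stop("estimate_frequency: trace must have columns 't' and 'y_out'")
  if (discard >= trace$t[nrow(trace)])
    stop("estimate_frequency: discard (", discard,
         " s) is not shorter than the trace")
  keep <- trace$t >= discard
  y <- trace$y_out[keep]
  t <- trace$t[keep]
  n <- length(y)
  i <- which(y[-n] < 0 & y[-1] >= 0)
  if (length(i) < 2) return(0)
  tc <- t[i] + (t[i + 1] - t[i]) * (-y[i]) / (y[i + 1] - y[i])
  1 / mean(diff(tc))
}

peak_to_peak <- function(x) diff(range(x))

#' Check stability of a CPG parameter set
#'
#' Two verdicts are produced. The *analytic* verdict checks the canonical
#' oscillation conditions by linearization: (i) a nonzero tonic drive
#' \eqn{c > 0}; (ii) no stable winner-take-all lock, which exists when
#' either inhibitory weight reaches \eqn{1 + \beta} (one neuron can then
#' silence the other permanently); (iii) the coexistence equilibrium (both
#' neurons active) is unstable, i.e. the 4x4 Jacobian there has an
#' eigenvalue with positive real part. For symmetric weights these reduce
#' to the familiar two-neuron rules \eqn{\mu > 1 + \tau_1/\tau_2} (onset)
#' and \eqn{\mu < 1 + \beta} (boundedness), which are also reported as
#' diagnostics via the geometric-mean coupling
#' \eqn{g = \sqrt{\mu_{12}\mu_{21}}}. The *empirical* verdict simulates
#' the oscillator and requires a sustained, non-decaying rhythm: the
#' peak-to-peak amplitude of `y_out` over the final window must exceed a
#' floor and be within 5\% of the preceding window. The empirical verdict
#' is authoritative (`stable`); the analytic one is an advisory
#' diagnostic.
#'
#' @param params A [cpg_params()].
#' @param duration,dt Simulation length and step used for the empirical
#'   check.
#' @param window Length (s) of the two trailing comparison windows.
#' @param floor Minimum peak-to-peak amplitude counted as oscillation.
#' @return A `cpg_stability` list: `stable`, `empirical` (list), and
#'   `analytic` (list with both conditions and the combined verdict).
#' @export
check_stability <- function(params, duration = 10, dt = 0.001,
                            window = 2, floor = 1e-3) {
  stopifnot(inherits(params, "cpg_params"))
  g <- sqrt(params$mu12 * params$mu21)
  b1 <- 1 + params$beta
  # coexistence equilibrium (y_i = x_i > 0):
  #   (1+beta) x1 + mu21 x2 = c ; mu12 x1 + (1+beta) x2 = c
  det2 <- b1^2 - params$mu12 * params$mu21
  coex <- if (abs(det2) > .Machine$double.eps^0.5)
    c(x1 = params$c * (b1 - params$mu21) / det2,
      x2 = params$c * (b1 - params$mu12) / det2)
  else c(x1 = NA_real_, x2 = NA_real_)
  unstable_coex <- FALSE
  if (all(is.finite(coex)) && all(coex > 0)) {
    t1 <- params$tau1; t2 <- params$tau2
    J <- rbind(c(-1 / t1, -params$beta / t1, -params$mu21 / t1, 0),
               c(1 / t2, -1 / t2, 0, 0),
               c(-params$mu12 / t1, 0, -1 / t1, -params$beta / t1),
               c(0, 0, 1 / t2, -1 / t2))
    unstable_coex <- max(Re(eigen(J, only.values = TRUE)$values)) > 0
  }
  analytic <- list(
    coupling = g,
    oscillation_condition = g > 1 + params$tau1 / params$tau2,
    boundedness_condition = g < 1 + params$beta,
    no_lock = params$mu12 < b1 && params$mu21 < b1,
    coexistence_unstable = unstable_coex,
    drive_condition = params$c > 0
  )
  analytic$oscillatory <- analytic$no_lock &&
    analytic$coexistence_unstable && analytic$drive_condition
  empirical <- list(oscillatory = FALSE, amp_last = NA_real_,
                    amp_prev = NA_real_, blew_up = FALSE)
  tr <- tryCatch(cpg_simulate(params, duration = duration, dt = dt),
                 error = function(e) NULL)
  if (is.null(tr)) {
    empirical$blew_up <- TRUE
  } else {
    t_end <- tr$t[nrow(tr)]
    last <- tr$y_out[tr$t >= t_end - window]
    prev <- tr$y_out[tr$t >= t_end - 2 * window & tr$t < t_end - window]
    empirical$amp_last <- peak_to_peak(last)
    empirical$amp_prev <- peak_to_peak(prev)
    empirical$oscillatory <- empirical$amp_last > floor &&
      empirical$amp_last >= 0.95 * empirical$amp_prev
  }
  structure(list(stable = empirical$oscillatory,
                 empirical = empirical, analytic = analytic,
                 params = params),
            class = "cpg_stability")
}

#' @export
print.cpg_stability <- function(x, ...) {
  cat("CPG stability report\n")
  cat(sprintf("  stable (empirical, authoritative): %s\n", x$stable))
  cat(sprintf("  empirical amplitude: last %.4g, previous %.4g%s\n",
              x$empirical$amp_last, x$empirical$amp_prev,
              if (x$empirical$blew_up) " [blow-up]" else ""))
  a <- x$analytic
  cat(sprintf(paste0("  analytic (advisory): oscillatory = %s ",
                     "(no lock %s, coexistence unstable %s, drive %s; ",
                     "g = %.3f)\n"),
              a$oscillatory, a$no_lock, a$coexistence_unstable,
              a$drive_condition, a$coupling))
  invisible(x)
}

#' Write a CPG trace to CSV with a JSON metadata sidecar
#'
#' @param trace A `cpg_trace`.
#' @param path Output CSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cpg_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace)[, c("t", "x1", "v1", "x2", "v2",
                                            "y1", "y2", "y_out")],
                   path, row.names = FALSE)
  meta <- list(params = unclass(attr(trace, "params")),
               dt = attr(trace, "dt"),
               init = attr(trace, "init"),
               perturbed = attr(trace, "perturbed"),
               package_version = as.character(utils::packageVersion("neurobypass")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a CPG trace written by [write_cpg_trace()]
#'
#' @param path CSV path.
#' @return A `cpg_trace` data frame (attributes restored from the sidecar
#'   when present).
#' @export
read_cpg_trace <- function(path) {
  tr <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    attr(tr, "params") <- do.call(cpg_params, as.list(meta$params))
    attr(tr, "dt") <- meta$dt
    attr(tr, "init") <- meta$init
    attr(tr, "perturbed") <- meta$perturbed
  }
  class(tr) <- c("cpg_trace", "data.frame")
  tr
}
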