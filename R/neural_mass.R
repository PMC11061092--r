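# Coupled excitatory-inhibitory neural masses on a structural connectome.
#
# Each mass is a lumped alpha-rhythm model: an excitatory population driven
# by extrinsic pulse density and by delayed excitatory pulse density from
# connected masses, with feedback inhibition from a local interneuron
# population. Postsynaptic responses are biexponential kernels realized as
# second-order linear filters; membrane potential maps to pulse density
# through a two-branch exponential sigmoid.

#' Neural mass model parameters
#'
#' Constructs the validated parameter set of the whole-brain neural-mass
#' network. Defaults are the standard alpha-rhythm settings; the two swept
#' parameters of the E-I study are `vd2` (inhibitory firing threshold,
#' swept 6-8 mV in steps of 0.5) and `s_couple` (global coupling gain,
#' swept 0-2 in steps of 0.5).
#'
#' @param dt Sample time in seconds.
#' @param p_input Mean extrinsic ("thalamic") input pulse density, spikes/s.
#' @param noise Amplitude of the random fluctuation of the input pulse
#'   density (standard deviation of per-sample Gaussian noise, spikes/s).
#' @param A_e,a_e,b_e EPSP kernel amplitude (mV) and shape rates (1/s).
#' @param A_i,a_i,b_i IPSP kernel amplitude (mV) and shape rates (1/s).
#' @param g Sigmoid maximum-slope rate parameter (1/s); pulse densities lie
#'   in (0, 2g).
#' @param q Sigmoid steepness (1/mV).
#' @param vd1 Firing threshold potential of the excitatory population (mV).
#' @param vd2 Firing threshold potential of the inhibitory interneuron
#'   population (mV). Raising it weakens inhibition and raises the E-I ratio.
#' @param c1 Excitatory-to-inhibitory coupling constant within a mass.
#' @param c2 Inhibitory-to-excitatory coupling constant within a mass.
#' @param s_couple Global gain on inter-mass coupling.
#' @param t_delay Inter-mass transmission delay in seconds; must be a
#'   positive integer multiple of `dt`.
#' @param n_regions Number of neural masses.
#' @return An `nm_params` object (validated named list).
#' @export
nm_params <- function(dt = 0.002, p_input = 480, noise = 1.0,
                      A_e = 1.6, a_e = 55, b_e = 605,
                      A_i = 32, a_i = 27.5, b_i = 55,
                      g = 25, q = 0.34, vd1 = 7, vd2 = 7,
                      c1 = 32, c2 = 3, s_couple = 1.0,
                      t_delay = 0.002, n_regions = 78) {
  p <- list(
    dt = dt, p_input = p_input, noise = noise,
    A_e = A_e, a_e = a_e, b_e = b_e, A_i = A_i, a_i = a_i, b_i = b_i,
    g = g, q = q, vd1 = vd1, vd2 = vd2, c1 = c1, c2 = c2,
    s_couple = s_couple, t_delay = t_delay, n_regions = as.integer(n_regions)
  )
  if (dt <= 0) abort("`dt` must be positive")
  if (!(b_e > a_e && a_e > 0)) abort("EPSP shape requires b_e > a_e > 0")
  if (!(b_i > a_i && a_i > 0)) abort("IPSP shape requires b_i > a_i > 0")
  if (g <= 0 || q <= 0) abort("sigmoid parameters g and q must be positive")
  if (s_couple < 0) abort("`s_couple` must be nonnegative")
  steps <- t_delay / dt
  if (t_delay <= 0 || abs(steps - round(steps)) > 1e-9) {
    abort("`t_delay` must be a positive integer multiple of `dt`")
  }
  if (p$n_regions < 1) abort("`n_regions` must be at least 1")
  structure(p, class = "nm_params")
}

#' @export
print.nm_params <- function(x, ...) {
  cat(sprintf(
    "<nm_params> N=%d, dt=%g s | vd2=%g mV, S=%g | P=%g, noise=%g\n",
    x$n_regions, x$dt, x$vd2, x$s_couple, x$p_input, x$noise
  ))
  invisible(x)
}

#' Biexponential postsynaptic impulse response
#'
#' \eqn{h(\tau) = A[\exp(-a\tau) - \exp(-b\tau)]} for \eqn{\tau \ge 0} and 0
#' for negative lags. The kernel peaks at \eqn{\tau = \log(b/a)/(b-a)}.
#'
#' @param tau Lag(s) in seconds; vectorized.
#' @param A Amplitude in mV.
#' @param a,b Shape rates in 1/s with `b != a`, both positive.
#' @return Kernel value(s) in mV.
#' @export
impulse_response <- function(tau, A, a, b) {
  stopifnot(a > 0, b > 0, a != b)
  ifelse(tau >= 0, A * (exp(-a * tau) - exp(-b * tau)), 0)
}

#' Potential-to-pulse-density sigmoid
#'
#' Two-branch exponential sigmoid mapping membrane potential to population
#' pulse density: \eqn{g e^{q(V_m - V_d)}} for \eqn{V_m \le V_d} and
#' \eqn{g[2 - e^{q(V_d - V_m)}]} above threshold. Continuous at threshold
#' (value `g`), bounded in (0, 2g).
#'
#' @param vm Membrane potential(s), mV; vectorized.
#' @param vd Firing threshold potential, mV.
#' @param g,q Sigmoid rate (1/s) and steepness (1/mV).
#' @return Pulse density in spikes/s.
#' @export
pulse_density <- function(vm, vd, g = 25, q = 0.34) {
  stopifnot(g > 0, q > 0)
  ifelse(vm <= vd, g * exp(q * (vm - vd)), g * (2 - exp(q * (vd - vm))))
}

#' Simulate the coupled neural-mass network
#'
#' Integrates the network with a fixed-step explicit Euler scheme at `dt`.
#' Each biexponential kernel is realized as its equivalent second-order
#' linear filter (two first-order states per synapse type). The excitatory
#' population of mass *k* receives the extrinsic pulse density
#' `p_input + noise * eta` (Gaussian `eta`, independent per region and step),
#' plus the excitatory pulse densities of connected masses delayed by
#' `t_delay` and scaled by `s_couple * weights[k, j]`, through the EPSP
#' kernel, and local feedback `c2 * I(t)` through the IPSP kernel. The
#' inhibitory population receives `c1 * E(t)` through the EPSP kernel.
#' All filter states start at zero and `burn_in` initial samples are
#' discarded before recording.
#'
#' @param params An [nm_params()] object; `params$n_regions` must match the
#'   connectome.
#' @param connectome A `connectome` object supplying the coupling weights.
#' @param n_samples Number of recorded samples (after burn-in).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @param burn_in Number of initial samples discarded (default 1000, i.e.
#'   2 s at the default `dt`).
#' @return An `nm_simulation` object with region-by-time matrices `eeg`
#'   (excitatory membrane potential, the simulated EEG), `e_rate` and
#'   `i_rate` (population pulse densities, spikes/s), plus `dt`, `seed`,
#'   `burn_in` and `params`.
#' @examples
#' conn <- synthetic_connectome(n_regions = 10, seed = 1)
#' sim <- simulate_network(nm_params(n_regions = 10), conn,
#'                         n_samples = 512, seed = 1)
#' dim(sim$eeg)
#' @export
simulate_network <- function(params, connectome, n_samples = 4096, seed = 1,
                             burn_in = 1000) {
  stopifnot(inherits(params, "nm_params"), inherits(connectome, "connectome"))
  if (connectome$n_regions != params$n_regions) {
    abort(sprintf(
      "connectome has %d regions but params$n_regions is %d",
      connectome$n_regions, params$n_regions
    ))
  }
  if (n_samples < 1) abort("`n_samples` must be at least 1")
  n <- params$n_regions
  n_total <- n_samples + burn_in
  dt <- params$dt
  d_steps <- as.integer(round(params$t_delay / dt))
  W <- connectome$weights

  eta <- with_seed(as.integer(seed), matrix(rnorm(n * n_total), n, n_total))

  # second-order filter: y'' = k*u - (a+b) y' - a b y, impulse response h()
  k_e <- params$A_e * (params$b_e - params$a_e)
  k_i <- params$A_i * (params$b_i - params$a_i)
  sum_e <- params$a_e + params$b_e; prod_e <- params$a_e * params$b_e
  sum_i <- params$a_i + params$b_i; prod_i <- params$a_i * params$b_i

  y1 <- z1 <- y2 <- z2 <- y3 <- z3 <- numeric(n)
  e_buf <- matrix(0, n, d_steps)  # ring buffer of transmitted E rates
  buf_pos <- 1L
  eeg <- e_rate <- i_rate <- matrix(0, n, n_samples)

  for (t in seq_len(n_total)) {
    ve <- y1 - y2
    vi <- y3
    if (any(!is.finite(ve))) {
      abort(sprintf(
        "simulation diverged at step %d (region %s)",
        t, connectome$labels[which(!is.finite(ve))[1L]]
      ), class = "eidyn_error_divergence")
    }
    E <- pulse_density(ve, params$vd1, params$g, params$q)
    I <- pulse_density(vi, params$vd2, params$g, params$q)
    u1 <- params$p_input + params$noise * eta[, t] +
      params$s_couple * as.vector(W %*% e_buf[, buf_pos])
    u2 <- params$c2 * I
    u3 <- params$c1 * E
    z1 <- z1 + dt * (k_e * u1 - sum_e * z1 - prod_e * y1); y1 <- y1 + dt * z1
    z2 <- z2 + dt * (k_i * u2 - sum_i * z2 - prod_i * y2); y2 <- y2 + dt * z2
    z3 <- z3 + dt * (k_e * u3 - sum_e * z3 - prod_e * y3); y3 <- y3 + dt * z3
    e_buf[, buf_pos] <- E
    buf_pos <- if (buf_pos == d_steps) 1L else buf_pos + 1L
    if (t > burn_in) {
      j <- t - burn_in
      eeg[, j] <- ve; e_rate[, j] <- E; i_rate[, j] <- I
    }
  }
  rownames(eeg) <- rownames(e_rate) <- rownames(i_rate) <- connectome$labels
  structure(
    list(eeg = eeg, e_rate = e_rate, i_rate = i_rate,
         dt = dt, seed = as.integer(seed), burn_in = as.integer(burn_in),
         params = params),
    class = "nm_simulation"
  )
}

#' @export
print.nm_simulation <- function(x, ...) {
  cat(sprintf(
    "<nm_simulation> %d regions x %d samples (%.2f s at dt=%g), vd2=%g, S=%g, seed=%d\n",
    nrow(x$eeg), ncol(x$eeg), ncol(x$eeg) * x$dt, x$dt,
    x$params$vd2, x$params$s_couple, x$seed
  ))
  invisible(x)
}

#' Tidy simulated traces into a long tibble
#'
#' @param x An `nm_simulation`.
#' @param signals Which traces to include; subset of
#'   `c("eeg", "e_rate", "i_rate")`.
#' @param ... Unused.
#' @return Tibble with columns `region`, `time` (s), `signal`, `value`.
#' @method tidy nm_simulation
#' @export
tidy.nm_simulation <- function(x, signals = "eeg", ...) {
  signals <- match.arg(signals, c("eeg", "e_rate", "i_rate"),
                       several.ok = TRUE)
  purrr::map(signals, function(sg) {
    m <- x[[sg]]
    tibble(
      region = rep(rownames(m), times = ncol(m)),
      time = rep(seq_len(ncol(m)) * x$dt, each = nrow(m)),
      signal = sg,
      value = as.vector(m)
    )
  }) |> list_rbind()
}

#' Whole-brain excitation-inhibition ratio of a simulation
#'
#' Computes per-region time-averaged excitatory and inhibitory pulse
#' densities, optionally min-max normalizes them with supplied ranges (used
#' to normalize rates across a whole parameter sweep), forms the per-region
#' ratio E/(E+I), and averages across regions.
#'
#' @param sim An `nm_simulation`.
#' @param e_range,i_range Optional length-2 numeric ranges used to min-max
#'   normalize the time-averaged rates before forming the ratio. By default
#'   raw rates are used.
#' @return Scalar in \[0, 1\].
#' @export
ei_ratio <- function(sim, e_range = NULL, i_range = NULL) {
  stopifnot(inherits(sim, "nm_simulation"))
  e <- rowMeans(sim$e_rate)
  i <- rowMeans(sim$i_rate)
  if (!is.null(e_range)) e <- (e - e_range[1]) / diff(e_range)
  if (!is.null(i_range)) i <- (i - i_range[1]) / diff(i_range)
  tot <- e + i
  if (any(tot == 0)) {
    abort("E + I is zero for at least one region; E-I ratio undefined",
          class = "eidyn_error_ei_undefined")
  }
  mean(e / tot)
}
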