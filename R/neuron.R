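#' Spiking neuron parameters
#'
#' Bundles the constants of the retinal-ganglion-cell (RGC) membrane dynamics
#' and of the leaky integrate-and-fire (LIF) baseline. The RGC membrane follows
#' a Hodgkin-Huxley-style ion-channel current
#' \deqn{I_{ion} = g_{Na} m^3 h (U - E_{Na}) + g_K n^4 (U - E_K) + g_L (U - E_L)}
#' and integrates, per simulation step,
#' \deqn{U_t = U_{t-1} + (dt/C)\,(I_{syn} - I_{ion}) - s_{t-1} V_{th},}
#' a soft reset that subtracts the firing threshold after each spike. A unit
#' fires when its membrane strictly exceeds \code{v_th}. Everything lives on a
#' normalised membrane scale compatible with the default threshold 0.5.
#'
#' Gating variables relax toward sigmoidal steady states at rate
#' \code{gate_rate}; the default rate 0 freezes them at \code{m = h = 1},
#' \code{n = 0.5} ("static channels"), so the dominant ion-channel effect is a
#' configurable leak \code{g_l}.
#'
#' @param v_th firing threshold (> 0); default 0.5.
#' @param a1 width of the rectangular surrogate-gradient window (> 0); the
#'   surrogate has height \code{1/a1} so its integral is always 1.
#' @param mode \code{"rgc"} or \code{"lif"}.
#' @param g_na,g_k,g_l channel conductances (normalised units).
#' @param e_na,e_k,e_l reversal potentials (normalised units).
#' @param capacitance membrane capacitance C (> 0).
#' @param dt integration step (> 0), one simulation step by default.
#' @param lif_decay LIF leak factor in (0, 1].
#' @param gate_rate relaxation rate of the gating variables (>= 0).
#' @param gate_theta,gate_kappa centre and width of the sigmoidal gating
#'   steady-state curves.
#' @param m0,n0,h0 initial gating values in [0, 1].
#' @return An object of class \code{neuron_params}.
#' @export
neuron_params <- function(v_th = 0.5, a1 = 1, mode = c("rgc", "lif"),
                          g_na = 0, g_k = 0, g_l = 0.1,
                          e_na = 1, e_k = -1, e_l = 0,
                          capacitance = 1, dt = 1, lif_decay = 0.5,
                          gate_rate = 0, gate_theta = 0.5, gate_kappa = 0.2,
                          m0 = 1, n0 = 0.5, h0 = 1) {
  mode <- match.arg(mode)
  stopifnot(v_th > 0, a1 > 0, dt > 0, capacitance > 0,
            lif_decay > 0, lif_decay <= 1, gate_rate >= 0,
            m0 >= 0, m0 <= 1, n0 >= 0, n0 <= 1, h0 >= 0, h0 <= 1)
  structure(list(v_th = v_th, a1 = a1, mode = mode,
                 g_na = g_na, g_k = g_k, g_l = g_l,
                 e_na = e_na, e_k = e_k, e_l = e_l,
                 capacitance = capacitance, dt = dt, lif_decay = lif_decay,
                 gate_rate = gate_rate, gate_theta = gate_theta,
                 gate_kappa = gate_kappa, m0 = m0, n0 = n0, h0 = h0),
            class = "neuron_params")
}

#' Per-unit membrane state
#'
#' Holds the membrane potential \code{u} (the pre-reset potential of the last
#' completed step), the gating variables \code{m}, \code{n}, \code{h} (each in
#' [0, 1]) and the binary \code{last_spike} flag used by the soft-reset term of
#' the next update.
#'
#' @param dim dimensions of the unit array (e.g. \code{c(HW, C)}).
#' @param params a \code{\link{neuron_params}} object.
#' @return A list of class \code{membrane_state}.
#' @export
membrane_state <- function(dim, params = neuron_params()) {
  z <- array(0, dim)
  structure(list(u = z, m = z + params$m0, n = z + params$n0,
                 h = z + params$h0, last_spike = z),
            class = "membrane_state")
}

#' Ion-channel current
#'
#' Evaluates the sodium + potassium + leak current
#' \code{g_na*m^3*h*(u - e_na) + g_k*n^4*(u - e_k) + g_l*(u - e_l)}
#' elementwise at the state's membrane potential.
#'
#' @param state a \code{\link{membrane_state}}.
#' @param params a \code{\link{neuron_params}}.
#' @return array of per-unit currents, same shape as \code{state$u}.
#' @export
ion_channel_current <- function(state, params) {
  if (!all(is.finite(state$u))) stop("non-finite membrane potential")
  if (any(state$m < 0 | state$m > 1) || any(state$n < 0 | state$n > 1) ||
      any(state$h < 0 | state$h > 1))
    stop("gating variables must lie in [0, 1]")
  params$g_na * state$m^3 * state$h * (state$u - params$e_na) +
    params$g_k * state$n^4 * (state$u - params$e_k) +
    params$g_l * (state$u - params$e_l)
}

# Total membrane conductance dI_ion/dU given the current gating values.
# Returns a scalar on the common leak-only fast path.
.total_conductance <- function(state, params) {
  if (params$g_na == 0 && params$g_k == 0) return(params$g_l)
  params$g_na * state$m^3 * state$h + params$g_k * state$n^4 + params$g_l
}

# Ion current without the exported function's validation overhead.
.ion_current <- function(state, params) {
  if (params$g_na == 0 && params$g_k == 0)
    return(params$g_l * (state$u - params$e_l))
  params$g_na * state$m^3 * state$h * (state$u - params$e_na) +
    params$g_k * state$n^4 * (state$u - params$e_k) +
    params$g_l * (state$u - params$e_l)
}

#' Advance the gating variables one step
#'
#' First-order relaxation \code{x <- x + dt*rate*(x_inf(u) - x)} with sigmoidal
#' steady states \code{x_inf(u) = plogis((u - gate_theta)/gate_kappa)}; results
#' are clamped to [0, 1]. With the default \code{gate_rate = 0} the gating
#' variables are frozen.
#'
#' @inheritParams ion_channel_current
#' @return the updated \code{membrane_state}.
#' @export
update_gating <- function(state, params) {
  r <- params$gate_rate * params$dt
  if (r == 0) return(state)
  xinf <- stats::plogis((state$u - params$gate_theta) / params$gate_kappa)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  state$m <- clamp01(state$m + r * (xinf - state$m))
  state$n <- clamp01(state$n + r * (xinf - state$n))
  state$h <- clamp01(state$h + r * ((1 - xinf) - state$h))
  state
}

#' Threshold firing with soft reset
#'
#' Where \code{u > v_th} (strict) the unit emits a spike and the membrane is
#' reset to \code{u - v_th}; elsewhere the membrane is unchanged.
#'
#' @param u membrane potential array (finite).
#' @param params a \code{\link{neuron_params}}.
#' @return list with binary \code{spikes} and \code{u_after}.
#' @export
fire_and_reset <- function(u, params) {
  if (!all(is.finite(u))) stop("non-finite membrane potential")
  s <- (u > params$v_th) + 0
  list(spikes = s, u_after = u - s * params$v_th)
}

#' One RGC membrane update
#'
#' Iterative update \code{u <- u + (dt/C)*(input - I_ion(u)) - last_spike*v_th},
#' followed by the gating update and threshold firing. The stored \code{u} is
#' the pre-reset potential; the soft reset is applied by the next step's
#' \code{-last_spike*v_th} term (equivalently, the post-reset potential is
#' \code{u - last_spike*v_th}).
#'
#' @param state a \code{\link{membrane_state}}.
#' @param input synaptic input current, same shape as \code{state$u}.
#' @param params a \code{\link{neuron_params}}.
#' @return list with the updated \code{state} and this step's binary
#'   \code{spikes}.
#' @export
rgc_step <- function(state, input, params) {
  if (!identical(dim(state$u), dim(input)) && length(state$u) != length(input))
    stop("state/input shape mismatch")
  scale <- params$dt / params$capacitance
  u <- state$u + scale * (input - ion_channel_current(state, params)) -
    state$last_spike * params$v_th
  state$u <- u
  state <- update_gating(state, params)
  fr <- fire_and_reset(u, params)
  state$last_spike <- fr$spikes
  list(state = state, spikes = fr$spikes)
}

#' One LIF membrane update
#'
#' \code{u <- lif_decay * u * (1 - last_spike) + input} (hard reset to 0 on
#' spike), followed by threshold firing.
#'
#' @inheritParams rgc_step
#' @return list with the updated \code{state} and this step's binary
#'   \code{spikes}.
#' @export
lif_step <- function(state, input, params) {
  u <- params$lif_decay * state$u * (1 - state$last_spike) + input
  state$u <- u
  s <- (u > params$v_th) + 0
  state$last_spike <- s
  list(state = state, spikes = s)
}

#' Rectangular surrogate gradient
#'
#' The backward-pass stand-in for the derivative of the spike nonlinearity:
#' \code{1/a1} where \code{|u - v_th| < a1/2}, else 0. Its integral over the
#' membrane axis is 1 for any \code{a1}. The forward pass always emits true
#' binary spikes.
#'
#' @param u membrane potential array.
#' @param params a \code{\link{neuron_params}}.
#' @return gradient array of the same shape.
#' @export
surrogate_grad <- function(u, params) {
  (abs(u - params$v_th) < params$a1 / 2) / params$a1
}

# Piecewise-linear relaxation of the spike step whose derivative equals the
# rectangular surrogate; used by the relaxed (differentiable) forward mode that
# gradient tests difference numerically.
.spike_relaxed <- function(u, params) {
  pmin(pmax((u - params$v_th) / params$a1 + 0.5, 0), 1)
}

# Run a spiking layer over all T steps. `currents` is a list of T matrices
# (units x channels). Returns spikes (list of T) plus the caches BPTT needs.
# relaxed = TRUE substitutes the piecewise-linear spike relaxation in the
# forward pass so the backward pass is the exact gradient of the forward map
# (used only for gradient verification).
neuron_forward <- function(currents, params, relaxed = FALSE) {
  tt <- length(currents)
  z <- currents[[1]] * 0
  st <- structure(list(u = z, m = z + params$m0, n = z + params$n0,
                       h = z + params$h0, last_spike = z),
                  class = "membrane_state")
  spikes <- vector("list", tt)
  u_pre <- vector("list", tt)
  gtot <- vector("list", tt)
  scale <- params$dt / params$capacitance
  lif <- params$mode == "lif"
  for (t in seq_len(tt)) {
    if (lif) {
      u <- params$lif_decay * st$u * (1 - st$last_spike) + currents[[t]]
    } else {
      gtot[[t]] <- .total_conductance(st, params)
      u <- st$u + scale * (currents[[t]] - .ion_current(st, params)) -
        st$last_spike * params$v_th
    }
    st$u <- u
    if (!lif) st <- update_gating(st, params)
    s <- if (relaxed) .spike_relaxed(u, params) else (u > params$v_th) + 0
    st$last_spike <- s
    spikes[[t]] <- s
    u_pre[[t]] <- u
  }
  list(spikes = spikes, u_pre = u_pre, gtot = gtot, params = params)
}

# BPTT adjoint of neuron_forward. g_spikes: list of T gradients w.r.t. the
# emitted spikes. Returns gradients w.r.t. the injected currents. Gating
# variables are treated as constants (detached), the standard surrogate
# practice; under the default frozen gating this is exact.
neuron_backward <- function(cache, g_spikes) {
  params <- cache$params
  tt <- length(g_spikes)
  scale <- params$dt / params$capacitance
  lif <- params$mode == "lif"
  g_currents <- vector("list", tt)
  gu_next <- NULL
  for (t in rev(seq_len(tt))) {
    sg <- surrogate_grad(cache$u_pre[[t]], params)
    gu <- g_spikes[[t]] * sg
    if (!is.null(gu_next)) {
      if (lif) {
        # u_{t+1} = decay * u_t * (1 - s_t) + I_{t+1}
        carry <- params$lif_decay *
          ((1 - cache$spikes[[t]]) - cache$u_pre[[t]] * sg)
      } else {
        # u_{t+1} = u_t + scale*(I - I_ion(u_t)) - s_t * v_th
        carry <- 1 - scale * cache$gtot[[t + 1]] - params$v_th * sg
      }
      gu <- gu + gu_next * carry
    }
    g_currents[[t]] <- if (lif) gu else gu * scale
    gu_next <- gu
  }
  g_currents
}
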