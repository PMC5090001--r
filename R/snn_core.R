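#' Leaky integrate-and-fire neuron parameters
#'
#' Membrane dynamics follow
#' `tau_m dV/dt = (v_rest - V) + R_m I_syn(t)` with `R_m = tau_m / c_m`;
#' a spike is emitted when `V` crosses `v_thresh`, after which `V` is held
#' at `v_reset` for the refractory period. Units: ms, mV, nF, nA (so
#' `R_m` is in megaohm and `R_m * I` in mV); delta-synapse weights are
#' charges in pC (`delta V = w / c_m` mV per spike).
#'
#' @param tau_m membrane time constant (ms).
#' @param v_rest resting potential (mV).
#' @param v_reset post-spike reset potential (mV).
#' @param v_thresh spike threshold (mV); must exceed `v_reset`.
#' @param c_m membrane capacitance (nF).
#' @param tau_refrac absolute refractory period (ms).
#' @param synapse `"exp_current"` (exponentially decaying current, time
#'   constant `tau_syn`) or `"delta_current"` (instantaneous charge).
#' @param tau_syn synaptic current time constant (ms), exp_current only.
#' @param i_offset constant injected current (nA).
#' @return a `lif_params` list (with derived `r_m`).
#' @export
lif_params <- function(tau_m = 20, v_rest = -65, v_reset = -65,
                       v_thresh = -50, c_m = 0.25, tau_refrac = 1,
                       synapse = c("exp_current", "delta_current"),
                       tau_syn = 5, i_offset = 0) {
  synapse <- match.arg(synapse)
  stopifnot(tau_m > 0, tau_refrac > 0, c_m > 0, v_thresh > v_reset)
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_thresh = v_thresh, c_m = c_m, r_m = tau_m / c_m,
                 tau_refrac = tau_refrac, synapse = synapse,
                 tau_syn = tau_syn, i_offset = i_offset),
            class = "lif_params")
}

#' Spike-timing-dependent plasticity parameters
#'
#' Pair-based additive STDP with a hard floor at zero: a causal pair
#' (pre before post, gap `dt`) potentiates by `a_plus * exp(-dt/tau_plus)`,
#' an anti-causal pair depresses by `a_minus * exp(-dt/tau_minus)`, and the
#' weight is clamped to `[w_min, w_max]` after every update. `w_min = 0`
#' keeps plastic synapses excitatory throughout learning.
#'
#' @param a_plus,a_minus potentiation / depression amplitudes (weight
#'   units, i.e. nA for exp_current synapses).
#' @param tau_plus,tau_minus pairing time constants (ms).
#' @param w_min,w_max hard weight bounds; `w_min` defaults to 0. The
#'   default `w_max` (0.03 nA) is sized so a saturated stroke template
#'   (~150 active pixels sharing a 2000 Hz total input rate, 5 ms
#'   synaptic and 20 ms membrane time constants, 80 Mohm membrane)
#'   depolarizes its decision neuron by roughly the 15 mV
#'   rest-to-threshold distance — near threshold, so firing is driven by
#'   template match rather than saturating for every stimulus.
#' @return an `stdp_params` list.
#' @export
stdp_params <- function(a_plus = 0.003, a_minus = 0.0018, tau_plus = 20,
                        tau_minus = 20, w_min = 0, w_max = 0.03) {
  stopifnot(tau_plus > 0, tau_minus > 0, w_max > w_min)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' Build a LIF network
#'
#' A network is a set of named populations (LIF or spike-source input)
#' joined by dense weighted projections. Spikes emitted at step `k` are
#' delivered to their targets at step `k + 1`; the membrane is advanced
#' with the exact exponential propagator of the LIF equation each step, so
#' solver error does not enter cross-simulator comparisons.
#'
#' @param dt simulation step in ms (0.1 default; must be <= 1).
#' @return an empty `lif_network`.
#' @seealso [add_population()], [add_input()], [add_projection()],
#'   [simulate.lif_network()]
#' @export
lif_network <- function(dt = 0.1) {
  stopifnot(dt > 0, dt <= 1)
  structure(list(populations = list(), projections = list(), dt = dt),
            class = "lif_network")
}

#' @export
print.lif_network <- function(x, ...) {
  cat("LIF network (dt =", x$dt, "ms):\n")
  for (p in x$populations)
    cat(sprintf("  population %-12s %5d neurons (%s)\n", p$name, p$n,
                p$type))
  for (pr in x$projections)
    cat(sprintf("  projection %s -> %s [%d x %d]%s\n", pr$pre, pr$post,
                nrow(pr$W), ncol(pr$W), if (pr$plastic) " plastic" else ""))
  invisible(x)
}

#' Add a LIF population
#' @param net a [lif_network()].
#' @param name population name.
#' @param n number of neurons.
#' @param params a [lif_params()].
#' @return the updated network.
#' @export
add_population <- function(net, name, n, params = lif_params()) {
  stopifnot(inherits(net, "lif_network"), n >= 1)
  net$populations[[name]] <- list(name = name, n = as.integer(n),
                                  type = "lif", params = params)
  net
}

#' Add a spike-source input population
#' @param net a [lif_network()].
#' @param name population name.
#' @param arrays a [spike_source_arrays()] giving each source neuron's
#'   spike times.
#' @return the updated network.
#' @export
add_input <- function(net, name, arrays) {
  stopifnot(inherits(net, "lif_network"),
            inherits(arrays, "spike_source_arrays"))
  net$populations[[name]] <- list(name = name, n = arrays$n_neurons,
                                  type = "input", arrays = arrays)
  net
}

#' Add a rate-defined Poisson input population
#'
#' Spike trains are drawn at simulation time from the master seed, one
#' substream per neuron, over `[start_ms, stop_ms)`.
#'
#' @param net a [lif_network()].
#' @param name population name.
#' @param rates_hz per-neuron rates.
#' @param start_ms,stop_ms drive window (stop `NA` = whole run).
#' @return the updated network.
#' @export
add_poisson_input <- function(net, name, rates_hz, start_ms = 0,
                              stop_ms = NA_real_) {
  stopifnot(inherits(net, "lif_network"))
  net$populations[[name]] <- list(name = name, n = length(rates_hz),
                                  type = "poisson", rates_hz = rates_hz,
                                  start_ms = start_ms, stop_ms = stop_ms)
  net
}

#' Add a dense projection
#' @param net a [lif_network()].
#' @param pre,post population names (pre may be an input population).
#' @param weights `n_pre x n_post` weight matrix; nA for exp_current
#'   synapses, pC for delta_current. Signs are unconstrained (negative =
#'   inhibitory).
#' @param plastic mark the projection plastic (trained outside the clock
#'   loop with [stdp_update()]).
#' @param synapse `"inherit"` (use the target population's synapse model,
#'   the default) or `"delta_current"` to force instantaneous charge
#'   injection for this projection regardless of the target's model (used
#'   e.g. by the teaching signal, whose spikes must map 1:1 onto forced
#'   decision spikes).
#' @return the updated network.
#' @export
add_projection <- function(net, pre, post, weights, plastic = FALSE,
                           synapse = c("inherit", "delta_current")) {
  synapse <- match.arg(synapse)
  stopifnot(inherits(net, "lif_network"),
            pre %in% names(net$populations),
            post %in% names(net$populations))
  weights <- as.matrix(weights)
  if (nrow(weights) != net$populations[[pre]]$n ||
      ncol(weights) != net$populations[[post]]$n)
    stop("weight matrix shape ", nrow(weights), "x", ncol(weights),
         " does not match populations ", pre, " (",
         net$populations[[pre]]$n, ") -> ", post, " (",
         net$populations[[post]]$n, ")")
  net$projections[[length(net$projections) + 1L]] <-
    list(pre = pre, post = post, W = weights, plastic = plastic,
         synapse = synapse)
  net
}

#' Declared synaptic fan-out per neuron of a population
#'
#' Number of outgoing synapses of each neuron in `pop`: every entry of
#' every projection leaving the population counts as one synapse (a
#' declared connection transmits one synaptic event per spike).
#'
#' @param net a [lif_network()].
#' @param pop population name.
#' @return integer vector of per-neuron fan-outs.
#' @export
network_fanout <- function(net, pop) {
  n <- net$populations[[pop]]$n
  f <- rep(0L, n)
  for (pr in net$projections)
    if (pr$pre == pop) f <- f + ncol(pr$W)
  f
}

# bin spike times (ms) to 1-based step ids for delivery bookkeeping
bin_spikes <- function(arrays, dt, n_steps) {
  counts <- lengths(arrays$spikes)
  if (sum(counts) == 0L)
    return(list(step = integer(), id = integer()))
  id <- rep(seq_along(arrays$spikes), counts)
  t <- unlist(arrays$spikes, use.names = FALSE)
  step <- pmin(floor(t / dt) + 1L, n_steps)
  o <- order(step)
  list(step = step[o], id = id[o])
}

#' Simulate a LIF network
#'
#' Clock-driven simulation: per step, (1) spikes from the previous step are
#' delivered through every projection (exp_current: the weight adds to the
#' post-synaptic current in nA; delta_current: the charge `w` adds
#' `w / c_m` mV instantly), (2) the membrane is advanced by the exact
#' exponential propagator, (3) threshold crossings are detected at the step
#' boundary, reset and refractory applied. The membrane is clamped at
#' `v_reset` while refractory. State is checked for NaN/overflow and a
#' hard error names the first offending neuron and time.
#'
#' @param object a [lif_network()].
#' @param nsim unused (one run per call; kept for the generic).
#' @param seed master seed for the rate-defined Poisson inputs; the rest
#'   of the simulation is deterministic.
#' @param duration_ms biological duration to simulate.
#' @param record_v optionally a character vector of population names whose
#'   membrane trace to record.
#' @param v_init optional named list of initial membrane potentials per
#'   population (default: every neuron starts at `v_rest`).
#' @param ... unused.
#' @return a `spike_record`: per population a list of per-neuron spike-time
#'   vectors (`$spikes[[pop]]`), spike counts, `dt`, `duration_ms`, and
#'   any recorded traces under `$v_trace`.
#' @export
simulate.lif_network <- function(object, nsim = 1, seed = 1,
                                 duration_ms, record_v = character(),
                                 v_init = list(), ...) {
  net <- object
  dt <- net$dt
  n_steps <- as.integer(round(duration_ms / dt))
  pops <- net$populations
  pnames <- names(pops)
  # realize rate-defined inputs
  for (nm in pnames) {
    p <- pops[[nm]]
    if (p$type == "poisson") {
      stop_ms <- if (is.na(p$stop_ms)) duration_ms else p$stop_ms
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      spikes <- vector("list", p$n)
      for (i in seq_len(p$n)) {
        set.seed(substream_seed(seed, match(nm, pnames), i - 1L),
                 kind = "Mersenne-Twister", normal.kind = "Inversion")
        s <- poisson_train(p$rates_hz[i], stop_ms - p$start_ms)
        spikes[[i]] <- s + p$start_ms
      }
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      pops[[nm]]$arrays <- spike_source_arrays(
        spikes, n_neurons = p$n, duration_ms = duration_ms)
      pops[[nm]]$type <- "input"
    }
  }
  # per-population state
  st <- list()
  for (nm in pnames) {
    p <- pops[[nm]]
    if (p$type == "input") {
      b <- bin_spikes(p$arrays, dt, n_steps)
      st[[nm]] <- list(kind = "input", bins = b, ptr = 1L)
    } else {
      pr <- p$params
      em <- exp(-dt / pr$tau_m)
      es <- if (pr$synapse == "exp_current") exp(-dt / pr$tau_syn) else NA
      n_ref <- as.integer(round(pr$tau_refrac / dt))
      v0 <- if (!is.null(v_init[[nm]])) rep_len(v_init[[nm]], p$n)
            else rep(pr$v_rest, p$n)
      st[[nm]] <- list(kind = "lif", v = v0,
                       i_syn = rep(0, p$n), v_kick = rep(0, p$n),
                       refrac = rep(0L, p$n), em = em, es = es,
                       n_ref = n_ref, p = pr)
    }
  }
  rec <- lapply(pops, function(p) vector("list", n_steps))
  vtr <- list()
  for (nm in record_v)
    vtr[[nm]] <- matrix(NA_real_, n_steps, pops[[nm]]$n)
  last_spikes <- lapply(pops, function(p) integer())
  proj_by_post <- split(seq_along(net$projections),
                        vapply(net$projections, `[[`, "", "post"))
  for (k in seq_len(n_steps)) {
    # input populations: spikes of this step (delivered next step)
    now_spikes <- list()
    for (nm in pnames) {
      s <- st[[nm]]
      if (s$kind != "input") next
      b <- s$bins; ptr <- s$ptr
      ids <- integer()
      while (ptr <= length(b$step) && b$step[ptr] == k) {
        ids <- c(ids, b$id[ptr]); ptr <- ptr + 1L
      }
      st[[nm]]$ptr <- ptr
      now_spikes[[nm]] <- ids
      if (length(ids)) rec[[nm]][[k]] <- ids
    }
    # LIF populations: deliver last step's spikes, integrate, threshold
    for (nm in pnames) {
      s <- st[[nm]]
      if (s$kind != "lif") next
      p <- s$p
      kick <- rep(0, length(s$v))
      i_inc <- rep(0, length(s$v))
      for (j in proj_by_post[[nm]]) {
        pr <- net$projections[[j]]
        ids <- last_spikes[[pr$pre]]
        if (!length(ids)) next
        wsum <- if (length(ids) == 1L) pr$W[ids, ]
                else colSums(pr$W[ids, , drop = FALSE])
        syn <- if (identical(pr$synapse, "delta_current")) "delta_current"
               else p$synapse
        if (syn == "exp_current") i_inc <- i_inc + wsum
        else kick <- kick + wsum / p$c_m
      }
      v <- s$v
      refr <- s$refrac
      free <- refr == 0L
      if (any(kick != 0)) v <- v + ifelse(free, kick, 0)
      if (p$synapse == "exp_current") {
        i_syn <- s$i_syn + i_inc
        if (abs(p$tau_syn - p$tau_m) < 1e-12) {
          # degenerate equal-tau case: t e^{-t/tau} kernel
          a <- p$r_m * i_syn * (dt / p$tau_m) * s$em
          v_new <- p$v_rest + (v - p$v_rest) * s$em + a +
            p$r_m * p$i_offset * (1 - s$em)
        } else {
          A <- p$r_m * i_syn * p$tau_syn / (p$tau_syn - p$tau_m)
          v_new <- p$v_rest + p$r_m * p$i_offset +
            A * s$es + (v - p$v_rest - p$r_m * p$i_offset - A) * s$em
        }
        st[[nm]]$i_syn <- i_syn * s$es
      } else {
        v_new <- p$v_rest + p$r_m * p$i_offset +
          (v - p$v_rest - p$r_m * p$i_offset) * s$em
      }
      v_new[!free] <- p$v_reset
      refr[!free] <- refr[!free] - 1L
      if (!all(is.finite(v_new))) {
        bad <- which(!is.finite(v_new))[1]
        stop("non-finite membrane potential: population ", nm,
             ", neuron ", bad - 1L, ", t = ", k * dt, " ms")
      }
      fired <- which(free & v_new >= p$v_thresh)
      if (length(fired)) {
        v_new[fired] <- p$v_reset
        refr[fired] <- s$n_ref
        rec[[nm]][[k]] <- fired
      }
      st[[nm]]$v <- v_new
      st[[nm]]$refrac <- refr
      if (nm %in% record_v) vtr[[nm]][k, ] <- v_new
      now_spikes[[nm]] <- if (length(fired)) fired else integer()
    }
    last_spikes <- now_spikes
  }
  spikes <- list()
  counts <- integer(length(pnames))
  names(counts) <- pnames
  for (nm in pnames) {
    n <- pops[[nm]]$n
    per <- rep(list(numeric()), n)
    steps_with <- which(lengths(rec[[nm]]) > 0)
    if (length(steps_with)) {
      ids <- unlist(rec[[nm]][steps_with], use.names = FALSE)
      ts <- rep(steps_with * dt, lengths(rec[[nm]][steps_with]))
      per <- split(ts, factor(ids, levels = seq_len(n)))
      per <- lapply(per, as.numeric)
    }
    spikes[[nm]] <- per
    counts[nm] <- sum(lengths(per))
  }
  structure(list(spikes = spikes, counts = counts, dt = dt,
                 duration_ms = duration_ms, v_trace = vtr),
            class = "spike_record")
}

#' @export
print.spike_record <- function(x, ...) {
  cat("Spike record over", x$duration_ms, "ms (dt =", x$dt, "ms):\n")
  for (nm in names(x$counts))
    cat(sprintf("  %-12s %d spikes\n", nm, x$counts[nm]))
  invisible(x)
}

#' Population spike times from a record
#' @param record a `spike_record`.
#' @param pop population name.
#' @return list of per-neuron spike-time vectors (ms).
#' @export
record_spikes <- function(record, pop) record$spikes[[pop]]

#' Pair-based nearest-neighbor STDP update
#'
#' Applies the additive pair rule to one synapse given the pre- and
#' post-synaptic spike trains of a training window: each post spike pairs
#' with the nearest preceding pre spike (potentiation), each pre spike
#' with the nearest preceding post spike (depression); simultaneous spikes
#' do not pair. The result is clamped to `[w_min, w_max]`, so with the
#' default `w_min = 0` a plastic weight can never become inhibitory.
#'
#' @param pre_spikes,post_spikes sorted spike times (ms).
#' @param w current weight (scalar or vector; vectorized over `w` with the
#'   same spike trains applied to each).
#' @param params an [stdp_params()].
#' @return updated weight(s).
#' @export
stdp_update <- function(pre_spikes, post_spikes, w, params) {
  stopifnot(inherits(params, "stdp_params"))
  dw <- 0
  if (length(pre_spikes) && length(post_spikes)) {
    # potentiation: nearest pre strictly before each post
    idx <- findInterval(post_spikes - 1e-12, pre_spikes)
    ok <- idx >= 1L
    if (any(ok)) {
      gap <- post_spikes[ok] - pre_spikes[idx[ok]]
      dw <- dw + params$a_plus * sum(exp(-gap / params$tau_plus))
    }
    # depression: nearest post strictly before each pre
    idx <- findInterval(pre_spikes - 1e-12, post_spikes)
    ok <- idx >= 1L
    if (any(ok)) {
      gap <- pre_spikes[ok] - post_spikes[idx[ok]]
      dw <- dw - params$a_minus * sum(exp(-gap / params$tau_minus))
    }
  }
  pmin(pmax(w + dw, params$w_min), params$w_max)
}

#' Attach a supervised teaching signal
#'
#' Adds a Poisson source firing at `rate_hz` (50 Hz in the template
#' training protocol) connected to one decision neuron with a weight sized
#' to be suprathreshold (single-spike EPSP of 1.5 x the rest-to-threshold
#' distance), so the target fires at approximately the teaching rate while
#' the signal is on and STDP potentiates whatever input synapses were
#' active just before each forced spike.
#'
#' @param net a [lif_network()].
#' @param pop name of the decision population.
#' @param target_neuron 1-based index of the neuron to teach.
#' @param rate_hz teaching rate.
#' @param start_ms,stop_ms teaching window.
#' @param name name for the created input population.
#' @return the updated network.
#' @export
attach_teaching_signal <- function(net, pop, target_neuron, rate_hz = 50,
                                   start_ms = 0, stop_ms = NA_real_,
                                   name = paste0("teach_", pop, "_",
                                                 target_neuron)) {
  p <- net$populations[[pop]]$params
  # instantaneous charge 1.5 x the rest-to-threshold distance: every
  # teaching spike outside the refractory period forces one output spike
  w <- 1.5 * (p$v_thresh - p$v_rest) * p$c_m
  net <- add_poisson_input(net, name, rates_hz = rate_hz,
                           start_ms = start_ms, stop_ms = stop_ms)
  W <- matrix(0, 1, net$populations[[pop]]$n)
  W[1, target_neuron] <- w
  add_projection(net, name, pop, W, synapse = "delta_current")
}
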