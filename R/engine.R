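#' Ring-buffer event queue for delayed spike delivery
#'
#' Spikes travel with axonal delays that are integer multiples of the
#' simulation step. The queue keeps one delivery slot per future step (a ring
#' of `max_delay/dt + 1` slots, each a per-target accumulator); an event
#' scheduled with delay `d` is delivered exactly `round(d/dt)` steps after
#' emission, never earlier.
#'
#' @param n_targets Number of delivery targets.
#' @param max_delay Largest representable delay, ms.
#' @param dt Simulation step, ms.
#' @return An event queue (environment of class `"event_queue"`).
#' @export
event_queue <- function(n_targets, max_delay, dt) {
  nslots <- .delay_steps(max_delay, dt) + 1L
  q <- new.env(parent = emptyenv())
  q$buf <- matrix(0, nrow = nslots, ncol = n_targets)
  q$nslots <- nslots
  q$dt <- dt
  q$cur <- 1L
  class(q) <- "event_queue"
  q
}

# Delay -> step count, enforcing causality (>= dt) and grid alignment
# (within 1e-6 ms of a multiple of dt).
.delay_steps <- function(delay, dt) {
  if (any(delay < dt - 1e-9))
    stop("delay below one time step violates causality")
  steps <- round(delay / dt)
  off <- abs(delay - steps * dt)
  if (any(off > 1e-6))
    stop(sprintf("delay %g ms is off the dt = %g ms grid by %g ms",
                 delay[which.max(off)], dt, max(off)))
  as.integer(steps)
}

#' Schedule delayed events
#'
#' Accumulates `increment` into the delivery slot `round(delay/dt)` steps
#' ahead of the current step. Several events for the same target and slot sum
#' additively. Delays must be at least one step and on the `dt` grid.
#'
#' @param queue An [event_queue()].
#' @param target Target index/indices (1-based).
#' @param increment Increment(s) to accumulate (recycled against `target`).
#' @param delay Delay(s), ms.
#' @return The queue, invisibly.
#' @export
schedule <- function(queue, target, increment, delay) {
  steps <- .delay_steps(delay, queue$dt)
  if (any(steps > queue$nslots - 1L))
    stop("delay exceeds the queue horizon (max_delay)")
  slot <- ((queue$cur - 1L + steps) %% queue$nslots) + 1L
  increment <- rep_len(increment, length(target))
  slot <- rep_len(slot, length(target))
  for (s in unique(slot)) {
    sel <- slot == s
    acc <- rowsum(increment[sel], target[sel])
    ids <- as.integer(rownames(acc))
    queue$buf[s, ids] <- queue$buf[s, ids] + acc[, 1]
  }
  invisible(queue)
}

#' Advance the queue one step and collect due events
#'
#' Moves the queue to the next step boundary and returns (then clears) the
#' per-target increments due at that boundary.
#'
#' @param queue An [event_queue()].
#' @return Numeric vector of per-target increments.
#' @export
deliver_due <- function(queue) {
  queue$cur <- (queue$cur %% queue$nslots) + 1L
  due <- queue$buf[queue$cur, ]
  queue$buf[queue$cur, ] <- 0
  due
}

#' Poisson spike train on the simulation grid
#'
#' Per-step Bernoulli thinning: at each step of length `dt` a spike is emitted
#' with probability `rate * dt / 1000` (rate in Hz, dt in ms). Valid while
#' `rate * dt / 1000 <= 0.1`, where the Bernoulli approximation to a Poisson
#' process is accurate.
#'
#' @param rate Mean rate, Hz (>= 0).
#' @param duration Train duration, ms.
#' @param dt Step, ms.
#' @param seed Optional integer seed (caller RNG preserved).
#' @return Numeric vector of spike times, ms (multiples of `dt`).
#' @examples
#' poisson_train(50, 1000, 0.1, seed = 1)
#' @export
poisson_train <- function(rate, duration, dt = 0.1, seed = NULL) {
  if (rate < 0) stop("`rate` must be non-negative")
  p <- rate * dt / 1000
  if (p > 0.1)
    stop("rate * dt too large for the per-step Bernoulli approximation")
  n <- round(duration / dt)
  .with_seed(seed, which(stats::runif(n) < p) * dt)
}

# Per-delay-class compressed delivery structure: edges sorted by source with
# start/degree indexing, so emitting the out-edges of a spiking source is a
# contiguous slice.
.build_delivery <- function(edges, n_sources, dt, transform = identity) {
  if (nrow(edges) == 0) return(list())
  lapply(split(seq_len(nrow(edges)), edges$delay), function(ii) {
    src <- edges$pre[ii] + 1L
    ord <- order(src)
    deg <- tabulate(src, nbins = n_sources)
    list(steps = .delay_steps(edges$delay[ii][1], dt),
         deg = deg,
         start = cumsum(c(1L, deg[-n_sources])),
         tgt = (edges$post[ii] + 1L)[ord],
         w = transform(edges$weight[ii][ord]))
  })
}

# Emit spikes from 1-based source ids through all delivery groups into the
# queue slots (relative to the queue's current step).
.emit <- function(q, delivery, sources) {
  if (length(sources) == 0) return(invisible())
  for (g in delivery) {
    cnt <- g$deg[sources]
    if (sum(cnt) == 0) next
    idx <- rep.int(g$start[sources], cnt) + sequence(cnt) - 1L
    slot <- ((q$cur - 1L + g$steps) %% q$nslots) + 1L
    acc <- rowsum(g$w[idx], g$tgt[idx])
    ids <- as.integer(rownames(acc))
    q$buf[slot, ids] <- q$buf[slot, ids] + acc[, 1]
  }
  invisible()
}

#' Assemble a spiking network
#'
#' Container tying together neuron model parameters, connectivity, optional
#' Poisson drive, and simulation defaults. Sources in `edges` are indexed
#' 0-based with neurons first (`0 .. n_neurons-1`) followed by generators
#' (`n_neurons .. n_neurons+n_generators-1`); targets are neurons only.
#'
#' @param kind `"lif"` or `"hh"`.
#' @param n_neurons Number of neurons.
#' @param edges An [edge_list()] with `n_pre = n_neurons + n_generators`,
#'   `n_post = n_neurons`.
#' @param params [lif_params()] or [hh_params()] matching `kind`.
#' @param dt Default step, ms.
#' @param duration Default duration, ms.
#' @param solver Default solver (`"exact"` for LIF; `"rk4"` or `"exp_euler"`
#'   for HH).
#' @param n_generators Number of Poisson generators.
#' @param gen_rate Generator rate, Hz.
#' @param syn_inh,syn_exc For HH networks: [double_exp_params()] for the
#'   inhibitory synapse and [single_exp_params()] for the (possibly silent)
#'   excitatory synapse integrated alongside it.
#' @param init Initial-condition spec: for LIF `list(v = <mV>)`; for HH either
#'   `list(v = <mV>)` (deterministic, gating at steady state),
#'   `list(v_min =, v_max =)` for a seeded per-neuron uniform draw with
#'   gating at steady state, or `list(state = <list>)` giving the full state
#'   (`v`, `m`, `h`, `n`, optionally `a_i`, `b_i`, `a_e`) to continue a
#'   previous run.
#' @param refractory_mode LIF refractory semantics (see [lif_step()]).
#' @param literal_weight_increment For HH networks: if `TRUE`, synapse traces
#'   are incremented by the edge weight itself so the peak-conductance factor
#'   applies twice (the literal reading of the model equations); default
#'   `FALSE` increments by `weight / g_peak` (unit increments for homogeneous
#'   weights), making `g_peak` the per-spike peak conductance.
#' @param populations Optional data frame (`name`, `offset`, `size`)
#'   documenting the global id layout.
#' @param build_time Seconds spent constructing the network (recorded by the
#'   case-study builders).
#' @return An object of class `"spiking_network"`.
#' @export
spiking_network <- function(kind = c("lif", "hh"), n_neurons, edges, params,
                            dt, duration, solver = NULL,
                            n_generators = 0L, gen_rate = 0,
                            syn_inh = NULL, syn_exc = NULL,
                            init = list(v = 0),
                            refractory_mode = "clamp",
                            literal_weight_increment = FALSE,
                            populations = NULL, build_time = NA_real_) {
  kind <- match.arg(kind)
  if (is.null(solver)) solver <- if (kind == "lif") "exact" else "rk4"
  structure(list(kind = kind, n_neurons = as.integer(n_neurons),
                 edges = edges, params = params, dt = dt, duration = duration,
                 solver = solver, n_generators = as.integer(n_generators),
                 gen_rate = gen_rate, syn_inh = syn_inh, syn_exc = syn_exc,
                 init = init, refractory_mode = refractory_mode,
                 literal_weight_increment = literal_weight_increment,
                 populations = populations, build_time = build_time),
            class = "spiking_network")
}

#' Run a fixed-step network simulation
#'
#' Integrates the network on the grid `t = 0, dt, ..., duration`. Per step
#' boundary the update order is fixed: deliver due events, advance synapse
#' traces, advance membranes with the chosen solver, apply
#' threshold/reset/refractory bookkeeping, record, and enqueue emitted spikes
#' with their delays. Spike times are stamped at step boundaries; an initial
#' threshold sweep at `t = 0` lets a suprathreshold initial condition fire
#' immediately. The whole run is a deterministic function of
#' `(network, seed)`.
#'
#' @param net A [spiking_network()].
#' @param duration,dt,solver Overrides of the network defaults.
#' @param seed Integer seed for all randomness in the run (generator draws,
#'   random initial conditions).
#' @param record_v Optional vector of 0-based neuron ids whose membrane
#'   potential is recorded at every boundary.
#' @param use_tables For HH networks: evaluate rate functions through 0.1 mV
#'   lookup tables with linear interpolation instead of directly.
#' @return A list with `spikes` (data frame `neuron` 0-based global id,
#'   `time` ms, time-sorted), `traces` (matrix with a `time` attribute, or
#'   `NULL`), `state` (the final dynamical state, reusable as
#'   `init = list(state = ...)`), and `times` (a list with `build_time` and
#'   `simulation_time` in seconds).
#' @export
run_network <- function(net, duration = NULL, dt = NULL, solver = NULL,
                        seed = 1L, record_v = NULL, use_tables = FALSE) {
  stopifnot(inherits(net, "spiking_network"))
  duration <- duration %||% net$duration
  dt <- dt %||% net$dt
  solver <- solver %||% net$solver
  if (duration <= 0) stop("`duration` must be positive")
  t0 <- Sys.time()
  out <- .with_seed(seed, {
    if (net$kind == "lif")
      .run_lif(net, duration, dt, record_v)
    else
      .run_hh(net, duration, dt, solver, record_v, use_tables)
  })
  out$times <- list(build_time = net$build_time,
                    simulation_time = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.run_lif <- function(net, duration, dt, record_v) {
  nn <- net$n_neurons; ng <- net$n_generators
  n_steps <- round(duration / dt)
  params <- net$params
  state <- lif_state(nn, v = net$init$v)
  max_delay <- if (nrow(net$edges) > 0) max(net$edges$delay) else dt
  q <- event_queue(nn, max_delay, dt)
  delivery <- .build_delivery(net$edges, nn + ng, dt)
  p_gen <- net$gen_rate * dt / 1000
  rec_ids <- if (!is.null(record_v)) record_v + 1L else NULL
  traces <- if (!is.null(rec_ids))
    matrix(NA_real_, n_steps + 1L, length(rec_ids)) else NULL
  sp_id <- vector("list", n_steps + 1L)
  # initial threshold sweep at t = 0
  sp <- which(state$v > rep_len(params$theta, nn))
  if (length(sp)) {
    state$v[sp] <- rep_len(params$v_reset, nn)[sp]
    state$last_spike[sp] <- 0
    state$refractory_until[sp] <- rep_len(params$t_ref, nn)[sp]
    sp_id[[1L]] <- sp
    .emit(q, delivery, sp)
  }
  if (!is.null(traces)) traces[1L, ] <- state$v[rec_ids]
  for (step in seq_len(n_steps)) {
    due <- deliver_due(q)
    gen_sp <- if (ng > 0) which(stats::runif(ng) < p_gen) else integer()
    res <- lif_step(state, params, dt, input_jump = due, t = step * dt,
                    refractory_mode = net$refractory_mode)
    state <- res$state
    if (anyNA(state$v) || any(!is.finite(state$v)))
      stop(sprintf("non-finite membrane potential (v) at step %d", step))
    sp <- which(res$spiked)
    if (length(sp)) sp_id[[step + 1L]] <- sp
    if (!is.null(traces)) traces[step + 1L, ] <- state$v[rec_ids]
    .emit(q, delivery, c(sp, nn + gen_sp))
  }
  out <- .collect_spikes(sp_id, dt, traces, n_steps)
  out$state <- state
  out
}

.run_hh <- function(net, duration, dt, solver, record_v, use_tables) {
  if (!solver %in% c("rk4", "exp_euler"))
    stop("unknown HH solver: ", solver)
  nn <- net$n_neurons
  n_steps <- round(duration / dt)
  params <- net$params
  si <- net$syn_inh; se <- net$syn_exc
  if (!is.null(net$init$state)) {
    st0 <- net$init$state
    v <- rep_len(st0$v, nn); m <- rep_len(st0$m, nn)
    h <- rep_len(st0$h, nn); n <- rep_len(st0$n, nn)
    a_i <- rep_len(st0$a_i %||% 0, nn)
    b_i <- rep_len(st0$b_i %||% 0, nn)
    a_e <- rep_len(st0$a_e %||% 0, nn)
  } else {
    v <- if (!is.null(net$init$v)) rep_len(net$init$v, nn)
         else stats::runif(nn, net$init$v_min, net$init$v_max)
    ss <- gating_steady_state(v)
    m <- ss$m_inf; h <- ss$h_inf; n <- ss$n_inf
    a_i <- b_i <- a_e <- numeric(nn)
  }
  rate_fn <- if (use_tables) .table_rates() else hh_rates
  max_delay <- if (nrow(net$edges) > 0) max(net$edges$delay) else dt
  q <- event_queue(nn, max_delay, dt)
  inc <- if (net$literal_weight_increment) identity
         else function(w) w / si$g_peak
  delivery <- .build_delivery(net$edges, nn, dt, transform = inc)
  d_ai <- exp(-dt / si$tau_rise); d_bi <- exp(-dt / si$tau_decay)
  d_ae <- if (!is.null(se)) exp(-dt / se$tau) else 0
  nS <- 1e-6 / params$area
  rec_ids <- if (!is.null(record_v)) record_v + 1L else NULL
  traces <- if (!is.null(rec_ids))
    matrix(NA_real_, n_steps + 1L, length(rec_ids)) else NULL
  if (!is.null(traces)) traces[1L, ] <- v[rec_ids]
  sp_id <- vector("list", n_steps + 1L)
  v_detect <- 0   # upward crossing of 0 mV marks a spike
  syn_e_rev <- si$e_rev
  exc_e_rev <- if (!is.null(se)) se$e_rev else 0
  ge <- if (!is.null(se)) se$g_peak else 0
  for (step in seq_len(n_steps)) {
    due <- deliver_due(q)
    v_prev <- v
    if (solver == "rk4") {
      a0 <- a_i; b0 <- b_i; e0 <- a_e
      f <- function(s, y) {
        r <- rate_fn(y$v)
        g_inh <- si$g_peak * si$k *
          (b0 * exp(-s / si$tau_decay) - a0 * exp(-s / si$tau_rise))
        g_exc <- ge * e0 * if (!is.null(se)) exp(-s / se$tau) else 0
        hh_derivatives(y, params,
                       syn = list(g_inh = g_inh, e_inh = syn_e_rev,
                                  g_exc = g_exc, e_exc = exc_e_rev),
                       rates = r)
      }
      y <- rk4_step(f, list(v = v, m = m, h = h, n = n), 0, dt)
      v <- y[[1]]; m <- y[[2]]; h <- y[[3]]; n <- y[[4]]
    } else {
      r <- rate_fn(v)
      m <- exp_euler_gating_step(m, r$alpha_m, r$beta_m, dt)
      h <- exp_euler_gating_step(h, r$alpha_h, r$beta_h, dt)
      n <- exp_euler_gating_step(n, r$alpha_n, r$beta_n, dt)
      g_inh <- si$g_peak * si$k * (b_i - a_i) * nS
      g_exc <- ge * a_e * nS
      g_na_eff <- params$g_na * m^3 * h
      g_k_eff <- params$g_k * n^4
      G <- g_na_eff + g_k_eff + params$g_l + g_inh + g_exc
      S <- g_na_eff * params$e_na + g_k_eff * params$e_k +
        params$g_l * params$e_l + params$i_inj +
        g_inh * syn_e_rev + g_exc * exc_e_rev
      v_inf <- S / G
      v <- v_inf + (v - v_inf) * exp(-dt * G / params$c)
    }
    # numerical safeguard: gating variables are clamped to [0, 1]
    m <- pmin(pmax(m, 0), 1); h <- pmin(pmax(h, 0), 1); n <- pmin(pmax(n, 0), 1)
    if (anyNA(v) || any(!is.finite(v)))
      stop(sprintf("non-finite membrane potential (v) at step %d", step))
    a_i <- a_i * d_ai + due
    b_i <- b_i * d_bi + due
    a_e <- a_e * d_ae
    sp <- which(v_prev < v_detect & v >= v_detect)
    if (length(sp)) sp_id[[step + 1L]] <- sp
    if (!is.null(traces)) traces[step + 1L, ] <- v[rec_ids]
    .emit(q, delivery, sp)
  }
  out <- .collect_spikes(sp_id, dt, traces, n_steps)
  out$state <- list(v = v, m = m, h = h, n = n, a_i = a_i, b_i = b_i,
                    a_e = a_e)
  out
}

.collect_spikes <- function(sp_id, dt, traces, n_steps) {
  counts <- lengths(sp_id)
  steps <- rep.int(seq_along(sp_id) - 1L, counts)
  spikes <- data.frame(neuron = unlist(sp_id, use.names = FALSE) - 1L,
                       time = steps * dt)
  if (is.null(spikes$neuron)) spikes <- data.frame(neuron = integer(),
                                                   time = numeric())
  if (!is.null(traces))
    attr(traces, "time") <- (0:n_steps) * dt
  list(spikes = spikes, traces = traces)
}

# Table-backed rate evaluation (0.1 mV grid on [-100, 50], probes clamped to
# the tabulated range).
.table_rates <- function(step = 0.1, v_min = -100, v_max = 50) {
  nm <- c("alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n", "beta_n")
  tabs <- lapply(nm, function(k)
    build_table(function(v) hh_rates(v)[[k]], v_min, v_max, step))
  names(tabs) <- nm
  top <- v_min + (length(tabs[[1]]$samples) - 1L) * step
  function(v) {
    vc <- pmin(pmax(v, v_min), top)
    lapply(tabs, table_lookup, v = vc)
  }
}

#' Minimum inter-spike interval
#'
#' Smallest difference between consecutive spike times of the same neuron,
#' across all neurons. For a LIF population this is bounded below by the
#' refractory period.
#'
#' @param spikes Spike data frame (`neuron`, `time`) from [run_network()].
#' @return Minimum ISI in ms, or `Inf` if no neuron spiked twice. An empty
#'   record raises an error of class `"spikenet_undefined_result"`.
#' @export
min_isi <- function(spikes) {
  if (nrow(spikes) == 0)
    .stop_undefined("minimum ISI is undefined for an empty spike record")
  isis <- unlist(lapply(split(spikes$time, spikes$neuron),
                        function(t) diff(sort(t))), use.names = FALSE)
  if (length(isis) == 0) return(Inf)
  min(isis)
}

#' Binned population firing rate
#'
#' Population spike count per time bin over `[0, duration]`.
#'
#' @param spikes Spike data frame (`neuron`, `time`).
#' @param duration Record length, ms.
#' @param bin Bin width, ms.
#' @return Data frame with bin centers `time` (ms) and spike `count`.
#' @export
population_rate <- function(spikes, duration, bin = 1) {
  nb <- ceiling(duration / bin)
  idx <- pmin(floor(spikes$time / bin) + 1L, nb)
  data.frame(time = (seq_len(nb) - 0.5) * bin,
             count = tabulate(idx, nbins = nb))
}

#' Dominant population-rate oscillation frequency
#'
#' Detects network oscillations from the periodogram of the mean-subtracted
#' binned population rate. The reported `frequency` is the raw-periodogram
#' argmax within `band` (the sharpest frequency estimate). Significance is
#' judged on a Daniell-smoothed periodogram (`span` bins averaged), because
#' network rhythms wander over a few hertz and spread their power across
#' neighboring bins: the smoothed peak in `band` is compared with the median
#' smoothed power over all positive frequencies. Under a flat (white)
#' spectrum each smoothed ordinate is approximately Gamma(`span`)-distributed
#' around the noise level, so the peak-to-median ratio stays below
#' `qgamma((1-alpha)^(1/n), span) / qgamma(0.5, span)` with probability about
#' `1 - alpha`; the record is flagged oscillatory when it exceeds that
#' threshold. A homogeneous-Poisson record is therefore not flagged even
#' though its raw periodogram maximum is routinely several times the median.
#'
#' @param spikes Spike data frame (`neuron`, `time`).
#' @param duration Record length, ms.
#' @param bin Rate bin, ms.
#' @param band Frequency band of interest `c(lo, hi)`, Hz; `hi` must not
#'   exceed the Nyquist frequency of the binned rate.
#' @param alpha Significance level of the flat-spectrum test.
#' @param span Daniell smoothing width, bins (odd).
#' @return A list with `frequency` (Hz), `peak_power` and `median_power`
#'   (smoothed scale), `ratio` (peak/median), `threshold` (the significance
#'   ratio the peak must exceed), and logical `oscillatory`.
#' @export
oscillation_frequency <- function(spikes, duration, bin = 1,
                                  band = c(20, 100), alpha = 0.01,
                                  span = 5) {
  if (nrow(spikes) == 0)
    .stop_undefined("oscillation frequency is undefined for an empty record")
  nyquist <- 1000 / (2 * bin)
  if (band[2] > nyquist)
    stop("`band` upper edge exceeds the Nyquist frequency of the bin")
  x <- population_rate(spikes, duration, bin)$count
  x <- x - mean(x)
  nb <- length(x)
  pw <- Mod(stats::fft(x))^2
  # circular Daniell smoothing; valid because the periodogram is periodic
  # and the DC ordinate of the mean-subtracted rate is zero
  sm <- as.numeric(stats::filter(pw, rep(1 / span, span), circular = TRUE))
  freq <- (seq_len(nb) - 1L) / (nb * bin / 1000)   # Hz
  pos <- which(freq > 0 & freq <= nyquist)
  in_band <- pos[freq[pos] >= band[1] & freq[pos] <= band[2]]
  if (length(in_band) == 0) stop("no spectral bins inside `band`")
  peak_raw <- in_band[which.max(pw[in_band])]
  peak_sm <- in_band[which.max(sm[in_band])]
  med <- stats::median(sm[pos])
  ratio <- if (med > 0) sm[peak_sm] / med else Inf
  p <- (1 - alpha)^(1 / length(pos))
  thr <- stats::qgamma(p, shape = span) / stats::qgamma(0.5, shape = span)
  list(frequency = freq[peak_raw], peak_power = sm[peak_sm],
       median_power = med, ratio = ratio, threshold = thr,
       oscillatory = ratio > thr)
}
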