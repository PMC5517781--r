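#' Build the LIF PING benchmark network
#'
#' A pyramidal-interneuron gamma (PING) network of 5,000 leaky
#' integrate-and-fire neurons with delta synapses: 4,000 excitatory (ids
#' 0-3999), 1,000 inhibitory (ids 4000-4999), driven by 500 independent 50 Hz
#' Poisson generators (source ids 5000-5499). All neurons share
#' `tau = 10 ms`, `theta = 1 mV`, `v_reset = 0 mV`, `t_ref = 5.01 ms` and
#' start at the reset potential. Connectivity is Bernoulli with
#' probabilities `P_ee = 0.005`, `P_ei = 0.3`, `P_ii = 0.3`, `P_ie = 0.2`,
#' `P_se = 0.15`; weights/delays are `g_ee = g_ei = +0.009 mV` at 0.8 ms,
#' `g_ii = g_ie = -0.05 mV` at 2.1 ms, and `g_se = +0.025 mV` at 0.5 ms.
#' The default run is 1,000 ms at `dt = 0.1 ms` with the exact exponential
#' membrane propagator.
#'
#' Each connection block gets its own sub-seed derived from `seed` (offsets
#' 1..5), so the whole construction is reproducible from a single integer.
#'
#' @param seed Integer seed for connectivity generation.
#' @param scale Divides the neuron population sizes by this factor;
#'   `scale = 1` is the benchmark network. To keep a scaled-down network in a
#'   comparable dynamical regime, the generator population and its connection
#'   probability are left unchanged (preserving the external drive each
#'   excitatory neuron receives) and the recurrent connection probabilities
#'   are multiplied by `scale` (capped at 1), approximately preserving
#'   recurrent in-degrees. Weights and delays are never changed.
#' @return A list with `network` (a [spiking_network()]) and `config` (a
#'   `case_study_config` list echoing every parameter).
#' @examples
#' cs <- build_case_study_1(seed = 1, scale = 50)
#' @export
build_case_study_1 <- function(seed = 1L, scale = 1) {
  t0 <- Sys.time()
  n_e <- as.integer(round(4000 / scale)); n_i <- as.integer(round(1000 / scale))
  n_g <- 500L
  nn <- n_e + n_i
  p <- list(ee = min(1, 0.005 * scale), ei = min(1, 0.3 * scale),
            ii = min(1, 0.3 * scale), ie = min(1, 0.2 * scale), se = 0.15)
  w <- list(ee = 0.009, ei = 0.009, ii = -0.05, ie = -0.05, se = 0.025)
  d <- list(ee = 0.8, ei = 0.8, ii = 2.1, ie = 2.1, se = 0.5)
  ee <- connect_bernoulli(n_e, n_e, p$ee, seed = seed + 1L,
                          same_population = TRUE, weight = w$ee, delay = d$ee)
  ei <- connect_bernoulli(n_e, n_i, p$ei, seed = seed + 2L,
                          weight = w$ei, delay = d$ei)
  ii <- connect_bernoulli(n_i, n_i, p$ii, seed = seed + 3L,
                          same_population = TRUE, weight = w$ii, delay = d$ii)
  ie <- connect_bernoulli(n_i, n_e, p$ie, seed = seed + 4L,
                          weight = w$ie, delay = d$ie)
  se <- connect_bernoulli(n_g, n_e, p$se, seed = seed + 5L,
                          weight = w$se, delay = d$se)
  # global id layout: E [0, n_e), I [n_e, nn), generators [nn, nn + n_g)
  edges <- edge_list(
    pre  = c(ee$pre, ei$pre, ii$pre + n_e, ie$pre + n_e, se$pre + nn),
    post = c(ee$post, ei$post + n_e, ii$post + n_e, ie$post, se$post),
    weight = c(ee$weight, ei$weight, ii$weight, ie$weight, se$weight),
    delay = c(ee$delay, ei$delay, ii$delay, ie$delay, se$delay),
    n_pre = nn + n_g, n_post = nn, validate = FALSE)
  pops <- data.frame(name = c("excitatory", "inhibitory", "generators"),
                     offset = c(0L, n_e, nn),
                     size = c(n_e, n_i, n_g))
  net <- spiking_network(
    kind = "lif", n_neurons = nn, edges = edges,
    params = lif_params(tau = 10, theta = 1, v_reset = 0, t_ref = 5.01),
    dt = 0.1, duration = 1000, solver = "exact",
    n_generators = n_g, gen_rate = 50,
    init = list(v = 0), refractory_mode = "clamp", populations = pops,
    build_time = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  cfg <- structure(list(
    model = "LIF-PING", seed = seed, scale = scale,
    n_excitatory = n_e, n_inhibitory = n_i, n_generators = n_g,
    tau = 10, theta = 1, v_reset = 0, t_ref = 5.01,
    p_ee = p$ee, p_ei = p$ei, p_ii = p$ii, p_ie = p$ie, p_se = p$se,
    g_ee = w$ee, g_ei = w$ei, g_ii = w$ii, g_ie = w$ie, g_se = w$se,
    d_ee = d$ee, d_ei = d$ei, d_ii = d$ii, d_ie = d$ie, d_se = d$se,
    generator_rate_hz = 50, dt = 0.1, duration = 1000,
    solver = "exact", refractory_mode = "clamp", initial_v = 0),
    class = "case_study_config")
  net$build_time <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(network = net, config = cfg)
}

#' Build the Hodgkin-Huxley PIR-ING benchmark network
#'
#' An all-inhibitory network of 400 classical Hodgkin-Huxley point neurons
#' whose gamma rhythm arises from post-inhibitory rebound (PIR-ING). Each
#' neuron projects double-exponential inhibitory synapses
#' (`tau_rise = 0.99 ms`, `tau_decay = 1 ms`, `g_i = 2 nS`, `E_i = -75 mV`,
#' delay 3 ms) onto 40 distinct random targets. There is no external drive
#' (`I = 0`) and no Poisson generators; activity is seeded by random initial
#' membrane potentials, `v ~ U(-75, -55) mV`, with gating variables at their
#' steady state. A silent single-exponential excitatory synapse is integrated
#' for every neuron so that each cell carries 7 dynamical variables
#' (v, m, h, n, a_i, b_i, a_e) — it receives no events but its ODE is solved,
#' equalizing the per-neuron equation count with simulators whose stock
#' modules bundle two synapses. The default run is 500 ms at `dt = 0.05 ms`
#' with the classical RK4 solver.
#'
#' @param seed Integer seed for connectivity generation.
#' @param n Population size (default 400).
#' @param out_degree Inhibitory out-degree (default 40).
#' @return A list with `network` and `config` as in [build_case_study_1()].
#' @export
build_case_study_2 <- function(seed = 1L, n = 400L, out_degree = 40L) {
  t0 <- Sys.time()
  syn_i <- double_exp_params(g_peak = 2, e_rev = -75,
                             tau_rise = 0.99, tau_decay = 1, delay = 3)
  syn_e <- single_exp_params(g_peak = 0, e_rev = 0, tau = 1, delay = 1)
  edges <- connect_fixed_outdegree(n, out_degree, seed = seed + 1L,
                                   weight = syn_i$g_peak, delay = syn_i$delay)
  pops <- data.frame(name = "inhibitory", offset = 0L, size = n)
  net <- spiking_network(
    kind = "hh", n_neurons = n, edges = edges,
    params = hh_params(i_inj = 0),
    dt = 0.05, duration = 500, solver = "rk4",
    syn_inh = syn_i, syn_exc = syn_e,
    init = list(v_min = -75, v_max = -55), populations = pops,
    build_time = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  cfg <- structure(list(
    model = "HH-PIR-ING", seed = seed, n_neurons = n, out_degree = out_degree,
    g_na = 120, g_k = 36, g_l = 0.3, e_na = 50, e_k = -77, e_l = -54.4,
    c = 1, i_inj = 0, area = 1e-4,
    g_i = syn_i$g_peak, e_i = syn_i$e_rev,
    tau_i1 = syn_i$tau_rise, tau_i2 = syn_i$tau_decay, d_i = syn_i$delay,
    g_e = syn_e$g_peak, e_e = syn_e$e_rev, tau_e = syn_e$tau,
    dt = 0.05, duration = 500, solver = "rk4",
    init_v_min = -75, init_v_max = -55),
    class = "case_study_config")
  net$build_time <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  list(network = net, config = cfg)
}

#' Write / read a case-study configuration as YAML
#'
#' @param config A `case_study_config` list.
#' @param path File path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "case_study_config")
}

#' Rebuild a network from a configuration
#'
#' Reconstructs the benchmark network a configuration describes (same seed,
#' same parameters), so runs can be reproduced from the YAML echo alone.
#'
#' @param config A `case_study_config` (e.g. from [read_config()]).
#' @return A list with `network` and `config`.
#' @export
build_from_config <- function(config) {
  switch(config$model,
         "LIF-PING" = build_case_study_1(seed = config$seed,
                                         scale = config$scale %||% 1),
         "HH-PIR-ING" = build_case_study_2(seed = config$seed,
                                           n = config$n_neurons,
                                           out_degree = config$out_degree),
         stop("unknown model kind: ", config$model))
}

#' Summarize a completed run into report files
#'
#' Writes, under `dir`: `spikes.gdf` (two-column ASCII: global neuron id,
#' spike time in ms), `rate.tsv` (binned population rate), `summary.yaml`
#' (spike counts, minimum ISI, dominant oscillation frequency and its
#' significance, build/simulation wall-clock times, configuration echo), and
#' `config.yaml`. Except for the wall-clock fields the report is a
#' deterministic function of (config, seed). A run with no spikes is flagged
#' `silent_network`.
#'
#' @param result A [run_network()] result.
#' @param config The matching `case_study_config`.
#' @param dir Output directory (created if needed).
#' @param bin Rate bin, ms.
#' @param band Oscillation search band, Hz.
#' @return Invisibly, the summary list written to `summary.yaml`.
#' @export
report <- function(result, config, dir, bin = 1, band = c(20, 100)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- result$spikes
  writeLines(sprintf("%d\t%s", sp$neuron, .fmt_double(sp$time)),
             file.path(dir, "spikes.gdf"))
  silent <- nrow(sp) == 0
  duration <- config$duration
  if (!silent) {
    pr <- population_rate(sp, duration, bin)
    utils::write.table(pr, file.path(dir, "rate.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    osc <- oscillation_frequency(sp, duration, bin, band)
    mi <- min_isi(sp)
  } else {
    osc <- NULL; mi <- NULL
  }
  summary <- list(
    silent_network = silent,
    n_spikes = nrow(sp),
    n_neurons_fired = length(unique(sp$neuron)),
    min_isi_ms = if (silent) NA else mi,
    oscillation_frequency_hz = if (silent) NA else osc$frequency,
    oscillation_peak_to_median = if (silent) NA else osc$ratio,
    oscillatory = if (silent) NA else osc$oscillatory,
    build_time_s = result$times$build_time,
    simulation_time_s = result$times$simulation_time,
    config = unclass(config))
  yaml::write_yaml(summary, file.path(dir, "summary.yaml"))
  write_config(config, file.path(dir, "config.yaml"))
  invisible(summary)
}
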