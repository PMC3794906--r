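# Shared fixtures and a lazy run cache. Protocol runs are expensive, so every
# test that needs a full simulation pulls it from here; the first request
# computes it, later requests (also from other test files) reuse it.

run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(run_cache[[key]])) run_cache[[key]] <- force(expr)
  run_cache[[key]]
}

# The scaled physiological run plus its matched control and the two peri-LPZ
# input manipulations, sharing one equilibrated pre-lesion network.
phys_set <- function(seed) {
  cached(paste0("phys_set_", seed),
         run_protocol_variants(scaled_scenario("physiological"), seed,
                               variants = c("lesion", "control", "blockade",
                                            "reduction")))
}

scen_run <- function(name, seed) {
  cached(paste0(name, "_", seed),
         run_protocol(scaled_scenario(name), seed))
}

# Large-lesion run under the growth curves of a named scenario.
large_run <- function(name, seed) {
  curves <- scaled_scenario(name)$curves
  cached(paste0("large_", name, "_", seed),
         run_protocol(scaled_scenario("large_lpz",
           seedless_overrides = list(curves = curves)), seed))
}

outcome_of <- function(name, seed) {
  std <- if (name == "physiological") phys_set(seed)$lesion
         else scen_run(name, seed)
  classify_outcome(std, large_run(name, seed))
}

# A small quiet network for unit tests: n neurons on a tiny grid, no
# connectivity, exact grid placement unless jitter is requested.
tiny_network <- function(dims = c(4, 4), jitter = 0, ...) {
  g <- network_geometry(dims, jitter_sd = jitter)
  build_network(g, ...)
}

# Plant `n_vac` vacant and `bound` pre-bound elements into one pool of a
# fresh network, keeping all invariants (bound elements are created by
# forming real synapses through the public machinery at distance ~0).
plant_vacant <- function(net, neuron, class, n_vac) {
  k <- switch(class, axonal = "ax", dendritic_exc = "de",
              dendritic_inh = "di")
  ids <- net$next_id + seq_len(n_vac) - 1
  net[[paste0("z_", k)]][neuron] <- net[[paste0("z_", k)]][neuron] + n_vac
  net[[paste0("ids_", k)]][[neuron]] <-
    c(net[[paste0("ids_", k)]][[neuron]], ids)
  net[[paste0("prt_", k)]][[neuron]] <-
    c(net[[paste0("prt_", k)]][[neuron]], numeric(n_vac))
  net[[paste0("pn_", k)]][[neuron]] <-
    c(net[[paste0("pn_", k)]][[neuron]], integer(n_vac))
  net$next_id <- net$next_id + n_vac
  net
}

# Deterministically bind one vacant axonal element of `pre` to one vacant
# dendritic element of `post` (both must exist).
bind_pair <- function(net, pre, post) {
  dk <- if (net$sgn[pre] > 0) "de" else "di"
  ai <- which(net$prt_ax[[pre]] == 0)[1]
  di <- which(net[[paste0("prt_", dk)]][[post]] == 0)[1]
  stopifnot(!is.na(ai), !is.na(di))
  aid <- net$ids_ax[[pre]][ai]
  did <- net[[paste0("ids_", dk)]][[post]][di]
  net$prt_ax[[pre]][ai] <- did
  net$pn_ax[[pre]][ai] <- post
  net[[paste0("prt_", dk)]][[post]][di] <- aid
  net[[paste0("pn_", dk)]][[post]][di] <- pre
  net$omega[pre, post] <- net$omega[pre, post] + 1
  net
}
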