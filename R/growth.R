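# Element classes. Internally each class is stored under a short key:
#   axonal -> ax, dendritic_exc -> de, dendritic_inh -> di
# and each pool set keeps, per neuron: the continuous count z, the element id
# vector, a parallel partner-element-id vector (0 = vacant) and a parallel
# partner-neuron vector (0 = vacant), plus a cumulative creation counter used
# by the metrics layer.
ELEMENT_CLASSES <- c("axonal", "dendritic_exc", "dendritic_inh")

# Precomputed field names per class key (avoids string building in the
# per-update hot path).
FLD <- lapply(c(ax = "ax", de = "de", di = "di"), function(k)
  c(z = paste0("z_", k), ids = paste0("ids_", k), prt = paste0("prt_", k),
    pn = paste0("pn_", k), created = paste0("created_", k)))

cls_key <- function(class) {
  k <- switch(class, axonal = "ax", dendritic_exc = "de",
              dendritic_inh = "di")
  if (is.null(k)) stop("unknown element class: ", class)
  k
}

# Bound-element counts per neuron for one class, from the connectivity
# matrix (row sums for axonal pools, sign-restricted column sums for
# dendritic pools).
bound_counts <- function(network, key) {
  switch(key,
    ax = rowSums(network$omega),
    de = colSums(network$omega[network$sgn > 0, , drop = FALSE]),
    di = colSums(network$omega[network$sgn < 0, , drop = FALSE]))
}

#' Evaluate a homeostatic growth curve
#'
#' Rate of change of the continuous element count as a function of the
#' calcium trace: `nu * (2 * exp(-((ca - xi)/zeta)^2) - 1)`. The rate is zero
#' at `eta` and `eps`, maximal (`+nu`) at the curve center `xi`, strictly
#' positive between the two zero crossings and negative (bounded by `-nu`)
#' outside them, so `eps` acts as a stable set-point approached from above
#' the curve's interior and `eta` as the minimum activity needed to form
#' elements.
#'
#' @param ca Calcium concentration(s), >= 0.
#' @param curve A [growth_curve()] object.
#' @return Growth rate(s) in elements per ms, within `[-nu, nu]`.
#' @export
growth_rate <- function(ca, curve) {
  curve$nu * (2 * exp(-((ca - curve$xi) / curve$zeta)^2) - 1)
}

#' Integrate continuous element counts over an activity window
#'
#' Advances the continuous count `z` of one element class by
#' `growth_rate(ca, curve) * window`, clamped at zero. Discrete element
#' records are not touched here; they are reconciled with `floor(z)` during
#' the connectivity update.
#'
#' @param z Continuous element count(s).
#' @param ca Calcium concentration(s), same length as `z`.
#' @param curve A [growth_curve()] object.
#' @param window Window length in ms between connectivity updates.
#' @return Updated `z`, element-wise `max(0, z + rate * window)`.
#' @export
integrate_elements <- function(z, ca, curve, window) {
  pmax(0, z + growth_rate(ca, curve) * window)
}

#' Extract one neuron's element pool
#'
#' Returns the discrete pool of one element class on one neuron in a tidy
#' form: element ids, bound/vacant state and synapse partners.
#'
#' @param network A network object.
#' @param neuron Neuron index.
#' @param class One of `"axonal"`, `"dendritic_exc"`, `"dendritic_inh"`.
#' @return A list with fields `owner`, `class`, `z`, and a data frame
#'   `elements` with columns `element_id`, `state` (`"bound"`/`"vacant"`),
#'   `partner_neuron`, `partner_element`.
#' @export
element_pool <- function(network, neuron, class) {
  k <- cls_key(class)
  ids <- network[[paste0("ids_", k)]][[neuron]]
  prt <- network[[paste0("prt_", k)]][[neuron]]
  pn <- network[[paste0("pn_", k)]][[neuron]]
  list(owner = neuron, class = class, z = network[[paste0("z_", k)]][neuron],
       elements = data.frame(
         element_id = ids,
         state = ifelse(prt > 0, "bound", "vacant"),
         partner_neuron = ifelse(pn > 0, pn, NA_integer_),
         partner_element = ifelse(prt > 0, prt, NA_real_)))
}

#' Count vacant elements of one pool
#'
#' The number of vacant elements is `floor(z)` minus the number of bound
#' elements; for axonal pools the bound count equals the row sum of the
#' connectivity matrix for the owner, for dendritic pools the column sum
#' restricted to presynaptic neurons of the matching sign.
#'
#' @inheritParams element_pool
#' @return Integer count of vacant elements.
#' @export
count_vacant <- function(network, neuron, class) {
  k <- cls_key(class)
  bound <- bound_counts(network, k)[neuron]
  v <- floor(network[[paste0("z_", k)]][neuron]) - bound
  if (v < 0)
    stop("element bookkeeping corrupted: neuron ", neuron, ", class ", class,
         " has more bound elements than floor(z)")
  as.integer(v)
}

# Vacant record positions (indices into the pool's id vector).
vacant_idx <- function(network, neuron, key) {
  which(network[[FLD[[key]][["prt"]]]][[neuron]] == 0)
}

#' Decay vacant synaptic elements
#'
#' Applies one connectivity update's worth of spontaneous decay to every
#' pool: the continuous count `z` is reduced by
#' `n_vacant * (1 - exp(-1/tau_vac))` (bound elements are unaffected), and
#' any resulting drop of `floor(z)` below the number of discrete records is
#' realized by deleting that many randomly chosen vacant records; their ids
#' are retired.
#'
#' @param network A network object.
#' @return The updated network.
#' @export
decay_vacant <- function(network) {
  tau <- network$params$vac$tau_vac
  if (!is.finite(tau)) return(network)
  frac <- 1 - exp(-1 / tau)
  for (k in c("ax", "de", "di")) {
    f <- FLD[[k]]
    zf <- f[["z"]]; idf <- f[["ids"]]; prtf <- f[["prt"]]; pnf <- f[["pn"]]
    nvac <- lengths(network[[idf]]) - bound_counts(network, k)
    z <- network[[zf]]
    hot <- which(nvac > 0)
    if (!length(hot)) next
    z[hot] <- z[hot] - nvac[hot] * frac
    drop <- lengths(network[[idf]]) - floor(z)
    network[[zf]] <- z
    for (i in hot[drop[hot] > 0]) {
      vac <- which(network[[prtf]][[i]] == 0)
      if (drop[i] > length(vac))
        stop("vacancy decay would remove bound elements (neuron ", i, ")")
      sel <- vac[sample.int(length(vac), drop[i])]
      network[[idf]][[i]] <- network[[idf]][[i]][-sel]
      network[[prtf]][[i]] <- network[[prtf]][[i]][-sel]
      network[[pnf]][[i]] <- network[[pnf]][[i]][-sel]
    }
  }
  network
}

# Create vacant records so that every pool has floor(z) discrete elements.
# Ids are allocated from one global, never-reused counter; the pool's
# cumulative creation counter (used for addition rates) is stamped.
reconcile_creations <- function(network) {
  for (k in c("ax", "de", "di")) {
    f <- FLD[[k]]
    idf <- f[["ids"]]; prtf <- f[["prt"]]; pnf <- f[["pn"]]
    need <- floor(network[[f[["z"]]]]) - lengths(network[[idf]])
    hot <- which(need > 0)
    if (!length(hot)) next
    nid <- network$next_id
    for (i in hot) {
      ni <- need[i]
      network[[idf]][[i]] <- c(network[[idf]][[i]], nid + seq_len(ni) - 1)
      network[[prtf]][[i]] <- c(network[[prtf]][[i]], numeric(ni))
      network[[pnf]][[i]] <- c(network[[pnf]][[i]], integer(ni))
      nid <- nid + ni
    }
    network$next_id <- nid
    network[[f[["created"]]]][hot] <- network[[f[["created"]]]][hot] + need[hot]
  }
  network
}
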