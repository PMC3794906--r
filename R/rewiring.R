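#' Distance-dependent synapse formation kernel
#'
#' Two-dimensional Gaussian likelihood `exp(-d^2 / (2 sigma_k^2))` for
#' synapse formation between neurons separated by Euclidean distance `d`;
#' symmetric in its arguments, equal to 1 at zero distance and strictly
#' decreasing with distance.
#'
#' @param pos_i,pos_j Positions in micrometers: length-2 vectors or
#'   two-column matrices (rows are paired).
#' @param params A [kernel_params()] object.
#' @return Probability(ies) in (0, 1\].
#' @export
formation_kernel <- function(pos_i, pos_j, params) {
  pos_i <- matrix(pos_i, ncol = 2)
  pos_j <- matrix(pos_j, ncol = 2)
  d2 <- (pos_i[, 1] - pos_j[, 1])^2 + (pos_i[, 2] - pos_j[, 2])^2
  exp(-d2 / (2 * params$sigma_k^2))
}

#' Expected synapse losses from random element deletion
#'
#' Analytic expectation of the synapse loss per partner when `n_delete`
#' elements are drawn uniformly without replacement from a pool of `n_total`
#' elements: `n_delete * omega_counts / n_total`. This is the analytic twin
#' of [delete_elements()] and is used as a test oracle and for reporting
#' only.
#'
#' @param omega_counts Synapse counts with each partner (a row or column of
#'   the connectivity matrix).
#' @param n_delete Number of elements to delete.
#' @param n_total Total number of elements in the pool (bound + vacant).
#' @return Expected loss per partner.
#' @export
expected_deletions <- function(omega_counts, n_delete, n_total) {
  if (n_total == 0) stop("n_total must be positive")
  n_delete * omega_counts / n_total
}

# Counterpart class of a bound element: axonal elements bind dendritic
# elements of the owner's sign; dendritic elements bind axonal elements.
counterpart_key <- function(key, owner_sign) {
  if (key == "ax") { if (owner_sign > 0) "de" else "di" } else "ax"
}

#' Delete synaptic elements from one pool
#'
#' Draws `n_delete` elements uniformly without replacement from the union of
#' vacant and bound elements of one pool (all elements have an equal chance,
#' regardless of binding state). Deleting a bound element immediately breaks
#' its synapse: the connectivity matrix is decremented and the counterpart
#' element on the partner neuron becomes vacant without changing that
#' partner's total element count. The continuous count `z` is not touched:
#' deletions realize a drop of `floor(z)` that the growth integration or
#' vacancy decay has already produced, so record counts are reconciled to
#' `floor(z)`, never the other way around.
#'
#' @inheritParams element_pool
#' @param n_delete Number of elements to delete; at most the pool size.
#' @return The updated network, with attribute `"freed"`: a list of
#'   parallel vectors (`neuron`, `class`, `element_id`) naming the
#'   counterpart elements made vacant.
#' @export
delete_elements <- function(network, neuron, class, n_delete) {
  k <- cls_key(class)
  f <- FLD[[k]]
  idf <- f[["ids"]]; prtf <- f[["prt"]]; pnf <- f[["pn"]]
  m <- length(network[[idf]][[neuron]])
  if (n_delete > m)
    stop("cannot delete ", n_delete, " elements from a pool of ", m)
  freed <- list(neuron = integer(0), class = character(0),
                element_id = numeric(0))
  if (n_delete > 0) {
    sel <- sample.int(m, n_delete)
    prt <- network[[prtf]][[neuron]][sel]
    pn <- network[[pnf]][[neuron]][sel]
    bound <- which(prt > 0)
    ck <- counterpart_key(k, network$sgn[neuron])
    cf <- FLD[[ck]]
    for (b in bound) {
      j <- pn[b]
      if (k == "ax") {
        network$omega[neuron, j] <- network$omega[neuron, j] - 1
      } else {
        network$omega[j, neuron] <- network$omega[j, neuron] - 1
      }
      at <- match(prt[b], network[[cf[["ids"]]]][[j]])
      network[[cf[["prt"]]]][[j]][at] <- 0
      network[[cf[["pn"]]]][[j]][at] <- 0L
    }
    if (length(bound))
      freed <- list(neuron = pn[bound],
                    class = ELEMENT_CLASSES[match(ck, c("ax", "de", "di"))],
                    element_id = prt[bound])
    network[[idf]][[neuron]] <- network[[idf]][[neuron]][-sel]
    network[[prtf]][[neuron]] <- network[[prtf]][[neuron]][-sel]
    network[[pnf]][[neuron]] <- network[[pnf]][[neuron]][-sel]
  }
  attr(network, "freed") <- freed
  network
}

#' Expected synapse formation matrix
#'
#' Analytic approximation of the expected number of new synapses per ordered
#' neuron pair in one connectivity update:
#' `a_vac[i] * d_vac[j] / max(sum(a_vac), sum(d_vac)) * K(i, j)`. Oracle and
#' reporting only; the algorithmic procedure is [form_synapses()].
#'
#' @param a_vac,d_vac Vacant axonal / dendritic element counts per neuron
#'   (sign-matched pools).
#' @param pos Two-column position matrix in micrometers.
#' @param params A [kernel_params()] object.
#' @param allow_autapse Keep the diagonal (self-pairs)? The simulator rejects
#'   autapses, so the default drops it.
#' @return Matrix of expected new synapses, `[i, j]` = from i to j.
#' @export
expected_formations <- function(a_vac, d_vac, pos, params,
                                allow_autapse = FALSE) {
  denom <- max(sum(a_vac), sum(d_vac))
  n <- length(a_vac)
  if (denom == 0) return(matrix(0, n, n))
  K <- exp(-as.matrix(stats::dist(pos))^2 / (2 * params$sigma_k^2))
  out <- outer(a_vac, d_vac) / denom * K
  if (!allow_autapse) diag(out) <- 0
  out
}

#' Form synapses from vacant complementary elements
#'
#' One proposal round of the random, simultaneous, distance-dependent merging
#' of vacant elements for one synapse sign: all vacant axonal elements of
#' neurons with the given sign and all vacant dendritic elements of the
#' matching class (on any neuron) are pooled; the smaller side is matched
#' uniformly at random, without replacement, into the larger. Each proposed
#' pair (i -> j) is accepted with probability [formation_kernel()] of the two
#' positions; self-pairs (autapses) are rejected. Accepted pairs bind both
#' elements and increment the connectivity matrix; rejected and unmatched
#' elements remain vacant until a later update.
#'
#' @param network A network object.
#' @param sign `"exc"` or `"inh"`: which synapse class to form.
#' @return The updated network, with attribute `"formed"`: a list of
#'   parallel vectors `pre`, `post`, `axonal_element`, `dendritic_element`,
#'   one entry per new synapse.
#' @export
form_synapses <- function(network, sign = c("exc", "inh")) {
  sign <- match.arg(sign, c("exc", "inh"))
  dk <- if (sign == "exc") "de" else "di"
  dkf <- FLD[[dk]]
  pre_ok <- if (sign == "exc") network$sgn > 0 else network$sgn < 0
  nv_ax <- lengths(network$ids_ax) - bound_counts(network, "ax")
  nv_de <- lengths(network[[dkf[["ids"]]]]) - bound_counts(network, dk)
  ax_n <- integer(0); ax_at <- integer(0)
  for (i in which(pre_ok & nv_ax > 0)) {
    v <- vacant_idx(network, i, "ax")
    ax_n <- c(ax_n, rep(i, length(v))); ax_at <- c(ax_at, v)
  }
  de_n <- integer(0); de_at <- integer(0)
  for (j in which(nv_de > 0)) {
    v <- vacant_idx(network, j, dk)
    de_n <- c(de_n, rep(j, length(v))); de_at <- c(de_at, v)
  }
  f_pre <- integer(0); f_post <- integer(0)
  f_aid <- numeric(0); f_did <- numeric(0)
  na <- length(ax_n); nd <- length(de_n)
  if (na > 0 && nd > 0) {
    if (na <= nd) {
      pick <- sample.int(nd, na)
      pa <- seq_len(na); pd <- pick
    } else {
      pick <- sample.int(na, nd)
      pa <- pick; pd <- seq_len(nd)
    }
    pre <- ax_n[pa]; post <- de_n[pd]
    acc <- stats::runif(length(pre)) <
      formation_kernel(network$pos[pre, , drop = FALSE],
                       network$pos[post, , drop = FALSE],
                       network$params$kernel)
    acc <- acc & pre != post
    hits <- which(acc)
    f_pre <- pre[hits]; f_post <- post[hits]
    f_aid <- numeric(length(hits)); f_did <- numeric(length(hits))
    for (w in seq_along(hits)) {
      q <- hits[w]
      i <- pre[q]; j <- post[q]
      ai <- ax_at[pa[q]]; dj <- de_at[pd[q]]
      aid <- network$ids_ax[[i]][ai]
      did <- network[[dkf[["ids"]]]][[j]][dj]
      network$prt_ax[[i]][ai] <- did
      network$pn_ax[[i]][ai] <- j
      network[[dkf[["prt"]]]][[j]][dj] <- aid
      network[[dkf[["pn"]]]][[j]][dj] <- i
      network$omega[i, j] <- network$omega[i, j] + 1
      f_aid[w] <- aid; f_did[w] <- did
    }
  }
  attr(network, "formed") <- list(
    pre = f_pre, post = f_post,
    axonal_element = f_aid, dendritic_element = f_did)
  network
}

#' Run one connectivity update
#'
#' The discrete rewiring step interleaved with activity windows. In order:
#' (1) integrate the continuous element counts of every class under the
#' current calcium trace; (2) delete elements wherever a pool holds more
#' discrete records than `floor(z)`, breaking synapses of bound victims;
#' (3) decay vacant elements; (4) instantiate new vacant records for
#' increases of `floor(z)`; (5) form synapses, excitatory and inhibitory
#' pools processed independently. On exit every pool satisfies
#' `#records == floor(z)` and the connectivity matrix is consistent with the
#' bound-element bookkeeping.
#'
#' @param network A network object.
#' @param window Activity-window length in ms represented by this update
#'   (defaults to the network's configured update interval).
#' @param validate Run the full invariant scan afterwards (slow; used in
#'   tests) and abort with a diagnostic on any breach.
#' @return The updated network, with attribute `"update_log"`: a named
#'   vector with the update index and formation/deletion/synapse totals.
#' @export
connectivity_update <- function(network, window = NULL, validate = FALSE) {
  if (is.null(window)) window <- network$params$update_interval_ms
  for (cls in ELEMENT_CLASSES) {
    k <- cls_key(cls)
    zf <- paste0("z_", k)
    network[[zf]] <- integrate_elements(network[[zf]], network$ca,
                                        network$params$curves[[cls]], window)
  }
  deleted <- 0L
  for (cls in ELEMENT_CLASSES) {
    k <- cls_key(cls)
    shortfall <- lengths(network[[paste0("ids_", k)]]) -
      floor(network[[paste0("z_", k)]])
    for (i in which(shortfall > 0)) {
      network <- delete_elements(network, i, cls, shortfall[i])
      deleted <- deleted + shortfall[i]
    }
  }
  network <- decay_vacant(network)
  network <- reconcile_creations(network)
  formed <- 0L
  for (sg in c("exc", "inh")) {
    network <- form_synapses(network, sg)
    formed <- formed + length(attr(network, "formed")$pre)
  }
  network$update_index <- network$update_index + 1L
  attr(network, "formed") <- NULL
  attr(network, "freed") <- NULL
  attr(network, "update_log") <- c(
    update = network$update_index, formed = formed,
    deleted = as.integer(deleted), synapses = sum(network$omega))
  if (validate) validate_network(network)
  network
}

#' Derive the synapse table
#'
#' One row per synapse, reconstructed from the bound axonal elements; the
#' number of rows always equals `sum(omega)`.
#'
#' @param network A network object.
#' @return Data frame with columns `pre`, `post`, `axonal_element`,
#'   `dendritic_element`.
#' @export
synapse_table <- function(network) {
  pre <- integer(0); post <- integer(0); ae <- numeric(0); de <- numeric(0)
  for (i in seq_len(network$n)) {
    b <- which(network$prt_ax[[i]] > 0)
    if (length(b)) {
      pre <- c(pre, rep(i, length(b)))
      post <- c(post, network$pn_ax[[i]][b])
      ae <- c(ae, network$ids_ax[[i]][b])
      de <- c(de, network$prt_ax[[i]][b])
    }
  }
  data.frame(pre = pre, post = post, axonal_element = ae,
             dendritic_element = de)
}

#' Scan all structural invariants
#'
#' Checks, and aborts with a diagnostic if violated: non-negative integer
#' connectivity; row/column sums of the connectivity matrix equal to the
#' bound axonal / sign-matched dendritic element counts; floor-consistency
#' of every pool (`#records == floor(z)`); reciprocal partner links; and sign
#' correctness of every synapse.
#'
#' @param network A network object.
#' @return Invisibly `TRUE` on success.
#' @export
validate_network <- function(network) {
  om <- network$omega
  if (any(om < 0) || any(om != round(om)))
    stop("connectivity matrix has negative or non-integer entries")
  for (cls in ELEMENT_CLASSES) {
    k <- cls_key(cls)
    nrec <- lengths(network[[paste0("ids_", k)]])
    fz <- floor(network[[paste0("z_", k)]])
    if (any(nrec != fz))
      stop("floor-consistency violated for ", cls, " pools of neurons ",
           paste(which(nrec != fz), collapse = ", "))
    bound <- vapply(network[[paste0("prt_", k)]],
                    function(p) sum(p > 0), integer(1))
    expected <- switch(k,
      ax = rowSums(om),
      de = colSums(om[network$sgn > 0, , drop = FALSE]),
      di = colSums(om[network$sgn < 0, , drop = FALSE]))
    if (any(bound != expected))
      stop("bound-element counts inconsistent with omega for ", cls)
  }
  for (i in seq_len(network$n)) {
    b <- which(network$prt_ax[[i]] > 0)
    for (q in b) {
      j <- network$pn_ax[[i]][q]
      dk <- if (network$sgn[i] > 0) "de" else "di"
      at <- match(network$prt_ax[[i]][q], network[[paste0("ids_", dk)]][[j]])
      if (is.na(at) ||
          network[[paste0("prt_", dk)]][[j]][at] != network$ids_ax[[i]][q])
        stop("broken partner link on synapse ", i, " -> ", j)
    }
  }
  invisible(TRUE)
}
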