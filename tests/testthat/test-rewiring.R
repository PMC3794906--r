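test_that("formation kernel: unit at zero distance, symmetric, monotone", {
  kp <- kernel_params(200)
  expect_equal(formation_kernel(c(0, 0), c(0, 0), kp), 1)
  set.seed(1)
  a <- matrix(runif(20, 0, 1000), 10)
  b <- matrix(runif(20, 0, 1000), 10)
  expect_equal(formation_kernel(a, b, kp), formation_kernel(b, a, kp))
  d <- seq(0, 1000, by = 50)
  k <- formation_kernel(cbind(d, 0), cbind(0, 0), kp)
  expect_true(all(diff(k) < 0))
  expect_true(all(k > 0 & k <= 1))
})

test_that("expected deletions follow the proportional-loss formula", {
  expect_equal(expected_deletions(0, 3, 10), 0)
  expect_equal(expected_deletions(c(5, 3), 2, 10), c(1.0, 0.6))
  # deleting everything loses every synapse
  expect_equal(expected_deletions(c(5, 3), 10, 10), c(5, 3))
  expect_error(expected_deletions(1, 1, 0), "positive")
})

test_that("random element deletion matches its analytic expectation", {
  # pool of 10 axonal elements on neuron 1: 5 bound to j1, 3 to j2, 2 vacant
  base <- tiny_network()
  base <- plant_vacant(base, 1, "axonal", 10)
  base <- plant_vacant(base, 2, "dendritic_exc", 5)
  base <- plant_vacant(base, 3, "dendritic_exc", 3)
  for (i in 1:5) base <- bind_pair(base, 1, 2)
  for (i in 1:3) base <- bind_pair(base, 1, 3)
  set.seed(11)
  trials <- 10000
  loss1 <- integer(trials); loss2 <- integer(trials)
  for (t in seq_len(trials)) {
    out <- delete_elements(base, 1, "axonal", 2)
    loss1[t] <- 5 - out$omega[1, 2]
    loss2[t] <- 3 - out$omega[1, 3]
  }
  exp12 <- expected_deletions(c(5, 3), 2, 10)
  expect_lt(abs(mean(loss1) - exp12[1]), 3 * sd(loss1) / sqrt(trials))
  expect_lt(abs(mean(loss2) - exp12[2]), 3 * sd(loss2) / sqrt(trials))
})

test_that("deletion bookkeeping frees the counterpart element", {
  net <- tiny_network()
  net <- plant_vacant(net, 1, "axonal", 1)
  net <- plant_vacant(net, 2, "dendritic_exc", 1)
  net <- bind_pair(net, 1, 2)
  # deleting the bound dendritic element on 2 decrements the presynaptic
  # row sum by exactly 1 and frees exactly one axonal element on 1
  out <- delete_elements(net, 2, "dendritic_exc", 1)
  expect_equal(sum(out$omega[1, ]), 0)
  expect_equal(length(out$ids_ax[[1]]), 1)
  expect_true(all(out$prt_ax[[1]] == 0))
  freed <- attr(out, "freed")
  expect_equal(freed$neuron, 1L)
  expect_equal(freed$class, "axonal")
  # no-op and contract violation
  expect_identical(delete_elements(net, 3, "axonal", 0)$omega, net$omega)
  expect_error(delete_elements(net, 1, "axonal", 5), "cannot delete")
})

test_that("synapse formation matches the vacancy-product expectation", {
  # two neurons at distance d: 2 vacant axons on 1, 3 vacant dendrites on 2
  g <- network_geometry(c(2, 2), jitter_sd = 0)
  base <- build_network(g, kernel = kernel_params(100))
  d <- sqrt(sum((base$pos[1, ] - base$pos[2, ])^2))
  K <- formation_kernel(base$pos[1, ], base$pos[2, ], base$params$kernel)
  base <- plant_vacant(base, 1, "axonal", 2)
  base <- plant_vacant(base, 2, "dendritic_exc", 3)
  E <- expected_formations(c(2, 0, 0, 0, 0), c(0, 3, 0, 0, 0), base$pos,
                           base$params$kernel)
  expect_equal(E[1, 2], 2 * K)
  set.seed(21)
  trials <- 10000
  formed <- integer(trials)
  for (t in seq_len(trials))
    formed[t] <- length(attr(form_synapses(base, "exc"), "formed")$pre)
  expect_lt(abs(mean(formed) - 2 * K), 3 * sd(formed) / sqrt(trials))
  # empty sides form nothing
  expect_equal(length(attr(form_synapses(tiny_network(), "exc"),
                           "formed")$pre), 0)
})

test_that("a complementary pair at zero distance always forms a synapse", {
  net <- tiny_network()
  net$pos[2, ] <- net$pos[1, ]
  net <- plant_vacant(net, 1, "axonal", 1)
  net <- plant_vacant(net, 2, "dendritic_exc", 1)
  set.seed(2)
  for (t in 1:50) {
    out <- form_synapses(net, "exc")
    expect_equal(out$omega[1, 2], 1)
  }
})

test_that("autapses are rejected and elements stay vacant", {
  net <- tiny_network()
  net <- plant_vacant(net, 1, "axonal", 1)
  net <- plant_vacant(net, 1, "dendritic_exc", 1)
  set.seed(3)
  for (t in 1:50) {
    out <- form_synapses(net, "exc")
    expect_equal(sum(out$omega), 0)
    expect_true(all(out$prt_ax[[1]] == 0))
  }
})

test_that("expected formations: totals, limits and autapse masking", {
  # everyone at the same position (kernel 1), equal totals: sum equals total
  pos <- matrix(0, 4, 2)
  E <- expected_formations(c(2, 1, 0, 1), c(1, 1, 1, 1), pos,
                           kernel_params(100), allow_autapse = TRUE)
  expect_equal(sum(E), 4)
  # infinite distance kills the expectation
  pos2 <- rbind(c(0, 0), c(1e7, 0))
  E2 <- expected_formations(c(1, 0), c(0, 1), pos2, kernel_params(100))
  expect_equal(E2[1, 2], 0)
  # no vacancies anywhere: all-zero matrix
  expect_equal(sum(expected_formations(c(0, 0), c(0, 0), pos2,
                                       kernel_params(100))), 0)
})

test_that("connectivity update is a no-op at the set-point fixed point", {
  net <- tiny_network()
  net$ca <- rep(net$params$curves$axonal$eps, net$n)
  out <- connectivity_update(net, validate = TRUE)
  expect_equal(out$z_ax, net$z_ax)
  expect_equal(sum(out$omega), 0)
  expect_equal(out$update_index, net$update_index + 1L)
})

test_that("a two-element drop breaks exactly two synapses", {
  net <- tiny_network()
  net <- plant_vacant(net, 1, "axonal", 4)
  net <- plant_vacant(net, 2, "dendritic_exc", 2)
  net <- plant_vacant(net, 3, "dendritic_exc", 2)
  for (i in 1:2) net <- bind_pair(net, 1, 2)
  for (i in 1:2) net <- bind_pair(net, 1, 3)
  net$z_ax[1] <- net$z_ax[1] - 2     # growth already lowered z by 2
  net$ca <- rep(net$params$curves$axonal$eps, net$n)  # freeze growth
  netInf <- net
  netInf$params$vac <- vacancy_decay_params(Inf)
  set.seed(9)
  out <- connectivity_update(netInf, validate = TRUE)
  expect_equal(length(out$ids_ax[[1]]), 2)
  expect_equal(sum(out$omega), 2)
  # exactly two counterpart dendritic elements became vacant, same totals
  expect_equal(length(out$ids_de[[2]]) + length(out$ids_de[[3]]), 4)
  nvac <- sum(out$prt_de[[2]] == 0) + sum(out$prt_de[[3]] == 0)
  expect_equal(nvac, 2)
})

test_that("below the axonal threshold no synapses ever form", {
  net <- tiny_network()
  net$ca <- rep(0.5 * net$params$curves$axonal$eta, net$n)
  set.seed(4)
  for (k in 1:50) net <- connectivity_update(net)
  expect_equal(sum(net$omega), 0)
  expect_equal(sum(net$z_ax), 0)
  # dendritic elements do grow (their threshold is lower), but find no plugs
  expect_gt(sum(net$z_de), 0)
})

test_that("conservation and sign invariants hold across a busy run", {
  set.seed(31)
  net <- tiny_network(dims = c(4, 4), jitter = 25,
                      input = input_config(mu_ext = 2.5, sigma_ext = 3,
                                           w_syn = 3),
                      curves = physiological_curves(nu = 3e-4),
                      kernel = kernel_params(125))
  for (k in 1:120) {
    net <- simulate_window(net, 100)$network
    net <- connectivity_update(net)
  }
  expect_silent(validate_network(net))
  st <- synapse_table(net)
  expect_equal(nrow(st), sum(net$omega))
  # every synapse record links sign-matched elements
  de_ids <- unlist(net$ids_de); di_ids <- unlist(net$ids_di)
  exc_pre <- net$sgn[st$pre] > 0
  expect_true(all(st$dendritic_element[exc_pre] %in% de_ids))
  expect_true(all(st$dendritic_element[!exc_pre] %in% di_ids))
  bound_ax <- sum(vapply(net$prt_ax, function(p) sum(p > 0), integer(1)))
  bound_de <- sum(vapply(net$prt_de, function(p) sum(p > 0), integer(1)))
  bound_di <- sum(vapply(net$prt_di, function(p) sum(p > 0), integer(1)))
  expect_equal(bound_ax, sum(net$omega))
  expect_equal(bound_de + bound_di, sum(net$omega))
})

test_that("formation statistics are invariant under neuron relabeling", {
  g <- network_geometry(c(2, 2), jitter_sd = 0)
  v_ax <- c(2, 1, 0, 0, 0)
  v_de <- c(0, 0, 2, 1, 0)
  # old_of_new[k] names the original neuron now labeled k: positions and
  # vacancies move together, so formation counts must follow the labels
  mk <- function(old_of_new) {
    net <- build_network(g, kernel = kernel_params(150))
    net$pos <- net$pos[old_of_new, ]
    for (k in seq_len(net$n)) {
      if (v_ax[old_of_new[k]] > 0)
        net <- plant_vacant(net, k, "axonal", v_ax[old_of_new[k]])
      if (v_de[old_of_new[k]] > 0)
        net <- plant_vacant(net, k, "dendritic_exc", v_de[old_of_new[k]])
    }
    net
  }
  run_counts <- function(net, trials) {
    counts <- matrix(0L, net$n, net$n)
    for (t in seq_len(trials))
      counts <- counts + form_synapses(net, "exc")$omega
    counts
  }
  set.seed(41)
  old_of_new <- c(2, 1, 4, 3, 5)
  id <- run_counts(mk(1:5), 2000)
  rl <- run_counts(mk(old_of_new), 2000)
  # pair (i -> j) in the original world is (k -> l) in the relabeled one
  # where old_of_new[k] = i, old_of_new[l] = j
  new_of_old <- order(old_of_new)
  a <- c(id[1, 3], id[1, 4], id[2, 3], id[2, 4])
  b <- c(rl[new_of_old[1], new_of_old[3]], rl[new_of_old[1], new_of_old[4]],
         rl[new_of_old[2], new_of_old[3]], rl[new_of_old[2], new_of_old[4]])
  expect_gt(suppressWarnings(chisq.test(rbind(a, b))$p.value), 0.001)
})
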