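test_that("network construction matches the stated geometry", {
  set.seed(1)
  net <- build_network()
  expect_equal(net$n, 400)
  expect_equal(sum(net$kind == "exc"), 320)
  expect_equal(sum(net$kind == "inh"), 80)
  # zero connectivity, zero elements, membrane at rest, calcium zero
  expect_equal(sum(net$omega), 0)
  expect_equal(sum(lengths(net$ids_ax)), 0)
  expect_true(all(net$v == net$params$membrane$c))
  expect_true(all(net$ca == 0))
  # no jitter puts neurons exactly on their grid points
  net0 <- build_network(network_geometry(jitter_sd = 0))
  expect_true(all(net0$pos[1:320, 1] %% 100 == 0))
  expect_true(all(net0$pos[321:400, 1] %% 100 == 50))
  # high-density control: 4x the neurons in the same extent
  hd <- high_density_geometry()
  expect_equal(hd$n_exc, 1280L)
  expect_equal(hd$n_inh, 320L)
  expect_equal(hd$spacing * (hd$exc_dims - 1),
               network_geometry()$spacing * (network_geometry()$exc_dims - 1) +
                 hd$spacing)
})

test_that("lesion membership uses the half-open square convention", {
  net <- build_network(network_geometry(c(4, 4), jitter_sd = 0))
  spec <- lesion_spec(square = c(100, 200, 0, 300), onset_update = 10,
                      post_updates = 10)
  net <- define_lesion(net, spec)
  on_lo <- which(net$pos[, 1] == 100 & net$pos[, 2] < 300)  # included edge
  on_hi <- which(net$pos[, 1] == 200 & net$pos[, 2] < 300)
  expect_true(all(net$regions[on_lo] %in% c("lpz_border", "lpz_center")))
  expect_false(any(net$regions[on_hi] %in% c("lpz_border", "lpz_center")))
  # labels partition the population
  expect_true(all(net$regions %in% c("lpz_center", "lpz_border",
                                     "peri_lpz", "outside")))
  # an empty square is an error
  expect_error(define_lesion(net, lesion_spec(c(1e5, 1e5 + 1, 0, 1),
                                              onset_update = 1)),
               "no neurons")
})

test_that("large lesions leave only a thin peri ring", {
  set.seed(2)
  net <- build_network()
  net <- define_lesion(net, large_lesion())
  lpz <- sum(net$regions %in% c("lpz_center", "lpz_border"))
  peri <- sum(net$regions == "peri_lpz")
  expect_gt(lpz, 2 * peri)
  expect_gt(lpz, 250)
})

test_that("the standard protocol executes pre + post updates", {
  # full-scale default: 8000 + 5000 = 13000 connectivity updates
  cfg <- scenario_config("physiological")
  expect_equal(cfg$pre_updates + cfg$post_updates, 13000L)
  # a miniature run executes exactly the configured number of updates
  mini <- scenario_config("control", geometry = network_geometry(c(2, 2)),
                          pre_updates = 3, post_updates = 2,
                          snapshot_every = 1)
  run <- run_protocol(mini, seed = 1)
  expect_equal(run$total_updates, 5L)
  expect_equal(run$network$update_index, 5L)
  expect_equal(nrow(run$log), 5)
  expect_equal(run$log$update, 1:5)
})

test_that("runs are reproducible and controls share the pre-lesion prefix", {
  g <- network_geometry(c(2, 2))
  cfg <- scenario_config("physiological", geometry = g,
                         pre_updates = 30, post_updates = 20,
                         snapshot_every = 5,
                         lesion = lesion_spec(c(25, 175, 25, 175),
                                              onset_update = 30,
                                              post_updates = 20))
  a <- run_protocol(cfg, seed = 7)
  b <- run_protocol(cfg, seed = 7)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$network$omega, b$network$omega)
  ctl <- run_protocol(cfg, seed = 7, control = TRUE)
  expect_true(ctl$control)
  pre_idx <- which(vapply(a$snapshots, `[[`, numeric(1), "update") <= 30)
  expect_identical(a$snapshots[pre_idx], ctl$snapshots[pre_idx])
  # variants built in one call are the same as separate runs
  both <- run_protocol_variants(cfg, seed = 7,
                                variants = c("lesion", "control"))
  expect_identical(both$lesion$snapshots, a$snapshots)
  expect_identical(both$control$snapshots, ctl$snapshots)
  expect_identical(both$lesion$network$omega, a$network$omega)
})

test_that("input manipulations scale the external drive as configured", {
  set.seed(3)
  net <- build_network(network_geometry(c(4, 4)))
  net <- define_lesion(net, lesion_spec(c(100, 250, 100, 250),
                                        onset_update = 1))
  peri <- net$regions == "peri_lpz"
  expect_error(apply_input_manipulation(net, "peri_lpz", 1.2), "0, 1")
  blocked <- apply_input_manipulation(net, "peri_lpz", 0)
  expect_true(all(sample_external_input(net$params$input,
                                        blocked$input_multiplier)[peri] == 0))
  reduced <- apply_input_manipulation(net, "peri_lpz", 0.8)
  set.seed(4)
  draws <- replicate(2000, mean(sample_external_input(
    net$params$input, reduced$input_multiplier)[peri]))
  expect_equal(mean(draws), 0.8 * net$params$input$mu_ext, tolerance = 0.02)
  # factor 1 leaves the multiplier untouched
  same <- apply_input_manipulation(net, "peri_lpz", 1)
  expect_identical(same$input_multiplier, net$input_multiplier)
})

test_that("phase windows reproduce the printed analysis windows", {
  ph <- phase_windows(5000)
  expect_equal(ph$early, c(1, 1000))
  expect_equal(ph$middle, c(2000, 3000))
  expect_equal(ph$late, c(4000, 5000))
  ph2 <- phase_windows(2500)
  expect_equal(ph2$middle, c(1000, 1500))
  # day mapping is linear with 5000 updates = 72 days
  expect_equal(update_to_day(0), 0)
  expect_equal(update_to_day(5000), 72)
  expect_equal(update_to_day(2500), 36)
})
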