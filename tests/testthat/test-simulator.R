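test_that("population initialization honors the requested mix", {
  net <- well_mixed_network(10000)
  set.seed(1)
  st <- initialize_population(net, c(C = 0.5, D = 0.5), "pairwise_plain")
  fC <- mean(strategy_action(st) == "C")
  se <- sqrt(0.25 / net$n)
  expect_lt(abs(fC - 0.5), 3 * se)

  st4 <- initialize_population(net, variant = "four_strategy")
  tab <- tabulate(st4, 4) / net$n
  expect_true(all(abs(tab - 0.25) < 3 * sqrt(0.25 * 0.75 / net$n)))

  all_c <- initialize_population(net, c(C = 1), "pairwise_plain")
  expect_true(all(strategy_action(all_c) == "C"))

  ex <- initialize_population(well_mixed_network(100),
                              c(HC = 0.25, HD = 0.25, NHC = 0.25, NHD = 0.25),
                              "four_strategy", exact = TRUE)
  expect_equal(tabulate(ex, 4), rep(25L, 4))

  expect_error(initialize_population(net, c(C = 0.6, D = 0.5),
                                     "pairwise_plain"), "sum to 1")
  expect_error(initialize_population(net, c(HX = 1), "four_strategy"),
               "unknown strategy")
})

test_that("realizations record a frequency partition every step", {
  net <- lattice_network(8, 8)
  sc <- sim_config(max_steps = 60, realizations = 1)
  ser <- run_realization(net, game_params(-0.2, 1.2), herding_params(1),
                         dynamics_params(variant = "four_strategy"), sc,
                         seed = 3)
  expect_equal(nrow(ser$freq), 61L)
  expect_true(all(abs(rowSums(ser$freq) - 1) < 1e-12))
  expect_true(all(ser$freq >= 0 & ser$freq <= 1))
  # same seed twice: bit-identical series
  ser2 <- run_realization(net, game_params(-0.2, 1.2), herding_params(1),
                          dynamics_params(variant = "four_strategy"), sc,
                          seed = 3)
  expect_identical(ser$freq, ser2$freq)
  expect_identical(ser$final_state, ser2$final_state)
})

test_that("the harmony game fixes cooperation from interior starts", {
  net <- lattice_network(10, 10)
  sc <- sim_config(max_steps = 400, realizations = 1)
  ser <- run_realization(net, game_params(0.5, 0.5), herding_params(0),
                         dynamics_params(mu = 0, variant = "pairwise_plain"),
                         sc, seed = 2)
  coop <- ser$freq[, "HC"] + ser$freq[, "NHC"]
  expect_equal(coop[length(coop)], 1)
  hit <- which(coop == 1)[1]
  expect_true(all(coop[hit:length(coop)] == 1))  # absorbing once reached
})

test_that("stationary summaries average the requested tail window", {
  const <- matrix(0.25, nrow = 40, ncol = 4,
                  dimnames = list(NULL, c("HC", "HD", "NHC", "NHD")))
  s <- summarize_stationary(const, 0.25)
  expect_equal(unname(s[c("HC", "HD", "NHC", "NHD")]), rep(0.25, 4))
  expect_equal(unname(s["cooperation"]), 0.5)
  expect_equal(unname(s["herder"]), 0.5)

  step <- matrix(0, nrow = 4, ncol = 4,
                 dimnames = list(NULL, c("HC", "HD", "NHC", "NHD")))
  step[, "HC"] <- c(0, 0, 1, 1)
  step[, "HD"] <- c(1, 1, 0, 0)
  expect_equal(unname(summarize_stationary(step, 0.5)["HC"]), 1)

  # a 3000-entry series with fraction 0.25 averages exactly the last 750
  ramp <- matrix(0, nrow = 3000, ncol = 4,
                 dimnames = list(NULL, c("HC", "HD", "NHC", "NHD")))
  ramp[, "HC"] <- seq(0, 1, length.out = 3000)
  ramp[, "HD"] <- 1 - ramp[, "HC"]
  expect_equal(unname(summarize_stationary(ramp, 0.25)["HC"]),
               mean(ramp[2251:3000, "HC"]))

  expect_error(summarize_stationary(ramp, 0), "measure_fraction")
})

test_that("experiments aggregate realizations deterministically", {
  net <- lattice_network(6, 6)
  gp <- game_params(0.3, 0.8); hp <- herding_params(1)
  dp <- dynamics_params(variant = "four_strategy")
  sc1 <- sim_config(max_steps = 40, realizations = 1, master_seed = 5)
  ex1 <- run_experiment(net, gp, hp, dp, sc1)
  ser <- run_realization(net, gp, hp, dp, sc1, seed = 6)  # master_seed + 1
  expect_equal(unname(ex1$mean), unname(summarize_stationary(ser, 0.25)))
  expect_true(all(ex1$sd == 0))

  sc3 <- sim_config(max_steps = 40, realizations = 3, master_seed = 5)
  exa <- run_experiment(net, gp, hp, dp, sc3)
  exb <- run_experiment(net, gp, hp, dp, sc3)
  expect_identical(exa$mean, exb$mean)
  expect_identical(exa$per_realization, exb$per_realization)
})

test_that("an all-defector start under zero mutation stays fully defecting", {
  net <- lattice_network(6, 6)
  sc <- sim_config(max_steps = 30, realizations = 2, master_seed = 2,
                   initial_mix = c(D = 1))
  ex <- run_experiment(net, game_params(-0.5, 1.5), herding_params(1),
                       dynamics_params(mu = 0, variant = "pairwise_herding"),
                       sc)
  expect_equal(unname(ex$mean["cooperation"]), 0)
  expect_equal(unname(ex$sd["cooperation"]), 0)
})

test_that("scale-free experiments draw a fresh network per realization", {
  spec <- network_spec("scale_free", n = 60, m = 2)
  sc <- sim_config(max_steps = 20, realizations = 2, master_seed = 9)
  ex <- run_experiment(spec, game_params(0, 1), herding_params(1),
                       dynamics_params(variant = "four_strategy"), sc)
  expect_equal(nrow(ex$per_realization), 2L)
  # deterministic: same config, same summary
  ex2 <- run_experiment(spec, game_params(0, 1), herding_params(1),
                        dynamics_params(variant = "four_strategy"), sc)
  expect_identical(ex$per_realization, ex2$per_realization)
})

test_that("experiment objects print, summarize and plot", {
  net <- lattice_network(5, 5)
  ex <- run_experiment(net, game_params(0.5, 0.5), herding_params(0),
                       dynamics_params(variant = "pairwise_plain"),
                       sim_config(max_steps = 20, realizations = 1),
                       keep_series = TRUE)
  expect_output(print(ex), "herd_experiment")
  s <- summary(ex)
  expect_s3_class(s, "data.frame")
  expect_true("cooperation" %in% s$quantity)
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(ex))
  expect_invisible(plot(ex$series, what = "payoffs"))
})
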