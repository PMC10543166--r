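test_that("Fermi rule is the logistic in the payoff difference", {
  expect_equal(fermi_probability(0, 5), 0.5)
  expect_equal(fermi_probability(1, 5), 1 / (1 + exp(-5)))
  x <- seq(-3, 3, by = 0.25)
  expect_equal(fermi_probability(x, 2) + fermi_probability(-x, 2),
               rep(1, length(x)))
  # strictly increasing, overflow-safe, clamped into the open interval
  p <- fermi_probability(c(-1e6, -10, 0, 10, 1e6), 5)
  expect_true(all(diff(p) >= 0))
  expect_true(all(is.finite(p)))
  expect_gt(p[1], 0)
  expect_lt(p[5], 1)
})

test_that("effective payoffs follow the focal player's herding trait", {
  net <- path5_network()
  gp <- game_params(-0.5, 1.5)
  hp <- herding_params(2)
  st <- c(1L, 4L, 2L, 3L, 1L)  # HC ~HD HD ~HC HC
  pv <- payoff_vector(st, net, gp, hp)

  # four-strategy: herding focal discounts both sides
  ep <- effective_payoffs(1, 2, pv, st, net, "four_strategy")
  expect_equal(unname(ep), c(pv$raw[1] - pv$herding_cost[1],
                             pv$raw[2] - pv$herding_cost[2]))
  # non-herding focal uses raw payoffs even against a herding model
  ep2 <- effective_payoffs(2, 3, pv, st, net, "four_strategy")
  expect_equal(unname(ep2), c(pv$raw[2], pv$raw[3]))
  # pairwise_herding discounts everyone; pairwise_plain no one
  ep3 <- effective_payoffs(1, 2, pv, st, net, "pairwise_herding")
  expect_equal(unname(ep3), unname(ep))
  ep4 <- effective_payoffs(1, 2, pv, st, net, "pairwise_plain")
  expect_equal(unname(ep4), c(pv$raw[1], pv$raw[2]))

  # tau = 0 collapses every variant to the plain comparison
  pv0 <- payoff_vector(st, net, gp, herding_params(0))
  for (v in c("pairwise_plain", "pairwise_herding", "four_strategy"))
    expect_equal(unname(effective_payoffs(1, 2, pv0, st, net, v)),
                 c(pv0$raw[1], pv0$raw[2]))

  expect_error(effective_payoffs(1, 4, pv, st, net, "four_strategy"),
               "not adjacent")
})

test_that("one synchronous step matches the straight-line oracle exactly", {
  net <- path5_network()
  gp <- game_params(-0.6, 1.3)
  hp <- herding_params(1.2)
  cases <- expand.grid(variant = c("pairwise_plain", "pairwise_herding",
                                   "four_strategy"),
                       mu = c(0, 0.3), seed = c(2, 17),
                       stringsAsFactors = FALSE)
  for (r in seq_len(nrow(cases))) {
    v <- cases$variant[r]
    st <- if (v == "four_strategy") c(1L, 2L, 3L, 4L, 1L)
          else c(3L, 4L, 4L, 3L, 3L)
    dp <- dynamics_params(beta = 5, mu = cases$mu[r], variant = v)
    set.seed(cases$seed[r])
    got <- synchronous_step(st, net, gp, hp, dp)
    set.seed(cases$seed[r])
    want <- oracle_step(st, net$adj, net$mean_degree, gp$S, gp$T,
                        hp$tau, dp$beta, dp$mu, v)
    expect_identical(got, want)
  }
})

test_that("the step oracle also agrees on a well-mixed population", {
  wm <- well_mixed_network(6)
  gp <- game_params(0.2, 1.1)
  hp <- herding_params(0.8, "well_mixed")
  dp <- dynamics_params(beta = 5, mu = 0.2, variant = "four_strategy")
  st <- c(1L, 2L, 3L, 4L, 1L, 2L)
  # oracle on the explicit complete graph; <k> reference is Z - 1
  adj <- lapply(1:6, function(i) setdiff(1:6, i))
  set.seed(31)
  got <- synchronous_step(st, wm, gp, hp, dp)
  set.seed(31)
  want <- oracle_step_wm(st, gp$S, gp$T, hp$tau, dp$beta, dp$mu)
  expect_identical(got, want)
})

test_that("homogeneous states are absorbing when mutation is off", {
  net <- lattice_network(4, 4)
  gp <- game_params(-1, 2)
  hp <- herding_params(1)
  for (v in c("pairwise_plain", "pairwise_herding", "four_strategy")) {
    code <- if (v == "four_strategy") 1L else 4L
    st <- rep(code, net$n)
    dp <- dynamics_params(mu = 0, variant = v)
    set.seed(5)
    expect_identical(synchronous_step(st, net, gp, hp, dp), st)
  }
})

test_that("full mutation redraws uniformly over the strategy set", {
  net <- lattice_network(10, 10)
  dp <- dynamics_params(mu = 1, variant = "four_strategy")
  gp <- game_params(0, 1); hp <- herding_params(1)
  set.seed(123)
  counts <- integer(4)
  for (rep in 1:30) {
    st <- synchronous_step(rep(1L, net$n), net, gp, hp, dp)
    counts <- counts + tabulate(st, 4)
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.001)
  # two-strategy variants stay inside their set
  dp2 <- dynamics_params(mu = 1, variant = "pairwise_plain")
  st2 <- synchronous_step(rep(3L, net$n), net, gp, hp, dp2)
  expect_true(all(st2 %in% 3:4))
})

test_that("strategy-set closure holds along random trajectories", {
  net <- scale_free_network(50, 2, seed = 2)
  gp <- game_params(-0.5, 1.5); hp <- herding_params(1)
  for (v in c("pairwise_plain", "four_strategy")) {
    dp <- dynamics_params(mu = 0.05, variant = v)
    set.seed(77)
    st <- initialize_population(net, variant = v)
    for (t in 1:20) {
      st <- synchronous_step(st, net, gp, hp, dp)
      expect_true(all(st %in% strategy_set(v)))
    }
  }
})

test_that("with tau = 0 the herding kernel is the plain kernel", {
  # identical RNG protocol => matched seeds give bit-identical trajectories
  net <- scale_free_network(80, 2, seed = 9)
  gp <- game_params(-0.4, 1.6)
  dp <- dynamics_params(mu = 0.02, variant = "pairwise_plain")
  dph <- dynamics_params(mu = 0.02, variant = "pairwise_herding")
  set.seed(14)
  st0 <- initialize_population(net, variant = "pairwise_plain")
  a <- st0; b <- st0
  set.seed(100)
  for (t in 1:30) a <- synchronous_step(a, net, gp, herding_params(0), dp)
  set.seed(100)
  for (t in 1:30) b <- synchronous_step(b, net, gp, herding_params(0), dph)
  expect_identical(a, b)
})

test_that("imitation probability is monotone in the model's payoff", {
  p <- fermi_probability(seq(-2, 2, by = 0.1), 5)
  expect_true(all(diff(p) > 0))
})
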