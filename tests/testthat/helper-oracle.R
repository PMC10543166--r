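# Straight-line pure-R oracles, independent of the package's engine.
# Strategy codes: 1 = HC, 2 = HD, 3 = ~HC, 4 = ~HD.

ORACLE_ACTION <- function(code) c("C", "D", "C", "D")[code]
ORACLE_HERD <- function(code) code <= 2L

oracle_payoff_entry <- function(a_focal, a_other, S, Tv) {
  if (a_focal == "C" && a_other == "C") return(1)
  if (a_focal == "C" && a_other == "D") return(S)
  if (a_focal == "D" && a_other == "C") return(Tv)
  0
}

# nested-loop payoff, cost and ratio recomputation from an adjacency list
oracle_payoff_vector <- function(state, adj, mean_k, S, Tv, tau) {
  n <- length(state)
  a <- ORACLE_ACTION(state)
  raw <- numeric(n); cost <- numeric(n); ratio <- numeric(n)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    p <- 0; d <- 0
    for (j in nb) {
      p <- p + oracle_payoff_entry(a[i], a[j], S, Tv)
      if (a[j] != a[i]) d <- d + 1
    }
    raw[i] <- p
    ratio[i] <- if (length(nb) > 0) d / length(nb) else 0
    k <- length(nb)
    cost[i] <- if (k > 0) tau * (k / mean_k) * ratio[i] else 0
  }
  list(raw = raw, cost = cost, ratio = ratio)
}

oracle_fermi <- function(diff, beta) 1 / (1 + exp(-beta * diff))

# One synchronous step, consuming runif(1) draws in the engine's documented
# order: per node u1 (mutation gate); then either u2 (mutation pick) or
# u2 (model neighbour) + u3 (Fermi coin). Crowdless nodes draw only u1.
oracle_step <- function(state, adj, mean_k, S, Tv, tau, beta, mu, variant) {
  n <- length(state)
  pv <- oracle_payoff_vector(state, adj, mean_k, S, Tv, tau)
  nset <- if (variant == "four_strategy") 4L else 2L
  base <- if (variant == "four_strategy") 0L else 2L
  out <- integer(n)
  for (i in seq_len(n)) {
    cur <- state[i]
    nxt <- cur
    u1 <- runif(1)
    if (u1 < mu) {
      u2 <- runif(1)
      pick <- min(floor(u2 * nset), nset - 1)
      nxt <- as.integer(base + pick + 1)
    } else if (length(adj[[i]]) > 0) {
      u2 <- runif(1)
      k <- length(adj[[i]])
      j <- adj[[i]][as.integer(min(floor(u2 * k), k - 1)) + 1L]
      discount <- switch(variant,
        pairwise_plain = FALSE,
        pairwise_herding = TRUE,
        four_strategy = ORACLE_HERD(cur))
      pi_i <- pv$raw[i]; pi_j <- pv$raw[j]
      if (discount) { pi_i <- pi_i - pv$cost[i]; pi_j <- pi_j - pv$cost[j] }
      p <- oracle_fermi(pi_j - pi_i, beta)
      u3 <- runif(1)
      if (u3 < p) nxt <- state[j]
    }
    out[i] <- nxt
  }
  out
}

# well-mixed synchronous step: crowd is everyone else, cost tau * r_i,
# model drawn uniformly among the other Z - 1 players
oracle_step_wm <- function(state, S, Tv, tau, beta, mu,
                           variant = "four_strategy") {
  n <- length(state)
  a <- ORACLE_ACTION(state)
  raw <- numeric(n); cost <- numeric(n)
  for (i in seq_len(n)) {
    p <- 0; d <- 0
    for (j in seq_len(n)[-i]) {
      p <- p + oracle_payoff_entry(a[i], a[j], S, Tv)
      if (a[j] != a[i]) d <- d + 1
    }
    raw[i] <- p
    cost[i] <- tau * d / (n - 1)
  }
  nset <- if (variant == "four_strategy") 4L else 2L
  base <- if (variant == "four_strategy") 0L else 2L
  out <- integer(n)
  for (i in seq_len(n)) {
    cur <- state[i]
    nxt <- cur
    u1 <- runif(1)
    if (u1 < mu) {
      u2 <- runif(1)
      nxt <- as.integer(base + min(floor(u2 * nset), nset - 1) + 1)
    } else if (n > 1) {
      u2 <- runif(1)
      idx <- min(floor(u2 * (n - 1)), n - 2)      # 0-based among others
      j0 <- if (idx >= i - 1) idx + 1 else idx    # skip self (0-based)
      j <- j0 + 1L
      discount <- switch(variant,
        pairwise_plain = FALSE,
        pairwise_herding = TRUE,
        four_strategy = ORACLE_HERD(cur))
      pi_i <- raw[i]; pi_j <- raw[j]
      if (discount) { pi_i <- pi_i - cost[i]; pi_j <- pi_j - cost[j] }
      u3 <- runif(1)
      if (u3 < oracle_fermi(pi_j - pi_i, beta)) nxt <- state[j]
    }
    out[i] <- nxt
  }
  out
}

# brute-force edge count / mean degree from a herd_network's adjacency
oracle_mean_degree <- function(net) {
  if (is.null(net$adj)) return(net$n - 1)
  edge_count <- 0
  for (i in seq_len(net$n)) for (j in net$adj[[i]]) {
    if (j > i) edge_count <- edge_count + 1
  }
  2 * edge_count / net$n
}

# small fixture: 5-node path 1-2-3-4-5
path5_adj <- function() list(2L, c(1L, 3L), c(2L, 4L), c(3L, 5L), 4L)

path5_network <- function() {
  read_edge_list(c("0 1", "1 2", "2 3", "3 4"))
}
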