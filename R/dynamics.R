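#' Fermi imitation probability
#'
#' Probability that a focal player copies a model whose effective payoff
#' exceeds its own by `payoff_diff`: `p = 1 / (1 + exp(-beta * payoff_diff))`.
#' Computed in the sign-split numerically stable form, so it never overflows
#' for large `|beta * payoff_diff|`; results lie in the open interval (0, 1)
#' up to floating-point underflow. Vectorized over `payoff_diff`.
#'
#' @param payoff_diff Model-minus-focal effective payoff difference(s).
#' @param beta Positive selection intensity.
#' @return Probabilities in (0, 1); `p(x) + p(-x) = 1` exactly.
#' @examples
#' fermi_probability(0, 5)   # 0.5
#' fermi_probability(1, 5)   # 1 / (1 + exp(-5))
#' @export
fermi_probability <- function(payoff_diff, beta) {
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta), beta > 0)
  x <- beta * payoff_diff
  p <- numeric(length(x))
  pos <- x >= 0
  p[pos] <- 1 / (1 + exp(-x[pos]))
  e <- exp(x[!pos])
  p[!pos] <- e / (1 + e)
  # clamp into the open interval so downstream log-odds stay finite
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Effective payoff pair entering one imitation comparison
#'
#' Which payoffs the Fermi rule compares depends on the game variant:
#' * `pairwise_plain`: the raw payoffs `(Pi_i, Pi_j)`.
#' * `pairwise_herding`: both payoffs discounted by each player's own herding
#'   cost, for every player.
#' * `four_strategy` (asymmetric game): the comparison is made from the focal
#'   player's perspective. If the focal player carries the herding trait,
#'   both its own and the model's payoffs are discounted by their respective
#'   costs; if the focal player does not herd, both payoffs are raw. The
#'   model's trait never enters this pair's comparison.
#'
#' @param focal,model Adjacent node indices (any distinct pair in a
#'   well-mixed population).
#' @param pv A [payoff_vector()] result for the current state.
#' @param state Integer strategy codes.
#' @param net A `herd_network`.
#' @param variant Game variant (see [dynamics_params()]).
#' @return Named numeric vector `c(focal = ..., model = ...)`.
#' @export
effective_payoffs <- function(focal, model, pv, state, net, variant) {
  variant <- match_variant(variant)
  stopifnot(inherits(net, "herd_network"))
  state <- check_state(state, net)
  focal <- as.integer(focal); model <- as.integer(model)
  if (focal == model) stop("focal and model must differ")
  if (net$kind != "well_mixed" && !(model %in% net$adj[[focal]]))
    stop("nodes ", focal, " and ", model, " are not adjacent")
  discount <- switch(variant,
    pairwise_plain = FALSE,
    pairwise_herding = TRUE,
    four_strategy = strategy_trait(state[focal]) == "H")
  if (discount) {
    c(focal = pv$raw[focal] - pv$herding_cost[focal],
      model = pv$raw[model] - pv$herding_cost[model])
  } else {
    c(focal = pv$raw[focal], model = pv$raw[model])
  }
}

#' One synchronous evolutionary step
#'
#' Computes every node's payoff and herding cost from the current state,
#' then for each node independently: with probability `mu` redraws its
#' strategy uniformly from the variant's strategy set; otherwise picks one
#' neighbour uniformly at random as model and copies the model's full
#' strategy (action and, in the four-strategy game, herding trait) with the
#' Fermi probability applied to the variant's effective payoff difference.
#' All replacements commit simultaneously. Randomness is consumed from R's
#' global RNG stream, so `set.seed()` makes the step reproducible.
#'
#' @param state Integer strategy codes, one per node.
#' @param net A `herd_network`.
#' @param gp A [game_params()] object.
#' @param hp A [herding_params()] object.
#' @param dp A [dynamics_params()] object.
#' @return The next population state (integer codes).
#' @export
synchronous_step <- function(state, net, gp, hp, dp) {
  check_engine_args(net, gp, hp, dp)
  state <- check_state(state, net)
  fa <- flatten_adjacency(net)
  res <- cpp_run(fa$adj, fa$offs, net$n, net$mean_degree, state - 1L,
                 gp$S, gp$T, hp$tau, dp$beta, dp$mu,
                 variant_code(dp$variant), 1L, fa$well_mixed)
  res$state + 1L
}

check_engine_args <- function(net, gp, hp, dp) {
  stopifnot(inherits(net, "herd_network"), inherits(gp, "game_params"),
            inherits(hp, "herding_params"), inherits(dp, "dynamics_params"))
  if (net$n < 1L) stop("empty network")
  if (hp$crowd_mode == "well_mixed" && net$kind != "well_mixed")
    stop("crowd_mode 'well_mixed' requires a well-mixed population; ",
         "structured populations use the local crowd")
  invisible(TRUE)
}
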