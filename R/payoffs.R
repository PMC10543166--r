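#' Single payoff-matrix entry
#'
#' Payoff of the focal action against the other action under the normalized
#' matrix: (C,C) -> 1, (C,D) -> S, (D,C) -> T, (D,D) -> 0. Vectorized over
#' the action arguments.
#'
#' @param action_focal,action_other `"C"` or `"D"` (recycled).
#' @param params A [game_params()] object.
#' @return Numeric payoffs to the focal player.
#' @export
payoff_entry <- function(action_focal, action_other, params) {
  stopifnot(inherits(params, "game_params"))
  af <- rep_len(as.character(action_focal), max(length(action_focal),
                                                length(action_other)))
  ao <- rep_len(as.character(action_other), length(af))
  if (!all(af %in% c("C", "D")) || !all(ao %in% c("C", "D")))
    stop("actions must be 'C' or 'D'")
  out <- numeric(length(af))
  out[af == "C" & ao == "C"] <- params$R
  out[af == "C" & ao == "D"] <- params$S
  out[af == "D" & ao == "C"] <- params$T
  out[af == "D" & ao == "D"] <- params$P
  out
}

state_actions <- function(state) strategy_action(state)

check_state <- function(state, net) {
  state <- as.integer(state)
  if (length(state) != net$n)
    stop("population state has length ", length(state),
         " but the network has ", net$n, " nodes")
  if (anyNA(state) || any(state < 1L | state > 4L))
    stop("strategy codes must lie in 1:4")
  state
}

#' Accumulated game payoff of every node
#'
#' For each node i, sums the payoff-matrix entries of i against each of its
#' neighbours given the current action profile. Payoffs are per step: they
#' are recomputed fresh from the state, with no carry-over. In a well-mixed
#' population the "neighbours" are all other players.
#'
#' @param state Integer strategy codes (one per node, see [strategy_set()]).
#' @param net A `herd_network`.
#' @param params A [game_params()] object.
#' @return Numeric vector of per-node payoffs; isolated nodes score 0.
#' @export
accumulate_payoffs <- function(state, net, params) {
  stopifnot(inherits(net, "herd_network"), inherits(params, "game_params"))
  state <- check_state(state, net)
  a <- state_actions(state)
  if (net$kind == "well_mixed") {
    nC <- sum(a == "C")
    oc <- nC - (a == "C")
    od <- (net$n - nC) - (a == "D")
    return(ifelse(a == "C", oc * params$R + od * params$S, oc * params$T))
  }
  isC <- a == "C"
  vapply(seq_len(net$n), function(i) {
    nb <- net$adj[[i]]
    if (length(nb) == 0L) return(0)
    nc <- sum(isC[nb]); nd <- length(nb) - nc
    if (isC[i]) nc * params$R + nd * params$S else nc * params$T + nd * params$P
  }, numeric(1))
}

#' Fraction of a node's crowd acting differently
#'
#' `r_i` is the share of the comparison crowd whose action (C vs D) differs
#' from the focal node's action: 0 when the crowd is action-homogeneous with
#' the focal player, 1 when every crowd member acts otherwise. Only the game
#' action enters the comparison; the herding trait is a mentality, not an
#' observable behaviour. A degree-0 node (possible only through custom edge
#' lists) gets ratio 0 with a warning rather than an error.
#'
#' @param node Node index (1-based).
#' @param state Integer strategy codes.
#' @param net A `herd_network`.
#' @param crowd_mode `"local"` (network neighbours) or `"well_mixed"` (all
#'   `Z - 1` other players).
#' @return A number in `[0, 1]`.
#' @export
herding_ratio <- function(node, state, net,
                          crowd_mode = c("local", "well_mixed")) {
  crowd_mode <- match.arg(crowd_mode)
  stopifnot(inherits(net, "herd_network"))
  state <- check_state(state, net)
  node <- as.integer(node)
  stopifnot(length(node) == 1L, node >= 1L, node <= net$n)
  a <- state_actions(state)
  if (crowd_mode == "well_mixed" || net$kind == "well_mixed") {
    if (net$n < 2L) stop("well-mixed crowd needs at least 2 players")
    return(sum(a[-node] != a[node]) / (net$n - 1L))
  }
  nb <- net$adj[[node]]
  if (length(nb) == 0L) {
    warning("node ", node, " has no neighbours; herding ratio taken as 0")
    return(0)
  }
  sum(a[nb] != a[node]) / length(nb)
}

#' Herding social cost of a node
#'
#' Implements the cost `h_i = tau * (|C_i| / <k>) * r_i`: in local mode the
#' crowd size is the node's degree `k_i`, so `h_i = tau * (k_i / <k>) * r_i`
#' and hubs pay proportionally more; in well-mixed mode the crowd is the
#' whole remaining population and the crowd-size factor cancels, leaving
#' `h_i = tau * r_i`.
#'
#' @param node Node index (1-based).
#' @param ratio The disagreement ratio `r_i` in `[0, 1]` (see
#'   [herding_ratio()]).
#' @param net A `herd_network`.
#' @param hp A [herding_params()] object.
#' @return A non-negative number, at most `tau * k_i / <k>`.
#' @export
herding_cost <- function(node, ratio, net, hp) {
  stopifnot(inherits(net, "herd_network"), inherits(hp, "herding_params"))
  stopifnot(is.numeric(ratio), length(ratio) == 1L,
            ratio >= 0, ratio <= 1)
  node <- as.integer(node)
  stopifnot(length(node) == 1L, node >= 1L, node <= net$n)
  if (hp$crowd_mode == "well_mixed" || net$kind == "well_mixed")
    return(hp$tau * ratio)
  k <- net$degrees[node]
  hp$tau * (k / net$mean_degree) * ratio
}

#' Raw payoffs, herding costs and adjusted payoffs for the whole population
#'
#' Convenience wrapper computing, from one state, the per-node raw payoff
#' `Pi_i`, the herding cost `h_i`, and the adjusted payoff `Pi_i - h_i`.
#' Which payoff a given imitation comparison actually uses depends on the
#' game variant; see [effective_payoffs()].
#'
#' @inheritParams accumulate_payoffs
#' @param hp A [herding_params()] object.
#' @return A list with numeric vectors `raw`, `herding_cost`, `adjusted`.
#' @export
payoff_vector <- function(state, net, params, hp) {
  stopifnot(inherits(hp, "herding_params"))
  state <- check_state(state, net)
  raw <- accumulate_payoffs(state, net, params)
  a <- state_actions(state)
  if (hp$crowd_mode == "well_mixed" || net$kind == "well_mixed") {
    nC <- sum(a == "C")
    d <- ifelse(a == "C", net$n - nC, nC)  # others acting differently
    cost <- hp$tau * d / (net$n - 1L)
  } else {
    isC <- a == "C"
    d <- vapply(seq_len(net$n), function(i) {
      nb <- net$adj[[i]]
      sum(a[nb] != a[i])
    }, numeric(1))
    # tau * (k/<k>) * (d/k) = tau * d / <k>; degree-0 nodes get cost 0
    cost <- hp$tau * d / net$mean_degree
  }
  list(raw = raw, herding_cost = cost, adjusted = raw - cost)
}
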