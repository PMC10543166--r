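# Strategy coding shared across the package (and mirrored in src/engine.cpp,
# 0-based there): 1 = HC, 2 = HD, 3 = NHC, 4 = NHD, where H / NH is the
# herding / non-herding mentality and C / D the game action. The two-strategy
# game variants use codes 3:4 (trait fixed at NH; only the action evolves).
STRATEGY_LEVELS <- c("HC", "HD", "NHC", "NHD")

#' Strategy sets, actions and traits
#'
#' Strategies are stored as integer codes `1:4` named `HC`, `HD`, `NHC`,
#' `NHD` (`NHC`/`NHD` denote non-herding cooperators/defectors). The
#' two-strategy game variants use only the first two codes, and the trait
#' field is inert there.
#'
#' @param variant One of `"pairwise_plain"`, `"pairwise_herding"`,
#'   `"four_strategy"`.
#' @return `strategy_set()`: the integer codes in the variant's strategy set,
#'   named by label. `strategy_action()` / `strategy_trait()`: `"C"`/`"D"`
#'   and `"H"`/`"NH"` character vectors for a vector of codes.
#' @export
strategy_set <- function(variant) {
  variant <- match_variant(variant)
  if (variant == "four_strategy")
    stats::setNames(1:4, STRATEGY_LEVELS)
  else  # trait fixed at non-herding; only the action evolves
    stats::setNames(3:4, STRATEGY_LEVELS[3:4])
}

#' @rdname strategy_set
#' @param code Integer strategy codes in `1:4`.
#' @export
strategy_action <- function(code) c("C", "D")[(as.integer(code) - 1L) %% 2L + 1L]

#' @rdname strategy_set
#' @export
strategy_trait <- function(code) c("H", "NH")[(as.integer(code) > 2L) + 1L]

match_variant <- function(variant) {
  match.arg(variant, c("pairwise_plain", "pairwise_herding", "four_strategy"))
}

#' Game parameters of the generalized pairwise game
#'
#' The two-player game is normalized so mutual cooperation pays `R = 1` and
#' mutual defection `P = 0`; the remaining free parameters are the sucker's
#' payoff `S` (cooperator against defector) and the temptation
#' `T` (defector against cooperator). The plane `S` in `[-1, 1]`, `T` in
#' `[0, 2]` spans the harmony, snowdrift (`T > 1 > S > 0`), stag-hunt
#' (`1 > T > 0 > S`) and prisoner's dilemma (`T > 1 > 0 > S`) regions;
#' values outside those ranges are accepted with a warning.
#'
#' @param S Sucker's payoff.
#' @param T_temptation Temptation to defect. (`T` alone would collide with
#'   the `TRUE` shorthand.)
#' @return A `game_params` list with fields `S`, `T`, `R = 1`, `P = 0`.
#' @examples
#' gp <- game_params(S = -1, T_temptation = 2)  # worst-case prisoner's dilemma
#' @export
game_params <- function(S, T_temptation) {
  stopifnot(is.numeric(S), length(S) == 1L, is.finite(S),
            is.numeric(T_temptation), length(T_temptation) == 1L,
            is.finite(T_temptation))
  if (S < -1 || S > 1)
    warning("S = ", S, " lies outside the usual exploration range [-1, 1]")
  if (T_temptation < 0 || T_temptation > 2)
    warning("T = ", T_temptation,
            " lies outside the usual exploration range [0, 2]")
  structure(list(S = S, T = T_temptation, R = 1, P = 0),
            class = "game_params")
}

#' Herding-cost parameters
#'
#' The herding social cost of a player i is
#' `h_i = tau * (|C_i| / <k>) * r_i`, where `C_i` is the comparison crowd
#' (network neighbours in local mode, all other players in well-mixed mode),
#' `r_i` the fraction of the crowd acting differently from i, and `tau >= 0`
#' the social weight. In well-mixed mode `|C_i| = Z - 1` is taken equal to
#' the reference degree, so the cost reduces to `tau * r_i`. `tau = 0`
#' switches the mechanism off entirely.
#'
#' @param tau Non-negative social-cost weight.
#' @param crowd_mode `"local"` (network neighbours) or `"well_mixed"`.
#' @return A `herding_params` list.
#' @export
herding_params <- function(tau = 1, crowd_mode = c("local", "well_mixed")) {
  crowd_mode <- match.arg(crowd_mode)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau))
  if (tau < 0) stop("`tau` must be non-negative (got ", tau, ")")
  structure(list(tau = tau, crowd_mode = crowd_mode),
            class = "herding_params")
}

#' Evolutionary dynamics parameters
#'
#' @param beta Selection intensity of the Fermi imitation rule (must be
#'   positive); larger values make imitation more payoff-deterministic.
#' @param mu Per-node mutation probability per step, in `[0, 1]`; with
#'   probability `mu` a node redraws its strategy uniformly from the
#'   variant's strategy set instead of imitating.
#' @param variant Game variant: `"pairwise_plain"` (no herding cost),
#'   `"pairwise_herding"` (cost subtracted for every player), or
#'   `"four_strategy"` (the asymmetric co-evolutionary game in which the
#'   herding trait is part of the heritable strategy and payoffs are
#'   discounted only from the perspective of a herding focal player).
#' @return A `dynamics_params` list.
#' @export
dynamics_params <- function(beta = 5, mu = 0.01,
                            variant = c("pairwise_plain", "pairwise_herding",
                                        "four_strategy")) {
  variant <- match_variant(variant)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.finite(beta),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (beta <= 0) stop("`beta` must be positive")
  if (mu < 0 || mu > 1) stop("`mu` must lie in [0, 1]")
  structure(list(beta = beta, mu = mu, variant = variant),
            class = "dynamics_params")
}

variant_code <- function(variant) {
  match(match_variant(variant),
        c("pairwise_plain", "pairwise_herding", "four_strategy")) - 1L
}
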