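#' Simulation configuration
#'
#' Bundles the Monte-Carlo driver settings. Defaults follow the study
#' conditions: 3000 synchronous steps per realization, 30 independent
#' realizations, stationary quantities averaged over the final 25% of the
#' recorded series, and (for scale-free specs) a fresh network per
#' realization to avoid anomalous network artifacts.
#'
#' @param max_steps Synchronous steps per realization.
#' @param realizations Number of independent Monte-Carlo realizations.
#' @param measure_fraction Fraction (0, 1] of the recorded series, taken
#'   from the end, over which stationary means are computed.
#' @param initial_mix Optional named per-strategy initial fractions summing
#'   to 1; `NULL` uses the variant default (25% of each of the four
#'   strategies, or 50% C / 50% D in the two-strategy games).
#' @param master_seed Integer master seed; realization i runs with seed
#'   `master_seed + i`, making the whole experiment a pure function of its
#'   configuration.
#' @param fresh_network_per_realization `NULL` (default: `TRUE` when the
#'   network argument is a scale-free [network_spec()], otherwise `FALSE`)
#'   or a logical. Only meaningful when a `network_spec` is supplied.
#' @param exact_counts If `TRUE`, initial strategies are placed in exact
#'   proportions (largest-remainder rounding) and shuffled, instead of
#'   i.i.d. categorical draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(max_steps = 3000L, realizations = 30L,
                       measure_fraction = 0.25, initial_mix = NULL,
                       master_seed = 1L,
                       fresh_network_per_realization = NULL,
                       exact_counts = FALSE) {
  stopifnot(max_steps >= 1, realizations >= 1,
            measure_fraction > 0, measure_fraction <= 1)
  structure(list(max_steps = as.integer(max_steps),
                 realizations = as.integer(realizations),
                 measure_fraction = measure_fraction,
                 initial_mix = initial_mix,
                 master_seed = as.integer(master_seed),
                 fresh_network_per_realization = fresh_network_per_realization,
                 exact_counts = isTRUE(exact_counts)),
            class = "sim_config")
}

#' Deferred network specification
#'
#' Describes how to build a population rather than building it, so the
#' Monte-Carlo driver can generate a fresh network for every realization
#' (the default for scale-free populations).
#'
#' @param kind `"lattice"`, `"scale_free"` or `"well_mixed"`.
#' @param ... Generator arguments: `rows`, `cols` for lattices; `n`, `m` for
#'   scale-free networks; `n` for well-mixed populations.
#' @return A `network_spec` object usable wherever [run_experiment()] takes
#'   a network.
#' @export
network_spec <- function(kind = c("lattice", "scale_free", "well_mixed"),
                         ...) {
  kind <- match.arg(kind)
  structure(c(list(kind = kind), list(...)), class = "network_spec")
}

realize_network <- function(spec, seed = NULL) {
  if (inherits(spec, "herd_network")) return(spec)
  stopifnot(inherits(spec, "network_spec"))
  switch(spec$kind,
    lattice = lattice_network(spec$rows, spec$cols),
    scale_free = scale_free_network(spec$n, if (is.null(spec$m)) 2L else spec$m,
                                    seed = seed),
    well_mixed = well_mixed_network(spec$n))
}

default_mix <- function(variant) {
  if (match_variant(variant) == "four_strategy")
    stats::setNames(rep(0.25, 4), STRATEGY_LEVELS)
  else c(C = 0.5, D = 0.5)
}

normalize_mix <- function(mix, variant) {
  set <- strategy_set(variant)
  nm <- names(mix)
  if (is.null(nm)) stop("`mix` must be a named vector of strategy fractions")
  # two-strategy games accept plain action names C / D
  if (length(set) == 2L) {
    nm[nm == "C"] <- "NHC"; nm[nm == "D"] <- "NHD"
  }
  if (!all(nm %in% names(set)))
    stop("unknown strategy name(s): ",
         paste(setdiff(nm, names(set)), collapse = ", "))
  p <- stats::setNames(numeric(length(set)), names(set))
  p[nm] <- mix
  if (any(p < 0)) stop("initial fractions must be non-negative")
  if (abs(sum(p) - 1) > 1e-9)
    stop("initial fractions must sum to 1 (got ", sum(p), ")")
  p
}

#' Initialize a population state
#'
#' Assigns a strategy to every node by independent categorical draws with
#' the given probabilities (so the realized fractions match `mix` in
#' expectation), or in exact largest-remainder proportions when
#' `exact = TRUE`. Uses R's global RNG stream.
#'
#' @param net A `herd_network`.
#' @param mix Named fractions over the variant's strategy set (two-strategy
#'   games also accept names `C` and `D`); must sum to 1 within `1e-9`.
#' @param variant Game variant (see [dynamics_params()]).
#' @param exact Use exact-count placement instead of i.i.d. draws.
#' @return Integer strategy codes, one per node.
#' @export
initialize_population <- function(net, mix = NULL,
                                  variant = "four_strategy", exact = FALSE) {
  stopifnot(inherits(net, "herd_network"))
  variant <- match_variant(variant)
  if (is.null(mix)) mix <- default_mix(variant)
  p <- normalize_mix(mix, variant)
  codes <- strategy_set(variant)
  if (exact) {
    counts <- floor(p * net$n)
    rem <- p * net$n - counts
    short <- net$n - sum(counts)
    if (short > 0) {
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      counts[add] <- counts[add] + 1L
    }
    pool <- rep(codes, times = counts)
    return(as.integer(sample(pool, net$n)))
  }
  as.integer(sample(codes, net$n, replace = TRUE, prob = p))
}

new_herd_series <- function(res, variant) {
  freq <- res$freq; pay <- res$pay
  colnames(freq) <- colnames(pay) <- STRATEGY_LEVELS
  structure(list(freq = freq, payoffs = pay,
                 final_state = res$state + 1L, variant = variant),
            class = "herd_series")
}

#' Run one Monte-Carlo realization
#'
#' Initializes a population and applies [synchronous_step()] dynamics for
#' `sc$max_steps` steps, recording every step's strategy frequencies and
#' per-strategy mean adjusted payoffs (each strategy's average of the payoff
#' its players would themselves use: cost-discounted for herding players in
#' the herding variants, raw otherwise). The same seed always reproduces the
#' identical series.
#'
#' @param net A `herd_network`.
#' @param gp,hp,dp,sc Parameter objects ([game_params()], [herding_params()],
#'   [dynamics_params()], [sim_config()]).
#' @param seed Integer seed for this realization.
#' @return A `herd_series` with matrices `freq` and `payoffs`
#'   (`max_steps + 1` rows: the initial state and every subsequent step) and
#'   the final population state.
#' @export
run_realization <- function(net, gp, hp, dp, sc, seed) {
  check_engine_args(net, gp, hp, dp)
  stopifnot(inherits(sc, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  state <- initialize_population(net, sc$initial_mix, dp$variant,
                                 exact = sc$exact_counts)
  fa <- flatten_adjacency(net)
  res <- cpp_run(fa$adj, fa$offs, net$n, net$mean_degree, state - 1L,
                 gp$S, gp$T, hp$tau, dp$beta, dp$mu,
                 variant_code(dp$variant), sc$max_steps, fa$well_mixed)
  new_herd_series(res, dp$variant)
}

#' Stationary-state summary of one realization
#'
#' Arithmetic mean of each strategy's frequency over the final
#' `ceiling(measure_fraction * n)` recorded entries, where `n` is the number
#' of recorded steps, plus the derived cooperation (action C: HC + NHC) and
#' herder (trait H: HC + HD) fractions.
#'
#' @param series A `herd_series`, or a numeric frequency matrix with one row
#'   per recorded step and the four strategy columns.
#' @param measure_fraction Fraction of the series, from the end, to average.
#' @return Named numeric vector: the four strategy means, `cooperation`, and
#'   `herder`.
#' @export
summarize_stationary <- function(series, measure_fraction = 0.25) {
  stopifnot(measure_fraction > 0, measure_fraction <= 1)
  freq <- if (inherits(series, "herd_series")) series$freq else as.matrix(series)
  n <- nrow(freq)
  if (is.null(n) || n == 0L) stop("empty series")
  w <- ceiling(measure_fraction * n)
  tailrows <- freq[seq.int(n - w + 1L, n), , drop = FALSE]
  m <- colMeans(tailrows)
  if (is.null(names(m)) || !all(STRATEGY_LEVELS %in% names(m)))
    names(m) <- STRATEGY_LEVELS[seq_along(m)]
  m <- m[STRATEGY_LEVELS]
  names(m) <- STRATEGY_LEVELS
  m[is.na(m)] <- 0
  c(m, cooperation = unname(m["HC"] + m["NHC"]),
    herder = unname(m["HC"] + m["HD"]))
}

#' Run a full Monte-Carlo experiment
#'
#' The central driver: runs `sc$realizations` independent realizations with
#' seeds `master_seed + 1, ..., master_seed + realizations`, building a
#' fresh network per realization when `network` is a scale-free
#' [network_spec()] (override via
#' `sc$fresh_network_per_realization`), and aggregates each realization's
#' stationary summary into means and standard deviations.
#'
#' @param network A `herd_network`, or a [network_spec()] to be realized
#'   (freshly per realization for scale-free populations).
#' @param gp,hp,dp,sc Parameter objects; `sc` defaults to [sim_config()].
#' @param keep_series If `TRUE`, the first realization's full `herd_series`
#'   is kept in the result for plotting.
#' @return A `herd_experiment` object with components `mean`, `sd`
#'   (named over the four strategies, `cooperation`, `herder`),
#'   `per_realization` (one row per realization), and the configuration.
#' @examples
#' net <- lattice_network(10, 10)
#' ex <- run_experiment(net, game_params(0.5, 0.5), herding_params(0),
#'                      dynamics_params(variant = "pairwise_plain"),
#'                      sim_config(max_steps = 50, realizations = 2,
#'                                 master_seed = 7))
#' ex$mean["cooperation"]
#' @export
run_experiment <- function(network, gp, hp, dp, sc = sim_config(),
                           keep_series = FALSE) {
  stopifnot(inherits(sc, "sim_config"))
  fresh <- sc$fresh_network_per_realization
  if (is.null(fresh))
    fresh <- inherits(network, "network_spec") && network$kind == "scale_free"
  if (fresh && !inherits(network, "network_spec"))
    stop("fresh_network_per_realization requires a network_spec")
  fixed_net <- if (!fresh) realize_network(network, seed = sc$master_seed)
  per <- matrix(NA_real_, nrow = sc$realizations, ncol = 6L,
                dimnames = list(NULL, c(STRATEGY_LEVELS, "cooperation",
                                        "herder")))
  first_series <- NULL
  for (i in seq_len(sc$realizations)) {
    seed_i <- sc$master_seed + i
    net_i <- if (fresh) realize_network(network, seed = seed_i) else fixed_net
    ser <- run_realization(net_i, gp, hp, dp, sc, seed = seed_i)
    per[i, ] <- summarize_stationary(ser, sc$measure_fraction)
    if (keep_series && i == 1L) first_series <- ser
  }
  sds <- apply(per, 2L, stats::sd)
  if (sc$realizations == 1L) sds[] <- 0
  structure(list(mean = colMeans(per), sd = sds, per_realization = per,
                 network = if (inherits(network, "network_spec")) network
                           else fixed_net,
                 gp = gp, hp = hp, dp = dp, sc = sc,
                 series = first_series),
            class = "herd_experiment")
}

#' @export
print.herd_experiment <- function(x, digits = 4, ...) {
  nd <- if (inherits(x$network, "network_spec"))
    sprintf("%s spec", x$network$kind) else x$network$kind
  cat(sprintf("<herd_experiment: %s, %s, S = %g, T = %g, tau = %g>\n",
              x$dp$variant, nd, x$gp$S, x$gp$T, x$hp$tau))
  cat(sprintf("  %d realization(s) x %d steps, stationary window = last %g%%\n",
              x$sc$realizations, x$sc$max_steps,
              100 * x$sc$measure_fraction))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, digits))
  invisible(x)
}

#' @export
summary.herd_experiment <- function(object, ...) {
  data.frame(quantity = names(object$mean),
             mean = unname(object$mean),
             sd = unname(object$sd),
             row.names = NULL)
}

#' @export
plot.herd_experiment <- function(x, ...) {
  if (!is.null(x$series)) return(plot(x$series, ...))
  mid <- graphics::barplot(x$mean, ylim = c(0, 1.05),
                           ylab = "stationary fraction", ...)
  graphics::arrows(mid, pmax(0, x$mean - x$sd), mid,
                   pmin(1, x$mean + x$sd),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' @export
plot.herd_series <- function(x, what = c("freq", "payoffs"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  keep <- colSums(!is.na(m)) > 0
  graphics::matplot(seq_len(nrow(m)) - 1L, m[, keep, drop = FALSE],
                    type = "l", lty = 1, col = seq_len(sum(keep)),
                    xlab = "step",
                    ylab = if (what == "freq") "strategy frequency"
                           else "mean adjusted payoff", ...)
  graphics::legend("topright", legend = colnames(m)[keep], lty = 1,
                   col = seq_len(sum(keep)), bty = "n")
  invisible(x)
}

#' @export
print.herd_series <- function(x, ...) {
  cat(sprintf("<herd_series: %s, %d recorded steps, final cooperation %.3f>\n",
              x$variant, nrow(x$freq) - 1L,
              sum(x$freq[nrow(x$freq), c("HC", "NHC")])))
  invisible(x)
}
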