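PHASE_TABLE_SCHEMA <- "herdgame phase_table v1"

new_phase_table <- function(rows) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("herd_phase_table", "data.frame")
  attr(df, "schema") <- PHASE_TABLE_SCHEMA
  df
}

cell_row <- function(ex, S, T_val, tau, base) {
  m <- ex$mean; s <- ex$sd
  data.frame(S = S, T = T_val, tau = tau, variant = ex$dp$variant,
             freq_HC = m[["HC"]], freq_HD = m[["HD"]],
             freq_NHC = m[["NHC"]], freq_NHD = m[["NHD"]],
             cooperation = m[["cooperation"]], herder = m[["herder"]],
             cooperation_sd = s[["cooperation"]], herder_sd = s[["herder"]],
             baseline_cooperation = base[["cooperation"]],
             baseline_herder = base[["herder"]],
             delta_cooperation = m[["cooperation"]] - base[["cooperation"]],
             delta_herder = m[["herder"]] - base[["herder"]])
}

run_cell <- function(S, T_val, tau, variant, network, sc, mix = NULL) {
  gp <- game_params(S, T_val)
  hp <- herding_params(tau)
  dp <- dynamics_params(beta = 5, mu = 0.01, variant = variant)
  sc$initial_mix <- mix
  tryCatch(run_experiment(network, gp, hp, dp, sc),
           error = function(e) stop("sweep cell (S = ", S, ", T = ", T_val,
                                    ", tau = ", tau, "): ",
                                    conditionMessage(e), call. = FALSE))
}

#' S-T phase sweep with baseline deltas
#'
#' Runs [run_experiment()] on every cell of an `S x T` grid for each
#' requested herding weight `tau`, and compares each cell against the
#' no-herding baseline: the plain pairwise game at `tau = 0` with the same
#' network specification, simulation settings and master seed. Cells with
#' `tau = 0` are their own baseline (their deltas are exactly zero). The
#' baseline always starts from the two-strategy 50/50 mix; `mix` applies to
#' the swept variant.
#'
#' @param S_values,T_values Numeric grids of game parameters.
#' @param tau_values Non-negative herding weights to sweep (default 1).
#' @param variant Game variant for the swept cells.
#' @param network A `herd_network` or [network_spec()].
#' @param sc A [sim_config()]; its `initial_mix` is replaced by `mix`.
#' @param mix Optional initial mix for the swept variant.
#' @param verbose Emit a progress message per cell.
#' @return A `herd_phase_table` data frame, one row per
#'   `(S, T, tau)` cell, with absolute stationary fractions and deltas
#'   against the baseline.
#' @export
sweep_st <- function(S_values, T_values, tau_values = 1,
                     variant = "four_strategy", network, sc = sim_config(),
                     mix = NULL, verbose = FALSE) {
  stopifnot(length(S_values) >= 1, length(T_values) >= 1,
            length(tau_values) >= 1, all(tau_values >= 0))
  variant <- match_variant(variant)
  rows <- list()
  for (S in S_values) for (T_val in T_values) {
    base_ex <- run_cell(S, T_val, 0, "pairwise_plain", network, sc)
    base <- base_ex$mean
    for (tau in tau_values) {
      ex <- if (tau == 0 && variant == "pairwise_plain") base_ex
            else run_cell(S, T_val, tau, variant, network, sc, mix)
      cell_base <- if (tau == 0) ex$mean else base
      rows[[length(rows) + 1L]] <- cell_row(ex, S, T_val, tau, cell_base)
      if (verbose)
        message(sprintf("cell S=%g T=%g tau=%g: coop %.3f (delta %+.3f)",
                        S, T_val, tau, ex$mean[["cooperation"]],
                        ex$mean[["cooperation"]] - cell_base[["cooperation"]]))
    }
  }
  new_phase_table(rows)
}

#' Herding-weight sensitivity sweep
#'
#' For a list of `(S, T)` pairs and a set of herding weights `tau`, runs the
#' four-strategy co-evolutionary game and records the stationary fractions,
#' in particular the herding-cooperator (`HC`) and non-herding-cooperator
#' (`NHC`) frequencies whose dependence on `tau` is the quantity of
#' interest. Deltas are against the plain-game baseline as in [sweep_st()].
#'
#' @param st_pairs Two-column matrix (or list of length-2 vectors) of
#'   `(S, T)` pairs; defaults to the three reference pairs
#'   `(-0.4, 0.9)`, `(0, 2)`, `(-0.1, 1.1)`.
#' @param tau_values Herding weights; defaults to `c(0.5, 1, 1.5, 2.5)`.
#' @param network A `herd_network` or [network_spec()].
#' @param sc A [sim_config()].
#' @param mix,verbose See [sweep_st()].
#' @return A `herd_phase_table`, one row per pair per `tau`.
#' @export
sweep_tau <- function(st_pairs = rbind(c(-0.4, 0.9), c(0, 2), c(-0.1, 1.1)),
                      tau_values = c(0.5, 1, 1.5, 2.5), network,
                      sc = sim_config(), mix = NULL, verbose = FALSE) {
  if (is.list(st_pairs)) st_pairs <- do.call(rbind, st_pairs)
  st_pairs <- as.matrix(st_pairs)
  stopifnot(ncol(st_pairs) == 2L, nrow(st_pairs) >= 1L,
            length(tau_values) >= 1L, all(tau_values >= 0))
  rows <- list()
  for (r in seq_len(nrow(st_pairs))) {
    S <- st_pairs[r, 1L]; T_val <- st_pairs[r, 2L]
    base_ex <- run_cell(S, T_val, 0, "pairwise_plain", network, sc)
    for (tau in tau_values) {
      ex <- run_cell(S, T_val, tau, "four_strategy", network, sc, mix)
      cell_base <- if (tau == 0) ex$mean else base_ex$mean
      rows[[length(rows) + 1L]] <- cell_row(ex, S, T_val, tau, cell_base)
      if (verbose)
        message(sprintf("pair (S=%g, T=%g) tau=%g: HC %.3f, NHC %.3f",
                        S, T_val, tau, ex$mean[["HC"]], ex$mean[["NHC"]]))
    }
  }
  new_phase_table(rows)
}

#' Write / read a phase table as CSV
#'
#' The CSV carries a one-line schema header comment
#' (`# herdgame phase_table v1`) followed by a standard header row; columns
#' are the absolute stationary fractions, their Monte-Carlo standard
#' deviations, and the deltas against the plain-game baseline.
#'
#' @param pt A `herd_phase_table`.
#' @param path Output (input) file path.
#' @return `write_phase_table()`: the path, invisibly;
#'   `read_phase_table()`: the table.
#' @export
write_phase_table <- function(pt, path) {
  stopifnot(inherits(pt, "herd_phase_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", PHASE_TABLE_SCHEMA), con)
  utils::write.csv(as.data.frame(pt), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phase_table
#' @export
read_phase_table <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  class(df) <- c("herd_phase_table", "data.frame")
  attr(df, "schema") <- PHASE_TABLE_SCHEMA
  df
}

#' Write an experiment or sweep summary as JSON
#'
#' @param x A `herd_experiment` or `herd_phase_table`.
#' @param path Output file path.
#' @export
write_summary_json <- function(x, path) {
  obj <- if (inherits(x, "herd_experiment")) {
    list(mean = as.list(x$mean), sd = as.list(x$sd),
         config = list(variant = x$dp$variant, S = x$gp$S, T = x$gp$T,
                       tau = x$hp$tau, beta = x$dp$beta, mu = x$dp$mu,
                       max_steps = x$sc$max_steps,
                       realizations = x$sc$realizations,
                       measure_fraction = x$sc$measure_fraction,
                       master_seed = x$sc$master_seed))
  } else if (inherits(x, "herd_phase_table")) {
    list(schema = PHASE_TABLE_SCHEMA, n_cells = nrow(x),
         mean_cooperation = mean(x$cooperation),
         mean_herder = mean(x$herder),
         mean_delta_cooperation = mean(x$delta_cooperation))
  } else stop("unsupported object for JSON summary")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
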