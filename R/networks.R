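#' @useDynLib herdgame, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

new_herd_network <- function(n, edges, kind) {
  # edges: 2-column integer matrix, 1-based node ids, i < j, unique rows
  if (is.null(edges)) {
    degrees <- rep.int(n - 1L, n)
    adj <- NULL
    mean_degree <- n - 1
  } else {
    storage.mode(edges) <- "integer"
    adj <- unname(build_adjacency(n, edges))
    degrees <- lengths(adj)
    mean_degree <- 2 * nrow(edges) / n
  }
  structure(
    list(n = n, adj = adj, degrees = degrees, mean_degree = mean_degree,
         edges = edges, kind = kind),
    class = "herd_network")
}

build_adjacency <- function(n, edges) {
  ends <- c(edges[, 1L], edges[, 2L])
  other <- c(edges[, 2L], edges[, 1L])
  adj <- split(other, factor(ends, levels = seq_len(n)))
  lapply(adj, function(x) sort(as.integer(x)))
}

#' Toroidal regular lattice population
#'
#' Builds a `rows x cols` lattice with periodic boundaries and von Neumann
#' (4-neighbour) connectivity, the standard homogeneous structured population
#' for spatial evolutionary games. Every node has degree exactly 4, so the
#' mean degree is 4 by construction.
#'
#' @param rows,cols Lattice dimensions; both must be at least 3, since
#'   smaller tori would create duplicate edges under the 4-neighbour rule.
#' @return A `herd_network` of kind `"lattice"` with `rows * cols` nodes.
#' @examples
#' net <- lattice_network(5, 4)
#' net$mean_degree  # 4
#' @export
lattice_network <- function(rows, cols) {
  if (!is.numeric(rows) || length(rows) != 1L || rows < 3)
    stop("`rows` must be a single integer >= 3 (got ", rows, ")")
  if (!is.numeric(cols) || length(cols) != 1L || cols < 3)
    stop("`cols` must be a single integer >= 3 (got ", cols, ")")
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- function(r, c) (r - 1L) * cols + c  # 1-based, row-major
  r <- rep(seq_len(rows), each = cols)
  c <- rep(seq_len(cols), times = rows)
  right <- idx(r, ifelse(c == cols, 1L, c + 1L))
  down <- idx(ifelse(r == rows, 1L, r + 1L), c)
  self <- idx(r, c)
  edges <- rbind(cbind(self, right), cbind(self, down))
  edges <- t(apply(edges, 1L, sort))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  net <- new_herd_network(rows * cols, edges, "lattice")
  net$dims <- c(rows = rows, cols = cols)
  net
}

#' Barabasi-Albert scale-free population
#'
#' Grows a scale-free network by preferential attachment: starting from a
#' complete graph on `m + 1` nodes, each new node attaches to `m` distinct
#' existing nodes with probability proportional to their current degree
#' (sampled via the repeated-endpoints bag). Every node therefore has degree
#' at least `m`, and the mean degree approaches `2m` for large `n`; the
#' default `m = 2` targets the mean degree of about 4 used throughout for
#' heterogeneous populations.
#'
#' @param n Number of nodes; must exceed `m`.
#' @param m Attachment parameter (edges added per new node).
#' @param seed Optional integer; when given, the generator is reproducible
#'   and the caller's RNG state is left untouched.
#' @return A `herd_network` of kind `"scale_free"`.
#' @examples
#' net <- scale_free_network(200, m = 2, seed = 1)
#' net$mean_degree  # close to 4
#' @export
scale_free_network <- function(n, m = 2L, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single integer >= 2")
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("`m` must be a single integer >= 1")
  n <- as.integer(n); m <- as.integer(m)
  if (n <= m) stop("`n` must exceed the attachment parameter `m` (n = ",
                   n, ", m = ", m, ")")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  # seed clique on m+1 nodes guarantees min degree >= m at every stage
  e1 <- unlist(lapply(seq_len(m), function(i) rep.int(i, m + 1L - i)))
  e2 <- unlist(lapply(seq_len(m), function(i) seq.int(i + 1L, m + 1L)))
  bag <- c(rbind(e1, e2))  # each endpoint once per incident edge
  edges_a <- e1
  edges_b <- e2
  if (n > m + 1L) {
    # preallocate: m edges per subsequent node
    extra <- (n - m - 1L) * m
    edges_a <- c(edges_a, integer(extra))
    edges_b <- c(edges_b, integer(extra))
    bag <- c(bag, integer(2L * extra))
    epos <- m * (m + 1L) / 2L
    bpos <- length(e1) * 2L
    for (v in seq.int(m + 2L, n)) {
      targets <- integer(0)
      while (length(targets) < m) {
        cand <- bag[sample.int(bpos, 1L)]
        if (!(cand %in% targets)) targets <- c(targets, cand)
      }
      for (tg in targets) {
        epos <- epos + 1L
        edges_a[epos] <- tg
        edges_b[epos] <- v
        bag[bpos + 1L] <- tg
        bag[bpos + 2L] <- v
        bpos <- bpos + 2L
      }
    }
  }
  edges <- cbind(pmin(edges_a, edges_b), pmax(edges_a, edges_b))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  net <- new_herd_network(n, edges, "scale_free")
  net$m <- m
  net
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Well-mixed (unstructured) population
#'
#' Represents a population in which every player's comparison crowd is the
#' whole remaining population (crowd size `Z - 1`). The complete adjacency is
#' implicit: no O(Z^2) edge structure is stored.
#'
#' @param n Population size (at least 2).
#' @return A `herd_network` of kind `"well_mixed"`.
#' @export
well_mixed_network <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 2)
    stop("`n` must be a single integer >= 2")
  new_herd_network(as.integer(n), NULL, "well_mixed")
}

#' Read a custom population from a plain-text edge list
#'
#' Parses whitespace-separated integer pairs, one undirected edge per line.
#' Node ids are remapped to a contiguous range; duplicate edges (in either
#' orientation) are collapsed; self-loops are rejected.
#'
#' @param source Path to a file, or a connection / character vector of lines.
#' @return A `herd_network` of kind `"custom"`.
#' @examples
#' net <- read_edge_list(textConnection("0 1\n1 2"))
#' net$mean_degree  # 4/3
#' @export
read_edge_list <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L &&
               !grepl("\n", source) && file.exists(source)) {
    readLines(source)
  } else if (inherits(source, "connection")) {
    readLines(source)
  } else {
    unlist(strsplit(as.character(source), "\n", fixed = TRUE))
  }
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  a <- integer(length(toks)); b <- integer(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    if (length(tk) != 2L || anyNA(suppressWarnings(as.integer(tk))))
      stop("edge list line ", lineno[i],
           ": expected two integer node ids, got '",
           paste(tk, collapse = " "), "'")
    a[i] <- as.integer(tk[1L]); b[i] <- as.integer(tk[2L])
    if (a[i] == b[i])
      stop("edge list line ", lineno[i], ": self-loop on node ", a[i])
  }
  if (length(a) == 0L) stop("edge list contains no edges")
  ids <- sort(unique(c(a, b)))
  a <- match(a, ids); b <- match(b, ids)
  edges <- unique(cbind(pmin(a, b), pmax(a, b)))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  net <- new_herd_network(length(ids), edges, "custom")
  net$original_ids <- ids
  net
}

#' Write a population as a plain-text edge list
#'
#' Emits one `i j` pair per line with 0-based node ids, the same format
#' accepted by [read_edge_list()].
#'
#' @param net A `herd_network` with explicit edges.
#' @param path Output file path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "herd_network"))
  if (is.null(net$edges))
    stop("well-mixed populations have no explicit edge list")
  writeLines(paste(net$edges[, 1L] - 1L, net$edges[, 2L] - 1L), path)
  invisible(path)
}

#' @export
print.herd_network <- function(x, ...) {
  ne <- if (is.null(x$edges)) x$n * (x$n - 1) / 2 else nrow(x$edges)
  cat(sprintf("<herd_network: %s, %d nodes, %d edges, <k> = %.4g>\n",
              x$kind, x$n, ne, x$mean_degree))
  invisible(x)
}

# flattened 0-based CSR view for the C++ engine
flatten_adjacency <- function(net) {
  if (net$kind == "well_mixed" || is.null(net$adj))
    return(list(adj = integer(0), offs = c(0L, integer(net$n)),
                well_mixed = TRUE))
  offs <- c(0L, cumsum(net$degrees))
  list(adj = unlist(net$adj, use.names = FALSE) - 1L,
       offs = as.integer(offs), well_mixed = FALSE)
}
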