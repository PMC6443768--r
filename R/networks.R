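#' Static contact network
#'
#' Constructor for the `"pd_network"` container used throughout the package:
#' an undirected, connected, simple graph on nodes `1..N`.  Edges are stored
#' as a canonical two-column integer matrix (`i < j`, sorted), together with
#' the degree sequence and a compressed adjacency index used by the compiled
#' simulation core.
#'
#' @param edges two-column matrix of 1-based node indices.
#' @param N node count (defaults to the largest index present).
#' @param kind free-form tag recording how the network was built.
#' @return A `"pd_network"` object with fields `N`, `edges`, `degree`,
#'   `k_max`, `k_mean`, `adj` (adjacency list) and the kind tag.
#' @seealso [build_lattice()], [build_random_network()], [read_edgelist()]
#' @export
pd_network <- function(edges, N = max(edges), kind = "custom") {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (any(edges < 1L) || any(edges > N)) stop("edge endpoints out of range 1..N")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]), pmax(edges[, 1L], edges[, 2L]))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  if (anyDuplicated(edges)) stop("multi-edges are not allowed")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, N - igraph::vcount(g)))
  if (!igraph::is_connected(g)) stop("network must be connected (single component)")
  deg <- as.integer(igraph::degree(g))
  net <- structure(
    list(
      N = as.integer(N), edges = edges, degree = deg,
      k_max = max(deg), k_mean = mean(deg),
      adj = lapply(igraph::as_adj_list(g), as.integer),
      kind = kind
    ),
    class = "pd_network"
  )
  net$csr <- .network_csr(net)
  net
}

# CSR adjacency with the reverse-direction index needed for the directed
# abstention counters: directed edge ids are positions in `adjn`.
.network_csr <- function(net) {
  deg <- net$degree
  xadj <- c(0L, cumsum(deg))
  adjn <- integer(2L * nrow(net$edges))
  pos <- xadj[-length(xadj)]
  eid <- integer(length(adjn))
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges[e, 1L]; j <- net$edges[e, 2L]
    pos[i] <- pos[i] + 1L; adjn[pos[i]] <- j - 1L; eid[pos[i]] <- e
    pos[j] <- pos[j] + 1L; adjn[pos[j]] <- i - 1L; eid[pos[j]] <- e
  }
  # reverse index: directed slots sharing an undirected edge point at each other
  rev <- integer(length(adjn))
  slot <- split(seq_along(adjn), eid)
  for (s in slot) {
    rev[s[1L]] <- s[2L] - 1L
    rev[s[2L]] <- s[1L] - 1L
  }
  list(xadj = xadj, adjn = adjn, rev = rev, eid = eid)
}

#' @export
print.pd_network <- function(x, ...) {
  cat(sprintf("pd_network '%s': N = %d, %d edges, <k> = %.3g, k_max = %d\n",
              x$kind, x$N, nrow(x$edges), x$k_mean, x$k_max))
  invisible(x)
}

.torus_index <- function(row, col, s) ((row %% s) * s + (col %% s)) + 1L

#' Regular lattices
#'
#' Builds the regular structures used in the numerical experiments:
#' `"ring4"`, a circulant ring where every node connects to its 4 nearest
#' loop neighbors (offsets 1 and 2); `"square4"`, the 4-neighbor
#' (von Neumann) square lattice; and `"moore8"`, the 8-neighbor (Moore)
#' square lattice.  Planar lattices are built on a torus (periodic
#' boundaries), so every node has degree exactly 4 or 8 and the lattice is
#' homogeneous; `N` must then be a perfect square.
#'
#' @param kind one of `"ring4"`, `"square4"`, `"moore8"`.
#' @param N node count; `>= 5` for the ring, a perfect square with side
#'   `>= 3` for the planar kinds.
#' @return A [pd_network()].
#' @examples
#' build_lattice("square4", 25)
#' @export
build_lattice <- function(kind = c("ring4", "square4", "moore8"), N) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(N), length(N) == 1L, N == floor(N))
  N <- as.integer(N)
  if (kind == "ring4") {
    if (N < 5L) stop("ring4 needs N >= 5 so that the offset-{1,2} circulant is simple")
    v <- 0:(N - 1L)
    edges <- rbind(
      cbind(v, (v + 1L) %% N),
      cbind(v, (v + 2L) %% N)
    ) + 1L
    return(pd_network(edges, N, kind = "ring4"))
  }
  s <- sqrt(N)
  if (s != floor(s)) {
    stop(sprintf("%s lattice needs a perfect-square N (torus side sqrt(N)); N = %d is invalid",
                 kind, N))
  }
  s <- as.integer(s)
  if (s < 3L) stop("planar lattices need side >= 3")
  if (kind == "square4") {
    g <- igraph::make_lattice(c(s, s), periodic = TRUE)
    net <- pd_network(igraph::as_edgelist(g), N, kind = "square4")
    stopifnot(all(net$degree == 4L))
    return(net)
  }
  # moore8: von Neumann plus diagonals, periodic; 4 forward offsets per cell
  rc <- expand.grid(row = 0:(s - 1L), col = 0:(s - 1L))
  from <- .torus_index(rc$row, rc$col, s)
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  edges <- do.call(rbind, lapply(offs, function(o) {
    cbind(from, .torus_index(rc$row + o[1L], rc$col + o[2L], s))
  }))
  edges <- unique(cbind(pmin(edges[, 1L], edges[, 2L]),
                        pmax(edges[, 1L], edges[, 2L])))
  net <- pd_network(edges, N, kind = "moore8")
  stopifnot(all(net$degree == 8L))
  net
}

#' Random and reference network models
#'
#' `single_scale` is a Watts-Strogatz ring fully rewired (rewiring
#' probability 1), giving a narrow, single-scale degree distribution;
#' `scale_free` is the Barabasi-Albert preferential-attachment model with
#' `m = mean_degree / 2` edges per new node (broad, hub-dominated degrees);
#' `holme_kim` adds a triad-formation step to preferential attachment with
#' probability `transitivity`, yielding scale-free networks with tunable
#' clustering; `complete` and `star` are the all-to-all benchmark and the
#' maximally heterogeneous star (`mean_degree` is ignored for both).
#' Generators that can return a disconnected graph are resampled (with the
#' seed advanced and a message) until connected.
#'
#' @param model one of `"single_scale"`, `"scale_free"`, `"holme_kim"`,
#'   `"complete"`, `"star"`.
#' @param N node count, `> mean_degree`.
#' @param mean_degree target average degree; must be even for the
#'   construction of the WS/BA-type models.
#' @param seed optional integer seed (sets R's RNG; the same seed reproduces
#'   the identical edge list).
#' @param transitivity triad-formation probability for `holme_kim`.
#' @param max_tries resampling budget for the connectivity repair.
#' @return A [pd_network()].
#' @examples
#' build_random_network("scale_free", N = 200, mean_degree = 4, seed = 1)
#' @export
build_random_network <- function(model = c("single_scale", "scale_free",
                                           "holme_kim", "complete", "star"),
                                 N, mean_degree = 4, seed = NULL,
                                 transitivity = 0, max_tries = 100L) {
  model <- match.arg(model)
  stopifnot(is.numeric(N), length(N) == 1L, N == floor(N), N >= 2)
  N <- as.integer(N)
  if (!is.null(seed)) set.seed(seed)
  if (model == "complete") {
    return(pd_network(t(utils::combn(N, 2L)), N, kind = "complete"))
  }
  if (model == "star") {
    return(pd_network(cbind(1L, 2:N), N, kind = "star"))
  }
  if (mean_degree %% 2 != 0) {
    stop("`mean_degree` must be even for the single_scale/scale_free/holme_kim constructions")
  }
  if (N <= mean_degree) stop("need N > mean_degree")
  m <- as.integer(mean_degree / 2)
  for (try in seq_len(max_tries)) {
    g <- switch(model,
      single_scale = .ws_rewired_graph(N, m, p = 1),
      scale_free = igraph::sample_pa(N, m = m, directed = FALSE),
      holme_kim = .holme_kim_graph(N, m, transitivity)
    )
    g <- igraph::simplify(g)
    if (igraph::is_connected(g)) {
      return(pd_network(igraph::as_edgelist(g), N, kind = model))
    }
    message(sprintf("%s draw %d disconnected; resampling", model, try))
  }
  stop("failed to draw a connected network within `max_tries`")
}

# Watts-Strogatz rewiring in its original form: start from the ring lattice
# with offsets 1..m and rewire the far endpoint of each edge with
# probability p to a uniform node (no self-loops or duplicates).  Each node
# keeps its m outgoing stubs, so the minimum degree stays m and full
# rewiring (p = 1) yields a connected single-scale graph with high
# probability.  (Rewiring both endpoints would strand isolated nodes at
# mean degree 4 almost surely.)
.ws_rewired_graph <- function(N, m, p = 1) {
  adj <- vector("list", N)
  for (off in seq_len(m)) {
    for (i in seq_len(N)) {
      j <- ((i - 1L + off) %% N) + 1L
      if (runif(1) < p) {
        repeat {
          j <- sample.int(N, 1L)
          if (j != i && !(j %in% adj[[i]])) break
        }
      } else if (j %in% adj[[i]]) {
        next # ring edge already replaced by an incoming rewire
      }
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  el <- do.call(rbind, lapply(seq_len(N), function(i) {
    js <- adj[[i]][adj[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Preferential attachment with triad formation: each new node attaches its
# first link preferentially, and each further link, with probability `pt`,
# to a random neighbor of the previous target (closing a triangle),
# otherwise preferentially again.
.holme_kim_graph <- function(N, m, pt) {
  stopifnot(pt >= 0, pt <= 1)
  targets_of <- vector("list", N)
  repeated <- integer(0) # node list weighted by degree
  seed_n <- m + 1L
  for (i in seq_len(seed_n)) targets_of[[i]] <- setdiff(seq_len(seed_n), i)
  repeated <- rep(seq_len(seed_n), each = seed_n - 1L)
  for (v in (seed_n + 1L):N) {
    chosen <- integer(0)
    prev <- NA_integer_
    while (length(chosen) < m) {
      cand <- NA_integer_
      if (!is.na(prev) && runif(1) < pt) {
        nb <- setdiff(targets_of[[prev]], c(chosen, v))
        if (length(nb)) cand <- nb[sample.int(length(nb), 1L)]
      }
      if (is.na(cand)) {
        repeat {
          cand <- repeated[sample.int(length(repeated), 1L)]
          if (!(cand %in% chosen)) break
        }
      }
      chosen <- c(chosen, cand)
      prev <- cand
    }
    for (u in chosen) {
      targets_of[[u]] <- c(targets_of[[u]], v)
      targets_of[[v]] <- c(targets_of[[v]], u)
    }
    repeated <- c(repeated, chosen, rep(v, m))
  }
  el <- do.call(rbind, lapply(seq_len(N), function(i) {
    js <- targets_of[[i]][targets_of[[i]] > i]
    if (length(js)) cbind(i, js) else NULL
  }))
  igraph::graph_from_edgelist(el, directed = FALSE)
}

#' Initial strategy assignment
#'
#' Places `count_C` cooperators on the network.  Schemes: `"random"`
#' (uniform without replacement), `"degree_rank"` (the `count_C`
#' highest-degree nodes, ties broken by ascending node index),
#' `"connected_pairs"` (`count_C / 2` disjoint edges whose endpoints become
#' C), and `"single"` (one specified or random node).  The fraction of
#' initial cooperators with no cooperating neighbor is reported, since
#' isolated cooperators defect at their first revision and invasion must
#' start from their neighbors.
#'
#' @param network a [pd_network()].
#' @param scheme placement scheme.
#' @param count_C number of cooperators, `0 <= count_C <= N` (even for
#'   `connected_pairs`; forced to 1 for `single`).
#' @param seed optional RNG seed.
#' @param node the cooperator for `scheme = "single"` (random if `NULL`).
#' @return A `"pd_strategies"` object: character vector `strategy` of
#'   `"C"`/`"D"` labels plus the scheme tag and the isolated-C fraction
#'   `frac_isolated_C`.
#' @export
assign_initial_strategies <- function(network,
                                      scheme = c("random", "degree_rank",
                                                 "connected_pairs", "single"),
                                      count_C, seed = NULL, node = NULL) {
  stopifnot(inherits(network, "pd_network"))
  scheme <- match.arg(scheme)
  N <- network$N
  if (scheme == "single") count_C <- 1L
  stopifnot(is.numeric(count_C), length(count_C) == 1L, count_C == floor(count_C))
  if (count_C < 0 || count_C > N) stop("`count_C` must lie in 0..N")
  count_C <- as.integer(count_C)
  if (!is.null(seed)) set.seed(seed)
  cs <- switch(scheme,
    random = if (count_C) sample.int(N, count_C) else integer(0),
    degree_rank = order(-network$degree, seq_len(N))[seq_len(count_C)],
    connected_pairs = {
      if (count_C %% 2L != 0L) stop("`count_C` must be even for connected_pairs")
      perm <- sample.int(nrow(network$edges))
      used <- logical(N); picked <- integer(0)
      for (e in perm) {
        ij <- network$edges[e, ]
        if (!used[ij[1L]] && !used[ij[2L]]) {
          used[ij] <- TRUE
          picked <- c(picked, ij)
          if (length(picked) == count_C) break
        }
      }
      if (length(picked) < count_C) stop("not enough disjoint edges for connected_pairs")
      picked
    },
    single = if (is.null(node)) sample.int(N, 1L) else {
      stopifnot(node >= 1, node <= N)
      as.integer(node)
    }
  )
  strategy <- rep("D", N)
  strategy[cs] <- "C"
  isC <- strategy == "C"
  iso <- if (any(isC)) {
    mean(vapply(which(isC), function(i) !any(isC[network$adj[[i]]]), logical(1)))
  } else NA_real_
  structure(
    list(strategy = strategy, scheme = scheme, count_C = count_C,
         frac_isolated_C = iso),
    class = "pd_strategies"
  )
}

#' @export
print.pd_strategies <- function(x, ...) {
  cat(sprintf("pd_strategies: %d C's (%s placement)", x$count_C, x$scheme))
  if (!is.na(x$frac_isolated_C)) {
    cat(sprintf("; %.0f%% of initial C's isolated", 100 * x$frac_isolated_C))
  }
  cat("\n")
  invisible(x)
}

#' Edge-list text files
#'
#' Plain-text interchange format: one `"i j"` pair per line, 0-based node
#' indices, whitespace-separated.  `write_edgelist()` then
#' `read_edgelist()` reproduces the identical network.
#'
#' @param network a [pd_network()].
#' @param path file path.
#' @param N node count; defaults to `max index + 1` on read.
#' @return `read_edgelist()` returns a [pd_network()];
#'   `write_edgelist()` returns `path` invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "pd_network"))
  write.table(network$edges - 1L, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path, N = NULL) {
  el <- as.matrix(read.table(path, header = FALSE, col.names = c("i", "j")))
  if (is.null(N)) N <- max(el) + 1L
  pd_network(el + 1L, N, kind = "file")
}

#' Strategy tables on disk
#'
#' Two-column CSV (`node`, `strategy`) with 0-based node ids.
#' @param strategies a `"pd_strategies"` object or `"C"`/`"D"` vector.
#' @param path file path.
#' @export
write_strategies <- function(strategies, path) {
  s <- if (inherits(strategies, "pd_strategies")) strategies$strategy else strategies
  utils::write.csv(
    data.frame(node = seq_along(s) - 1L, strategy = s),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_strategies
#' @export
read_strategies <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("node", "strategy") %in% names(df)),
            all(df$strategy %in% c("C", "D")))
  df$strategy[order(df$node)]
}
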