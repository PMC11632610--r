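# Left-right planarity test (Brandes' formulation of the de Fraysseix /
# Rosenstiehl criterion). Decision version only: no embedding is produced.
# Vertices are 1..n_vertices; edges are given as an m x 2 integer matrix.
# Runs in O(V + E) per call, which keeps greedy planar-graph construction
# tractable in pure R.

#' Planarity test for a simple undirected graph
#'
#' @param edges integer matrix with two columns (vertex indices); parallel
#'   edges and self loops are removed before testing.
#' @param n_vertices number of vertices (>= max index).
#' @return `TRUE` when the graph admits a planar embedding.
#' @export
is_planar <- function(edges, n_vertices) {
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges)) {
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  n <- as.integer(n_vertices)
  m <- nrow(edges)
  if (m == 0 || n <= 2) return(TRUE)
  if (m > 3 * n - 6) return(FALSE)
  if (m <= 8) return(TRUE)  # smallest non-planar graphs have 9 edges

  INF <- n + 1L
  # adjacency: incident (neighbour, edge id) pairs per vertex
  adj_v <- vector("list", n)
  ends1 <- edges[, 1]; ends2 <- edges[, 2]
  for (i in seq_len(m)) {
    adj_v[[ends1[i]]] <- c(adj_v[[ends1[i]]], ends2[i], i)
    adj_v[[ends2[i]]] <- c(adj_v[[ends2[i]]], ends1[i], i)
  }

  height <- rep(INF, n)
  parent_edge <- integer(n)             # 0 = none
  oriented <- logical(m)
  esrc <- integer(m); etgt <- integer(m)
  lowpt <- integer(m); lowpt2 <- integer(m)
  nesting <- integer(m)

  dfs1 <- function(v) {
    e <- parent_edge[v]
    a <- adj_v[[v]]
    if (is.null(a)) return(invisible())
    for (i in seq(1, length(a), by = 2)) {
      w <- a[i]; id <- a[i + 1]
      if (oriented[id]) next
      oriented[id] <<- TRUE
      esrc[id] <<- v; etgt[id] <<- w
      lowpt[id] <<- height[v]; lowpt2[id] <<- height[v]
      if (height[w] == INF) {           # tree edge
        parent_edge[w] <<- id
        height[w] <<- height[v] + 1L
        dfs1(w)
      } else {
        lowpt[id] <<- height[w]         # back edge
      }
      nesting[id] <<- 2L * lowpt[id]
      if (lowpt2[id] < height[v]) nesting[id] <<- nesting[id] + 1L
      if (e != 0L) {
        if (lowpt[id] < lowpt[e]) {
          lowpt2[e] <<- min(lowpt[e], lowpt2[id])
          lowpt[e] <<- lowpt[id]
        } else if (lowpt[id] > lowpt[e]) {
          lowpt2[e] <<- min(lowpt2[e], lowpt[id])
        } else {
          lowpt2[e] <<- min(lowpt2[e], lowpt2[id])
        }
      }
    }
    invisible()
  }

  roots <- integer(0)
  for (s in seq_len(n)) {
    if (height[s] == INF) {
      height[s] <- 0L
      roots <- c(roots, s)
      dfs1(s)
    }
  }

  # outgoing adjacency ordered by nesting depth
  out_adj <- vector("list", n)
  for (id in seq_len(m)) out_adj[[esrc[id]]] <- c(out_adj[[esrc[id]]], id)
  for (v in seq_len(n)) {
    ids <- out_adj[[v]]
    if (length(ids) > 1) out_adj[[v]] <- ids[order(nesting[ids])]
  }

  # conflict-pair stack; intervals hold edge ids (0 = empty)
  S <- vector("list", m + 1L)           # entries: c(Llow, Lhigh, Rlow, Rhigh)
  s_top <- 0L
  ref <- integer(m)
  side <- rep(1L, m)
  lowpt_edge <- integer(m)
  stack_bottom <- integer(m)

  lowest <- function(P) {
    if (P[1] == 0L) return(lowpt[P[3]])
    if (P[3] == 0L) return(lowpt[P[1]])
    min(lowpt[P[1]], lowpt[P[3]])
  }
  conflicting <- function(low, high, b) high != 0L && lowpt[high] > lowpt[b]

  add_constraints <- function(ei, e) {
    P <- c(0L, 0L, 0L, 0L)
    # merge return edges of ei into P's right interval
    repeat {
      if (s_top <= stack_bottom[ei]) break
      Q <- S[[s_top]]; s_top <<- s_top - 1L
      if (Q[1] != 0L) Q <- c(Q[3], Q[4], Q[1], Q[2])
      if (Q[1] != 0L) return(FALSE)
      if (lowpt[Q[3]] > lowpt[e]) {
        if (P[3] == 0L) P[4] <- Q[4] else ref[P[3]] <<- Q[4]
        P[3] <- Q[3]
      } else {
        ref[Q[3]] <<- lowpt_edge[e]
      }
      if (s_top == stack_bottom[ei]) break
    }
    # merge conflicting return edges of earlier siblings into the left side
    while (s_top > 0L &&
           (conflicting(S[[s_top]][1], S[[s_top]][2], ei) ||
            conflicting(S[[s_top]][3], S[[s_top]][4], ei))) {
      Q <- S[[s_top]]; s_top <<- s_top - 1L
      if (conflicting(Q[3], Q[4], ei)) Q <- c(Q[3], Q[4], Q[1], Q[2])
      if (conflicting(Q[3], Q[4], ei)) return(FALSE)
      if (P[3] != 0L) ref[P[3]] <<- Q[4]
      if (Q[3] != 0L) P[3] <- Q[3]
      if (P[1] == 0L) P[2] <- Q[2] else ref[P[1]] <<- Q[2]
      P[1] <- Q[1]
    }
    if (!(P[1] == 0L && P[3] == 0L)) {
      s_top <<- s_top + 1L
      S[[s_top]] <<- P
    }
    TRUE
  }

  remove_back_edges <- function(e) {
    u <- esrc[e]
    while (s_top > 0L && lowest(S[[s_top]]) == height[u]) {
      P <- S[[s_top]]; s_top <<- s_top - 1L
      if (P[1] != 0L) side[P[1]] <<- -1L
    }
    if (s_top > 0L) {
      P <- S[[s_top]]; s_top <<- s_top - 1L
      while (P[2] != 0L && etgt[P[2]] == u) P[2] <- ref[P[2]]
      if (P[2] == 0L && P[1] != 0L) {
        ref[P[1]] <<- P[3]; side[P[1]] <<- -1L; P[1] <- 0L
      }
      while (P[4] != 0L && etgt[P[4]] == u) P[4] <- ref[P[4]]
      if (P[4] == 0L && P[3] != 0L) {
        ref[P[3]] <<- P[1]; side[P[3]] <<- -1L; P[3] <- 0L
      }
      s_top <<- s_top + 1L
      S[[s_top]] <<- P
    }
    invisible()
  }

  dfs2 <- function(v) {
    e <- parent_edge[v]
    ids <- out_adj[[v]]
    if (!is.null(ids)) {
      first <- ids[1]
      for (ei in ids) {
        w <- etgt[ei]
        stack_bottom[ei] <<- s_top
        if (ei == parent_edge[w]) {     # tree edge
          if (!dfs2(w)) return(FALSE)
        } else {                        # back edge
          lowpt_edge[ei] <<- ei
          s_top <<- s_top + 1L
          S[[s_top]] <<- c(0L, 0L, ei, ei)
        }
        if (lowpt[ei] < height[v]) {    # ei has a return edge
          if (ei == first) {
            if (e != 0L) lowpt_edge[e] <<- lowpt_edge[ei]
          } else if (!add_constraints(ei, e)) {
            return(FALSE)
          }
        }
      }
    }
    if (e != 0L) {
      u <- esrc[e]
      remove_back_edges(e)
      if (lowpt[e] < height[u] && s_top > 0L) {
        hl <- S[[s_top]][2]; hr <- S[[s_top]][4]
        if (hl != 0L && (hr == 0L || lowpt[hl] > lowpt[hr])) {
          ref[e] <<- hl
        } else {
          ref[e] <<- hr
        }
      }
    }
    TRUE
  }

  for (s in roots) if (!dfs2(s)) return(FALSE)
  TRUE
}
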