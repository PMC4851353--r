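# Tracklet relinking: a gated graph over tracklet endpoints solved as a
# min-cost max-flow problem, reconnecting trajectory fragments caused by
# occlusion and detection failure.

#' Build the gated tracklet link graph
#'
#' For every ordered tracklet pair (i, j), a candidate link edge is added
#' iff the temporal gap `st_j - ed_i` is strictly positive and smaller than
#' `max_interf` frames, and the Euclidean distance `D` between the head
#' joint at the end of i and the start of j is below `max_interd` px. The
#' edge cost is `exp(D) * exp(-V)` with `V` the von Mises similarity of the
#' two endpoint head orientations. Body-rectangle information is
#' deliberately excluded: body geometry changes too much across a gap to be
#' a reliable cue.
#'
#' @param tracklets list of tracklets from [track_sequence()].
#' @param max_interf maximum frame gap (exclusive), frames.
#' @param max_interd maximum endpoint distance (exclusive), px.
#' @param k von Mises concentration for the orientation term.
#' @return A `link_graph`: list with `n` (tracklet count) and `edges`
#'   (tibble: `edge`, `i`, `j`, `gap`, `D`, `V`, `cost`).
#' @export
build_link_graph <- function(tracklets, max_interf = 6, max_interd = 80,
                             k = 4) {
  stopifnot(length(tracklets) >= 1L)
  n <- length(tracklets)
  rows <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      gap <- tracklets[[j]]$st - tracklets[[i]]$ed
      if (!(gap > 0 && gap < max_interf)) next
      pi_ <- tracklets[[i]]$head_out
      pj <- tracklets[[j]]$head_in
      D <- sqrt(sum((pj[1:2] - pi_[1:2])^2))
      if (!(D < max_interd)) next
      V <- von_mises_density(pj[3], pi_[3], k)
      rows[[length(rows) + 1L]] <-
        tibble(i = i, j = j, gap = gap, D = D, V = V,
               cost = exp(D) * exp(-V))
    }
  }
  edges <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(i = integer(0), j = integer(0), gap = numeric(0),
           D = numeric(0), V = numeric(0), cost = numeric(0))
  edges <- dplyr::arrange(edges, .data$i, .data$j)
  edges$edge <- seq_len(nrow(edges))
  structure(list(n = n, edges = edges,
                 max_interf = max_interf, max_interd = max_interd, k = k),
            class = "link_graph")
}

# Min-cost selection of exactly `k_links` link edges such that every
# tracklet has at most one outgoing and one incoming link (vertex-disjoint
# chains). Solved by successive shortest augmenting paths on the unit-
# capacity network S -> out_i -> in_j -> E with Bellman-Ford on the
# residual graph; ties are broken towards the lexicographically smallest
# edge id, making the solution deterministic.
mcmf_matching <- function(edges, n, k_links) {
  chosen <- rep(FALSE, nrow(edges))
  if (k_links == 0L) {
    return(list(feasible = TRUE, chosen = chosen, total_cost = 0))
  }
  # node ids: 1 = S, 2 = E, 2 + i = out_i, 2 + n + j = in_j
  nn <- 2L + 2L * n
  # arcs as parallel vectors; each arc has a residual partner rev[a]
  from <- to <- rev_ <- integer(0)
  cost <- numeric(0)
  cap <- integer(0)
  eid <- integer(0)   # link-edge id carried by out->in arcs (0 otherwise)
  add_arc <- function(f, t, c, cp, id) {
    from <<- c(from, f, t)
    to <<- c(to, t, f)
    cost <<- c(cost, c, -c)
    cap <<- c(cap, cp, 0L)
    a <- length(from)
    rev_ <<- c(rev_, a, a - 1L)
    eid <<- c(eid, id, id)
  }
  outs <- sort(unique(edges$i))
  ins <- sort(unique(edges$j))
  for (i in outs) add_arc(1L, 2L + i, 0, 1L, 0L)
  for (r in seq_len(nrow(edges))) {
    add_arc(2L + edges$i[r], 2L + n + edges$j[r], edges$cost[r], 1L,
            edges$edge[r])
  }
  for (j in ins) add_arc(2L + n + j, 2L, 0, 1L, 0L)

  flow <- 0L
  total <- 0
  arcs_from <- split(seq_along(from), from)
  while (flow < k_links) {
    dist <- rep(Inf, nn)
    dist[1L] <- 0
    pre <- integer(nn)
    # Bellman-Ford; deterministic relaxation order
    repeat {
      changed <- FALSE
      for (a in seq_along(from)) {
        if (cap[a] > 0L && is.finite(dist[from[a]])) {
          nd <- dist[from[a]] + cost[a]
          if (nd < dist[to[a]] - 1e-12) {
            dist[to[a]] <- nd
            pre[to[a]] <- a
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
    if (!is.finite(dist[2L])) {
      return(list(feasible = FALSE, chosen = chosen, total_cost = NA_real_))
    }
    v <- 2L
    while (v != 1L) {
      a <- pre[v]
      cap[a] <- cap[a] - 1L
      cap[rev_[a]] <- cap[rev_[a]] + 1L
      # traversing a link arc selects it; traversing its residual cancels
      if (eid[a] > 0L) chosen[eid[a]] <- !chosen[eid[a]]
      v <- from[a]
    }
    total <- total + dist[2L]
    flow <- flow + 1L
  }
  list(feasible = TRUE, chosen = chosen,
       total_cost = sum(edges$cost[chosen]))
}

#' Solve the relinking flow problem at a given total flow
#'
#' A total flow `f` corresponds to `f` final trajectories, i.e. choosing
#' `n - f` link edges such that each tracklet gains at most one successor
#' and at most one predecessor; among all such selections the minimum-cost
#' one is found by a successive-shortest-path min-cost-flow solver with
#' deterministic (lexicographic edge id) tie-breaking.
#'
#' @param graph a [build_link_graph()] result.
#' @param f desired total flow (number of final trajectories),
#'   `1 <= f <= n`.
#' @return A list with `feasible`, `links` (the chosen edge rows of
#'   `graph$edges`) and `total_cost`.
#' @export
solve_mcmf <- function(graph, f) {
  n <- graph$n
  stopifnot(f >= 1L, f <= n)
  k_links <- n - f
  sol <- mcmf_matching(graph$edges, n, k_links)
  list(feasible = sol$feasible,
       links = graph$edges[sol$chosen, , drop = FALSE],
       total_cost = sol$total_cost)
}

# Largest feasible number of links (maximum matching size).
max_links <- function(graph) {
  lo <- 0L
  hi <- nrow(graph$edges)
  hi <- min(hi, graph$n - 1L)
  best <- 0L
  k <- 0L
  while (k <= hi) {
    if (mcmf_matching(graph$edges, graph$n, k)$feasible) best <- k else break
    k <- k + 1L
  }
  best
}

#' Relink tracklets into maximal trajectories
#'
#' Builds the gated link graph and chooses links by min-cost flow. When the
#' number of fish is known, the flow is fixed to it; otherwise feasible
#' flow values are enumerated and the solution with the most links whose
#' edges all fall below `cost_ceiling` is taken (with the default ceiling
#' of `Inf` this simply maximizes the number of links, then minimizes
#' cost). Linked tracklets are chained, each chain keeping the identity of
#' its earliest tracklet; unlinked tracklets pass through unchanged.
#'
#' @param tracklets list of tracklets from [track_sequence()].
#' @param params parameter list from [fishchain_config()].
#' @param n_fish optional known number of fish (fixes the total flow).
#' @param cost_ceiling links costlier than this are not acceptable when
#'   enumerating flows.
#' @return A list with `tracklets` (relabeled, same structure), `links`
#'   (audit tibble: `i`, `j`, `gap`, `D`, `V`, `cost`), and `id_map`
#'   (named vector mapping original tracklet ids to final trajectory ids).
#' @export
relink <- function(tracklets, params = fishchain_config(), n_fish = NULL,
                   cost_ceiling = Inf) {
  n <- length(tracklets)
  if (n == 0L) {
    return(list(tracklets = tracklets,
                links = tibble(i = integer(0), j = integer(0)),
                id_map = integer(0)))
  }
  graph <- build_link_graph(tracklets, params$max_interf, params$max_interd,
                            params$k)
  if (nrow(graph$edges) == 0L) {
    ids <- vapply(tracklets, function(t) as.numeric(t$id), 0)
    return(list(tracklets = tracklets, links = graph$edges,
                id_map = setNames(ids, ids)))
  }
  if (!is.null(n_fish)) {
    sol <- solve_mcmf(graph, max(1L, as.integer(n_fish)))
    if (!sol$feasible) {
      sol <- solve_mcmf(graph, graph$n - max_links(graph))
    }
  } else {
    k <- max_links(graph)
    while (k > 0L) {
      sol <- solve_mcmf(graph, graph$n - k)
      if (sol$feasible && all(sol$links$cost <= cost_ceiling)) break
      k <- k - 1L
    }
    if (k == 0L) sol <- list(links = graph$edges[0, ], total_cost = 0)
  }
  links <- sol$links

  # chain the links: successor map over tracklet indices
  succ <- rep(NA_integer_, n)
  succ[links$i] <- links$j
  has_pred <- rep(FALSE, n)
  has_pred[links$j] <- TRUE
  ids <- vapply(tracklets, function(t) as.numeric(t$id), 0)
  id_map <- setNames(ids, as.character(ids))
  for (s in seq_len(n)) {
    if (has_pred[s]) next
    cur <- s
    while (!is.na(succ[cur])) {
      cur <- succ[cur]
      id_map[as.character(ids[cur])] <- id_map[as.character(ids[s])]
    }
  }
  out <- lapply(tracklets, function(tk) {
    new_id <- unname(id_map[as.character(tk$id)])
    tk$id <- new_id
    tk$poses <- lapply(tk$poses, function(p) {
      p$id <- new_id
      p
    })
    tk
  })
  list(tracklets = out, links = links, id_map = id_map)
}

#' Merge relinked tracklets into one trajectory table
#'
#' @param relinked result of [relink()].
#' @param spec a [rect_spec()].
#' @return A `fish_trajectories` tibble of pose rows (one per fish-frame),
#'   sorted by id then frame.
#' @export
trajectories_table <- function(relinked, spec) {
  tab <- dplyr::bind_rows(lapply(relinked$tracklets, function(tk) {
    poses_to_table(tk$poses, spec)
  }))
  tab <- dplyr::arrange(tab, .data$id, .data$frame)
  class(tab) <- c("fish_trajectories", class(tab))
  tab
}
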