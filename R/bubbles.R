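# Doubled (oriented) view of a bidirected graph: each node contributes two
# directed vertices, (node, "+") traversing left-to-right and (node, "-")
# right-to-left. Vertex 2i-1 is (ids[i], "+"), vertex 2i is (ids[i], "-").
doubled_index <- function(g) {
  ids <- g$ids
  n <- length(ids)
  nE <- 2L * n
  node_of <- rep(seq_len(n), each = 2L)
  children <- vector("list", nE)
  parents <- vector("list", nE)
  lookup <- function(node, side) {
    # oriented vertex that EXITS through `side`
    i <- match(node, ids)
    if (side == "R") 2L * i - 1L else 2L * i
  }
  for (i in seq_len(n)) {
    for (dir in c(1L, 2L)) {            # 1 = "+", 2 = "-"
      v <- 2L * i - 2L + dir
      exit <- if (dir == 1L) "R" else "L"
      a <- adj_at(g, ids[i], exit)
      if (length(a$node)) {
        # entering neighbor w at side s means w continues in direction
        # exiting opp(s)
        children[[v]] <- vapply(seq_along(a$node), function(j) {
          lookup(a$node[j], opp_side(a$side[j]))
        }, integer(1))
      } else children[[v]] <- integer(0)
      ent <- if (dir == 1L) "L" else "R"
      b <- adj_at(g, ids[i], ent)
      if (length(b$node)) {
        # a parent exits through the side it attaches with
        parents[[v]] <- vapply(seq_along(b$node), function(j) {
          lookup(b$node[j], b$side[j])
        }, integer(1))
      } else parents[[v]] <- integer(0)
    }
  }
  list(ids = ids, n = n, nE = nE, node_of = node_of,
       children = children, parents = parents)
}

flip_vertex <- function(v) v + ifelse(v %% 2L == 1L, 1L, -1L)

vertex_dir <- function(v) if (v %% 2L == 1L) "+" else "-"

# exit side of an oriented vertex ("+": R, "-": L)
vertex_exit <- function(v) if (v %% 2L == 1L) "R" else "L"

# Superbubble search from a single oriented source vertex, in the style of
# the average-case linear-time algorithm of Onodera, Sadakane and Shibuya:
# repeatedly visit a frontier vertex all of whose parents are visited, mark
# its children seen; abort on a tip (childless vertex), on returning to the
# source node, or on meeting a node in both orientations; succeed when the
# frontier holds exactly one vertex and nothing else remains seen-but-
# unvisited. The candidate sink is rejected if it links back to the source.
sb_search <- function(idx, s) {
  nE <- idx$nE
  status <- integer(nE)        # 0 unseen, 1 seen, 2 visited
  status[s] <- 1L
  nseen <- 1L
  stack <- s
  s_node <- idx$node_of[s]
  repeat {
    if (!length(stack)) return(NULL)
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    status[v] <- 2L
    nseen <- nseen - 1L
    ch <- idx$children[[v]]
    if (!length(ch)) return(NULL)                 # tip
    for (u in ch) {
      if (idx$node_of[u] == s_node) return(NULL)  # cycle back to the source
      if (status[u] == 2L) return(NULL)           # re-entering a visited vertex
      if (status[flip_vertex(u)] != 0L) return(NULL)  # both orientations
      if (status[u] == 0L) {
        status[u] <- 1L
        nseen <- nseen + 1L
      }
      pa <- idx$parents[[u]]
      if (all(status[pa] == 2L)) stack <- c(stack, u)
    }
    if (length(stack) == 1L && nseen == 1L) {
      t <- stack[1L]
      for (u in idx$children[[t]])
        if (idx$node_of[u] == s_node) return(NULL)  # sink linked back to source
      interior <- idx$ids[unique(idx$node_of[which(status == 2L)])]
      interior <- setdiff(interior, idx$ids[s_node])
      return(list(t = t, interior = sort(interior)))
    }
  }
}

canonical_ends <- function(e1, e2) {
  # order the two (node, side) ends lexicographically
  k1 <- paste(e1$node, e1$side)
  k2 <- paste(e2$node, e2$side)
  if (k1 <= k2) list(source = e1, sink = e2) else list(source = e2, sink = e1)
}

source_end_of <- function(idx, s) list(node = idx$ids[idx$node_of[s]], side = vertex_exit(s))
sink_end_of <- function(idx, t) list(node = idx$ids[idx$node_of[t]], side = opp_side(vertex_exit(t)))

#' Find the minimal superbubble headed by an oriented node end
#'
#' Searches for the unique minimal sink `t` such that the subgraph between
#' the given source end and `t` is directed, acyclic, and the set of nodes
#' reachable from the source equals the set of nodes from which `t` can be
#' reached. Sources with fewer than two children cannot head a minimal
#' superbubble and return `NULL` immediately.
#'
#' @param graph a [bdgraph] object.
#' @param node source node id.
#' @param side the side of `node` out of which the bubble opens
#'   (`"L"` or `"R"`).
#' @return `NULL`, or a list with elements `source` and `sink` (each a
#'   `list(node, side)` where `side` faces into the bubble) and `interior`
#'   (sorted character vector of interior node ids).
#' @export
find_superbubble <- function(graph, node, side) {
  stopifnot(inherits(graph, "bdgraph"))
  side <- match.arg(side, c("L", "R"))
  if (!node %in% graph$ids) stop_lookup(sprintf("unknown node '%s'", node))
  idx <- doubled_index(graph)
  i <- match(node, graph$ids)
  s <- if (side == "R") 2L * i - 1L else 2L * i
  if (length(idx$children[[s]]) < 2L) return(NULL)
  r <- sb_search(idx, s)
  if (is.null(r)) return(NULL)
  list(source = source_end_of(idx, s), sink = sink_end_of(idx, r$t),
       interior = r$interior)
}

# classify a (source, sink, interior) triple on the given graph
bubble_type_of <- function(g, source, sink, interior) {
  branchlike <- function(id) {
    aL <- adj_at(g, id, "L"); aR <- adj_at(g, id, "R")
    ends <- paste(c(aL$node, aR$node), c(aL$side, aR$side))
    if (length(ends) != 2) return(FALSE)
    setequal(ends, c(paste(source$node, source$side), paste(sink$node, sink$side))) &&
      !anyDuplicated(ends)
  }
  st <- has_edge(g, source, sink)
  if (length(interior) == 2 && !st && all(vapply(interior, branchlike, logical(1))))
    return("simple")
  if (length(interior) == 1 && st && branchlike(interior))
    return("insertion")
  "super"
}

#' Is a bubble a simple bubble?
#'
#' A simple bubble has exactly two disjoint interior paths between source and
#' sink: after compaction, exactly two interior nodes, each adjacent only to
#' the source end and the sink end, with no direct source-sink edge.
#'
#' @param graph the [bdgraph] the bubble was detected on (compacted, for the
#'   two-path criterion to be meaningful).
#' @param bubble a bubble as returned in [detect_bubbles()]`$bubbles`, or any
#'   list with `source`, `sink` and `interior` in the same layout.
#' @return logical.
#' @export
is_simple_bubble <- function(graph, bubble) {
  bubble_type_of(graph, bubble$source, bubble$sink, bubble$interior) == "simple"
}

#' Detect all bubbles and superbubbles of a bidirected graph
#'
#' Runs the superbubble search from every oriented end of every node (in
#' sorted order, so the result is deterministic), canonicalizes duplicates
#' (the same bubble found forward from its source and backward from its sink
#' is one object), classifies each bubble as `"simple"`, `"insertion"`
#' (one interior branch in parallel with a direct source-sink edge) or
#' `"super"`, and links nested bubbles to their smallest enclosing
#' superbubble.
#'
#' Simple/insertion classification is meaningful on a compacted graph (see
#' [bdg_compact()]); on an uncompacted graph multi-node branches make every
#' bubble look "super".
#'
#' @param graph a [bdgraph] object.
#' @return an object of class `gfab_bubbles`: a list with element `bubbles`,
#'   a list of bubbles, each of class `gfab_bubble` with fields `source`,
#'   `sink` (each `list(node, side)`, sides facing into the bubble),
#'   `interior` (sorted node ids), `type`, and `parent` (index of the
#'   enclosing bubble in `bubbles`, or `NA` for top-level bubbles).
#' @export
detect_bubbles <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  idx <- doubled_index(graph)
  found <- list()
  keys <- character()
  for (v in seq_len(idx$nE)) {
    if (length(idx$children[[v]]) < 2L) next
    r <- sb_search(idx, v)
    if (is.null(r)) next
    ce <- canonical_ends(source_end_of(idx, v), sink_end_of(idx, r$t))
    key <- paste(ce$source$node, ce$source$side, ce$sink$node, ce$sink$side)
    j <- match(key, keys)
    if (is.na(j)) {
      keys <- c(keys, key)
      found[[length(found) + 1]] <- list(source = ce$source, sink = ce$sink,
                                         interior = r$interior)
    }
  }
  # deterministic order by canonical key
  if (length(found)) {
    o <- order(keys)
    found <- found[o]
  }
  bubbles <- lapply(found, function(b) {
    structure(list(
      source = b$source, sink = b$sink, interior = b$interior,
      type = bubble_type_of(graph, b$source, b$sink, b$interior),
      parent = NA_integer_
    ), class = "gfab_bubble")
  })
  bubbles <- assign_parents(bubbles)
  structure(list(bubbles = bubbles, n_nodes = length(graph$ids)),
            class = "gfab_bubbles")
}

# parent = smallest enclosing bubble: interior of the parent contains the
# child's interior and both child endpoint nodes
assign_parents <- function(bubbles) {
  if (length(bubbles) < 2) return(bubbles)
  spans <- lapply(bubbles, function(b) c(b$interior, b$source$node, b$sink$node))
  isize <- vapply(bubbles, function(b) length(b$interior), integer(1))
  for (i in seq_along(bubbles)) {
    enclosing <- which(vapply(seq_along(bubbles), function(j) {
      j != i && isize[j] > isize[i] && all(spans[[i]] %in% bubbles[[j]]$interior)
    }, logical(1)))
    if (length(enclosing)) {
      bubbles[[i]]$parent <- enclosing[which.min(isize[enclosing])]
    }
  }
  bubbles
}

#' @export
print.gfab_bubbles <- function(x, ...) {
  tys <- vapply(x$bubbles, `[[`, "", "type")
  nested <- sum(!is.na(vapply(x$bubbles, `[[`, NA_integer_, "parent")))
  cat(sprintf("bubble set: %d bubbles (%d simple, %d superbubbles, %d insertion; %d nested)\n",
              length(x$bubbles), sum(tys == "simple"), sum(tys == "super"),
              sum(tys == "insertion"), nested))
  invisible(x)
}

#' @export
print.gfab_bubble <- function(x, ...) {
  cat(sprintf("<%s bubble> %s.%s -- %s.%s | interior: %s%s\n",
              x$type, abbrev_id(x$source$node), x$source$side,
              abbrev_id(x$sink$node), x$sink$side,
              paste(abbrev_id(x$interior), collapse = ","),
              if (!is.na(x$parent)) sprintf(" (nested, parent #%d)", x$parent) else ""))
  invisible(x)
}
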