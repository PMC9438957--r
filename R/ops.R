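#' Compact linear stretches of nodes into unitigs
#'
#' A maximal path of nodes in which every internal junction has exactly one
#' edge on each of the two connecting sides is replaced by a single merged
#' node. The merged sequence is the concatenation of the member sequences in
#' path orientation (a member traversed right-to-left contributes its reverse
#' complement) with each edge's overlap trimmed from the successor's prefix.
#' External edges are reattached to the merged node's outer ends. In
#' length-only graphs, lengths are summed minus overlaps. A node whose two
#' edges attach to the same side is a junction and is never merged through,
#' as is any node carrying a self-loop. Circular linear paths compact to a
#' single self-loop node starting from the lexicographically smallest member
#' id. Merged node ids concatenate the member ids with `"_"` in path order.
#'
#' The result contains no further compactable pair, so the operation is
#' idempotent.
#'
#' @param graph a [bdgraph] object.
#' @return a compacted [bdgraph] object.
#' @export
bdg_compact <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  if (length(graph$ids) < 2) return(graph)
  ed <- graph$edges
  if (nrow(ed) == 0) return(graph)

  deg <- lengths(lapply(graph$adj, `[[`, "node"))
  end_deg <- function(node, side) {
    d <- deg[end_key(node, side)]
    if (is.na(d)) 0L else d
  }
  blocked <- graph$selfloops

  # mergeable links: both incident ends have degree exactly 1, distinct nodes,
  # neither node blocked by a self-loop
  merge_ok <- logical(nrow(ed))
  for (i in seq_len(nrow(ed))) {
    merge_ok[i] <- ed$from[i] != ed$to[i] &&
      !(ed$from[i] %in% blocked) && !(ed$to[i] %in% blocked) &&
      end_deg(ed$from[i], ed$from_side[i]) == 1L &&
      end_deg(ed$to[i], ed$to_side[i]) == 1L
  }

  if (!any(merge_ok)) return(graph)

  # link map over mergeable edges: end key -> (partner node, partner side, ov)
  linkmap <- new.env(parent = emptyenv())
  edge_id_of <- new.env(parent = emptyenv())
  for (i in which(merge_ok)) {
    k1 <- end_key(ed$from[i], ed$from_side[i])
    k2 <- end_key(ed$to[i], ed$to_side[i])
    assign(k1, list(node = ed$to[i], side = ed$to_side[i], overlap = ed$overlap[i], edge = i), linkmap)
    assign(k2, list(node = ed$from[i], side = ed$from_side[i], overlap = ed$overlap[i], edge = i), linkmap)
  }
  getlink <- function(node, side) {
    k <- end_key(node, side)
    if (exists(k, envir = linkmap, inherits = FALSE)) get(k, envir = linkmap) else NULL
  }

  in_path <- new.env(parent = emptyenv())
  seen <- function(id) exists(id, envir = in_path, inherits = FALSE)

  # walk from (node, entry) through merge links exiting the opposite side
  follow <- function(node, entry) {
    nodes <- node; entries <- entry; overlaps <- integer(); edges_used <- integer()
    cyc <- FALSE
    repeat {
      cur <- nodes[length(nodes)]
      ex <- opp_side(entries[length(entries)])
      lk <- getlink(cur, ex)
      if (is.null(lk)) break
      if (lk$node == nodes[1] && lk$side == entries[1]) {
        cyc <- TRUE
        overlaps <- c(overlaps, lk$overlap)
        edges_used <- c(edges_used, lk$edge)
        break
      }
      nodes <- c(nodes, lk$node)
      entries <- c(entries, lk$side)
      overlaps <- c(overlaps, lk$overlap)
      edges_used <- c(edges_used, lk$edge)
    }
    list(nodes = nodes, entries = entries, overlaps = overlaps,
         edges = edges_used, cycle = cyc)
  }

  merged <- list()        # each: nodes, entries, overlaps, edges, cycle, closing ov
  consumed_edges <- integer()

  for (id in graph$ids) {
    if (seen(id)) next
    if (is.null(getlink(id, "L")) && is.null(getlink(id, "R"))) next
    p1 <- follow(id, "L")  # walks rightward (exits R first)
    if (p1$cycle) {
      path <- p1
    } else {
      p2 <- follow(id, "R")  # walks leftward
      # reverse p2 (minus the shared seed) and flip entry sides, then append p1
      n2 <- length(p2$nodes)
      if (n2 > 1) {
        nodes <- c(rev(p2$nodes[-1]), p1$nodes)
        entries <- c(opp_side(rev(p2$entries[-1])), p1$entries)
        overlaps <- c(rev(p2$overlaps), p1$overlaps)
        edges_used <- c(rev(p2$edges), p1$edges)
      } else {
        nodes <- p1$nodes; entries <- p1$entries
        overlaps <- p1$overlaps; edges_used <- p1$edges
      }
      path <- list(nodes = nodes, entries = entries, overlaps = overlaps,
                   edges = edges_used, cycle = FALSE)
    }
    if (length(path$nodes) < 2) next
    if (path$cycle) {
      # rotate so the lexicographically smallest member comes first
      closing <- path$overlaps[length(path$overlaps)]
      m <- length(path$nodes)
      r <- which(path$nodes == min(path$nodes))[1]
      if (r > 1) {
        rot <- c(r:m, seq_len(r - 1))
        # overlaps[i] joins nodes[i] -> nodes[i+1]; closing joins last -> first
        ov_full <- path$overlaps  # length m, last is closing
        path$nodes <- path$nodes[rot]
        path$entries <- path$entries[rot]
        ov_full <- ov_full[c(r:m, seq_len(r - 1))]
        path$overlaps <- ov_full
      }
      path$closing <- path$overlaps[m]
      path$overlaps <- path$overlaps[-m]
    }
    for (nd in path$nodes) assign(nd, TRUE, in_path)
    merged[[length(merged) + 1]] <- path
    consumed_edges <- c(consumed_edges, path$edges)
  }

  if (!length(merged)) return(graph)

  # build merged nodes and the end-translation map
  trans <- new.env(parent = emptyenv())
  new_ids <- character(); new_seqs <- character(); new_lens <- integer()
  loop_edges <- empty_edges()
  for (p in merged) {
    newid <- paste(p$nodes, collapse = "_")
    segs <- character(length(p$nodes))
    lens <- integer(length(p$nodes))
    lenonly <- any(is.na(graph$seq[p$nodes]))
    for (i in seq_along(p$nodes)) {
      nd <- p$nodes[i]
      lens[i] <- graph$len[[nd]]
      if (!lenonly) {
        s <- graph$seq[[nd]]
        segs[i] <- if (p$entries[i] == "L") s else revcomp(s)
      }
      if (i > 1) {
        ov <- p$overlaps[i - 1]
        if (ov >= lens[i])
          stop_input(sprintf(
            "cannot compact: overlap %d on edge %s-%s is not smaller than the successor length %d",
            ov, p$nodes[i - 1], p$nodes[i], lens[i]))
        lens[i] <- lens[i] - ov
        if (!lenonly) segs[i] <- substring(segs[i], ov + 1)
      }
    }
    new_ids <- c(new_ids, newid)
    new_seqs <- c(new_seqs, if (lenonly) NA_character_ else paste(segs, collapse = ""))
    new_lens <- c(new_lens, sum(lens))
    if (p$cycle) {
      loop_edges <- rbind(loop_edges, data.frame(
        from = newid, from_side = "R", to = newid, to_side = "L",
        overlap = p$closing, stringsAsFactors = FALSE))
    } else {
      first <- p$nodes[1]; last <- p$nodes[length(p$nodes)]
      assign(end_key(first, p$entries[1]), c(newid, "L"), trans)
      assign(end_key(last, opp_side(p$entries[length(p$entries)])), c(newid, "R"), trans)
    }
  }

  tr <- function(node, side) {
    k <- end_key(node, side)
    if (exists(k, envir = trans, inherits = FALSE)) get(k, envir = trans)
    else c(node, side)
  }

  keep_ids <- setdiff(graph$ids, unlist(lapply(merged, `[[`, "nodes")))
  nodes_new <- data.frame(
    id = c(keep_ids, new_ids),
    seq = c(unname(graph$seq[keep_ids]), new_seqs),
    len = c(unname(graph$len[keep_ids]), new_lens),
    stringsAsFactors = FALSE)

  keep <- setdiff(seq_len(nrow(ed)), consumed_edges)
  rows <- ed[keep, , drop = FALSE]
  if (nrow(rows)) {
    for (i in seq_len(nrow(rows))) {
      f <- tr(rows$from[i], rows$from_side[i])
      t <- tr(rows$to[i], rows$to_side[i])
      rows$from[i] <- f[1]; rows$from_side[i] <- f[2]
      rows$to[i] <- t[1]; rows$to_side[i] <- t[2]
    }
  }
  edges_new <- rbind(rows, loop_edges)
  out <- suppressWarnings(bdgraph(nodes_new, edges_new, k = graph$k))
  out
}

# node-level connectivity (edges of both sides count)
node_adjacency <- function(graph) {
  ed <- graph$edges
  adj <- lapply(stats::setNames(vector("list", length(graph$ids)), graph$ids), function(x) character())
  if (nrow(ed)) {
    both <- rbind(data.frame(a = ed$from, b = ed$to, stringsAsFactors = FALSE),
                  data.frame(a = ed$to, b = ed$from, stringsAsFactors = FALSE))
    sp <- split(both$b, both$a)
    for (nm in names(sp)) adj[[nm]] <- sort(unique(sp[[nm]]))
  }
  adj
}

#' Connected components of a bidirected graph
#'
#' Connectivity ignores sides: two nodes are connected if any edge joins any
#' of their sides. Components are returned largest first; ties are broken by
#' the lexicographically smallest member id.
#'
#' @param graph a [bdgraph] object.
#' @return list of character vectors of node ids (each sorted).
#' @export
bdg_components <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  adj <- node_adjacency(graph)
  unvisited <- new.env(parent = emptyenv())
  for (id in graph$ids) assign(id, TRUE, unvisited)
  comps <- list()
  for (id in graph$ids) {
    if (!exists(id, envir = unvisited, inherits = FALSE)) next
    comp <- character(); queue <- id
    rm(list = id, envir = unvisited)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (exists(w, envir = unvisited, inherits = FALSE)) {
          rm(list = w, envir = unvisited)
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  mins <- vapply(comps, `[[`, "", 1)
  comps[order(-lengths(comps), mins)]
}

#' Biggest connected component
#'
#' Returns the induced subgraph on the component with the most nodes. On a
#' tie, the component containing the lexicographically smallest node id wins.
#'
#' @param graph a non-empty [bdgraph] object.
#' @return a [bdgraph] object.
#' @export
bdg_biggest_component <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  if (length(graph$ids) == 0) stop_input("biggest_component of an empty graph")
  bdg_subgraph(graph, bdg_components(graph)[[1]])
}

#' Extract a fixed-size neighborhood around a node
#'
#' Breadth-first expansion from `start` over both node sides until `size`
#' nodes are collected (or the component is exhausted); returns the induced
#' subgraph. Neighbors are enqueued in sorted node-id order, so the result is
#' reproducible. `size` counts nodes, not hops; `start` is always included.
#'
#' @param graph a [bdgraph] object.
#' @param start node id at the center of the neighborhood.
#' @param size maximum number of nodes to collect (>= 1).
#' @return a [bdgraph] object.
#' @export
bdg_neighborhood <- function(graph, start, size) {
  stopifnot(inherits(graph, "bdgraph"))
  if (!start %in% graph$ids) stop_lookup(sprintf("unknown start node '%s'", start))
  size <- as.integer(size)
  if (is.na(size) || size < 1) stop_input("neighborhood size must be >= 1")
  adj <- node_adjacency(graph)
  collected <- new.env(parent = emptyenv())
  assign(start, TRUE, collected)
  n_coll <- 1L
  queue <- start
  while (length(queue) && n_coll < size) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {   # already sorted
      if (!exists(w, envir = collected, inherits = FALSE)) {
        assign(w, TRUE, collected)
        n_coll <- n_coll + 1L
        queue <- c(queue, w)
        if (n_coll >= size) break
      }
    }
  }
  bdg_subgraph(graph, ls(collected))
}
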