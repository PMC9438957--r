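# Longest source-to-sink walk through a bubble, in bases, counting both
# endpoint nodes fully and subtracting edge overlaps. Memoized DFS over the
# oriented vertices restricted to the bubble's node set (acyclic by the
# superbubble definition).
bubble_span_bases <- function(g, bubble) {
  allowed <- c(bubble$interior, bubble$source$node, bubble$sink$node)
  sinkn <- bubble$sink$node
  sinks <- bubble$sink$side
  memo <- new.env(parent = emptyenv())
  rec <- function(node, exit) {
    key <- end_key(node, exit)
    if (exists(key, envir = memo, inherits = FALSE)) return(get(key, envir = memo))
    a <- adj_at(g, node, exit)
    best <- -Inf
    for (j in seq_along(a$node)) {
      w <- a$node[j]; sw <- a$side[j]; ov <- a$overlap[j]
      if (w == sinkn && sw == sinks) {
        best <- max(best, g$len[[sinkn]] - ov)
      } else if (w %in% bubble$interior) {
        best <- max(best, rec(w, opp_side(sw)) - ov)
      }
    }
    val <- if (is.finite(best)) g$len[[node]] + best else -Inf
    assign(key, val, memo)
    val
  }
  v <- rec(bubble$source$node, bubble$source$side)
  if (!is.finite(v)) NA_integer_ else as.integer(v)
}

#' Assemble top-level bubbles into bubble chains
#'
#' A bubble chain is a maximal linear run of bubbles in which the sink node
#' of one bubble is the source node of the next. Only top-level bubbles
#' (those not nested inside a superbubble) become chain members; an isolated
#' bubble forms a chain of length one. An endpoint node shared by three or
#' more bubbles breaks the chain there (chains are linear, never branching).
#' Chains are ordered deterministically: each chain starts from its
#' lexicographically smaller outer endpoint, and chain ids are consecutive
#' integers after sorting chains by their starting endpoint id.
#'
#' @param bubbles a `gfab_bubbles` object from [detect_bubbles()].
#' @param graph the [bdgraph] the bubbles were detected on (used to measure
#'   chain lengths in bases).
#' @return an object of class `gfab_chains`: a list of chains, each of class
#'   `gfab_chain` with fields `id`, `bubble_idx` (indices into
#'   `bubbles$bubbles`, in chain order), `ends` (the two outermost endpoint
#'   node ids), `length_in_bubbles`, and `length_in_bases` (sum of each
#'   bubble's longest source-to-sink walk, shared endpoints counted once,
#'   overlaps subtracted).
#' @export
bubble_chains <- function(bubbles, graph) {
  stopifnot(inherits(bubbles, "gfab_bubbles"), inherits(graph, "bdgraph"))
  bl <- bubbles$bubbles
  top <- which(vapply(bl, function(b) is.na(b$parent), logical(1)))
  if (!length(top)) {
    return(structure(list(), class = "gfab_chains"))
  }
  eps <- lapply(bl[top], function(b) c(b$source$node, b$sink$node))
  inc <- split(rep(seq_along(top), each = 2L), unlist(eps))  # node -> positions in `top`
  # endpoint nodes shared by exactly two bubbles link them; >= 3 breaks
  nbr <- lapply(seq_along(top), function(i) integer(0))
  for (node in names(inc)) {
    members <- inc[[node]]
    if (length(members) == 2L && members[1] != members[2]) {
      nbr[[members[1]]] <- c(nbr[[members[1]]], members[2])
      nbr[[members[2]]] <- c(nbr[[members[2]]], members[1])
    }
  }
  nbr <- lapply(nbr, unique)
  deg <- lengths(nbr)
  assigned <- logical(length(top))
  chains_raw <- list()

  walk_from <- function(start) {
    path <- start
    assigned[start] <<- TRUE
    repeat {
      nxt <- setdiff(nbr[[path[length(path)]]], path)
      nxt <- nxt[!assigned[nxt]]
      if (!length(nxt)) break
      assigned[nxt[1]] <<- TRUE
      path <- c(path, nxt[1])
    }
    path
  }

  # open paths first (bubbles of degree <= 1), then any remaining cycles,
  # broken at the bubble with the lexicographically smallest endpoint
  order_hint <- order(vapply(eps, min, ""))
  for (i in order_hint) {
    if (assigned[i] || deg[i] > 1L) next
    chains_raw[[length(chains_raw) + 1]] <- walk_from(i)
  }
  for (i in order_hint) {
    if (assigned[i]) next
    chains_raw[[length(chains_raw) + 1]] <- walk_from(i)
  }

  chains <- lapply(chains_raw, function(path) {
    bidx <- top[path]
    m <- length(bidx)
    # endpoint node sequence along the chain
    if (m == 1L) {
      b <- bl[[bidx]]
      nodes_seq <- sort(c(b$source$node, b$sink$node))
    } else {
      nodes_seq <- character(m + 1L)
      for (j in seq_len(m)) {
        ej <- c(bl[[bidx[j]]]$source$node, bl[[bidx[j]]]$sink$node)
        if (j == 1L) {
          shared <- intersect(ej, c(bl[[bidx[2]]]$source$node, bl[[bidx[2]]]$sink$node))
          outer <- setdiff(ej, shared)
          # a 2-bubble cycle shares both endpoints; pick deterministically
          nodes_seq[1] <- if (length(outer)) outer[1] else min(ej)
          nodes_seq[2] <- setdiff(ej, nodes_seq[1])[1]
        } else {
          nodes_seq[j + 1L] <- if (ej[1] == nodes_seq[j]) ej[2] else ej[1]
        }
      }
    }
    # orient the chain from its smaller outer endpoint
    if (nodes_seq[1] > nodes_seq[length(nodes_seq)]) {
      nodes_seq <- rev(nodes_seq)
      bidx <- rev(bidx)
    }
    spans <- vapply(bidx, function(j) bubble_span_bases(graph, bl[[j]]), integer(1))
    internal <- nodes_seq[-c(1L, length(nodes_seq))]
    bases <- sum(spans) - sum(graph$len[internal])
    structure(list(
      id = NA_integer_,
      bubble_idx = bidx,
      ends = c(nodes_seq[1], nodes_seq[length(nodes_seq)]),
      length_in_bubbles = m,
      length_in_bases = as.integer(bases)
    ), class = "gfab_chain")
  })
  starts <- vapply(chains, function(ch) ch$ends[1], "")
  seconds <- vapply(chains, function(ch) ch$ends[2], "")
  chains <- chains[order(starts, seconds)]
  for (i in seq_along(chains)) chains[[i]]$id <- i
  structure(chains, class = "gfab_chains")
}

#' @export
print.gfab_chains <- function(x, ...) {
  if (!length(x)) {
    cat("bubble chains: none\n")
    return(invisible(x))
  }
  nb <- vapply(x, `[[`, integer(1), "length_in_bubbles")
  cat(sprintf("bubble chains: %d chain(s), %d bubble(s) total, longest chain %d bubble(s)\n",
              length(x), sum(nb), max(nb)))
  invisible(x)
}

# merged unitig ids concatenate their member ids; abbreviate for display
abbrev_id <- function(id, max = 24L) {
  ifelse(nchar(id) > max,
         sprintf("%s..[%d more]", substr(id, 1, max),
                 lengths(regmatches(id, gregexpr("_", id, fixed = TRUE)))),
         id)
}

#' @export
print.gfab_chain <- function(x, ...) {
  cat(sprintf("chain %s: %s .. %s | %d bubble(s), %d bases\n",
              ifelse(is.na(x$id), "?", x$id),
              abbrev_id(x$ends[1]), abbrev_id(x$ends[2]),
              x$length_in_bubbles, x$length_in_bases))
  invisible(x)
}
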