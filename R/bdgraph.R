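#' Construct a bidirected sequence graph
#'
#' A bidirected graph models sequences as nodes with a left (`"L"`) and right
#' (`"R"`) side; every edge joins a specific side of one node to a specific
#' side of another, which encodes the relative orientation of the two
#' sequences. Edges may be blunt (overlap 0) or carry an exact overlap in
#' bases, as in a de Bruijn graph where consecutive k-mers overlap by k-1.
#'
#' Edges are stored symmetrically: an edge is discoverable from both of its
#' incident node ends, and each undirected edge is kept once in canonical
#' order. Duplicate edges (including the reverse statement of the same link)
#' are dropped with a warning. Self-loops are stored but flagged; they never
#' participate in compaction or bubble interiors.
#'
#' @param nodes data.frame with columns `id` (unique character) and `seq`
#'   (DNA string, may be `NA` for length-only graphs) and/or `len`
#'   (sequence length in bases). When `seq` is given, `len` defaults to
#'   `nchar(seq)`.
#' @param edges data.frame with columns `from`, `from_side`, `to`, `to_side`,
#'   `overlap`, or `NULL` for an edgeless graph. Sides are `"L"`/`"R"`.
#' @param k optional k-mer size hint carried along with the graph.
#' @return an object of class `bdgraph`.
#' @examples
#' g <- bdgraph(
#'   nodes = data.frame(id = c("A", "B"), seq = c("ACGT", "CGTA")),
#'   edges = data.frame(from = "A", from_side = "R",
#'                      to = "B", to_side = "L", overlap = 3)
#' )
#' bdg_neighbors(g, "A", "R")
#' @export
bdgraph <- function(nodes, edges = NULL, k = NULL) {
  stopifnot(is.data.frame(nodes))
  ids <- as.character(nodes$id)
  if (length(ids) == 0) {
    return(new_bdgraph_internal(character(), character(), integer(),
                                empty_edges(), k))
  }
  if (anyDuplicated(ids)) stop_input("duplicate node ids in graph construction")
  seqs <- if ("seq" %in% names(nodes)) as.character(nodes$seq) else rep(NA_character_, length(ids))
  lens <- if ("len" %in% names(nodes)) as.integer(nodes$len) else rep(NA_integer_, length(ids))
  lens[is.na(lens) & !is.na(seqs)] <- nchar(seqs[is.na(lens) & !is.na(seqs)])
  if (any(is.na(lens))) {
    stop_input(sprintf("node '%s' has neither sequence nor length",
                       ids[which(is.na(lens))[1]]))
  }
  bad <- !is.na(seqs) & nchar(seqs) != lens
  if (any(bad)) stop_input(sprintf("node '%s': seq_length does not match sequence", ids[bad][1]))

  ed <- normalize_edges(edges, ids, lens)
  new_bdgraph_internal(ids, seqs, lens, ed, k)
}

empty_edges <- function() {
  data.frame(from = character(), from_side = character(),
             to = character(), to_side = character(),
             overlap = integer(), stringsAsFactors = FALSE)
}

# Canonicalize, validate and deduplicate an edge table.
normalize_edges <- function(edges, ids, lens) {
  if (is.null(edges) || nrow(edges) == 0) return(empty_edges())
  ed <- data.frame(from = as.character(edges$from),
                   from_side = as.character(edges$from_side),
                   to = as.character(edges$to),
                   to_side = as.character(edges$to_side),
                   overlap = as.integer(edges$overlap),
                   stringsAsFactors = FALSE)
  if (!all(ed$from_side %in% c("L", "R")) || !all(ed$to_side %in% c("L", "R")))
    stop_input("edge sides must be 'L' or 'R'")
  miss <- setdiff(c(ed$from, ed$to), ids)
  if (length(miss))
    stop_input(sprintf("edge references unknown node '%s'", miss[1]))
  if (any(ed$overlap < 0)) stop_input("negative edge overlap")
  names(lens) <- ids
  too_big <- ed$overlap >= lens[ed$from] | ed$overlap >= lens[ed$to]
  if (any(too_big)) {
    i <- which(too_big)[1]
    stop_input(sprintf("overlap %d on edge %s.%s-%s.%s is not smaller than both node lengths",
                       ed$overlap[i], ed$from[i], ed$from_side[i], ed$to[i], ed$to_side[i]))
  }
  # canonical order of the two ends
  a <- end_key(ed$from, ed$from_side)
  b <- end_key(ed$to, ed$to_side)
  swap <- a > b
  if (any(swap)) {
    tmp <- ed[swap, c("from", "from_side")]
    ed[swap, c("from", "from_side")] <- ed[swap, c("to", "to_side")]
    ed[swap, c("to", "to_side")] <- tmp
  }
  key <- paste(end_key(ed$from, ed$from_side), end_key(ed$to, ed$to_side), sep = "\t")
  if (anyDuplicated(key)) {
    first <- !duplicated(key)
    conflicting <- vapply(split(ed$overlap, key), function(o) length(unique(o)) > 1, logical(1))
    if (any(conflicting))
      stop_input("duplicate edges with conflicting overlaps")
    warning(sprintf("dropped %d duplicate link(s)", sum(!first)), call. = FALSE)
    ed <- ed[first, , drop = FALSE]
    key <- key[first]
  }
  if (any(ed$from == ed$to))
    warning("graph contains self-loop(s); they are excluded from compaction and bubble interiors",
            call. = FALSE)
  ed[order(ed$from, ed$from_side, ed$to, ed$to_side), , drop = FALSE]
}

new_bdgraph_internal <- function(ids, seqs, lens, edges, k) {
  o <- order(ids)
  ids <- ids[o]
  seqs <- seqs[o]
  lens <- lens[o]
  names(seqs) <- ids
  names(lens) <- ids
  rownames(edges) <- NULL
  structure(list(
    ids = ids,
    seq = seqs,
    len = lens,
    edges = edges,
    adj = build_adjacency(edges),
    selfloops = unique(edges$from[edges$from == edges$to]),
    k = k
  ), class = "bdgraph")
}

# adjacency: named list keyed by "<id>\t<side>"; each element has parallel
# vectors node / side / overlap, sorted for determinism.
build_adjacency <- function(edges) {
  if (nrow(edges) == 0) return(list())
  k1 <- c(end_key(edges$from, edges$from_side), end_key(edges$to, edges$to_side))
  pn <- c(edges$to, edges$from)
  ps <- c(edges$to_side, edges$from_side)
  ov <- c(edges$overlap, edges$overlap)
  # a same-end self-loop duplicates its own entry; keep one copy
  rowkey <- paste(k1, pn, ps, sep = "\t")
  keep <- !duplicated(rowkey)
  k1 <- k1[keep]; pn <- pn[keep]; ps <- ps[keep]; ov <- ov[keep]
  idx <- split(seq_along(k1), k1)
  lapply(idx, function(i) {
    i <- i[order(pn[i], ps[i])]
    list(node = pn[i], side = ps[i], overlap = ov[i])
  })
}

adj_at <- function(g, node, side) {
  g$adj[[end_key(node, side)]] %||% list(node = character(), side = character(), overlap = integer())
}

#' Neighboring node ends of an oriented node end
#'
#' Returns the ends adjacent to `(node, side)`. Traversal through a
#' bidirected graph that reaches a neighbor at one of its sides continues
#' out of the opposite side of that neighbor.
#'
#' @param graph a [bdgraph] object.
#' @param node node id.
#' @param side `"L"` or `"R"`.
#' @return data.frame with columns `node`, `side`, `overlap` — one row per
#'   adjacent end.
#' @export
bdg_neighbors <- function(graph, node, side) {
  stopifnot(inherits(graph, "bdgraph"))
  side <- match.arg(side, c("L", "R"))
  if (!node %in% graph$ids) stop_lookup(sprintf("unknown node '%s'", node))
  a <- adj_at(graph, node, side)
  data.frame(node = a$node, side = a$side, overlap = a$overlap,
             stringsAsFactors = FALSE)
}

has_edge <- function(g, e1, e2) {
  # e1, e2: list(node=, side=)
  a <- adj_at(g, e1$node, e1$side)
  any(a$node == e2$node & a$side == e2$side)
}

#' Number of nodes in a bidirected graph
#' @param graph a [bdgraph] object.
#' @return integer node count.
#' @export
bdg_size <- function(graph) length(graph$ids)

#' Node ids of a bidirected graph
#' @param graph a [bdgraph] object.
#' @return character vector of node ids (sorted).
#' @export
bdg_node_ids <- function(graph) graph$ids

#' Induced subgraph on a node set
#'
#' Keeps the given nodes and every edge whose two endpoints both survive.
#'
#' @param graph a [bdgraph] object.
#' @param ids character vector of node ids to keep.
#' @return a [bdgraph] object.
#' @export
bdg_subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "bdgraph"))
  miss <- setdiff(ids, graph$ids)
  if (length(miss)) stop_lookup(sprintf("unknown node '%s'", miss[1]))
  ids <- unique(ids)
  ed <- graph$edges
  ed <- ed[ed$from %in% ids & ed$to %in% ids, , drop = FALSE]
  new_bdgraph_internal(ids, graph$seq[ids], graph$len[ids], ed, graph$k)
}

#' Check the structural invariants of a bidirected graph
#'
#' Verifies referential integrity, adjacency symmetry (every edge is
#' discoverable from both of its ends with the same overlap), absence of
#' duplicate adjacency entries, and length/sequence agreement. Intended for
#' tests and defensive checks after graph surgery.
#'
#' @param graph a [bdgraph] object.
#' @return `TRUE`, invisibly; otherwise an error describing the violation.
#' @export
validate_bdgraph <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  ed <- graph$edges
  if (nrow(ed)) {
    if (!all(c(ed$from, ed$to) %in% graph$ids))
      stop("adjacency references a missing node")
  }
  ok_len <- is.na(graph$seq) | nchar(graph$seq) == graph$len
  if (!all(ok_len)) stop("sequence/length mismatch")
  # symmetry: rebuild adjacency from the edge table and compare
  if (!identical(build_adjacency(ed), graph$adj))
    stop("adjacency index out of sync with edge table")
  for (key in names(graph$adj)) {
    a <- graph$adj[[key]]
    if (anyDuplicated(paste(a$node, a$side))) stop("duplicate adjacency entries")
    parts <- strsplit(key, "\t", fixed = TRUE)[[1]]
    for (i in seq_along(a$node)) {
      back <- adj_at(graph, a$node[i], a$side[i])
      j <- which(back$node == parts[1] & back$side == parts[2])
      if (length(j) != 1 || back$overlap[j] != a$overlap[i])
        stop("asymmetric edge detected")
    }
  }
  invisible(TRUE)
}

#' @export
print.bdgraph <- function(x, ...) {
  mode <- if (all(is.na(x$seq)) && length(x$ids)) "length-only" else "sequence"
  cat(sprintf("bidirected genome graph: %d nodes, %d edges (%s%s)\n",
              length(x$ids), nrow(x$edges), mode,
              if (!is.null(x$k)) sprintf(", k = %d", x$k) else ""))
  invisible(x)
}

#' @export
summary.bdgraph <- function(object, ...) {
  deg <- lengths(lapply(object$adj, `[[`, "node"))
  cat(sprintf("nodes: %d\nedges: %d\ntotal bases: %s\nmax end degree: %d\nself-loops: %d\n",
              length(object$ids), nrow(object$edges),
              format(sum(as.numeric(object$len))),
              if (length(deg)) max(deg) else 0L,
              length(object$selfloops)))
  invisible(object)
}
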