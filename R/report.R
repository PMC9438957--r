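# recursive JSON-ready description of one bubble and the bubbles nested in it
bubble_entry <- function(i, bl, children_of) {
  b <- bl[[i]]
  list(
    source = b$source$node,
    sink = b$sink$node,
    type = b$type,
    interior = I(as.list(b$interior)),
    nested = lapply(children_of[[i]], bubble_entry, bl = bl, children_of = children_of)
  )
}

#' Build a detection report from bubbles and chains
#'
#' Summarizes a bubble/chain detection run into a JSON-serializable
#' structure: the chains with their bubbles (nested bubbles reported inside
#' their enclosing superbubble, never as separate chain members), the count
#' summary, and a per-node chain assignment usable as GFA `BC:i:` tags
#' (nodes outside every chain get chain 0).
#'
#' Counts include every detected bubble at any nesting level;
#' `nested_simple_bubbles` additionally reports how many of the simple
#' bubbles sit inside a superbubble.
#'
#' @param graph the [bdgraph] that was analyzed.
#' @param bubbles a `gfab_bubbles` object from [detect_bubbles()].
#' @param chains a `gfab_chains` object from [bubble_chains()].
#' @return an object of class `gfab_report` with elements `chains`, `counts`
#'   and `node_chain` (named integer vector).
#' @export
detection_report <- function(graph, bubbles, chains) {
  stopifnot(inherits(graph, "bdgraph"), inherits(bubbles, "gfab_bubbles"),
            inherits(chains, "gfab_chains"))
  bl <- bubbles$bubbles
  parents <- vapply(bl, `[[`, NA_integer_, "parent")
  children_of <- lapply(seq_along(bl), function(i) which(parents == i))
  tys <- vapply(bl, `[[`, "", "type")
  nb <- vapply(chains, `[[`, integer(1), "length_in_bubbles")

  chains_json <- lapply(chains, function(ch) {
    list(
      id = ch$id,
      ends = I(as.list(ch$ends)),
      length_in_bubbles = ch$length_in_bubbles,
      length_in_bases = ch$length_in_bases,
      bubbles = lapply(ch$bubble_idx, bubble_entry, bl = bl, children_of = children_of)
    )
  })

  counts <- list(
    simple_bubbles = sum(tys == "simple"),
    superbubbles = sum(tys == "super"),
    insertion_bubbles = sum(tys == "insertion"),
    nested_simple_bubbles = sum(tys == "simple" & !is.na(parents)),
    chains = length(chains),
    longest_chain_in_bubbles = if (length(nb)) max(nb) else 0L
  )

  node_chain <- stats::setNames(rep(0L, length(graph$ids)), graph$ids)
  for (ch in chains) {
    members <- unique(unlist(lapply(ch$bubble_idx, function(i) {
      b <- bl[[i]]
      c(b$source$node, b$sink$node, b$interior)
    })))
    node_chain[members] <- ch$id
  }

  structure(list(chains = chains_json, counts = counts, node_chain = node_chain),
            class = "gfab_report")
}

#' Write a detection report as JSON
#'
#' Serialization is deterministic: keys are emitted in a fixed order and the
#' report carries no timestamps, so identical inputs produce byte-identical
#' files.
#'
#' @param report a `gfab_report` from [detection_report()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "gfab_report"))
  payload <- list(chains = report$chains, counts = report$counts)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Per-node GFA chain tags from a report
#'
#' @param report a `gfab_report` from [detection_report()].
#' @return named list mapping each node id to a `BC:i:<chain>` tag, suitable
#'   for the `tags` argument of [write_gfa()].
#' @export
chain_tags <- function(report) {
  stopifnot(inherits(report, "gfab_report"))
  as.list(stats::setNames(sprintf("BC:i:%d", report$node_chain),
                          names(report$node_chain)))
}

#' @export
print.gfab_report <- function(x, ...) {
  cat("bubble detection report\n")
  for (nm in names(x$counts)) cat(sprintf("  %s: %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
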