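# graph builders shared across test files --------------------------------

# edges given as strings "from fside to tside overlap"
g_from <- function(ids, edges = character(), seqs = NULL) {
  if (is.null(seqs)) seqs <- strrep("ACGTAC", 1)[rep(1, length(ids))]
  ed <- NULL
  if (length(edges)) {
    parts <- do.call(rbind, strsplit(edges, " ", fixed = TRUE))
    ed <- data.frame(from = parts[, 1], from_side = parts[, 2],
                     to = parts[, 3], to_side = parts[, 4],
                     overlap = as.integer(parts[, 5]),
                     stringsAsFactors = FALSE)
  }
  suppressWarnings(bdgraph(data.frame(id = ids, seq = seqs,
                                      stringsAsFactors = FALSE), ed))
}

diamond_graph <- function() {
  g_from(c("s", "a", "b", "t"),
         c("s R a L 0", "s R b L 0", "a R t L 0", "b R t L 0"))
}

# superbubble with a nested simple bubble:
# s->{a,b}; b->t; a->{c,d}; c->e; d->e; e->t
nested_graph <- function() {
  g_from(c("s", "a", "b", "c", "d", "e", "t"),
         c("s R a L 0", "s R b L 0", "b R t L 0", "a R c L 0", "a R d L 0",
           "c R e L 0", "d R e L 0", "e R t L 0"))
}

# bubble chain as in the k = 9 figure construction: one simple bubble
# (x..y) followed by a superbubble (y..t) with a nested simple bubble
fig_chain_graph <- function() {
  g_from(c("x", "p", "q", "y", "a", "b", "c", "d", "e", "t"),
         c("x R p L 0", "x R q L 0", "p R y L 0", "q R y L 0",
           "y R a L 0", "y R b L 0", "b R t L 0", "a R c L 0", "a R d L 0",
           "c R e L 0", "d R e L 0", "e R t L 0"))
}

path_graph <- function(ids) {
  n <- length(ids)
  g_from(ids, if (n > 1) sprintf("%s R %s L 0", ids[-n], ids[-1]) else character())
}

# de Bruijn graph of the k-mers of one string
kmer_chain_graph <- function(s, k) {
  km <- substring(s, 1:(nchar(s) - k + 1), k:nchar(s))
  ids <- sprintf("x%03d", seq_along(km))
  suppressWarnings(bdgraph(
    data.frame(id = ids, seq = km, stringsAsFactors = FALSE),
    if (length(ids) > 1)
      data.frame(from = ids[-length(ids)], from_side = "R",
                 to = ids[-1], to_side = "L", overlap = k - 1L,
                 stringsAsFactors = FALSE)))
}

graphs_identical <- function(g1, g2) {
  identical(g1$ids, g2$ids) &&
    identical(g1$seq, g2$seq) &&
    identical(g1$len, g2$len) &&
    identical(g1$edges, g2$edges)
}

flip_sides_graph <- function(g) {
  ed <- g$edges
  ed$from_side <- ifelse(ed$from_side == "L", "R", "L")
  ed$to_side <- ifelse(ed$to_side == "L", "R", "L")
  suppressWarnings(bdgraph(data.frame(id = g$ids, seq = unname(g$seq),
                                      len = unname(g$len),
                                      stringsAsFactors = FALSE), ed, k = g$k))
}

flip_bubble_keys <- function(keys) {
  x <- gsub(".L", ".#", keys, fixed = TRUE)
  x <- gsub(".R", ".L", x, fixed = TRUE)
  sort(gsub(".#", ".R", x, fixed = TRUE))
}

bubble_types <- function(bset) vapply(bset$bubbles, `[[`, "", "type")

write_tmp_gfa <- function(lines) {
  f <- tempfile(fileext = ".gfa")
  writeLines(lines, f)
  f
}
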