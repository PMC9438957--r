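# Random DNA string of length L in which every k-mer is unique, built by a
# restarted random walk: at each step, a base is accepted only if the k-mer
# it completes has not been used. Uniqueness prevents collapsed repeats from
# confounding the planted-bubble ground truth.
gen_unique_kmer_seq <- function(L, k, max_restarts = 50L) {
  bases <- c("A", "C", "G", "T")
  for (attempt in seq_len(max_restarts)) {
    chars <- character(L)
    used <- new.env(parent = emptyenv())
    ok <- TRUE
    i <- 1L
    while (i <= L) {
      cand <- sample(bases)
      placed <- FALSE
      for (b in cand) {
        if (i < k) {
          chars[i] <- b
          placed <- TRUE
          break
        }
        km <- paste(c(chars[(i - k + 1L):(i - 1L)], b), collapse = "")
        if (!exists(km, envir = used, inherits = FALSE)) {
          assign(km, TRUE, used)
          chars[i] <- b
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
      i <- i + 1L
    }
    if (ok) return(paste(chars, collapse = ""))
  }
  stop_input(sprintf("could not generate a repeat-free sequence of length %d for k = %d", L, k))
}

kmers_of <- function(s, k) {
  n <- nchar(s)
  substring(s, 1:(n - k + 1L), k:n)
}

substitute_base <- function(s, pos, base) {
  substr(s, pos, pos) <- base
  s
}

random_alt <- function(ref) sample(setdiff(c("A", "C", "G", "T"), ref), 1L)

#' Generate a planted-variant diploid de Bruijn graph with known truth
#'
#' Emulates the construction of a de Bruijn graph from the two haplotypes of
#' a diploid sample: a random repeat-free sequence is copied and `n_snps`
#' heterozygous substitutions are planted at positions at least
#' `min_spacing` apart (and at least `k + 1`, so that a homozygous anchor
#' k-mer separates consecutive variant loci and every isolated SNP yields
#' exactly one simple bubble with two branch nodes of length `2k - 1`).
#' Optionally, `n_clusters` clusters of two SNPs closer than `k` are planted;
#' each cluster is additionally covered by a third, recombinant sequence copy
#' carrying only the first SNP of the pair (multi-sample construction), which
#' makes the cluster locus a genuine superbubble with more than two paths
#' instead of one long two-branch bubble.
#'
#' All k-mers of each generated sequence occur at a single position, so the
#' graph is exactly the "aligned columns" graph of the planted variants and
#' the returned truth is guaranteed by construction.
#'
#' @param seq_length length of the haplotype sequence in bases.
#' @param k k-mer size.
#' @param n_snps number of isolated heterozygous SNPs.
#' @param min_spacing minimum distance in bases between consecutive variant
#'   loci; must be greater than `k`.
#' @param n_clusters number of two-SNP clusters (superbubble loci).
#' @param cluster_gap distance between the two SNPs of a cluster; must be
#'   smaller than `k`.
#' @param seed integer seed; the fixture is deterministic given the seed.
#' @param compacted return the compacted graph (default) or the raw k-mer
#'   graph.
#' @return list with elements `graph` (a [bdgraph]) and `truth` (list with
#'   `n_simple`, `n_super`, `snp_positions`, `cluster_positions`,
#'   `sequence` — the reference haplotype).
#' @export
make_diploid_graph <- function(seq_length = 1000L, k = 9L, n_snps = 5L,
                               min_spacing = 3L * k, n_clusters = 0L,
                               cluster_gap = max(2L, k %/% 2L), seed = 1L,
                               compacted = TRUE) {
  stopifnot(k >= 3L, n_snps >= 0L, n_clusters >= 0L)
  if (min_spacing <= k)
    stop_input("min_spacing must exceed k: loci closer than k+1 share no anchor k-mer and fuse")
  if (n_clusters > 0L && cluster_gap >= k)
    stop_input("cluster_gap must be smaller than k to form a superbubble locus")
  margin <- k + 1L
  nloci <- n_snps + n_clusters
  widths <- c(rep(0L, n_snps), rep(cluster_gap, n_clusters))
  need <- 2L * margin + sum(widths) + if (nloci > 1L) (nloci - 1L) * min_spacing else 0L
  if (nloci > 0L && need > seq_length)
    stop_input(sprintf("seq_length %d too short for %d loci with spacing %d (need >= %d)",
                       seq_length, nloci, min_spacing, need))

  with_seed(seed, {
    for (attempt in 1:50) {
      hap1 <- gen_unique_kmer_seq(seq_length, k)
      # lay the loci out left to right with random slack in the gaps
      is_cluster <- sample(rep(c(FALSE, TRUE), c(n_snps, n_clusters)))
      widths_o <- ifelse(is_cluster, cluster_gap, 0L)
      slack <- seq_length - need
      cuts <- if (nloci > 0L) sort(sample.int(slack + 1L, nloci, replace = TRUE) - 1L) else integer(0)
      pos1 <- integer(nloci)
      at <- margin
      for (j in seq_len(nloci)) {
        at <- at + cuts[j] - (if (j > 1L) cuts[j - 1L] else 0L) +
          (if (j > 1L) min_spacing + widths_o[j - 1L] else 0L)
        pos1[j] <- at
      }
      snp_pos <- pos1[!is_cluster]
      cl_pos <- pos1[is_cluster]

      hap2 <- hap1
      alleles <- character(0)
      for (p in c(snp_pos, cl_pos, cl_pos + cluster_gap)) {
        hap2 <- substitute_base(hap2, p, random_alt(substr(hap1, p, p)))
      }
      seqs <- list(hap1, hap2)
      # recombinant copy per cluster: alt at the first cluster SNP only
      if (n_clusters > 0L) {
        hap3 <- hap1
        for (p in cl_pos) {
          hap3 <- substitute_base(hap3, p, substr(hap2, p, p))
        }
        seqs <- c(seqs, list(hap3))
      }

      # the aligned-columns guarantee: every k-mer maps to one position only
      km <- lapply(seqs, kmers_of, k = k)
      pos_map <- split(rep(seq_len(seq_length - k + 1L), length(seqs)), unlist(km))
      if (all(vapply(pos_map, function(p) length(unique(p)) == 1L, logical(1)))) {
        g <- kmer_graph(seqs, k)
        if (compacted) g <- bdg_compact(g)
        return(list(
          graph = g,
          truth = list(n_simple = n_snps, n_super = n_clusters,
                       snp_positions = sort(snp_pos),
                       cluster_positions = sort(cl_pos),
                       cluster_gap = cluster_gap,
                       k = k, sequence = hap1)
        ))
      }
    }
    stop_input("failed to plant variants without k-mer collisions; increase k or seq_length")
  })
}

# de Bruijn graph over the union of the k-mers of several sequences; nodes
# are deduplicated k-mers, edges join consecutive k-mers with overlap k-1.
kmer_graph <- function(seqs, k) {
  km <- lapply(seqs, kmers_of, k = k)
  all_km <- unique(unlist(km))
  ids <- sprintf("n%0*d", nchar(length(all_km)), seq_along(all_km))
  names(ids) <- all_km
  edges <- do.call(rbind, lapply(km, function(x) {
    if (length(x) < 2L) return(NULL)
    data.frame(from = ids[x[-length(x)]], from_side = "R",
               to = ids[x[-1L]], to_side = "L",
               overlap = k - 1L, stringsAsFactors = FALSE)
  }))
  suppressWarnings(bdgraph(
    data.frame(id = unname(ids), seq = all_km, stringsAsFactors = FALSE),
    edges, k = k))
}

#' Generate a random bidirected graph
#'
#' Samples side-to-side edges independently over all pairs of node ends,
#' with random short sequences and random small overlaps (blunt and overlap
#' edges mixed). Intended as input for the exhaustive oracle, so keep
#' `n_nodes` small.
#'
#' @param n_nodes number of nodes (<= 15 recommended for oracle feasibility).
#' @param edge_prob probability of including each possible end-to-end edge.
#' @param seed integer seed; the graph is deterministic given the seed.
#' @param allow_self_loops include self-loop candidates.
#' @param max_overlap overlaps are drawn uniformly from `0:max_overlap`.
#' @return a [bdgraph] object.
#' @export
make_random_graph <- function(n_nodes, edge_prob, seed = 1L,
                              allow_self_loops = FALSE, max_overlap = 2L) {
  stopifnot(n_nodes >= 1L, edge_prob >= 0, edge_prob <= 1)
  with_seed(seed, {
    ids <- sprintf("n%02d", seq_len(n_nodes))
    lens <- sample(6:12, n_nodes, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    ends <- data.frame(node = rep(ids, each = 2L),
                       side = rep(c("L", "R"), n_nodes),
                       stringsAsFactors = FALSE)
    ne <- nrow(ends)
    cand <- NULL
    if (ne >= 2L) {
      ij <- utils::combn(ne, 2L)
      keep <- ends$node[ij[1, ]] != ends$node[ij[2, ]] | allow_self_loops
      ij <- ij[, keep, drop = FALSE]
      take <- stats::runif(ncol(ij)) < edge_prob
      ij <- ij[, take, drop = FALSE]
      if (ncol(ij)) {
        cand <- data.frame(
          from = ends$node[ij[1, ]], from_side = ends$side[ij[1, ]],
          to = ends$node[ij[2, ]], to_side = ends$side[ij[2, ]],
          overlap = sample(0:max_overlap, ncol(ij), replace = TRUE),
          stringsAsFactors = FALSE)
      }
    }
    suppressWarnings(
      bdgraph(data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE), cand))
  })
}

# ---------------------------------------------------------------------------
# Brute-force definitional oracle
# ---------------------------------------------------------------------------

reach_from <- function(adjlist, start, stop_at) {
  seen <- logical(length(adjlist))
  seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[length(queue)]
    queue <- queue[-length(queue)]
    if (v == stop_at) next
    for (u in adjlist[[v]]) {
      if (!seen[u]) {
        seen[u] <- TRUE
        queue <- c(queue, u)
      }
    }
  }
  seen
}

acyclic_induced <- function(children, members) {
  # Kahn's algorithm on the induced directed subgraph
  mem <- which(members)
  if (!length(mem)) return(TRUE)
  indeg <- stats::setNames(integer(length(mem)), mem)
  adj <- lapply(mem, function(v) {
    ch <- children[[v]]
    ch[members[ch]]
  })
  names(adj) <- as.character(mem)
  for (v in mem) for (u in adj[[as.character(v)]])
    indeg[as.character(u)] <- indeg[as.character(u)] + 1L
  queue <- mem[indeg[as.character(mem)] == 0L]
  removed <- 0L
  while (length(queue)) {
    v <- queue[length(queue)]
    queue <- queue[-length(queue)]
    removed <- removed + 1L
    for (u in adj[[as.character(v)]]) {
      indeg[as.character(u)] <- indeg[as.character(u)] - 1L
      if (indeg[as.character(u)] == 0L) queue <- c(queue, u)
    }
  }
  removed == length(mem)
}

#' Exhaustive definitional superbubble enumeration (oracle)
#'
#' Checks every ordered pair of oriented node ends `(s, t)` directly against
#' the superbubble definition: the set of oriented nodes reachable from `s`
#' (stopping at `t`) must equal the set of oriented nodes from which `t` is
#' reachable (stopping at `s`); the induced directed subgraph must be acyclic
#' and contain no node in both orientations; and no other node inside the
#' subgraph may satisfy the same conditions with `s` or with `t`
#' (minimality). Pairs with an empty interior participate in the minimality
#' filter but are not reported.
#'
#' This is quadratic-and-worse in graph size and exists purely as an
#' independent correctness anchor for [detect_bubbles()]; use it only on
#' small graphs.
#'
#' @param graph a small [bdgraph] object (<= 15 nodes recommended).
#' @return a `gfab_bubbles` object in the same canonical form as
#'   [detect_bubbles()] (parents are not assigned).
#' @export
oracle_superbubbles <- function(graph) {
  stopifnot(inherits(graph, "bdgraph"))
  idx <- doubled_index(graph)
  nE <- idx$nE
  if (nE == 0L) return(structure(list(bubbles = list(), n_nodes = 0L),
                                 class = "gfab_bubbles"))
  closure <- lapply(seq_len(nE), function(s) reach_from(idx$children, s, 0L))
  cand <- list()
  for (s in seq_len(nE)) {
    for (t in seq_len(nE)) {
      if (idx$node_of[s] == idx$node_of[t]) next
      if (!closure[[s]][t]) next
      U <- reach_from(idx$children, s, t)
      # no node in both orientations
      if (any(U & U[flip_vertex(seq_len(nE))])) next
      W <- reach_from(idx$parents, t, s)
      if (!identical(U, W)) next
      if (!acyclic_induced(idx$children, U)) next
      cand[[length(cand) + 1]] <- list(s = s, t = t, U = U)
    }
  }
  if (!length(cand)) return(structure(list(bubbles = list(), n_nodes = idx$n),
                                      class = "gfab_bubbles"))
  # minimality: drop (s,t) if some other valid pair shares s with its sink
  # inside U, or shares t with its source inside U
  keep <- vapply(seq_along(cand), function(i) {
    ci <- cand[[i]]
    for (j in seq_along(cand)) {
      if (j == i) next
      cj <- cand[[j]]
      if (cj$s == ci$s && cj$t != ci$t && ci$U[cj$t]) return(FALSE)
      if (cj$t == ci$t && cj$s != ci$s && ci$U[cj$s]) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- cand[keep]
  cand <- Filter(function(c) sum(c$U) > 2L, cand)  # non-empty interior only

  keys <- character(); out <- list()
  for (c in cand) {
    ce <- canonical_ends(source_end_of(idx, c$s), sink_end_of(idx, c$t))
    key <- paste(ce$source$node, ce$source$side, ce$sink$node, ce$sink$side)
    if (key %in% keys) next
    keys <- c(keys, key)
    interior <- sort(setdiff(idx$ids[unique(idx$node_of[which(c$U)])],
                             c(ce$source$node, ce$sink$node)))
    out[[length(out) + 1]] <- structure(list(
      source = ce$source, sink = ce$sink, interior = interior,
      type = bubble_type_of(graph, ce$source, ce$sink, interior),
      parent = NA_integer_
    ), class = "gfab_bubble")
  }
  o <- order(keys)
  structure(list(bubbles = out[o], n_nodes = idx$n), class = "gfab_bubbles")
}

#' Canonical comparison keys for a bubble set
#'
#' One string per bubble (`source -- sink | interior`), sorted; two bubble
#' sets are equal iff their key vectors are identical. Used to compare
#' [detect_bubbles()] with [oracle_superbubbles()].
#'
#' @param bubbles a `gfab_bubbles` object.
#' @return sorted character vector.
#' @export
bubble_keys <- function(bubbles) {
  stopifnot(inherits(bubbles, "gfab_bubbles"))
  sort(vapply(bubbles$bubbles, function(b) {
    paste0(b$source$node, ".", b$source$side, "--", b$sink$node, ".", b$sink$side,
           "|", paste(b$interior, collapse = ","))
  }, character(1)))
}
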