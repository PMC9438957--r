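#' Read a GFA1 file into a bidirected graph
#'
#' Parses S (segment) and L (link) records of a GFA1 file. An L line
#' `L u ou v ov cigar` is mapped onto node sides using standard GFA1
#' orientation semantics: `ou = "+"` means the link leaves the right side of
#' `u`, `ou = "-"` its left side; `ov = "+"` means the link enters the left
#' side of `v`, `ov = "-"` its right side. Only overlap CIGARs of the form
#' `<int>M` (exact match, as produced by de Bruijn graph builders) or `*`
#' (treated as overlap 0) are accepted. Record types other than S and L
#' (H, P, W, C, ...) are ignored. Files ending in `.gz` are decompressed
#' transparently.
#'
#' @param path path to a GFA1 file (optionally gzip-compressed).
#' @param keep_sequences if `FALSE`, sequences are dropped after measuring
#'   their length, yielding a length-only graph (lower memory on big graphs).
#' @return a [bdgraph] object.
#' @export
read_gfa <- function(path, keep_sequences = TRUE) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop_input(sprintf("input file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  is_s <- startsWith(lines, "S\t")
  is_l <- startsWith(lines, "L\t")

  ids <- character(); seqs <- character(); lens <- integer()
  if (any(is_s)) {
    sl <- strsplit(lines[is_s], "\t", fixed = TRUE)
    lineno <- which(is_s)
    nf <- lengths(sl)
    if (any(nf < 3))
      stop_parse("S line has fewer than 3 fields", lineno[which(nf < 3)[1]])
    ids <- vapply(sl, `[[`, "", 2)
    seqs <- vapply(sl, `[[`, "", 3)
    if (anyDuplicated(ids))
      stop_parse(sprintf("duplicate segment '%s'", ids[duplicated(ids)][1]),
                 lineno[which(duplicated(ids))[1]])
    lens <- integer(length(ids))
    star <- seqs == "*"
    lens[!star] <- nchar(seqs[!star])
    seqs[star] <- NA_character_
    if (any(star)) {
      for (i in which(star)) {
        tags <- sl[[i]][-(1:3)]
        ln <- grep("^LN:i:", tags, value = TRUE)
        if (!length(ln))
          stop_parse(sprintf("segment '%s' has '*' sequence but no LN:i: tag", ids[i]),
                     lineno[i])
        lens[i] <- as.integer(sub("^LN:i:", "", ln[1]))
      }
    }
    if (!keep_sequences) seqs[] <- NA_character_
  }

  edges <- empty_edges()
  if (any(is_l)) {
    ll <- strsplit(lines[is_l], "\t", fixed = TRUE)
    lineno <- which(is_l)
    nf <- lengths(ll)
    if (any(nf < 6))
      stop_parse("L line has fewer than 6 fields", lineno[which(nf < 6)[1]])
    u <- vapply(ll, `[[`, "", 2)
    ou <- vapply(ll, `[[`, "", 3)
    v <- vapply(ll, `[[`, "", 4)
    ov <- vapply(ll, `[[`, "", 5)
    cig <- vapply(ll, `[[`, "", 6)
    bad_or <- !(ou %in% c("+", "-")) | !(ov %in% c("+", "-"))
    if (any(bad_or))
      stop_parse("link orientation must be '+' or '-'", lineno[which(bad_or)[1]])
    miss <- !(u %in% ids)
    if (any(miss))
      stop_parse(sprintf("link references undeclared segment '%s'", u[miss][1]),
                 lineno[which(miss)[1]])
    miss <- !(v %in% ids)
    if (any(miss))
      stop_parse(sprintf("link references undeclared segment '%s'", v[miss][1]),
                 lineno[which(miss)[1]])
    ok_cig <- cig == "*" | grepl("^[0-9]+M$", cig)
    if (!all(ok_cig))
      stop_parse(sprintf("unsupported overlap CIGAR '%s' (only '<int>M' or '*')",
                         cig[!ok_cig][1]),
                 lineno[which(!ok_cig)[1]])
    overlap <- ifelse(cig == "*", 0L, as.integer(sub("M$", "", cig)))
    edges <- data.frame(
      from = u, from_side = ifelse(ou == "+", "R", "L"),
      to = v, to_side = ifelse(ov == "+", "L", "R"),
      overlap = overlap, stringsAsFactors = FALSE
    )
  }

  bdgraph(data.frame(id = ids, seq = seqs, len = lens, stringsAsFactors = FALSE),
          edges)
}

#' Write a bidirected graph as GFA1
#'
#' Emits one S line per node and one L line per undirected edge (each edge is
#' written exactly once, in canonical end order). Length-only nodes are
#' written with a `*` sequence and an `LN:i:` tag, so that
#' `read_gfa(write_gfa(g))` reconstructs an isomorphic graph in either mode.
#'
#' @param graph a [bdgraph] object.
#' @param path output file path (plain text; a `.gz` suffix writes gzip).
#' @param tags optional named list (`node id` -> character vector of GFA tags,
#'   e.g. `"BC:i:7"`) appended verbatim to the corresponding S lines.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(graph, path, tags = NULL) {
  stopifnot(inherits(graph, "bdgraph"))
  seqf <- ifelse(is.na(graph$seq), "*", graph$seq)
  s_lines <- paste("S", graph$ids, seqf, sep = "\t")
  ln_needed <- is.na(graph$seq)
  s_lines[ln_needed] <- paste(s_lines[ln_needed],
                              sprintf("LN:i:%d", graph$len[ln_needed]), sep = "\t")
  if (!is.null(tags)) {
    for (id in names(tags)) {
      i <- match(id, graph$ids)
      if (is.na(i)) stop_lookup(sprintf("tag for unknown node '%s'", id))
      s_lines[i] <- paste(c(s_lines[i], tags[[id]]), collapse = "\t")
    }
  }
  ed <- graph$edges
  l_lines <- character(0)
  if (nrow(ed)) {
    l_lines <- paste("L",
                     ed$from, ifelse(ed$from_side == "R", "+", "-"),
                     ed$to, ifelse(ed$to_side == "L", "+", "-"),
                     sprintf("%dM", ed$overlap), sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(s_lines, l_lines), con)
  invisible(path)
}
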