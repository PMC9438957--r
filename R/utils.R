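`%||%` <- function(x, y) if (is.null(x)) y else x

opp_side <- function(s) ifelse(s == "L", "R", "L")

end_key <- function(node, side) paste(node, side, sep = "\t")

#' Reverse complement of DNA strings
#'
#' Plain-character reverse complement; `N` (and lowercase) are preserved as
#' their complements in the usual IUPAC sense for ACGTN only.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  vapply(chartr("ACGTNacgtn", "TGCANtgcan", x), function(s) {
    intToUtf8(rev(utf8ToInt(s)))
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# condition constructors -------------------------------------------------

gfab_error <- function(msg, class, ...) {
  structure(
    class = c(class, "gfab_error", "error", "condition"),
    list(message = msg, call = NULL, ...)
  )
}

stop_parse <- function(msg, line = NA_integer_) {
  m <- if (is.na(line)) msg else sprintf("GFA parse error at line %d: %s", line, msg)
  stop(gfab_error(m, "gfab_parse_error", line = line))
}

stop_input <- function(msg) stop(gfab_error(msg, "gfab_input_error"))

stop_lookup <- function(msg) stop(gfab_error(msg, "gfab_lookup_error"))
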