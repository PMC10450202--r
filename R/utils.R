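#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# A residue range table: data.frame with integer columns start, end.
#' @noRd
residue_ranges <- function(start = integer(), end = integer()) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(start < 1L)) stop("residue ranges are 1-based: start >= 1 required")
  if (any(end < start)) stop("invalid residue range: end < start")
  data.frame(start = start, end = end)
}

#' @noRd
range_width <- function(ranges) ranges$end - ranges$start + 1L

#' @noRd
range_residues <- function(ranges) {
  if (nrow(ranges) == 0L) return(integer())
  unlist(Map(seq.int, ranges$start, ranges$end), use.names = FALSE)
}

# Assert that a set of ranges tiles 1..n with no gaps or overlaps.
#' @noRd
assert_tiling <- function(ranges, n, what = "segments") {
  res <- sort(range_residues(ranges))
  if (length(res) != n || !identical(res, seq_len(n)))
    stop(sprintf("%s do not tile residues 1..%d", what, n))
  invisible(TRUE)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
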