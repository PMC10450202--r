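#' Running-median smoothing of a pLDDT profile
#'
#' Running median with an odd window; near the chain ends the window shrinks
#' symmetrically so that the output has the same length as the input
#' (`stats::runmed` with `endrule = "median"`). A window of 1 is the
#' identity.
#'
#' @param values Numeric vector of per-residue scores.
#' @param window Odd positive integer window width.
#' @return Numeric vector of the same length.
#' @export
smooth_plddt <- function(values, window = 9L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("window must be an odd integer >= 1")
  if (window == 1L || length(values) == 1L) return(as.numeric(values))
  k <- min(window, if (length(values) %% 2 == 0) length(values) - 1L
           else length(values))
  as.numeric(stats::runmed(values, k, endrule = "median"))
}

#' @noRd
runs_to_segments <- function(structured, plddt) {
  r <- rle(structured)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end,
             klass = ifelse(r$values, "structured", "disordered"),
             mean_plddt = vapply(seq_along(start), function(i)
               mean(plddt[start[i]:end[i]]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Structured/disordered segmentation of a confidence profile
#'
#' Residues whose smoothed pLDDT is at or above `plddt_cutoff` are called
#' structured. Two cleanup rules mirror how architecture diagrams are read:
#' structured runs shorter than `min_struct` are relabelled disordered (short
#' isolated elements with residual secondary-structure propensity are not
#' annotated), and disordered runs shorter than `min_gap` sandwiched between
#' structured runs are absorbed into them. The returned segments tile the
#' chain.
#'
#' @param model A [structure_model()].
#' @param plddt_cutoff Confidence threshold (default 70, the conventional
#'   low-confidence boundary of the AFDB colour scale).
#' @param window Odd smoothing window (default 9).
#' @param min_struct Minimum structured run length (default 10).
#' @param min_gap Minimum disordered gap length kept between structured runs
#'   (default 4).
#' @return Data frame of segments with columns `start`, `end`, `klass`
#'   (`"structured"` or `"disordered"`) and `mean_plddt`, tiling `1..N`.
#' @export
segment_disorder <- function(model, plddt_cutoff = 70, window = 9L,
                             min_struct = 10L, min_gap = 4L) {
  n <- n_residues(model)
  sm <- smooth_plddt(model$plddt, window)
  structured <- sm >= plddt_cutoff
  # absorb short sandwiched disordered gaps first, then drop short
  # structured islands (order matters: a short island must not be rescued
  # by absorbing its flanking gaps)
  r <- rle(structured)
  if (length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    absorb <- inner[!r$values[inner] & r$lengths[inner] < min_gap]
    r$values[absorb] <- TRUE
    structured <- inverse.rle(r)
    r <- rle(structured)
  }
  drop <- which(r$values & r$lengths < min_struct)
  r$values[drop] <- FALSE
  structured <- inverse.rle(r)
  seg <- runs_to_segments(structured, model$plddt)
  assert_tiling(seg, n)
  seg
}

# Median symmetrized cross-PAE between two index sets.
#' @noRd
median_cross <- function(sym, idx_a, idx_b) {
  stats::median(sym[idx_a, idx_b, drop = FALSE])
}

#' Refine structured segments at PAE change-points
#'
#' Recursively bisects each structured segment at the cut point that
#' maximises the contrast between blocks of the symmetrized PAE:
#' `gain(cut) = median cross-block PAE - mean(median intra-block PAEs)`.
#' A cut is accepted only when that gain is at least `gain` Angstrom and
#' both halves are at least `min_sub` residues long; otherwise the segment
#' is returned unchanged. This recovers domain boundaries that the
#' confidence profile alone cannot see (two domains joined without a
#' disordered linker), while leaving rigid multi-subdomain arrangements
#' (low cross-PAE) intact. Disordered segments are untouched.
#'
#' @param segments Segment data frame tiling the chain (from
#'   [segment_disorder()]).
#' @param pae A [pae_matrix()] for the same chain.
#' @param min_sub Minimum sub-segment length (default 25).
#' @param gain Minimum contrast gain in A to accept a cut (default 5).
#' @param symmetrize PAE symmetrization mode, see [symmetrize_pae()].
#' @return Segment data frame of the same form, still tiling the chain.
#' @export
refine_segments_with_pae <- function(segments, pae, min_sub = 25L, gain = 5,
                                     symmetrize = "min") {
  n <- nrow(pae$values)
  assert_tiling(segments, n)
  sym <- symmetrize_pae(pae, symmetrize)
  split_range <- function(s, e) {
    len <- e - s + 1L
    if (len < 2L * min_sub) return(data.frame(start = s, end = e))
    cuts <- (s + min_sub - 1L):(e - min_sub)
    g <- vapply(cuts, function(cut) {
      left <- s:cut; right <- (cut + 1L):e
      median_cross(sym, left, right) -
        mean(c(stats::median(sym[left, left]), stats::median(sym[right, right])))
    }, numeric(1))
    best <- which.max(g)
    if (g[best] < gain) return(data.frame(start = s, end = e))
    cut <- cuts[best]
    rbind(split_range(s, cut), split_range(cut + 1L, e))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(segments)), function(i) {
    seg <- segments[i, ]
    if (seg$klass == "disordered") return(seg[c("start", "end", "klass",
                                                "mean_plddt")])
    parts <- split_range(seg$start, seg$end)
    data.frame(start = parts$start, end = parts$end, klass = "structured",
               mean_plddt = seg$mean_plddt, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  assert_tiling(out, n)
  out
}
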