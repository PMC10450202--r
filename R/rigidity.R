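#' Symmetrize a PAE matrix
#'
#' Real predicted-aligned-error matrices are asymmetric (the error of
#' residue i aligned on j differs from j aligned on i); clustering needs a
#' symmetric dissimilarity. The default takes the element-wise minimum of
#' the matrix and its transpose (the more confident direction), `"mean"`
#' averages the two.
#'
#' @param pae A [pae_matrix()].
#' @param mode `"min"` (default) or `"mean"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
symmetrize_pae <- function(pae, mode = c("min", "mean")) {
  mode <- match.arg(mode)
  v <- pae$values
  if (mode == "min") pmin(v, t(v)) else (v + t(v)) / 2
}

# Dissimilarity between structured segments: median symmetrized PAE over
# all residue pairs of the two segments.
#' @noRd
segment_dissimilarity <- function(segments, sym) {
  k <- nrow(segments)
  d <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    d[i, j] <- d[j, i] <- median_cross(sym,
                                       segments$start[i]:segments$end[i],
                                       segments$start[j]:segments$end[j])
  }
  d
}

#' Cluster structured segments by mutual rigidity
#'
#' Average-linkage hierarchical clustering of structured segments on the
#' dissimilarity `d(A, B) = median symmetrized PAE over residue pairs
#' (a in A, b in B)`, with the dendrogram cut at height `tau`. Segments whose
#' predicted relative positional error is below the cut fall into one
#' cluster — the algorithmic reading of the dark rectangles of a PAE plot.
#' Deterministic; cluster ids are renumbered by the lowest member segment
#' start.
#'
#' @param segments Data frame of structured segments (`start`, `end`).
#' @param pae A [pae_matrix()] for the same chain.
#' @param tau Cut height in Angstrom.
#' @param symmetrize PAE symmetrization mode, see [symmetrize_pae()].
#' @return Integer vector of cluster memberships, one per segment.
#' @export
cluster_segments <- function(segments, pae, tau, symmetrize = "min") {
  if (nrow(segments) < 1L) stop("at least one structured segment required")
  if (nrow(segments) == 1L) return(1L)
  sym <- symmetrize_pae(pae, symmetrize)
  d <- segment_dissimilarity(segments, sym)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  memb <- stats::cutree(hc, h = tau)
  # renumber deterministically by first (lowest-start) occurrence
  first <- vapply(split(segments$start, memb), min, numeric(1))
  as.integer(factor(memb, levels = names(sort(first))))
}

#' Nested domain- and assembly-level rigid units
#'
#' Cuts one average-linkage dendrogram of the structured segments at two
#' heights: `tau_domain` groups segments that belong to one domain (e.g. the
#' two sequence parts of a split domain, or rigid subdomains), and
#' `tau_assembly` groups domains into larger rigid assemblies stabilised by
#' interdomain contacts. Because both partitions come from the same
#' dendrogram, every domain-level unit nests inside exactly one
#' assembly-level unit.
#'
#' @param segments Data frame of structured segments.
#' @param pae A [pae_matrix()].
#' @param tau_domain Cut height for domains (default 5 A).
#' @param tau_assembly Cut height for assemblies (default 10 A); must exceed
#'   `tau_domain`.
#' @param symmetrize PAE symmetrization mode, see [symmetrize_pae()].
#' @return List with integer vectors `domain` and `assembly` (memberships
#'   per segment) and `n_domains`, `n_assemblies`.
#' @export
rigid_assemblies <- function(segments, pae, tau_domain = 5, tau_assembly = 10,
                             symmetrize = "min") {
  if (tau_domain >= tau_assembly)
    stop("tau_domain must be smaller than tau_assembly")
  dom <- cluster_segments(segments, pae, tau_domain, symmetrize)
  asm <- cluster_segments(segments, pae, tau_assembly, symmetrize)
  # nestedness is guaranteed by cutting one dendrogram; assert anyway
  if (any(tapply(asm, dom, function(x) length(unique(x))) != 1L))
    stop("internal error: domain-level units straddle assemblies")
  list(domain = dom, assembly = asm,
       n_domains = length(unique(dom)),
       n_assemblies = length(unique(asm)))
}

#' Score interdomain contacts from the PAE matrix
#'
#' For every unordered pair of domain-level units, the contact score is the
#' median symmetrized PAE between the two units' residues; a pair is called
#' in contact when the score is at or below `tau_contact`. Darker
#' off-diagonal patches of a PAE plot (relative immobilisation) thus become
#' explicit contact calls.
#'
#' @param domains List of [domain_call()] objects (or any objects with a
#'   `ranges` data frame and `domain_id`).
#' @param pae A [pae_matrix()].
#' @param tau_contact Contact threshold in A (default 12).
#' @param symmetrize PAE symmetrization mode, see [symmetrize_pae()].
#' @return Data frame with columns `domain_a`, `domain_b`, `score`,
#'   `is_contact`, one row per unordered pair.
#' @export
contact_matrix <- function(domains, pae, tau_contact = 12, symmetrize = "min") {
  if (length(domains) < 2L)
    return(data.frame(domain_a = character(), domain_b = character(),
                      score = numeric(), is_contact = logical()))
  sym <- symmetrize_pae(pae, symmetrize)
  ids <- vapply(domains, `[[`, character(1), "domain_id")
  res <- lapply(domains, function(d) range_residues(d$ranges))
  cmb <- utils::combn(seq_along(domains), 2)
  score <- vapply(seq_len(ncol(cmb)), function(k)
    median_cross(sym, res[[cmb[1, k]]], res[[cmb[2, k]]]), numeric(1))
  data.frame(domain_a = ids[cmb[1, ]], domain_b = ids[cmb[2, ]],
             score = score, is_contact = score <= tau_contact,
             stringsAsFactors = FALSE)
}
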