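#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired C-alpha coordinate sets, using the SVD of the cross-covariance
#' matrix with the usual determinant correction so that reflections are
#' never returned. The fitted mobile set is `X %*% t(rotation) + translation`
#' (row vectors).
#'
#' @param X Mobile coordinates, n x 3 matrix (paired row-for-row with `Y`).
#' @param Y Target coordinates, n x 3 matrix.
#' @return An object of class `"superposition"`: list with `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length-3), `rmsd` (A, over all
#'   pairs), `n_core` (= n), `n_input` (= n), `rejected` (empty).
#' @export
kabsch <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(dim(X) == dim(Y)) || ncol(X) != 3L)
    stop("X and Y must be paired n x 3 coordinate matrices")
  n <- nrow(X)
  if (n < 3L) stop("degenerate input: at least 3 atom pairs required")
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv_x <- svd(Xc)$d
  if (sv_x[2] < 1e-8 * max(sv_x[1], 1))
    stop("degenerate input: mobile coordinates are collinear")
  H <- crossprod(Xc, Yc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Yc)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cy - R %*% cx),
                 rmsd = rmsd,
                 n_core = n,
                 n_input = n,
                 rejected = integer()),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.3f A over %d of %d C-alpha pairs (%d rejected)\n",
              x$rmsd, x$n_core, x$n_input, length(x$rejected)))
  invisible(x)
}

#' Apply a superposition to coordinates
#' @param fit A `"superposition"` object.
#' @param X n x 3 coordinate matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(fit, X) {
  sweep(as.matrix(X) %*% t(fit$rotation), 2, fit$translation, "+")
}

#' Core superposition with iterative outlier rejection
#'
#' Emulates the refinement behaviour of interactive "super"-style fitting:
#' repeatedly fit the current core with [kabsch()], then reject pairs whose
#' deviation exceeds `kappa` times the current core RMSD. Iteration stops
#' when no pair is rejected, after `max_cycles` cycles, or when a further
#' rejection would shrink the core below `min_core_frac` of the input pairs
#' (the last admissible core is kept). The reported RMSD and atom count
#' refer to the final core only.
#'
#' @param X Mobile coordinates, n x 3 (n >= 10), paired with `Y`.
#' @param Y Target coordinates, n x 3.
#' @param max_cycles Maximum rejection cycles (default 5).
#' @param kappa Rejection multiplier on the current RMSD (default 2.0).
#' @param min_core_frac Smallest admissible core as a fraction of the input
#'   (default 0.3).
#' @return A `"superposition"` object; `rejected` lists the indices of the
#'   pairs excluded from the final core.
#' @export
core_superpose <- function(X, Y, max_cycles = 5L, kappa = 2.0,
                           min_core_frac = 0.3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 10L) stop("core superposition needs at least 10 atom pairs")
  core <- seq_len(n)
  fit <- kabsch(X, Y)
  for (cycle in seq_len(max_cycles)) {
    if (fit$rmsd <= 1e-8) break  # already an exact fit

    dev <- sqrt(rowSums((apply_superposition(fit, X[core, , drop = FALSE]) -
                           Y[core, , drop = FALSE])^2))
    keep <- dev <= kappa * fit$rmsd
    if (all(keep)) break
    new_core <- core[keep]
    if (length(new_core) < max(3L, ceiling(min_core_frac * n))) break
    core <- new_core
    fit <- kabsch(X[core, , drop = FALSE], Y[core, , drop = FALSE])
  }
  fit$n_input <- n
  fit$n_core <- length(core)
  fit$rejected <- setdiff(seq_len(n), core)
  fit
}

#' Pair residues of two sequences by global alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties (defaults -11 open, -1 extend); the correspondence consists of
#' the aligned non-gap columns. Provides the explicit, reproducible pairing
#' rule behind reference-based domain labelling.
#'
#' @param seq_a,seq_b One-letter amino-acid strings.
#' @param gap_open Gap opening penalty (negative; default -11).
#' @param gap_extend Gap extension penalty (negative; default -1).
#' @return Data frame with columns `a`, `b`: 1-based positions of paired
#'   residues in `seq_a` and `seq_b`.
#' @export
pair_by_sequence <- function(seq_a, seq_b, gap_open = -11, gap_extend = -1) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", type = "global",
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  pa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  sb <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  ia <- cumsum(pa != "-")
  ib <- cumsum(sb != "-")
  keep <- pa != "-" & sb != "-"
  data.frame(a = ia[keep], b = ib[keep])
}
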