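# Independent oracles and small geometry utilities used across tests.

# Horn's quaternion method for optimal rigid superposition: an independent
# check on the SVD-based Kabsch implementation. Returns the minimal RMSD.
quaternion_rmsd <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  M <- crossprod(Xc, Yc)  # 3x3 correlation matrix
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(Xc^2) + sum(Yc^2) - 2 * lambda
  sqrt(max(ss, 0) / nrow(X))
}

# Uniform random proper rotation via quaternion draw.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rigid_transform <- function(X, R = random_rotation(),
                            t = stats::rnorm(3, sd = 20)) {
  sweep(as.matrix(X) %*% t(R), 2, t, "+")
}

random_cloud <- function(n, sd = 10) matrix(stats::rnorm(3 * n, sd = sd), n, 3)

# A structure_model with a trivial extended trace and a given pLDDT profile
# (for segmentation tests where geometry is irrelevant).
profile_model <- function(plddt, entry_id = "profile") {
  n <- length(plddt)
  ca <- cbind(3.8 * seq_len(n), sin(seq_len(n)), cos(seq_len(n)))
  seqc <- paste(rep("A", n), collapse = "")
  structure_model(entry_id, "A", seq_len(n), seqc, ca, plddt)
}

# Random valid pae_matrix of size n (diagonal zero, entries in [0, 30]).
random_pae <- function(n, max_value = 31.75) {
  v <- matrix(stats::runif(n * n, 0, 30), n, n)
  diag(v) <- 0
  pae_matrix(v, max_value)
}

# Random tiling of 1..n into k contiguous segments, all structured.
random_segments <- function(n, k) {
  cuts <- sort(sample(seq_len(n - 1), k - 1))
  start <- c(1L, cuts + 1L)
  end <- c(cuts, n)
  data.frame(start = start, end = end, klass = "structured",
             mean_plddt = 90)
}

# Local cache of real reference coordinates (AFDB models, PDB entries) for
# the printed-value anchors. Populated manually (see README); absent in
# offline runs.
external_file <- function(name) {
  p <- file.path(system.file("extdata", package = "afdomains"),
                 "external", name)
  if (file.exists(p)) p else NA_character_
}
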