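two_domain_spec <- function(seed, assembly = FALSE)
  synthetic_spec(list(list(kind = "domain", length = 60, domain_id = "X"),
                      list(kind = "linker", length = 20),
                      list(kind = "domain", length = 60, domain_id = "Y")),
                 assemblies = if (assembly) list(c("X", "Y")) else list(),
                 seed = seed)

test_that("spec validation enforces the planted-truth contract", {
  expect_error(synthetic_spec(list(list(kind = "domain", length = 10,
                                        domain_id = "A"))), ">= 30")
  expect_error(synthetic_spec(list(list(kind = "linker", length = 50,
                                        domain_id = "A"))), "linkers never")
  expect_error(synthetic_spec(list(list(kind = "domain", length = 50,
                                        domain_id = "A")),
                              assemblies = list(c("A", "Z"))), "unknown")
  sp <- default_synthetic_spec()
  expect_named(sp$split_memberships, "A")
  expect_equal(sp$split_memberships$A, c(1L, 5L))
})

test_that("generated traces have 3.8 A virtual bonds and confined domains", {
  sp <- synthetic_spec(list(list(kind = "domain", length = 50,
                                 domain_id = "A")), seed = 7)
  gen <- generate_model(sp)
  steps <- sqrt(rowSums(diff(gen$model$ca)^2))
  expect_true(all(abs(steps - 3.8) <= 0.01))
  # confinement: all residues within the stated sphere radius
  ctr <- colMeans(gen$model$ca)
  rad <- 2.5 * 50^(1 / 3)
  expect_true(all(sqrt(rowSums(sweep(gen$model$ca, 2, ctr)^2)) <= 2 * rad))
  # split domain parts share one spatial unit: part centroids nearly coincide
  gen2 <- generate_model(default_synthetic_spec(seed = 3))
  ca <- gen2$model$ca
  c1 <- colMeans(ca[1:70, ]); c2 <- colMeans(ca[236:285, ])
  expect_lt(sqrt(sum((c1 - c2)^2)), 2.5 * 120^(1 / 3))
})

test_that("pLDDT profile separates domains from linkers", {
  sp <- synthetic_spec(list(list(kind = "domain", length = 120, domain_id = "A"),
                            list(kind = "linker", length = 40),
                            list(kind = "domain", length = 140, domain_id = "B")),
                       seed = 1)
  gen <- generate_model(sp)
  expect_gt(mean(gen$model$plddt[1:120]), 83)
  expect_lt(mean(gen$model$plddt[1:120]), 93)
  expect_lt(mean(gen$model$plddt[125:155]), 55)
  expect_true(all(gen$model$plddt >= 0 & gen$model$plddt <= 100))
})

test_that("generation is deterministic given spec and seed", {
  sp <- default_synthetic_spec(seed = 9)
  expect_identical(generate_model(sp)$model$ca, generate_model(sp)$model$ca)
  expect_identical(generate_pae(sp)$values, generate_pae(sp)$values)
  expect_identical(generate_intensity_profiles(sp, "A"),
                   generate_intensity_profiles(sp, "A"))
  # and differs across seeds
  expect_false(identical(generate_model(default_synthetic_spec(1))$model$ca,
                         generate_model(default_synthetic_spec(2))$model$ca))
})

test_that("planted PAE blocks carry the designed contrast", {
  pae <- generate_pae(two_domain_spec(4))
  v <- symmetrize_pae(pae, "mean")
  intra <- v[1:60, 1:60][upper.tri(matrix(0, 60, 60))]
  cross <- v[1:60, 81:140]
  expect_lt(median(intra), 5)
  expect_gt(median(cross), 12)
  # declaring the assembly darkens the cross block to ~6 A
  pae2 <- generate_pae(two_domain_spec(4, assembly = TRUE))
  cross2 <- symmetrize_pae(pae2, "mean")[1:60, 81:140]
  expect_lte(median(cross2), 8)
  expect_true(all(diag(pae$values) == 0))
  # near-diagonal band stays low everywhere, like real PAE
  sep <- abs(row(pae$values) - col(pae$values))
  expect_true(all(pae$values[sep <= 4 & sep > 0] <= 4))
})

test_that("generated PAE satisfies matrix invariants over many seeds", {
  for (s in 1:100) {
    sp <- synthetic_spec(list(list(kind = "domain", length = 30,
                                   domain_id = "A"),
                              list(kind = "linker", length = 12),
                              list(kind = "domain", length = 25,
                                   domain_id = "B")), seed = s)
    # pae_matrix() itself asserts: square, in [0, ceiling], diagonal <= 1
    expect_s3_class(generate_pae(sp), "pae_matrix")
  }
})

test_that("intensity profiles scale immobilized domains down, linkers not", {
  sp <- default_synthetic_spec(seed = 6)
  lay_linkers <- c(71:95, 206:235, 286:310)
  tab <- generate_intensity_profiles(sp, c("A", "B", "C"))
  ratio <- tab$intensity_bound / tab$intensity_free
  expect_gt(mean(ratio[lay_linkers], na.rm = TRUE), 0.6)
  expect_lt(mean(ratio[1:70], na.rm = TRUE), 0.3)
  # nothing immobilized: every element keeps high bound/free ratio
  tab0 <- generate_intensity_profiles(sp, character())
  r0 <- tab0$intensity_bound / tab0$intensity_free
  expect_gt(min(tapply(r0, rep(1:7, c(70, 25, 110, 30, 50, 25, 90)),
                       mean, na.rm = TRUE)), 0.6)
  # ~10% unassigned residues
  expect_equal(sum(is.na(tab$intensity_free)), 40)
  expect_error(generate_intensity_profiles(sp, "Q"), "subset")
})

test_that("ground truth always passes architecture invariants", {
  for (s in 1:5) {
    tr <- ground_truth(default_synthetic_spec(seed = s))
    expect_s3_class(tr$architecture, "architecture")
    expect_equal(tr$contact_pairs,
                 data.frame(domain_a = "A", domain_b = "B"))
  }
})

test_that("simulate_bundle writes a coherent file set", {
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- simulate_bundle(default_synthetic_spec(seed = 2), prefix,
                           immobilized = c("A", "B"))
  expect_true(all(file.exists(paths)))
  m <- read_structure_model(paths[["model"]])
  p <- read_pae(paths[["pae"]])
  expect_equal(n_residues(m), 400)
  expect_equal(nrow(p$values), 400)
  expect_s3_class(read_architecture(paths[["architecture"]]), "architecture")
})
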