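test_that("running-median smoothing behaves at windows and edges", {
  x <- c(40, 40, 40, 40, 90, 40, 40, 40, 40, 40, 40)
  expect_identical(smooth_plddt(x, 1L), x)
  expect_identical(smooth_plddt(rep(77, 50), 9L), rep(77, 50))
  sm <- smooth_plddt(x, 9L)
  expect_length(sm, length(x))
  expect_true(all(sm <= 41))  # a lone spike cannot survive a width-9 median
  expect_error(smooth_plddt(x, 4L), "odd")
})

test_that("constant-confidence chains give a single segment", {
  hi <- profile_model(rep(90, 100))
  seg <- segment_disorder(hi)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$klass, "structured")
  expect_equal(c(seg$start, seg$end), c(1L, 100L))
  lo <- profile_model(rep(40, 100))
  seg2 <- segment_disorder(lo)
  expect_equal(seg2$klass, "disordered")
})

test_that("short structured islands are dropped, short gaps absorbed", {
  # 12-residue high island in disorder, below min_struct = 15
  p <- rep(40, 120); p[50:61] <- 92
  seg <- segment_disorder(profile_model(p), window = 1L, min_struct = 15L)
  expect_equal(seg$klass, "disordered")
  # 2-residue dip inside structure is absorbed (min_gap = 4)
  p2 <- rep(90, 120); p2[60:61] <- 45
  seg2 <- segment_disorder(profile_model(p2), window = 1L)
  expect_equal(nrow(seg2), 1L)
  expect_equal(seg2$klass, "structured")
})

test_that("planted domain/linker boundaries are recovered within 3 residues", {
  sp <- synthetic_spec(list(list(kind = "domain", length = 120, domain_id = "A"),
                            list(kind = "linker", length = 40),
                            list(kind = "domain", length = 140, domain_id = "B")),
                       seed = 1)
  gen <- generate_model(sp)
  seg <- segment_disorder(gen$model)
  str <- seg[seg$klass == "structured", ]
  expect_equal(nrow(str), 2L)
  expect_lte(abs(str$end[1] - 120), 3)
  expect_lte(abs(str$start[2] - 161), 3)
  assert_ok <- sort(unlist(Map(seq.int, seg$start, seg$end)))
  expect_identical(assert_ok, 1:300)
})

test_that("raising the confidence cutoff never adds structured residues", {
  gen <- generate_model(default_synthetic_spec(seed = 8))
  counts <- vapply(c(50, 60, 70, 80, 90), function(cut) {
    seg <- segment_disorder(gen$model, plddt_cutoff = cut)
    sum((seg$end - seg$start + 1L)[seg$klass == "structured"])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("PAE refinement splits flexible junctions and spares rigid ones", {
  # one structured segment with a uniform low PAE block stays whole
  n <- 80
  v <- matrix(3, n, n); diag(v) <- 0
  flat <- pae_matrix(v)
  seg <- data.frame(start = 1L, end = n, klass = "structured", mean_plddt = 90)
  expect_equal(nrow(refine_segments_with_pae(seg, flat)), 1L)

  # two adjacent domains with no linker: confidence sees one segment,
  # the PAE change-point recovers the planted boundary at 60
  sp <- synthetic_spec(list(list(kind = "domain", length = 60, domain_id = "X"),
                            list(kind = "domain", length = 60, domain_id = "Y")),
                       seed = 2)
  gen <- generate_model(sp); pae <- generate_pae(sp)
  seg1 <- segment_disorder(gen$model)
  expect_equal(nrow(seg1), 1L)
  ref <- refine_segments_with_pae(seg1, pae)
  expect_equal(nrow(ref), 2L)
  expect_lte(abs(ref$end[1] - 60), 3)

  # same two domains declared one rigid assembly: cross-PAE ~6 A versus
  # intra ~3 A gives a gain of ~3 A, below the 5 A default -> no split
  sp2 <- synthetic_spec(list(list(kind = "domain", length = 60, domain_id = "X"),
                             list(kind = "domain", length = 60, domain_id = "Y")),
                        assemblies = list(c("X", "Y")), seed = 2)
  gen2 <- generate_model(sp2); pae2 <- generate_pae(sp2)
  ref2 <- refine_segments_with_pae(segment_disorder(gen2$model), pae2)
  expect_equal(nrow(ref2), 1L)
})

test_that("segmentation output always tiles the chain", {
  for (s in 1:10) {
    gen <- generate_model(default_synthetic_spec(seed = s))
    pae <- generate_pae(default_synthetic_spec(seed = s))
    seg <- segment_disorder(gen$model)
    ref <- refine_segments_with_pae(seg, pae)
    res <- sort(unlist(Map(seq.int, ref$start, ref$end)))
    expect_identical(res, seq_len(n_residues(gen$model)))
  }
})
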