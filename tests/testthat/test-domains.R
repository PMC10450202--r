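seg_row <- function(start, end)
  data.frame(start = start, end = end, klass = "structured", mean_plddt = 90)

test_that("domain calls merge adjacent member ranges and keep gaps", {
  segs <- rbind(seg_row(10, 60), seg_row(61, 100), seg_row(200, 260))
  calls <- call_domains(c(1L, 1L, 1L), segs)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$ranges, data.frame(start = c(10L, 200L),
                                             end = c(100L, 260L)))
  calls2 <- call_domains(c(1L, 1L, 2L), segs)
  expect_length(calls2, 2)
  expect_equal(nrow(calls2[[1]]$ranges), 1L)
  # calls are numbered in sequence order of their first residue
  expect_equal(vapply(calls2, `[[`, character(1), "domain_id"), c("D1", "D2"))
})

test_that("split detection uses the insertion length and quarter display", {
  long_gap <- domain_call("D1", residue_ranges(c(1, 121), c(90, 150)))
  short_gap <- domain_call("D2", residue_ranges(c(1, 96), c(90, 150)))
  out <- detect_split_domains(list(long_gap, short_gap), min_insertion = 30)
  expect_true(out[[1]]$split)
  expect_false(out[[2]]$split)
  expect_equal(out[[1]]$part_fractions, c(0.75, 0.25))
  expect_equal(fraction_display(out[[1]]$part_fractions), c("\u00be", "\u00bc"))
  # display rounding never alters the stored exact fractions
  odd <- domain_call("D3", residue_ranges(c(1, 200), c(70, 230)))
  expect_equal(sum(odd$part_fractions), 1, tolerance = 1e-9)
  expect_equal(odd$part_fractions, c(70, 31) / 101)
})

test_that("part fractions always sum to one", {
  withr::with_seed(11, {
    for (k in 1:50) {
      nr <- sample(1:4, 1)
      w <- sample(5:50, nr, replace = TRUE)
      gap <- sample(1:40, nr, replace = TRUE)
      end <- cumsum(w + gap)
      start <- end - w + 1L
      d <- domain_call("X", residue_ranges(start, end))
      expect_equal(sum(d$part_fractions), 1, tolerance = 1e-9)
    }
  })
})

test_that("reference labelling attaches core RMSD or skips cleanly", {
  gen <- generate_model(default_synthetic_spec(seed = 4))
  model <- gen$model
  call <- gen$truth$architecture$domains[[2]]  # domain B, 96-205
  # self-reference: identity pairing, rmsd 0, full core
  ref_self <- extract_region(model, call$ranges)
  out <- label_by_reference(call, model, ref_self, label = "selftest")
  expect_equal(out$label, "selftest")
  expect_equal(out$label_rmsd, 0, tolerance = 1e-10)
  expect_equal(out$label_core_atoms, 110L)

  # rotated copy with 10% of residues displaced by 10 A:
  # the core excludes them and the rmsd stays at the planted noise level
  withr::with_seed(21, {
    ref <- ref_self
    ref$ca <- ref$ca + matrix(rnorm(3 * 110, sd = 0.3), 110, 3)
    disp <- sample(110, 11)
    ref$ca[disp, ] <- ref$ca[disp, ] + matrix(rnorm(33, sd = 10), 11, 3)
    ref$ca <- rigid_transform(ref$ca)
    out2 <- label_by_reference(call, model, ref, label = "decoy")
    expect_lte(out2$label_rmsd, 1.0)
    expect_lte(out2$label_core_atoms, 110 - 9)
  })

  # too few pairs: warning, call unchanged
  tiny <- structure_model("tiny", "A", 1:12, "ACDEFGHIKLMN",
                          cbind(3.8 * (1:12), sin(1:12), cos(1:12)),
                          rep(90, 12))
  expect_warning(out3 <- label_by_reference(call, model, tiny, label = "no"),
                 "skipped")
  expect_identical(out3, call)  # unchanged, no label attached
})

test_that("architecture comparison scores overlap and boundary slack", {
  tr <- ground_truth(default_synthetic_spec(seed = 1))
  self <- compare_architecture(tr$architecture, tr$architecture, slack = 5)
  expect_equal(self$agreement, 1)
  expect_true(all(self$matches$max_boundary_delta == 0))
  expect_equal(self$n_extra, 0)

  shifted <- architecture(
    "shift", 400,
    domains = lapply(tr$architecture$domains, function(d) {
      r <- d$ranges
      r$start <- r$start + 3L; r$end <- pmin(r$end + 3L, 400L)
      domain_call(d$domain_id, r, label = d$label, split = d$split)
    }),
    disordered = local({
      dd <- tr$architecture$disordered
      keep <- residue_ranges(pmax(dd$start + 3L, 1L), dd$end + 3L)
      rbind(data.frame(start = 1L, end = 3L),
            keep[keep$start <= keep$end, ])
    }))
  cmp <- compare_architecture(shifted, tr$architecture, slack = 5)
  expect_equal(cmp$agreement, 1)
  expect_true(all(cmp$matches$max_boundary_delta == 3))
  cmp1 <- compare_architecture(shifted, tr$architecture, slack = 2)
  expect_equal(cmp1$agreement, 0)

  # matched counts are symmetric at equal slack
  ab <- compare_architecture(shifted, tr$architecture, slack = 5)
  ba <- compare_architecture(tr$architecture, shifted, slack = 5)
  expect_equal(sum(!is.na(ab$matches$matched_id)),
               sum(!is.na(ba$matches$matched_id)))
})

test_that("packaged reference ranges and vocabulary are consistent", {
  ref <- parp_reference_ranges()
  expect_true(all(c("PARP4_HUMAN", "PARP6_HUMAN", "PARP1_HUMAN") %in%
                    names(ref)))
  mvpid <- ref$PARP4_HUMAN[ref$PARP4_HUMAN$label == "MVPID", ]
  expect_equal(c(mvpid$start, mvpid$end), c(1570, 1724))
  expect_equal(ref$PARP6_HUMAN$start, 284)
  expect_equal(ref$PARP8_HUMAN$end, 552)
  vocab <- known_domain_labels()
  expect_true(all(c("MZAP", "NZAP", "MVPID", "HD", "HE", "C4*", "KH", "RWD")
                  %in% vocab$label))
  # every labelled reference range uses the controlled vocabulary or a
  # descriptive free-text label
  expect_true(all(vapply(ref, function(e) all(nchar(e$label) > 0),
                         logical(1))))
})
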