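test_that("pLDDT is read from the C-alpha B-factor column of a PDB file", {
  pdb <- c(
    "ATOM      1  N   MET A   1       0.000   0.000   0.000  1.00 91.20           N",
    "ATOM      2  CA  MET A   1       1.458   0.000   0.000  1.00 91.20           C",
    "ATOM      3  CA  ALA A   2       5.258   0.000   0.000  1.00 40.00           C",
    "ATOM      4  CA  GLY A   3       9.058   0.000   0.000  1.00 88.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  m <- read_structure_model(path)
  expect_equal(m$plddt, c(91.2, 40.0, 88.0))
  expect_equal(m$resno, 1:3)
  expect_equal(m$sequence, "MAG")
  expect_error(read_structure_model(path, chain = "B"), "empty input")
})

test_that("out-of-range B-factors are clipped with a warning", {
  pdb <- c(
    "ATOM      1  CA  MET A   1       0.000   0.000   0.000  1.00112.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00 50.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00 20.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  expect_warning(m <- read_structure_model(path), "clipping")
  expect_equal(m$plddt[1], 100)
})

test_that("structure models survive a write/read round trip", {
  gen <- generate_model(default_synthetic_spec(seed = 11))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure_model(gen$model, path)
  back <- read_structure_model(path, entry_id = gen$model$entry_id)
  expect_equal(back$resno, gen$model$resno)
  expect_equal(back$sequence, gen$model$sequence)
  expect_equal(back$ca, gen$model$ca, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$plddt, gen$model$plddt, tolerance = 1e-2)
  # residue order is author order, never rearranged
  expect_true(all(diff(back$resno) > 0))
  # a perfect-confidence residue serialises as 100.00
  m100 <- structure_model("x", "A", 1:3, "AAA",
                          cbind(c(0, 3.8, 7.6), 0, c(0, 0, 3.8)),
                          c(100, 50, 0))
  write_structure_model(m100, path)
  expect_match(readLines(path)[1], "100\\.00")
})

test_that("model constructor rejects invalid input", {
  ca <- cbind(1:3, 0, 0)
  expect_error(structure_model("x", "A", c(1, 2, 2), "AAA", ca, c(1, 2, 3)),
               "strictly increasing")
  expect_error(structure_model("x", "A", 1:3, "AAA", ca, c(1, 2, 101)),
               "plddt")
  ca[2, 1] <- NaN
  expect_error(structure_model("x", "A", 1:3, "AAA", ca, c(1, 2, 3)),
               "non-finite")
  expect_error(structure_model("x", "A", integer(), "", ca[0, ], numeric()),
               "empty")
})

test_that("AFDB PAE JSON reading preserves asymmetry and validates shape", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"predicted_aligned_error": [[0, 5], [7, 0]]}', path)
  pae <- read_pae(path)
  expect_equal(pae$values[1, 2], 5)
  expect_equal(pae$values[2, 1], 7)
  expect_equal(pae$max_value, 31.75)  # default ceiling when absent
  writeLines('{"predicted_aligned_error": [[0, 5], [7, 0], [1, 2]]}', path)
  expect_error(read_pae(path), "non-square|malformed")
  writeLines('{"predicted_aligned_error": [[0, -5], [7, 0]]}', path)
  expect_error(read_pae(path), "negative")
  # array-of-objects AFDB dialect
  writeLines('[{"predicted_aligned_error": [[0, 3], [4, 0]], "max_predicted_aligned_error": 31.75}]',
             path)
  expect_equal(read_pae(path)$values[2, 1], 4)
})

test_that("PAE matrices round-trip exactly through JSON", {
  pae <- generate_pae(synthetic_spec(list(
    list(kind = "domain", length = 40, domain_id = "X"),
    list(kind = "linker", length = 15)), seed = 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_pae(pae, path)
  back <- read_pae(path)
  expect_identical(back$values, pae$values)
  expect_identical(back$max_value, pae$max_value)
})

test_that("architectures round-trip through versioned JSON", {
  # three mutually flexible domains, in the style of a two-Macro + ART chain
  arch <- architecture("PARP15-like", 678, domains = list(
    domain_call("D1", residue_ranges(5, 190), label = "Macro"),
    domain_call("D2", residue_ranges(205, 380), label = "Macro"),
    domain_call("D3", residue_ranges(481, 678), label = "ART")),
    disordered = residue_ranges(c(1, 191, 381), c(4, 204, 480)),
    contacts = data.frame(domain_a = c("D1", "D1", "D2"),
                          domain_b = c("D2", "D3", "D3"),
                          score = c(14.2, 20.1, 18.3),
                          is_contact = c(FALSE, FALSE, FALSE)))
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(arch, path)
  expect_identical(read_architecture(path), arch)

  empty <- architecture("bare", 50, disordered = residue_ranges(1, 50))
  write_architecture(empty, path)
  expect_identical(read_architecture(path), empty)
  expect_length(read_architecture(path)$domains, 0)

  writeLines('{"schema": "something-else/9", "entry_id": "x"}', path)
  expect_error(read_architecture(path), "schema")
})

test_that("random architectures round-trip identically", {
  withr::with_seed(42, {
    for (k in 1:100) {
      n <- sample(60:400, 1)
      seg <- random_segments(n, sample(2:6, 1))
      is_dom <- seq_len(nrow(seg)) %% 2 == 1
      doms <- lapply(which(is_dom), function(i)
        domain_call(sprintf("D%d", i), seg[i, c("start", "end")],
                    label = sample(c("KH", "WWE", "ART", "unassigned"), 1)))
      arch <- architecture(sprintf("rand%d", k), n, domains = doms,
                           disordered = seg[!is_dom, c("start", "end")])
      path <- withr::local_tempfile(fileext = ".json")
      write_architecture(arch, path)
      expect_identical(read_architecture(path), arch)
    }
  })
})

test_that("intensity tables round-trip with missing values", {
  tab <- data.frame(residue = 1:6,
                    intensity_free = c(1.0, NA, 0.9, 1.2, 1.1, 0.8),
                    intensity_bound = c(0.1, NA, NA, 1.0, 0.12, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_intensity_table(tab, path)
  back <- read_intensity_table(path)
  expect_equal(back, tab)
})
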