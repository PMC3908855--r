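test_that("read_fasta parses records in order and upper-cases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "acde"), f)
  expect_identical(read_fasta(f), c(p1 = "ACDE"))

  writeLines(c(">p1 some description", "ACDE", ">p2", "GG", "HH"), f)
  got <- read_fasta(f)
  expect_identical(names(got), c("p1", "p2"))
  expect_identical(unname(got), c("ACDE", "GGHH"))
})

test_that("read_fasta rejects malformed input with a line reference", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines("ACDE", f)
  expect_error(read_fasta(f), "line 1")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")
})

test_that("PSSM ASCII profiles round-trip through writer and reader", {
  set.seed(3)
  scores <- matrix(round(rnorm(3 * 20, 0, 3), 3), 3, 20)
  res <- c("M", "K", "V")
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm_ascii(scores, res, f)
  got <- read_pssm_ascii(f)
  expect_equal(got$scores, scores)
  expect_identical(got$residues, res)
})

test_that("truncated or corrupt profile rows are parse errors with row info", {
  set.seed(4)
  f <- withr::local_tempfile(fileext = ".pssm")
  write_pssm_ascii(matrix(rnorm(40), 2, 20), c("A", "G"), f)
  lines <- readLines(f)
  i <- grep("^\\s*2\\s+G", lines)
  lines[i] <- substr(lines[i], 1, 40)   # drop most of the score block
  writeLines(lines, f)
  expect_error(read_pssm_ascii(f), "line")
})

test_that("sigmoid PSSM scaling has the right fixed points and symmetry", {
  expect_equal(scale_pssm(matrix(0, 1, 1))[1, 1], 0.5)
  expect_equal(scale_pssm(10), 0.9999546, tolerance = 1e-6)
  x <- seq(-8, 8, by = 0.37)
  expect_equal(scale_pssm(x) + scale_pssm(-x), rep(1, length(x)))
  expect_true(all(scale_pssm(c(-500, 500)) > 0 &
                  scale_pssm(c(-500, 500)) < 1))
  expect_error(scale_pssm(c(1, NA)), "non-finite")
  expect_error(scale_pssm(Inf), "non-finite")
})

test_that("state encodings are the fixed one-hot vectors", {
  expect_equal(unname(encode_pss("H")), c(1, 0, 0))
  expect_equal(unname(encode_pss("E")), c(0, 1, 0))
  expect_equal(unname(encode_pss("C")), c(0, 0, 1))
  expect_error(encode_pss("X", pos = 4), "'X' at position 4")

  expect_equal(unname(encode_shape("S")), c(1, rep(0, 8)))
  expect_equal(unname(encode_shape("R")), c(0, 1, rep(0, 7)))
  expect_equal(unname(encode_shape("N")), c(rep(0, 8), 1))
  expect_error(encode_shape("Q"), "unknown")
})

test_that("window dimensions follow the mode formulas", {
  p <- toy_protein(L = 10)
  for (mode in c("pssm_window_pss_window", "pssm_window_central_pss",
                 "pssm_pss_shape_window")) {
    for (w in c(3L, 7L, 9L)) {
      out <- build_windows(p, window = w, mode = mode)
      expect_identical(dim(out$features), c(10L, feature_count(mode, w)))
    }
  }
  expect_identical(feature_count("pssm_window_pss_window", 7), 161L)
  expect_identical(feature_count("pssm_window_central_pss", 7), 143L)
  expect_identical(feature_count("pssm_pss_shape_window", 7), 224L)
  expect_error(build_windows(p, window = 4), "odd")
})

test_that("termini are zero-padded and the centre block is the residue's own encoding", {
  p <- toy_protein(L = 10)
  out <- build_windows(p, window = 7, mode = "pssm_window_pss_window")
  # first residue: window positions -3..-1 are pad
  expect_true(all(out$features[1, 1:(3 * 23)] == 0))
  expect_true(all(out$features[10, (4 * 23 + 1):161] == 0))
  enc <- cbind(scale_pssm(p$pssm),
               t(vapply(strsplit(p$pss, "")[[1]], encode_pss, numeric(3))))
  for (i in seq_len(10)) {
    centre <- out$features[i, (3 * 23 + 1):(4 * 23)]
    expect_equal(unname(centre), unname(enc[i, ]))
  }
  # every feature value within [0, 1]
  expect_true(all(out$features >= 0 & out$features <= 1))
})

test_that("shape-requiring mode demands a shape string", {
  p <- toy_protein(L = 8)
  p$shape <- NULL
  expect_error(build_windows(p, mode = "pssm_pss_shape_window"),
               "requires a shape string")
})

test_that("encoding a protein set is deterministic and keeps bookkeeping", {
  prots <- list(toy_protein(L = 9, id = "a", seed = 1),
                toy_protein(L = 12, id = "b", seed = 2))
  ds1 <- encode_dataset(prots)
  ds2 <- encode_dataset(prots)
  expect_identical(ds1, ds2)
  expect_identical(nrow(ds1$features), 21L)
  expect_identical(ds1$protein_ids, c(rep("a", 9), rep("b", 12)))
  expect_identical(length(ds1$labels), 21L)
})

test_that("a written dataset reads back losslessly through the manifest", {
  prots <- simulate_dataset(synthetic_config(n_proteins = 3,
                                             length_range = c(10L, 20L),
                                             seed = 42))
  dir <- withr::local_tempdir()
  man <- write_dataset(prots, dir)
  back <- read_manifest(man)
  expect_length(back, 3)
  for (i in seq_along(prots)) {
    expect_identical(back[[i]]$sequence, prots[[i]]$sequence)
    expect_equal(back[[i]]$pssm, prots[[i]]$pssm)
    expect_identical(back[[i]]$pss, prots[[i]]$pss)
    expect_identical(back[[i]]$shape, prots[[i]]$shape)
    expect_identical(back[[i]]$labels, prots[[i]]$labels)
  }
})

test_that("manifest validation catches sequence/profile disagreement", {
  prots <- simulate_dataset(synthetic_config(n_proteins = 1,
                                             length_range = c(10L, 10L),
                                             seed = 1))
  dir <- withr::local_tempdir()
  man <- write_dataset(prots, dir)
  fa <- file.path(dir, paste0(prots[[1]]$id, ".fasta"))
  writeLines(c(paste0(">", prots[[1]]$id), strrep("W", 10)), fa)
  expect_error(read_manifest(man), "disagree")
})

test_that("two-column TSV state files are accepted", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "x.pss")
  writeLines(paste(3:1, c("C", "E", "H"), sep = "\t"), f)
  expect_identical(betaturn:::read_state_file(f, "pss"), "HEC")
})

test_that("protein_record enforces its invariants", {
  expect_error(protein_record("x", "ACD", matrix(0, 3, 19), "CCC"),
               "20 columns")
  expect_error(protein_record("x", "ACD", matrix(0, 2, 20), "CCC"), "rows")
  expect_error(protein_record("x", "ACD", matrix(0, 3, 20), "CC"), "length")
  expect_error(protein_record("x", "ACD", matrix(0, 3, 20), "CCZ"),
               "invalid pss symbol 'Z'")
  expect_error(protein_record("x", "ACD", matrix(0, 3, 20), "CCC",
                              labels = c(0, 1, 2)), "0/1")
})
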