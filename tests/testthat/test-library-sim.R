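test_that("generated clones honor the CDR length design", {
  lib <- generate_library(default_library_design(), M = 1000, seed = 1)
  expect_identical(nrow(lib), 1000L)
  expect_true(all(nchar(lib$cdr1) == 7L))
  expect_true(all(nchar(lib$cdr2) == 7L))
  expect_true(all(lib$cdr3_len %in% c(9L, 12L, 15L, 18L)))
  expect_identical(nchar(lib$cdr3), lib$cdr3_len)
  # DNA is the in-frame realization of the protein
  i <- sample.int(1000L, 5L)
  for (k in i) expect_identical(translate_dna(lib$dna[k]), lib$protein[k])
})

test_that("point-mass designs yield identical clones; seeds reproduce", {
  point <- position_profile(c(A = 1))
  d <- library_design(
    baseline_scaffold(),
    cdr_design("CDR1", rep(list(point), 7)),
    cdr_design("CDR2", rep(list(point), 7)),
    cdr_design("CDR3", rep(list(point), 9), length_weights = c("9" = 1)),
    nominal_size = 10, template_molecules = 10)
  lib <- generate_library(d, M = 20, seed = 3)
  expect_identical(length(unique(lib$protein)), 1L)
  expect_identical(length(unique(lib$dna)), 1L)

  a <- generate_library(default_library_design(), M = 50, seed = 9)
  b <- generate_library(default_library_design(), M = 50, seed = 9)
  expect_identical(a, b)
})

test_that("per-position residue frequencies track the design profiles", {
  M <- 20000L  # scaled down from 1e5 to keep the suite fast; bands widen
  d <- default_library_design()
  lib <- generate_library(d, M = M, seed = 17)
  chars <- matrix(unlist(strsplit(lib$cdr1, "")), nrow = M, byrow = TRUE)
  for (j in c(1L, 4L, 7L)) {
    p <- d$cdr1$profiles[[j]]
    for (aa in c("S", "G", "Y", "F")) {
      phat <- mean(chars[, j] == aa)
      se <- sqrt(p[[aa]] * (1 - p[[aa]]) / M)
      expect_lt(abs(phat - p[[aa]]), 3.5 * se + 1e-9)
    }
  }
})

test_that("defect injection produces verifiable lesions", {
  lib <- generate_library(default_library_design(), M = 10, seed = 4)
  clone <- lib[1, ]

  fs <- inject_defect(clone, "frameshift", seed = 5)
  expect_identical(nchar(fs$dna), nchar(clone$dna) - 1L)
  expect_identical(fs$truth_defect, "frameshift")

  st <- inject_defect(clone, "in_frame_stop", seed = 6)
  expect_identical(nchar(st$dna), nchar(clone$dna))
  prot <- translate_dna(st$dna)
  stop_at <- regexpr("*", prot, fixed = TRUE)
  fr4_start_aa <- 103L + clone$cdr3_len + 1L
  expect_gt(stop_at, 0L)
  expect_lt(stop_at, fr4_start_aa)  # stop falls before FR4

  mr1 <- inject_defect(clone, "missing_region", seed = 7, variant = "cdr1")
  expect_identical(nchar(mr1$dna), nchar(clone$dna) - 21L)
  mr2 <- inject_defect(clone, "missing_region", seed = 7,
                       variant = "cdr1_fr2_cdr2")
  expect_identical(nchar(mr2$dna), nchar(clone$dna) - 3L * (7L + 20L + 7L))

  em <- inject_defect(clone, "empty", seed = 8)
  expect_false(grepl(scaffold_dna(baseline_scaffold())[["FR1"]], em$dna,
                     fixed = TRUE))
  expect_identical(inject_defect(clone, "ok"), clone)
  em2 <- inject_defect(em, "empty", seed = 9)
  expect_match(attr(em2, "noop"), "already-empty")
})

test_that("the Sanger fixture is deterministic with 13 seeded defects", {
  fx <- make_sanger_fixture()
  expect_identical(nrow(fx), 315L)
  truth <- attr(fx, "truth")
  expect_identical(sum(truth$truth_defect != "ok"), 13L)
  tab <- table(truth$truth_defect)
  expect_identical(as.integer(tab[c("in_frame_stop", "frameshift",
                                    "missing_region", "empty")]),
                   c(4L, 4L, 3L, 2L))
  expect_identical(make_sanger_fixture(), fx)  # byte-identical

  clean <- make_sanger_fixture(defect_counts = c(in_frame_stop = 0L),
                               n_clones = 50L)
  expect_true(all(attr(clean, "truth")$truth_defect == "ok"))
})

test_that("read emission: identity at zero noise, involution under flips", {
  lib <- generate_library(default_library_design(), M = 30, seed = 10)
  reads <- emit_reads(lib, seed = 1)
  expect_identical(reads$sequence, lib$dna)

  flipped <- emit_reads(lib, profile = list(flip_prob = 1), seed = 1)
  expect_true(all(flipped$flipped))
  back <- vapply(flipped$sequence,
                 function(s) as.character(
                   Biostrings::reverseComplement(Biostrings::DNAString(s))),
                 character(1), USE.NAMES = FALSE)
  expect_identical(back, lib$dna)
})

test_that("substitution noise hits the configured rate", {
  lib <- generate_library(default_library_design(), M = 2000, seed = 11)
  rate <- 0.01
  reads <- emit_reads(lib, profile = list(substitution_rate = rate), seed = 2)
  mismatches <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, lib$dna, reads$sequence)
  n_bases <- sum(nchar(lib$dna))
  phat <- sum(mismatches) / n_bases
  se <- sqrt(rate * (1 - rate) / n_bases)
  expect_lt(abs(phat - rate), 3.5 * se)
})

test_that("cytometry events encode the designed subpopulations", {
  ev0 <- generate_cytometry_events(500, transfected_fraction = 0, seed = 1)
  expect_true(all(ev0$truth == "untransfected"))

  ev <- generate_cytometry_events(1e5, transfected_fraction = 0.4,
                                  gfp_medians = c(untransfected = 1000,
                                                  transfected = 300),
                                  seed = 2)
  kd <- knockdown_percentage(ev, mcherry_threshold = 320)
  expect_equal(kd$percentage, 30, tolerance = 2)  # quantile sampling error
  expect_identical(generate_cytometry_events(100, 0.5, seed = 3),
                   generate_cytometry_events(100, 0.5, seed = 3))
})

test_that("panning enrichment follows closed-form geometric growth", {
  f0 <- rep(0.25, 4)
  flat <- simulate_panning_pool(f0, rep(2, 4), rounds = 3)
  for (r in 1:4) expect_equal(unname(flat[r, ]), f0)
  expect_true(all(abs(rowSums(flat) - 1) < 1e-12))

  f0 <- rep(1 / 100, 100)
  e <- c(10, rep(1, 99))
  traj <- simulate_panning_pool(f0, e, rounds = 5)
  # closed form: f_r = f0*10^r / (f0*10^r + (1-f0))
  for (r in 0:5) {
    pred <- f0[1] * 10^r / (f0[1] * 10^r + (1 - f0[1]))
    expect_equal(unname(traj[r + 1, 1]), pred, tolerance = 1e-12)
  }
  # 10^r > (1 - f0)/f0 = 99 first holds at round 2
  expect_gt(traj[3, 1], 0.5)
  expect_lt(traj[2, 1], 0.5)
})
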