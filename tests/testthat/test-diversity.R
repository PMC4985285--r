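test_that("repertoire profiles equal brute-force column counts", {
  p <- profile_from_repertoire(c("AY", "AY", "GY"))
  expect_equal(p[[1]][["A"]], 2 / 3)
  expect_equal(p[[1]][["G"]], 1 / 3)
  expect_equal(p[[2]][["Y"]], 1)

  one <- profile_from_repertoire("QVQ")
  expect_true(all(vapply(one, max, numeric(1)) == 1))

  set.seed(5)
  seqs <- random_aa_seqs(50, 7)
  profs <- profile_from_repertoire(seqs)
  for (j in 1:7)
    expect_equal(unname(as.numeric(profs[[j]])),
                 unname(brute_column_freq(seqs, j, AA_CANONICAL)))
  expect_error(profile_from_repertoire(character(0)), "empty")
  expect_error(profile_from_repertoire(c("AA", "A")), "equal length")
})

test_that("constrain_profile caps hydrophobic mass and renormalizes", {
  p <- position_profile(c(F = 0.5, A = 0.5))
  q <- constrain_profile(p, banned = "C", hydrophobic_set = "F", cap = 0.1)
  expect_equal(q[["F"]], 0.1)
  expect_equal(q[["A"]], 0.9)

  # banning Cys on a Cys-free profile with low hydrophobic mass is identity
  r <- position_profile(c(A = 0.5, S = 0.4, F = 0.1))
  expect_equal(as.numeric(constrain_profile(r, cap = 0.15)),
               as.numeric(r))

  set.seed(6)
  for (i in 1:25) {
    p <- random_profile(support = AA_CANONICAL)
    cap <- runif(1, 0.05, 0.5)
    q <- constrain_profile(p, banned = "C", cap = cap)
    expect_equal(sum(q), 1, tolerance = 1e-12)
    expect_identical(q[["C"]], 0)
    expect_lte(sum(q[AA_HYDROPHOBIC]), cap + 1e-12)
  }
  expect_error(constrain_profile(position_profile(c(C = 1)), banned = "C"),
               "banned")
})

test_that("codon mixes translate back to the profile exactly, no stops/Cys", {
  m <- codon_mix_for_profile(position_profile(c(A = 1)))
  expect_equal(unclass(m), c(GCG = 1), ignore_attr = TRUE)

  set.seed(7)
  for (i in 1:25) {
    p <- random_profile()  # Cys-free support
    mix <- codon_mix_for_profile(p)
    expect_false(any(names(mix) %in% c("TAA", "TAG", "TGA")))
    expect_false(any(names(mix) == default_codon_table()[["C"]]))
    back <- translate_codon_mix(mix)
    expect_equal(sum(mix), 1, tolerance = 1e-12)
    supp <- names(p)[p > 0]
    expect_setequal(names(back), supp)
    expect_equal(back[supp], as.numeric(p[supp]), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  expect_error(
    codon_mix_for_profile(position_profile(c(A = 1)),
                          codon_choice = c(G = "GGC")),
    "missing codon")
})

test_that("NNK mode admits stop codons, as degenerate schemes must", {
  nnk <- nnk_codon_mix()
  aa <- translate_codon_mix(nnk)
  expect_true("*" %in% names(aa))   # TAG survives NNK
  expect_true("C" %in% names(aa))
  expect_equal(sum(aa), 1, tolerance = 1e-12)
})

test_that("sequence_space_size equals exhaustive enumeration on toy designs", {
  s <- baseline_scaffold()
  point <- position_profile(c(A = 1))
  p3 <- position_profile(c(A = 0.5, G = 0.3, S = 0.2))

  # 2 positions x 3 residues, 2 CDR3 lengths -> enumerate everything
  toy <- library_design(
    s,
    cdr1 = cdr_design("CDR1", rep(list(point), 7)),
    cdr2 = cdr_design("CDR2", rep(list(point), 7)),
    cdr3 = cdr_design("CDR3", list(p3, p3),
                      length_weights = c("1" = 0.5, "2" = 0.5)),
    nominal_size = 10, template_molecules = 100)
  # brute force: 3 sequences of length 1 plus 3x3 of length 2
  enum <- c("A", "G", "S",
            as.vector(outer(c("A", "G", "S"), c("A", "G", "S"), paste0)))
  expect_identical(as.character(sequence_space_size(toy)),
                   as.character(length(unique(enum))))

  # all point-mass -> single sequence
  single <- library_design(
    s, cdr_design("CDR1", rep(list(point), 7)),
    cdr_design("CDR2", rep(list(point), 7)),
    cdr_design("CDR3", rep(list(point), 9),
               length_weights = c("9" = 1)),
    nominal_size = 1, template_molecules = 1)
  expect_identical(as.character(sequence_space_size(single)), "1")

  # CDR3-only design at length 9 with 19-residue support: 19^9, exact digits
  free <- position_profile(setNames(rep(1 / 19, 19),
                                    setdiff(AA_CANONICAL, "C")))
  d19 <- library_design(
    s, cdr_design("CDR1", rep(list(point), 7)),
    cdr_design("CDR2", rep(list(point), 7)),
    cdr_design("CDR3", rep(list(free), 9), length_weights = c("9" = 1)),
    nominal_size = 10, template_molecules = 100)
  expect_identical(as.character(sequence_space_size(d19)),
                   format(19^9, scientific = FALSE))  # 322687697779 < 2^53
})

test_that("default design sequence space is an exact huge integer", {
  n <- sequence_space_size(default_library_design())
  # 19^14 CDR1/2 combinations times sum over CDR3 lengths of 19^L; the
  # result must be exact decimal digits, far beyond double precision
  expect_true(nchar(n) > 30)
  expect_match(as.character(n), "^[0-9]+$")
})

test_that("collision probability matches the extended-precision oracle", {
  expect_identical(collision_probability(1, 10), 0)
  expect_identical(collision_probability(0, 10), 0)
  expect_identical(collision_probability(3, 2), 1)

  for (case in list(c(315, 3e9), c(100, 1e6), c(50, 1e3), c(23, 365))) {
    got <- collision_probability(case[1], case[2])
    want <- collision_oracle_dd(case[1], case[2])
    expect_equal(got, want, tolerance = 1e-12)
  }
  # approximate mode close to exact in the sparse regime
  expect_equal(collision_probability(315, 3e9, method = "approx"),
               collision_probability(315, 3e9), tolerance = 1e-3)
})

test_that("collision probability is monotone in n and N", {
  n_grid <- c(2, 10, 50, 200, 1000)
  p_n <- vapply(n_grid, collision_probability, numeric(1), N = 1e6)
  expect_true(all(diff(p_n) > 0))
  N_grid <- c(1e4, 1e5, 1e6, 1e7)
  p_N <- vapply(N_grid, function(N) collision_probability(100, N), numeric(1))
  expect_true(all(diff(p_N) < 0))
})

test_that("compare_profiles is the total-variation distance", {
  p <- list(position_profile(c(A = 1)), position_profile(c(G = 0.5, S = 0.5)))
  expect_equal(compare_profiles(p, p)$per_position, c(0, 0))

  q <- list(position_profile(c(Y = 1)), position_profile(c(W = 1)))
  expect_equal(compare_profiles(p, q)$per_position, c(1, 1))

  set.seed(8)
  for (i in 1:10) {
    a <- list(random_profile(), random_profile())
    b <- list(random_profile(), random_profile())
    got <- compare_profiles(a, b)
    direct <- vapply(1:2, function(j)
      0.5 * sum(abs(as.numeric(a[[j]]) - as.numeric(b[[j]]))), numeric(1))
    expect_equal(got$per_position, direct)
    # symmetry
    expect_equal(compare_profiles(b, a)$per_position, got$per_position)
    expect_true(all(got$per_position >= 0 & got$per_position <= 1))
  }
  expect_error(compare_profiles(p, p[1]), "equal position counts")
})

test_that("every default-design profile is normalized and Cys-free", {
  d <- default_library_design()
  all_profiles <- c(d$cdr1$profiles, d$cdr2$profiles, d$cdr3$profiles)
  for (p in all_profiles) {
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_identical(p[["C"]], 0)
    expect_lte(sum(p[AA_HYDROPHOBIC]), 0.15 + 1e-12)
  }
  expect_equal(sum(d$cdr3$length_weights), 1)
})
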