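#' Create a per-position amino-acid profile
#'
#' A position profile is a categorical distribution over the 20 canonical
#' amino acids. Probabilities must be non-negative and sum to 1 (tolerance
#' 1e-9); residues absent from `probs` get probability exactly 0.
#'
#' @param probs Named numeric vector of residue probabilities.
#' @return Named numeric vector of length 20 (class `position_profile`).
#' @export
position_profile <- function(probs) {
  if (!length(probs)) stop("empty profile")
  bad <- setdiff(names(probs), AA_CANONICAL)
  if (length(bad)) stop("non-canonical residues: ", paste(bad, collapse = ","))
  if (any(probs < 0)) stop("negative probability")
  s <- sum(probs)
  if (abs(s - 1) > 1e-9)
    stop("profile probabilities sum to ", format(s), ", not 1")
  full <- setNames(numeric(20L), AA_CANONICAL)
  full[names(probs)] <- probs
  structure(full, class = "position_profile")
}

profile_support <- function(profile) names(profile)[profile > 0]

#' Per-position profiles from an aligned repertoire
#'
#' Computes per-column relative amino-acid frequencies from equal-length
#' aligned CDR sequences (the natural-repertoire route for shaping designed
#' diversity).
#'
#' @param aligned_cdrs Character vector of equal-length amino-acid strings.
#' @param pseudocount Added to every canonical residue count per column
#'   before normalization (default 0).
#' @return List of [position_profile()]s, one per column.
#' @examples
#' profile_from_repertoire(c("AY", "AY", "GY"))[[1]][c("A", "G")]
#' @export
profile_from_repertoire <- function(aligned_cdrs, pseudocount = 0) {
  if (!length(aligned_cdrs)) stop("empty input")
  lens <- nchar(aligned_cdrs)
  if (length(unique(lens)) != 1L) stop("sequences must have equal lengths")
  L <- lens[[1L]]
  chars <- matrix(unlist(strsplit(aligned_cdrs, "")),
                  nrow = length(aligned_cdrs), ncol = L, byrow = TRUE)
  lapply(seq_len(L), function(j) {
    counts <- table(factor(chars[, j], levels = AA_CANONICAL)) + pseudocount
    position_profile(setNames(as.numeric(counts) / sum(counts), AA_CANONICAL))
  })
}

#' Constrain a position profile
#'
#' Zeroes banned residues, caps the total mass on a hydrophobic set by
#' proportional down-scaling, and renormalizes to 1.
#'
#' @param profile A [position_profile()].
#' @param banned Residues forced to probability 0 (default cysteine, which
#'   is excluded from all CDR positions by design).
#' @param hydrophobic_set Residues whose combined mass is capped.
#' @param cap Maximum combined probability of `hydrophobic_set` (in `[0,1]`).
#' @return The constrained [position_profile()].
#' @examples
#' p <- position_profile(c(F = 0.5, A = 0.5))
#' constrain_profile(p, banned = "C", hydrophobic_set = "F", cap = 0.1)[["F"]]
#' @export
constrain_profile <- function(profile, banned = "C",
                              hydrophobic_set = AA_HYDROPHOBIC, cap = 0.15) {
  stopifnot(cap >= 0, cap <= 1)
  p <- as.numeric(profile)
  names(p) <- names(profile)
  p[names(p) %in% banned] <- 0
  tot <- sum(p)
  if (tot <= 0) stop("all profile mass banned")
  p <- p / tot
  hyd <- names(p) %in% hydrophobic_set & !(names(p) %in% banned)
  hmass <- sum(p[hyd])
  if (hmass > cap) {
    other <- sum(p[!hyd])
    if (other <= 0) stop("cannot cap hydrophobic mass: no residual support")
    p[hyd] <- p[hyd] * (cap / hmass)
    p[!hyd] <- p[!hyd] * ((1 - cap) / other)
  }
  position_profile(p / sum(p))
}

#' CDR design
#'
#' Bundles ordered position profiles for one CDR; for CDR3 additionally a
#' mixture over loop lengths. CDR1/CDR2 must have exactly 7 profiles, and no
#' profile may assign mass to cysteine.
#'
#' @param region_name "CDR1", "CDR2" or "CDR3".
#' @param profiles List of [position_profile()]s. For CDR3 supply profiles
#'   for the longest designed length; shorter loops use the first `L`.
#' @param length_weights For CDR3: named numeric vector of length weights
#'   (names are lengths) summing to 1.
#' @return A `cdr_design` object.
#' @export
cdr_design <- function(region_name, profiles, length_weights = NULL) {
  stopifnot(region_name %in% c("CDR1", "CDR2", "CDR3"))
  if (region_name != "CDR3" && length(profiles) != 7L)
    stop(region_name, " requires exactly 7 position profiles")
  for (p in profiles)
    if (p[["C"]] > 0) stop("CDR profiles must carry zero cysteine mass")
  if (region_name == "CDR3") {
    if (is.null(length_weights))
      length_weights <- setNames(rep(0.25, 4), CDR3_DESIGN_LENGTHS)
    if (abs(sum(length_weights) - 1) > 1e-9)
      stop("CDR3 length weights must sum to 1")
    if (max(as.integer(names(length_weights))) > length(profiles))
      stop("not enough profiles for the longest CDR3 length")
  }
  structure(list(region_name = region_name, profiles = profiles,
                 length_weights = length_weights),
            class = "cdr_design")
}

#' Codon mix realizing a position profile
#'
#' Maps a designed amino-acid distribution to a trinucleotide mix. With one
#' preferred codon per residue (the trinucleotide-synthesis route) the
#' translated distribution of the mix equals the profile exactly and no stop
#' codon can occur.
#'
#' @param profile A [position_profile()].
#' @param codon_choice Named residue-to-codon vector.
#' @return A `codon_mix`: named numeric vector of codon fractions.
#' @export
codon_mix_for_profile <- function(profile, codon_choice = default_codon_table()) {
  supp <- profile_support(profile)
  miss <- setdiff(supp, names(codon_choice))
  if (length(miss))
    stop("missing codon assignment for: ", paste(miss, collapse = ", "))
  codons <- codon_choice[supp]
  if (any(codons %in% STOP_CODONS))
    stop("codon choice maps a residue to a stop codon")
  mix <- tapply(as.numeric(profile[supp]), codons, sum)
  structure(setNames(as.numeric(mix), names(mix)), class = "codon_mix")
}

#' Translate a codon mix back to an amino-acid distribution
#'
#' @param mix A `codon_mix`.
#' @return Named numeric vector over the residues the mix encodes.
#' @export
translate_codon_mix <- function(mix) {
  aa <- vapply(names(mix), function(cod) {
    if (cod %in% STOP_CODONS) "*" else
      as.character(Biostrings::GENETIC_CODE[[cod]])
  }, character(1))
  out <- tapply(as.numeric(mix), aa, sum)
  setNames(as.numeric(out), names(out))
}

#' Degenerate NNK codon mix (comparison mode)
#'
#' The classical NNK degenerate-codon scheme (N = A/C/G/T, K = G/T),
#' provided for comparison with trinucleotide mixes. Unlike trinucleotide
#' assembly it cannot exclude stop codons (TAG) or cysteine, nor realize an
#' arbitrary designed distribution.
#'
#' @return A `codon_mix` over the 32 NNK codons (uniform).
#' @export
nnk_codon_mix <- function() {
  nts <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(nts, nts, paste0)),
                            c("G", "T"), paste0))
  structure(setNames(rep(1 / length(codons), length(codons)), codons),
            class = "codon_mix")
}

#' Full library design
#'
#' @param scaffold A [scaffold_model()].
#' @param cdr1,cdr2,cdr3 [cdr_design()] objects.
#' @param codon_table Residue-to-codon table used for DNA realization.
#' @param nominal_size Nominal library size N in clones (> 0).
#' @param template_molecules Template molecule count T (>= N).
#' @return A `library_design` object.
#' @export
library_design <- function(scaffold, cdr1, cdr2, cdr3,
                           codon_table = default_codon_table(),
                           nominal_size = 3e9, template_molecules = 2e11) {
  stopifnot(inherits(scaffold, "scaffold_model"),
            nominal_size > 0, template_molecules >= nominal_size)
  structure(list(scaffold = scaffold, cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
                 codon_table = codon_table, nominal_size = nominal_size,
                 template_molecules = template_molecules),
            class = "library_design")
}

# natural-repertoire-shaped residue weights used by the default design for
# CDR1/CDR2 (S/G/Y/T-rich, as in camelid loops); normalized + constrained at
# construction
natural_cdr_weights <- function() {
  c(S = 12, G = 10, Y = 9, T = 9, A = 8, D = 7, N = 7, R = 7,
    I = 5, L = 5, V = 5, E = 4, F = 4, K = 4, Q = 3, H = 2,
    P = 2, W = 2, M = 1)
}

#' Default library design
#'
#' The package's stated design: CDR1 and CDR2 fixed at 7 positions with
#' natural-repertoire-shaped profiles; CDR3 drawn from four lengths
#' (9/12/15/18, uniform weights) with near-uniform profiles; cysteine banned
#' at every CDR position; hydrophobic mass (F,I,L,V,W,M) capped at 0.15 per
#' position; one preferred codon per residue.
#'
#' @param scaffold Scaffold to design around (default [baseline_scaffold()]).
#' @param hydrophobic_cap Per-position cap on hydrophobic mass.
#' @param cdr3_weights CDR3 length mixture (names 9/12/15/18).
#' @return A [library_design()].
#' @export
default_library_design <- function(scaffold = baseline_scaffold(),
                                   hydrophobic_cap = 0.15,
                                   cdr3_weights = NULL) {
  w <- natural_cdr_weights()
  nat <- constrain_profile(position_profile(w / sum(w)),
                           cap = hydrophobic_cap)
  unif <- constrain_profile(
    position_profile(setNames(rep(1 / 19, 19), setdiff(AA_CANONICAL, "C"))),
    cap = hydrophobic_cap)
  library_design(
    scaffold = scaffold,
    cdr1 = cdr_design("CDR1", rep(list(nat), 7L)),
    cdr2 = cdr_design("CDR2", rep(list(nat), 7L)),
    cdr3 = cdr_design("CDR3", rep(list(unif), max(CDR3_DESIGN_LENGTHS)),
                      length_weights = cdr3_weights))
}

#' Exact sequence-space size of a design
#'
#' Number of distinct CDR-combination proteins a design can emit: the product
#' of per-position support sizes, summed over CDR3 lengths. Computed in exact
#' arbitrary-precision integer arithmetic (no floating-point rounding).
#'
#' @param design A [library_design()].
#' @return Decimal integer as a character string, with attribute
#'   `approx` holding a double approximation.
#' @export
sequence_space_size <- function(design) {
  base <- big_one()
  for (p in design$cdr1$profiles) base <- big_mul_small(base, length(profile_support(p)))
  for (p in design$cdr2$profiles) base <- big_mul_small(base, length(profile_support(p)))
  total <- big_zero()
  for (L in as.integer(names(design$cdr3$length_weights))) {
    if (design$cdr3$length_weights[[as.character(L)]] <= 0) next
    term <- base
    for (p in design$cdr3$profiles[seq_len(L)])
      term <- big_mul_small(term, length(profile_support(p)))
    total <- big_add(total, term)
  }
  out <- big_to_string(total)
  attr(out, "approx") <- as.numeric(out)
  out
}

#' Collision (redundancy) probability of a clone sample
#'
#' Probability that at least two of `n` uniform draws from a library of `N`
#' distinct clones coincide — the birthday-problem check behind "no redundant
#' clone among the sampled picks". The exact product
#' `1 - prod_{i=0}^{n-1}(1 - i/N)` is evaluated in a numerically stable way
#' via `-expm1(sum(log1p(-i/N)))`.
#'
#' @param n Number of sampled clones (>= 0).
#' @param N Number of distinct clones in the library (>= 1).
#' @param method `"exact"` (default) or `"approx"` for the classical
#'   `1 - exp(-n(n-1)/(2N))` approximation.
#' @return Collision probability in `[0, 1]`.
#' @examples
#' collision_probability(315, 3e9)
#' @export
collision_probability <- function(n, N, method = c("exact", "approx")) {
  method <- match.arg(method)
  stopifnot(n >= 0, N >= 1)
  if (method == "approx") return(-expm1(-n * (n - 1) / (2 * N)))
  if (n > N) return(1)
  if (n < 2) return(0)
  i <- seq_len(n - 1)
  -expm1(sum(log1p(-i / N)))
}

#' Compare designed and observed profile lists
#'
#' Per-position total-variation distance `0.5 * sum(|p - q|)` between two
#' equally long lists of position profiles, plus the maximum and mean.
#' Symmetric in its arguments.
#'
#' @param designed,observed Lists of [position_profile()]s of equal length.
#' @return List with `per_position` (numeric vector), `max`, `mean`.
#' @export
compare_profiles <- function(designed, observed) {
  if (length(designed) != length(observed))
    stop("profile lists must have equal position counts")
  tv <- vapply(seq_along(designed), function(i) {
    p <- as.numeric(designed[[i]])[match(AA_CANONICAL, names(designed[[i]]))]
    q <- as.numeric(observed[[i]])[match(AA_CANONICAL, names(observed[[i]]))]
    0.5 * sum(abs(p - q))
  }, numeric(1))
  list(per_position = tv, max = max(tv), mean = mean(tv))
}

## ---- minimal exact big-integer arithmetic (base 1e4 digit vectors) ----
## support sizes are <= 20 and position counts small, so products of small
## multipliers and additions are all that is needed; kept internal.

big_zero <- function() integer(0)
big_one <- function() 1L

big_mul_small <- function(x, k) {
  stopifnot(k >= 0, k < 1e4)
  if (length(x) == 0L || k == 0L) return(big_zero())
  prod <- as.integer(x) * as.integer(k)
  carry <- 0
  out <- integer(0)
  for (d in prod) {
    v <- d + carry
    out <- c(out, v %% 10000L)
    carry <- v %/% 10000L
  }
  while (carry > 0) {
    out <- c(out, carry %% 10000L)
    carry <- carry %/% 10000L
  }
  out
}

big_add <- function(x, y) {
  n <- max(length(x), length(y))
  if (n == 0L) return(big_zero())
  x <- c(x, integer(n - length(x)))
  y <- c(y, integer(n - length(y)))
  s <- x + y
  carry <- 0L
  out <- integer(0)
  for (d in s) {
    v <- d + carry
    out <- c(out, v %% 10000L)
    carry <- v %/% 10000L
  }
  if (carry > 0L) out <- c(out, carry)
  out
}

big_to_string <- function(x) {
  if (length(x) == 0L) return("0")
  digits <- rev(x)
  paste0(digits[1],
         paste(sprintf("%04d", digits[-1]), collapse = ""))
}
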