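DEFECT_CLASSES <- c("ok", "in_frame_stop", "frameshift", "missing_region",
                    "empty")

#' Generate an in-silico clone library
#'
#' Draws `M` clones i.i.d. from a library design: CDR3 length from the
#' design's length mixture, each CDR residue from its position profile, and
#' DNA realized through the design's trinucleotide codon assignment.
#' Reproducible under a fixed seed.
#'
#' @param design A [library_design()].
#' @param M Number of clones (>= 1).
#' @param seed Integer seed.
#' @return A `clone_set`: data.frame with columns `clone_id`, `dna`,
#'   `protein`, `cdr1`, `cdr2`, `cdr3`, `cdr3_len`, `truth_defect`.
#' @examples
#' lib <- generate_library(default_library_design(), M = 5, seed = 1)
#' nchar(lib$cdr1)
#' @export
generate_library <- function(design, M, seed = 1L) {
  stopifnot(inherits(design, "library_design"), M >= 1)
  M <- as.integer(M)
  set.seed(seed)
  scaffold <- design$scaffold
  ct <- design$codon_table

  # sample() treats a length-1 vector as 1:x; guard against that
  sample_vec <- function(x, n, prob) {
    if (length(x) == 1L) rep(x, n)
    else sample(x, n, replace = TRUE, prob = prob)
  }
  sample_region <- function(cdr, L, n) {
    # n x L residue matrix drawn column-wise from the position profiles
    mat <- matrix("", nrow = n, ncol = L)
    for (j in seq_len(L)) {
      p <- cdr$profiles[[j]]
      supp <- profile_support(p)
      mat[, j] <- sample_vec(supp, n, as.numeric(p[supp]))
    }
    mat
  }
  collapse <- function(mat) do.call(paste0, as.data.frame(mat,
                                                          stringsAsFactors = FALSE))
  to_dna <- function(mat) collapse(matrix(ct[mat], nrow = nrow(mat)))

  cdr1_mat <- sample_region(design$cdr1, 7L, M)
  cdr2_mat <- sample_region(design$cdr2, 7L, M)
  w <- design$cdr3$length_weights
  lens <- as.integer(names(w))
  cdr3_len <- sample_vec(lens, M, as.numeric(w))
  cdr3 <- character(M)
  cdr3_dna <- character(M)
  for (L in unique(cdr3_len)) {
    idx <- which(cdr3_len == L)
    mat <- sample_region(design$cdr3, L, length(idx))
    cdr3[idx] <- collapse(mat)
    cdr3_dna[idx] <- to_dna(mat)
  }
  cdr1 <- collapse(cdr1_mat)
  cdr2 <- collapse(cdr2_mat)
  frs <- scaffold$frameworks
  fr_dna <- scaffold_dna(scaffold, ct)
  protein <- paste0(frs[["FR1"]], cdr1, frs[["FR2"]], cdr2, frs[["FR3"]],
                    cdr3, frs[["FR4"]])
  dna <- paste0(fr_dna[["FR1"]], to_dna(cdr1_mat), fr_dna[["FR2"]],
                to_dna(cdr2_mat), fr_dna[["FR3"]], cdr3_dna,
                fr_dna[["FR4"]])
  structure(
    data.frame(clone_id = sprintf("clone%06d", seq_len(M)), dna = dna,
               protein = protein, cdr1 = cdr1, cdr2 = cdr2, cdr3 = cdr3,
               cdr3_len = cdr3_len, truth_defect = "ok",
               stringsAsFactors = FALSE),
    class = c("clone_set", "data.frame"), design_seed = seed)
}

# deterministic synthetic stuffer standing in for the ccdB suicide-gene
# insert of an empty clone: no scaffold anchors, fixed content
stuffer_sequence <- function(length_nt = 450L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(8712L)
  paste(sample(c("A", "C", "G", "T"), length_nt, replace = TRUE),
        collapse = "")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Inject a construction defect into a clone
#'
#' Applies one of the defect classes observed in synthetic library
#' construction: an in-frame stop codon (one sense codon replaced by a stop
#' before FR4), a frameshift (exactly one base deleted), a missing region
#' (the CDR1 span, or the CDR1 through CDR2 span, excised; chosen 50/50
#' unless forced), or an empty clone (insert replaced by the vector
#' stuffer). Defect positions are uniform within the eligible span, which
#' excludes the FR1 and FR4 anchors so that every class remains verifiable
#' from the DNA alone.
#'
#' @param clone One-row `clone_set` record.
#' @param class Defect class (see `DEFECT_CLASSES`); `"ok"` is a no-op.
#' @param seed Integer seed.
#' @param variant For `missing_region`: `"cdr1"`, `"cdr1_fr2_cdr2"` or
#'   `NULL` (random 50/50).
#' @return The modified one-row record with `truth_defect` updated.
#' @export
inject_defect <- function(clone, class, seed = 1L, variant = NULL) {
  stopifnot(class %in% DEFECT_CLASSES, nrow(clone) == 1L)
  if (class == "ok") return(clone)
  if (class == "empty" && clone$truth_defect == "empty") {
    attr(clone, "noop") <- "empty applied to already-empty clone"
    return(clone)
  }
  set.seed(seed)
  L3 <- clone$cdr3_len
  fr4_start_aa <- 103L + L3 + 1L
  dna <- clone$dna
  if (class == "in_frame_stop") {
    pos_aa <- sample(26:(103L + L3), 1L)   # CDR1 start .. CDR3 end
    stop_codon <- sample(STOP_CODONS, 1L)
    substr(dna, 3L * (pos_aa - 1L) + 1L, 3L * pos_aa) <- stop_codon
  } else if (class == "frameshift") {
    pos_nt <- sample.int(3L * (fr4_start_aa - 1L), 1L)  # before FR4
    dna <- paste0(substr(dna, 1L, pos_nt - 1L),
                  substr(dna, pos_nt + 1L, nchar(dna)))
  } else if (class == "missing_region") {
    variant <- variant %||% sample(c("cdr1", "cdr1_fr2_cdr2"), 1L)
    span_aa <- if (variant == "cdr1") c(26L, 32L) else c(26L, 59L)
    dna <- paste0(substr(dna, 1L, 3L * (span_aa[1] - 1L)),
                  substr(dna, 3L * span_aa[2] + 1L, nchar(dna)))
  } else if (class == "empty") {
    dna <- stuffer_sequence()
  }
  clone$dna <- dna
  clone$protein <- translate_dna(dna)
  clone$truth_defect <- class
  clone
}

#' Packaged Sanger-scale QC fixture
#'
#' Emulates the Sanger quality-control step of library construction:
#' 315 randomly picked clones of which 13 carry a construction defect. The
#' default per-class split (4 in-frame stop, 4 frameshift, 3 missing region,
#' 2 empty) is a fixture convention; the taxonomy total is what matters.
#' Byte-identical output under a fixed seed.
#'
#' @param seed Pinned fixture seed.
#' @param n_clones Number of clones.
#' @param defect_counts Named integer vector of per-class defect counts.
#' @param design Library design (default [default_library_design()]).
#' @return A `clone_set` of `n_clones` rows; attribute `truth` holds a
#'   data.frame of `clone_id` and `truth_defect`.
#' @export
make_sanger_fixture <- function(seed = 315L, n_clones = 315L,
                                defect_counts = c(in_frame_stop = 4L,
                                                  frameshift = 4L,
                                                  missing_region = 3L,
                                                  empty = 2L),
                                design = default_library_design()) {
  stopifnot(sum(defect_counts) <= n_clones,
            all(names(defect_counts) %in% DEFECT_CLASSES))
  clones <- generate_library(design, n_clones, seed = seed)
  set.seed(seed + 1L)
  total_def <- sum(defect_counts)
  if (total_def > 0) {
    idx <- sample.int(n_clones, total_def)
    classes <- rep(names(defect_counts), times = defect_counts)
    for (k in seq_along(idx)) {
      clones[idx[k], ] <- inject_defect(clones[idx[k], ], classes[k],
                                        seed = seed + 1L + k)
    }
  }
  attr(clones, "truth") <- data.frame(clone_id = clones$clone_id,
                                      truth_defect = clones$truth_defect,
                                      stringsAsFactors = FALSE)
  clones
}

#' Emit sequencing reads from clones
#'
#' Produces one read per clone under a simple platform error profile:
#' optional strand flipping (reverse complement) with a stated probability,
#' then per-base substitutions and indels at the profile rates. A zero-noise
#' profile reproduces the clone DNA exactly.
#'
#' @param clones A `clone_set` (or data.frame with `clone_id`, `dna`).
#' @param profile List with `substitution_rate`, `insertion_rate`,
#'   `deletion_rate`, `flip_prob` (all default 0).
#' @param seed Integer seed.
#' @return A `read_set`: data.frame with `read_id`, `sequence`, `flipped`.
#' @export
emit_reads <- function(clones,
                       profile = list(substitution_rate = 0,
                                      insertion_rate = 0,
                                      deletion_rate = 0,
                                      flip_prob = 0),
                       seed = 1L) {
  set.seed(seed)
  sub_r <- profile$substitution_rate %||% 0
  ins_r <- profile$insertion_rate %||% 0
  del_r <- profile$deletion_rate %||% 0
  flip_p <- profile$flip_prob %||% 0
  n <- nrow(clones)
  seqs <- clones$dna
  flipped <- runif(n) < flip_p
  if (any(flipped))
    seqs[flipped] <- vapply(seqs[flipped], revcomp, character(1),
                            USE.NAMES = FALSE)
  if (sub_r > 0 || ins_r > 0 || del_r > 0)
    seqs <- vapply(seqs, mutate_sequence, character(1), sub_r, ins_r, del_r,
                   USE.NAMES = FALSE)
  structure(
    data.frame(read_id = paste0("read_", clones$clone_id),
               sequence = seqs, flipped = flipped, stringsAsFactors = FALSE),
    class = c("read_set", "data.frame"), profile = profile)
}

mutate_sequence <- function(dna, sub_rate, ins_rate, del_rate) {
  bases <- strsplit(dna, "")[[1]]
  nts <- c("A", "C", "G", "T")
  n <- length(bases)
  ksub <- rbinom(1L, n, sub_rate)
  if (ksub > 0) {
    pos <- sample.int(n, ksub)
    for (p in pos) bases[p] <- sample(setdiff(nts, bases[p]), 1L)
  }
  kdel <- rbinom(1L, n, del_rate)
  if (kdel > 0) bases <- bases[-sample.int(length(bases), kdel)]
  kins <- rbinom(1L, n, ins_rate)
  if (kins > 0) {
    for (i in seq_len(kins)) {
      p <- sample.int(length(bases) + 1L, 1L)
      bases <- append(bases, sample(nts, 1L), after = p - 1L)
    }
  }
  paste(bases, collapse = "")
}

#' Synthetic two-channel cytometry events
#'
#' Emulates a protein-knockdown readout: a mixture of transfected and
#' untransfected cells with log-normal GFP and mCherry intensities. The
#' transfected subpopulation carries the mCherry transfection marker
#' (median `mcherry_separation`-fold above background) and a GFP median set
#' by `gfp_medians["transfected"]`.
#'
#' @param n_events Number of events.
#' @param transfected_fraction Fraction of transfected cells in `[0,1]`.
#' @param gfp_medians Named pair `c(untransfected=, transfected=)` of GFP
#'   medians (arbitrary units).
#' @param mcherry_separation Fold separation of mCherry medians between the
#'   subpopulations.
#' @param seed Integer seed.
#' @param gfp_sdlog,mcherry_sdlog Log-normal shape parameters.
#' @param mcherry_background Median mCherry of untransfected cells.
#' @return data.frame with `gfp`, `mcherry`, `truth` columns.
#' @export
generate_cytometry_events <- function(n_events, transfected_fraction,
                                      gfp_medians = c(untransfected = 1000,
                                                      transfected = 300),
                                      mcherry_separation = 20,
                                      seed = 1L,
                                      gfp_sdlog = 0.5, mcherry_sdlog = 0.4,
                                      mcherry_background = 50) {
  stopifnot(transfected_fraction >= 0, transfected_fraction <= 1)
  set.seed(seed)
  n_t <- rbinom(1L, n_events, transfected_fraction)
  if (transfected_fraction == 0) n_t <- 0L
  if (transfected_fraction == 1) n_t <- n_events
  n_u <- n_events - n_t
  truth <- c(rep("transfected", n_t), rep("untransfected", n_u))
  gfp <- c(stats::rlnorm(n_t, log(gfp_medians[["transfected"]]), gfp_sdlog),
           stats::rlnorm(n_u, log(gfp_medians[["untransfected"]]), gfp_sdlog))
  mch <- c(stats::rlnorm(n_t, log(mcherry_background * mcherry_separation),
                         mcherry_sdlog),
           stats::rlnorm(n_u, log(mcherry_background), mcherry_sdlog))
  out <- data.frame(gfp = gfp, mcherry = mch, truth = truth,
                    stringsAsFactors = FALSE)
  out[sample.int(n_events), , drop = FALSE]
}

#' Simulate phage-display panning enrichment
#'
#' Multiplicative per-round enrichment with renormalization: after each
#' round the frequency of clone `i` is proportional to
#' `f_i * e_i`. Returns the full trajectory.
#'
#' @param initial_frequencies Non-negative numeric vector summing to 1.
#' @param enrichment_factors Positive per-clone enrichment per round.
#' @param rounds Number of rounds (>= 0).
#' @return Matrix of dimension `(rounds + 1) x n`: row `r + 1` holds the
#'   frequencies after round `r`.
#' @export
simulate_panning_pool <- function(initial_frequencies, enrichment_factors,
                                  rounds) {
  stopifnot(length(initial_frequencies) == length(enrichment_factors),
            all(initial_frequencies >= 0), all(enrichment_factors > 0),
            rounds >= 0)
  f <- initial_frequencies / sum(initial_frequencies)
  out <- matrix(NA_real_, nrow = rounds + 1L,
                ncol = length(f))
  out[1L, ] <- f
  for (r in seq_len(rounds)) {
    f <- f * enrichment_factors
    f <- f / sum(f)
    out[r + 1L, ] <- f
  }
  rownames(out) <- paste0("round", 0:rounds)
  out
}
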