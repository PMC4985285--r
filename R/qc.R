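#' Default per-anchor edit-distance tolerance
#'
#' Anchor alignment tolerance scales with anchor length (8% of the anchor,
#' never below 2 edits) so that long framework anchors stay findable at
#' realistic per-base error rates while short anchors remain specific.
#'
#' @param anchor_length Anchor length in nucleotides.
#' @return Integer maximum edit distance.
#' @export
default_anchor_tolerance <- function(anchor_length) {
  pmax(2L, as.integer(ceiling(0.08 * anchor_length)))
}

# leftmost best occurrence of `pattern` in `subject` within max_edit edits.
# Three tiers, cheapest first: exact fixed-string search; a substitution-only
# Hamming scan (keeps the anchor width — and hence the CDR boundaries —
# exact when the read carries only substitutions); and finally an
# indel-tolerant alignment for true insertion/deletion lesions.
find_anchor <- function(subject, pattern, max_edit) {
  hit <- regexpr(pattern, subject, fixed = TRUE)
  if (hit > 0L)
    return(list(found = TRUE, start = as.integer(hit),
                end = as.integer(hit) + nchar(pattern) - 1L, edits = 0L))

  readv <- strsplit(subject, "")[[1L]]
  patv <- strsplit(pattern, "")[[1L]]
  L <- length(patv)
  n <- length(readv)
  if (n >= L) {
    best_s <- NA_integer_
    best_m <- max_edit + 1L
    for (s in seq_len(n - L + 1L)) {
      m <- sum(readv[s:(s + L - 1L)] != patv)
      if (m < best_m) {
        best_m <- m
        best_s <- s
      }
    }
    if (best_m <= max_edit)
      return(list(found = TRUE, start = best_s, end = best_s + L - 1L,
                  edits = best_m))
  }

  subj <- Biostrings::DNAString(subject)
  for (k in seq_len(max_edit)) {
    m <- Biostrings::matchPattern(pattern, subj, max.mismatch = k,
                                  with.indels = TRUE)
    if (length(m) > 0L) {
      i <- which.min(abs(BiocGenerics::width(m) - L))
      return(list(found = TRUE, start = BiocGenerics::start(m)[i],
                  end = BiocGenerics::end(m)[i], edits = k))
    }
  }
  list(found = FALSE, start = NA_integer_, end = NA_integer_,
       edits = NA_integer_)
}

#' Annotate a sequencing read against a scaffold
#'
#' Locates the four framework anchors (realized as DNA through the design's
#' codon table) in a read by tolerant alignment, trying both strands. CDRs
#' are the inter-anchor spans. The inferred defect class is attached via
#' [classify_defect()].
#'
#' @param read Read sequence (character) or one-row `read_set` record.
#' @param scaffold A [scaffold_model()].
#' @param codon_table Residue-to-codon table used for the anchors.
#' @param max_edit Named or unnamed integer vector of per-anchor maximum
#'   edit distances; default scales with anchor length
#'   ([default_anchor_tolerance()]).
#' @param cdr3_lengths Designed CDR3 lengths (for classification).
#' @return A `clone_annotation` list: `read_id`, `orientation`, `frame`,
#'   `anchors` (data.frame), `cdr_dna`, `cdr_aa`, `oriented_sequence`,
#'   `inferred_defect`.
#' @export
annotate_read <- function(read, scaffold = baseline_scaffold(),
                          codon_table = default_codon_table(),
                          max_edit = NULL,
                          cdr3_lengths = CDR3_DESIGN_LENGTHS) {
  if (is.data.frame(read)) {
    read_id <- read$read_id[1L]
    seq <- read$sequence[1L]
  } else {
    read_id <- attr(read, "read_id") %||% "read"
    seq <- as.character(read)
  }
  anchors <- scaffold_dna(scaffold, codon_table)
  tol <- max_edit %||% default_anchor_tolerance(nchar(anchors))
  if (length(tol) == 1L) tol <- rep(tol, 4L)

  locate_all <- function(s) {
    hits <- lapply(seq_along(anchors),
                   function(i) find_anchor(s, anchors[[i]], tol[i]))
    names(hits) <- names(anchors)
    hits
  }
  fwd <- locate_all(seq)
  n_fwd <- sum(vapply(fwd, `[[`, logical(1), "found"))
  if (n_fwd < length(anchors)) {
    rc <- revcomp(seq)
    rev <- locate_all(rc)
    n_rev <- sum(vapply(rev, `[[`, logical(1), "found"))
  } else n_rev <- -1L
  if (n_rev > n_fwd) {
    hits <- rev; oriented <- rc; orientation <- "-"
  } else {
    hits <- fwd; oriented <- seq; orientation <- "+"
  }

  adf <- data.frame(
    region = names(hits),
    found = vapply(hits, `[[`, logical(1), "found"),
    start = vapply(hits, `[[`, integer(1), "start"),
    end = vapply(hits, `[[`, integer(1), "end"),
    edits = vapply(hits, `[[`, integer(1), "edits"),
    stringsAsFactors = FALSE, row.names = NULL)

  gap <- function(a, b) {
    ia <- match(a, adf$region); ib <- match(b, adf$region)
    if (!adf$found[ia] || !adf$found[ib]) return(NA_character_)
    s <- adf$end[ia] + 1L; e <- adf$start[ib] - 1L
    if (e < s) "" else substr(oriented, s, e)
  }
  cdr_dna <- c(CDR1 = gap("FR1", "FR2"), CDR2 = gap("FR2", "FR3"),
               CDR3 = gap("FR3", "FR4"))
  cdr_aa <- vapply(cdr_dna, function(d) {
    if (is.na(d) || nchar(d) %% 3L != 0L) NA_character_ else translate_dna(d)
  }, character(1))

  ann <- structure(
    list(read_id = read_id, orientation = orientation,
         frame = if (adf$found[1L]) ((adf$start[1L] - 1L) %% 3L) + 1L
                 else NA_integer_,
         anchors = adf, cdr_dna = cdr_dna, cdr_aa = cdr_aa,
         oriented_sequence = oriented,
         inferred_defect = NA_character_),
    class = "clone_annotation")
  ann$inferred_defect <- classify_defect(ann, oriented, scaffold = scaffold,
                                         cdr3_lengths = cdr3_lengths)
  ann
}

#' Classify a clone's construction defect
#'
#' Committed decision order: empty (no anchors at all) -> frameshift
#' (FR1-to-FR4 spacing off by a non-multiple of 3) -> missing region
#' (spacing a whole number of codons short of every designed length) ->
#' in-frame stop (stop codon in frame between the anchors) -> ok.
#' Contradictory evidence yields `"unclassified"`, never a silent ok.
#'
#' @param annotation A `clone_annotation` from [annotate_read()].
#' @param dna The oriented read DNA (defaults to the annotation's).
#' @param scaffold Scaffold model the annotation was made against.
#' @param cdr3_lengths Designed CDR3 lengths.
#' @param cdr12_len Designed CDR1/CDR2 length.
#' @return One of `"ok"`, `"in_frame_stop"`, `"frameshift"`,
#'   `"missing_region"`, `"empty"`, `"unclassified"`.
#' @export
classify_defect <- function(annotation, dna = NULL,
                            scaffold = baseline_scaffold(),
                            cdr3_lengths = CDR3_DESIGN_LENGTHS,
                            cdr12_len = 7L) {
  dna <- dna %||% annotation$oriented_sequence
  adf <- annotation$anchors
  if (!any(adf$found)) return("empty")
  fr1 <- adf[adf$region == "FR1", ]
  fr4 <- adf[adf$region == "FR4", ]
  if (!fr1$found || !fr4$found) return("unclassified")

  frl <- vapply(scaffold$frameworks, nchar, integer(1))
  aa_before_cdr3 <- frl[["FR1"]] + cdr12_len + frl[["FR2"]] + cdr12_len +
    frl[["FR3"]]
  legit <- 3L * (aa_before_cdr3 + as.integer(cdr3_lengths))
  spacing <- fr4$start - fr1$start

  if (spacing %% 3L != 0L) return("frameshift")
  if (!spacing %in% legit) {
    if (spacing < max(legit)) return("missing_region")
    return("unclassified")
  }
  orf <- substr(dna, fr1$start, fr4$start - 1L)
  if (grepl("*", translate_dna(orf), fixed = TRUE)) return("in_frame_stop")

  # structural sanity for an ok call
  ok_lengths <- !is.na(annotation$cdr_dna["CDR1"]) &&
    !is.na(annotation$cdr_dna["CDR2"]) &&
    !is.na(annotation$cdr_dna["CDR3"]) &&
    nchar(annotation$cdr_dna[["CDR1"]]) == 3L * cdr12_len &&
    nchar(annotation$cdr_dna[["CDR2"]]) == 3L * cdr12_len &&
    (nchar(annotation$cdr_dna[["CDR3"]]) / 3L) %in% cdr3_lengths
  if (!ok_lengths) return("unclassified")
  "ok"
}

#' Aggregate QC report over annotated reads
#'
#' Summarizes a set of annotations the way a library quality-control run is
#' reported: defect counts and fraction, CDR3 length proportions, observed
#' per-position profiles over intact clones, total-variation distances to
#' the design, unique-clone count and clonal dominance.
#'
#' @param annotations List of `clone_annotation` objects.
#' @param design A [library_design()] for the comparison.
#' @param dominance_threshold Top-clone fraction above which the pool is
#'   flagged dominant.
#' @return A `qc_report` list.
#' @export
qc_report <- function(annotations, design = default_library_design(),
                      dominance_threshold = 0.5) {
  classes <- c(DEFECT_CLASSES, "unclassified")
  if (length(annotations) == 0L) {
    return(structure(list(
      empty_input = TRUE, total = 0L,
      defect_counts = setNames(integer(length(classes)), classes),
      defect_fraction = NA_real_, cdr3_length_counts = integer(0),
      cdr3_length_proportions = numeric(0), observed_profiles = list(),
      design_distances = list(), unique_clones = 0L,
      dominance = NA_real_, dominant = NA), class = "qc_report"))
  }
  inferred <- vapply(annotations, `[[`, character(1), "inferred_defect")
  counts <- table(factor(inferred, levels = classes))
  total <- length(annotations)
  ok <- annotations[inferred == "ok"]

  cdr_aa <- function(region) vapply(ok, function(a) a$cdr_aa[[region]],
                                    character(1))
  res <- list(empty_input = FALSE, total = total,
              defect_counts = setNames(as.integer(counts), classes),
              defect_fraction = sum(inferred != "ok") / total)

  if (length(ok)) {
    c3 <- cdr_aa("CDR3")
    lens <- nchar(c3)
    ltab <- table(lens)
    res$cdr3_length_counts <- setNames(as.integer(ltab), names(ltab))
    res$cdr3_length_proportions <- res$cdr3_length_counts / length(ok)
    obs <- list(CDR1 = profile_from_repertoire(cdr_aa("CDR1")),
                CDR2 = profile_from_repertoire(cdr_aa("CDR2")))
    dists <- list(
      CDR1 = compare_profiles(design$cdr1$profiles, obs$CDR1),
      CDR2 = compare_profiles(design$cdr2$profiles, obs$CDR2))
    for (L in sort(unique(lens))) {
      key <- paste0("CDR3_", L)
      obs[[key]] <- profile_from_repertoire(c3[lens == L])
      dists[[key]] <- compare_profiles(design$cdr3$profiles[seq_len(L)],
                                       obs[[key]])
    }
    res$observed_profiles <- obs
    res$design_distances <- dists
    prot <- vapply(ok, function(a) paste(a$cdr_aa, collapse = "|"),
                   character(1))
    cl <- collapse_unique(prot)
    res$unique_clones <- nrow(cl)
    dom <- dominance(prot, threshold = dominance_threshold)
    res$dominance <- dom$top_fraction
    res$dominant <- dom$dominant
  } else {
    res$cdr3_length_counts <- integer(0)
    res$cdr3_length_proportions <- numeric(0)
    res$observed_profiles <- list()
    res$design_distances <- list()
    res$unique_clones <- 0L
    res$dominance <- NA_real_
    res$dominant <- NA
  }
  structure(res, class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report over", x$total, "reads\n")
  if (isTRUE(x$empty_input)) {
    cat("  (empty input)\n"); return(invisible(x))
  }
  cat("  defects:",
      paste0(names(x$defect_counts), "=", x$defect_counts, collapse = " "),
      "\n")
  cat(sprintf("  defect fraction: %.4f\n", x$defect_fraction))
  if (length(x$cdr3_length_proportions))
    cat("  CDR3 length mix:",
        paste0(names(x$cdr3_length_proportions), "aa=",
               sprintf("%.3f", x$cdr3_length_proportions), collapse = " "),
        "\n")
  cat("  unique clones:", x$unique_clones,
      sprintf(" dominance: %.3f (%s)\n", x$dominance,
              if (isTRUE(x$dominant)) "dominant" else "not dominant"))
  invisible(x)
}

#' Collapse clones to unique sequences
#'
#' Exact-identity grouping at the DNA, protein or CDR3 level. "Independent
#' binders" in a selection output are distinct at the protein level by
#' default (synonymous DNA variants merge).
#'
#' @param clones A `clone_set`, or a character vector of sequences.
#' @param level `"protein"` (default), `"dna"` or `"cdr3"`.
#' @return data.frame of `sequence` and `size`, sorted by decreasing size;
#'   cluster sizes sum to the input count.
#' @export
collapse_unique <- function(clones, level = c("protein", "dna", "cdr3")) {
  level <- match.arg(level)
  seqs <- if (is.character(clones)) clones
          else clones[[if (level == "cdr3") "cdr3" else level]]
  tab <- sort(table(seqs), decreasing = TRUE)
  data.frame(sequence = names(tab), size = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Clonal dominance of a pool
#'
#' Fraction held by the most frequent clone, with a dominance flag (a pool
#' is "dominated" when one clone exceeds the threshold, default one half).
#'
#' @param x Numeric frequency vector, or character vector of clone
#'   sequences/identifiers.
#' @param threshold Dominance threshold on the top-clone fraction.
#' @return List with `top_fraction`, `top_clone`, `dominant`.
#' @export
dominance <- function(x, threshold = 0.5) {
  if (is.character(x)) {
    tab <- table(x)
    f <- as.numeric(tab) / length(x)
    names(f) <- names(tab)
  } else {
    stopifnot(all(x >= 0), sum(x) > 0)
    f <- x / sum(x)
  }
  i <- which.max(f)
  list(top_fraction = unname(f[i]),
       top_clone = names(f)[i] %||% as.character(i),
       dominant = unname(f[i]) > threshold)
}

#' Confusion matrix of inferred vs truth defect classes
#'
#' @param truth Character vector of truth classes.
#' @param inferred Character vector of inferred classes (same length).
#' @return Contingency table truth x inferred over all defect classes.
#' @export
defect_confusion <- function(truth, inferred) {
  classes <- c(DEFECT_CLASSES, "unclassified")
  table(truth = factor(truth, levels = classes),
        inferred = factor(inferred, levels = classes))
}
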