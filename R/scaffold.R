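REGION_NAMES <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
CDR3_DESIGN_LENGTHS <- c(9L, 12L, 15L, 18L)

#' Build a scaffold region map
#'
#' A region map partitions a single-domain antibody into its seven segments
#' FR1-CDR1-FR2-CDR2-FR3-CDR3-FR4 using scaffold-local 1-based sequential
#' numbering (inclusive coordinates). Regions are contiguous, non-overlapping
#' and strictly ordered.
#'
#' @param cdr3_len CDR3 length in residues (design lengths are 9, 12, 15, 18).
#' @param fr_lengths Named integer vector with elements FR1, FR2, FR3, FR4.
#' @param cdr12_len Length of CDR1 and CDR2 (default design fixes both at 7).
#' @param numbering Label describing the numbering scheme.
#' @return An object of class `region_map`: a data.frame with columns
#'   `region`, `start`, `end`, plus attributes `numbering` and `span`.
#' @examples
#' region_map(cdr3_len = 12)
#' @export
region_map <- function(cdr3_len = 12L,
                       fr_lengths = c(FR1 = 25L, FR2 = 20L, FR3 = 44L, FR4 = 11L),
                       cdr12_len = 7L,
                       numbering = "scaffold-local sequential (1-based)") {
  stopifnot(cdr3_len >= 1L, cdr12_len >= 1L,
            all(c("FR1", "FR2", "FR3", "FR4") %in% names(fr_lengths)))
  lens <- c(FR1 = unname(fr_lengths["FR1"]), CDR1 = cdr12_len,
            FR2 = unname(fr_lengths["FR2"]), CDR2 = cdr12_len,
            FR3 = unname(fr_lengths["FR3"]), CDR3 = as.integer(cdr3_len),
            FR4 = unname(fr_lengths["FR4"]))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  map <- data.frame(region = REGION_NAMES, start = as.integer(starts),
                    end = as.integer(ends), stringsAsFactors = FALSE)
  structure(map, class = c("region_map", "data.frame"),
            numbering = numbering, span = as.integer(ends[[7L]]))
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map (", attr(x, "numbering"), "), span ", attr(x, "span"),
      " aa\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

map_span <- function(map) attr(map, "span")

# 1-based inclusive region row -> 0-based half-open (for substr use we keep
# 1-based; this helper returns start/end for substr directly)
region_bounds <- function(map, region) {
  i <- match(region, map$region)
  c(start = map$start[i], end = map$end[i])
}

region_of_position <- function(map, pos) {
  i <- which(map$start <= pos & map$end >= pos)
  if (length(i) != 1L) stop("position ", pos, " outside map span")
  map$region[i]
}

#' Construct a scaffold model
#'
#' A scaffold model holds the four framework segments of a single-domain
#' antibody together with its region map and hallmark residues. Hallmark
#' positions are framework positions whose residues must never be altered:
#' by default the four framework-2 solubility hallmarks (positions 42, 49,
#' 50, 52) and the glutamine at position 103.
#'
#' @param frameworks Named character vector of amino-acid strings for
#'   FR1, FR2, FR3, FR4.
#' @param map A [region_map()]. Framework lengths must match the map.
#' @param hallmarks Named character vector: names are scaffold positions,
#'   values the required residues.
#' @param name Scaffold name.
#' @return An object of class `scaffold_model`.
#' @export
scaffold_model <- function(frameworks, map = region_map(),
                           hallmarks = c("42" = "F", "49" = "E",
                                         "50" = "R", "52" = "G",
                                         "103" = "Q"),
                           name = "scaffold") {
  stopifnot(all(c("FR1", "FR2", "FR3", "FR4") %in% names(frameworks)))
  for (fr in c("FR1", "FR2", "FR3", "FR4")) {
    b <- region_bounds(map, fr)
    if (nchar(frameworks[[fr]]) != b["end"] - b["start"] + 1L)
      stop(fr, " length ", nchar(frameworks[[fr]]),
           " does not match region map span ", b["end"] - b["start"] + 1L)
  }
  obj <- structure(
    list(frameworks = frameworks[c("FR1", "FR2", "FR3", "FR4")],
         map = map, hallmarks = hallmarks, name = name),
    class = "scaffold_model")
  validate_hallmarks(obj)
  obj
}

validate_hallmarks <- function(scaffold) {
  for (pos in as.integer(names(scaffold$hallmarks))) {
    reg <- region_of_position(scaffold$map, pos)
    if (!startsWith(reg, "FR"))
      stop("hallmark position ", pos, " falls in ", reg, ", not a framework")
    found <- scaffold_residue(scaffold, pos)
    want <- scaffold$hallmarks[[as.character(pos)]]
    if (found != want)
      stop("hallmark residue at position ", pos, " is ", found,
           ", expected ", want)
  }
  invisible(TRUE)
}

# residue at a framework position (errors inside CDRs)
scaffold_residue <- function(scaffold, pos) {
  reg <- region_of_position(scaffold$map, pos)
  if (!startsWith(reg, "FR")) stop("position ", pos, " is in ", reg)
  b <- region_bounds(scaffold$map, reg)
  substr(scaffold$frameworks[[reg]], pos - b["start"] + 1L,
         pos - b["start"] + 1L)
}

set_scaffold_residue <- function(scaffold, pos, residue) {
  reg <- region_of_position(scaffold$map, pos)
  if (!startsWith(reg, "FR")) stop("position ", pos, " is in ", reg)
  b <- region_bounds(scaffold$map, reg)
  s <- scaffold$frameworks[[reg]]
  substr(s, pos - b["start"] + 1L, pos - b["start"] + 1L) <- residue
  scaffold$frameworks[[reg]] <- s
  scaffold
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat("Scaffold model '", x$name, "' (span ", map_span(x$map), " aa)\n",
      sep = "")
  for (fr in names(x$frameworks))
    cat(" ", fr, ": ", x$frameworks[[fr]], "\n", sep = "")
  cat("  hallmarks: ",
      paste0(names(x$hallmarks), "=", x$hallmarks, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Packaged baseline scaffold
#'
#' A synthetic humanization-ready single-domain scaffold with realistic
#' framework lengths (FR1 25, FR2 20, FR3 44, FR4 11 aa; 126 aa total with
#' the default 12-residue CDR3). It is a constructed stand-in, not a
#' published sequence: it carries the canonical cysteine pair (positions 22
#' and 89), llama-type framework-2 hallmarks F42/E49/R50/G52 and the
#' hallmark Q103 at the end of FR3.
#'
#' @return A [scaffold_model()].
#' @export
baseline_scaffold <- function() {
  scaffold_model(
    frameworks = c(
      FR1 = "QVQLVESGGGLVQPGGSLRLSCAAS",
      FR2 = "WVRQAPGKGFEWVSAIERSG",
      FR3 = "RFTISRDNSKNTLYLQMNSLRAEDTAVYYCARDSSGYGSYDYEQ",
      FR4 = "WGQGTQVTVSS"),
    map = region_map(cdr3_len = 12L),
    name = "baseline-synthetic-sdAb")
}

#' Default humanization rule set
#'
#' Seven framework substitutions moving the baseline scaffold towards the
#' residues most represented in human VH3, while five divergent framework
#' residues — and all hallmark positions — are explicitly protected and
#' kept unchanged.
#'
#' @return An object of class `humanization_rules` with elements
#'   `substitutions` (named character vector, names = positions) and
#'   `protected` (integer positions).
#' @export
default_humanization_rules <- function() {
  humanization_rules(
    substitutions = c("5" = "L", "11" = "V", "14" = "A", "16" = "R",
                      "45" = "L", "78" = "A", "80" = "K"),
    protected = c(37L, 47L, 71L, 76L, 84L))
}

#' Create a humanization rule set
#'
#' @param substitutions Named character vector: names are scaffold positions,
#'   values the target residues.
#' @param protected Integer vector of positions that must not be altered
#'   (hallmark positions are always protected in addition).
#' @return A `humanization_rules` object.
#' @export
humanization_rules <- function(substitutions, protected = integer()) {
  pos <- as.integer(names(substitutions))
  if (anyNA(pos)) stop("substitution names must be integer positions")
  if (anyDuplicated(pos)) stop("duplicated substitution positions")
  if (length(intersect(pos, protected)))
    stop("substitution and protected positions must be disjoint")
  structure(list(substitutions = substitutions,
                 protected = as.integer(protected)),
            class = "humanization_rules")
}

#' Split a protein into its scaffold regions
#'
#' Cuts an amino-acid string into the seven FR/CDR segments described by a
#' region map. The concatenation of the returned segments reproduces the
#' input exactly.
#'
#' @param protein Amino-acid string whose length equals the map span.
#' @param map A [region_map()].
#' @return Named list of seven region substrings.
#' @examples
#' s <- baseline_scaffold()
#' p <- graft_cdrs(s, c(CDR1 = "GFTFSSY", CDR2 = "ISSGGST",
#'                      CDR3 = "ARDLGSYYPMDY"))
#' segment_sequence(p, s$map)$CDR3
#' @export
segment_sequence <- function(protein, map) {
  stopifnot(is.character(protein), length(protein) == 1L)
  if (nchar(protein) != map_span(map))
    stop("segmentation error: sequence length ", nchar(protein),
         " does not equal map span ", map_span(map))
  out <- mapply(function(s, e) substr(protein, s, e), map$start, map$end)
  setNames(as.list(out), map$region)
}

#' Consensus of an amino-acid alignment
#'
#' Takes the modal residue per column; ties are broken alphabetically by
#' one-letter code (documented, deterministic).
#'
#' @param sequences Character vector of equal-length aligned sequences.
#' @return List with `consensus` (string) and `frequencies` (matrix,
#'   residues x columns, each column summing to 1).
#' @examples
#' derive_consensus(c("AAC", "AAC", "AAG"))$consensus
#' @export
derive_consensus <- function(sequences) {
  if (length(sequences) == 0L) stop("empty input: need at least one sequence")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stop("sequences must have equal lengths")
  L <- lens[[1L]]
  chars <- matrix(unlist(strsplit(sequences, "")), nrow = length(sequences),
                  ncol = L, byrow = TRUE)
  letters_seen <- sort(unique(as.vector(chars)))
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = letters_seen))
    as.numeric(tab) / length(sequences)
  }, numeric(length(letters_seen)))
  freq <- matrix(freq, nrow = length(letters_seen), ncol = L,
                 dimnames = list(letters_seen, NULL))
  # which.max on a sorted-level table breaks ties alphabetically
  cons <- paste(letters_seen[apply(freq, 2L, which.max)], collapse = "")
  list(consensus = cons, frequencies = freq)
}

#' Humanize a scaffold
#'
#' Applies a substitution rule set to the framework regions of a scaffold.
#' Hallmark positions and explicitly protected positions are refused;
#' substitutions targeting CDR regions are impossible by construction
#' (frameworks only). The output differs from the input at exactly the rule
#' positions whose target differs from the current residue.
#'
#' @param scaffold A [scaffold_model()].
#' @param rules A [humanization_rules()] object.
#' @return The humanized `scaffold_model`.
#' @export
humanize <- function(scaffold, rules = default_humanization_rules()) {
  stopifnot(inherits(scaffold, "scaffold_model"),
            inherits(rules, "humanization_rules"))
  hall <- as.integer(names(scaffold$hallmarks))
  forbidden <- union(hall, rules$protected)
  for (p in as.integer(names(rules$substitutions))) {
    if (p %in% forbidden)
      stop("humanization rule targets protected/hallmark position ", p)
    reg <- region_of_position(scaffold$map, p)
    if (!startsWith(reg, "FR"))
      stop("humanization rule targets CDR position ", p)
    scaffold <- set_scaffold_residue(scaffold, p,
                                     rules$substitutions[[as.character(p)]])
  }
  validate_hallmarks(scaffold)
  if (!endsWith(scaffold$name, "-humanized"))
    scaffold$name <- paste0(scaffold$name, "-humanized")
  scaffold
}

#' Graft CDR loops onto a scaffold
#'
#' Inserts three CDR sequences between the scaffold's framework segments
#' and returns the full-length protein. Under the default design contract
#' CDR1 and CDR2 must be 7 residues and CDR3 one of 9/12/15/18; pass
#' `override = TRUE` to graft other lengths.
#'
#' @param scaffold A [scaffold_model()].
#' @param cdrs Character vector of three amino-acid strings, in order
#'   CDR1, CDR2, CDR3 (names optional).
#' @param override Allow CDR lengths outside the design contract.
#' @return The grafted protein as a single string.
#' @export
graft_cdrs <- function(scaffold, cdrs, override = FALSE) {
  stopifnot(length(cdrs) == 3L)
  cdrs <- unname(cdrs)
  cdr12 <- nchar(cdrs[1:2])
  cdr3 <- nchar(cdrs[3])
  if (!override) {
    if (any(cdr12 != 7L))
      stop("CDR1/CDR2 must be 7 aa in the default design ",
           "(got ", cdr12[1], "/", cdr12[2], "); use override = TRUE")
    if (!cdr3 %in% CDR3_DESIGN_LENGTHS)
      stop("CDR3 length ", cdr3, " outside design lengths {",
           paste(CDR3_DESIGN_LENGTHS, collapse = ","),
           "}; use override = TRUE")
  }
  paste0(scaffold$frameworks[["FR1"]], cdrs[1],
         scaffold$frameworks[["FR2"]], cdrs[2],
         scaffold$frameworks[["FR3"]], cdrs[3],
         scaffold$frameworks[["FR4"]])
}

# map matching a grafted protein's CDR lengths, sharing the scaffold's FR
# lengths
map_for_cdrs <- function(scaffold, cdrs) {
  frl <- vapply(scaffold$frameworks, nchar, integer(1))
  region_map(cdr3_len = nchar(cdrs[[3]]),
             fr_lengths = frl,
             cdr12_len = nchar(cdrs[[1]]))
}

#' Scaffold framework DNA anchors
#'
#' Realizes the framework segments as DNA using a one-codon-per-residue
#' table. These fixed nucleotide anchors are what the QC annotator aligns
#' against when locating CDRs in sequencing reads.
#'
#' @param scaffold A [scaffold_model()].
#' @param codon_table Named residue-to-codon vector.
#' @return Named character vector of FR1..FR4 DNA strings.
#' @export
scaffold_dna <- function(scaffold, codon_table = default_codon_table()) {
  vapply(scaffold$frameworks, function(aa) protein_to_dna(aa, codon_table),
         character(1))
}

protein_to_dna <- function(protein, codon_table = default_codon_table()) {
  res <- strsplit(protein, "")[[1]]
  miss <- setdiff(res, names(codon_table))
  if (length(miss)) stop("no codon assigned for residue(s): ",
                         paste(miss, collapse = ", "))
  paste(codon_table[res], collapse = "")
}
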