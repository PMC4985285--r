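#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"AA"` or `"DNA"`.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param type `"AA"` or `"DNA"`.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a read set to FASTQ
#'
#' Reads without per-base qualities get a constant placeholder quality.
#'
#' @param reads A `read_set` from [emit_reads()].
#' @param path Output FASTQ file.
#' @param quality_char Placeholder Phred character.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n)
    strrep(quality_char, n), character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file.
#' @return A `read_set` data.frame (`read_id`, `sequence`).
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  structure(data.frame(read_id = names(set), sequence = as.character(set),
                       flipped = NA, stringsAsFactors = FALSE),
            class = c("read_set", "data.frame"))
}

#' Write a sensorgram to CSV
#'
#' Columns `time_s`, `response_RU`, `phase`.
#' @param sensorgram A `sensorgram`.
#' @param path Output CSV file.
#' @export
write_sensorgram <- function(sensorgram, path) {
  utils::write.csv(
    data.frame(time_s = sensorgram$time, response_RU = sensorgram$response,
               phase = sensorgram$phase),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sensorgram from CSV
#'
#' @param path CSV with columns `time_s`, `response_RU`, `phase`.
#' @return A `sensorgram` data.frame.
#' @export
read_sensorgram <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(data.frame(time = d$time_s, response = d$response_RU,
                       phase = d$phase, stringsAsFactors = FALSE),
            class = c("sensorgram", "data.frame"))
}

#' Write a QC report as JSON
#'
#' Profile matrices are flattened to per-position named probability lists.
#'
#' @param report A `qc_report`.
#' @param path Output JSON file.
#' @export
write_qc_report <- function(report, path) {
  x <- unclass(report)
  x$observed_profiles <- lapply(x$observed_profiles, function(pl)
    lapply(pl, function(p) as.list(p[p > 0])))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write position profiles as a TSV matrix
#'
#' Positions are rows, the 20 canonical residues are columns.
#'
#' @param profiles List of [position_profile()]s.
#' @param path Output TSV file.
#' @export
write_profiles_tsv <- function(profiles, path) {
  m <- do.call(rbind, lapply(profiles, as.numeric))
  colnames(m) <- AA_CANONICAL
  rownames(m) <- seq_len(nrow(m))
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read position profiles from a TSV matrix
#'
#' @param path TSV written by [write_profiles_tsv()] (positions x residues).
#' @return List of [position_profile()]s.
#' @export
read_profiles_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1L,
                                   check.names = FALSE))
  lapply(seq_len(nrow(m)), function(i)
    position_profile(setNames(as.numeric(m[i, ]), colnames(m))))
}
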