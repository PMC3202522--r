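# File-format boundaries: FASTA via Biostrings, SNP tables as 4-column TSV or
# a minimal VCF subset whose CHROM column carries transcript ids.

#' Read a FASTA file into a named character vector of RNA sequences
#'
#' Record descriptions are truncated at the first whitespace to form ids.
#' Sequences are normalized with [normalize_sequence()] unless `normalize`
#' is `FALSE`.
#'
#' @param path Path to a FASTA file.
#' @param normalize Normalize to the RNA alphabet (default `TRUE`).
#' @return Named character vector.
#' @export
read_fasta <- function(path, normalize = TRUE) {
  set <- Biostrings::readBStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate record ids in ", path, call. = FALSE)
  }
  if (normalize) {
    seqs <- vapply(seqs, normalize_sequence, character(1))
  }
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read SNP records from a TSV file or a minimal VCF subset
#'
#' Two layouts are accepted. A headerless 4-column TSV
#' `transcript_id <tab> pos_1based <tab> ref <tab> alt`, or a VCF-style file
#' (detected by a `##fileformat`/`#CHROM` header or a `.vcf` extension) whose
#' CHROM column holds the transcript id; only CHROM, POS, REF and ALT are
#' used, all other columns are ignored.
#'
#' @param path Path to the SNP file.
#' @return A [snp_records()] data.frame.
#' @export
read_snps <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    return(snp_records(character(0), integer(0)))
  }
  is_vcf <- grepl("\\.vcf$", path, ignore.case = TRUE) ||
    startsWith(first, "##fileformat") || startsWith(first, "#CHROM")
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(snp_records(character(0), integer(0)))
  }
  header <- startsWith(lines[1], "#")
  if (header) lines <- lines[-1L]
  if (length(lines) == 0L) {
    return(snp_records(character(0), integer(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (is_vcf) {
    if (any(ncols < 5L)) stop("VCF lines need at least 5 columns", call. = FALSE)
    snp_records(
      transcript_id = vapply(fields, `[[`, character(1), 1L),
      pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
      ref = vapply(fields, `[[`, character(1), 4L),
      alt = vapply(fields, `[[`, character(1), 5L)
    )
  } else {
    if (any(ncols < 4L)) stop("SNP TSV needs 4 columns", call. = FALSE)
    snp_records(
      transcript_id = vapply(fields, `[[`, character(1), 1L),
      pos = as.integer(vapply(fields, `[[`, character(1), 2L)),
      ref = vapply(fields, `[[`, character(1), 3L),
      alt = vapply(fields, `[[`, character(1), 4L)
    )
  }
}
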