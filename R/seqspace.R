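# Sequence-space preprocessing: normalization, conservation across transcript
# isoforms, and SNP masking. Coordinates are 0-based half-open internally;
# SNP input is 1-based (VCF convention) and converted at the boundary.

#' Normalize a nucleotide sequence to the RNA alphabet
#'
#' Uppercases, strips whitespace and maps `T` to `U`. The only ambiguity code
#' accepted is `N`; any other IUPAC ambiguity character is rejected so that no
#' downstream filter ever scores an ambiguous base silently.
#'
#' @param raw Character scalar holding the raw sequence (DNA or RNA case
#'   insensitive, whitespace and line breaks allowed).
#' @return Character scalar over the alphabet `A`, `C`, `G`, `U`, `N`.
#' @examples
#' normalize_sequence("acgt")     # "ACGU"
#' normalize_sequence("AC GU\n")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw)) {
    stop("`raw` must be a single non-NA character string", call. = FALSE)
  }
  s <- chartr("T", "U", toupper(gsub("[[:space:]]", "", raw)))
  bad <- unique(strsplit(gsub("[ACGUN]", "", s), "")[[1]])
  if (length(bad) > 0L) {
    stop("malformed sequence: unsupported character(s) ",
         paste(bad, collapse = ", "),
         " (only A/C/G/T/U/N are accepted)", call. = FALSE)
  }
  s
}

#' Bundle a gene's reference transcript with its sibling transcripts
#'
#' The reference transcript is the design template; siblings are the gene's
#' other isoforms. All sequences are normalized to the RNA alphabet. Candidate
#' design is later restricted to regions of the reference that occur verbatim
#' in every sibling, so that one duplex silences all isoforms.
#'
#' @param gene_id Non-empty gene identifier.
#' @param reference Reference transcript sequence; if named, the name is used
#'   as the transcript id (default `"ref"`).
#' @param siblings Optional named character vector of sibling transcript
#'   sequences.
#' @param utr3 Optional named list mapping transcript ids to 0-based half-open
#'   `c(start, end)` intervals marking the 3' UTR.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(gene_id, reference, siblings = character(),
                           utr3 = NULL) {
  if (!is.character(gene_id) || length(gene_id) != 1L || !nzchar(gene_id)) {
    stop("`gene_id` must be a non-empty string", call. = FALSE)
  }
  ref_id <- if (!is.null(names(reference)) && nzchar(names(reference)[1])) {
    names(reference)[1]
  } else {
    "ref"
  }
  ref <- normalize_sequence(unname(reference[1]))
  if (!nzchar(ref)) stop("reference transcript must be non-empty", call. = FALSE)
  sib_ids <- names(siblings)
  if (length(siblings) > 0L && is.null(sib_ids)) {
    sib_ids <- paste0("sibling", seq_along(siblings))
  }
  sibs <- vapply(siblings, normalize_sequence, character(1), USE.NAMES = FALSE)
  names(sibs) <- sib_ids
  structure(
    list(gene_id = gene_id, reference_id = ref_id, reference = ref,
         siblings = sibs, utr3 = utr3),
    class = "transcript_set"
  )
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set for gene", x$gene_id, "\n")
  cat("  reference:", x$reference_id, sprintf("(%d nt)", nchar(x$reference)), "\n")
  cat("  siblings: ", length(x$siblings), "\n")
  invisible(x)
}

new_sequence_space <- function(reference_id, intervals, reference_length) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) > 0L) {
    o <- order(intervals$start, intervals$end)
    intervals <- intervals[o, , drop = FALSE]
    rownames(intervals) <- NULL
    stopifnot(all(intervals$end - intervals$start >= 1L),
              all(intervals$start >= 0L),
              all(intervals$end <= reference_length))
  }
  structure(
    list(reference_id = reference_id, intervals = intervals,
         reference_length = reference_length),
    class = "sequence_space"
  )
}

#' Construct a sequence space from explicit intervals
#'
#' Mostly useful for tests and for driving [mask_snps()] /
#' [enumerate_candidates()] on hand-picked regions; [conserved_blocks()] is
#' the usual producer.
#'
#' @param reference_id Transcript id the intervals live on.
#' @param starts,ends Parallel vectors of 0-based half-open interval bounds.
#' @param reference_length Length of the reference transcript.
#' @return A `sequence_space`.
#' @export
sequence_space <- function(reference_id, starts, ends, reference_length) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  stopifnot(length(starts) == length(ends))
  iv <- if (length(starts) == 0L) {
    empty_intervals()
  } else {
    data.frame(start = starts, end = ends,
               conserved = rep(NA, length(starts)),
               snp_masked = rep(FALSE, length(starts)))
  }
  new_sequence_space(reference_id, iv, as.integer(reference_length))
}

empty_intervals <- function() {
  data.frame(start = integer(0), end = integer(0),
             conserved = logical(0), snp_masked = logical(0))
}

#' @export
print.sequence_space <- function(x, ...) {
  cat("sequence_space on", x$reference_id,
      sprintf("(%d nt): %d interval(s), %d nt total\n",
              x$reference_length, nrow(x$intervals),
              sum(x$intervals$end - x$intervals$start)))
  invisible(x)
}

# Matching statistics: ms[i] = length of the longest substring of `ref`
# starting at i (1-based) that occurs somewhere in `sib`. Uses the standard
# ms[i+1] >= ms[i] - 1 bound to avoid rescanning from scratch.
matching_stats <- function(ref, sib) {
  n <- nchar(ref)
  ms <- integer(n)
  l <- 0L
  for (i in seq_len(n)) {
    if (l > 0L) l <- l - 1L
    while (i + l <= n &&
           grepl(substr(ref, i, i + l), sib, fixed = TRUE)) {
      l <- l + 1L
    }
    ms[i] <- l
  }
  ms
}

#' Conserved blocks of the reference transcript
#'
#' Returns all maximal intervals of the reference, of length at least
#' `min_len`, whose substring occurs as an exact contiguous substring in every
#' sibling transcript. Conservation is defined as exact (un-gapped, 100%)
#' substring presence, so the result is deterministic and needs no external
#' aligner. With no siblings the whole reference is the sequence space.
#'
#' Maximal conserved intervals are sorted by start; they can overlap only in
#' staircase-like conservation patterns (each interval is conserved but their
#' union is not). Candidate enumeration de-duplicates windows, so overlapping
#' intervals never duplicate candidates.
#'
#' @param tset A [transcript_set()].
#' @param min_len Minimum block length to report (default 19, one siRNA site).
#' @return A `sequence_space` with 0-based half-open intervals.
#' @examples
#' ts <- transcript_set("g", "AAAACCCCGGGG", c(s1 = "UUCCCCGG"))
#' conserved_blocks(ts, min_len = 4)$intervals  # (4, 10) = "CCCCGG"
#' @export
conserved_blocks <- function(tset, min_len = 19L) {
  stopifnot(inherits(tset, "transcript_set"))
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) {
    stop("`min_len` must be a positive integer", call. = FALSE)
  }
  n <- nchar(tset$reference)
  if (length(tset$siblings) == 0L) {
    iv <- data.frame(start = 0L, end = n, conserved = TRUE, snp_masked = FALSE)
    return(new_sequence_space(tset$reference_id, iv, n))
  }
  ml <- rep.int(n, n)
  for (sib in tset$siblings) {
    ml <- pmin(ml, matching_stats(tset$reference, sib))
  }
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n)) {
    if (ml[i] >= min_len && (i == 1L || ml[i - 1L] <= ml[i])) {
      starts <- c(starts, i - 1L)        # to 0-based
      ends <- c(ends, i - 1L + ml[i])
    }
  }
  iv <- data.frame(start = starts, end = ends,
                   conserved = rep(TRUE, length(starts)),
                   snp_masked = rep(FALSE, length(starts)))
  if (length(starts) == 0L) iv <- empty_intervals()
  new_sequence_space(tset$reference_id, iv, n)
}

#' Construct SNP records
#'
#' @param transcript_id Transcript each record refers to.
#' @param pos 1-based position on that transcript.
#' @param ref,alt Single-character reference and alternate bases.
#' @return A data.frame of class `snp_records`.
#' @export
snp_records <- function(transcript_id, pos, ref = NA_character_,
                        alt = NA_character_) {
  n <- length(pos)
  df <- data.frame(transcript_id = rep_len(as.character(transcript_id), n),
                   pos = as.integer(pos),
                   ref = rep_len(as.character(ref), n),
                   alt = rep_len(as.character(alt), n))
  if (any(is.na(df$pos)) || any(df$pos < 1L)) {
    stop("SNP positions must be 1-based positive integers", call. = FALSE)
  }
  class(df) <- c("snp_records", "data.frame")
  df
}

# Remove a set of 0-based positions from every interval, splitting around
# them and dropping empty fragments. Fragments produced by a split are
# flagged snp_masked.
mask_positions <- function(space, pos0) {
  stopifnot(inherits(space, "sequence_space"))
  pos0 <- sort(unique(as.integer(pos0)))
  if (length(pos0) == 0L || nrow(space$intervals) == 0L) return(space)
  out <- empty_intervals()
  for (r in seq_len(nrow(space$intervals))) {
    s <- space$intervals$start[r]
    e <- space$intervals$end[r]
    cuts <- pos0[pos0 >= s & pos0 < e]
    if (length(cuts) == 0L) {
      out <- rbind(out, space$intervals[r, , drop = FALSE])
      next
    }
    bounds_s <- c(s, cuts + 1L)
    bounds_e <- c(cuts, e)
    keep <- bounds_e - bounds_s >= 1L
    if (any(keep)) {
      out <- rbind(out, data.frame(
        start = bounds_s[keep], end = bounds_e[keep],
        conserved = space$intervals$conserved[r],
        snp_masked = TRUE
      ))
    }
  }
  out <- unique(out)
  new_sequence_space(space$reference_id, out, space$reference_length)
}

#' Mask SNP positions out of the sequence space
#'
#' Every SNP position on the reference transcript (1-based input, converted to
#' 0-based internally) is removed from the interval set; intervals are split
#' around SNPs and empty fragments dropped. A single nucleotide difference
#' between duplex and target can abolish silencing, hence positional exclusion
#' rather than penalty. Records for other transcripts are ignored with a
#' warning. The operation is idempotent.
#'
#' @param space A `sequence_space`.
#' @param snps A [snp_records()] data.frame (or anything with `transcript_id`
#'   and `pos` columns).
#' @return The masked `sequence_space`.
#' @export
mask_snps <- function(space, snps) {
  stopifnot(inherits(space, "sequence_space"))
  if (is.null(snps) || nrow(snps) == 0L) return(space)
  stopifnot(all(c("transcript_id", "pos") %in% names(snps)))
  other <- snps$transcript_id != space$reference_id
  if (any(other)) {
    warning(sum(other), " SNP record(s) for other transcripts ignored (",
            paste(unique(snps$transcript_id[other]), collapse = ", "), ")",
            call. = FALSE)
  }
  pos <- as.integer(snps$pos[!other])
  if (any(pos < 1L | pos > space$reference_length)) {
    stop("SNP position outside reference transcript (length ",
         space$reference_length, ")", call. = FALSE)
  }
  mask_positions(space, pos - 1L)
}

# N bases cannot be designed against: mask them exactly like SNPs.
mask_ns <- function(space, reference) {
  npos <- which(strsplit(reference, "")[[1]] == "N") - 1L
  mask_positions(space, npos)
}

#' Total number of reference positions covered by a sequence space
#'
#' @param space A `sequence_space`.
#' @return Integer count of covered positions (union of intervals).
#' @export
space_coverage <- function(space) {
  stopifnot(inherits(space, "sequence_space"))
  if (nrow(space$intervals) == 0L) return(0L)
  covered <- logical(space$reference_length)
  for (r in seq_len(nrow(space$intervals))) {
    covered[(space$intervals$start[r] + 1L):space$intervals$end[r]] <- TRUE
  }
  sum(covered)
}
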