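# Candidate enumeration: every 19-nt window of the sequence space, one
# nucleotide shift, with derived duplex strands.
#
# Position conventions used throughout the package: scoring rules index
# 1..19 along the SENSE target site 5'->3'; guide positions count 1..19 from
# the guide 5' end (guide position i faces sense position 20 - i).

SITE_LEN <- 19L

#' Reverse complement of an RNA sequence
#'
#' Watson-Crick complement, reversed. `N` maps to `N`.
#'
#' @param seq Character scalar over `A`, `C`, `G`, `U`, `N`.
#' @return The reverse complement.
#' @examples
#' reverse_complement("AUGC")  # "GCAU"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq)) {
    stop("`seq` must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGUN]", seq)) {
    stop("non-RNA character in sequence (expected A/C/G/U/N)", call. = FALSE)
  }
  paste(rev(strsplit(chartr("ACGUN", "UGCAN", seq), "")[[1]]), collapse = "")
}

#' Build duplex strands for a 19-nt target site
#'
#' The sense strand is the site plus a 3' overhang; the antisense (guide)
#' strand is the reverse complement of the site plus the same overhang. The
#' default `"UU"` overhang is the RNA-alphabet analogue of the classical dTdT
#' duplex ends.
#'
#' @param site 19-nt sense-strand target sequence.
#' @param overhang 3' overhang appended to both strands (may be `""`).
#' @return List with elements `sense` and `antisense`.
#' @export
make_duplex <- function(site, overhang = "UU") {
  if (nchar(site) != SITE_LEN) {
    stop("target site must be exactly ", SITE_LEN, " nt", call. = FALSE)
  }
  if (grepl("[^ACGU]", overhang)) {
    stop("overhang must contain only A/C/G/U", call. = FALSE)
  }
  list(sense = paste0(site, overhang),
       antisense = paste0(reverse_complement(site), overhang))
}

#' Enumerate all 19-nt siRNA candidates in a sequence space
#'
#' One candidate per window of length 19 fully contained in a single interval
#' of the space, advancing by one nucleotide. Windows containing `N` are
#' skipped; windows contained in more than one (overlapping) interval are
#' reported once. Candidates are sorted by start.
#'
#' @param space A `sequence_space` on the reference transcript.
#' @param reference The reference transcript sequence (normalized).
#' @param overhang 3' overhang for [make_duplex()].
#' @return A data.frame of class `sirna_candidates` with columns
#'   `reference_id`, `start` (0-based), `site`, `sense`, `antisense`.
#' @export
enumerate_candidates <- function(space, reference, overhang = "UU") {
  stopifnot(inherits(space, "sequence_space"))
  reference <- normalize_sequence(reference)
  if (nchar(reference) != space$reference_length) {
    stop("reference length does not match the sequence space", call. = FALSE)
  }
  starts <- integer(0)
  if (nrow(space$intervals) > 0L) {
    for (r in seq_len(nrow(space$intervals))) {
      s <- space$intervals$start[r]
      e <- space$intervals$end[r]
      if (e - s >= SITE_LEN) starts <- c(starts, s:(e - SITE_LEN))
    }
  }
  starts <- sort(unique(starts))
  if (length(starts) > 0L) {
    sites <- substring(reference, starts + 1L, starts + SITE_LEN)
    ok <- !grepl("N", sites, fixed = TRUE)
    starts <- starts[ok]
    sites <- sites[ok]
  } else {
    sites <- character(0)
  }
  duplexes <- lapply(sites, make_duplex, overhang = overhang)
  out <- data.frame(
    reference_id = rep(space$reference_id, length(starts)),
    start = starts,
    site = sites,
    sense = vapply(duplexes, `[[`, character(1), "sense"),
    antisense = vapply(duplexes, `[[`, character(1), "antisense"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "overhang") <- overhang
  class(out) <- c("sirna_candidates", "data.frame")
  out
}
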