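# Two-tier off-target rejection. Tier 1: complete (19/19) or near-complete
# (18/19) homology of the target site, on either strand, anywhere in a
# background transcriptome -- found with a guaranteed-complete pigeonhole
# k-mer search (for <= 1 mismatch at least one half of the 19-mer is exact).
# Tier 2: miRNA-like seed matching -- the guide seed (positions 2-7 from the
# guide 5' end) finding its Watson-Crick match in an unintended 3' UTR.
# Complete homology is checked first; a candidate is accepted only when both
# hit lists (restricted to unintended transcripts) are empty.

#' Build a k-mer index over a transcript set
#'
#' @param transcripts Named character vector of transcript sequences.
#' @param k K-mer length (default 9; must be between 4 and 9 for the
#'   pigeonhole scan to remain complete at one mismatch).
#' @return An object of class `kmer_index`.
#' @export
build_kmer_index <- function(transcripts, k = 9L) {
  k <- as.integer(k)
  if (k < 4L) stop("k must be >= 4", call. = FALSE)
  if (is.null(names(transcripts)) || anyDuplicated(names(transcripts))) {
    stop("transcripts must have unique ids", call. = FALSE)
  }
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (id in names(transcripts)) {
    s <- transcripts[[id]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    sp <- split(starts - 1L, kmers)          # offsets 0-based
    for (km in names(sp)) {
      env[[km]] <- c(env[[km]], list(list(id = id, offsets = sp[[km]])))
    }
  }
  structure(list(k = k, env = env, store = transcripts), class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("kmer_index: k = %d over %d transcript(s) (%d nt)\n",
              x$k, length(x$store), sum(nchar(x$store))))
  invisible(x)
}

kmer_lookup <- function(index, kmer) {
  hits <- index$env[[kmer]]
  if (is.null(hits)) {
    return(data.frame(id = character(0), offset = integer(0)))
  }
  data.frame(
    id = rep(vapply(hits, `[[`, character(1), "id"),
             vapply(hits, function(h) length(h$offsets), integer(1))),
    offset = unlist(lapply(hits, `[[`, "offsets"), use.names = FALSE)
  )
}

count_mismatches_at <- function(text, offset0, pattern) {
  m <- nchar(pattern)
  sub <- substr(text, offset0 + 1L, offset0 + m)
  if (nchar(sub) < m) return(NA_integer_)
  sum(utf8ToInt(sub) != utf8ToInt(pattern))
}

# Mismatch count of `pattern` against `text` at every alignment offset
# (0-based), vectorized over offsets.
mismatch_profile <- function(text, pattern) {
  tl <- utf8ToInt(text)
  pl <- utf8ToInt(pattern)
  n <- length(tl)
  m <- length(pl)
  if (n < m) return(integer(0))
  mm <- integer(n - m + 1L)
  for (j in seq_len(m)) {
    mm <- mm + as.integer(tl[j:(n - m + j)] != pl[j])
  }
  mm
}

scan_pattern_pigeonhole <- function(pattern, index, max_mismatch,
                                    exclude_ids = character()) {
  k <- index$k
  # halves 1..9 and 10..19; an exact half implies an exact k-prefix of it
  probes <- list(list(kmer = substr(pattern, 1L, k), shift = 0L),
                 list(kmer = substr(pattern, 10L, 9L + k), shift = 9L))
  cand <- unique(do.call(rbind, lapply(probes, function(p) {
    h <- kmer_lookup(index, p$kmer)
    h$offset <- h$offset - p$shift
    h
  })))
  cand <- cand[cand$offset >= 0L & !cand$id %in% exclude_ids, , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(id = character(0), offset = integer(0),
                      mismatches = integer(0)))
  }
  mm <- mapply(function(id, off) {
    count_mismatches_at(index$store[[id]], off, pattern)
  }, cand$id, cand$offset)
  keep <- !is.na(mm) & mm <= max_mismatch
  data.frame(id = cand$id[keep], offset = cand$offset[keep],
             mismatches = as.integer(mm[keep]))
}

scan_pattern_naive <- function(pattern, index, max_mismatch) {
  out <- lapply(names(index$store), function(id) {
    mm <- mismatch_profile(index$store[[id]], pattern)
    hit <- which(mm <= max_mismatch)
    data.frame(id = rep(id, length(hit)), offset = hit - 1L,
               mismatches = mm[hit])
  })
  do.call(rbind, out)
}

#' Scan a transcriptome for complete / near-complete homology of a site
#'
#' Finds every occurrence of the 19-nt site -- and of its reverse complement,
#' since both duplex strands can load into RISC -- with at most
#' `max_mismatch` mismatches over the 19 positions, on transcripts other than
#' the intended ones. For `max_mismatch <= 1` the pigeonhole split of the
#' 19-mer into two halves guarantees a complete search from exact k-mer
#' lookups; `max_mismatch = 2` falls back to a naive full scan.
#'
#' @param site 19-nt sense target site.
#' @param index A [build_kmer_index()] over the background transcriptome.
#' @param max_mismatch 0, 1 (default) or 2.
#' @param intended_ids Transcript ids of the targeted gene (never reported).
#' @return data.frame with columns `id`, `offset` (0-based), `mismatches`,
#'   `strand` (`"sense"` = site found verbatim, `"antisense"` = reverse
#'   complement found).
#' @export
scan_full_homology <- function(site, index, max_mismatch = 1L,
                               intended_ids = character()) {
  stopifnot(inherits(index, "kmer_index"))
  if (nchar(site) != SITE_LEN) {
    stop("site must be ", SITE_LEN, " nt", call. = FALSE)
  }
  max_mismatch <- as.integer(max_mismatch)
  if (!max_mismatch %in% 0:2) {
    stop("max_mismatch must be 0, 1 or 2", call. = FALSE)
  }
  use_pigeonhole <- max_mismatch <= 1L && index$k <= 9L
  patterns <- c(sense = site, antisense = reverse_complement(site))
  out <- lapply(names(patterns), function(strand) {
    h <- if (use_pigeonhole) {
      scan_pattern_pigeonhole(patterns[[strand]], index, max_mismatch,
                              intended_ids)
    } else {
      scan_pattern_naive(patterns[[strand]], index, max_mismatch)
    }
    if (nrow(h) > 0L) h$strand <- strand
    h
  })
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0L])
  if (is.null(out)) {
    out <- data.frame(id = character(0), offset = integer(0),
                      mismatches = integer(0), strand = character(0))
  }
  out <- out[!out$id %in% intended_ids, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan 3' UTRs for guide-seed matches
#'
#' The guide seed (positions `seed[1]`..`seed[2]` from the guide 5' end,
#' default 2-7) drives miRNA-like translational repression when its
#' Watson-Crick match occurs in an unintended transcript's 3' UTR. This scans
#' every UTR record for exact occurrences of the reverse complement of the
#' guide seed.
#'
#' @param guide Guide (antisense) strand, 5'->3'; may carry a 3' overhang.
#' @param utrs Named character vector of 3' UTR sequences (ids matching the
#'   transcriptome).
#' @param seed 1-based inclusive positions of the seed on the guide.
#' @param intended_ids Transcript ids never reported.
#' @return data.frame with columns `id` and `offset` (0-based within the
#'   UTR record).
#' @export
scan_seed <- function(guide, utrs, seed = c(2L, 7L),
                      intended_ids = character()) {
  seed <- as.integer(seed)
  if (seed[1] < 1L || seed[2] > nchar(guide) || seed[1] > seed[2]) {
    stop("seed window outside guide", call. = FALSE)
  }
  pattern <- reverse_complement(substr(guide, seed[1], seed[2]))
  ids <- setdiff(names(utrs), intended_ids)
  out <- lapply(ids, function(id) {
    m <- gregexpr(pattern, utrs[[id]], fixed = TRUE)[[1]]
    if (m[1] == -1L) {
      return(NULL)
    }
    data.frame(id = rep(id, length(m)), offset = as.integer(m) - 1L)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(id = character(0), offset = integer(0))
  rownames(out) <- NULL
  out
}

#' Off-target verdict for one candidate
#'
#' Decision order: any complete/near-complete homology hit on an unintended
#' transcript rejects outright (`reject_full`); otherwise any seed hit on an
#' unintended 3' UTR rejects (`reject_seed`); otherwise the candidate is
#' off-target free (`accept`).
#'
#' @param full_hits data.frame from [scan_full_homology()].
#' @param seed_hits data.frame from [scan_seed()].
#' @param candidate Optional candidate identifier carried in the report.
#' @return List of class `offtarget_report` with `full_homology_hits`,
#'   `seed_hits` and `verdict`.
#' @export
offtarget_filter <- function(full_hits, seed_hits, candidate = NULL) {
  verdict <- if (nrow(full_hits) > 0L) {
    "reject_full"
  } else if (nrow(seed_hits) > 0L) {
    "reject_seed"
  } else {
    "accept"
  }
  structure(list(candidate = candidate, full_homology_hits = full_hits,
                 seed_hits = seed_hits, verdict = verdict),
            class = "offtarget_report")
}

#' @export
print.offtarget_report <- function(x, ...) {
  cat(sprintf("offtarget_report: %s (%d full-homology, %d seed hit(s))\n",
              x$verdict, nrow(x$full_homology_hits), nrow(x$seed_hits)))
  invisible(x)
}

#' Screen a duplex for immunostimulatory sequence motifs
#'
#' Optional literal-motif screen for Toll-like-receptor triggering motifs
#' (5'-UGUGU-3', 5'-GUCCUUCAA-3') and tetrad-forming poly-G stretches (>= 4
#' G). Off by default in the pipeline; exposed for users who want it.
#'
#' @param sense,antisense Duplex strands.
#' @param motifs Literal motifs to search.
#' @param polyg Minimal poly-G run length flagged.
#' @return `TRUE` when any motif occurs on either strand.
#' @export
immunostimulatory_motifs <- function(sense, antisense,
                                     motifs = c("UGUGU", "GUCCUUCAA"),
                                     polyg = 4L) {
  strands <- c(sense, antisense)
  any(vapply(strands, function(s) {
    any(vapply(motifs, grepl, logical(1), x = s, fixed = TRUE)) ||
      grepl(sprintf("G{%d,}", polyg), s)
  }, logical(1)))
}
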