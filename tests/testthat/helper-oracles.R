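# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: substring containment by direct
# extension, off-target hits by per-offset comparison, structure ensembles by
# explicit enumeration.

random_rna <- function(n, alphabet = c("A", "C", "G", "U")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Maximal intervals of `ref` (0-based half-open, length >= min_len) whose
# substring occurs in every sibling: extend every start as far as possible,
# then drop intervals contained in another.
oracle_conserved <- function(ref, sibs, min_len) {
  n <- nchar(ref)
  if (length(sibs) == 0L) return(data.frame(start = 0L, end = n))
  in_all <- function(sub) {
    all(vapply(sibs, function(x) grepl(sub, x, fixed = TRUE), logical(1)))
  }
  cand_s <- integer(0)
  cand_e <- integer(0)
  for (s in seq_len(n)) {
    e <- s - 1L
    while (e + 1L <= n && in_all(substr(ref, s, e + 1L))) e <- e + 1L
    if (e - s + 1L >= min_len) {
      cand_s <- c(cand_s, s)
      cand_e <- c(cand_e, e)
    }
  }
  keep <- vapply(seq_along(cand_s), function(i) {
    !any(cand_s <= cand_s[i] & cand_e >= cand_e[i] &
           (cand_s != cand_s[i] | cand_e != cand_e[i]))
  }, logical(1))
  out <- data.frame(start = cand_s[keep] - 1L, end = cand_e[keep])
  out[order(out$start), , drop = FALSE]
}

# Per-offset mismatch counting scan of a pattern over named transcripts,
# both the pattern and its reverse complement.
oracle_full_scan <- function(site, transcripts, max_mm,
                             intended = character()) {
  pats <- c(sense = site, antisense = reverse_complement(site))
  rows <- list()
  for (strand in names(pats)) {
    pc <- strsplit(pats[[strand]], "")[[1]]
    m <- length(pc)
    for (id in setdiff(names(transcripts), intended)) {
      tc <- strsplit(transcripts[[id]], "")[[1]]
      L <- length(tc)
      if (L < m) next
      for (off in 0:(L - m)) {
        mm <- sum(tc[(off + 1):(off + m)] != pc)
        if (mm <= max_mm) {
          rows[[length(rows) + 1L]] <-
            data.frame(id = id, offset = off, mismatches = mm,
                       strand = strand)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), offset = integer(0),
                      mismatches = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$id, out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_seed_scan <- function(guide, utrs, seed = c(2L, 7L),
                             intended = character()) {
  pat <- reverse_complement(substr(guide, seed[1], seed[2]))
  rows <- list()
  for (id in setdiff(names(utrs), intended)) {
    s <- utrs[[id]]
    m <- nchar(pat)
    if (nchar(s) < m) next
    for (off in 0:(nchar(s) - m)) {
      if (substr(s, off + 1L, off + m) == pat) {
        rows[[length(rows) + 1L]] <- data.frame(id = id, offset = off)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), offset = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

oracle_pair_weight <- function(a, b, model) {
  e <- if ((a == "G" && b == "C") || (a == "C" && b == "G")) {
    model$gc
  } else if ((a == "A" && b == "U") || (a == "U" && b == "A")) {
    model$au
  } else if ((a == "G" && b == "U") || (a == "U" && b == "G")) {
    model$gu
  } else {
    return(0)
  }
  if (is.na(e)) 0 else exp(-e / model$rt)
}

# Exhaustive Boltzmann ensemble: enumerate every nested structure obeying the
# minimum loop, sum weights, and accumulate per-position unpaired mass.
oracle_unpaired_probs <- function(seq, model = energy_model()) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i >= model$min_loop + 1L) {
        W[i, j] <- oracle_pair_weight(chars[i], chars[j], model)
      }
    }
  }
  memo <- new.env(parent = emptyenv())
  structs <- function(i, j) {
    if (i > j) return(list(integer(0)))
    key <- paste(i, j)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    out <- structs(i + 1L, j)           # i unpaired
    if (i + model$min_loop + 1L <= j) {
      rng <- seq.int(i + model$min_loop + 1L, j)
      for (k in rng[W[i, rng] > 0]) {   # i pairs k
        for (a in structs(i + 1L, k - 1L)) {
          for (b in structs(k + 1L, j)) {
            out[[length(out) + 1L]] <- c(i, k, a, b)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  all_s <- structs(1L, n)
  Z <- 0
  up <- numeric(n)
  for (s in all_s) {
    w <- 1
    if (length(s) > 0L) {
      ii <- s[seq(1L, length(s), by = 2L)]
      jj <- s[seq(2L, length(s), by = 2L)]
      w <- prod(W[cbind(ii, jj)])
    }
    Z <- Z + w
    unp <- rep(1, n)
    unp[s] <- 0
    up <- up + w * unp
  }
  up / Z
}

# Independent per-position summation for linear scorers.
oracle_linear <- function(seq, scorer) {
  chars <- strsplit(seq, "")[[1]]
  total <- scorer$intercept
  for (p in seq_along(chars)) {
    total <- total + scorer$weights[p, chars[p]]
  }
  unname(total)
}

random_coefficient_table <- function(L = 19L, id = "rand") {
  w <- matrix(runif(L * 4, -3, 3), nrow = L,
              dimnames = list(NULL, c("A", "C", "G", "U")))
  coefficient_table(id, runif(1, 0, 100), w)
}
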