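# Seed-deterministic synthetic data: multi-transcript genes built from shared
# exonic blocks interleaved with per-transcript unique exons, planted SNPs,
# and decoy transcriptomes with planted full-homology and seed off-targets.
# Backgrounds are rejection-sampled so that planted ground truth is exact:
# no accidental 19-mer (<= 1 mismatch, either strand) or seed 6-mer
# collisions with the protected site list.

#' Random RNA sequence with a given GC content
#'
#' @param n Length in nt.
#' @param gc Expected GC fraction (default 0.5).
#' @param alphabet Bases to sample from (with `gc` split evenly inside
#'   `{G,C}` and `{A,U}`).
#' @return Character scalar.
#' @export
random_seq <- function(n, gc = 0.5, alphabet = c("A", "C", "G", "U")) {
  prob <- ifelse(alphabet %in% c("G", "C"), gc / sum(alphabet %in% c("G", "C")),
                 (1 - gc) / sum(!alphabet %in% c("G", "C")))
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

#' Specification for a synthetic multi-transcript gene
#'
#' @param seed RNG seed (reproducible construction).
#' @param n_transcripts Number of transcripts (1 to 13, the isoform range
#'   typical of human genes).
#' @param shared_block_lengths Lengths of the exonic blocks shared by every
#'   transcript (the ground-truth conserved regions).
#' @param unique_exon_length Length of each per-transcript unique exon
#'   (flanks and linkers between shared blocks).
#' @param n_snps Number of SNPs planted uniformly on the reference.
#' @param gc GC content of all generated sequence.
#' @return List of class `synth_gene_spec`.
#' @export
synth_gene_spec <- function(seed = 1L, n_transcripts = 3L,
                            shared_block_lengths = c(60L, 60L),
                            unique_exon_length = 30L, n_snps = 2L,
                            gc = 0.5) {
  stopifnot(n_transcripts >= 1L, n_transcripts <= 13L,
            all(shared_block_lengths >= 1L), unique_exon_length >= 1L,
            n_snps >= 0L)
  structure(list(seed = as.integer(seed),
                 n_transcripts = as.integer(n_transcripts),
                 shared_block_lengths = as.integer(shared_block_lengths),
                 unique_exon_length = as.integer(unique_exon_length),
                 n_snps = as.integer(n_snps), gc = gc),
            class = "synth_gene_spec")
}

#' Generate a synthetic gene with known conserved regions
#'
#' Each transcript is a concatenation of the shared blocks interleaved with
#' per-transcript unique exons; the reference is the first transcript, so the
#' ground-truth conserved intervals are the block positions on it. Samples
#' are rejected and redrawn until the maximal conserved intervals of the
#' construction equal the planted blocks exactly (accidental boundary
#' extensions or cross-exon repeats are rare but possible).
#'
#' @param spec A [synth_gene_spec()].
#' @param min_len Conservation length scale used for the self-check
#'   (default 19).
#' @return List with `tset` (a [transcript_set()]), `truth` (data.frame of
#'   0-based half-open ground-truth conserved intervals on the reference)
#'   and `snps` (a [snp_records()] table).
#' @export
make_gene <- function(spec, min_len = 19L) {
  stopifnot(inherits(spec, "synth_gene_spec"))
  withr::with_seed(spec$seed, {
    nb <- length(spec$shared_block_lengths)
    for (attempt in seq_len(50L)) {
      blocks <- vapply(spec$shared_block_lengths, random_seq, character(1),
                       gc = spec$gc)
      tx <- character(spec$n_transcripts)
      for (t in seq_len(spec$n_transcripts)) {
        parts <- character(2L * nb + 1L)
        for (s in seq_len(nb + 1L)) {
          parts[2L * s - 1L] <- random_seq(spec$unique_exon_length, spec$gc)
        }
        parts[2L * seq_len(nb)] <- blocks
        tx[t] <- paste(parts, collapse = "")
      }
      names(tx) <- paste0("tx", seq_len(spec$n_transcripts))
      starts <- spec$unique_exon_length +
        cumsum(c(0L, spec$shared_block_lengths[-nb] + spec$unique_exon_length))
      truth <- if (spec$n_transcripts == 1L) {
        data.frame(start = 0L, end = nchar(tx[1]))
      } else {
        data.frame(start = as.integer(starts),
                   end = as.integer(starts + spec$shared_block_lengths))
      }
      tset <- transcript_set("synthgene", tx[1],
                             if (spec$n_transcripts > 1L) tx[-1] else
                               character())
      got <- conserved_blocks(tset, min_len = min_len)$intervals
      if (nrow(got) == nrow(truth) && all(got$start == truth$start) &&
          all(got$end == truth$end)) {
        ref_len <- nchar(tx[1])
        snp_pos <- sort(sample.int(ref_len, min(spec$n_snps, ref_len)))
        ref_chars <- strsplit(tx[[1]], "")[[1]]
        alts <- vapply(snp_pos, function(p) {
          sample(setdiff(c("A", "C", "G", "U"), ref_chars[p]), 1L)
        }, character(1))
        snps <- snp_records(rep(tset$reference_id, length(snp_pos)),
                            snp_pos, ref_chars[snp_pos], alts)
        return(list(tset = tset, truth = truth, snps = snps))
      }
    }
    stop("could not construct a clean synthetic gene in 50 attempts",
         call. = FALSE)
  })
}

# Hits of `site` (both strands, <= max_mm mismatches) in each transcript;
# naive vectorized scan used for generator self-verification.
naive_site_hits <- function(site, transcripts, max_mm = 1L) {
  pats <- c(sense = site, antisense = reverse_complement(site))
  out <- lapply(names(pats), function(strand) {
    hits <- lapply(names(transcripts), function(id) {
      mm <- mismatch_profile(transcripts[[id]], pats[[strand]])
      w <- which(mm <= max_mm)
      if (length(w) == 0L) return(NULL)
      data.frame(id = id, offset = w - 1L, mismatches = mm[w],
                 strand = strand)
    })
    do.call(rbind, hits)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(id = character(0), offset = integer(0),
                      mismatches = integer(0), strand = character(0))
  }
  out
}

clean_background <- function(n, gc, avoid19, avoid6 = character(),
                             max_mm = 1L, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    bg <- random_seq(n, gc)
    hit19 <- any(vapply(avoid19, function(p) {
      any(mismatch_profile(bg, p) <= max_mm)
    }, logical(1)))
    if (hit19) next
    hit6 <- any(vapply(avoid6, grepl, logical(1), x = bg, fixed = TRUE))
    if (!hit6) return(bg)
  }
  stop("could not sample a collision-free background", call. = FALSE)
}

#' Generate a decoy transcriptome with planted off-targets
#'
#' Decoy transcripts consist of a body plus a 3' UTR suffix (returned as a
#' separate record set, ids matching the transcriptome). Backgrounds are
#' rejection-sampled against `avoid_sites`: no 19-mer of any avoided site (or
#' its reverse complement) occurs with at most `max_mm` mismatches, and none
#' of the sites' seed-complement 6-mers (site positions 13-18) occurs in a
#' UTR. Plants then insert exact copies, one-substitution copies (into
#' bodies) or seed complements (into UTRs) of designated sites, and the
#' construction is re-verified by a naive scan so the returned ground truth
#' is exact.
#'
#' @param sites Character vector of 19-nt sites the decoys are scanned with.
#' @param plants data.frame with columns `type` (one of `"exact"`,
#'   `"mismatch1"`, `"seed"`), `site` (index into `sites`) and `decoy`
#'   (decoy number); `NULL` for a clean background.
#' @param n_decoys Number of decoy transcripts.
#' @param body_length,utr_length Lengths of body and UTR parts.
#' @param gc Background GC content.
#' @param seed RNG seed.
#' @param avoid_sites Sites protected from accidental collisions (default:
#'   `sites`).
#' @param max_mm Mismatch radius protected against (default 1).
#' @param ids Decoy ids (default `decoy1..n`).
#' @return List with `transcripts` (body + UTR), `utrs` (UTR records) and
#'   `truth` (data.frame `type`, `site`, `id`, `offset`; offsets are 0-based
#'   on the full transcript for homology plants and on the UTR record for
#'   seed plants).
#' @export
make_decoy_transcriptome <- function(sites, plants = NULL, n_decoys = 3L,
                                     body_length = 220L, utr_length = 80L,
                                     gc = 0.5, seed = 1L,
                                     avoid_sites = sites, max_mm = 1L,
                                     ids = paste0("decoy",
                                                  seq_len(n_decoys))) {
  stopifnot(all(nchar(sites) == 19L))
  avoid19 <- unique(c(avoid_sites,
                      vapply(avoid_sites, reverse_complement, character(1))))
  avoid6 <- unique(substr(avoid_sites, 13L, 18L))
  withr::with_seed(seed, {
    for (attempt in seq_len(50L)) {
      bodies <- vapply(seq_len(n_decoys), function(i) {
        clean_background(body_length, gc, avoid19)
      }, character(1))
      utrs <- vapply(seq_len(n_decoys), function(i) {
        clean_background(utr_length, gc, avoid19, avoid6)
      }, character(1))
      truth <- data.frame(type = character(0), site = integer(0),
                          id = character(0), offset = integer(0))
      ok <- TRUE
      if (!is.null(plants) && nrow(plants) > 0L) {
        for (r in seq_len(nrow(plants))) {
          d <- plants$decoy[r]
          s <- sites[[plants$site[r]]]
          if (plants$type[r] %in% c("exact", "mismatch1")) {
            insert <- s
            if (plants$type[r] == "mismatch1") {
              p <- sample.int(19L, 1L)
              substr(insert, p, p) <-
                sample(setdiff(c("A", "C", "G", "U"),
                               substr(s, p, p)), 1L)
            }
            off <- sample.int(body_length - 19L + 1L, 1L) - 1L
            substr(bodies[d], off + 1L, off + 19L) <- insert
            truth <- rbind(truth, data.frame(
              type = plants$type[r], site = plants$site[r], id = ids[d],
              offset = off))
          } else if (plants$type[r] == "seed") {
            pat <- substr(s, 13L, 18L)
            off <- sample.int(utr_length - 6L + 1L, 1L) - 1L
            substr(utrs[d], off + 1L, off + 6L) <- pat
            truth <- rbind(truth, data.frame(
              type = "seed", site = plants$site[r], id = ids[d],
              offset = off))
          } else {
            stop("unknown plant type: ", plants$type[r], call. = FALSE)
          }
        }
      }
      transcripts <- setNames(paste0(bodies, utrs), ids)
      utr_set <- setNames(utrs, ids)
      # verify: unplanted sites clean; homology plants found at their offsets
      for (si in seq_along(sites)) {
        expected <- truth[truth$site == si & truth$type != "seed", ,
                          drop = FALSE]
        got <- naive_site_hits(sites[[si]], transcripts, max_mm)
        if (nrow(expected) == 0L) {
          if (nrow(got) > 0L) { ok <- FALSE; break }
        } else {
          found <- all(mapply(function(id, off) {
            any(got$id == id & got$offset == off)
          }, expected$id, expected$offset))
          if (!found) { ok <- FALSE; break }
        }
      }
      if (ok) {
        # verify seed ground truth in UTR records
        for (si in seq_along(sites)) {
          pat <- substr(sites[[si]], 13L, 18L)
          exp_ids <- truth$id[truth$site == si & truth$type == "seed"]
          for (id in ids) {
            present <- grepl(pat, utr_set[[id]], fixed = TRUE)
            if (present != (id %in% exp_ids)) { ok <- FALSE; break }
          }
          if (!ok) break
        }
      }
      if (ok) {
        return(list(transcripts = transcripts, utrs = utr_set,
                    truth = truth))
      }
    }
    stop("could not construct a clean decoy transcriptome in 50 attempts",
         call. = FALSE)
  })
}

# Handcrafted high-scoring 19-nt sites over the {A,G} alphabet. G/C at sense
# position 1, A at 3 and 19, A-rich 3' half, 6 G+C total, no G at 13, no
# self-complementary stretch: each scores 9 on the shipped additive rule
# table (inside its 1.9-9.15 window) and top class on the ordinal table.
# With no C or U anywhere in the gene, no base pair can form, so every site
# is maximally accessible by construction.
fixture_sites <- function() {
  c(ok   = paste0("GGAGGAGGA", strrep("A", 10)),
    full = paste0("GGAGAGGGA", strrep("A", 10)),
    seed = paste0("GGAGGAGA", strrep("A", 5), "G", strrep("A", 5)))
}

#' Planted end-to-end design fixture
#'
#' Builds a synthetic gene carrying three planted high-scoring sites in an
#' unstructured (pair-free) reference, a sibling transcript embedding the
#' full reference, one SNP splitting the sequence space between the first
#' two sites, and a decoy transcriptome in which the second site has an
#' exact full-homology copy and the third site's seed complement sits in a
#' decoy 3' UTR. Under the shipped default filters the first site is
#' accepted, the second is rejected as a complete off-target and the third
#' as a seed off-target.
#'
#' @param seed RNG seed for the random parts (sibling flanks, decoy
#'   backgrounds, plant offsets).
#' @return List with `target`, `siblings`, `snps`, `transcriptome`, `utrs`
#'   (ready for [design_config()]) and `truth` (named 0-based starts of the
#'   planted sites: `accept`, `reject_full`, `reject_seed`).
#' @export
make_design_fixture <- function(seed = 1L) {
  sites <- fixture_sites()
  spacer <- strrep("A", 30)
  ref <- paste0(spacer, sites[["ok"]], spacer, sites[["full"]], spacer,
                sites[["seed"]], spacer)
  starts <- c(accept = 30L, reject_full = 79L, reject_seed = 128L)
  withr::with_seed(seed, {
    flank1 <- random_seq(15L, alphabet = c("C", "U"))
    flank2 <- random_seq(15L, alphabet = c("C", "U"))
    decoy_seed <- sample.int(.Machine$integer.max, 1L)
  })
  sibling <- c(gene_t2 = paste0(flank1, ref, flank2))
  # protect every 19-mer window of the reference, not just the planted sites
  windows <- unique(substring(ref, seq_len(nchar(ref) - 18L),
                              seq_len(nchar(ref) - 18L) + 18L))
  decoys <- make_decoy_transcriptome(
    sites = unname(sites),
    plants = data.frame(type = c("exact", "seed"), site = c(2L, 3L),
                        decoy = c(2L, 3L)),
    n_decoys = 3L, seed = decoy_seed, avoid_sites = windows
  )
  snps <- snp_records("gene_t1", 64L, "A", "G")  # mid-spacer, 0-based 63
  transcriptome <- c(c(gene_t1 = ref), sibling, decoys$transcripts)
  list(target = c(gene_t1 = ref), siblings = sibling, snps = snps,
       transcriptome = transcriptome, utrs = decoys$utrs,
       truth = starts, decoy_truth = decoys$truth)
}
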