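# End-to-end orchestration: normalize -> conserved blocks -> SNP/N masking ->
# candidate enumeration -> multi-score filter -> accessibility filter ->
# off-target filter -> optional final ranking. The three filters are
# conjunctive, so the accepted set does not depend on their order; every
# stage is evaluated for every candidate and `stage_order` only determines
# which stage a rejected candidate is attributed to.

#' Assemble and validate a design configuration
#'
#' Sequence inputs may be given as named character vectors or as FASTA paths;
#' SNPs as a [snp_records()] data.frame or a TSV/VCF path.
#'
#' @param target Reference transcript (single-record named vector or FASTA
#'   path; with a multi-record FASTA the first record is the reference unless
#'   `reference_id` names one, and the rest become siblings).
#' @param gene_id Gene identifier (default: reference id).
#' @param siblings Additional transcripts of the same gene.
#' @param snps SNP records, path, or `NULL`.
#' @param transcriptome Background transcriptome for off-target scanning.
#' @param utrs 3' UTR records (ids matching the transcriptome), or `NULL` to
#'   skip seed scanning.
#' @param reference_id Record id to use as the reference.
#' @param intended_ids Transcript ids belonging to the targeted gene
#'   (default: the reference and sibling ids).
#' @param scorers Scorer registry (default [default_scorers()]).
#' @param thresholds Threshold configuration (default
#'   [default_thresholds()]).
#' @param min_block_len Minimum conserved block length (default 19).
#' @param overhang Duplex 3' overhang (default `"UU"`).
#' @param accessibility List of accessibility options: `model`,
#'   `min_accessibility`, `windows`, `window`, `step`.
#' @param offtarget List of off-target options: `k`, `max_mismatch`, `seed`.
#' @param ranker Final efficacy ranker (function, linear `sirna_scorer`, or
#'   `NULL` to skip the ranking stage).
#' @param rank_threshold Final acceptance threshold (default: the configured
#'   final-ranker threshold, 93).
#' @param stage_order Order in which the conjunctive filters are attributed
#'   (permutation of `c("score", "accessibility", "offtarget")`).
#' @param motif_screen Also reject duplexes carrying immunostimulatory motifs
#'   (default `FALSE`; not a core workflow stage).
#' @return List of class `design_config`.
#' @export
design_config <- function(target, gene_id = NULL, siblings = character(),
                          snps = NULL, transcriptome = character(),
                          utrs = NULL, reference_id = NULL,
                          intended_ids = NULL,
                          scorers = default_scorers(),
                          thresholds = default_thresholds(),
                          min_block_len = 19L, overhang = "UU",
                          accessibility = list(), offtarget = list(),
                          ranker = NULL, rank_threshold = NULL,
                          stage_order = c("score", "accessibility",
                                          "offtarget"),
                          motif_screen = FALSE) {
  if (is.character(target) && length(target) == 1L && is.null(names(target)) &&
      file.exists(target)) {
    target <- read_fasta(target)
  } else {
    target <- vapply(target, normalize_sequence, character(1))
  }
  if (length(target) > 1L) {
    ref_i <- if (!is.null(reference_id)) {
      match(reference_id, names(target))
    } else {
      1L
    }
    if (is.na(ref_i)) stop("reference_id not found in target records",
                           call. = FALSE)
    siblings <- c(target[-ref_i], siblings)
    target <- target[ref_i]
  }
  if (is.character(siblings) && length(siblings) == 1L &&
      is.null(names(siblings)) && file.exists(siblings)) {
    siblings <- read_fasta(siblings)
  }
  if (is.character(snps) && length(snps) == 1L && file.exists(snps)) {
    snps <- read_snps(snps)
  }
  if (is.character(transcriptome) && length(transcriptome) == 1L &&
      is.null(names(transcriptome)) && file.exists(transcriptome)) {
    transcriptome <- read_fasta(transcriptome)
  }
  if (is.character(utrs) && length(utrs) == 1L && is.null(names(utrs)) &&
      file.exists(utrs)) {
    utrs <- read_fasta(utrs)
  }
  if (is.null(gene_id)) {
    gene_id <- if (!is.null(names(target))) names(target)[1] else "gene"
  }
  stopifnot(setequal(stage_order, c("score", "accessibility", "offtarget")))
  if (is.null(intended_ids)) {
    intended_ids <- c(names(target), names(siblings))
  }
  acc_defaults <- list(model = energy_model(), min_accessibility = 0.1,
                       windows = list(c(12L, 19L), c(1L, 19L)),
                       window = 80L, step = 10L)
  ot_defaults <- list(k = 9L, max_mismatch = 1L, seed = c(2L, 7L))
  accessibility <- utils::modifyList(acc_defaults, accessibility)
  offtarget <- utils::modifyList(ot_defaults, offtarget)
  if (is.null(rank_threshold)) {
    rank_threshold <- thresholds$final_ranker$threshold
    if (is.null(rank_threshold)) rank_threshold <- 93
  }
  structure(
    list(target = target, gene_id = gene_id, siblings = siblings,
         snps = snps, transcriptome = transcriptome, utrs = utrs,
         intended_ids = intended_ids, scorers = scorers,
         thresholds = thresholds, min_block_len = as.integer(min_block_len),
         overhang = overhang, accessibility = accessibility,
         offtarget = offtarget, ranker = ranker,
         rank_threshold = rank_threshold, stage_order = stage_order,
         motif_screen = isTRUE(motif_screen)),
    class = "design_config"
  )
}

#' Run the full siRNA design workflow
#'
#' Executes the seven phases: sequence normalization, conserved-block
#' detection across the gene's transcripts, SNP (and `N`) masking, 19-nt
#' candidate enumeration, multi-score intersection filtering, target-site
#' accessibility filtering, off-target filtering and (optionally) final
#' ranking. Every enumerated candidate appears exactly once in the result
#' with a terminal status.
#'
#' @param config A [design_config()].
#' @param verbose Log per-stage counts to stderr.
#' @return List of class `design_result`: `gene_id`, `reference_id`,
#'   `reference`, `space`, `candidates` (full annotated table),
#'   `accepted` (accepted subset in rank order), `stage_counts`, `config`.
#' @export
run_design <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "design_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  tset <- transcript_set(config$gene_id, config$target, config$siblings)
  space <- conserved_blocks(tset, config$min_block_len)
  say("conserved space: %d interval(s), %d nt", nrow(space$intervals),
      space_coverage(space))
  space <- mask_ns(space, tset$reference)
  if (!is.null(config$snps) && nrow(config$snps) > 0L) {
    space <- mask_snps(space, config$snps)
  }
  say("after SNP/N masking: %d interval(s), %d nt", nrow(space$intervals),
      space_coverage(space))

  cands <- enumerate_candidates(space, tset$reference, config$overhang)
  say("enumerated %d candidate(s)", nrow(cands))
  n <- nrow(cands)

  empty_result <- function() {
    structure(list(gene_id = config$gene_id,
                   reference_id = tset$reference_id,
                   reference = tset$reference, space = space,
                   candidates = cands, accepted = cands,
                   stage_counts = c(enumerated = 0L, accepted = 0L),
                   config = config),
              class = "design_result")
  }
  if (n == 0L) return(empty_result())

  # Stage: multi-score intersection
  sc <- score_candidates(cands$site, config$scorers, config$thresholds)
  tab <- cbind(cands, sc)
  tab$score_pass <- sc$ensemble_accept

  # Stage: accessibility
  acc <- config$accessibility
  tab <- accessibility_filter(tab, tset$reference, model = acc$model,
                              min_accessibility = acc$min_accessibility,
                              windows = acc$windows, window = acc$window,
                              step = acc$step)

  # Stage: off-target
  ot <- config$offtarget
  verdicts <- rep("accept", n)
  n_full <- n_seed <- integer(n)
  if (length(config$transcriptome) > 0L) {
    index <- build_kmer_index(config$transcriptome, ot$k)
    for (i in seq_len(n)) {
      fh <- scan_full_homology(tab$site[i], index, ot$max_mismatch,
                               config$intended_ids)
      sh <- if (!is.null(config$utrs) && length(config$utrs) > 0L) {
        scan_seed(tab$antisense[i], config$utrs, ot$seed,
                  config$intended_ids)
      } else {
        data.frame(id = character(0), offset = integer(0))
      }
      rep <- offtarget_filter(fh, sh, candidate = tab$start[i])
      verdicts[i] <- rep$verdict
      n_full[i] <- nrow(fh)
      n_seed[i] <- nrow(sh)
    }
  }
  tab$offtarget_verdict <- verdicts
  tab$n_full_hits <- n_full
  tab$n_seed_hits <- n_seed
  tab$offtarget_pass <- verdicts == "accept"
  if (config$motif_screen) {
    flagged <- mapply(immunostimulatory_motifs, tab$sense, tab$antisense)
    tab$offtarget_pass <- tab$offtarget_pass & !flagged
    tab$motif_flag <- flagged
  }

  # Stage: final ranking (optional)
  if (!is.null(config$ranker)) {
    f <- if (inherits(config$ranker, "sirna_scorer")) {
      function(site) linear_score(site, config$ranker)
    } else {
      match.fun(config$ranker)
    }
    rs <- vapply(tab$site, function(s) as.numeric(f(s)), numeric(1),
                 USE.NAMES = FALSE)
    if (any(!is.finite(rs))) {
      stop("final ranker returned non-finite score(s)", call. = FALSE)
    }
    tab$rank_score <- rs
    tab$rank_pass <- rs > config$rank_threshold
  } else {
    tab$rank_score <- NA_real_
    tab$rank_pass <- TRUE
    say("no final ranker configured; ranking stage skipped")
  }

  pass_of <- list(score = tab$score_pass,
                  accessibility = tab$access_pass,
                  offtarget = tab$offtarget_pass)
  status <- rep("accepted", n)
  for (stage in rev(c(config$stage_order, "rank"))) {
    fail <- if (stage == "rank") !tab$rank_pass else !pass_of[[stage]]
    status[fail] <- paste0("rejected_", stage)
  }
  if (is.null(config$ranker)) {
    status[status == "rejected_rank"] <- "accepted"   # unreachable; safety
  }
  tab$status <- status

  accepted <- tab[tab$status == "accepted", , drop = FALSE]
  if (!is.null(config$ranker)) {
    accepted <- accepted[order(-accepted$rank_score, accepted$start), ,
                         drop = FALSE]
  }
  rownames(accepted) <- NULL

  counts <- c(enumerated = n, table(factor(
    status, levels = c(paste0("rejected_", c(config$stage_order, "rank")),
                       "accepted"))))
  say("per-stage: %s", paste(names(counts), counts, sep = "=",
                             collapse = ", "))
  structure(list(gene_id = config$gene_id, reference_id = tset$reference_id,
                 reference = tset$reference, space = space, candidates = tab,
                 accepted = accepted, stage_counts = counts,
                 config = config),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("siRNA design result for gene", x$gene_id, "\n")
  cat("  sequence space:", nrow(x$space$intervals), "interval(s),",
      space_coverage(x$space), "nt\n")
  cat("  candidates:", nrow(x$candidates), " accepted:", nrow(x$accepted),
      "\n")
  if (length(x$stage_counts) > 2L) {
    cat("  per stage:", paste(names(x$stage_counts), x$stage_counts,
                              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", as.character(signif(x, 4)))
}

#' Write design results as annotated FASTA plus a TSV sidecar
#'
#' Each accepted candidate produces two FASTA records: the sense strand under
#' a header carrying position, per-scorer scores, accessibility, total
#' interaction energy, rank score and status, then the antisense strand under
#' the same header suffixed `|strand=antisense`. Numbers are printed with 4
#' significant digits. The TSV sidecar lists every enumerated candidate with
#' its per-stage verdicts.
#'
#' @param result A `design_result`.
#' @param path Output FASTA path.
#' @param tsv_path Output TSV path (default: `path` + `".tsv"`).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, tsv_path = paste0(path, ".tsv")) {
  stopifnot(inherits(result, "design_result"))
  acc <- result$accepted
  score_cols <- grep("^score\\.", names(acc), value = TRUE)
  lines <- character(0)
  if (nrow(acc) > 0L) {
    for (i in seq_len(nrow(acc))) {
      kv <- paste0(sub("^score\\.", "", score_cols), "=",
                   fmt_num(unlist(acc[i, score_cols])), collapse = "|")
      head <- sprintf("%s|pos=%d-%d|%s|access=%s|dG=%s|rank=%s|status=%s",
                      result$gene_id, acc$start[i], acc$start[i] + SITE_LEN,
                      kv, fmt_num(acc$accessibility[i]),
                      fmt_num(acc$dG_total[i]), fmt_num(acc$rank_score[i]),
                      acc$status[i])
      lines <- c(lines,
                 paste0(">", head), acc$sense[i],
                 paste0(">", head, "|strand=antisense"), acc$antisense[i])
    }
  }
  writeLines(lines, path)
  tab <- result$candidates
  keep <- setdiff(names(tab), c("sense", "antisense"))
  write.table(tab[, keep, drop = FALSE], tsv_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a results FASTA written by [write_results()]
#'
#' @param path Path to the FASTA.
#' @return data.frame with one row per sense record: `gene`, `start`, `end`,
#'   one numeric column per scorer, `access`, `dG`, `rank`, `status`,
#'   `sense`, `antisense`.
#' @export
parse_result_fasta <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(data.frame(gene = character(0), start = integer(0)))
  }
  heads <- lines[seq(1L, length(lines), by = 4L)]
  sense <- lines[seq(2L, length(lines), by = 4L)]
  anti <- lines[seq(4L, length(lines), by = 4L)]
  rows <- lapply(seq_along(heads), function(i) {
    fields <- strsplit(sub("^>", "", heads[i]), "|", fixed = TRUE)[[1]]
    gene <- fields[1]
    kv <- strsplit(fields[-1], "=", fixed = TRUE)
    vals <- setNames(vapply(kv, `[[`, character(1), 2L),
                     vapply(kv, `[[`, character(1), 1L))
    pos <- as.integer(strsplit(vals[["pos"]], "-", fixed = TRUE)[[1]])
    num <- setNames(suppressWarnings(as.numeric(vals)), names(vals))
    out <- data.frame(gene = gene, start = pos[1], end = pos[2])
    for (k in setdiff(names(vals), c("pos", "status", "strand"))) {
      out[[k]] <- num[[k]]
    }
    out$status <- vals[["status"]]
    out$sense <- sense[i]
    out$antisense <- anti[i]
    out
  })
  do.call(rbind, rows)
}
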