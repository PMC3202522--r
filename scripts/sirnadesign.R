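#!/usr/bin/env Rscript

# Thin command-line wrapper over the sirnadesign package.
#
#   Rscript scripts/sirnadesign.R run --target t.fa --transcriptome tx.fa \
#       [--siblings s.fa] [--snps snps.tsv|.vcf] [--utrs utr.fa] \
#       [--rank-threshold 93] [--min-block-len 19] --out results.fa
#   Rscript scripts/sirnadesign.R thresholds --scores scores.tsv
#   Rscript scripts/sirnadesign.R synth --seed 1 --out dir/
#
# `thresholds` expects a one-column (or first-column) table of scores of
# high-efficacy siRNAs and prints the mean +/- 2 SD acceptance window.

suppressPackageStartupMessages({
  library(sirnadesign)
  library(optparse)
})

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) < 1L) {
  stop("usage: sirnadesign.R <run|thresholds|synth> [options]")
}
cmd <- argv[1]
rest <- argv[-1]

if (cmd == "run") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--target", type = "character"),
    make_option("--siblings", type = "character", default = NULL),
    make_option("--snps", type = "character", default = NULL),
    make_option("--transcriptome", type = "character"),
    make_option("--utrs", type = "character", default = NULL),
    make_option("--ranker", type = "character", default = NULL,
                help = "coefficient table (YAML/TSV) for the final ranker"),
    make_option("--rank-threshold", type = "double", default = NULL,
                dest = "rank_threshold"),
    make_option("--min-block-len", type = "integer", default = 19L,
                dest = "min_block_len"),
    make_option("--out", type = "character", default = "results.fa")
  )), args = rest)
  cfg <- design_config(
    target = opts$target,
    siblings = if (is.null(opts$siblings)) character() else opts$siblings,
    snps = opts$snps,
    transcriptome = if (is.null(opts$transcriptome)) character() else
      opts$transcriptome,
    utrs = opts$utrs,
    ranker = if (is.null(opts$ranker)) NULL else read_scorer(opts$ranker),
    rank_threshold = opts$rank_threshold,
    min_block_len = opts$min_block_len
  )
  res <- run_design(cfg, verbose = TRUE)
  write_results(res, opts$out)
  message("wrote ", opts$out, " and ", opts$out, ".tsv")
} else if (cmd == "thresholds") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--scores", type = "character")
  )), args = rest)
  scores <- read.table(opts$scores, header = FALSE)[[1]]
  th <- derive_thresholds(scores)
  cat(sprintf("min_threshold\t%.4f\nmax_threshold\t%.4f\n",
              th[["min"]], th[["max"]]))
} else if (cmd == "synth") {
  opts <- parse_args(OptionParser(option_list = list(
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = "synth")
  )), args = rest)
  dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
  fx <- make_design_fixture(seed = opts$seed)
  write_fasta(fx$target, file.path(opts$out, "target.fa"))
  write_fasta(fx$siblings, file.path(opts$out, "siblings.fa"))
  write_fasta(fx$transcriptome, file.path(opts$out, "transcriptome.fa"))
  write_fasta(fx$utrs, file.path(opts$out, "utrs.fa"))
  writeLines(sprintf("%s\t%d\t%s\t%s", fx$snps$transcript_id, fx$snps$pos,
                     fx$snps$ref, fx$snps$alt),
             file.path(opts$out, "snps.tsv"))
  writeLines(sprintf("%s\t%d", names(fx$truth), fx$truth),
             file.path(opts$out, "planted_truth.tsv"))
  message("fixture written to ", opts$out)
} else {
  stop("unknown command: ", cmd)
}
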