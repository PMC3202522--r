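# Ensemble efficacy scoring. Two scorer families are supported:
#   * first-generation rule tables (position preferences, composition windows,
#     absence-of-stretch criteria), either additive ("rules") or ordinal
#     class-based ("ordinal");
#   * second-generation linear models (intercept + position x base weights),
#     predicting percent inhibition.
# Acceptance is the intersection of all registered scorers: first-generation
# scores must fall inside a [min, max] window derived as mean +/- 2 SD of
# scores of high-efficacy training siRNAs; second-generation predictions must
# reach a minimum predicted inhibition (default 70). Tables are data files,
# not code: the engine plus schema is the contract, and the shipped defaults
# are documented rule sets in inst/extdata/scorers/.

RNA_BASES <- c("A", "C", "G", "U")

site_chars <- function(site) {
  if (nchar(site) != SITE_LEN || grepl("[^ACGU]", site)) {
    stop("scoring expects a 19-nt A/C/G/U site", call. = FALSE)
  }
  strsplit(site, "")[[1]]
}

# Does the site contain a self-complementary stretch of at least `min_len`
# nt, i.e. a substring whose reverse complement is also a substring? Used as
# a deterministic proxy for internal-hairpin propensity.
has_self_complementary_stretch <- function(site, min_len) {
  n <- nchar(site)
  if (min_len > n) return(FALSE)
  for (i in seq_len(n - min_len + 1L)) {
    sub <- substr(site, i, i + min_len - 1L)
    if (grepl(reverse_complement(sub), site, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

validate_rule <- function(rule) {
  if (is.null(rule$kind)) stop("rule without a `kind`", call. = FALSE)
  switch(rule$kind,
    base_at_position = {
      pos <- as.integer(unlist(rule$positions))
      if (any(pos < 1L | pos > SITE_LEN)) {
        stop("rule position outside 1..", SITE_LEN, call. = FALSE)
      }
    },
    composition_window = {
      w <- as.integer(unlist(rule$window))
      if (length(w) != 2L || w[1] < 1L || w[2] > SITE_LEN || w[1] > w[2]) {
        stop("composition window must lie within 1..", SITE_LEN, call. = FALSE)
      }
    },
    absence_of_stretch = {
      if (as.integer(rule$min_len) < 1L) {
        stop("stretch length must be positive", call. = FALSE)
      }
    },
    stop("unknown rule kind: ", rule$kind, call. = FALSE)
  )
  invisible(rule)
}

# TRUE/FALSE for composition_window and absence_of_stretch; a count of
# matching positions for base_at_position.
eval_rule <- function(chars, site, rule) {
  switch(rule$kind,
    base_at_position = {
      sum(chars[as.integer(unlist(rule$positions))] %in% unlist(rule$bases))
    },
    composition_window = {
      w <- as.integer(unlist(rule$window))
      cnt <- sum(chars[w[1]:w[2]] %in% unlist(rule$bases))
      as.integer(cnt >= rule$min_count && cnt <= rule$max_count)
    },
    absence_of_stretch = {
      k <- as.integer(rule$min_len)
      if (identical(rule$stretch, "self_complementary")) {
        as.integer(!has_self_complementary_stretch(site, k))
      } else {
        pat <- sprintf("[%s]{%d,}", paste(unlist(rule$stretch), collapse = ""), k)
        as.integer(!grepl(pat, site))
      }
    }
  )
}

#' Construct a first-generation rule-table scorer
#'
#' @param scorer_id Scorer identifier (used to look up its thresholds).
#' @param rules List of rules; each has `kind` (one of `base_at_position`,
#'   `composition_window`, `absence_of_stretch`) plus kind-specific fields and
#'   a `weight`.
#' @param score_range Numeric `c(min, max)` of attainable scores.
#' @return Scorer object of class `sirna_scorer`.
#' @export
rule_table <- function(scorer_id, rules, score_range) {
  lapply(rules, validate_rule)
  w <- vapply(rules, function(r) as.numeric(r$weight), numeric(1))
  if (any(!is.finite(w))) stop("rule weights must be finite", call. = FALSE)
  structure(list(scorer_id = scorer_id, generation = 1L, type = "rules",
                 rules = rules, score_range = as.numeric(score_range)),
            class = "sirna_scorer")
}

#' Construct an ordinal (class-based) first-generation scorer
#'
#' Conditions are rules without weights; the returned score is the 0-based
#' index into `classes` (worst to best), assigned from the number of satisfied
#' conditions: all conditions give the top class, and each unmet condition
#' drops one class (floored at the worst class).
#'
#' @param scorer_id Scorer identifier.
#' @param conditions List of rules (a `base_at_position` condition is
#'   satisfied when all its positions match).
#' @param classes Character vector of class labels, worst first.
#' @return Scorer object of class `sirna_scorer`.
#' @export
ordinal_table <- function(scorer_id, conditions, classes) {
  lapply(conditions, validate_rule)
  if (length(classes) < 2L) stop("need at least two classes", call. = FALSE)
  structure(list(scorer_id = scorer_id, generation = 1L, type = "ordinal",
                 conditions = conditions, classes = as.character(classes)),
            class = "sirna_scorer")
}

#' Construct a second-generation linear scorer
#'
#' Score = intercept + sum over positions of `weights[position, base]`.
#'
#' @param scorer_id Scorer identifier.
#' @param intercept Numeric intercept.
#' @param weights Numeric matrix, `L` rows (positions) by 4 columns named
#'   `A`, `C`, `G`, `U`.
#' @return Scorer object of class `sirna_scorer`.
#' @export
coefficient_table <- function(scorer_id, intercept, weights) {
  weights <- as.matrix(weights)
  if (!all(RNA_BASES %in% colnames(weights))) {
    stop("weight matrix needs columns A, C, G, U", call. = FALSE)
  }
  weights <- weights[, RNA_BASES, drop = FALSE]
  if (!nrow(weights) %in% c(19L, 21L)) {
    stop("linear scorers support site length 19 or 21", call. = FALSE)
  }
  if (any(!is.finite(weights)) || !is.finite(intercept)) {
    stop("coefficients must be finite", call. = FALSE)
  }
  structure(list(scorer_id = scorer_id, generation = 2L, type = "linear",
                 intercept = as.numeric(intercept), weights = weights,
                 length = nrow(weights)),
            class = "sirna_scorer")
}

#' @export
print.sirna_scorer <- function(x, ...) {
  cat(sprintf("scorer '%s' (generation %d, %s)\n",
              x$scorer_id, x$generation, x$type))
  invisible(x)
}

#' Read a scorer definition from a YAML or TSV file
#'
#' YAML files describe rule, ordinal or linear scorers (field `type`). TSV
#' files describe linear scorers: columns `position`, `A`, `C`, `G`, `U`,
#' with the row at position 0 holding the intercept in column `A`.
#'
#' @param path Path to the scorer file.
#' @return A `sirna_scorer`.
#' @export
read_scorer <- function(path) {
  if (grepl("\\.(ya?ml)$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    switch(y$type,
      rules = rule_table(y$scorer_id, y$rules, unlist(y$score_range)),
      ordinal = ordinal_table(y$scorer_id, y$conditions, unlist(y$classes)),
      linear = {
        w <- do.call(rbind, lapply(y$weights, function(r) unlist(r[RNA_BASES])))
        coefficient_table(y$scorer_id, y$intercept, w)
      },
      stop("unknown scorer type: ", y$type, call. = FALSE)
    )
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    stopifnot(all(c("position", RNA_BASES) %in% names(tab)))
    inter_row <- tab$position == 0L
    intercept <- if (any(inter_row)) tab$A[inter_row][1] else 0
    w <- as.matrix(tab[!inter_row, RNA_BASES, drop = FALSE])
    rownames(w) <- tab$position[!inter_row]
    w <- w[order(as.integer(rownames(w))), , drop = FALSE]
    id <- sub("\\.[^.]*$", "", basename(path))
    coefficient_table(id, intercept, w)
  }
}

#' Score a site with a first-generation rule or ordinal scorer
#'
#' Rule scorers return the weighted sum of satisfied rules (a
#' `base_at_position` rule contributes its weight once per matching
#' position). Ordinal scorers return the 0-based class index.
#'
#' @param site 19-nt sense target site.
#' @param scorer A `sirna_scorer` of type `rules` or `ordinal`.
#' @return Numeric score.
#' @export
rule_score <- function(site, scorer) {
  stopifnot(inherits(scorer, "sirna_scorer"))
  chars <- site_chars(site)
  if (scorer$type == "rules") {
    if (length(scorer$rules) == 0L) return(0)
    sum(vapply(scorer$rules, function(r) {
      as.numeric(r$weight) * eval_rule(chars, site, r)
    }, numeric(1)))
  } else if (scorer$type == "ordinal") {
    sat <- vapply(scorer$conditions, function(r) {
      v <- eval_rule(chars, site, r)
      if (r$kind == "base_at_position") {
        v == length(unlist(r$positions))
      } else {
        v == 1L
      }
    }, logical(1))
    top <- length(scorer$classes) - 1L
    max(0L, top - sum(!sat))
  } else {
    stop("rule_score applies to rule/ordinal scorers; see linear_score",
         call. = FALSE)
  }
}

#' Score a sequence with a second-generation linear scorer
#'
#' @param seq Sequence of length matching the scorer (19 or 21 nt, A/C/G/U).
#' @param scorer A `sirna_scorer` of type `linear`.
#' @return Numeric predicted inhibition.
#' @export
linear_score <- function(seq, scorer) {
  stopifnot(inherits(scorer, "sirna_scorer"), scorer$type == "linear")
  if (nchar(seq) != scorer$length) {
    stop("sequence length ", nchar(seq), " does not match scorer length ",
         scorer$length, call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  if (any(!chars %in% RNA_BASES)) {
    stop("linear scoring expects A/C/G/U only", call. = FALSE)
  }
  idx <- cbind(seq_len(scorer$length), match(chars, RNA_BASES))
  scorer$intercept + sum(scorer$weights[idx])
}

#' Evaluate any scorer on a site
#'
#' @param scorer A `sirna_scorer`.
#' @param site 19-nt site (or scorer-length sequence for linear scorers).
#' @return Numeric score.
#' @export
evaluate_scorer <- function(scorer, site) {
  if (scorer$type == "linear") linear_score(site, scorer) else
    rule_score(site, scorer)
}

#' Derive acceptance thresholds from high-efficacy training scores
#'
#' The acceptance window for a first-generation scorer is the mean of the
#' scores of experimentally high-efficacy siRNAs, minus and plus two sample
#' standard deviations.
#'
#' @param active_scores Numeric vector of at least two scores of
#'   high-efficacy siRNAs.
#' @return Named numeric `c(min = mean - 2*sd, max = mean + 2*sd)`.
#' @examples
#' derive_thresholds(c(1, 2, 3))  # c(min = 0, max = 4)
#' @export
derive_thresholds <- function(active_scores) {
  active_scores <- as.numeric(active_scores)
  if (length(active_scores) < 2L || any(!is.finite(active_scores))) {
    stop("need at least two finite scores", call. = FALSE)
  }
  m <- mean(active_scores)
  s <- stats::sd(active_scores)
  c(min = m - 2 * s, max = m + 2 * s)
}

#' Shipped default threshold configuration
#'
#' Reads `inst/extdata/thresholds.yaml`: per first-generation scorer a
#' `[min, max]` window (or a minimum ordinal class), a second-generation
#' minimum predicted inhibition (70), and the final-ranker threshold (93).
#'
#' @param path Optional path to an alternative YAML file.
#' @return Threshold configuration list of class `threshold_config`.
#' @export
default_thresholds <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "thresholds.yaml", package = "sirnadesign")
  }
  y <- yaml::read_yaml(path)
  for (id in names(y$first_generation)) {
    th <- y$first_generation[[id]]
    if (!is.null(th$min) && !is.null(th$max) && th$min > th$max) {
      stop("threshold min > max for scorer ", id, call. = FALSE)
    }
  }
  structure(y, class = "threshold_config")
}

#' Shipped default scorer registry
#'
#' Loads the documented first-generation defaults from
#' `inst/extdata/scorers/`: an additive rule table (`reynolds_like`) and an
#' ordinal condition set (`ui_tei_like`).
#'
#' @return Named list of `sirna_scorer` objects.
#' @export
default_scorers <- function() {
  dir <- system.file("extdata", "scorers", package = "sirnadesign")
  paths <- c(reynolds_like = file.path(dir, "reynolds_like.yaml"),
             ui_tei_like = file.path(dir, "ui_tei_like.yaml"))
  lapply(paths, read_scorer)
}

scorer_accept <- function(scorer, score, thresholds) {
  if (scorer$generation == 2L) {
    min_inh <- thresholds$second_generation$min_inhibition
    if (is.null(min_inh)) {
      stop("no second-generation minimum inhibition configured", call. = FALSE)
    }
    return(score >= min_inh)
  }
  th <- thresholds$first_generation[[scorer$scorer_id]]
  if (is.null(th)) {
    stop("no thresholds configured for scorer ", scorer$scorer_id,
         call. = FALSE)
  }
  if (scorer$type == "ordinal") {
    min_class <- match(th$min_class, scorer$classes) - 1L
    if (is.na(min_class)) {
      stop("unknown ordinal class ", th$min_class, " for scorer ",
           scorer$scorer_id, call. = FALSE)
    }
    score >= min_class
  } else {
    score >= th$min && score <= th$max
  }
}

#' Apply the multi-score intersection filter to one score panel
#'
#' First-generation scorers accept when their score lies inside the
#' configured `[min, max]` window (ordinal scorers: class at least the
#' configured minimum class); second-generation scorers accept when predicted
#' inhibition reaches the configured minimum. The ensemble accepts only if
#' every registered scorer accepts.
#'
#' @param scores Named numeric vector of raw scores, names matching
#'   `scorers`.
#' @param scorers Named list of registered `sirna_scorer`s.
#' @param thresholds A `threshold_config` (see [default_thresholds()]).
#' @return List of class `score_panel` with `scores`, `accept` and
#'   `ensemble_accept`.
#' @export
apply_filter <- function(scores, scorers, thresholds = default_thresholds()) {
  if (length(scorers) == 0L) {
    stop("no scorers registered", call. = FALSE)
  }
  stopifnot(all(names(scorers) %in% names(scores)))
  accept <- vapply(names(scorers), function(id) {
    scorer_accept(scorers[[id]], scores[[id]], thresholds)
  }, logical(1))
  structure(list(scores = scores[names(scorers)], accept = accept,
                 ensemble_accept = all(accept)),
            class = "score_panel")
}

#' Score candidate sites with a scorer registry
#'
#' @param sites Character vector of 19-nt sites (or a `sirna_candidates`
#'   data.frame, whose `site` column is used).
#' @param scorers Named list of `sirna_scorer`s (default: shipped registry).
#' @param thresholds A `threshold_config`.
#' @return A data.frame with one row per site: `score.<id>` and
#'   `accept.<id>` per scorer plus `ensemble_accept`.
#' @export
score_candidates <- function(sites, scorers = default_scorers(),
                             thresholds = default_thresholds()) {
  if (is.data.frame(sites)) sites <- sites$site
  if (length(scorers) == 0L) stop("no scorers registered", call. = FALSE)
  if (is.null(names(scorers))) {
    names(scorers) <- vapply(scorers, `[[`, character(1), "scorer_id")
  }
  out <- data.frame(row.names = seq_along(sites))
  accept_all <- rep(TRUE, length(sites))
  for (id in names(scorers)) {
    sc <- vapply(sites, evaluate_scorer, numeric(1),
                 scorer = scorers[[id]], USE.NAMES = FALSE)
    ac <- vapply(sc, function(s) {
      scorer_accept(scorers[[id]], s, thresholds)
    }, logical(1))
    out[[paste0("score.", id)]] <- sc
    out[[paste0("accept.", id)]] <- ac
    accept_all <- accept_all & ac
  }
  out$ensemble_accept <- accept_all
  out
}

#' Rank accepted candidates with a pluggable final scorer
#'
#' The final ranker re-evaluates candidates with a user-supplied efficacy
#' model returning a predicted inhibition in `[0, 100]`; candidates scoring
#' strictly above `threshold` are returned sorted by decreasing score. Ties
#' keep input order (stable sort, then candidate start ascending).
#'
#' @param candidates A data.frame with at least `site` (and optionally
#'   `start`) columns.
#' @param ranker Function mapping a 19-nt site to a numeric score in
#'   `[0, 100]`, or a linear `sirna_scorer`.
#' @param threshold Acceptance threshold (default 93).
#' @return The accepted subset with a `rank_score` column, ordered by
#'   decreasing score.
#' @export
final_rank <- function(candidates, ranker, threshold = 93) {
  stopifnot(is.data.frame(candidates), "site" %in% names(candidates))
  f <- if (inherits(ranker, "sirna_scorer")) {
    function(site) linear_score(site, ranker)
  } else {
    match.fun(ranker)
  }
  scores <- vapply(candidates$site, function(s) as.numeric(f(s)), numeric(1),
                   USE.NAMES = FALSE)
  if (any(!is.finite(scores))) {
    stop("final ranker returned non-finite score(s)", call. = FALSE)
  }
  out <- candidates
  out$rank_score <- scores
  out <- out[scores > threshold, , drop = FALSE]
  key2 <- if ("start" %in% names(out)) out$start else seq_len(nrow(out))
  out <- out[order(-out$rank_score, key2), , drop = FALSE]
  rownames(out) <- NULL
  out
}
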