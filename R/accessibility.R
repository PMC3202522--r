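# Target-site accessibility. The RISC machinery binds single-stranded mRNA
# and cannot unwind structure, so candidates are gated on (i) the probability
# that the target site is unpaired in the Boltzmann ensemble of the mRNA's
# secondary structures, and (ii) the total interaction energy: hybridization
# energy of the guide:site duplex plus the opening energy -RT * ln P(site
# unpaired). The structure model is a deliberately simple Boltzmann-weighted
# base-pair-sum over nested structures (no pseudoknots, no nearest-neighbor
# stacking terms), which keeps the module self-contained and exactly
# verifiable against exhaustive structure enumeration; an external
# per-position probability backend can be plugged in instead.

#' Energy model for the base-pairing partition function
#'
#' @param gc,au,gu Pair energies in kcal/mol (must be <= 0). `NA` disables a
#'   pair type entirely (e.g. `gu = NA` for a wobble-free, strictly
#'   Watson-Crick model).
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param rt Thermal energy RT in kcal/mol (default 0.6163, 37 C).
#' @return List of class `energy_model`.
#' @export
energy_model <- function(gc = -3.0, au = -2.0, gu = -1.0, min_loop = 3L,
                         rt = 0.6163) {
  e <- c(gc, au, gu)
  if (any(e[!is.na(e)] > 0)) stop("pair energies must be <= 0", call. = FALSE)
  if (min_loop < 0L) stop("min_loop must be >= 0", call. = FALSE)
  if (rt <= 0) stop("rt must be positive", call. = FALSE)
  structure(list(gc = gc, au = au, gu = gu, min_loop = as.integer(min_loop),
                 rt = rt),
            class = "energy_model")
}

encode_rna <- function(seq) {
  m <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U", "N")) - 1L
  if (any(is.na(m))) stop("sequence must be over A/C/G/U/N", call. = FALSE)
  m
}

pair_weights <- function(model) {
  w <- function(e) if (is.na(e)) 0 else exp(-e / model$rt)
  c(gc = w(model$gc), au = w(model$au), gu = w(model$gu))
}

new_accessibility_profile <- function(id, p_unpaired, window, step) {
  stopifnot(all(p_unpaired >= 0 & p_unpaired <= 1 + 1e-12))
  structure(list(id = id, p_unpaired = pmin(p_unpaired, 1),
                 window = window, step = step),
            class = "accessibility_profile")
}

#' Per-position unpaired probabilities of a whole sequence
#'
#' Computes, for every position, the Boltzmann probability of being unpaired
#' over all nested secondary structures obeying the minimum hairpin loop,
#' under the pair-sum energy model. Positions holding `N` cannot pair and get
#' probability 1.
#'
#' @param seq RNA sequence (A/C/G/U/N).
#' @param model An [energy_model()].
#' @param id Sequence id stored in the profile.
#' @return An `accessibility_profile` with `p_unpaired` of length
#'   `nchar(seq)`.
#' @export
pair_partition <- function(seq, model = energy_model(), id = "seq") {
  stopifnot(inherits(model, "energy_model"))
  seq <- normalize_sequence(seq)
  if (nchar(seq) < 1L) stop("sequence must be non-empty", call. = FALSE)
  w <- pair_weights(model)
  p <- unpaired_probs_cpp(encode_rna(seq), w[["gc"]], w[["au"]], w[["gu"]],
                          model$min_loop)
  new_accessibility_profile(id, p, window = nchar(seq), step = nchar(seq))
}

#' Local-window accessibility profile of a transcript
#'
#' Slides a folding window of length `window` over the transcript in steps of
#' `step` (a final window flush with the 3' end is always included) and
#' averages per-position unpaired probabilities across all windows covering a
#' position. When `window >= nchar(seq)` this reduces to a single global
#' fold.
#'
#' @param seq RNA sequence.
#' @param model An [energy_model()].
#' @param window Folding window length in nt (default 80).
#' @param step Window step in nt (default 10).
#' @param id Sequence id stored in the profile.
#' @return An `accessibility_profile`.
#' @export
fold_accessibility <- function(seq, model = energy_model(), window = 80L,
                               step = 10L, id = "seq") {
  stopifnot(inherits(model, "energy_model"))
  seq <- normalize_sequence(seq)
  n <- nchar(seq)
  if (n < 1L) stop("sequence must be non-empty", call. = FALSE)
  window <- as.integer(window)
  step <- as.integer(step)
  if (window < 1L || step < 1L) stop("window and step must be >= 1", call. = FALSE)
  if (window >= n) {
    p <- pair_partition(seq, model, id = id)$p_unpaired
    return(new_accessibility_profile(id, p, window, step))
  }
  starts0 <- seq.int(0L, n - window, by = step)
  if (starts0[length(starts0)] != n - window) starts0 <- c(starts0, n - window)
  acc <- numeric(n)
  cnt <- numeric(n)
  enc <- encode_rna(seq)
  w <- pair_weights(model)
  for (s in starts0) {
    idx <- (s + 1L):(s + window)
    p <- unpaired_probs_cpp(enc[idx], w[["gc"]], w[["au"]], w[["gu"]],
                            model$min_loop)
    acc[idx] <- acc[idx] + p
    cnt[idx] <- cnt[idx] + 1
  }
  new_accessibility_profile(id, acc / cnt, window, step)
}

#' Accessibility score of a 19-nt target site
#'
#' Geometric mean, over the configured sub-windows of the site, of the mean
#' unpaired probability inside each sub-window. The defaults weight the
#' site's 3' end (positions 12-19, where RISC seeds target recognition)
#' together with the full site.
#'
#' @param profile An `accessibility_profile` of the transcript.
#' @param site_start 0-based start of the site on the transcript.
#' @param windows List of 1-based inclusive `c(from, to)` sub-intervals
#'   relative to the site.
#' @param site_len Site length (default 19).
#' @return Accessibility score in `[0, 1]`.
#' @export
site_accessibility <- function(profile, site_start,
                               windows = list(c(12L, 19L), c(1L, 19L)),
                               site_len = 19L) {
  stopifnot(inherits(profile, "accessibility_profile"))
  site_start <- as.integer(site_start)
  n <- length(profile$p_unpaired)
  if (site_start < 0L || site_start + site_len > n) {
    stop("site outside profile", call. = FALSE)
  }
  means <- vapply(windows, function(w) {
    w <- as.integer(w)
    if (w[1] < 1L || w[2] > site_len || w[1] > w[2]) {
      stop("accessibility window outside the site", call. = FALSE)
    }
    mean(profile$p_unpaired[(site_start + w[1]):(site_start + w[2])])
  }, numeric(1))
  prod(means)^(1 / length(means))
}

#' Total guide:target interaction energy
#'
#' `dG_total = dG_hybridization + dG_open`, where hybridization is the sum of
#' pair energies over the 19 guide:site Watson-Crick pairs and the opening
#' cost is `-RT * ln P(site unpaired)`, with the joint probability
#' approximated by the product of per-position unpaired probabilities. A
#' zero probability yields `+Inf` (site effectively never open).
#'
#' @param site 19-nt target site.
#' @param profile `accessibility_profile` of the transcript.
#' @param site_start 0-based start of the site on the transcript.
#' @param model An [energy_model()].
#' @param guide Optional guide strand; when given, its 19-nt core must be the
#'   reverse complement of the site.
#' @return Numeric `dG_total` in kcal/mol with attributes `hybridization`
#'   and `opening`.
#' @export
interaction_energy <- function(site, profile, site_start,
                               model = energy_model(), guide = NULL) {
  stopifnot(inherits(profile, "accessibility_profile"),
            inherits(model, "energy_model"))
  chars <- site_chars(site)
  if (!is.null(guide) &&
      substr(guide, 1L, SITE_LEN) != reverse_complement(site)) {
    stop("guide core is not complementary to the site", call. = FALSE)
  }
  hyb <- sum(ifelse(chars %in% c("G", "C"), model$gc, model$au))
  p <- profile$p_unpaired[(site_start + 1L):(site_start + SITE_LEN)]
  open <- if (any(p == 0)) Inf else -model$rt * sum(log(p))
  structure(hyb + open, hybridization = hyb, opening = open)
}

#' Filter candidates by target-site accessibility
#'
#' Accepts a candidate when its [site_accessibility()] reaches
#' `min_accessibility` and its [interaction_energy()] is negative (binding
#' energetically favourable after paying the opening cost).
#'
#' @param candidates A `sirna_candidates` data.frame.
#' @param reference Reference transcript sequence (used to fold the profile
#'   unless one is supplied).
#' @param model An [energy_model()].
#' @param min_accessibility Acceptance threshold on the accessibility score
#'   (default 0.1).
#' @param windows Sub-window definition passed to [site_accessibility()].
#' @param window,step Local folding parameters for [fold_accessibility()].
#' @param profile Optional precomputed `accessibility_profile`.
#' @return `candidates` with added columns `accessibility`, `dG_total`,
#'   `dG_hybridization`, `dG_opening` and logical `access_pass`.
#' @export
accessibility_filter <- function(candidates, reference,
                                 model = energy_model(),
                                 min_accessibility = 0.1,
                                 windows = list(c(12L, 19L), c(1L, 19L)),
                                 window = 80L, step = 10L, profile = NULL) {
  stopifnot(is.data.frame(candidates))
  if (is.null(profile)) {
    profile <- fold_accessibility(reference, model, window, step)
  }
  n <- nrow(candidates)
  acc <- numeric(n)
  dg <- dgh <- dgo <- numeric(n)
  for (i in seq_len(n)) {
    acc[i] <- site_accessibility(profile, candidates$start[i], windows)
    e <- interaction_energy(candidates$site[i], profile, candidates$start[i],
                            model)
    dg[i] <- as.numeric(e)
    dgh[i] <- attr(e, "hybridization")
    dgo[i] <- attr(e, "opening")
  }
  candidates$accessibility <- acc
  candidates$dG_total <- dg
  candidates$dG_hybridization <- dgh
  candidates$dG_opening <- dgo
  candidates$access_pass <- acc >= min_accessibility & dg < 0
  candidates
}
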