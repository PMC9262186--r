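#' Randomly mutate half of a terminator section
#'
#' Picks `floor(length/2)` positions (at least 1) uniformly without
#' replacement inside the named section and replaces each with a uniformly
#' chosen *different* nucleotide. All positions outside the section are
#' untouched.
#'
#' @param record an `annotated_terminator`.
#' @param section one of the seven section names.
#' @param seed integer seed.
#' @return mutated sequence string.
#' @export
mutate_section <- function(record, section, seed = 1L) {
  if (!section %in% TERMINATOR_SECTIONS)
    stop("unknown section '", section, "'", call. = FALSE)
  iv <- record$sections[[section]]
  len <- iv[2] - iv[1]
  if (len == 0) stop("section '", section, "' is empty", call. = FALSE)
  n_mut <- max(1L, len %/% 2L)
  with_seed(seed, {
    chars <- strsplit(record$sequence, "")[[1]]
    pos <- sample(iv[1]:(iv[2] - 1L), n_mut) + 1L
    for (p in pos) chars[p] <- sample(setdiff(RNA_BASES, chars[p]), 1L)
    paste(chars, collapse = "")
  })
}

stem_pair_positions <- function(record) {
  s5 <- record$sections$stem5
  s3 <- record$sections$stem3
  cbind(five = s5[1]:(s5[2] - 1L), three = rev(s3[1]:(s3[2] - 1L)))
}

# ordered dinucleotides outside the canonical + wobble pairing set
nonpairing_dinucs <- function() {
  setdiff(as.vector(outer(RNA_BASES, RNA_BASES, paste0)), PAIRING_DINUCS)
}

#' Mutate stem base pairs, retaining or disrupting the pairing
#'
#' Chooses `k` stem pairs uniformly without replacement and replaces both
#' nucleotides of each chosen pair: in `retain` mode the new dinucleotide is
#' drawn uniformly from the canonical + wobble pairs in which both positions
#' differ from the original bases, so the pairing state survives; in
#' `disrupt` mode it is drawn from the non-pairing dinucleotides with both
#' positions changed, breaking the pair. Feasibility of both modes holds for
#' every starting pair (verifiable by enumeration over the six pair types).
#'
#' @param record an `annotated_terminator`.
#' @param k number of stem pairs to mutate.
#' @param pairing_fate `"retain"` or `"disrupt"`.
#' @param seed integer seed.
#' @return mutated sequence string.
#' @export
mutate_stem_pairs <- function(record, k, pairing_fate = c("retain", "disrupt"),
                              seed = 1L) {
  pairing_fate <- match.arg(pairing_fate)
  pp <- stem_pair_positions(record)
  if (k < 1 || k > nrow(pp))
    stop("k must lie in 1..", nrow(pp), " (number of stem pairs)",
         call. = FALSE)
  pool <- if (pairing_fate == "retain") PAIRING_DINUCS else
    nonpairing_dinucs()
  with_seed(seed, {
    chars <- strsplit(record$sequence, "")[[1]]
    chosen <- sample.int(nrow(pp), k)
    for (idx in chosen) {
      p5 <- pp[idx, 1] + 1L
      p3 <- pp[idx, 2] + 1L
      feasible <- pool[substr(pool, 1, 1) != chars[p5] &
                       substr(pool, 2, 2) != chars[p3]]
      d <- if (length(feasible) == 1) feasible else sample(feasible, 1L)
      chars[p5] <- substr(d, 1, 1)
      chars[p3] <- substr(d, 2, 2)
    }
    paste(chars, collapse = "")
  })
}

as_scorer <- function(model) {
  if (inherits(model, "termscan_model"))
    function(seqs) predict(model, seqs)
  else if (is.function(model)) model
  else stop("model must be a termscan_model or a function(seqs) -> scores",
            call. = FALSE)
}

#' Relative activation impact of terminator sections
#'
#' For each of the seven sections, half of the section's nucleotides are
#' mutated (`n_repeats` independent mutants per sequence, default 15) and
#' the relative activation impact is computed as `1 - xS / x0`, where `x0`
#' and `xS` are the mean model outputs over the original and the
#' section-mutated sequences.
#'
#' @param model trained `termscan_model` or a scoring function.
#' @param records list of `annotated_terminator` records.
#' @param n_repeats mutants per sequence per section (default 15).
#' @param seed integer seed.
#' @param sections section names to test (default all seven).
#' @return object of class `impact_result`: data frame with columns
#'   `section`, `x0`, `xS`, `impact`, `n`.
#' @export
section_impact <- function(model, records, n_repeats = 15L, seed = 1L,
                           sections = TERMINATOR_SECTIONS) {
  score <- as_scorer(model)
  if (length(records) == 0) stop("no records supplied", call. = FALSE)
  x0 <- mean(score(vapply(records, `[[`, character(1), "sequence")))
  if (x0 <= 0)
    stop("mean activation on original sequences is zero; ",
         "relative impact undefined", call. = FALSE)
  rows <- lapply(sections, function(sec) {
    muts <- unlist(lapply(seq_along(records), function(ri) {
      vapply(seq_len(n_repeats), function(rep)
        mutate_section(records[[ri]], sec,
                       seed = subseed(seed, ri * 1000L + rep)),
        character(1))
    }))
    xS <- mean(score(muts))
    data.frame(section = sec, x0 = x0, xS = xS, impact = 1 - xS / x0,
               n = length(records), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("impact_result", class(out))
  out
}

#' Relative activation impact of stem base pairing
#'
#' For each `k` in `k_range`, `k` stem pairs are mutated per mutant under
#' both fates (pairing retained vs. disrupted; `n_repeats` mutants per
#' sequence and fate). The relative activation impact of stem stability is
#' `1 - xd / xr` with `xr`, `xd` the mean outputs under retaining and
#' disrupting mutations.
#'
#' @inheritParams section_impact
#' @param k_range integer vector of pair counts (must not exceed the
#'   smallest stem in `records`).
#' @return `impact_result` data frame: `k`, `xr`, `xd`, `impact`, `n`.
#' @export
structure_impact <- function(model, records, k_range = 1:5, n_repeats = 15L,
                             seed = 1L) {
  score <- as_scorer(model)
  if (length(records) == 0) stop("no records supplied", call. = FALSE)
  min_stem <- min(vapply(records, function(r)
    diff(r$sections$stem5), numeric(1)))
  if (max(k_range) > min_stem)
    stop("k_range exceeds the smallest stem (", min_stem, " bp)",
         call. = FALSE)
  rows <- lapply(k_range, function(k) {
    one_fate <- function(fate, off) {
      muts <- unlist(lapply(seq_along(records), function(ri) {
        vapply(seq_len(n_repeats), function(rep)
          mutate_stem_pairs(records[[ri]], k, fate,
                            seed = subseed(seed, off + ri * 1000L + rep)),
          character(1))
      }))
      mean(score(muts))
    }
    xr <- one_fate("retain", k * 1000000L)
    xd <- one_fate("disrupt", k * 1000000L + 500000L)
    if (xr <= 0)
      stop("mean activation under retaining mutations is zero at k = ", k,
           "; relative impact undefined", call. = FALSE)
    data.frame(k = k, xr = xr, xd = xd, impact = 1 - xd / xr,
               n = length(records))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("impact_result", class(out))
  out
}

#' Relative detection impact for a binary external detector
#'
#' Applies the mutagenesis framework to a detector that reports hit counts
#' per sequence (e.g. an external terminator finder): the detection rate is
#' the fraction of sequences with at least one hit, and the impact formulas
#' are evaluated on rates instead of mean activations.
#'
#' @param detector function mapping a character vector of sequences to
#'   integer hit counts (one per sequence).
#' @param records list of `annotated_terminator` records.
#' @param mode `"section"` or `"structure"`.
#' @param sections,k_range scope of the mutation experiment.
#' @param n_repeats,seed as in [section_impact()].
#' @return `impact_result` data frame with rate columns in place of mean
#'   activations.
#' @export
detection_impact <- function(detector, records,
                             mode = c("section", "structure"),
                             sections = TERMINATOR_SECTIONS, k_range = 1:5,
                             n_repeats = 15L, seed = 1L) {
  mode <- match.arg(mode)
  if (length(records) == 0) stop("no records supplied", call. = FALSE)
  wrapped <- function(seqs) {
    hits <- detector(seqs)
    if (length(hits) != length(seqs))
      stop("detector returned ", length(hits), " hit counts for ",
           length(seqs), " sequences", call. = FALSE)
    as.numeric(hits >= 1)
  }
  if (mode == "section") {
    out <- section_impact(wrapped, records, n_repeats = n_repeats,
                          seed = seed, sections = sections)
    names(out)[names(out) == "x0"] <- "rate0"
    names(out)[names(out) == "xS"] <- "rateS"
  } else {
    out <- structure_impact(wrapped, records, k_range = k_range,
                            n_repeats = n_repeats, seed = seed)
    names(out)[names(out) == "xr"] <- "rate_retain"
    names(out)[names(out) == "xd"] <- "rate_disrupt"
  }
  out
}

#' Analytic reference scorers for the mutagenesis framework
#'
#' `intact_stem_fraction_scorer` returns, for any variant of `record`, the
#' fraction of the annotated stem pairs that still form a canonical or
#' wobble pair — the closed-form model for which the structure impact at
#' `k` disrupted pairs equals `k / stem_length`.
#' `section_identity_scorer` returns the fraction of positions inside one
#' section that are unchanged relative to the original record, so the
#' expected section impact of mutating half a section is 0.5.
#'
#' @param record the reference `annotated_terminator`.
#' @param section section name (identity scorer only).
#' @return `function(seqs) -> numeric` scorer.
#' @export
intact_stem_fraction_scorer <- function(record) {
  pp <- stem_pair_positions(record)
  w <- pairing_weights()
  function(seqs) {
    vapply(seqs, function(s) {
      chars <- strsplit(s, "")[[1]]
      mean(w[cbind(chars[pp[, 1] + 1L], chars[pp[, 2] + 1L])] > 0)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' @rdname intact_stem_fraction_scorer
#' @export
section_identity_scorer <- function(record, section) {
  iv <- record$sections[[section]]
  ref <- strsplit(record$sequence, "")[[1]][(iv[1] + 1L):iv[2]]
  function(seqs) {
    vapply(seqs, function(s) {
      mean(strsplit(s, "")[[1]][(iv[1] + 1L):iv[2]] == ref)
    }, numeric(1), USE.NAMES = FALSE)
  }
}
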