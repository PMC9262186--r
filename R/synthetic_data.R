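#' Parameters for the synthetic terminator generator
#'
#' Intrinsic terminators are modelled as seven contiguous sections:
#' `left_pad`, `a_tail` (A-rich), `stem5`, `loop`, `stem3`, `u_tail`
#' (U-rich), `right_pad`. Section lengths are drawn uniformly from the
#' declared ranges; pads absorb the remaining length up to
#' `target_length`, split symmetrically with the extra nucleotide on the
#' 3' side.
#'
#' @param a_tail integer range (nt) for the A-rich region 5' of the hairpin.
#' @param stem integer range (bp) for the hairpin stem.
#' @param stem_gc fraction of stem pairs drawn as G-C (the rest are A-U).
#' @param loop integer range (nt) for the hairpin loop.
#' @param u_tail integer range (nt) for the U-rich 3' region.
#' @param u_tail_u fraction of U in the U-tail.
#' @param a_tail_a fraction of A in the A-tail.
#' @param target_length total padded length in nt (default 75).
#' @return object of class `generator_params`.
#' @export
generator_params <- function(a_tail = c(6L, 10L), stem = c(4L, 8L),
                             stem_gc = 0.8, loop = c(3L, 6L),
                             u_tail = c(6L, 10L), u_tail_u = 0.8,
                             a_tail_a = 0.8, target_length = 75L) {
  check_range <- function(r, name) {
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || any(r < 1L) || r[1] > r[2])
      stop("invalid ", name, " range: must be positive and ordered",
           call. = FALSE)
    as.integer(r)
  }
  p <- list(a_tail = check_range(a_tail, "a_tail"),
            stem = check_range(stem, "stem"),
            stem_gc = stem_gc,
            loop = check_range(loop, "loop"),
            u_tail = check_range(u_tail, "u_tail"),
            u_tail_u = u_tail_u, a_tail_a = a_tail_a,
            target_length = as.integer(target_length))
  for (f in c("stem_gc", "u_tail_u", "a_tail_a"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  max_core <- p$a_tail[2] + 2L * p$stem[2] + p$loop[2] + p$u_tail[2]
  if (max_core > p$target_length)
    stop("infeasible length budget: maximal section lengths sum to ",
         max_core, " > target_length ", p$target_length, call. = FALSE)
  structure(p, class = "generator_params")
}

# biased single-section samplers
sample_biased <- function(n, major, frac) {
  minor <- setdiff(RNA_BASES, major)
  probs <- setNames(rep((1 - frac) / 3, 4), RNA_BASES)
  probs[major] <- frac
  paste(sample(RNA_BASES, n, replace = TRUE, prob = probs), collapse = "")
}

draw_terminator_once <- function(params, id) {
  runi <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)
  la <- runi(params$a_tail); ls <- runi(params$stem)
  ll <- runi(params$loop); lu <- runi(params$u_tail)
  pad_total <- params$target_length - (la + 2L * ls + ll + lu)
  lp <- pad_total %/% 2L
  rp <- pad_total - lp  # extra nucleotide goes 3'

  # stem pairs: G-C with probability stem_gc, A-U otherwise; orientation uniform
  gc <- runif(ls) < params$stem_gc
  flip <- runif(ls) < 0.5
  five <- ifelse(gc, ifelse(flip, "G", "C"), ifelse(flip, "A", "U"))
  three <- chartr("ACGU", "UGCA", five)

  seqs <- c(random_rna(lp),
            sample_biased(la, "A", params$a_tail_a),
            paste(five, collapse = ""),
            random_rna(ll),
            paste(rev(three), collapse = ""),
            sample_biased(lu, "U", params$u_tail_u),
            random_rna(rp))
  lens <- c(lp, la, ls, ll, ls, lu, rp)
  ends <- cumsum(lens)
  starts <- ends - lens
  sections <- setNames(lapply(seq_along(lens),
                              function(k) c(starts[k], ends[k])),
                       TERMINATOR_SECTIONS)
  structure_db <- paste(c(strrep(".", lp + la), strrep("(", ls),
                          strrep(".", ll), strrep(")", ls),
                          strrep(".", lu + rp)), collapse = "")
  structure(list(id = id, sequence = paste(seqs, collapse = ""),
                 sections = sections, structure = structure_db),
            class = "annotated_terminator")
}

#' Generate an annotated synthetic terminator
#'
#' Draws a terminator-like sequence with a GC-rich complementary stem, an
#' A-rich 5' tail, a U-rich 3' tail and random flanking pads, annotated with
#' its seven section intervals (0-based, half-open) and dot-bracket
#' structure. Candidates are drawn until the package folder's
#' maximum-pairing structure contains every annotated stem pair, so the
#' hairpin annotation is guaranteed to be realised by the sequence.
#'
#' @param params a [generator_params()] object.
#' @param seed integer seed; identical seed and parameters give identical
#'   records.
#' @param id record identifier.
#' @param check_fold verify stem-pair containment by refolding (default TRUE).
#' @param max_tries rejection-sampling cap.
#' @return object of class `annotated_terminator` with fields `id`,
#'   `sequence`, `sections`, `structure`.
#' @export
make_terminator <- function(params = generator_params(), seed = 1L,
                            id = "terminator_1", check_fold = TRUE,
                            max_tries = 60L) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      rec <- draw_terminator_once(params, id)
      if (!check_fold) return(rec)
      annot <- parse_dotbracket(rec$structure)
      fold <- fold_nussinov(rec$sequence)
      ka <- paste(annot[, 1], annot[, 2])
      kf <- paste(fold[, 1], fold[, 2])
      if (all(ka %in% kf)) return(rec)
    }
    stop("failed to generate a terminator whose fold realises the annotated ",
         "stem within ", max_tries, " draws; widen stem/GC parameters",
         call. = FALSE)
  })
}

#' Validate the internal consistency of an annotated terminator
#'
#' Checks that the section intervals are contiguous, non-overlapping and
#' cover the sequence, that the stem halves have equal length, and that the
#' dot-bracket structure pairs exactly the annotated stem positions in
#' mirrored order.
#'
#' @param record an `annotated_terminator`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_annotated_terminator <- function(record) {
  L <- nchar(record$sequence)
  secs <- record$sections
  if (!identical(names(secs), TERMINATOR_SECTIONS))
    stop("sections must be exactly: ",
         paste(TERMINATOR_SECTIONS, collapse = ", "), call. = FALSE)
  bounds <- do.call(rbind, secs)
  if (bounds[1, 1] != 0 || bounds[nrow(bounds), 2] != L ||
      any(bounds[-1, 1] != bounds[-nrow(bounds), 2]))
    stop("section intervals must be contiguous and cover [0, L)",
         call. = FALSE)
  s5 <- secs$stem5; s3 <- secs$stem3
  if (diff(s5) != diff(s3))
    stop("stem halves differ in length", call. = FALSE)
  ps <- parse_dotbracket(record$structure)
  stem_pairs <- cbind(s5[1]:(s5[2] - 1L),
                      rev(s3[1]:(s3[2] - 1L)))
  if (diff(s5) == 0) stem_pairs <- stem_pairs[0, , drop = FALSE]
  if (nrow(ps) != nrow(stem_pairs) ||
      !all(paste(ps[, 1], ps[, 2]) %in%
           paste(stem_pairs[, 1], stem_pairs[, 2])))
    stop("structure pairs do not match the mirrored stem annotation",
         call. = FALSE)
  invisible(TRUE)
}

#' Default cloverleaf template for tRNA-like records
#'
#' A balanced dot-bracket cloverleaf: 7-bp acceptor stem enclosing three
#' hairpin arms (4, 5 and 5 bp stems with 7-nt loops) joined by short
#' single-stranded linkers, followed by a 4-nt 3' tail (72 nt total).
#'
#' @return dot-bracket string.
#' @export
trna_cloverleaf_template <- function() {
  hairpin <- function(stem, loop)
    paste0(strrep("(", stem), strrep(".", loop), strrep(")", stem))
  paste0(strrep("(", 7), "..", hairpin(4, 7), hairpin(5, 7), "...",
         hairpin(5, 7), strrep(")", 7), "....")
}

#' Generate a tRNA-like record by inverse folding a cloverleaf
#'
#' Inverse-folds the template so the core sequence refolds exactly to the
#' cloverleaf under the package folder, then pads the core with random
#' flanking nucleotides to the target length (default 95 nt), symmetric with
#' the extra base on the 3' side. The padded structure annotates flanks as
#' unpaired; refolding guarantees apply to the core interval.
#'
#' @param template_structure balanced dot-bracket cloverleaf.
#' @param seed integer seed.
#' @param target_length padded length (default 95).
#' @param id record identifier.
#' @param max_iter inverse-folding iteration cap.
#' @return list of class `trna_like` with `id`, `sequence`, `core`
#'   (0-based half-open interval of the unpadded cloverleaf), `structure`
#'   (padded dot-bracket), `template`, `achieved_distance`.
#' @export
make_trna_like <- function(template_structure = trna_cloverleaf_template(),
                           seed = 1L, target_length = 95L, id = "trna_1",
                           max_iter = 20000L) {
  core_len <- nchar(template_structure)
  if (core_len > target_length)
    stop("template longer than target_length", call. = FALSE)
  res <- inverse_fold(template_structure, seed = seed, max_iter = max_iter)
  if (res$achieved_distance > 0)
    stop("inverse-folding search failed to reach the cloverleaf within ",
         max_iter, " iterations (distance ", res$achieved_distance, ")",
         call. = FALSE)
  pad_total <- target_length - core_len
  lp <- pad_total %/% 2L
  rp <- pad_total - lp
  pads <- with_seed(subseed(seed, 999L),
                    list(l = random_rna(lp), r = random_rna(rp)))
  structure(list(id = id,
                 sequence = paste0(pads$l, res$sequence, pads$r),
                 core = c(lp, lp + core_len),
                 structure = paste0(strrep(".", lp), template_structure,
                                    strrep(".", rp)),
                 template = template_structure,
                 achieved_distance = res$achieved_distance),
            class = "trna_like")
}

#' Generate a synthetic genome with implanted terminator elements
#'
#' Background nucleotides are i.i.d. uniform over A, C, G, U. Terminator
#' cores (A-tail through U-tail, pads stripped so genomic context is the
#' genome itself) are implanted at non-overlapping positions; the
#' termination site of each element is the 3'-most base of its U-tail.
#'
#' @param n_elements number of implanted terminators.
#' @param genome_length genome size in nt.
#' @param params [generator_params()] for the implanted elements.
#' @param seed integer seed.
#' @param id genome identifier.
#' @param minus_strand if TRUE, elements are implanted on the minus strand
#'   (reverse-complemented) with probability 1/2.
#' @return object of class `synthetic_genome`: `id`, `sequence`, and
#'   `implanted` (data frame: element_id, strand, start, end, site;
#'   coordinates 0-based half-open).
#' @export
make_genome <- function(n_elements, genome_length,
                        params = generator_params(), seed = 1L,
                        id = "synth_genome", minus_strand = FALSE) {
  if (!is_count(n_elements) || !is_count(genome_length, 1L))
    stop("n_elements and genome_length must be counts", call. = FALSE)
  max_el <- params$a_tail[2] + 2L * params$stem[2] + params$loop[2] +
    params$u_tail[2]
  if (n_elements * max_el >= genome_length)
    stop("genome too small for the requested number of elements",
         call. = FALSE)

  bg <- with_seed(subseed(seed, 1L), random_rna(genome_length))
  if (n_elements == 0) {
    return(structure(list(id = id, sequence = bg,
                          implanted = data.frame(element_id = character(0),
                                                 strand = character(0),
                                                 start = integer(0),
                                                 end = integer(0),
                                                 site = integer(0))),
                     class = "synthetic_genome"))
  }

  cores <- lapply(seq_len(n_elements), function(k) {
    t <- make_terminator(params, seed = subseed(seed, 100L + k),
                         id = sprintf("element_%03d", k))
    core <- c(t$sections$a_tail[1], t$sections$u_tail[2])
    substr(t$sequence, core[1] + 1L, core[2])
  })

  placed <- with_seed(subseed(seed, 2L), {
    starts <- integer(0); ends <- integer(0)
    for (k in seq_len(n_elements)) {
      len <- nchar(cores[[k]])
      ok <- FALSE
      for (try in seq_len(200L * n_elements)) {
        s <- sample.int(genome_length - len + 1L, 1L) - 1L
        if (all(s + len <= starts | s >= ends)) {
          starts <- c(starts, s); ends <- c(ends, s + len)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place element ", k,
                    " without overlap; enlarge the genome", call. = FALSE)
    }
    strands <- if (minus_strand) sample(c("+", "-"), n_elements, TRUE)
               else rep("+", n_elements)
    list(starts = starts, ends = ends, strands = strands)
  })

  chars <- strsplit(bg, "")[[1]]
  for (k in seq_len(n_elements)) {
    el <- cores[[k]]
    if (placed$strands[k] == "-") el <- reverse_complement(el)
    chars[(placed$starts[k] + 1L):placed$ends[k]] <- strsplit(el, "")[[1]]
  }
  site <- ifelse(placed$strands == "+", placed$ends - 1L, placed$starts)
  implanted <- data.frame(element_id = sprintf("element_%03d",
                                               seq_len(n_elements)),
                          strand = placed$strands,
                          start = placed$starts, end = placed$ends,
                          site = site, stringsAsFactors = FALSE)
  implanted <- implanted[order(implanted$start), ]
  rownames(implanted) <- NULL
  structure(list(id = id, sequence = paste(chars, collapse = ""),
                 implanted = implanted),
            class = "synthetic_genome")
}

#' Derive transcripts and termination-site lists from a synthetic genome
#'
#' Builds one transcript per implanted element by extending the element with
#' random flanks (clamped at contig ends and at neighbouring elements so each
#' element lies inside exactly one transcript). The termination-site list is
#' the implanted ground truth.
#'
#' @param genome a [make_genome()] result with implanted elements.
#' @param seed integer seed.
#' @param flank integer range of transcript extension beyond the element.
#' @return list with `transcripts` (BED-like data frame: chrom, start, end,
#'   name, score, strand; 0-based half-open) and `sites` (chrom, start, end,
#'   name, score, strand; single-nucleotide intervals at termination sites).
#' @export
make_transcripts <- function(genome, seed = 1L, flank = c(80L, 200L)) {
  stopifnot(inherits(genome, "synthetic_genome"))
  imp <- genome$implanted
  if (nrow(imp) == 0)
    stop("genome has no implanted elements", call. = FALSE)
  L <- nchar(genome$sequence)
  n <- nrow(imp)
  with_seed(seed, {
    left <- sample(flank[1]:flank[2], n, replace = TRUE)
    right <- sample(flank[1]:flank[2], n, replace = TRUE)
    start <- pmax(0L, imp$start - left)
    end <- pmin(L, imp$end + right)
    # keep neighbouring elements out of this transcript
    if (n > 1) {
      start[-1] <- pmax(start[-1], imp$end[-n])
      end[-n] <- pmin(end[-n], imp$start[-1])
    }
    transcripts <- data.frame(chrom = genome$id, start = start, end = end,
                              name = sprintf("transcript_%03d", seq_len(n)),
                              score = 0L, strand = imp$strand,
                              stringsAsFactors = FALSE)
    sites <- data.frame(chrom = genome$id, start = imp$site,
                        end = imp$site + 1L, name = imp$element_id,
                        score = 0L, strand = imp$strand,
                        stringsAsFactors = FALSE)
    list(transcripts = transcripts, sites = sites)
  })
}

#' Generate a labelled synthetic terminator classification dataset
#'
#' Positives are annotated synthetic terminators; negatives are uniform
#' random sequences of the same length (the background model of the
#' synthetic genomes).
#'
#' @param n_positive,n_negative class sizes.
#' @param params [generator_params()].
#' @param seed integer seed.
#' @return list with `data` (data frame: id, sequence, label) and
#'   `positives` (the annotated terminator records, for mutagenesis).
#' @export
make_terminator_dataset <- function(n_positive, n_negative,
                                    params = generator_params(), seed = 1L) {
  pos <- lapply(seq_len(n_positive), function(k)
    make_terminator(params, seed = subseed(seed, k),
                    id = sprintf("pos_%04d", k)))
  neg <- with_seed(subseed(seed, -2L),
                   vapply(seq_len(n_negative),
                          function(k) random_rna(params$target_length),
                          character(1)))
  data <- data.frame(
    id = c(vapply(pos, `[[`, character(1), "id"),
           sprintf("neg_%04d", seq_len(n_negative))),
    sequence = c(vapply(pos, `[[`, character(1), "sequence"), neg),
    label = rep(c(1L, 0L), c(n_positive, n_negative)),
    stringsAsFactors = FALSE)
  list(data = data, positives = pos)
}
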