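make_fixture_record <- function(seed = 1) {
  make_terminator(generator_params(a_tail = c(8, 8), stem = c(6, 6),
                                   loop = c(4, 4), u_tail = c(8, 8)),
                  seed = seed)
}

test_that("section mutation changes exactly half the section, nothing else", {
  rec <- make_fixture_record()
  for (sec in c("a_tail", "loop", "u_tail", "left_pad")) {
    mut <- mutate_section(rec, sec, seed = 3)
    expect_equal(nchar(mut), nchar(rec$sequence))
    orig <- strsplit(rec$sequence, "")[[1]]
    new <- strsplit(mut, "")[[1]]
    diff_pos <- which(orig != new) - 1L
    iv <- rec$sections[[sec]]
    expect_equal(length(diff_pos), max(1, (iv[2] - iv[1]) %/% 2), info = sec)
    expect_true(all(diff_pos >= iv[1] & diff_pos < iv[2]), info = sec)
  }
  expect_identical(mutate_section(rec, "loop", seed = 5),
                   mutate_section(rec, "loop", seed = 5))
  expect_error(mutate_section(rec, "hairpin"), "unknown section")
})

test_that("retaining mutations change both bases but keep the pairing", {
  rec <- make_fixture_record()
  pp <- termscan:::stem_pair_positions(rec)
  orig <- strsplit(rec$sequence, "")[[1]]
  pairing <- c("GC", "CG", "AU", "UA", "GU", "UG")
  for (s in 1:30) {
    mut <- strsplit(mutate_stem_pairs(rec, k = 3, "retain", seed = s), "")[[1]]
    changed <- which(orig != mut) - 1L
    expect_equal(length(changed), 6)  # both bases of 3 pairs
    for (r in seq_len(nrow(pp))) {
      d <- paste0(mut[pp[r, 1] + 1], mut[pp[r, 2] + 1])
      expect_true(d %in% pairing, info = d)
    }
  }
})

test_that("retain on a G-C pair lands in the enumerable constrained set", {
  # single-pair stem forced to G-C: feasible retain outcomes have both
  # positions changed and still pairing: {CG, UA, AU, UG}
  rec <- list(sequence = "AAAGAAAACAAA",
              sections = list(left_pad = c(0, 3), a_tail = c(3, 3),
                              stem5 = c(3, 4), loop = c(4, 8),
                              stem3 = c(8, 9), u_tail = c(9, 9),
                              right_pad = c(9, 12)),
              structure = "...(....)...")
  class(rec) <- "annotated_terminator"
  seen <- vapply(1:60, function(s) {
    mut <- mutate_stem_pairs(rec, 1, "retain", seed = s)
    paste0(substr(mut, 4, 4), substr(mut, 9, 9))
  }, character(1))
  expect_true(all(seen %in% c("CG", "UA", "AU", "UG")))
  expect_gt(length(unique(seen)), 2)  # draws cover the feasible set
})

test_that("disrupting mutations break the chosen pairs and spare the rest", {
  rec <- make_fixture_record()
  pp <- termscan:::stem_pair_positions(rec)
  orig <- strsplit(rec$sequence, "")[[1]]
  pairing <- c("GC", "CG", "AU", "UA", "GU", "UG")
  mut <- strsplit(mutate_stem_pairs(rec, k = 6, "disrupt", seed = 2), "")[[1]]
  # all six stem pairs mutated: every pair broken, loop/tails untouched
  for (r in seq_len(nrow(pp))) {
    d <- paste0(mut[pp[r, 1] + 1], mut[pp[r, 2] + 1])
    expect_false(d %in% pairing)
  }
  outside <- setdiff(seq_along(orig) - 1L, c(pp[, 1], pp[, 2]))
  expect_equal(orig[outside + 1], mut[outside + 1])
  expect_error(mutate_stem_pairs(rec, 7, "disrupt"), "stem pairs")
})

test_that("section impact recovers the analytic half-mutation expectation", {
  rec <- make_fixture_record()
  scorer <- section_identity_scorer(rec, "a_tail")
  res <- section_impact(scorer, list(rec), n_repeats = 50, seed = 11,
                        sections = c("a_tail", "loop"))
  # mutating half of the 8-nt a_tail leaves fraction 0.5 intact
  expect_equal(res$impact[res$section == "a_tail"], 0.5, tolerance = 0.02)
  # a section the scorer ignores has no impact
  expect_equal(res$impact[res$section == "loop"], 0, tolerance = 1e-12)
  expect_equal(res$x0[1], 1)
})

test_that("structure impact matches the intact-stem closed form", {
  records <- lapply(1:20, make_fixture_record)
  scorer <- intact_stem_fraction_scorer(records[[1]])
  # all records share the same stem geometry (6 bp), so one scorer serves
  res <- structure_impact(scorer, records[1], k_range = 1:6,
                          n_repeats = 40, seed = 5)
  expect_equal(res$impact, (1:6) / 6, tolerance = 0.02)
  # impact non-decreasing in k for the analytic model
  expect_true(all(diff(res$impact) >= -1e-9))
  # retain keeps every pair intact
  expect_equal(res$xr, rep(1, 6))
})

test_that("pairing-insensitive scorers yield zero structure impact", {
  rec <- make_fixture_record()
  res <- structure_impact(function(seqs) rep(0.8, length(seqs)), list(rec),
                          k_range = c(1, 3), n_repeats = 5, seed = 2)
  expect_equal(res$impact, c(0, 0))
})

test_that("detection impact works on rates and propagates detector contracts", {
  rec <- make_fixture_record()
  # detector fires iff at least 4 of the 6 stem pairs are intact
  detector <- function(seqs) {
    frac <- intact_stem_fraction_scorer(rec)(seqs)
    as.integer(frac >= 4 / 6)
  }
  res <- detection_impact(detector, list(rec), mode = "structure",
                          k_range = c(1, 6), n_repeats = 10, seed = 3)
  expect_equal(res$rate_retain, c(1, 1))
  expect_equal(res$rate_disrupt[res$k == 6], 0)
  expect_equal(res$impact[res$k == 6], 1)

  always <- detection_impact(function(seqs) rep(1L, length(seqs)),
                             list(rec), mode = "section", n_repeats = 3,
                             seed = 1)
  expect_equal(always$impact, rep(0, 7))

  expect_error(detection_impact(function(seqs) 1L, list(rec, rec),
                                mode = "section", n_repeats = 2, seed = 1),
               "hit counts")
  expect_error(section_impact(function(seqs) rep(1, length(seqs)), list()),
               "no records")
})

test_that("mutation operators never change length or stray positions", {
  for (s in 1:10) {
    rec <- make_terminator(seed = 400 + s)
    mut1 <- mutate_section(rec, "stem5", seed = s)
    mut2 <- mutate_stem_pairs(rec, 2, "disrupt", seed = s)
    expect_equal(nchar(mut1), 75)
    expect_equal(nchar(mut2), 75)
    pp <- termscan:::stem_pair_positions(rec)
    orig <- strsplit(rec$sequence, "")[[1]]
    m2 <- strsplit(mut2, "")[[1]]
    changed <- which(orig != m2) - 1L
    expect_true(all(changed %in% c(pp[, 1], pp[, 2])))
  }
})
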