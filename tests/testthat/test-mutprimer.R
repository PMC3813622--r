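test_that("codon choice minimises mismatches with a first-listed tie rule", {
  p <- design_params()
  expect_identical(choose_mutation_codon("TCT", p)$codon, "GCT")  # 1 vs 2
  expect_identical(choose_mutation_codon("GAA", p)$codon, "GCT")  # tie 2-2
  fb <- choose_mutation_codon("GCA", p)                           # already Ala
  expect_identical(fb$codon, "GGT")                               # tie 2-2
  expect_identical(fb$target_aa, "G")
  expect_identical(choose_mutation_codon("TCT", p)$target_aa, "A")
})

test_that("the designer matches the exhaustive oracle on random templates", {
  p <- design_params()
  for (seed in c(101, 202, 303, 404)) {
    ctx <- make_ctx(seed)
    for (pos in c(12L, 40L, 71L)) {
      got <- enumerate_pairs(ctx, pos, p)[[1]]
      want <- oracle_best_pair(ctx, pos, p)
      expect_false(is.null(want))
      expect_identical(got$forward$sequence, want$forward)
      expect_identical(got$reverse$sequence, want$reverse)
      expect_identical(got$overlap_len, want$k)
      validate_pair(ctx, got, p)
    }
  }
})

test_that("optimised GC clamp ranking also agrees with the oracle", {
  p <- design_params(use_optimised_gc_clamp = TRUE)
  ctx <- make_ctx(77)
  for (pos in c(20L, 55L)) {
    got <- enumerate_pairs(ctx, pos, p)[[1]]
    want <- oracle_best_pair(ctx, pos, p)
    expect_identical(got$forward$sequence, want$forward)
    expect_identical(got$reverse$sequence, want$reverse)
    validate_pair(ctx, got, p)
  }
})

test_that("max_suggestions returns distinct ranked geometries", {
  p <- design_params(max_suggestions = 5L)
  ctx <- make_ctx(55)
  got <- enumerate_pairs(ctx, 33L, p)
  expect_true(length(got) > 1L && length(got) <= 5L)
  keys <- vapply(got, function(x)
    paste(x$forward$sequence, x$reverse$sequence), "")
  expect_identical(anyDuplicated(keys), 0L)
  for (g in got) validate_pair(ctx, g, p)
})

test_that("positions too close to the template edge are rejected", {
  p <- design_params()
  fx <- generate_fixture(fixture_spec(9, plasmid_length = 400,
                                      orf_length_aa = 80))
  # re-anchor the ORF start so codon 1 has almost no 5' flank
  ctx <- template_context(substr(fx$plasmid, fx$orf_start - 10L,
                                 nchar(fx$plasmid)), 11L, 80L)
  expect_error(enumerate_pairs(ctx, 1L, p),
               class = "scanmut_position_out_of_range")
  expect_error(enumerate_pairs(ctx, 200L, p),
               class = "scanmut_position_out_of_range")
})

test_that("adaptive Tm relaxes only as far as needed", {
  ctx <- make_ctx(31)
  p <- design_params(adaptive_tm = TRUE)
  # a position feasible at min_tm keeps the unrelaxed bound
  r <- design_with_adaptive_tm(ctx, 40L, p)
  expect_identical(r$relaxed_min_tm, p$min_tm)
  expect_identical(r$pairs[[1]]$forward$sequence,
                   enumerate_pairs(ctx, 40L, p)[[1]]$forward$sequence)
  # an AT-rich neighbourhood needs relaxation; result equals a plain run at
  # the relaxed threshold
  set.seed(99)
  at_rich <- random_dna(120, gc_fraction = 0.18)
  plasmid <- paste0(substr(ctx$plasmid, 1, 60),
                    "ATG", at_rich, substr(ctx$plasmid, 184, 500))
  ctx2 <- template_context(plasmid, 61L, 40L)
  hard <- design_with_adaptive_tm(ctx2, 20L, p)
  expect_true(hard$relaxed_min_tm < p$min_tm)
  again <- enumerate_pairs(ctx2, 20L, p, relaxed_min_tm = hard$relaxed_min_tm)
  expect_identical(hard$pairs[[1]]$forward$sequence,
                   again[[1]]$forward$sequence)
  want <- oracle_best_pair(ctx2, 20L, p, relaxed = hard$relaxed_min_tm)
  expect_identical(hard$pairs[[1]]$forward$sequence, want$forward)
  expect_null(oracle_best_pair(ctx2, 20L, p,
                               relaxed = hard$relaxed_min_tm + 1))
  # nothing is feasible on a poly-A template even at the floor
  polyA <- paste0(strrep("A", 100), "ATG", strrep("A", 200))
  ctx3 <- suppressWarnings(template_context(polyA, 101L, 30L))
  expect_error(design_with_adaptive_tm(ctx3, 15L, p),
               class = "scanmut_no_feasible_primer")
})

test_that("batch design isolates per-position failures", {
  ctx <- make_ctx(47)
  p <- design_params()
  single <- enumerate_pairs(ctx, 25L, p)[[1]]
  batch <- batch_design(ctx, 25L, 25L, p)
  expect_identical(batch[[1]]$pairs[[1]]$forward$sequence,
                   single$forward$sequence)
  batch <- batch_design(ctx, 20L, 39L, p)
  expect_length(batch, 20L)
  expect_identical(vapply(batch, `[[`, 0L, "aa_position"), 20:39)
  # poison one stretch of the template; its positions fail, the rest stand
  plasmid <- ctx$plasmid
  c0 <- ctx$orf_start + 3L * 29L
  substr(plasmid, c0 - 20L, c0 + 25L) <- strrep("A", 46)
  ctx2 <- suppressWarnings(template_context(plasmid, ctx$orf_start,
                                            ctx$orf_length_aa))
  batch2 <- batch_design(ctx2, 20L, 39L, p)
  df <- as.data.frame(batch2)
  expect_false(df$ok[df$aa_position == 30L])
  expect_true(any(df$ok))
  expect_error(batch_design(ctx, 0L, 10L, p), class = "scanmut_range_invalid")
  expect_error(batch_design(ctx, 10L, 5L, p), class = "scanmut_range_invalid")
})

test_that("widening the search space never loses a feasible design", {
  narrow <- design_params()
  wide <- design_params(min_len = narrow$min_len - 3L,
                        max_len = narrow$max_len + 5L,
                        min_tm = narrow$min_tm - 2,
                        min_overlap = narrow$min_overlap,
                        max_overlap = narrow$max_overlap + 2L)
  for (seed in c(61, 62)) {
    ctx <- make_ctx(seed)
    for (pos in c(18L, 52L)) {
      got_n <- tryCatch(enumerate_pairs(ctx, pos, narrow)[[1]],
                        scanmut_no_feasible_primer = function(e) NULL)
      if (is.null(got_n)) next
      # the narrow winner is still valid under the wide parameters ...
      validate_pair(ctx, got_n, wide, relaxed = wide$min_tm)
      # ... and the wide search finds at least as good a solution
      got_w <- enumerate_pairs(ctx, pos, wide)[[1]]
      expect_lte(max(nchar(got_w$forward$sequence),
                     nchar(got_w$reverse$sequence)),
                 max(nchar(got_n$forward$sequence),
                     nchar(got_n$reverse$sequence)))
    }
  }
})

test_that("simulated mutagenesis applies exactly the planted codon change", {
  p <- design_params()
  for (seed in c(13, 14)) {
    fx <- generate_fixture(fixture_spec(seed, plasmid_length = 500,
                                        orf_length_aa = 80))
    ctx <- template_context(fx$plasmid, fx$orf_start, fx$orf_length_aa)
    for (pos in c(10L, 44L, 70L)) {
      pair <- enumerate_pairs(ctx, pos, p)[[1]]
      mutant <- simulate_mutagenesis(ctx, pair)
      expect_identical(nchar(mutant), nchar(ctx$plasmid))
      diffs <- which(strsplit(mutant, "")[[1]] != strsplit(ctx$plasmid,
                                                           "")[[1]])
      expect_lte(length(diffs), 3L)
      expect_true(all(diffs >= pair$codon_span[1] &
                      diffs <= pair$codon_span[2]))
      wt_prot <- translate(ctx$plasmid, ctx$orf_start - 1L)
      mu_prot <- translate(mutant, ctx$orf_start - 1L)
      daa <- which(strsplit(wt_prot, "")[[1]] != strsplit(mu_prot, "")[[1]])
      expect_identical(daa, as.integer(pos))
    }
  }
})

test_that("a tampered reverse primer is caught as an end mismatch", {
  ctx <- make_ctx(21)
  pair <- enumerate_pairs(ctx, 35L, design_params())[[1]]
  bad <- pair
  s <- bad$reverse$sequence  # 5' end of the reverse primer forms a product end
  substr(s, 1L, 1L) <- if (substr(s, 1L, 1L) == "A") "C" else "A"
  bad$reverse$sequence <- s
  expect_error(simulate_mutagenesis(ctx, bad),
               class = "scanmut_end_mismatch")
})

test_that("two-fragment design assembles the same mutant as whole-plasmid PCR", {
  p <- design_params()
  fx <- generate_fixture(fixture_spec(88, plasmid_length = 3000,
                                      orf_length_aa = 150))
  ctx <- template_context(fx$plasmid, fx$orf_start, fx$orf_length_aa)
  anchor <- c(2000L, 2400L)  # roughly opposite the ORF on the circle
  d <- design_two_fragment(ctx, 60L, anchor, p)
  expect_gte(d$mutagenic$overlap_len, 15L)
  expect_identical(d$anchor$overlap_len, 15L)
  assembled <- simulate_two_fragment_assembly(ctx, d)
  expect_identical(assembled, simulate_mutagenesis(ctx, d$mutagenic))
  # anchor span colliding with the mutation region is refused
  c0 <- ctx$orf_start + 3L * 59L
  expect_error(design_two_fragment(ctx, 60L, c(c0 - 10L, c0 + 50L), p),
               class = "scanmut_anchor_overlaps_mutation")
})
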