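test_that("window score counts complete 7-mer match windows", {
  x <- random_dna_seeded(1, 10)
  expect_identical(window_score(x, x, 0L), 4L)
  y <- random_dna_seeded(2, 20)
  y2 <- y
  substr(y2, 10, 10) <- if (substr(y, 10, 10) == "A") "C" else "A"
  expect_identical(window_score(y, y2, 0L), 7L)  # 14 windows, 7 spoiled
  expect_identical(window_score("ACGTAC", "ACGTAC", 0L), 0L)  # overlap < 7
  # self score at offset 0 is N - 6
  for (L in c(7L, 8L, 30L, 111L)) {
    z <- random_dna_seeded(L, L)
    expect_identical(window_score(z, z, 0L), L - 6L)
  }
  # N never supports a window
  w <- strrep("ACGTACG", 3)
  wn <- w; substr(wn, 11, 11) <- "N"
  expect_lt(window_score(w, wn, 0L), window_score(w, w, 0L))
})

test_that("window score equals the brute-force double loop at every offset", {
  set.seed(33)
  for (i in 1:12) {
    ref <- random_dna(sample(20:60, 1))
    read <- if (i %% 3 == 0) substr(ref, 5, 5 + sample(10:30, 1))
            else random_dna(sample(15:40, 1))
    if (i %% 4 == 0) {
      ch <- strsplit(read, "")[[1]]
      ch[sample(length(ch), 2)] <- "N"
      read <- paste(ch, collapse = "")
    }
    for (off in (-nchar(read) + 1L):(nchar(ref) - 1L)) {
      expect_identical(window_score(ref, read, off),
                       oracle_window_score_loop(ref, read, off))
    }
  }
})

test_that("co-translating both sequences only relabels the profile", {
  set.seed(8)
  core <- random_dna(120)
  read <- substr(core, 31, 90)
  p1 <- score_profile(core, read)
  shifted <- paste0(random_dna(10), core)
  p2 <- score_profile(shifted, read)
  expect_identical(p2$best_offset, p1$best_offset + 10L)
  # exact relabeling holds wherever the read sits fully inside the original
  # reference portion (boundary offsets gain new overlap in the padding)
  inner <- 0:(nchar(core) - nchar(read))
  expect_identical(p1$profile$score[match(inner, p1$profile$offset)],
                   p2$profile$score[match(inner + 10L, p2$profile$offset)])
})

test_that("profiles separate unique slices from duplicated blocks", {
  set.seed(71)
  ref <- random_dna(300)
  read <- substr(ref, 101, 160)
  res <- score_profile(ref, read)
  expect_identical(res$best_offset, 100L)
  expect_false(res$ambiguous)
  expect_identical(res$peaks, 100L)
  # duplicated 80 bp block: a read from the block aligns twice
  block <- random_dna(80)
  dup <- paste0(random_dna(60), block, random_dna(50), block, random_dna(40))
  res2 <- score_profile(dup, substr(block, 10, 70))
  expect_true(res2$ambiguous)
  expect_gte(length(res2$peaks), 2L)
  expect_error(score_profile(random_dna(50), strrep("A", 40)),
               class = "scanmut_no_overlap")
})

test_that("read orientation modes behave as documented", {
  set.seed(3)
  ref <- random_dna(200)
  read <- substr(ref, 50, 120)
  rc <- reverse_complement(read)
  expect_identical(orient_read(ref, read, "as_is")$sequence, read)
  expect_identical(orient_read(ref, read, "reverse_complement")$sequence, rc)
  auto <- orient_read(ref, rc, "auto")
  expect_identical(auto$orientation, "reverse_complement")
  expect_identical(auto$sequence, read)
  # palindromic tie prefers as_is
  pal <- "GAATTCGAATTC"
  expect_identical(orient_read(pal, pal, "auto")$orientation, "as_is")
})

test_that("mutation calling recovers planted substitutions codon by codon", {
  fx <- generate_fixture(fixture_spec(5, plasmid_length = 520,
                                      orf_length_aa = 90))
  orf <- substr(fx$plasmid, fx$orf_start, fx$orf_start + 269L)
  ref <- reference_context(orf)
  # plant GCT -> GAT style change at codon 25 (A -> D by construction)
  read <- substr(orf, 10, 200)
  c0 <- 3L * 24L + 1L
  mut_read <- read
  substr(mut_read, c0 - 9L, c0 - 7L) <- "GAT"
  rep <- align_and_call(ref, mut_read)
  expect_identical(nrow(rep$calls), 1L)
  expect_identical(rep$calls$aa_position, 25L)
  expect_identical(rep$calls$obs_aa, "D")
  expect_identical(rep$calls$codon_obs, "GAT")
  expect_false(rep$calls$silent)
  # identical slice: no calls
  expect_identical(nrow(align_and_call(ref, read)$calls), 0L)
  # reverse-strand read is auto-oriented to the same call
  rep_rc <- align_and_call(ref, reverse_complement(mut_read))
  expect_identical(rep_rc$alignment$orientation, "reverse_complement")
  expect_identical(rep_rc$calls$aa_position, 25L)
})

test_that("silent changes are flagged and N positions are uncallable", {
  fx <- generate_fixture(fixture_spec(6, plasmid_length = 520,
                                      orf_length_aa = 90))
  orf <- substr(fx$plasmid, fx$orf_start, fx$orf_start + 269L)
  ref <- reference_context(orf)
  read <- substr(orf, 1, 150)
  cod10 <- substr(orf, 28, 30)
  silent_codon <- {  # synonymous change at codon 10
    cands <- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE == translate(cod10)]
    setdiff(cands, cod10)[[1]]
  }
  sread <- read
  substr(sread, 28, 30) <- silent_codon
  rep <- align_and_call(ref, sread)
  expect_true(all(rep$calls$silent))
  expect_true(10L %in% rep$calls$aa_position)
  # an N over a difference makes the codon uncallable, not a mutation
  nread <- read
  substr(nread, 28, 28) <- "N"
  repn <- align_and_call(ref, nread)
  expect_false(10L %in% repn$calls$aa_position)
  expect_true(10L %in% repn$uncallable)
})

test_that("region of interest restricts the headline calls only", {
  set.seed(40)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  orf <- paste0("ATG", paste(sample(sense, 59, replace = TRUE),
                             collapse = ""))
  ref <- reference_context(orf, region_of_interest = c(10L, 30L))
  read <- orf
  substr(read, 3L * 4L + 1L, 3L * 4L + 3L) <- "GCA"   # codon 5, outside
  substr(read, 3L * 19L + 1L, 3L * 19L + 3L) <- "GCA" # codon 20, inside
  rep <- align_and_call(ref, read)
  expect_setequal(rep$calls$aa_position, c(5L, 20L))
  expect_identical(rep$calls$aa_position[rep$calls$in_region], 20L)
})

test_that("batch verdicts follow the planted truth", {
  fx <- generate_fixture(fixture_spec(
    77, plasmid_length = 700, orf_length_aa = 120,
    planted_mutations = data.frame(residue = c(10L, 25L, 40L, 60L, 80L,
                                               100L),
                                   target_aa = c("A", "D", "A", "G", "A",
                                                 "K")),
    n_clean_reads = 4L))
  orf <- substr(fx$plasmid, fx$orf_start, fx$orf_start + 3L * 120L - 1L)
  ref <- reference_context(orf)
  truth <- fx$truth
  expected <- stats::setNames(
    ifelse(is.na(truth$residue), NA_character_,
           paste0(truth$ref_aa, truth$residue, truth$obs_aa)),
    truth$read)
  rep <- batch_check(ref, fx$reads, expected = expected)
  expect_identical(rep$read, names(fx$reads))
  mut_rows <- !is.na(truth$residue)
  expect_true(all(rep$verdict[mut_rows] == "expected-mutation-present"))
  expect_true(all(rep$verdict[!mut_rows] == "clean"))
  # without expectations the verdict set collapses to clean/unexpected
  rep2 <- batch_check(ref, fx$reads)
  expect_true(all(rep2$verdict[mut_rows] == "unexpected"))
  expect_true(all(rep2$verdict[!mut_rows] == "clean"))
  # a read sharing no 7-mer with the reference cannot be aligned
  stray <- strrep("TA", 30)
  expect_false(grepl("TATATAT", orf) || grepl("ATATATA", orf))
  rep3 <- batch_check(ref, c(stray = stray))
  expect_identical(rep3$verdict, "no-overlap")
  # duplicate names are suffixed deterministically
  expect_warning(rep4 <- batch_check(ref, c(a = orf, a = orf)),
                 "duplicate")
  expect_identical(rep4$read, c("a", "a_dup1"))
})
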