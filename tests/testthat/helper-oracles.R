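# Independent oracles used across the suite.  They deliberately share no
# code with the implementation paths they check: Tm and window scores are
# recomputed with plain string/table arithmetic, and the designer oracle
# enumerates geometries from raw substrings.

oracle_tm <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  64.9 + 41 * (sum(ch == "G" | ch == "C") - 16.4) / length(ch)
}

# brute-force double loop over window starts (small inputs only)
oracle_window_score_loop <- function(ref, read, offset, window = 7L) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  d <- strsplit(read, "", fixed = TRUE)[[1]]
  lo <- max(1L, 1L + offset); hi <- min(length(r), length(d) + offset)
  if (hi - lo + 1L < window) return(0L)
  a <- r[lo:hi]; b <- d[(lo - offset):(hi - offset)]
  score <- 0L
  for (i in 1:(length(a) - window + 1L)) {
    win_a <- a[i:(i + window - 1L)]; win_b <- b[i:(i + window - 1L)]
    if (all(win_a == win_b & win_a != "N" & win_b != "N"))
      score <- score + 1L
  }
  score
}

# column-stacked variant, fast enough for the full acceptance sweep
oracle_window_score_embed <- function(ref, read, offset, window = 7L) {
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  d <- strsplit(read, "", fixed = TRUE)[[1]]
  lo <- max(1L, 1L + offset); hi <- min(length(r), length(d) + offset)
  N <- hi - lo + 1L
  if (N < window) return(0L)
  a <- r[lo:hi]; b <- d[(lo - offset):(hi - offset)]
  m <- a == b & a != "N" & b != "N"
  cols <- sapply(1:window, function(j) m[j:(N - window + j)])
  if (is.null(dim(cols))) cols <- matrix(cols, nrow = 1L)
  sum(rowSums(cols) == window)
}

gc_count_str <- function(x) nchar(gsub("[AT]", "", x))

# Exhaustive designer oracle: enumerates every (overlap k, overlap start s,
# forward length lf, reverse length lr) from raw substrings, applies all
# constraints, and ranks with the documented lexicographic order.  Returns
# NULL when nothing is feasible.
oracle_best_pair <- function(ctx, aa_position, params,
                             relaxed = params$min_tm) {
  plasmid <- ctx$plasmid
  n <- nchar(plasmid)
  c0 <- ctx$orf_start + 3L * (aa_position - 1L)
  tcod <- substr(plasmid, c0, c0 + 2L)
  wt <- scanmut::translate(tcod)
  cands <- if (wt == params$primary_aa) params$fallback_codons
           else params$primary_codons
  mm <- sapply(cands, function(cd)
    sum(strsplit(cd, "")[[1]] != strsplit(tcod, "")[[1]]))
  mutc <- cands[[which.min(mm)]]
  mm_rel <- which(strsplit(mutc, "")[[1]] != strsplit(tcod, "")[[1]])

  g <- expand.grid(k = params$min_overlap:params$max_overlap,
                   s = (c0 + 3L - params$max_len):(c0 + params$max_len),
                   lf = params$min_len:params$max_len,
                   lr = params$min_len:params$max_len)
  g$f2 <- g$s + g$lf - 1L
  g$e <- g$s + g$k - 1L
  g$r1 <- g$e - g$lr + 1L
  g <- g[g$lf >= g$k & g$lr >= g$k & g$f2 <= n & g$r1 >= 1L, ]
  if (nrow(g) == 0L) return(NULL)

  fw_cov <- g$s <= c0 & g$f2 >= c0 + 2L
  rv_cov <- g$r1 <= c0 & g$e >= c0 + 2L
  fw_hit <- g$f2 >= c0 & g$s <= c0 + 2L
  rv_hit <- g$e >= c0 & g$r1 <= c0 + 2L
  keep <- (fw_cov | rv_cov) & (fw_cov | !fw_hit) & (rv_cov | !rv_hit) &
    (!fw_cov | g$f2 - (c0 + 2L) >= params$min_anneal_len) &
    (!rv_cov | c0 - g$r1 >= params$min_anneal_len)
  g <- g[keep, ]; fw_cov <- fw_cov[keep]; rv_cov <- rv_cov[keep]
  if (nrow(g) == 0L) return(NULL)

  with_codon <- function(w1, w2, use) {
    wt_win <- substring(plasmid, w1, w2)
    ifelse(use,
           paste0(substring(plasmid, w1, c0 - 1L), mutc,
                  substring(plasmid, c0 + 3L, w2)),
           wt_win)
  }
  # template window with the mismatched codon positions deleted, built as a
  # concatenation of the segments between the deleted positions
  mm_pos <- c0 - 1L + mm_rel
  drop_mm <- function(w1, w2) {
    out <- ""
    prev <- w1
    for (p in mm_pos) {
      out <- paste0(out, substring(plasmid, prev, p - 1L))
      prev <- p + 1L
    }
    paste0(out, substring(plasmid, prev, w2))
  }

  f_seq <- with_codon(g$s, g$f2, fw_cov)
  r_top <- with_codon(g$r1, g$e, rv_cov)
  f_ann <- ifelse(fw_cov, drop_mm(g$s, g$f2), substring(plasmid, g$s, g$f2))
  r_ann <- ifelse(rv_cov, drop_mm(g$r1, g$e), substring(plasmid, g$r1, g$e))

  tm_of <- function(x) 64.9 + 41 * (gc_count_str(x) - 16.4) / nchar(x)
  tm_f <- tm_of(f_ann); tm_r <- tm_of(r_ann)
  ok <- tm_f >= relaxed - 1e-9 & tm_f <= params$max_tm + 1e-9 &
        tm_r >= relaxed - 1e-9 & tm_r <= params$max_tm + 1e-9 &
        abs(tm_f - tm_r) <= params$max_delta_tm + 1e-9
  if (params$min_gc_clamp > 0L) {
    run_f <- nchar(sub(".*[AT]", "", f_seq))
    # reverse primer 3' run: leading G/C run of the top-strand window
    run_r <- nchar(sub("[AT].*", "", r_top))
    ok <- ok & run_f >= params$min_gc_clamp & run_r >= params$min_gc_clamp
  }
  g <- g[ok, ]; f_seq <- f_seq[ok]; r_top <- r_top[ok]
  tm_f <- tm_f[ok]; tm_r <- tm_r[ok]
  if (nrow(g) == 0L) return(NULL)

  clamp_key <- integer(nrow(g))
  if (params$use_optimised_gc_clamp) {
    score3 <- function(tri) {
      ifelse(grepl("[AT]$", tri), 1L,
             ifelse(grepl("[AT][GC]$", tri), 2L,
                    ifelse(grepl("^[AT][GC][GC]$", tri), 3L, 0L)))
    }
    tri_f <- substring(f_seq, nchar(f_seq) - 2L, nchar(f_seq))
    # reverse primer last three bases = complement of top-strand first three
    # reversed; GC class is complement-invariant, so score the reversed
    # leading trinucleotide of the top-strand window
    tri_r_top <- substring(r_top, 1L, 3L)
    tri_r <- sapply(strsplit(tri_r_top, ""), function(x)
      paste(rev(x), collapse = ""))
    clamp_key <- -(score3(tri_f) + score3(tri_r))
  }
  ord <- order(pmax(g$lf, g$lr), g$lf + g$lr,
               (tm_f - relaxed) + (tm_r - relaxed), clamp_key, g$s, g$k, g$lf)
  i <- ord[[1]]
  list(s = g$s[[i]], k = g$k[[i]], lf = g$lf[[i]], lr = g$lr[[i]],
       forward = f_seq[[i]],
       reverse = as.character(Biostrings::reverseComplement(
         Biostrings::DNAString(r_top[[i]]))),
       n_feasible = nrow(g))
}

# Constraint re-validation of an emitted pair from raw sequences, through
# the public seqcore operations only.
validate_pair <- function(ctx, pair, params, relaxed = params$min_tm) {
  plasmid <- ctx$plasmid
  c0 <- pair$codon_span[[1]]
  fs <- pair$forward$template_span; rs <- pair$reverse$template_span
  ok <- TRUE
  expect_true(nchar(pair$forward$sequence) >= params$min_len &&
              nchar(pair$forward$sequence) <= params$max_len)
  expect_true(nchar(pair$reverse$sequence) >= params$min_len &&
              nchar(pair$reverse$sequence) <= params$max_len)
  # overlap = intersection of the two top-strand spans
  ov <- min(fs[2], rs[2]) - max(fs[1], rs[1]) + 1L
  expect_identical(ov, pair$overlap_len)
  expect_true(ov >= params$min_overlap && ov <= params$max_overlap)
  # the two primers must agree on the shared overlap region
  fw_top <- pair$forward$sequence
  rv_top <- reverse_complement(pair$reverse$sequence)
  expect_identical(substr(fw_top, max(fs[1], rs[1]) - fs[1] + 1L,
                          min(fs[2], rs[2]) - fs[1] + 1L),
                   substr(rv_top, max(fs[1], rs[1]) - rs[1] + 1L,
                          min(fs[2], rs[2]) - rs[1] + 1L))
  for (cand in list(pair$forward, pair$reverse)) {
    span <- cand$template_span
    tm <- tm_pair_for_primer(cand$sequence,
                             if (cand$strand == "forward")
                               substr(plasmid, span[1], span[2])
                             else reverse_complement(substr(plasmid, span[1],
                                                            span[2])))
    expect_equal(tm$tm_anneal, cand$tm_anneal)
    expect_true(tm$tm_anneal >= relaxed - 1e-9 &&
                tm$tm_anneal <= params$max_tm + 1e-9)
    expect_true(gc_clamp_run(cand$sequence) >= params$min_gc_clamp)
    if (cand$carries_mutation) {
      anneal <- if (cand$strand == "forward") span[2] - (c0 + 2L)
                else c0 - span[1]
      expect_identical(as.integer(anneal), cand$anneal_len_3prime)
      expect_true(anneal >= params$min_anneal_len)
    }
  }
  expect_true(pair$delta_tm <= params$max_delta_tm + 1e-9)
  expect_true(pair$forward$carries_mutation || pair$reverse$carries_mutation)
  expect_identical(translate(pair$mutated_codon), pair$mut_aa)
  invisible(ok)
}

# small deterministic template factory for designer tests
make_ctx <- function(seed, plasmid_length = 500L, orf_length_aa = 80L,
                     gc = 0.5) {
  fx <- generate_fixture(fixture_spec(seed, plasmid_length = plasmid_length,
                                      orf_length_aa = orf_length_aa,
                                      gc_fraction = gc))
  template_context(fx$plasmid, fx$orf_start, fx$orf_length_aa)
}

random_dna_seeded <- function(seed, n, gc = 0.5) {
  set.seed(seed)
  random_dna(n, gc)
}
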