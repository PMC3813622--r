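# Mutagenic primer-pair design for whole-plasmid overlapping PCR.
#
# Geometry convention: a candidate pair is described by the top-strand
# overlap window [s, s+k-1] (k bases shared by the ends of the linear PCR
# product), the forward primer extending rightwards from s, and the reverse
# primer whose top-strand annealing window ends at s+k-1 and extends
# leftwards.  The mutated codon may sit anywhere covered by a primer, not
# necessarily inside the overlap; a primer covering only part of the codon
# is rejected so that a partial substitution is never emitted.

#' Choose the mutagenesis codon for one residue
#'
#' Selects among the two primary codon choices (or, when the template
#' residue already encodes the primary target amino acid, among the two
#' fallback choices) the codon introducing the fewest mismatches against the
#' template codon.  Ties go to the first listed codon.
#'
#' @param template_codon Wild-type codon at the residue (string of 3).
#' @param params A [design_params()] object carrying the codon choices.
#' @return List with elements `codon` (chosen codon), `target_aa` and
#'   `mismatches`.
#' @examples
#' choose_mutation_codon("TCT", design_params())  # GCT, 1 mismatch
#' @export
choose_mutation_codon <- function(template_codon, params) {
  stopifnot(inherits(params, "design_params"))
  wt <- translate(template_codon)
  if (wt == params$primary_aa) {
    cands <- params$fallback_codons
    target <- params$fallback_aa
  } else {
    cands <- params$primary_codons
    target <- params$primary_aa
  }
  mm <- vapply(cands, codon_mismatches, integer(1L), b = template_codon)
  i <- which.min(mm)  # first on ties
  list(codon = cands[[i]], target_aa = target, mismatches = mm[[i]])
}

# Vectorised Tm rule used inside the enumerations.
eq_tm <- function(gc, len) 64.9 + 41 * (gc - 16.4) / len

# Build one materialised primer pair from a surviving geometry row.
# All stored properties are recomputed through the seqcore operations on the
# actual primer strings.
build_pair <- function(ctx, s, k, lf, lr, mut, relaxed_min_tm, params) {
  plasmid <- ctx$plasmid
  aa_position <- mut$aa_position
  c0 <- codon_start(ctx, aa_position)
  f1 <- s; f2 <- s + lf - 1L
  e <- s + k - 1L
  r1 <- e - lr + 1L; r2 <- e

  put_codon <- function(window, w1) {
    substr(window, c0 - w1 + 1L, c0 - w1 + 3L) <- mut$codon
    window
  }
  fw_cov <- f1 <= c0 && f2 >= c0 + 2L
  rv_cov <- r1 <= c0 && r2 >= c0 + 2L

  f_tpl <- substr(plasmid, f1, f2)
  f_seq <- if (fw_cov) put_codon(f_tpl, f1) else f_tpl
  r_tpl_top <- substr(plasmid, r1, r2)
  r_top <- if (rv_cov) put_codon(r_tpl_top, r1) else r_tpl_top
  r_seq <- reverse_complement(r_top)

  cand <- function(seq, tpl, span, strand, cov, anneal) {
    tm <- tm_pair_for_primer(seq, tpl)
    list(sequence = seq, coding_strand = if (strand == "forward") seq
           else reverse_complement(seq),
         template_span = span, strand = strand,
         tm_anneal = tm$tm_anneal, tm_full = tm$tm_full,
         clamp_run = gc_clamp_run(seq), clamp_score = gc_clamp_score(seq),
         anneal_len_3prime = if (cov) as.integer(anneal) else NA_integer_,
         carries_mutation = cov)
  }
  fwd <- cand(f_seq, f_tpl, c(f1, f2), "forward", fw_cov, f2 - (c0 + 2L))
  rev <- cand(r_seq, reverse_complement(r_tpl_top), c(r1, r2), "reverse",
              rv_cov, c0 - r1)
  structure(list(
    forward = fwd, reverse = rev,
    overlap_len = as.integer(k),
    delta_tm = abs(fwd$tm_anneal - rev$tm_anneal),
    mutated_codon = mut$codon, template_codon = codon_at(ctx, aa_position),
    wt_aa = translate(codon_at(ctx, aa_position)), mut_aa = mut$target_aa,
    aa_position = as.integer(aa_position),
    codon_span = c(c0, c0 + 2L),
    relaxed_min_tm = relaxed_min_tm
  ), class = "primer_pair")
}

#' Enumerate feasible mutagenic primer pairs for one residue
#'
#' Exhaustively enumerates all pair geometries (overlap length, overlap
#' placement, forward and reverse primer length), applies the codon
#' substitution wherever a primer fully covers the mutated codon, and keeps
#' a candidate only if every constraint holds: primer lengths in
#' `[min_len, max_len]`, annealing Tm of both primers in
#' `[min_tm, max_tm]`, Tm difference at most `max_delta_tm`, 3' annealing
#' length at least `min_anneal_len` for every mutation-carrying primer, and
#' a 3' G/C run of at least `min_gc_clamp` on both primers.  Survivors are
#' ranked deterministically: smallest maximal primer length, then smallest
#' total length, then smallest total Tm excess over the (possibly relaxed)
#' `min_tm`, then -- if `use_optimised_gc_clamp` -- largest summed clamp
#' score, then leftmost overlap start.
#'
#' @param ctx A [template_context()].
#' @param aa_position 1-based residue index in the ORF.
#' @param params A [design_params()].
#' @param relaxed_min_tm Lower Tm bound actually applied (used by the
#'   adaptive-Tm driver); defaults to `params$min_tm`.
#' @return List of `primer_pair` objects, best first, at most
#'   `params$max_suggestions` long.
#' @export
enumerate_pairs <- function(ctx, aa_position, params,
                            relaxed_min_tm = params$min_tm) {
  stopifnot(inherits(ctx, "template_context"),
            inherits(params, "design_params"))
  n <- nchar(ctx$plasmid)
  aa_position <- as.integer(aa_position)
  if (aa_position < 1L || aa_position > ctx$orf_length_aa)
    stop_scanmut("position_out_of_range",
                 sprintf("residue %d outside ORF of %d aa", aa_position,
                         ctx$orf_length_aa))
  c0 <- codon_start(ctx, aa_position)
  if (c0 - params$max_len < 1L || c0 + 2L + params$max_len > n)
    stop_scanmut("position_out_of_range",
                 sprintf(paste0("codon at %d needs %d bp of flanking template",
                                " on each side"), c0, params$max_len))

  mut <- choose_mutation_codon(codon_at(ctx, aa_position), params)
  mut$aa_position <- aa_position
  tch <- strsplit(codon_at(ctx, aa_position), "", fixed = TRUE)[[1L]]
  mch <- strsplit(mut$codon, "", fixed = TRUE)[[1L]]
  mm_rel <- which(tch != mch)
  mm_pos <- c0 - 1L + mm_rel
  n_mm <- length(mm_rel)
  mm_t_gc <- sum(tch[mm_rel] %in% GC_BASES)
  mm_m_gc <- sum(mch[mm_rel] %in% GC_BASES)
  mut_gc <- as.integer(mch %in% GC_BASES)  # by codon offset 1:3

  gcv <- as.integer(strsplit(ctx$plasmid, "", fixed = TRUE)[[1L]] %in% GC_BASES)
  G <- c(0L, cumsum(gcv))

  g <- expand.grid(
    k = params$min_overlap:params$max_overlap,
    s = (c0 + 3L - params$max_len):(c0 + params$max_len),
    lf = params$min_len:params$max_len,
    lr = params$min_len:params$max_len,
    KEEP.OUT.ATTRS = FALSE
  )
  # primer lengths can never be shorter than the overlap they must contain
  g <- g[g$lf >= g$k & g$lr >= g$k, , drop = FALSE]
  g$f1 <- g$s; g$f2 <- g$s + g$lf - 1L
  g$e <- g$s + g$k - 1L
  g$r1 <- g$e - g$lr + 1L; g$r2 <- g$e

  fail <- function(what)
    stop_scanmut("no_feasible_primer",
                 sprintf("no feasible primer pair for residue %d: %s",
                         aa_position, what),
                 aa_position = aa_position, constraint = what)

  g <- g[g$f2 <= n & g$r1 >= 1L, , drop = FALSE]
  if (nrow(g) == 0L) fail("template bounds")

  fw_cov <- g$f1 <= c0 & g$f2 >= c0 + 2L
  rv_cov <- g$r1 <= c0 & g$r2 >= c0 + 2L
  fw_hit <- g$f2 >= c0 & g$f1 <= c0 + 2L
  rv_hit <- g$r2 >= c0 & g$r1 <= c0 + 2L
  ok <- (fw_cov | rv_cov) & !(fw_hit & !fw_cov) & !(rv_hit & !rv_cov)
  g <- g[ok, , drop = FALSE]; fw_cov <- fw_cov[ok]; rv_cov <- rv_cov[ok]
  if (nrow(g) == 0L) fail("codon coverage geometry")

  ok <- (!fw_cov | (g$f2 - (c0 + 2L)) >= params$min_anneal_len) &
        (!rv_cov | (c0 - g$r1) >= params$min_anneal_len)
  g <- g[ok, , drop = FALSE]; fw_cov <- fw_cov[ok]; rv_cov <- rv_cov[ok]
  if (nrow(g) == 0L) fail("3' annealing length from the mutation site")

  # effective GC class at template position `pos` of a primer that carries
  # the mutation when `cov` is TRUE
  eff_gc <- function(pos, cov) {
    v <- gcv[pos]
    for (j in seq_len(3L)) {
      sel <- cov & pos == (c0 + j - 1L)
      if (any(sel)) v[sel] <- mut_gc[[j]]
    }
    v
  }
  if (params$min_gc_clamp > 0L) {
    okf <- rep(TRUE, nrow(g)); okr <- okf
    for (d in 0L:(params$min_gc_clamp - 1L)) {
      okf <- okf & eff_gc(g$f2 - d, fw_cov) == 1L
      okr <- okr & eff_gc(g$r1 + d, rv_cov) == 1L
    }
    ok <- okf & okr
    g <- g[ok, , drop = FALSE]; fw_cov <- fw_cov[ok]; rv_cov <- rv_cov[ok]
    if (nrow(g) == 0L) fail("3' GC clamp")
  }

  gc_f <- G[g$f2 + 1L] - G[g$f1]
  gc_r <- G[g$r2 + 1L] - G[g$r1]
  tm_ann_f <- ifelse(fw_cov, eq_tm(gc_f - mm_t_gc, g$lf - n_mm),
                     eq_tm(gc_f, g$lf))
  tm_ful_f <- ifelse(fw_cov, eq_tm(gc_f - mm_t_gc + mm_m_gc, g$lf),
                     eq_tm(gc_f, g$lf))
  tm_ann_r <- ifelse(rv_cov, eq_tm(gc_r - mm_t_gc, g$lr - n_mm),
                     eq_tm(gc_r, g$lr))

  ok <- tm_ann_f >= relaxed_min_tm & tm_ann_f <= params$max_tm &
        tm_ann_r >= relaxed_min_tm & tm_ann_r <= params$max_tm
  g <- g[ok, , drop = FALSE]
  tm_ann_f <- tm_ann_f[ok]; tm_ann_r <- tm_ann_r[ok]
  fw_cov <- fw_cov[ok]; rv_cov <- rv_cov[ok]
  if (nrow(g) == 0L) fail("annealing Tm window")

  ok <- abs(tm_ann_f - tm_ann_r) <= params$max_delta_tm
  g <- g[ok, , drop = FALSE]
  tm_ann_f <- tm_ann_f[ok]; tm_ann_r <- tm_ann_r[ok]
  fw_cov <- fw_cov[ok]; rv_cov <- rv_cov[ok]
  if (nrow(g) == 0L) fail("Tm difference between the primers")

  clamp_key <- integer(nrow(g))
  if (params$use_optimised_gc_clamp) {
    score3 <- function(first, mid, last) {
      ifelse(last == 0L, 1L, ifelse(mid == 0L, 2L, ifelse(first == 0L, 3L, 0L)))
    }
    cs_f <- score3(eff_gc(g$f2 - 2L, fw_cov), eff_gc(g$f2 - 1L, fw_cov),
                   eff_gc(g$f2, fw_cov))
    # reverse primer read 5'->3': its last three bases are the complements of
    # top-strand r1+2, r1+1, r1 (GC class is complement-invariant)
    cs_r <- score3(eff_gc(g$r1 + 2L, rv_cov), eff_gc(g$r1 + 1L, rv_cov),
                   eff_gc(g$r1, rv_cov))
    clamp_key <- -(cs_f + cs_r)
  }

  ord <- order(pmax(g$lf, g$lr), g$lf + g$lr,
               (tm_ann_f - relaxed_min_tm) + (tm_ann_r - relaxed_min_tm),
               clamp_key, g$s, g$k, g$lf)
  top <- g[utils::head(ord, params$max_suggestions), , drop = FALSE]
  lapply(seq_len(nrow(top)), function(i)
    build_pair(ctx, top$s[[i]], top$k[[i]], top$lf[[i]], top$lr[[i]], mut,
               relaxed_min_tm, params))
}

#' Design with stepwise Tm relaxation
#'
#' Runs [enumerate_pairs()] at `min_tm`, then `min_tm - 1`, `min_tm - 2`,
#' ... until a feasible pair is found or the floor (10 degrees below
#' `min_tm`) is reached.  The relaxation applies only to the requested
#' position; the parameter set itself is not modified.
#'
#' @inheritParams enumerate_pairs
#' @param floor_delta Maximal relaxation in degrees (default 10).
#' @return List with elements `pairs` (as [enumerate_pairs()]) and
#'   `relaxed_min_tm` (the bound actually used).
#' @export
design_with_adaptive_tm <- function(ctx, aa_position, params,
                                    floor_delta = 10) {
  for (d in 0:floor_delta) {
    res <- tryCatch(
      enumerate_pairs(ctx, aa_position, params,
                      relaxed_min_tm = params$min_tm - d),
      scanmut_no_feasible_primer = function(e) NULL
    )
    if (!is.null(res))
      return(list(pairs = res, relaxed_min_tm = params$min_tm - d))
  }
  stop_scanmut("no_feasible_primer",
               sprintf("residue %d infeasible even at min_tm - %d",
                       as.integer(aa_position), floor_delta))
}

#' Batch design over a residue range
#'
#' One entry per residue; a failure at one position is recorded in its entry
#' and does not abort the batch.  With `params$adaptive_tm` the Tm bound is
#' relaxed per position as in [design_with_adaptive_tm()].
#'
#' @inheritParams enumerate_pairs
#' @param aa_from,aa_to 1-based inclusive residue range.
#' @return A list of class `batch_design`; each element has `aa_position`,
#'   `ok`, `pairs`, `relaxed_min_tm` and `error` (message or `NA`).
#' @export
batch_design <- function(ctx, aa_from, aa_to, params) {
  aa_from <- as.integer(aa_from); aa_to <- as.integer(aa_to)
  if (is.na(aa_from) || is.na(aa_to) || aa_from < 1L || aa_from > aa_to ||
      aa_to > ctx$orf_length_aa)
    stop_scanmut("range_invalid",
                 sprintf("need 1 <= aa_from <= aa_to <= %d",
                         ctx$orf_length_aa))
  out <- lapply(aa_from:aa_to, function(pos) {
    tryCatch({
      if (params$adaptive_tm) {
        r <- design_with_adaptive_tm(ctx, pos, params)
        list(aa_position = pos, ok = TRUE, pairs = r$pairs,
             relaxed_min_tm = r$relaxed_min_tm, error = NA_character_)
      } else {
        list(aa_position = pos, ok = TRUE,
             pairs = enumerate_pairs(ctx, pos, params),
             relaxed_min_tm = params$min_tm, error = NA_character_)
      }
    }, scanmut_error = function(e) {
      list(aa_position = pos, ok = FALSE, pairs = list(),
           relaxed_min_tm = NA_real_, error = conditionMessage(e))
    })
  })
  structure(out, class = "batch_design")
}

#' Collect designed pairs from a batch result
#'
#' @param batch A [batch_design()] result.
#' @param top_only Keep only the top-ranked pair per position.
#' @return Flat list of `primer_pair` objects (failed positions contribute
#'   nothing).
#' @export
batch_pairs <- function(batch, top_only = TRUE) {
  stopifnot(inherits(batch, "batch_design"))
  out <- list()
  for (entry in batch) {
    if (!entry$ok || length(entry$pairs) == 0L) next
    out <- c(out, if (top_only) entry$pairs[1L] else entry$pairs)
  }
  out
}

#' @export
as.data.frame.batch_design <- function(x, ...) {
  do.call(rbind, lapply(x, function(e) data.frame(
    aa_position = e$aa_position, ok = e$ok, n_pairs = length(e$pairs),
    relaxed_min_tm = e$relaxed_min_tm, error = e$error %||% NA_character_,
    stringsAsFactors = FALSE)))
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("%s%d%s  overlap %d bp  dTm %.2f C (min Tm used %.1f C)\n",
              x$wt_aa, x$aa_position, x$mut_aa, x$overlap_len, x$delta_tm,
              x$relaxed_min_tm))
  for (p in list(x$forward, x$reverse))
    cat(sprintf("  %-7s %s  [%d-%d] len %d Tm %.2f/%.2f clamp %d/%d%s\n",
                p$strand, p$sequence, p$template_span[[1L]],
                p$template_span[[2L]], nchar(p$sequence), p$tm_anneal,
                p$tm_full, p$clamp_run, p$clamp_score,
                if (p$carries_mutation)
                  sprintf(" anneal3' %d", p$anneal_len_3prime) else ""))
  invisible(x)
}

# substring on a circular sequence; from/to are 1-based and may wrap
circular_substr <- function(seq, from, to) {
  n <- nchar(seq)
  from <- ((from - 1L) %% n) + 1L
  to <- ((to - 1L) %% n) + 1L
  if (from <= to) substr(seq, from, to)
  else paste0(substr(seq, from, n), substr(seq, 1L, to))
}

#' Simulate whole-plasmid mutagenesis with a designed pair
#'
#' Builds the linear PCR product (forward primer, template around the
#' circle, reverse complement of the reverse primer), verifies that the two
#' product ends share exactly `overlap_len` identical bases, collapses them
#' and returns the re-circularised plasmid in the original coordinate frame.
#' The result equals the template with only the codon substitution applied.
#'
#' @param ctx The [template_context()] the pair was designed on.
#' @param pair A `primer_pair` from [enumerate_pairs()].
#' @return Mutant plasmid sequence (same length as the template).
#' @export
simulate_mutagenesis <- function(ctx, pair) {
  stopifnot(inherits(ctx, "template_context"), inherits(pair, "primer_pair"))
  plasmid <- ctx$plasmid
  n <- nchar(plasmid)
  f <- pair$forward$template_span; r <- pair$reverse$template_span
  k <- pair$overlap_len
  mid <- if (f[[2L]] + 1L > n && r[[1L]] == 1L) ""
         else circular_substr(plasmid, f[[2L]] + 1L, n + r[[1L]] - 1L)
  product <- paste0(pair$forward$sequence, mid,
                    reverse_complement(pair$reverse$sequence))
  if (nchar(product) != n + k ||
      substr(product, 1L, k) != substr(product, n + 1L, n + k))
    stop_scanmut("end_mismatch",
                 "product ends do not share the expected identical overlap")
  circ <- substr(product, 1L, n)  # circle starting at the forward 5' end
  s <- f[[1L]]
  if (s == 1L) circ
  else paste0(substr(circ, n - s + 2L, n), substr(circ, 1L, n - s + 1L))
}

# Enumerate a non-mutagenic primer pair sharing a k-bp overlap window inside
# `span` (used as the anchor of the two-fragment design).  Same ranking as
# the mutagenic designer, minus everything codon-related.
enumerate_anchor_pair <- function(ctx, span, params, k = 15L) {
  plasmid <- ctx$plasmid
  a1 <- as.integer(span[[1L]]); a2 <- as.integer(span[[2L]])
  if (a2 - a1 + 1L < max(k, params$min_len))
    stop_scanmut("no_feasible_primer", "anchor span too short")
  gcv <- as.integer(strsplit(plasmid, "", fixed = TRUE)[[1L]] %in% GC_BASES)
  G <- c(0L, cumsum(gcv))
  g <- expand.grid(s = a1:(a2 - k + 1L),
                   lf = params$min_len:params$max_len,
                   lr = params$min_len:params$max_len,
                   KEEP.OUT.ATTRS = FALSE)
  g$e <- g$s + k - 1L
  g$f2 <- g$s + g$lf - 1L
  g$r1 <- g$e - g$lr + 1L
  g <- g[g$f2 <= a2 & g$r1 >= a1 & g$lf >= k & g$lr >= k, , drop = FALSE]
  if (nrow(g) == 0L)
    stop_scanmut("no_feasible_primer", "no anchor geometry fits the span")
  tm_f <- eq_tm(G[g$f2 + 1L] - G[g$s], g$lf)
  tm_r <- eq_tm(G[g$e + 1L] - G[g$r1], g$lr)
  ok <- tm_f >= params$min_tm & tm_f <= params$max_tm &
        tm_r >= params$min_tm & tm_r <= params$max_tm &
        abs(tm_f - tm_r) <= params$max_delta_tm
  if (params$min_gc_clamp > 0L) {
    for (d in 0L:(params$min_gc_clamp - 1L))
      ok <- ok & gcv[g$f2 - d] == 1L & gcv[g$r1 + d] == 1L
  }
  g <- g[ok, , drop = FALSE]; tm_f <- tm_f[ok]; tm_r <- tm_r[ok]
  if (nrow(g) == 0L)
    stop_scanmut("no_feasible_primer", "no anchor primer satisfies Tm/clamp")
  ord <- order(pmax(g$lf, g$lr), g$lf + g$lr,
               (tm_f - params$min_tm) + (tm_r - params$min_tm), g$s, g$lf)
  b <- g[ord[[1L]], ]
  fwd_seq <- substr(plasmid, b$s, b$f2)
  rev_top <- substr(plasmid, b$r1, b$e)
  list(
    forward = list(sequence = fwd_seq, template_span = c(b$s, b$f2),
                   strand = "forward", tm_anneal = tm_basic(fwd_seq),
                   tm_full = tm_basic(fwd_seq), carries_mutation = FALSE),
    reverse = list(sequence = reverse_complement(rev_top),
                   template_span = c(b$r1, b$e), strand = "reverse",
                   tm_anneal = tm_basic(rev_top), tm_full = tm_basic(rev_top),
                   carries_mutation = FALSE),
    overlap_len = as.integer(k)
  )
}

#' Two-fragment mutagenesis design
#'
#' Fallback for positions where whole-plasmid mutagenesis fails in the lab:
#' the plasmid is amplified as two roughly half-size fragments, each primed
#' by one mutagenic primer and one non-mutagenic anchor primer on the
#' opposite side of the circle (typically the origin region), and the
#' fragments are joined in vitro via their identical ends.  The mutagenic
#' pair is designed as usual but with the end overlap forced to at least 15
#' bp, the assembly overlap required by seamless joining; the anchor pair is
#' designed inside `anchor_span` under the Tm/length/clamp constraints only,
#' sharing a 15 bp window so that the second junction also carries 15 bp of
#' terminal identity.
#'
#' @inheritParams enumerate_pairs
#' @param anchor_span 1-based inclusive interval on the template, disjoint
#'   from the mutation region, where the anchor primers anneal.
#' @return List of class `two_fragment_design` with elements `mutagenic`
#'   (a `primer_pair`), `anchor` (the anchor pair) and `assembly_overlap`.
#' @export
design_two_fragment <- function(ctx, aa_position, anchor_span, params) {
  c0 <- codon_start(ctx, aa_position)
  a1 <- as.integer(anchor_span[[1L]]); a2 <- as.integer(anchor_span[[2L]])
  if (a1 > a2 || a1 < 1L || a2 > nchar(ctx$plasmid))
    stop_scanmut("range_invalid", "anchor span outside the template")
  p2 <- params
  p2$min_overlap <- max(params$min_overlap, 15L)
  p2$max_overlap <- max(params$max_overlap, 15L)
  mpair <- if (params$adaptive_tm)
    design_with_adaptive_tm(ctx, aa_position, p2)$pairs[[1L]]
  else enumerate_pairs(ctx, aa_position, p2)[[1L]]
  foot <- c(mpair$reverse$template_span[[1L]],
            mpair$forward$template_span[[2L]])
  if (a1 <= foot[[2L]] && a2 >= foot[[1L]])
    stop_scanmut("anchor_overlaps_mutation",
                 "anchor span overlaps the mutagenic primer region")
  anchor <- enumerate_anchor_pair(ctx, c(a1, a2), params, k = 15L)
  structure(list(mutagenic = mpair, anchor = anchor,
                 assembly_overlap = c(mutation_junction = mpair$overlap_len,
                                      anchor_junction = anchor$overlap_len)),
            class = "two_fragment_design")
}

#' Simulate the two-fragment assembly
#'
#' Builds both PCR fragments from their primers and the template, verifies
#' the terminal identities at the two junctions (>= 15 bp) and joins the
#' fragments into the circular mutant plasmid, returned in the original
#' coordinate frame.
#'
#' @param ctx The [template_context()].
#' @param design A [design_two_fragment()] result.
#' @return Mutant plasmid sequence.
#' @export
simulate_two_fragment_assembly <- function(ctx, design) {
  stopifnot(inherits(design, "two_fragment_design"))
  plasmid <- ctx$plasmid
  n <- nchar(plasmid)
  m <- design$mutagenic; a <- design$anchor
  # fragment 1: mutagenic forward -> anchor reverse
  f1 <- paste0(m$forward$sequence,
               circular_substr(plasmid, m$forward$template_span[[2L]] + 1L,
                               a$reverse$template_span[[1L]] - 1L),
               reverse_complement(a$reverse$sequence))
  # fragment 2: anchor forward -> mutagenic reverse
  f2 <- paste0(a$forward$sequence,
               circular_substr(plasmid, a$forward$template_span[[2L]] + 1L,
                               m$reverse$template_span[[1L]] - 1L),
               reverse_complement(m$reverse$sequence))
  km <- m$overlap_len; ka <- a$overlap_len
  if (substr(f2, nchar(f2) - km + 1L, nchar(f2)) != substr(f1, 1L, km))
    stop_scanmut("end_mismatch", "mutation-junction overlap does not match")
  if (substr(f1, nchar(f1) - ka + 1L, nchar(f1)) != substr(f2, 1L, ka))
    stop_scanmut("end_mismatch", "anchor-junction overlap does not match")
  circ <- paste0(f1, substr(f2, ka + 1L, nchar(f2) - km))
  if (nchar(circ) != n)
    stop_scanmut("end_mismatch", "assembled circle has the wrong length")
  s <- m$forward$template_span[[1L]]
  if (s == 1L) circ
  else paste0(substr(circ, n - s + 2L, n), substr(circ, 1L, n - s + 1L))
}
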