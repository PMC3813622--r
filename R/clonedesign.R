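# Seamless (ligation-independent) cloning primer design: a quartet of
# primers amplifying the linearised vector and the insert so that the two
# amplicons end in identical overlap sequence at both junctions, with
# optional inclusion sequences carried on primer overhangs.
#
# Amplicon model: the vector amplicon runs from the start of the downstream
# vector part, around the (circular) vector, to the end of the upstream
# part; pv5 primes its left end (sense prefix of the downstream part) and
# pv3 its right end (reverse complement of the upstream part's suffix).
# The insert amplicon is primed by pi5 (sense prefix of the insert) and pi3
# (reverse complement of the insert's suffix).  Overhangs are copied from
# the target construct so the joints are seamless by construction.

#' Five-part cloning design
#'
#' @param upstream_vector Vector sequence upstream of the insertion point
#'   (roughly 50 bp).
#' @param add5 Optional inclusion placed between the vector and the 5' end
#'   of the insert (e.g. a protease-site coding sequence); may be empty.
#' @param insert Insert sequence.
#' @param add3 Optional inclusion at the 3' junction; may be empty.
#' @param downstream_vector Vector sequence downstream of the insertion
#'   point.
#' @param strategy Overhang placement: `"A"` puts the junction sequence on
#'   the vector primers, `"B"` on the insert primers, `"C"` splits it so the
#'   two primers at each junction have balanced lengths.
#' @param params A [design_params()]; only the length window, Tm window and
#'   GC-clamp minimum are used for the annealing cores.
#' @param overlap_len Required terminal identity at each junction
#'   (default 15 bp).
#' @param max_overhang Synthesis limit for a primer overhang (default 60
#'   nt); a longer inclusion triggers an error.
#' @return A list of class `cloning_design`.
#' @export
cloning_design <- function(upstream_vector, add5 = "", insert, add3 = "",
                           downstream_vector, strategy = c("A", "B", "C"),
                           params = design_params(), overlap_len = 15L,
                           max_overhang = 60L) {
  strategy <- match.arg(strategy)
  d <- list(upstream_vector = normalize_sequence(upstream_vector),
            add5 = normalize_sequence(add5),
            insert = normalize_sequence(insert),
            add3 = normalize_sequence(add3),
            downstream_vector = normalize_sequence(downstream_vector),
            strategy = strategy, params = params,
            overlap_len = as.integer(overlap_len),
            max_overhang = as.integer(max_overhang))
  min_part <- d$overlap_len + params$min_len
  if (nchar(d$upstream_vector) < min_part ||
      nchar(d$downstream_vector) < min_part)
    stop_scanmut("range_invalid",
                 sprintf("vector parts must be at least %d bp", min_part))
  if (nchar(d$insert) < params$min_len)
    stop_scanmut("range_invalid", "insert shorter than the minimal core")
  structure(d, class = "cloning_design")
}

#' Target construct of a cloning design
#'
#' Plain concatenation of the five parts: upstream vector, 5' inclusion,
#' insert, 3' inclusion, downstream vector.
#'
#' @param design A [cloning_design()].
#' @return The target sequence.
#' @export
assemble_target <- function(design) {
  stopifnot(inherits(design, "cloning_design"))
  paste0(design$upstream_vector, design$add5, design$insert, design$add3,
         design$downstream_vector)
}

#' Shortest feasible annealing core at one end of a template part
#'
#' Scans lengths from `min_len` upwards and returns the shortest core whose
#' Tm lies in `[min_tm, max_tm]` and whose 3' G/C run reaches
#' `min_gc_clamp`.  `end = "left"` gives a forward primer (sense prefix of
#' the part); `end = "right"` gives a reverse primer (reverse complement of
#' the part's suffix).
#'
#' @param template_part Part sequence.
#' @param end `"left"` or `"right"`.
#' @param params A [design_params()].
#' @return List with `sequence`, `length`, `tm` and `end`.
#' @export
design_anneal_core <- function(template_part, end = c("left", "right"),
                               params = design_params()) {
  end <- match.arg(end)
  part <- normalize_sequence(template_part)
  n <- nchar(part)
  if (n < params$min_len)
    stop_scanmut("no_feasible_primer",
                 "template part shorter than the minimal primer length")
  for (L in params$min_len:min(params$max_len, n)) {
    cand <- if (end == "left") substr(part, 1L, L)
            else reverse_complement(substr(part, n - L + 1L, n))
    tm <- tm_basic(cand)
    if (tm < params$min_tm || tm > params$max_tm) next
    if (params$min_gc_clamp > 0L && gc_clamp_run(cand) < params$min_gc_clamp)
      next
    return(list(sequence = cand, length = L, tm = tm, end = end))
  }
  stop_scanmut("no_feasible_primer",
               sprintf("no %s-end core satisfies the Tm/clamp constraints",
                       end))
}

# Split of the junction sequence (inclusion plus enough flanking bases to
# reach overlap_len of terminal identity) between the vector-side and
# insert-side primer at one junction.  `a` is carried by the vector primer,
# `b` by the insert primer; a + b = overlap_len + inclusion length always,
# which makes the junction identity exactly overlap_len.
junction_split <- function(strategy, total, len_vector_core, len_insert_core) {
  switch(strategy,
    A = c(a = total, b = 0L),
    B = c(a = 0L, b = total),
    C = {
      a <- round((total - len_vector_core + len_insert_core) / 2)
      a <- max(0L, min(total, as.integer(a)))
      c(a = a, b = total - a)
    })
}

#' Design the four cloning primers
#'
#' Builds the annealing cores (pv5/pv3 on the vector parts, pi5/pi3 on the
#' insert), then attaches 5' overhangs copied from the target construct so
#' that the vector and insert amplicons end in `overlap_len` identical bases
#' at both junctions, with the inclusion sequences carried according to the
#' chosen strategy.
#'
#' @param design A [cloning_design()].
#' @return A list of class `primer_quartet` with elements `pv5`, `pv3`,
#'   `pi5`, `pi3` (each with `sequence`, `overhang`, `core`, `core_tm` and
#'   the covered target span), `junction_overlaps` and `strategy`.
#' @export
design_quartet <- function(design) {
  stopifnot(inherits(design, "cloning_design"))
  p <- design$params
  ov <- design$overlap_len
  target <- assemble_target(design)
  n <- nchar(target)
  u <- nchar(design$upstream_vector)
  m5 <- nchar(design$add5); m3 <- nchar(design$add3)
  ilen <- nchar(design$insert)
  insert_start <- u + m5 + 1L
  insert_end <- u + m5 + ilen
  d_start <- insert_end + m3 + 1L

  ci5 <- design_anneal_core(design$insert, "left", p)
  ci3 <- design_anneal_core(design$insert, "right", p)
  cv3 <- design_anneal_core(design$upstream_vector, "right", p)
  cv5 <- design_anneal_core(design$downstream_vector, "left", p)

  s5 <- junction_split(design$strategy, ov + m5, cv3$length, ci5$length)
  s3 <- junction_split(design$strategy, ov + m3, cv5$length, ci3$length)
  if (max(s5, s3) > design$max_overhang)
    stop_scanmut("inclusion_too_long",
                 sprintf("overhang of %d nt exceeds the %d nt synthesis limit",
                         max(s5, s3), design$max_overhang))

  v5 <- u + s5[["a"]]                 # right edge of the vector amplicon
  p5 <- insert_start - s5[["b"]]      # left edge of the insert amplicon
  w3 <- d_start - s3[["a"]]           # left edge of the vector amplicon
  q3 <- insert_end + s3[["b"]]        # right edge of the insert amplicon

  oligo <- function(name, seq, overhang, core, span) {
    list(name = name, sequence = seq, overhang = overhang,
         core = core$sequence, core_tm = core$tm, target_span = span)
  }
  quartet <- structure(list(
    pv5 = oligo("pv5", substr(target, w3, d_start - 1L + cv5$length),
                substr(target, w3, d_start - 1L), cv5,
                c(w3, d_start - 1L + cv5$length)),
    pv3 = oligo("pv3", reverse_complement(substr(target, u - cv3$length + 1L,
                                                 v5)),
                reverse_complement(substr(target, u + 1L, v5)), cv3,
                c(u - cv3$length + 1L, v5)),
    pi5 = oligo("pi5", substr(target, p5, insert_start - 1L + ci5$length),
                substr(target, p5, insert_start - 1L), ci5,
                c(p5, insert_start - 1L + ci5$length)),
    pi3 = oligo("pi3", reverse_complement(substr(target,
                                                 insert_end - ci3$length + 1L,
                                                 q3)),
                reverse_complement(substr(target, insert_end + 1L, q3)), ci3,
                c(insert_end - ci3$length + 1L, q3)),
    junction_overlaps = c(five_prime = v5 - p5 + 1L,
                          three_prime = q3 - w3 + 1L),
    amplicon_edges = c(v5 = v5, p5 = p5, w3 = w3, q3 = q3),
    strategy = design$strategy
  ), class = "primer_quartet")
  quartet
}

#' @export
print.primer_quartet <- function(x, ...) {
  cat(sprintf("Cloning quartet, strategy %s (junction identity %d/%d bp)\n",
              x$strategy, x$junction_overlaps[["five_prime"]],
              x$junction_overlaps[["three_prime"]]))
  for (o in x[c("pv5", "pv3", "pi5", "pi3")])
    cat(sprintf("  %s  %-60s  core Tm %.2f C, overhang %d nt\n", o$name,
                o$sequence, o$core_tm, nchar(o$overhang)))
  invisible(x)
}

#' Simulate the seamless assembly of a cloning design
#'
#' Reconstructs both amplicons from the primer sequences and the template
#' parts, verifies the exact terminal identity at both junctions (at least
#' `overlap_len` bases) and joins the amplicons.  The joined sequence must
#' equal [assemble_target()]; any discrepancy raises a junction-mismatch
#' error, which flags a corrupted quartet.
#'
#' @param design A [cloning_design()].
#' @param quartet The [design_quartet()] output for it.
#' @return The assembled sequence (equal to the target construct).
#' @export
simulate_assembly <- function(design, quartet) {
  stopifnot(inherits(design, "cloning_design"),
            inherits(quartet, "primer_quartet"))
  target <- assemble_target(design)
  n <- nchar(target)
  u <- nchar(design$upstream_vector)
  insert_end <- u + nchar(design$add5) + nchar(design$insert)
  d_start <- insert_end + nchar(design$add3) + 1L

  # vector amplicon: pv5 ... downstream part | upstream part ... rc(pv3)
  pv5 <- quartet$pv5; pv3 <- quartet$pv3
  pi5 <- quartet$pi5; pi3 <- quartet$pi3
  amp_v <- paste0(pv5$sequence,
                  substr(target, pv5$target_span[[2L]] + 1L, n),
                  substr(target, 1L, pv3$target_span[[1L]] - 1L),
                  reverse_complement(pv3$sequence))
  amp_i <- paste0(pi5$sequence,
                  substr(target, pi5$target_span[[2L]] + 1L,
                         pi3$target_span[[1L]] - 1L),
                  reverse_complement(pi3$sequence))

  id5 <- quartet$junction_overlaps[["five_prime"]]
  id3 <- quartet$junction_overlaps[["three_prime"]]
  if (id5 < design$overlap_len || id3 < design$overlap_len)
    stop_scanmut("junction_mismatch", "junction identity below the overlap")
  if (substr(amp_v, nchar(amp_v) - id5 + 1L, nchar(amp_v)) !=
      substr(amp_i, 1L, id5))
    stop_scanmut("junction_mismatch", "5' junction ends are not identical")
  merged <- paste0(amp_v, substr(amp_i, id5 + 1L, nchar(amp_i)))
  if (substr(merged, 1L, id3) !=
      substr(merged, nchar(merged) - id3 + 1L, nchar(merged)))
    stop_scanmut("junction_mismatch", "3' junction ends are not identical")
  circ <- substr(merged, 1L, nchar(merged) - id3)  # starts at w3
  w3 <- quartet$amplicon_edges[["w3"]]
  out <- if (w3 == 1L) circ
         else paste0(substr(circ, n - w3 + 2L, n), substr(circ, 1L, n - w3 + 1L))
  if (out != target)
    stop_scanmut("junction_mismatch",
                 "assembled sequence does not reproduce the target construct")
  out
}
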