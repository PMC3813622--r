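# Design parameter set and template description used by the mutagenic
# primer designer.

#' Primer design parameter set
#'
#' Every numeric and boolean option of the mutagenic primer designer, with
#' working defaults for alanine scanning.  Lengths are in bp, temperatures
#' in degrees Celsius.
#'
#' @param min_len,max_len Allowed primer length window.
#' @param min_tm,max_tm Allowed annealing-Tm window; the designer aims as
#'   close to `min_tm` as possible without exceeding `max_tm`.
#' @param max_delta_tm Maximal difference between the annealing Tm of the
#'   forward and reverse primer of a pair.
#' @param min_anneal_len Minimal distance (bp) from the mutated codon to the
#'   3' end of a mutation-carrying primer.
#' @param min_gc_clamp Required length of the consecutive G/C run at the 3'
#'   end of each primer; 0 disables the check.
#' @param use_optimised_gc_clamp If `TRUE`, the trinucleotide clamp quality
#'   score enters the candidate ranking (maximised after the length and Tm
#'   criteria).
#' @param min_overlap,max_overlap Window for the length of identical
#'   sequence at the two ends of the linear whole-plasmid PCR product.
#'   Overlaps shorter than 11 bp reduce end-repair efficiency, hence a
#'   warning.
#' @param max_suggestions Number of ranked primer pairs to return per
#'   position.
#' @param adaptive_tm If `TRUE`, batch design relaxes `min_tm` in 1 degree
#'   steps (at most 10) for positions that are otherwise infeasible.
#' @param primary_codons Two codon choices for the scanning substitution
#'   (default alanine, GCT/GCC); both must encode the same amino acid.
#' @param fallback_codons Two codon choices used when the template residue
#'   already is the primary target (default glycine, GGT/GGC).
#' @return A list of class `design_params`.
#' @examples
#' p <- design_params(min_tm = 58)
#' p$min_tm
#' @export
design_params <- function(min_len = 25L, max_len = 45L,
                          min_tm = 60, max_tm = 75,
                          max_delta_tm = 3,
                          min_anneal_len = 15L,
                          min_gc_clamp = 0L,
                          use_optimised_gc_clamp = FALSE,
                          min_overlap = 13L, max_overlap = 15L,
                          max_suggestions = 1L,
                          adaptive_tm = FALSE,
                          primary_codons = c("GCT", "GCC"),
                          fallback_codons = c("GGT", "GGC")) {
  p <- list(
    min_len = as.integer(min_len), max_len = as.integer(max_len),
    min_tm = as.numeric(min_tm), max_tm = as.numeric(max_tm),
    max_delta_tm = as.numeric(max_delta_tm),
    min_anneal_len = as.integer(min_anneal_len),
    min_gc_clamp = as.integer(min_gc_clamp),
    use_optimised_gc_clamp = isTRUE(use_optimised_gc_clamp),
    min_overlap = as.integer(min_overlap),
    max_overlap = as.integer(max_overlap),
    max_suggestions = as.integer(max_suggestions),
    adaptive_tm = isTRUE(adaptive_tm),
    primary_codons = toupper(as.character(primary_codons)),
    fallback_codons = toupper(as.character(fallback_codons))
  )
  if (p$min_len < 1L || p$min_len > p$max_len)
    stop_scanmut("range_invalid", "need 1 <= min_len <= max_len")
  if (p$min_tm > p$max_tm)
    stop_scanmut("range_invalid", "need min_tm <= max_tm")
  if (p$min_overlap < 1L || p$min_overlap > p$max_overlap)
    stop_scanmut("range_invalid", "need 1 <= min_overlap <= max_overlap")
  if (p$max_delta_tm < 0)
    stop_scanmut("range_invalid", "max_delta_tm must be non-negative")
  if (p$min_overlap < 11L)
    warning("overlaps shorter than 11 bp reduce end-repair efficiency",
            call. = FALSE)
  aa_of <- function(codons, what) {
    aa <- vapply(codons, translate, character(1L))
    if (length(unique(aa)) != 1L)
      stop_scanmut("range_invalid",
                   sprintf("%s codons encode different amino acids", what))
    aa[[1L]]
  }
  p$primary_aa <- aa_of(p$primary_codons, "primary")
  p$fallback_aa <- aa_of(p$fallback_codons, "fallback")
  if (p$primary_aa == p$fallback_aa)
    warning("fallback codons encode the same amino acid as the primary ones",
            call. = FALSE)
  structure(p, class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat("Primer design parameters\n")
  cat(sprintf("  length %d-%d bp, Tm %.1f-%.1f C (max delta %.1f)\n",
              x$min_len, x$max_len, x$min_tm, x$max_tm, x$max_delta_tm))
  cat(sprintf("  overlap %d-%d bp, min 3' anneal %d bp, min GC clamp %d%s\n",
              x$min_overlap, x$max_overlap, x$min_anneal_len, x$min_gc_clamp,
              if (x$use_optimised_gc_clamp) ", clamp score optimised" else ""))
  cat(sprintf("  codons: %s (%s), fallback %s (%s); %d suggestion(s)%s\n",
              paste(x$primary_codons, collapse = "/"), x$primary_aa,
              paste(x$fallback_codons, collapse = "/"), x$fallback_aa,
              x$max_suggestions,
              if (x$adaptive_tm) ", adaptive Tm" else ""))
  invisible(x)
}

#' Template description for mutagenic primer design
#'
#' Holds the full template (plasmid) sequence and the coordinate of the
#' first base of the open reading frame, so that residue numbers can be
#' converted to nucleotide coordinates.  The template should include
#' flanking sequence on both sides of the ORF at least as long as the
#' maximal primer length, because primers near the protein termini anneal
#' outside the coding region.
#'
#' @param plasmid Template sequence (free text accepted; normalised).
#' @param orf_start 1-based position of the A of the initial ATG.
#' @param orf_length_aa Number of codons in the ORF (excluding the stop).
#'   If omitted, inferred as the number of codons before the first in-frame
#'   stop (or to the end of the template).
#' @param circular Whether the template is a circular plasmid.  Designs are
#'   laid out on the linear view; circularity is honoured where a PCR
#'   product necessarily crosses the origin (product simulation and the
#'   two-fragment design).
#' @return A list of class `template_context`.
#' @export
template_context <- function(plasmid, orf_start, orf_length_aa = NULL,
                             circular = TRUE) {
  plasmid <- normalize_sequence(plasmid)
  n <- nchar(plasmid)
  orf_start <- as.integer(orf_start)
  if (is.na(orf_start) || orf_start < 1L || orf_start > n - 2L)
    stop_scanmut("position_out_of_range",
                 sprintf("orf_start %d outside template of length %d",
                         orf_start, n))
  if (is.null(orf_length_aa)) {
    prot <- translate(plasmid, frame_offset = orf_start - 1L)
    stop_at <- regexpr("*", prot, fixed = TRUE)
    orf_length_aa <- if (stop_at > 0L) as.integer(stop_at) - 1L
                     else nchar(prot)
  }
  orf_length_aa <- as.integer(orf_length_aa)
  if (orf_length_aa < 1L || orf_start + 3L * orf_length_aa - 1L > n)
    stop_scanmut("range_invalid",
                 "ORF does not fit in the template at the given start")
  if (substr(plasmid, orf_start, orf_start + 2L) != "ATG")
    warning("ORF does not begin with ATG", call. = FALSE)
  structure(list(plasmid = plasmid, orf_start = orf_start,
                 orf_length_aa = orf_length_aa, circular = isTRUE(circular)),
            class = "template_context")
}

#' @export
print.template_context <- function(x, ...) {
  cat(sprintf("Template: %d bp%s, ORF at %d (%d aa)\n", nchar(x$plasmid),
              if (x$circular) " (circular)" else "", x$orf_start,
              x$orf_length_aa))
  invisible(x)
}

# 1-based coordinate of the first base of codon `aa_position`.
codon_start <- function(ctx, aa_position) {
  ctx$orf_start + 3L * (as.integer(aa_position) - 1L)
}

codon_at <- function(ctx, aa_position) {
  c0 <- codon_start(ctx, aa_position)
  substr(ctx$plasmid, c0, c0 + 2L)
}
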