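# Core sequence primitives shared by the designers and the read checker:
# input normalisation, reverse complement, translation, the GC-fraction
# melting-temperature rule and GC-clamp quality measures.

GC_BASES <- c("G", "C")

assert_dna <- function(x, arg = "seq", allow_n = TRUE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_scanmut("illegal_character",
                 sprintf("`%s` must be a single character string", arg))
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  hit <- regexpr(pat, x)
  if (hit > 0L)
    stop_scanmut("illegal_character",
                 sprintf("illegal character '%s' at position %d in `%s`",
                         substr(x, hit, hit), hit, arg),
                 position = as.integer(hit), char = substr(x, hit, hit))
  invisible(x)
}

#' Normalise pasted sequence text
#'
#' Accepts free text as pasted into a sequence field: FASTA header lines are
#' dropped, whitespace, digits and line numbers are removed and the result is
#' uppercased.  Any residual character outside `A`, `C`, `G`, `T`, `N` is an
#' error.
#'
#' @param raw Character scalar; arbitrary text, possibly multi-line.
#' @return A single uppercase string over the `ACGTN` alphabet (possibly
#'   empty).
#' @examples
#' normalize_sequence("atg c\n1 gta")
#' normalize_sequence(">clone1\nACGT")
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop_scanmut("illegal_character", "`raw` must be a single character string")
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1L]]
  if (length(lines) == 0L) return("")
  keep <- !startsWith(trimws(lines), ">")
  s <- paste(lines[keep], collapse = "")
  s <- toupper(gsub("[[:space:][:digit:]]", "", s))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop_scanmut("illegal_character",
                 sprintf("illegal character '%s' at position %d",
                         substr(s, bad, bad), bad),
                 position = as.integer(bad), char = substr(s, bad, bad))
  s
}

#' Reverse complement
#'
#' Watson-Crick reverse complement; `N` complements to `N`.  The empty
#' sequence maps to itself.
#'
#' @param seq DNA string over `ACGTN`.
#' @return The reverse complement, same length.
#' @examples
#' reverse_complement("ATGC")
#' @export
reverse_complement <- function(seq) {
  assert_dna(seq)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate DNA to protein
#'
#' Standard genetic code; stop codons render as `*`, codons containing `N`
#' (or otherwise untranslatable) as `X`.  A trailing partial codon is
#' dropped.
#'
#' @param seq DNA string.
#' @param frame_offset 0-based offset of the reading frame.
#' @return Amino-acid string (one-letter codes).
#' @examples
#' translate("ATGGCT")
#' translate("ATGTAA")
#' @export
translate <- function(seq, frame_offset = 0L) {
  assert_dna(seq)
  n <- nchar(seq)
  frame_offset <- as.integer(frame_offset)
  if (frame_offset < 0L || frame_offset >= n)
    stop_scanmut("frame_out_of_range",
                 sprintf("frame offset %d outside sequence of length %d",
                         frame_offset, n))
  ncod <- (n - frame_offset) %/% 3L
  if (ncod == 0L) return("")
  starts <- frame_offset + 1L + 3L * (seq_len(ncod) - 1L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

count_gc <- function(seq) nchar(gsub("[ATN]", "", seq))

#' Primer melting temperature (GC-fraction rule)
#'
#' `Tm = 64.9 + 41 * (gc - 16.4) / length` where `gc` is the number of G and
#' C bases.  Applied verbatim at any length >= 1; short or AT-rich sequences
#' legitimately give low (even negative) values, which the designers then
#' filter against their Tm window.
#'
#' @param seq DNA string without `N`.
#' @return Melting temperature in degrees Celsius.
#' @examples
#' tm_basic("ATGCATGCATGCATGCATGC")  # 51.78
#' @export
tm_basic <- function(seq) {
  assert_dna(seq, allow_n = FALSE)
  n <- nchar(seq)
  if (n == 0L)
    stop_scanmut("empty_sequence", "cannot compute Tm of an empty sequence")
  64.9 + 41 * (count_gc(seq) - 16.4) / n
}

#' Annealing and full-length melting temperatures of a mutagenic primer
#'
#' A mutagenic primer anneals to the original template with mismatches at
#' the substituted bases (early PCR cycles) but matches the newly made
#' mutant template in full (later cycles).  `tm_full` is [tm_basic()] of the
#' whole primer; `tm_anneal` applies the same rule to the primer bases that
#' match the template position-by-position, i.e. mismatched positions are
#' deleted from both the GC count and the length.
#'
#' @param primer Primer sequence, 5' to 3'.
#' @param template_region Template strand region of identical length,
#'   aligned position-by-position with the primer.
#' @return A list of class `tm_pair` with elements `tm_anneal` and
#'   `tm_full`.
#' @export
tm_pair_for_primer <- function(primer, template_region) {
  assert_dna(primer, "primer", allow_n = FALSE)
  assert_dna(template_region, "template_region", allow_n = FALSE)
  if (nchar(primer) != nchar(template_region))
    stop_scanmut("length_mismatch",
                 sprintf("primer length %d != template region length %d",
                         nchar(primer), nchar(template_region)))
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  t <- strsplit(template_region, "", fixed = TRUE)[[1L]]
  anneal <- paste(p[p == t], collapse = "")
  structure(list(tm_anneal = tm_basic(anneal), tm_full = tm_basic(primer)),
            class = "tm_pair")
}

#' Length of the 3'-terminal G/C run
#'
#' Number of consecutive G or C bases counted backwards from the 3' end of
#' the primer.  A minimum-run requirement (`min_gc_clamp`) of 0 disables the
#' GC-clamp check in the designers.
#'
#' @param seq Primer sequence, 5' to 3'.
#' @return Integer run length (0 when the terminal base is A/T).
#' @examples
#' gc_clamp_run("ATGCC")  # 2
#' @export
gc_clamp_run <- function(seq) {
  assert_dna(seq)
  n <- nchar(seq)
  if (n == 0L)
    stop_scanmut("empty_sequence", "cannot compute GC clamp of an empty sequence")
  ch <- rev(strsplit(seq, "", fixed = TRUE)[[1L]])
  isgc <- ch %in% GC_BASES
  first_non <- match(FALSE, isgc)
  if (is.na(first_non)) n else first_non - 1L
}

#' GC-clamp quality score of the three 3'-terminal bases
#'
#' The 64 possible terminal trinucleotides partition into four quality
#' classes, written 5' to 3' with the rightmost base at the 3' terminus:
#' `[GC][GC][GC]` scores 0 (worst), `[ATGC][ATGC][AT]` scores 1,
#' `[ATGC][AT][GC]` scores 2 and `[AT][GC][GC]` scores 3 (best).
#'
#' @param seq Primer sequence of length >= 3, 5' to 3'.
#' @return Integer score in `0:3`.
#' @examples
#' gc_clamp_score("ATATAGCG")  # 0
#' gc_clamp_score("ATATAAGC")  # 3
#' @export
gc_clamp_score <- function(seq) {
  assert_dna(seq)
  n <- nchar(seq)
  if (n < 3L)
    stop_scanmut("too_short", "GC-clamp score needs at least 3 bases")
  b <- strsplit(substr(seq, n - 2L, n), "", fixed = TRUE)[[1L]]
  gc <- b %in% GC_BASES
  if (!gc[3L]) 1L
  else if (!gc[2L]) 2L
  else if (!gc[1L]) 3L
  else 0L
}

#' Hamming distance between two codons
#'
#' @param a,b Codon strings of length 3.
#' @return Integer in `0:3`.
#' @export
codon_mismatches <- function(a, b) {
  assert_dna(a, "a")
  assert_dna(b, "b")
  if (nchar(a) != 3L || nchar(b) != 3L)
    stop_scanmut("length_mismatch", "codons must have length 3")
  sum(strsplit(a, "", fixed = TRUE)[[1L]] != strsplit(b, "", fixed = TRUE)[[1L]])
}

#' @export
print.tm_pair <- function(x, ...) {
  cat(sprintf("Tm (annealing, mismatches excluded): %.2f C\n", x$tm_anneal))
  cat(sprintf("Tm (full-length primer):             %.2f C\n", x$tm_full))
  invisible(x)
}
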