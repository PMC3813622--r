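# Semi-automatic verification of mutant sequencing reads: gapless
# offset-scan alignment against a reference ORF, ambiguity detection from
# the score profile and codon-level mutation calling.

#' Reference description for read checking
#'
#' @param sequence Reference sequence starting at the first base of the
#'   expressed ORF (the A of the initial ATG); free text accepted.
#' @param region_of_interest 1-based inclusive residue interval used for the
#'   headline mutation report; defaults to the whole translated length.
#' @return A list of class `reference_context`.
#' @export
reference_context <- function(sequence, region_of_interest = NULL) {
  sequence <- normalize_sequence(sequence)
  if (nchar(sequence) < 3L)
    stop_scanmut("too_short", "reference must contain at least one codon")
  n_aa <- nchar(sequence) %/% 3L
  if (is.null(region_of_interest)) region_of_interest <- c(1L, n_aa)
  region_of_interest <- as.integer(region_of_interest)
  if (length(region_of_interest) != 2L ||
      region_of_interest[[1L]] < 1L || region_of_interest[[2L]] > n_aa ||
      region_of_interest[[1L]] > region_of_interest[[2L]])
    stop_scanmut("range_invalid", "region of interest outside the reference")
  structure(list(sequence = sequence, region_of_interest = region_of_interest,
                 n_aa = n_aa),
            class = "reference_context")
}

# Core scorer on pre-converted integer vectors.  `offset` shifts the read
# relative to the reference: read position i aligns with reference position
# i + offset.  An N on either side never supports a match.
N_INT <- utf8ToInt("N")

window_score_int <- function(r, d, offset, window = 7L) {
  lo <- max(1L, 1L + offset)
  hi <- min(length(r), length(d) + offset)
  N <- hi - lo + 1L
  if (N < window) return(0L)
  a <- r[lo:hi]
  b <- d[(lo - offset):(hi - offset)]
  m <- as.integer(a == b & a != N_INT & b != N_INT)
  cs <- c(0L, cumsum(m))
  sum(cs[(window + 1L):(N + 1L)] - cs[1L:(N - window + 1L)] == window)
}

#' Alignment score at one offset
#'
#' The score of a read against a reference at a fixed shift is the number of
#' positions of a sliding 7-nucleotide window inside the overlap at which
#' all 7 aligned bases match.  Gaps are not modelled; an `N` on either side
#' never counts as a match.  Overlaps shorter than the window score 0.
#'
#' @param ref,read DNA strings (`N` allowed).
#' @param offset Signed shift of the read relative to the reference: read
#'   position `i` aligns with reference position `i + offset`.
#' @param window Window length (default 7).
#' @return Integer score.
#' @examples
#' window_score("ACGTACGTAC", "ACGTACGTAC", 0)  # 4
#' @export
window_score <- function(ref, read, offset, window = 7L) {
  assert_dna(ref, "ref"); assert_dna(read, "read")
  window_score_int(utf8ToInt(ref), utf8ToInt(read), as.integer(offset),
                   as.integer(window))
}

#' Score profile over all offsets
#'
#' Computes the window score at every offset with an overlap of at least the
#' window length.  The best offset is the argmax (smallest offset on ties);
#' peaks are all offsets scoring at least `ambiguity_fraction` of the
#' maximum.  More than one peak flags the alignment as ambiguous -- the
#' signature of duplications or other rearrangements in a non-productive
#' clone.
#'
#' @inheritParams window_score
#' @param ambiguity_fraction Fraction of the maximal score a secondary
#'   offset must reach to count as an alternative alignment (default 0.5).
#' @return A list of class `alignment_result` with `profile` (data frame of
#'   offset and score), `best_offset`, `max_score`, `peaks` and `ambiguous`.
#' @export
score_profile <- function(ref, read, ambiguity_fraction = 0.5, window = 7L) {
  assert_dna(ref, "ref"); assert_dna(read, "read")
  if (nchar(ref) == 0L || nchar(read) == 0L)
    stop_scanmut("no_overlap", "empty sequence")
  window <- as.integer(window)
  r <- utf8ToInt(ref); d <- utf8ToInt(read)
  offsets <- (-(length(d) - window)):(length(r) - window)
  if (length(offsets) == 0L || offsets[[1L]] > offsets[[length(offsets)]])
    stop_scanmut("no_overlap", "sequences shorter than the window")
  scores <- vapply(offsets, function(o) window_score_int(r, d, o, window),
                   integer(1L))
  mx <- max(scores)
  if (mx == 0L)
    stop_scanmut("no_overlap", "no alignment window matches at any offset")
  peaks <- offsets[scores >= ambiguity_fraction * mx]
  structure(list(profile = data.frame(offset = offsets, score = scores),
                 best_offset = offsets[[which.max(scores)]],
                 max_score = mx, peaks = peaks,
                 ambiguous = length(peaks) > 1L),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("best offset %d, max score %d, %d peak(s)%s\n", x$best_offset,
              x$max_score, length(x$peaks),
              if (x$ambiguous) " -- AMBIGUOUS" else ""))
  invisible(x)
}

#' Orient a read against the reference
#'
#' `as_is` and `reverse_complement` apply the stated orientation (reads
#' sequenced with a reverse primer must be reverse complemented before
#' alignment).  `auto` scores both orientations and keeps the one with the
#' higher maximal window score, preferring `as_is` on ties.
#'
#' @inheritParams score_profile
#' @param mode One of `"auto"`, `"as_is"`, `"reverse_complement"`.
#' @return List with `sequence` (the oriented read) and `orientation`.
#' @export
orient_read <- function(ref, read, mode = c("auto", "as_is",
                                            "reverse_complement"),
                        window = 7L) {
  mode <- match.arg(mode)
  if (nchar(read) == 0L)
    stop_scanmut("no_overlap", "empty read")
  if (mode == "as_is")
    return(list(sequence = read, orientation = "as_is"))
  rc <- reverse_complement(read)
  if (mode == "reverse_complement")
    return(list(sequence = rc, orientation = "reverse_complement"))
  mx <- function(s) tryCatch(score_profile(ref, s, window = window)$max_score,
                             scanmut_no_overlap = function(e) 0L)
  if (mx(rc) > mx(read)) list(sequence = rc, orientation = "reverse_complement")
  else list(sequence = read, orientation = "as_is")
}

#' Align a read and call mutations codon by codon
#'
#' Orients the read, aligns it at the best offset and compares aligned bases
#' position by position (no gaps).  Differences are grouped by reference
#' codon; each differing codon yields one call with the reference and
#' observed codons, both translations, the nucleotide-level changes and a
#' silent flag.  Read positions containing `N` are reported as uncallable,
#' never as mutations.  If the profile has several peaks the calls are still
#' made at the best offset but the whole report is flagged ambiguous.
#'
#' @param refctx A [reference_context()].
#' @param read Read sequence (free text accepted; `N` allowed).
#' @param mode Orientation mode, see [orient_read()].
#' @inheritParams score_profile
#' @return A list of class `mutation_report`: `alignment` (with the oriented
#'   read in `$oriented_read` and `$orientation`), `calls` (data frame, one
#'   row per differing codon, with `in_region` marking the headline region),
#'   and `uncallable` (codons touched by `N`).
#' @export
align_and_call <- function(refctx, read, mode = "auto",
                           ambiguity_fraction = 0.5, window = 7L) {
  stopifnot(inherits(refctx, "reference_context"))
  read <- normalize_sequence(read)
  ref <- refctx$sequence
  ori <- orient_read(ref, read, mode, window = window)
  aln <- score_profile(ref, ori$sequence, ambiguity_fraction, window)
  aln$oriented_read <- ori$sequence
  aln$orientation <- ori$orientation
  off <- aln$best_offset

  refch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  readch <- strsplit(ori$sequence, "", fixed = TRUE)[[1L]]
  lo <- max(1L, 1L + off)
  hi <- min(length(refch), length(readch) + off)
  a <- refch[lo:hi]
  b <- readch[(lo - off):(hi - off)]
  pos <- lo:hi                         # reference coordinates
  ncod <- refctx$n_aa
  in_frame <- pos <= 3L * ncod
  is_n <- b == "N"
  diff <- a != b & !is_n & in_frame
  unc_codons <- sort(unique((pos[is_n & in_frame] + 2L) %/% 3L))

  empty_calls <- data.frame(aa_position = integer(), ref_aa = character(),
                            obs_aa = character(), codon_ref = character(),
                            codon_obs = character(), nt_changes = character(),
                            silent = logical(), in_region = logical(),
                            stringsAsFactors = FALSE)
  calls <- empty_calls
  cod_idx <- sort(unique((pos[diff] + 2L) %/% 3L))
  cod_idx <- setdiff(cod_idx, unc_codons)  # N anywhere in codon: uncallable
  for (j in cod_idx) {
    cpos <- (3L * j - 2L):(3L * j)
    codon_ref <- paste(refch[cpos], collapse = "")
    obs <- refch[cpos]
    covered <- cpos >= lo & cpos <= hi
    obs[covered] <- readch[cpos[covered] - off]
    codon_obs <- paste(obs, collapse = "")
    changed <- which(obs != refch[cpos])
    nt <- paste(sprintf("%d%s>%s", cpos[changed], refch[cpos[changed]],
                        obs[changed]), collapse = ";")
    ref_aa <- translate(codon_ref); obs_aa <- translate(codon_obs)
    calls <- rbind(calls, data.frame(
      aa_position = j, ref_aa = ref_aa, obs_aa = obs_aa,
      codon_ref = codon_ref, codon_obs = codon_obs, nt_changes = nt,
      silent = ref_aa == obs_aa,
      in_region = j >= refctx$region_of_interest[[1L]] &
                  j <= refctx$region_of_interest[[2L]],
      stringsAsFactors = FALSE))
  }
  structure(list(alignment = aln, calls = calls,
                 uncallable = unc_codons,
                 region_of_interest = refctx$region_of_interest),
            class = "mutation_report")
}

format_call <- function(calls) {
  if (nrow(calls) == 0L) return(character())
  paste0(calls$ref_aa, calls$aa_position, calls$obs_aa,
         ifelse(calls$silent, "(silent)", ""))
}

#' @export
print.mutation_report <- function(x, ...) {
  print(x$alignment)
  hl <- x$calls[x$calls$in_region, , drop = FALSE]
  if (nrow(hl) == 0L) cat("no mutations in the region of interest\n")
  else cat("calls:", paste(format_call(hl), collapse = ", "), "\n")
  if (length(x$uncallable))
    cat("uncallable codons (N in read):",
        paste(x$uncallable, collapse = ", "), "\n")
  invisible(x)
}

#' Batch verification of sequencing reads
#'
#' Runs [align_and_call()] on every read and condenses each into one report
#' row.  The verdict is `no-overlap` when the read cannot be aligned at all,
#' `ambiguous` when the score profile has several peaks, otherwise
#' `expected-mutation-present` when the non-silent in-region calls equal the
#' expected call supplied for that read, `clean` when there is no call, and
#' `unexpected` otherwise.
#'
#' @param refctx A [reference_context()].
#' @param reads Named character vector of read sequences.  Unnamed reads are
#'   named `read_1`, `read_2`, ...; duplicated names are suffixed
#'   deterministically with a warning.
#' @param mode Orientation mode, see [orient_read()].
#' @param expected Optional named character vector mapping read names to the
#'   expected call in `<refAA><position><obsAA>` notation (e.g. `"A25D"`).
#' @inheritParams score_profile
#' @return Data frame with one row per read, in input order: `read`,
#'   `best_offset`, `max_score`, `ambiguous`, `calls`, `verdict`.
#' @export
batch_check <- function(refctx, reads, mode = "auto", expected = NULL,
                        ambiguity_fraction = 0.5, window = 7L) {
  if (length(reads) == 0L)
    stop_scanmut("range_invalid", "no reads supplied")
  nm <- names(reads) %||% rep("", length(reads))
  nm[nm == ""] <- paste0("read_", which(nm == ""))
  if (anyDuplicated(nm)) {
    warning("duplicate read names; suffixing deterministically", call. = FALSE)
    nm <- make.unique(nm, sep = "_dup")
  }
  rows <- lapply(seq_along(reads), function(i) {
    rep_or_err <- tryCatch(
      align_and_call(refctx, reads[[i]], mode, ambiguity_fraction, window),
      scanmut_no_overlap = function(e) e
    )
    if (inherits(rep_or_err, "condition"))
      return(data.frame(read = nm[[i]], best_offset = NA_integer_,
                        max_score = 0L, ambiguous = NA,
                        calls = "", verdict = "no-overlap",
                        stringsAsFactors = FALSE))
    rep <- rep_or_err
    hl <- rep$calls[rep$calls$in_region, , drop = FALSE]
    calls_str <- paste(format_call(hl), collapse = ",")
    exp_call <- if (!is.null(expected)) expected[nm[[i]]] else NA_character_
    verdict <- if (rep$alignment$ambiguous) "ambiguous"
    else if (nrow(hl) == 0L) "clean"
    else if (!is.na(exp_call) &&
             identical(sort(format_call(hl)),
                       sort(trimws(strsplit(exp_call, ",")[[1L]]))))
      "expected-mutation-present"
    else "unexpected"
    data.frame(read = nm[[i]], best_offset = rep$alignment$best_offset,
               max_score = rep$alignment$max_score,
               ambiguous = rep$alignment$ambiguous,
               calls = calls_str, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
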