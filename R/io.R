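# FASTA reading/writing, the four primer output formats and the
# human-readable project configuration.

#' Read a (multi-)FASTA file
#'
#' @param path File path.
#' @return Named character vector of uppercase sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path))
    stop_scanmut("malformed_fasta", sprintf("no such file: %s", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e)
                    stop_scanmut("malformed_fasta",
                                 sprintf("cannot parse %s as FASTA: %s",
                                         path, conditionMessage(e))))
  if (length(set) == 0L)
    stop_scanmut("malformed_fasta", sprintf("no FASTA records in %s", path))
  out <- toupper(as.character(set))
  names(out) <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, "", 1L)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

primer_base_name <- function(pair) {
  paste0(pair$wt_aa, pair$aa_position, pair$mut_aa)
}

# Coding-strand display of one primer: lowercase template bases, the mutated
# codon capitalised, substituted bases shown as 'X'.
display_coding <- function(pair, cand) {
  span <- cand$template_span
  disp <- tolower(cand$coding_strand)
  if (!cand$carries_mutation) return(disp)
  tch <- strsplit(pair$template_codon, "", fixed = TRUE)[[1L]]
  mch <- strsplit(pair$mutated_codon, "", fixed = TRUE)[[1L]]
  for (j in 1:3) {
    at <- pair$codon_span[[1L]] + j - 1L - span[[1L]] + 1L
    substr(disp, at, at) <- if (tch[[j]] == mch[[j]]) tch[[j]] else "X"
  }
  disp
}

pairs_table <- function(pairs) {
  rows <- lapply(pairs, function(pair) {
    base <- primer_base_name(pair)
    do.call(rbind, lapply(list(pair$forward, pair$reverse), function(cand) {
      data.frame(
        name = paste0(base, if (cand$strand == "forward") "_F" else "_R"),
        strand = cand$strand,
        coding_strand = display_coding(pair, cand),
        length = nchar(cand$sequence),
        tm = round(cand$tm_anneal, 2), tm_full = round(cand$tm_full, 2),
        gc_clamp_score = cand$clamp_score, gc_clamp_run = cand$clamp_run,
        anneal_len_3prime = cand$anneal_len_3prime,
        overlap_len = pair$overlap_len,
        primer = cand$sequence,
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

split_f_r <- function(tab, render) {
  list(forward = render(tab[tab$strand == "forward", , drop = FALSE]),
       reverse = render(tab[tab$strand == "reverse", , drop = FALSE]))
}

#' Render designed pairs in the four output formats
#'
#' `render_long1()` gives a verbose per-primer text block: the primer on the
#' coding strand with the mutated codon capitalised and substituted bases
#' shown as `X`, followed by length, annealing Tm (mismatches excluded),
#' full-length Tm, GC-clamp score, 3' annealing length, and the orderable
#' primer sequence (reverse complemented where needed).  `render_long2()`
#' emits the same fields as a header plus one tab-separated row per primer.
#' `render_short()` emits `name<TAB>sequence` order lines and
#' `render_fasta()` a FASTA listing.  Names follow
#' `<wtAA><position><mutAA>_F/_R`.
#'
#' @param pairs List of `primer_pair` objects (see [enumerate_pairs()]).
#' @param separate_f_r If `TRUE`, return a list with `forward` and
#'   `reverse` blocks instead of one interleaved block.
#' @return Character vector of output lines (or a list of two such vectors).
#' @name render_formats
NULL

#' @rdname render_formats
#' @export
render_long1 <- function(pairs, separate_f_r = FALSE) {
  tab <- pairs_table(pairs)
  render <- function(t) unlist(lapply(seq_len(nrow(t)), function(i) c(
    sprintf("%s  %s", t$name[[i]], t$coding_strand[[i]]),
    sprintf("    len %d  Tm %.2f  Tm_full %.2f  GCclamp %d  anneal3' %s",
            t$length[[i]], t$tm[[i]], t$tm_full[[i]], t$gc_clamp_score[[i]],
            ifelse(is.na(t$anneal_len_3prime[[i]]), "-",
                   t$anneal_len_3prime[[i]])),
    sprintf("    order: %s", t$primer[[i]]))))
  if (separate_f_r) split_f_r(tab, render) else render(tab)
}

#' @rdname render_formats
#' @export
render_long2 <- function(pairs, separate_f_r = FALSE) {
  tab <- pairs_table(pairs)
  render <- function(t) {
    cols <- c("name", "strand", "coding_strand", "length", "tm", "tm_full",
              "gc_clamp_score", "anneal_len_3prime", "overlap_len", "primer")
    c(paste(cols, collapse = "\t"),
      vapply(seq_len(nrow(t)), function(i)
        paste(vapply(cols, function(cl) {
          v <- t[[cl]][[i]]
          if (is.na(v)) "NA" else as.character(v)
        }, ""), collapse = "\t"), ""))
  }
  if (separate_f_r) split_f_r(tab, render) else render(tab)
}

#' @rdname render_formats
#' @export
render_short <- function(pairs, separate_f_r = FALSE) {
  tab <- pairs_table(pairs)
  render <- function(t) sprintf("%s\t%s", t$name, t$primer)
  if (separate_f_r) split_f_r(tab, render) else render(tab)
}

#' @rdname render_formats
#' @export
render_fasta <- function(pairs, separate_f_r = FALSE) {
  tab <- pairs_table(pairs)
  render <- function(t) as.vector(rbind(paste0(">", t$name), t$primer))
  if (separate_f_r) split_f_r(tab, render) else render(tab)
}

OUTPUT_FORMATS <- c(Long1 = "render_long1", Long2 = "render_long2",
                    Short = "render_short", FASTA = "render_fasta")

render_pairs <- function(pairs, format = "Long2", separate_f_r = FALSE) {
  if (!format %in% names(OUTPUT_FORMATS))
    stop_scanmut("range_invalid",
                 sprintf("unknown output format '%s'", format))
  get(OUTPUT_FORMATS[[format]])(pairs, separate_f_r = separate_f_r)
}

#' Project configuration
#'
#' A human-readable description of one design project: the template, ORF
#' start, full parameter set and output options.  Saved and loaded as YAML;
#' the round trip is lossless.
#'
#' @param template Template sequence (inline) or a path to a FASTA/text
#'   file.
#' @param orf_start 1-based ORF start coordinate.
#' @param params A [design_params()].
#' @param format One of `Long1`, `Long2`, `Short`, `FASTA`.
#' @param separate_f_r Split forward and reverse primers into two lists.
#' @param verbose Print additional design information.
#' @return A list of class `project_config`.
#' @export
project_config <- function(template, orf_start, params = design_params(),
                           format = "Long2", separate_f_r = FALSE,
                           verbose = FALSE) {
  if (!format %in% names(OUTPUT_FORMATS))
    stop_scanmut("range_invalid", sprintf("unknown format '%s'", format))
  structure(list(template = as.character(template),
                 orf_start = as.integer(orf_start),
                 params = params, format = format,
                 separate_f_r = isTRUE(separate_f_r),
                 verbose = isTRUE(verbose)),
            class = "project_config")
}

#' @rdname project_config
#' @param config A `project_config` object.
#' @param path YAML file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "project_config"))
  x <- unclass(config)
  x$params <- unclass(x$params)
  x$params$primary_aa <- NULL
  x$params$fallback_aa <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname project_config
#' @export
load_config <- function(path) {
  x <- yaml::read_yaml(path)
  project_config(template = x$template, orf_start = x$orf_start,
                 params = do.call(design_params, x$params),
                 format = x$format, separate_f_r = x$separate_f_r,
                 verbose = x$verbose)
}
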