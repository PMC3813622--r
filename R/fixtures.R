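# Seeded synthetic fixtures: random plasmids with an embedded ORF, mutant
# sequencing reads with known truth, and helpers shared by the test suite
# and the command-line fixture generator.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random DNA sequence
#'
#' Draws bases independently with the given GC fraction (G and C equally
#' likely, likewise A and T).  Uses the current RNG state; seed externally
#' for reproducibility.
#'
#' @param length Number of bases.
#' @param gc_fraction Expected fraction of G+C in `[0, 1]`.
#' @return DNA string.
#' @export
random_dna <- function(length, gc_fraction = 0.5) {
  if (length <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
               prob = c((1 - gc_fraction) / 2, (1 - gc_fraction) / 2,
                        gc_fraction / 2, gc_fraction / 2)),
        collapse = "")
}

SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]

# deterministic codon choice for a target amino acid: the alphabetically
# first codon among those with the fewest mismatches to the template codon
codon_for_aa <- function(aa, template_codon) {
  cands <- sort(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa])
  if (length(cands) == 0L)
    stop_scanmut("spec_invalid", sprintf("no codon encodes '%s'", aa))
  mm <- vapply(cands, codon_mismatches, integer(1L), b = template_codon)
  cands[[which.min(mm)]]
}

#' Fixture specification
#'
#' Describes one deterministic synthetic dataset: a plasmid with an embedded
#' ORF (ATG start, no internal stops, a stop codon immediately after), plus
#' sequencing reads carrying planted codon substitutions and optional
#' uniform per-base read errors.
#'
#' @param seed Integer seed; the same spec always produces byte-identical
#'   output.
#' @param plasmid_length Total template length in bp; must leave at least 60
#'   bp of flank on each side of the ORF.
#' @param orf_length_aa Number of codons in the ORF (including the initial
#'   Met, excluding the stop).
#' @param gc_fraction GC fraction of the non-coding backbone.
#' @param planted_mutations Data frame with columns `residue` and
#'   `target_aa`; one mutant read is generated per row.
#' @param read_error_rate Per-base probability of a random substitution in
#'   the reads.
#' @param n_clean_reads Additional wild-type reads.
#' @param read_flank Bases kept on each side of the mutated codon in a read.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed, plasmid_length = 600L, orf_length_aa = 100L,
                         gc_fraction = 0.5, planted_mutations = NULL,
                         read_error_rate = 0, n_clean_reads = 0L,
                         read_flank = 75L) {
  plasmid_length <- as.integer(plasmid_length)
  orf_length_aa <- as.integer(orf_length_aa)
  if (plasmid_length < 3L * orf_length_aa + 120L)
    stop_scanmut("spec_invalid",
                 "ORF does not fit in the plasmid with 60 bp flanks")
  if (!is.null(planted_mutations)) {
    stopifnot(is.data.frame(planted_mutations),
              all(c("residue", "target_aa") %in% names(planted_mutations)))
    if (any(planted_mutations$residue < 1L |
            planted_mutations$residue > orf_length_aa))
      stop_scanmut("spec_invalid", "planted residue outside the ORF")
  }
  structure(list(seed = as.integer(seed), plasmid_length = plasmid_length,
                 orf_length_aa = orf_length_aa,
                 gc_fraction = as.numeric(gc_fraction),
                 planted_mutations = planted_mutations,
                 read_error_rate = as.numeric(read_error_rate),
                 n_clean_reads = as.integer(n_clean_reads),
                 read_flank = as.integer(read_flank)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @return A list of class `fixture`: `plasmid`, `orf_start`,
#'   `orf_length_aa`, `reads` (named character vector), `truth` (data frame
#'   `read`, `residue`, `ref_aa`, `obs_aa`; `NA` residue for clean reads)
#'   and the `spec`.
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    orf_nt <- 3L * spec$orf_length_aa
    flank_total <- spec$plasmid_length - orf_nt
    flank5 <- flank_total %/% 2L
    flank3 <- flank_total - flank5
    orf <- paste0("ATG", paste(sample(SENSE_CODONS, spec$orf_length_aa - 1L,
                                      replace = TRUE), collapse = ""))
    plasmid <- paste0(random_dna(flank5, spec$gc_fraction), orf, "TAA",
                      random_dna(flank3 - 3L, spec$gc_fraction))
    orf_start <- flank5 + 1L

    reads <- character(); truth <- NULL
    add_read <- function(name, seq, residue, ref_aa, obs_aa) {
      if (spec$read_error_rate > 0) {
        ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
        hit <- which(stats::runif(length(ch)) < spec$read_error_rate)
        for (i in hit) ch[[i]] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 ch[[i]]), 1L)
        seq <- paste(ch, collapse = "")
      }
      reads[[name]] <<- seq
      truth <<- rbind(truth, data.frame(read = name, residue = residue,
                                        ref_aa = ref_aa, obs_aa = obs_aa,
                                        stringsAsFactors = FALSE))
    }

    pm <- spec$planted_mutations
    n_mut <- if (is.null(pm)) 0L else nrow(pm)
    for (i in seq_len(n_mut)) {
      res <- as.integer(pm$residue[[i]])
      target <- as.character(pm$target_aa[[i]])
      c0 <- orf_start + 3L * (res - 1L)
      tcod <- substr(plasmid, c0, c0 + 2L)
      mcod <- codon_for_aa(target, tcod)
      mutant <- plasmid
      substr(mutant, c0, c0 + 2L) <- mcod
      lo <- max(1L, c0 - spec$read_flank)
      hi <- min(nchar(mutant), c0 + 2L + spec$read_flank)
      add_read(sprintf("read_%03d", i), substr(mutant, lo, hi),
               res, translate(tcod), target)
    }
    for (j in seq_len(spec$n_clean_reads)) {
      lo <- sample.int(nchar(plasmid) - (2L * spec$read_flank + 3L) + 1L, 1L)
      add_read(sprintf("read_%03d", n_mut + j),
               substr(plasmid, lo, lo + 2L * spec$read_flank + 2L),
               NA_integer_, NA_character_, NA_character_)
    }
    structure(list(plasmid = plasmid, orf_start = orf_start,
                   orf_length_aa = spec$orf_length_aa, reads = reads,
                   truth = truth %||% data.frame(read = character(),
                                                 residue = integer(),
                                                 ref_aa = character(),
                                                 obs_aa = character(),
                                                 stringsAsFactors = FALSE),
                   spec = spec),
              class = "fixture")
  })
}

#' Write a fixture to disk
#'
#' Writes `plasmid.fasta`, `reads.fasta` and `truth.tsv` into `dir`.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  stopifnot(inherits(fixture, "fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(plasmid = fixture$plasmid), file.path(dir, "plasmid.fasta"))
  if (length(fixture$reads))
    write_fasta(fixture$reads, file.path(dir, "reads.fasta"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
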