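# IUPAC nucleotide classes and their complements.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
                D = "H", H = "D", N = "N")

iupac_revcomp <- function(motif) {
  chars <- rev(strsplit(toupper(motif), "")[[1]])
  paste(IUPAC_COMP[chars], collapse = "")
}

is_palindromic <- function(motif) toupper(motif) == iupac_revcomp(motif)

#' Built-in restriction enzyme table
#'
#' Six workhorse enzymes for CAPS/dCAPS design, including the type IIS
#' enzyme FokI (recognition `GGATG`, non-palindromic; only site presence is
#' modelled, not its offset cutting). The table is an editable TSV with
#' columns `enzyme` and `motif` (IUPAC codes).
#'
#' @param path Path to an enzyme TSV; defaults to the table shipped with the
#'   package.
#' @return A tibble `enzyme`, `motif`, `palindromic`.
#' @export
restriction_enzymes <- function(path = system.file("extdata", "enzymes.tsv",
                                                   package = "bsamapr")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  tab$motif <- toupper(tab$motif)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]{4,}$", tab$motif)
  if (any(bad)) {
    abort(sprintf("invalid motif(s): %s (IUPAC alphabet, length >= 4)",
                  paste(tab$motif[bad], collapse = ", ")))
  }
  mutate(tab, palindromic = vapply(.data$motif, is_palindromic, logical(1)))
}

# logical vector over 1-based window starts: does the window match the motif?
iupac_window_match <- function(seq_chars, motif_chars) {
  n <- length(seq_chars) - length(motif_chars) + 1L
  if (n < 1L) return(logical(0))
  ok <- rep(TRUE, n)
  for (j in seq_along(motif_chars)) {
    ok <- ok & seq_chars[seq_len(n) + j - 1L] %in% IUPAC_SETS[[motif_chars[j]]]
  }
  ok
}

#' In-silico digestion: all recognition sites of an enzyme
#'
#' Scans both strands for IUPAC matches of the recognition motif and
#' returns 0-based start positions (forward-strand coordinates of the
#' matched window). Palindromic motifs are reported on the forward strand
#' only, since both strands match at the same windows.
#'
#' @param sequence A DNA string.
#' @param motif IUPAC recognition motif (or a one-row slice of
#'   [restriction_enzymes()]).
#' @return A tibble `position` (0-based), `strand`.
#' @export
digest <- function(sequence, motif) {
  if (is.data.frame(motif)) motif <- motif$motif[1]
  motif <- toupper(motif)
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  fwd <- which(iupac_window_match(seq_chars, strsplit(motif, "")[[1]])) - 1L
  out <- tibble(position = fwd, strand = rep("+", length(fwd)))
  if (!is_palindromic(motif)) {
    rc <- iupac_revcomp(motif)
    rev_hits <- which(iupac_window_match(seq_chars, strsplit(rc, "")[[1]])) - 1L
    out <- bind_rows(out, tibble(position = rev_hits,
                                 strand = rep("-", length(rev_hits))))
  }
  arrange(out, .data$position, .data$strand)
}

apply_substitutions <- function(seq, positions0, bases) {
  chars <- strsplit(seq, "")[[1]]
  chars[positions0 + 1L] <- bases
  paste(chars, collapse = "")
}

revcomp_chr <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Design dCAPS (and CAPS) markers for a SNP
#'
#' Considers every enzyme, strand and motif placement whose recognition
#' window covers the SNP. A placement yields a design when (a) the SNP base
#' matches the motif for exactly one allele, and (b) every other window
#' position either already matches the motif or can be made to match by an
#' engineered substitution, using at most `max_mismatches` substitutions
#' (never at the SNP itself). Zero-mismatch designs are CAPS; designs
#' needing engineered bases are dCAPS. For each valid placement the minimal
#' substitution set is reported, choosing the alphabetically first
#' compatible base at each engineered position.
#'
#' The genotyping primer is reported on the placement strand, ending one
#' nucleotide 3' of the recognition window, built from the reference-allele
#' amplicon with the engineered substitutions applied;
#' `primer_mismatch_offsets` gives their 0-based offsets from the primer 5'
#' end.
#'
#' @param flank_left,flank_right Flanking sequence either side of the SNP.
#'   Each flank must be at least `min(motif length) - 1` bases; placements
#'   of longer motifs that do not fit the available sequence are skipped.
#' @param ref,alt The two SNP alleles (single bases).
#' @param enzymes An enzyme table from [restriction_enzymes()].
#' @param max_mismatches Maximum engineered substitutions (default 1; 0
#'   reduces the search to CAPS designs).
#' @param primer_length Primer length in nt, measured back from its 3' end
#'   (default 25; clipped at the amplicon boundary).
#' @return A `marker_design` tibble: `type` (CAPS/dCAPS), `enzyme`, `motif`,
#'   `strand`, `motif_start` (0-based, in `flank_left + allele +
#'   flank_right` coordinates), `motif_start_rel` (relative to the SNP),
#'   `cut_allele` (which allele carries the site), `n_mismatches`,
#'   `mismatch_positions` (0-based amplicon coordinates, comma-separated),
#'   `primer`, `primer_mismatch_offsets`, and the two allele amplicons with
#'   substitutions applied (`amplicon_ref_mod`, `amplicon_alt_mod`).
#' @export
find_dcaps <- function(flank_left, ref, alt, flank_right,
                       enzymes = restriction_enzymes(),
                       max_mismatches = 1, primer_length = 25) {
  flank_left <- toupper(flank_left); flank_right <- toupper(flank_right)
  ref <- toupper(ref); alt <- toupper(alt)
  stopifnot(nchar(ref) == 1L, nchar(alt) == 1L, ref != alt)
  need <- min(nchar(enzymes$motif)) - 1L
  if (nchar(flank_left) < need || nchar(flank_right) < need) {
    abort(sprintf("flanks must be at least %d bases each side of the SNP", need))
  }
  amp_ref <- paste0(flank_left, ref, flank_right)
  amp_alt <- paste0(flank_left, alt, flank_right)
  snp0 <- nchar(flank_left)           # 0-based SNP position in the amplicon
  seq_chars <- strsplit(amp_ref, "")[[1]]
  total <- length(seq_chars)
  designs <- list()
  for (i in seq_len(nrow(enzymes))) {
    motif <- enzymes$motif[i]
    strands <- if (enzymes$palindromic[i]) "+" else c("+", "-")
    for (strand in strands) {
      m <- strsplit(if (strand == "+") motif else iupac_revcomp(motif), "")[[1]]
      L <- length(m)
      for (s0 in max(0L, snp0 - L + 1L):snp0) {
        if (s0 + L > total) next
        sub_pos <- integer(0); sub_base <- character(0)
        ref_ok <- alt_ok <- NA
        feasible <- TRUE
        for (j in seq_len(L)) {
          idx0 <- s0 + j - 1L
          set <- IUPAC_SETS[[m[j]]]
          if (idx0 == snp0) {
            ref_ok <- ref %in% set
            alt_ok <- alt %in% set
          } else if (!(seq_chars[idx0 + 1L] %in% set)) {
            sub_pos <- c(sub_pos, idx0)
            sub_base <- c(sub_base, sort(set)[1])
          }
          if (length(sub_pos) > max_mismatches) { feasible <- FALSE; break }
        }
        if (!feasible || !xor(ref_ok, alt_ok)) next
        mod_ref <- apply_substitutions(amp_ref, sub_pos, sub_base)
        mod_alt <- apply_substitutions(amp_alt, sub_pos, sub_base)
        # primer on the placement strand, 3' end one nt past the motif
        if (strand == "+") {
          p_hi <- min(s0 + L, total - 1L)
          p_lo <- max(0L, p_hi - primer_length + 1L)
          primer <- substring(mod_ref, p_lo + 1L, p_hi + 1L)
          offsets <- sub_pos - p_lo
        } else {
          p_lo <- max(0L, s0 - 1L)
          p_hi <- min(total - 1L, p_lo + primer_length - 1L)
          primer <- revcomp_chr(substring(mod_ref, p_lo + 1L, p_hi + 1L))
          offsets <- p_hi - sub_pos
        }
        keep <- offsets >= 0 & offsets < nchar(primer)
        designs[[length(designs) + 1L]] <- tibble(
          type = if (length(sub_pos) == 0L) "CAPS" else "dCAPS",
          enzyme = enzymes$enzyme[i], motif = motif, strand = strand,
          motif_start = s0, motif_start_rel = s0 - snp0,
          cut_allele = if (ref_ok) "reference" else "alternate",
          n_mismatches = length(sub_pos),
          mismatch_positions = paste(sub_pos, collapse = ","),
          primer = primer,
          primer_mismatch_offsets = paste(sort(offsets[keep]), collapse = ","),
          amplicon_ref_mod = mod_ref, amplicon_alt_mod = mod_alt
        )
      }
    }
  }
  out <- bind_rows(designs)
  if (nrow(out) == 0L) {
    out <- tibble(type = character(), enzyme = character(), motif = character(),
                  strand = character(), motif_start = integer(),
                  motif_start_rel = integer(), cut_allele = character(),
                  n_mismatches = integer(), mismatch_positions = character(),
                  primer = character(), primer_mismatch_offsets = character(),
                  amplicon_ref_mod = character(), amplicon_alt_mod = character())
  }
  class(out) <- c("marker_design", class(out))
  out
}

#' Design CAPS markers (no engineered mismatches)
#'
#' A CAPS marker exists when the SNP itself creates or destroys a
#' recognition site, so digestion distinguishes the alleles without any
#' primer engineering. Equivalent to [find_dcaps()] with
#' `max_mismatches = 0`.
#'
#' @inheritParams find_dcaps
#' @return A `marker_design` tibble (see [find_dcaps()]).
#' @export
find_caps <- function(flank_left, ref, alt, flank_right,
                      enzymes = restriction_enzymes(), primer_length = 25) {
  find_dcaps(flank_left, ref, alt, flank_right, enzymes,
             max_mismatches = 0, primer_length = primer_length)
}
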