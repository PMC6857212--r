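#' Read gene models (CDS structure) from GFF3
#'
#' Keeps `CDS` features and returns one row per CDS segment with 1-based
#' inclusive coordinates and phase, grouped by gene id (the `Parent`
#' attribute when present, else `ID`).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_models` tibble: `gene_id`, `chrom`, `strand`, `start`,
#'   `end`, `phase`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0) abort("no CDS features found in GFF3")
  md <- S4Vectors::mcols(cds)
  pick_id <- function(i) {
    p <- if ("Parent" %in% names(md)) as.character(unlist(md$Parent[i]))[1] else NA
    if (is.na(p) || length(p) == 0) p <- as.character(md$ID[i])
    p
  }
  out <- tibble(
    gene_id = vapply(seq_along(cds), pick_id, character(1)),
    chrom = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds),
    phase = ifelse(is.na(md$phase), 0L, as.integer(md$phase))
  )
  out <- arrange(out, .data$gene_id, .data$start)
  class(out) <- c("gene_models", class(out))
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return A named character vector of chromosome sequences (names trimmed
#'   to the first whitespace-delimited word).
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  stats::setNames(as.character(seqs), names(seqs))
}

# Spliced CDS of one gene in transcription orientation, plus a map from
# genomic position to CDS coordinate. `segs` must be sorted by start.
splice_cds <- function(segs, chrom_seq) {
  minus <- segs$strand[1] == "-"
  ord <- if (minus) rev(seq_len(nrow(segs))) else seq_len(nrow(segs))
  pieces <- substring(chrom_seq, segs$start, segs$end)
  genomic_pos <- unlist(lapply(ord, function(i) {
    p <- segs$start[i]:segs$end[i]
    if (minus) rev(p) else p
  }))
  cds <- paste0(if (minus) {
    vapply(pieces[ord], function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1))
  } else pieces[ord], collapse = "")
  phase <- segs$phase[ord[1]]
  if (phase > 0) {
    cds <- substring(cds, phase + 1)
    genomic_pos <- genomic_pos[-seq_len(phase)]
  }
  list(seq = cds, genomic_pos = genomic_pos, minus = minus)
}

translate_cds <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), pmin(seq(3, nchar(cds) + 2, 3), nchar(cds)))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

empty_effects <- function() {
  tibble(gene_id = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), classification = character(),
         codon_ref = character(), codon_alt = character(), residue = integer(),
         aa_ref = character(), aa_alt = character(),
         protein_ref = character(), protein_alt = character())
}

#' Classify the coding consequence of a SNP
#'
#' Splices each overlapping gene's CDS (reverse-complemented for
#' minus-strand genes, honouring the phase of the first segment), locates
#' the affected codon, translates the reference and mutated CDS under the
#' standard nuclear genetic code, and classifies the change as synonymous,
#' missense, nonsense (stop gained), stop_loss or start_loss. SNPs outside
#' every CDS are classified `non_coding`. Genes whose CDS length is not a
#' multiple of three are flagged with a warning and skipped.
#'
#' @param models A `gene_models` tibble from [read_gene_models()].
#' @param genome Named character vector of chromosome sequences
#'   (see [read_genome()]).
#' @param chrom,pos,ref,alt The SNP (1-based; `ref`/`alt` on the forward
#'   genomic strand). `ref` must match the genome at `pos`.
#' @return An `effect_call` tibble with one row per overlapping gene (one
#'   `non_coding` row when none overlaps): classification, codons before and
#'   after, residue position, amino acids before and after, and the full
#'   reference and mutant protein sequences.
#' @export
classify_snp <- function(models, genome, chrom, pos, ref, alt) {
  if (!chrom %in% names(genome)) abort(sprintf("chromosome %s absent from genome", chrom))
  genome_base <- toupper(substring(genome[[chrom]], pos, pos))
  if (genome_base != toupper(ref)) {
    abort(sprintf("ref allele mismatch at %s:%d: genome has %s, record says %s",
                  chrom, pos, genome_base, ref))
  }
  hits <- unique(models$gene_id[models$chrom == chrom &
                                  models$start <= pos & models$end >= pos])
  if (length(hits) == 0) {
    out <- empty_effects()
    out[1, ] <- list(NA_character_, chrom, as.integer(pos), ref, alt, "non_coding",
                     NA_character_, NA_character_, NA_integer_, NA_character_,
                     NA_character_, NA_character_, NA_character_)
    return(out)
  }
  rows <- lapply(hits, function(g) {
    segs <- models[models$gene_id == g, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    sp <- splice_cds(segs, genome[[chrom]])
    if (nchar(sp$seq) %% 3 != 0) {
      warn(sprintf("gene %s: CDS length %d is not a multiple of 3; skipped",
                   g, nchar(sp$seq)))
      return(NULL)
    }
    cds_pos <- match(pos, sp$genomic_pos)
    if (is.na(cds_pos)) return(NULL)   # inside gene span but between segments
    alt_base <- if (sp$minus) comp_base[[toupper(alt)]] else toupper(alt)
    cds_alt <- sp$seq
    substring(cds_alt, cds_pos, cds_pos) <- alt_base
    residue <- (cds_pos - 1L) %/% 3L + 1L
    codon_at <- function(s) substring(s, (residue - 1L) * 3L + 1L, residue * 3L)
    prot_ref <- translate_cds(sp$seq)
    prot_alt <- translate_cds(cds_alt)
    aa_ref <- substring(prot_ref, residue, residue)
    aa_alt <- substring(prot_alt, residue, residue)
    classification <-
      if (aa_ref == aa_alt) "synonymous"
      else if (aa_alt == "*") "nonsense"
      else if (aa_ref == "*") "stop_loss"
      else if (residue == 1L && aa_ref == "M") "start_loss"
      else "missense"
    tibble(gene_id = g, chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
           classification = classification,
           codon_ref = codon_at(sp$seq), codon_alt = codon_at(cds_alt),
           residue = residue, aa_ref = aa_ref, aa_alt = aa_alt,
           protein_ref = prot_ref, protein_alt = prot_alt)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    out <- empty_effects()
    out[1, ] <- list(NA_character_, chrom, as.integer(pos), ref, alt, "non_coding",
                     NA_character_, NA_character_, NA_integer_, NA_character_,
                     NA_character_, NA_character_, NA_character_)
    return(out)
  }
  bind_rows(rows)
}

#' Classify many SNPs at once
#'
#' @param models,genome As in [classify_snp()].
#' @param snps A data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return A combined `effect_call` tibble.
#' @export
classify_variants <- function(models, genome, snps) {
  bind_rows(purrr::pmap(
    list(snps$chrom, snps$pos, snps$ref, snps$alt),
    function(chrom, pos, ref, alt) classify_snp(models, genome, chrom, pos, ref, alt)
  ))
}

#' Report a residue motif window before and after a mutation
#'
#' Locates a motif (default the Aux/IAA domain II degron core `GWPPV`) at
#' its leftmost occurrence in the reference protein and returns the aligned
#' window from both proteins, e.g. `("GWPPV", "EWPPV")` for a degron
#' substitution.
#'
#' @param protein_ref,protein_alt Protein sequences (single-letter).
#' @param motif Residue string to locate in `protein_ref`.
#' @return A one-row tibble `motif`, `start`, `before`, `after`, or a
#'   zero-row tibble when the motif is absent.
#' @export
motif_report <- function(protein_ref, protein_alt, motif = "GWPPV") {
  at <- regexpr(motif, protein_ref, fixed = TRUE)
  if (at < 0) {
    return(tibble(motif = character(), start = integer(),
                  before = character(), after = character()))
  }
  end <- at + nchar(motif) - 1L
  tibble(motif = motif, start = as.integer(at),
         before = substring(protein_ref, at, end),
         after = substring(protein_alt, at, end))
}

#' Candidate genes: non-synonymous changes inside a region
#'
#' @param effects An `effect_call` tibble from [classify_variants()].
#' @param models The `gene_models` used for classification.
#' @param region A one-row data frame with `chrom`, `start`, `end`
#'   (1-based inclusive), e.g. a row of [call_regions()] output.
#' @return A tibble of candidate genes (`gene_id`, `chrom`, `start`, `end`)
#'   overlapping the region and carrying at least one missense, nonsense,
#'   start-loss or stop-loss call.
#' @export
filter_candidate_genes <- function(effects, models, region) {
  spans <- summarise(group_by(as_tibble(models), .data$gene_id),
                     chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), .groups = "drop")
  if (nrow(region) == 0) return(spans[0, ])
  nonsyn <- c("missense", "nonsense", "start_loss", "stop_loss")
  hit_genes <- unique(effects$gene_id[effects$classification %in% nonsyn])
  keep <- spans$gene_id %in% hit_genes &
    spans$chrom == region$chrom[1] &
    spans$start <= region$end[1] & spans$end >= region$start[1]
  spans[keep, , drop = FALSE]
}
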