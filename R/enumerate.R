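# Exhaustive enumeration of missense single-nucleotide substitutions
# in mitochondrial protein-coding genes under the vertebrate
# mitochondrial genetic code (NCBI translation table 2). Overlapping
# genes are evaluated independently: a substitution falling in two
# genes is assessed once per gene.

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

.read_genome <- function(genome) {
  if (inherits(genome, "DNAString")) return(as.character(genome))
  if (inherits(genome, "DNAStringSet")) return(as.character(genome[[1]]))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    return(as.character(seqs[[1]]))
  }
  toupper(as.character(genome))
}

#' Enumerate all possible missense substitutions
#'
#' Evaluates every single-nucleotide substitution at every coding
#' position of every annotated gene and emits a record wherever the
#' encoded amino acid changes, translating with the vertebrate
#' mitochondrial genetic code. Genes are processed independently, so
#' positions shared by overlapping genes are enumerated once per gene.
#' Output ordering is deterministic: gene symbol, position, alt.
#'
#' @param genome genome sequence: a FASTA path, a
#'   `Biostrings::DNAString`(Set), or a plain character string.
#' @param genes coordinate table with columns `gene`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`) and `codon_start`
#'   (1-based offset of the first full codon, usually 1).
#' @param include_stop count amino-acid changes involving a stop codon
#'   (stop gain/loss) as missense (default `TRUE`); when `FALSE`,
#'   substitutions whose reference or alternate amino acid is a stop
#'   are not emitted.
#' @return data.frame of records with columns `gene`, `position`,
#'   `ref`, `alt` (plus-strand alleles), `aa_change`.
#' @export
enumerate_missense <- function(genome, genes, include_stop = TRUE) {
  seq <- .read_genome(genome)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!("codon_start" %in% names(genes))) genes$codon_start <- 1L
  needed <- c("gene", "start", "end", "strand", "codon_start")
  miss <- setdiff(needed, names(genes))
  if (length(miss) > 0)
    format_error(paste0("gene table lacks column(s): ",
                        paste(miss, collapse = ", ")))
  if (any(genes$end > nchar(seq)) || any(genes$start < 1))
    apogee_error("gene coordinates exceed the sequence length",
                 "apogee_annotation_error")
  gc_table <- Biostrings::getGeneticCode("2")  # vertebrate mitochondrial
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (g in seq_len(nrow(genes))) {
    gene <- genes$gene[g]
    sub <- substr(seq, genes$start[g], genes$end[g])
    minus <- genes$strand[g] == "-"
    cds <- if (minus) .revcomp(sub) else sub
    off <- genes$codon_start[g] - 1L
    cds <- substr(cds, off + 1L, nchar(cds))
    if (nchar(cds) %% 3 != 0)
      apogee_error(sprintf(
        "gene %s: frame length %d not divisible by 3 after codon_start adjustment",
        gene, nchar(cds)), "apogee_annotation_error")
    cds_chars <- strsplit(cds, "")[[1]]
    n_codons <- length(cds_chars) / 3
    for (i in seq_len(n_codons)) {
      codon <- cds_chars[(3 * i - 2):(3 * i)]
      ref_aa <- gc_table[[paste(codon, collapse = "")]]
      for (w in 1:3) {
        cds_pos <- 3 * (i - 1) + w          # 1-based within trimmed CDS
        genome_pos <- if (minus)
          genes$end[g] - off - (cds_pos - 1L)
        else genes$start[g] + off + (cds_pos - 1L)
        ref_base_cds <- codon[w]
        for (alt_base_cds in setdiff(bases, ref_base_cds)) {
          mut <- codon; mut[w] <- alt_base_cds
          alt_aa <- gc_table[[paste(mut, collapse = "")]]
          if (alt_aa == ref_aa) next
          if (!include_stop && (ref_aa == "*" || alt_aa == "*")) next
          ref_g <- if (minus) chartr("ACGT", "TGCA", ref_base_cds) else ref_base_cds
          alt_g <- if (minus) chartr("ACGT", "TGCA", alt_base_cds) else alt_base_cds
          out[[length(out) + 1]] <- c(gene, genome_pos, ref_g, alt_g,
                                      paste0(ref_aa, i, alt_aa))
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(gene = character(0), position = integer(0),
                      ref = character(0), alt = character(0),
                      aa_change = character(0)))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("gene", "position", "ref", "alt", "aa_change")
  df$position <- as.integer(df$position)
  df <- df[order(df$gene, df$position, df$alt), , drop = FALSE]
  rownames(df) <- NULL
  df
}
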