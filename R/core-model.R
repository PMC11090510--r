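#' @keywords internal
"_PACKAGE"

# Internal coordinate convention: 0-based half-open on the nucleotide level,
# 0-based half-open on the amino-acid level. External (GFF3) I/O is 1-based
# inclusive. Strand is stored per gene; "same direction" always compares the
# strand symbol, never coordinate order.

GENE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
               "protein_id", "protein_length")

#' Construct a gene record
#'
#' A gene record is a single row of the feature table used throughout the
#' pipeline: a protein-coding gene with contig coordinates (internal 0-based
#' half-open), strand, and an optional link to its protein product.
#'
#' @param gene_id,contig_id Character identifiers.
#' @param start,end Integer nucleotide coordinates, 0-based half-open
#'   (`0 <= start < end`).
#' @param strand `"+"` or `"-"`.
#' @param protein_id Optional protein identifier (`NA` for none).
#' @param protein_length Protein length in amino acids; required (>= 1) when
#'   `protein_id` is given.
#' @return A one-row `data.frame` with the gene-table columns.
#' @export
gene_record <- function(gene_id, contig_id, start, end, strand,
                        protein_id = NA_character_,
                        protein_length = NA_integer_) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end)
    stop("gene '", gene_id, "': need 0 <= start < end, got [",
         start, ", ", end, ")")
  if (!strand %in% c("+", "-"))
    stop("gene '", gene_id, "': strand must be '+' or '-'")
  if (!is.na(protein_id)) {
    protein_length <- as.integer(protein_length)
    if (is.na(protein_length) || protein_length < 1L)
      stop("gene '", gene_id, "': protein_length >= 1 required when ",
           "protein_id is present")
  }
  data.frame(gene_id = as.character(gene_id),
             contig_id = as.character(contig_id),
             start = start, end = end, strand = strand,
             protein_id = as.character(protein_id),
             protein_length = as.integer(protein_length),
             stringsAsFactors = FALSE)
}

#' Construct a contig
#'
#' Bundles an ordered gene table with the contig length. Genes are sorted by
#' `start`; features outside `[0, length)` are rejected.
#'
#' @param contig_id Character identifier.
#' @param genes A gene table (rows as produced by [gene_record()]).
#' @param length Contig length in nucleotides.
#' @return An object of class `contig`: a list with elements `contig_id`,
#'   `genes` (sorted gene table) and `length`.
#' @export
contig <- function(contig_id, genes, length) {
  length <- as.integer(length)
  if (nrow(genes) > 0) {
    missing_cols <- setdiff(GENE_COLS, names(genes))
    if (base::length(missing_cols) > 0)
      stop("gene table lacks columns: ", paste(missing_cols, collapse = ", "))
    bad <- genes$start < 0L | genes$end > length
    if (any(bad))
      stop("contig '", contig_id, "': gene(s) out of bounds: ",
           paste(genes$gene_id[bad], collapse = ", "))
    genes <- genes[order(genes$start, genes$end, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(list(contig_id = as.character(contig_id), genes = genes,
                 length = length),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat("<contig> ", x$contig_id, ": ", nrow(x$genes), " genes, ",
      x$length, " nt\n", sep = "")
  invisible(x)
}

#' Convert internal to external (1-based inclusive) coordinates
#'
#' @param g A one-row gene table (or any list with `start`/`end`).
#' @return Integer vector `c(start_1based, end_inclusive)`.
#' @seealso [from_external_coords()] for the lossless inverse.
#' @export
to_external_coords <- function(g) {
  c(start_1based = as.integer(g$start) + 1L,
    end_inclusive = as.integer(g$end))
}

#' Convert external (1-based inclusive) to internal coordinates
#'
#' @param start_1based,end_inclusive GFF3-style coordinates.
#' @return Integer vector `c(start, end)` in the internal 0-based half-open
#'   convention.
#' @export
from_external_coords <- function(start_1based, end_inclusive) {
  c(start = as.integer(start_1based) - 1L, end = as.integer(end_inclusive))
}

#' Intergenic gap between two genes
#'
#' For genes A (the one further left) and B, the gap is `start(B) - end(A)`
#' in nucleotides, regardless of strand. Overlapping genes yield a gap <= 0,
#' so tightly linked genes with overlapping reading frames always satisfy any
#' non-negative distance threshold.
#'
#' @param a,b One-row gene tables on the same contig.
#' @return Integer gap in nt (possibly negative).
#' @export
intergenic_gap <- function(a, b) {
  if (a$contig_id != b$contig_id)
    stop("intergenic_gap: genes on different contigs")
  if (a$start <= b$start) as.integer(b$start) - as.integer(a$end)
  else as.integer(a$start) - as.integer(b$end)
}

#' Construct a genome bundle
#'
#' The unit of input for the pipeline: a set of contigs, the protein sequences
#' referenced by their genes, and (optionally) a precomputed domain-hit table.
#' Every `protein_id` used in a gene or hit must resolve into `proteins`.
#'
#' @param contigs List of [contig()] objects.
#' @param proteins Named character vector of amino-acid sequences.
#' @param hits Optional domain-hit table (see [read_domain_hits()]).
#' @return An object of class `genome_bundle`.
#' @export
genome_bundle <- function(contigs, proteins, hits = NULL) {
  pids <- unlist(lapply(contigs, function(ct) ct$genes$protein_id))
  pids <- pids[!is.na(pids)]
  unresolved <- setdiff(pids, names(proteins))
  if (length(unresolved) > 0)
    stop("gene protein_id(s) not in proteins: ",
         paste(utils::head(unresolved, 5), collapse = ", "))
  if (!is.null(hits) && nrow(hits) > 0) {
    bad <- setdiff(hits$protein_id, names(proteins))
    if (length(bad) > 0)
      stop("domain-hit protein_id(s) not in proteins: ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  structure(list(contigs = contigs, proteins = proteins, hits = hits),
            class = "genome_bundle")
}

#' @export
print.genome_bundle <- function(x, ...) {
  cat("<genome_bundle> ", length(x$contigs), " contig(s), ",
      length(x$proteins), " protein(s), ",
      if (is.null(x$hits)) "no" else nrow(x$hits), " domain hit(s)\n",
      sep = "")
  invisible(x)
}

#' Flatten the gene tables of a bundle into one data frame
#' @param bundle A [genome_bundle()].
#' @return A gene table with one row per gene, contigs in order.
#' @export
all_genes <- function(bundle) {
  do.call(rbind, lapply(bundle$contigs, function(ct) ct$genes))
}

# empty hit table with canonical columns
empty_hits <- function() {
  data.frame(protein_id = character(), domain_name = character(),
             start_aa = integer(), end_aa = integer(),
             evalue = numeric(), source = character(),
             stringsAsFactors = FALSE)
}

domain_hit <- function(protein_id, domain_name, start_aa, end_aa,
                       evalue = NA_real_, source = "profile") {
  if (any(start_aa < 0L) || any(start_aa >= end_aa))
    stop("domain hit: need 0 <= start_aa < end_aa")
  data.frame(protein_id = protein_id, domain_name = domain_name,
             start_aa = as.integer(start_aa), end_aa = as.integer(end_aa),
             evalue = as.numeric(evalue), source = source,
             stringsAsFactors = FALSE)
}
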