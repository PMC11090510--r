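# Readers and writers for the standard formats the pipeline touches.
# All readers reject rather than silently repair malformed records.

#' Read CDS features from a GFF3 file
#'
#' Parses `CDS` features (all other feature types are ignored: the census
#' operates on protein-coding genes) into contigs. Coordinates are converted
#' from the GFF3 1-based inclusive convention to the internal 0-based
#' half-open convention. Recognised attributes: `ID` (required),
#' `protein_id`, `protein_length`. Contig lengths come from
#' `##sequence-region` pragmas when present, otherwise from the rightmost
#' feature end.
#'
#' @param path Path to a GFF3 file.
#' @return A list of [contig()] objects, genes sorted by start.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  seqlen <- list()
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || grepl("^#", ln)) {
      if (grepl("^##sequence-region", ln)) {
        f <- strsplit(trimws(ln), "[ \t]+")[[1]]
        if (length(f) >= 4) seqlen[[f[2]]] <- as.integer(f[4])
      }
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != 9)
      stop("GFF3 parse error at line ", i, ": expected 9 tab-separated ",
           "columns, got ", length(f))
    if (f[3] != "CDS") next
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 < 1 || end1 < start1)
      stop("GFF3 parse error at line ", i, ": bad coordinates '",
           f[4], "', '", f[5], "'")
    if (!f[7] %in% c("+", "-"))
      stop("GFF3 parse error at line ", i, ": missing or invalid strand '",
           f[7], "'")
    attrs <- parse_gff3_attrs(f[9], i)
    if (is.null(attrs$ID))
      stop("GFF3 parse error at line ", i, ": CDS without ID attribute")
    ic <- from_external_coords(start1, end1)
    rows[[length(rows) + 1L]] <- gene_record(
      gene_id = attrs$ID, contig_id = f[1],
      start = ic[["start"]], end = ic[["end"]], strand = f[7],
      protein_id = if (is.null(attrs$protein_id)) NA_character_
                   else attrs$protein_id,
      protein_length = if (is.null(attrs$protein_length)) NA_integer_
                       else as.integer(attrs$protein_length))
  }
  genes <- if (length(rows) > 0) do.call(rbind, rows) else
    gene_record("x", "x", 0, 1, "+")[0, ]
  ids <- unique(c(names(seqlen), genes$contig_id))
  lapply(ids, function(cid) {
    g <- genes[genes$contig_id == cid, , drop = FALSE]
    len <- if (!is.null(seqlen[[cid]])) seqlen[[cid]] else
      if (nrow(g) > 0) max(g$end) else 0L
    contig(cid, g, len)
  })
}

parse_gff3_attrs <- function(s, line) {
  out <- list()
  for (kv in strsplit(s, ";", fixed = TRUE)[[1]]) {
    if (kv == "") next
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0)
      stop("GFF3 parse error at line ", line, ": malformed attribute '",
           kv, "'")
    out[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  out
}

#' Write contigs as GFF3
#'
#' Inverse of [read_gff3()]: emits one `##sequence-region` pragma per contig
#' and one CDS line per gene, attributes in the fixed order
#' `ID;protein_id;protein_length`, so that read/write round-trips are
#' field-for-field lossless for the stored fields.
#'
#' @param contigs List of [contig()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(contigs, path) {
  out <- c("##gff-version 3")
  for (ct in contigs) {
    out <- c(out, paste("##sequence-region", ct$contig_id, 1L, ct$length))
    if (nrow(ct$genes) == 0) next
    g <- ct$genes
    attrs <- paste0("ID=", g$gene_id,
                    ifelse(is.na(g$protein_id), "",
                           paste0(";protein_id=", g$protein_id)),
                    ifelse(is.na(g$protein_length), "",
                           paste0(";protein_length=", g$protein_length)))
    out <- c(out, paste(g$contig_id, "coconutscan", "CDS",
                        g$start + 1L, g$end, ".", g$strand, "0", attrs,
                        sep = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the protein ID.
#' Sequences are uppercased; duplicate IDs and empty sequences are rejected.
#'
#' @param path Path to an amino-acid FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("[ \t].*$", "", names(aas))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ID(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(aas))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0))
    stop("empty FASTA sequence for: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a precomputed domain-hit table
#'
#' Tab-separated columns `protein_id`, `domain_name`, `start_1based`,
#' `end_inclusive`, `evalue`, `source`. Hits with an E-value above the
#' threshold (default 0.001, the profile-search cutoff applied at read time)
#' are dropped; hits without an E-value (`NA`, e.g. motif hits) are kept.
#' Coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path Path to the TSV file (a header line is required).
#' @param evalue_max E-value retention threshold.
#' @return Domain-hit `data.frame` with columns `protein_id`, `domain_name`,
#'   `start_aa`, `end_aa`, `evalue`, `source`.
#' @export
read_domain_hits <- function(path, evalue_max = 0.001) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(empty_hits())
  need <- c("protein_id", "domain_name", "start_1based", "end_inclusive")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0)
    stop("domain-hit table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  if (is.null(d$evalue)) d$evalue <- NA_real_
  if (is.null(d$source)) d$source <- "profile"
  if (any(d$start_1based < 1 | d$end_inclusive < d$start_1based))
    stop("domain-hit table: negative or inverted coordinates")
  keep <- is.na(d$evalue) | d$evalue <= evalue_max
  d <- d[keep, , drop = FALSE]
  domain_hit(d$protein_id, d$domain_name,
             start_aa = d$start_1based - 1L, end_aa = d$end_inclusive,
             evalue = d$evalue, source = d$source)
}

#' Write a domain-hit table
#' @param hits Domain-hit data frame (internal coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_hits <- function(hits, path) {
  out <- data.frame(protein_id = hits$protein_id,
                    domain_name = hits$domain_name,
                    start_1based = hits$start_aa + 1L,
                    end_inclusive = hits$end_aa,
                    evalue = hits$evalue, source = hits$source,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialise a tree as a Newick string
#'
#' @param tree An `ape` `phylo` object.
#' @return A single Newick string with branch lengths, terminated by `";"`.
#' @export
write_newick <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("write_newick: not a phylo object")
  n_tip <- length(tree$tip.label)
  # a tree with n tips and m internal nodes has n + m - 1 edges; anything
  # else (e.g. a cyclic edge table) is rejected
  if (nrow(tree$edge) != n_tip + tree$Nnode - 1L)
    stop("write_newick: edge table is not a tree")
  ape::write.tree(tree)
}

#' Parse a Newick string
#' @param s Newick string.
#' @return An `ape` `phylo` object.
#' @export
read_newick <- function(s) {
  ape::read.tree(text = s)
}

#' Write the census/classification report
#'
#' Emits a TSV with one row per classified locus and a JSON report holding
#' the per-tier census funnel, the fully resolved configuration and the
#' package version, so every report is self-describing.
#'
#' @param calls Data frame of classified loci (may have zero rows).
#' @param funnel Named list or vector of per-tier census counts.
#' @param dir Output directory (created if needed).
#' @param config Resolved pipeline configuration to embed.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report <- function(calls, funnel, dir, config = default_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "calls.tsv")
  json <- file.path(dir, "report.json")
  utils::write.table(calls, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(
    funnel = as.list(funnel),
    n_calls = nrow(calls),
    config = config,
    version = as.character(utils::packageVersion("coconutscan")))
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(tsv, json))
}
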