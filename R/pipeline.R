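# Configuration and the end-to-end driver:
# (simulate) -> annotate -> census -> cluster -> classify -> report.

#' Default pipeline configuration
#'
#' Every threshold used by the pipeline, overridable per call:
#' 10-gene neighborhood flanks; 90 nt adjacency gap; size gates > 200 aa
#' (McrB) and > 150 aa (McrC); E-value 0.001 for domain hits; clustering at
#' identity 0.5 with profile merging at score ratio > 0.1 for 3 iterations;
#' representatives at identity 0.9; 200 nt superoperon gap; 28-residue
#' coiled-coil window at threshold 0.5; 60-aa signature-motif window with a
#' 200-aa extended scan and an 80-aa helical-insert gate.
#'
#' @param ... Named overrides of individual keys; unknown keys are an
#'   error (listing the valid keys).
#' @return Named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    flank_genes = 10L,
    gap_nt = 90L,
    min_mcrB_aa = 200L,
    min_mcrC_aa = 150L,
    evalue = 0.001,
    cluster_threshold = 0.5,
    representative_threshold = 0.9,
    ratio_threshold = 0.1,
    ratio_denominator = "max",
    iterations = 3L,
    superoperon_gap_nt = 200L,
    coiled_coil_window = 28L,
    coiled_coil_threshold = 0.5,
    signature_window = 60L,
    insert_scan_window = 200L,
    helical_insert_min_aa = 80L,
    max_intervening = 2L,
    midas_t_window = c(20L, 80L),
    midas_d_window = c(10L, 60L),
    seed = 1L)
  over <- list(...)
  if (length(over) > 0) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "; valid keys: ", paste(names(cfg), collapse = ", "))
    cfg[names(over)] <- over
  }
  cfg
}

#' Evaluate pipeline calls against a planted truth table
#'
#' Matches calls to planted loci by the McrB gene ID (falling back to the
#' McrC gene for orphan architectures).
#'
#' @param calls Call table from [run_all()] (needs `mcrB_gene`,
#'   `mcrC_gene`, `label`).
#' @param truth Truth list from [generate_genome()].
#' @return List with `recall`, `precision`, `subtype_accuracy` (label
#'   agreement among matched loci), `n_planted`, `n_called`.
#' @export
evaluate_against_truth <- function(calls, truth) {
  planted <- truth$loci
  key <- function(df) ifelse(is.na(df$mcrB_gene), df$mcrC_gene,
                             df$mcrB_gene)
  pk <- key(planted); ck <- key(calls)
  matched <- intersect(pk, ck)
  recall <- if (nrow(planted) == 0) NA_real_ else
    length(matched) / nrow(planted)
  precision <- if (nrow(calls) == 0) NA_real_ else
    sum(ck %in% pk) / nrow(calls)
  acc <- if (length(matched) == 0) NA_real_ else
    mean(planted$label[match(matched, pk)] ==
           calls$label[match(matched, ck)])
  list(recall = recall, precision = precision, subtype_accuracy = acc,
       n_planted = nrow(planted), n_called = nrow(calls))
}

#' Run the full pipeline
#'
#' Composition of the stages: (optionally) simulate a genome, annotate all
#' proteins, run the neighborhood census, classify every validated system,
#' cluster the detected McrB proteins and build a representative NJ tree.
#' Deterministic for a fixed configuration and inputs.
#'
#' @param config Pipeline configuration ([default_config()]).
#' @param bundle A [genome_bundle()] (ignored when `simulate = TRUE`).
#' @param adapter Profile-search adapter, or `NULL` to rely on
#'   `bundle$hits`.
#' @param simulate Generate the input with [generate_genome()].
#' @param sim A [sim_config()] (defaults to `sim_config(seed =
#'   config$seed)`).
#' @return List of class `coconut_report`: `calls` (one row per system
#'   with label, tier, signature, roles, ancillary flags), `funnel`,
#'   `clusters` (summary list), `representatives`, `newick` (or `NA`),
#'   `config`, `version`, and, when simulated, `truth` and `evaluation`.
#' @export
run_all <- function(config = default_config(), bundle = NULL,
                    adapter = NULL, simulate = FALSE, sim = NULL) {
  truth <- NULL
  if (simulate) {
    if (is.null(sim)) sim <- sim_config(seed = config$seed)
    gen <- generate_genome(sim)
    bundle <- gen$bundle
    truth <- gen$truth
    adapter <- mock_profile_adapter(truth$tags, names(bundle$proteins),
                                    fp_rate = sim$fp_rate,
                                    fp_seed = sim$seed)
  }
  if (is.null(bundle)) stop("run_all: no input bundle (or --simulate)")
  alias <- alias_tables()
  ann <- annotate_proteins(bundle, adapter, alias, config)
  census <- run_census(bundle, ann, alias, config)
  sys <- census$systems

  calls <- list()
  contig_of <- stats::setNames(bundle$contigs,
                               vapply(bundle$contigs, `[[`, character(1),
                                      "contig_id"))
  for (r in seq_len(nrow(sys))) {
    ct <- contig_of[[sys$contig_id[r]]]
    anchor <- if (!is.na(sys$mcrB_gene[r])) sys$mcrB_gene[r] else
      sys$mcrC_gene[r]
    n <- extract_neighborhood(ct, anchor, config$flank_genes)
    cl <- classify_locus(sys[r, ], ann, n, ct, config)
    calls[[r]] <- data.frame(
      locus_id = sys$locus_id[r], contig_id = sys$contig_id[r],
      label = cl$label, tier = sys$tier[r], signature = cl$signature,
      mcrB_gene = sys$mcrB_gene[r], mcrC_gene = sys$mcrC_gene[r],
      order_reversed = sys$order_reversed[r], fused = sys$fused[r],
      tery_p = cl$tery_p, extended_IIIA = cl$extended_IIIA,
      carf_superoperon = !is.null(cl$carf_association),
      embedded_systems = if (is.null(cl$carf_association)) "" else
        paste(cl$carf_association$embedded_systems, collapse = ","),
      roles = paste(cl$components$role, "=", cl$components$gene_id,
                    sep = "", collapse = ";"),
      stringsAsFactors = FALSE)
  }
  calls <- if (length(calls) > 0) do.call(rbind, calls) else
    data.frame(locus_id = character(), contig_id = character(),
               label = character(), tier = character(),
               signature = character(), mcrB_gene = character(),
               mcrC_gene = character(), order_reversed = logical(),
               fused = logical(), tery_p = logical(),
               extended_IIIA = character(), carf_superoperon = logical(),
               embedded_systems = character(), roles = character(),
               stringsAsFactors = FALSE)

  # cluster the detected McrB proteins and build the representative tree
  bpids <- unique(stats::na.omit(sys$mcrB_protein))
  seqs <- bundle$proteins[bpids]
  clusters <- list(); reps <- character(0); newick <- NA_character_
  if (length(seqs) >= 2) {
    clusters <- iterate_clustering(seqs, config)
    reps <- select_representatives(seqs, config$representative_threshold)
    if (length(reps) >= 2)
      newick <- write_newick(nj_tree(seqs[reps]))
  } else if (length(seqs) == 1) {
    reps <- names(seqs)
  }

  report <- list(
    calls = calls, funnel = census$funnel,
    clusters = list(n_clusters = length(clusters),
                    rounds = attr(clusters, "rounds") %||% 0L,
                    sizes = vapply(clusters, function(cl)
                      length(cl$members), integer(1))),
    representatives = reps, newick = newick,
    config = config,
    version = as.character(utils::packageVersion("coconutscan")))
  if (!is.null(truth)) {
    report$truth <- truth
    report$evaluation <- evaluate_against_truth(calls, truth)
  }
  class(report) <- "coconut_report"
  report
}

#' @export
print.coconut_report <- function(x, ...) {
  cat("<coconut_report> ", nrow(x$calls), " system(s)\n", sep = "")
  cat("  funnel:", paste(names(x$funnel), x$funnel, sep = "=",
                         collapse = " "), "\n")
  if (nrow(x$calls) > 0) {
    tab <- table(x$calls$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n")
  }
  if (!is.null(x$evaluation))
    cat(sprintf("  vs truth: recall %.2f, precision %.2f, subtype accuracy %.2f\n",
                x$evaluation$recall, x$evaluation$precision,
                x$evaluation$subtype_accuracy))
  invisible(x)
}
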