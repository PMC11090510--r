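# Neighborhood extraction, the three-tier filtering logic, and McrB-McrC
# pairing/validation.
#
# A neighborhood is the anchor gene plus up to 10 genes on each side in
# contig order; filter tiers partition neighborhoods:
#   strict  - a COG1401 hit, or an McrB alias plus an McrC alias;
#   relaxed - one alias class only, rescued by an adjacent (<= 90 nt),
#             co-oriented gene large enough to be the missing component
#             (> 200 aa for McrB, > 150 aa for McrC, strict inequalities);
#   rescue  - no aliases at all, but a raw homology-search anchor in
#             operonic association (same strand, gaps <= 90 nt, chained
#             transitively) with a sufficiently large partner.

# domain names marking a raw homology-search hit (rescue-tier anchors)
RAW_SEARCH_TAG <- "McrB_search_hit"

#' Extract the genomic neighborhood of an anchor gene
#'
#' @param ct A [contig()].
#' @param anchor_gene_id Gene ID of the anchor (must be on the contig).
#' @param k Flank size: up to `k` genes on each side (default 10).
#' @return List of class `neighborhood` with `anchor` (one-row gene table),
#'   `genes` (gene table including the anchor, contig order) and
#'   `contig_id`.
#' @export
extract_neighborhood <- function(ct, anchor_gene_id, k = 10L) {
  idx <- which(ct$genes$gene_id == anchor_gene_id)
  if (length(idx) != 1)
    stop("anchor '", anchor_gene_id, "' not found on contig '",
         ct$contig_id, "'")
  lo <- max(1L, idx - k); hi <- min(nrow(ct$genes), idx + k)
  structure(list(anchor = ct$genes[idx, , drop = FALSE],
                 genes = ct$genes[lo:hi, , drop = FALSE],
                 contig_id = ct$contig_id),
            class = "neighborhood")
}

#' @export
print.neighborhood <- function(x, ...) {
  cat("<neighborhood> anchor ", x$anchor$gene_id, ", ",
      nrow(x$genes), " genes on ", x$contig_id, "\n", sep = "")
  invisible(x)
}

hits_by_protein <- function(hits) split(hits$domain_name, hits$protein_id)

gene_domains <- function(n, hitidx) {
  lapply(seq_len(nrow(n$genes)), function(i) {
    pid <- n$genes$protein_id[i]
    if (is.na(pid)) character(0) else hitidx[[pid]] %||% character(0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Strict neighborhood filter
#'
#' Passes when any gene has a COG1401 (McrB GTPase) hit, or some gene has
#' an McrB-alias hit and some (possibly different) gene has an McrC-alias
#' hit.
#'
#' @param n A [extract_neighborhood()] result.
#' @param hits Domain-hit table.
#' @param alias [alias_tables()].
#' @return List with `pass` (logical) and `reason`.
#' @export
strict_filter <- function(n, hits, alias = alias_tables()) {
  doms <- gene_domains(n, hits_by_protein(hits))
  has_primary <- any(vapply(doms, function(d)
    any(d %in% alias$primary_mcrB), logical(1)))
  has_b <- any(vapply(doms, function(d) any(d %in% alias$mcrB), logical(1)))
  has_c <- any(vapply(doms, function(d) any(d %in% alias$mcrC), logical(1)))
  if (has_primary) list(pass = TRUE, reason = "COG1401 hit")
  else if (has_b && has_c) list(pass = TRUE, reason = "McrB and McrC aliases")
  else list(pass = FALSE,
            reason = if (has_b) "McrB alias only"
                     else if (has_c) "McrC alias only" else "no aliases")
}

# nearest gene on either side of index i (by intergenic gap)
adjacent_candidates <- function(n, i) {
  cand <- c(if (i > 1L) i - 1L, if (i < nrow(n$genes)) i + 1L)
  if (length(cand) == 0) return(integer(0))
  gaps <- vapply(cand, function(j)
    intergenic_gap(n$genes[i, ], n$genes[j, ]), integer(1))
  cand[order(gaps, -cand)]   # smaller gap first; tie -> downstream gene
}

#' Relaxed neighborhood filter (one alias class)
#'
#' Applies to neighborhoods with hits to exactly one alias class. Passes
#' when a gene adjacent to the alias-hit gene (the nearest gene on either
#' side) lies within 90 nt, is oriented in the same direction, and encodes
#' a protein large enough to be the missing component: strictly > 200 aa
#' when the missing component is McrB, strictly > 150 aa when it is McrC.
#'
#' @inheritParams strict_filter
#' @param config Pipeline configuration (`gap_nt`, `min_mcrB_aa`,
#'   `min_mcrC_aa`).
#' @return List with `pass`, `hit_gene`, `partner` (one-row gene tables or
#'   `NULL`), `missing` (`"McrB"`/`"McrC"`) and `reason`.
#' @export
relaxed_filter <- function(n, hits, alias = alias_tables(),
                           config = default_config()) {
  doms <- gene_domains(n, hits_by_protein(hits))
  is_b <- vapply(doms, function(d)
    any(d %in% c(alias$mcrB, alias$primary_mcrB)), logical(1))
  is_c <- vapply(doms, function(d) any(d %in% alias$mcrC), logical(1))
  fail <- function(reason) list(pass = FALSE, hit_gene = NULL,
                                partner = NULL, missing = NA_character_,
                                reason = reason)
  if (any(is_b) == any(is_c))
    return(fail("not exactly one alias class"))
  i <- which(if (any(is_b)) is_b else is_c)[1]
  missing <- if (any(is_b)) "McrC" else "McrB"
  min_aa <- if (missing == "McrB") config$min_mcrB_aa else config$min_mcrC_aa
  for (j in adjacent_candidates(n, i)) {
    gap <- intergenic_gap(n$genes[i, ], n$genes[j, ])
    if (gap > config$gap_nt) next
    if (n$genes$strand[j] != n$genes$strand[i]) next
    plen <- n$genes$protein_length[j]
    if (is.na(plen) || plen <= min_aa) next
    return(list(pass = TRUE, hit_gene = n$genes[i, , drop = FALSE],
                partner = n$genes[j, , drop = FALSE], missing = missing,
                reason = sprintf("partner %s (%d aa, gap %d nt)",
                                 n$genes$gene_id[j], plen, gap)))
  }
  fail("no qualifying adjacent gene")
}

# transitive operonic chain from gene index i: same strand, successive
# gaps <= gap_nt, extended in both directions
operonic_chain <- function(n, i, gap_nt) {
  s <- n$genes$strand[i]
  members <- i
  j <- i
  while (j > 1L && n$genes$strand[j - 1L] == s &&
         intergenic_gap(n$genes[j - 1L, ], n$genes[j, ]) <= gap_nt) {
    j <- j - 1L; members <- c(j, members)
  }
  j <- i
  while (j < nrow(n$genes) && n$genes$strand[j + 1L] == s &&
         intergenic_gap(n$genes[j, ], n$genes[j + 1L, ]) <= gap_nt) {
    j <- j + 1L; members <- c(members, j)
  }
  members
}

#' Rescue filter (no aliases, raw search anchor)
#'
#' Applies to neighborhoods with no alias hits whose anchor is a raw
#' homology-search hit. Passes when a gene in operonic association with the
#' anchor (same strand, successive gaps within the 90 nt rule, chained
#' transitively) is large enough to be the missing McrBC component.
#'
#' @inheritParams relaxed_filter
#' @param anchor_class Assumed class of the raw search hit (`"McrB"`
#'   default, so the partner must exceed the McrC size gate).
#' @return List with `pass`, `partner`, `missing`, `reason`.
#' @export
rescue_filter <- function(n, hits, config = default_config(),
                          anchor_class = "McrB") {
  i <- which(n$genes$gene_id == n$anchor$gene_id)
  missing <- if (anchor_class == "McrB") "McrC" else "McrB"
  min_aa <- if (missing == "McrB") config$min_mcrB_aa else config$min_mcrC_aa
  chain <- setdiff(operonic_chain(n, i, config$gap_nt), i)
  for (j in chain) {
    plen <- n$genes$protein_length[j]
    if (!is.na(plen) && plen > min_aa)
      return(list(pass = TRUE, partner = n$genes[j, , drop = FALSE],
                  missing = missing,
                  reason = sprintf("operonic partner %s (%d aa)",
                                   n$genes$gene_id[j], plen)))
  }
  list(pass = FALSE, partner = NULL, missing = missing,
       reason = "no operonic partner of sufficient size")
}

count_intervening <- function(n, gi, gj) {
  ii <- which(n$genes$gene_id == gi); jj <- which(n$genes$gene_id == gj)
  abs(jj - ii) - 1L
}

#' Pair McrB-class with McrC-class genes in a neighborhood
#'
#' Greedy nearest-neighbor pairing: candidate McrB/McrC pairs are ranked by
#' the number of intervening genes (at most `max_intervening`, default 2),
#' then genomic distance; each gene is used at most once; unpaired
#' components are emitted as orphans. A gene carrying both alias classes
#' (rare gene fusion) is emitted as a single-gene fused system. The operon
#' order is recorded as reversed when McrC precedes McrB in the
#' transcription direction of the McrB gene.
#'
#' @inheritParams relaxed_filter
#' @param tier Validation tier label to stamp on the systems.
#' @return Data frame of candidate systems: `mcrB_gene`, `mcrC_gene`
#'   (gene IDs, `NA` for orphans), `intervening_gene_count`,
#'   `order_reversed`, `fused`, `tier`.
#' @export
pair_mcrbc <- function(n, hits, alias = alias_tables(),
                       config = default_config(), tier = "strict") {
  doms <- gene_domains(n, hits_by_protein(hits))
  is_b <- vapply(doms, function(d)
    any(d %in% c(alias$mcrB, alias$primary_mcrB)), logical(1))
  is_c <- vapply(doms, function(d) any(d %in% alias$mcrC), logical(1))
  fused <- is_b & is_c
  is_b <- is_b & !fused; is_c <- is_c & !fused
  sys <- list()
  add <- function(b, c, intervening, reversed, fus) {
    sys[[length(sys) + 1L]] <<- data.frame(
      mcrB_gene = b, mcrC_gene = c,
      intervening_gene_count = intervening,
      order_reversed = reversed, fused = fus, tier = tier,
      stringsAsFactors = FALSE)
  }
  for (i in which(fused))
    add(n$genes$gene_id[i], n$genes$gene_id[i], 0L, FALSE, TRUE)
  bi <- which(is_b); ci <- which(is_c)
  if (length(bi) > 0 && length(ci) > 0) {
    pairs <- expand.grid(b = bi, c = ci)
    pairs$intervening <- abs(pairs$b - pairs$c) - 1L
    pairs$dist <- vapply(seq_len(nrow(pairs)), function(r)
      abs(intergenic_gap(n$genes[pairs$b[r], ], n$genes[pairs$c[r], ])),
      integer(1))
    pairs <- pairs[pairs$intervening <= config$max_intervening, ,
                   drop = FALSE]
    pairs <- pairs[order(pairs$intervening, pairs$dist, pairs$b), ,
                   drop = FALSE]
    used_b <- integer(0); used_c <- integer(0)
    for (r in seq_len(nrow(pairs))) {
      b <- pairs$b[r]; c <- pairs$c[r]
      if (b %in% used_b || c %in% used_c) next
      used_b <- c(used_b, b); used_c <- c(used_c, c)
      bstrand <- n$genes$strand[b]
      reversed <- if (bstrand == "+") n$genes$start[c] < n$genes$start[b]
                  else n$genes$start[c] > n$genes$start[b]
      add(n$genes$gene_id[b], n$genes$gene_id[c], pairs$intervening[r],
          reversed, FALSE)
    }
    bi <- setdiff(bi, used_b); ci <- setdiff(ci, used_c)
  }
  for (i in bi) add(n$genes$gene_id[i], NA_character_, 0L, FALSE, FALSE)
  for (i in ci) add(NA_character_, n$genes$gene_id[i], 0L, FALSE, FALSE)
  if (length(sys) == 0)
    return(data.frame(mcrB_gene = character(), mcrC_gene = character(),
                      intervening_gene_count = integer(),
                      order_reversed = logical(), fused = logical(),
                      tier = character(), stringsAsFactors = FALSE))
  do.call(rbind, sys)
}

#' Run the full neighborhood census
#'
#' Identifies anchors (genes with a COG1401, alias, or raw search hit),
#' extracts their neighborhoods, applies the strict / relaxed / rescue
#' filter cascade (each neighborhood receives exactly one outcome), pairs
#' McrB with McrC genes, scans the GTPase signature motif of each system,
#' and tallies the census funnel. Anchors falling inside an already
#' validated island are not re-counted.
#'
#' @param bundle A [genome_bundle()].
#' @param hits Annotated domain-hit table (see [annotate_proteins()]).
#' @param alias [alias_tables()].
#' @param config Pipeline configuration.
#' @return List with `systems` (data frame: locus_id, contig_id, tier,
#'   mcrB/mcrC gene and protein IDs, intervening_gene_count,
#'   order_reversed, fused, signature) and `funnel` (named integer vector:
#'   input, strict_pass, relaxed_pass, rescued_pass, rejected, paired,
#'   orphan).
#' @export
run_census <- function(bundle, hits, alias = alias_tables(),
                       config = default_config()) {
  funnel <- c(input = 0L, strict_pass = 0L, relaxed_pass = 0L,
              rescued_pass = 0L, rejected = 0L, paired = 0L, orphan = 0L)
  systems <- list()
  hitidx <- hits_by_protein(hits)
  anchor_doms <- c(alias$primary_mcrB, alias$mcrB, alias$mcrC,
                   RAW_SEARCH_TAG)
  for (ct in bundle$contigs) {
    if (nrow(ct$genes) == 0) next
    consumed <- character(0)
    anchors <- ct$genes$gene_id[vapply(seq_len(nrow(ct$genes)), function(i) {
      pid <- ct$genes$protein_id[i]
      !is.na(pid) && any((hitidx[[pid]] %||% character(0)) %in% anchor_doms)
    }, logical(1))]
    for (a in anchors) {
      if (a %in% consumed) next
      n <- extract_neighborhood(ct, a, config$flank_genes)
      funnel[["input"]] <- funnel[["input"]] + 1L
      sf <- strict_filter(n, hits, alias)
      island_sys <- NULL
      if (sf$pass) {
        funnel[["strict_pass"]] <- funnel[["strict_pass"]] + 1L
        island_sys <- pair_mcrbc(n, hits, alias, config, tier = "strict")
      } else if (sf$reason %in% c("McrB alias only", "McrC alias only")) {
        rf <- relaxed_filter(n, hits, alias, config)
        if (rf$pass) {
          funnel[["relaxed_pass"]] <- funnel[["relaxed_pass"]] + 1L
          b <- if (rf$missing == "McrC") rf$hit_gene else rf$partner
          cc <- if (rf$missing == "McrC") rf$partner else rf$hit_gene
          reversed <- if (b$strand == "+") cc$start < b$start
                      else cc$start > b$start
          island_sys <- data.frame(
            mcrB_gene = b$gene_id, mcrC_gene = cc$gene_id,
            intervening_gene_count = count_intervening(n, b$gene_id,
                                                       cc$gene_id),
            order_reversed = reversed, fused = FALSE,
            tier = "relaxed_one_alias", stringsAsFactors = FALSE)
        } else funnel[["rejected"]] <- funnel[["rejected"]] + 1L
      } else {
        pid <- n$anchor$protein_id
        raw <- !is.na(pid) &&
          RAW_SEARCH_TAG %in% (hitidx[[pid]] %||% character(0))
        xf <- if (raw) rescue_filter(n, hits, config) else NULL
        if (!is.null(xf) && xf$pass) {
          funnel[["rescued_pass"]] <- funnel[["rescued_pass"]] + 1L
          b <- n$anchor; cc <- xf$partner
          reversed <- if (b$strand == "+") cc$start < b$start
                      else cc$start > b$start
          island_sys <- data.frame(
            mcrB_gene = b$gene_id, mcrC_gene = cc$gene_id,
            intervening_gene_count = count_intervening(n, b$gene_id,
                                                       cc$gene_id),
            order_reversed = reversed, fused = FALSE,
            tier = "rescued_no_alias", stringsAsFactors = FALSE)
        } else funnel[["rejected"]] <- funnel[["rejected"]] + 1L
      }
      if (!is.null(island_sys) && nrow(island_sys) > 0) {
        island_sys$contig_id <- ct$contig_id
        systems[[length(systems) + 1L]] <- island_sys
        consumed <- c(consumed,
                      stats::na.omit(c(island_sys$mcrB_gene,
                                       island_sys$mcrC_gene)),
                      n$genes$gene_id)
      }
    }
  }
  sys_df <- if (length(systems) > 0) do.call(rbind, systems) else
    data.frame(mcrB_gene = character(), mcrC_gene = character(),
               intervening_gene_count = integer(),
               order_reversed = logical(), fused = logical(),
               tier = character(), contig_id = character(),
               stringsAsFactors = FALSE)
  # signature motif of each system's McrB gene
  gene_lookup <- all_genes(bundle)
  sig <- character(nrow(sys_df))
  bpid <- character(nrow(sys_df))
  cpid <- character(nrow(sys_df))
  for (r in seq_len(nrow(sys_df))) {
    bpid[r] <- if (!is.na(sys_df$mcrB_gene[r]))
      gene_lookup$protein_id[match(sys_df$mcrB_gene[r],
                                   gene_lookup$gene_id)] else NA_character_
    cpid[r] <- if (!is.na(sys_df$mcrC_gene[r]))
      gene_lookup$protein_id[match(sys_df$mcrC_gene[r],
                                   gene_lookup$gene_id)] else NA_character_
    sig[r] <- "none"
    if (!is.na(bpid[r])) {
      d <- hits[hits$protein_id == bpid[r] &
                hits$domain_name %in% c("NxD", "NxxD", "NxxxD"), ,
                drop = FALSE]
      if (nrow(d) > 0) {
        sig[r] <- d$domain_name[1]
      } else {
        s <- scan_signature_motif(bundle$proteins[[bpid[r]]],
                                  window = config$insert_scan_window)
        sig[r] <- s$variant
      }
    }
  }
  sys_df$mcrB_protein <- bpid
  sys_df$mcrC_protein <- cpid
  sys_df$signature <- sig
  sys_df$locus_id <- if (nrow(sys_df) > 0)
    sprintf("locus_%03d", seq_len(nrow(sys_df))) else character(0)
  funnel[["paired"]] <- sum(!is.na(sys_df$mcrB_gene) &
                            !is.na(sys_df$mcrC_gene))
  funnel[["orphan"]] <- sum(is.na(sys_df$mcrB_gene) |
                            is.na(sys_df$mcrC_gene))
  rownames(sys_df) <- NULL
  list(systems = sys_df, funnel = funnel)
}
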