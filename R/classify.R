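# The CoCoNuT typing grammar: assign each validated McrBC system a
# type/subtype label, name the component roles (CnuA-CnuH), and detect
# ancillary modules (TerY-P, extended Type III-A inserts, CARF/RtcR
# superoperons).
#
# Classification is rule-based on domain architecture plus the GTPase
# signature motif: the NxD gate plus the Type I-A helical-insert rule stand
# in for the phylogenetic dimension (placement by tree is an adapter
# concern, not part of this grammar).

#' The CoCoNuT label set
#'
#' Three types, seven subtypes, plus Pseudo-I-B and the two non-CoCoNuT
#' outcomes.
#' @return Character vector of valid locus labels.
#' @export
coconut_labels <- function() {
  c("I-A", "I-B", "Pseudo-I-B", "I-C", "II", "III-A", "III-B", "III-C",
    "non_CoCoNuT_McrBC", "unclassified")
}

# canonical tag vocabulary used by the grammar (adapter/fixture hit names)
TAG_HELICASE <- "SF1_helicase"
TAG_WHTH <- "wHTH"
TAG_CARF <- "CARF_RtcR"
EMBEDDED_SYSTEM_TAGS <- c(HsdR = "TypeI_RM", HsdM = "TypeI_RM",
                          HsdS = "TypeI_RM", Druantia_III = "Druantia_III",
                          BREX = "BREX", ShdA = "Shield_ShdA",
                          BrnT = "BrnT_like")

island_domains <- function(neighborhood, hits) {
  idx <- hits_by_protein(hits)
  stats::setNames(gene_domains(neighborhood, idx),
                  neighborhood$genes$gene_id)
}

protein_domains <- function(hits, pid) {
  if (is.na(pid)) character(0) else
    hits$domain_name[hits$protein_id == pid]
}

# locate island genes by the domains on their proteins
genes_with <- function(neighborhood, doms_by_gene, what, all_of = FALSE) {
  keep <- vapply(doms_by_gene, function(d)
    if (all_of) all(what %in% d) else any(what %in% d), logical(1))
  neighborhood$genes$gene_id[keep[neighborhood$genes$gene_id]]
}

#' Classify a validated McrBC system
#'
#' Applies the CoCoNuT decision grammar (first matching rule wins):
#' the NxD signature gates membership; then III-B (Vsr-like nuclease fused
#' to the CnuH helicase, no separate CnuE), III-C (CnuE with two PLD
#' domains), III-A (CnuE with two HEPN domains and/or CnuC fused to an
#' Hsp70-like unit), II (CnuE with one HEPN, CnuH present), I-A (helical
#' insert in the CnuB GTPase between Walker B and NxD), I-B (separate CnuA
#' with PYD and REC), Pseudo-I-B (I-B-like CnuB with no CnuA anywhere in
#' the island), I-C (CnuB with CSD and fused coiled-coil), else
#' unclassified. TerY-P and the CARF/RtcR superoperon are only recorded for
#' Type II / III-A (they are never part of III-B or III-C); extended III-A
#' variants are sought only for III-A calls.
#'
#' @param system One row of the census `systems` table.
#' @param hits Annotated domain-hit table.
#' @param neighborhood The system's [extract_neighborhood()] island.
#' @param ct The [contig()] carrying the locus (for superoperon walking;
#'   optional, defaults to the neighborhood genes).
#' @param config Pipeline configuration.
#' @return List of class `coconut_call`: `locus_id`, `label`, `components`
#'   (data frame gene_id/role/evidence), `tery_p`, `carf_association`
#'   (list or `NULL`), `extended_IIIA`, `signature`, `diagnostics`.
#' @export
classify_locus <- function(system, hits, neighborhood, ct = NULL,
                           config = default_config()) {
  doms <- island_domains(neighborhood, hits)
  bpid <- system$mcrB_protein
  cpid <- system$mcrC_protein
  bdoms <- protein_domains(hits, bpid)
  cdoms <- protein_domains(hits, cpid)
  sig <- system$signature

  helicase_genes <- genes_with(neighborhood, doms, TAG_HELICASE)
  cnuE_genes <- setdiff(genes_with(neighborhood, doms, TAG_WHTH),
                        helicase_genes)
  cnuH <- if (length(helicase_genes) > 0) helicase_genes[1] else NULL
  cnuE <- if (length(cnuE_genes) > 0) cnuE_genes[1] else NULL
  cnuH_doms <- if (is.null(cnuH)) character(0) else doms[[cnuH]]
  cnuE_doms <- if (is.null(cnuE)) character(0) else doms[[cnuE]]
  n_hepn_E <- sum(cnuE_doms == "HEPN")
  n_pld_E <- sum(cnuE_doms == "PLD")
  # CnuA: separate coiled-coil protein, not one of the named components
  core_ids <- stats::na.omit(c(system$mcrB_gene, system$mcrC_gene,
                               cnuH, cnuE))
  cc_genes <- genes_with(neighborhood, doms, "CC")
  cnuA_candidates <- setdiff(cc_genes, core_ids)
  # CnuA is a separate coiled-coil protein: either coiled-coil only
  # (Type III-B) or the PYD + coiled-coil + REC architecture (Type I-B);
  # any other domain content rules a gene out
  cnuA_candidates <- cnuA_candidates[vapply(cnuA_candidates, function(g)
    all(doms[[g]] %in% c("CC", "PYD", "REC")), logical(1))]
  cnuA <- if (length(cnuA_candidates) > 0) cnuA_candidates[1] else NULL
  cnuA_doms <- if (is.null(cnuA)) character(0) else doms[[cnuA]]
  helical_insert <- "helical_insert" %in% bdoms

  label <- NULL
  diag <- character(0)
  if (sig != "NxD") {
    label <- "non_CoCoNuT_McrBC"
  } else if (!is.null(cnuH) && "Vsr" %in% cnuH_doms && is.null(cnuE)) {
    label <- "III-B"
  } else if (!is.null(cnuE) && n_pld_E >= 2) {
    label <- "III-C"
  } else if ((!is.null(cnuE) && n_hepn_E >= 2) || "Hsp70" %in% cdoms) {
    label <- "III-A"
  } else if (!is.null(cnuE) && n_hepn_E == 1 && !is.null(cnuH)) {
    label <- "II"
  } else if (is.null(cnuH) && is.null(cnuE) && helical_insert) {
    label <- "I-A"
  } else if (is.null(cnuH) && is.null(cnuE) && !is.null(cnuA) &&
             all(c("PYD", "REC") %in% cnuA_doms)) {
    label <- "I-B"
  } else if (is.null(cnuH) && is.null(cnuE) && is.null(cnuA) &&
             "CSD" %in% bdoms && !"CC" %in% bdoms) {
    # I-B-like CnuB (coiled coil encoded separately) with the separate
    # coiled-coil protein lost from the entire island
    label <- "Pseudo-I-B"
  } else if (is.null(cnuH) && is.null(cnuE) && is.null(cnuA) &&
             all(c("CSD", "CC") %in% bdoms) && !helical_insert) {
    label <- "I-C"
  } else {
    label <- "unclassified"
    diag <- c(diag, "no grammar rule matched the locus architecture")
  }

  tery <- FALSE
  carf <- NULL
  extended <- "none"
  if (label %in% c("II", "III-A")) {
    tery <- detect_tery_p(neighborhood, hits)
    if (!is.null(ct))
      carf <- detect_carf_superoperon(ct, system, hits, config)
  }
  if (label == "III-A")
    extended <- detect_extended_IIIA(neighborhood, hits, config)$variant

  call <- structure(list(locus_id = system$locus_id, label = label,
                         signature = sig, components = NULL,
                         tery_p = tery, carf_association = carf,
                         extended_IIIA = extended, diagnostics = diag),
                    class = "coconut_call")
  assign_roles(call, system, hits, neighborhood,
               cnuH = cnuH, cnuE = cnuE, cnuA = cnuA)
}

#' @export
print.coconut_call <- function(x, ...) {
  cat("<coconut_call> ", x$locus_id, ": ", x$label,
      " (signature ", x$signature, ")\n", sep = "")
  if (!is.null(x$components) && nrow(x$components) > 0)
    cat("  roles: ", paste(x$components$role, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Detect a TerY-P triad in a neighborhood
#'
#' True when three consecutive same-strand genes carry VWA, PP2C and
#' STK-plus-ZnR hits in that order (or the reverse order, for the opposite
#' reading direction).
#'
#' @param neighborhood A [extract_neighborhood()] result.
#' @param hits Annotated domain-hit table.
#' @return Logical.
#' @export
detect_tery_p <- function(neighborhood, hits) {
  doms <- island_domains(neighborhood, hits)
  g <- neighborhood$genes
  if (nrow(g) < 3) return(FALSE)
  for (i in seq_len(nrow(g) - 2L)) {
    trio <- i:(i + 2L)
    if (length(unique(g$strand[trio])) != 1) next
    d1 <- doms[[g$gene_id[i]]]; d2 <- doms[[g$gene_id[i + 1L]]]
    d3 <- doms[[g$gene_id[i + 2L]]]
    fwd <- "VWA" %in% d1 && "PP2C" %in% d2 &&
      all(c("STK", "ZnR") %in% d3)
    rev <- "VWA" %in% d3 && "PP2C" %in% d2 &&
      all(c("STK", "ZnR") %in% d1)
    if (fwd || rev) return(TRUE)
  }
  FALSE
}

#' Detect extended Type III-A operon variants
#'
#' Looks for two VWA-bearing genes flanking a gene block whose diagnostic
#' ATPase names the variant: an EssC-like FtsK ATPase with at least one
#' WXG100 protein (`EssC_like`), a SpoVK-family AAA+ ATPase next to a
#' glycine-zipper protein (`SpoVK_like`), or a VirB4-like ATPase
#' (`VirB4_like`; also accepted at the 3' end when the VWA genes are
#' duplicated at the 5' end). The MIDAS states of the two VWA genes are
#' recorded (the 5' copy is expected intact, the internal copy degraded).
#'
#' @inheritParams detect_tery_p
#' @param config Pipeline configuration.
#' @return List with `variant` (`"EssC_like"`, `"SpoVK_like"`,
#'   `"VirB4_like"` or `"none"`), `midas_first`, `midas_internal`.
#' @export
detect_extended_IIIA <- function(neighborhood, hits, config = default_config()) {
  doms <- island_domains(neighborhood, hits)
  g <- neighborhood$genes
  vwa_idx <- which(vapply(g$gene_id, function(id) "VWA" %in% doms[[id]],
                          logical(1)))
  none <- list(variant = "none", midas_first = NA_character_,
               midas_internal = NA_character_)
  midas_state <- function(i) {
    d <- hits[hits$protein_id == g$protein_id[i] &
              grepl("^MIDAS_", hits$domain_name), , drop = FALSE]
    if (nrow(d) == 0) "absent" else sub("^MIDAS_", "", d$domain_name[1])
  }
  if (length(vwa_idx) >= 2) {
    for (a in seq_len(length(vwa_idx) - 1L)) {
      i <- vwa_idx[a]; j <- vwa_idx[a + 1L]
      if (j - i < 2) next
      block <- unlist(doms[g$gene_id[(i + 1L):(j - 1L)]])
      variant <-
        if ("EssC_ATPase" %in% block && "WXG100" %in% block) "EssC_like"
        else if ("SpoVK_ATPase" %in% block && "Gly_zipper" %in% block)
          "SpoVK_like"
        else if ("VirB4_ATPase" %in% block) "VirB4_like"
        else NA_character_
      if (!is.na(variant))
        return(list(variant = variant, midas_first = midas_state(i),
                    midas_internal = midas_state(j)))
    }
    # VirB4 variant with the ATPase migrated to the 3' end: duplicated VWA
    # genes adjacent at the 5' end, ATPase elsewhere in the island
    adj <- which(diff(vwa_idx) == 1)
    has_virb4 <- any(vapply(g$gene_id, function(id)
      "VirB4_ATPase" %in% doms[[id]], logical(1)))
    if (length(adj) > 0 && has_virb4) {
      i <- vwa_idx[adj[1]]; j <- vwa_idx[adj[1] + 1L]
      return(list(variant = "VirB4_like", midas_first = midas_state(i),
                  midas_internal = midas_state(j)))
    }
    return(none)
  }
  none
}

#' Detect a CARF/RtcR superoperon upstream of a locus
#'
#' Walks upstream of the locus in its transcription direction while genes
#' share the locus strand and successive intergenic gaps stay within
#' `superoperon_gap_nt` (default 200 nt). If a CARF/RtcR-tagged gene is
#' reached, the association is returned with system tags for the
#' intervening genes (Type I RM, Druantia III, BREX, Shield ShdA,
#' BrnT-like). An opposite-strand gene or an oversized gap stops the walk:
#' superoperon membership requires consistent direction and close spacing.
#'
#' @param ct The [contig()] carrying the locus.
#' @param system One row of the census `systems` table.
#' @param hits Annotated domain-hit table.
#' @param config Pipeline configuration.
#' @return `NULL`, or a list with `carf_gene`, `member_genes` (gene IDs
#'   from the CARF gene to the locus edge, transcription order),
#'   `same_direction` (always `TRUE` for a returned record), `span_nt` and
#'   `embedded_systems`.
#' @export
detect_carf_superoperon <- function(ct, system, hits,
                                    config = default_config()) {
  g <- ct$genes
  idx <- hits_by_protein(hits)
  locus_gene <- if (!is.na(system$mcrB_gene)) system$mcrB_gene else
    system$mcrC_gene
  i <- match(locus_gene, g$gene_id)
  if (is.na(i)) return(NULL)
  s <- g$strand[i]
  step <- if (s == "+") -1L else 1L   # upstream in transcription direction
  walked <- integer(0)
  j <- i
  carf_at <- NA_integer_
  repeat {
    nxt <- j + step
    if (nxt < 1L || nxt > nrow(g)) break
    if (g$strand[nxt] != s) break
    gap <- intergenic_gap(g[j, ], g[nxt, ])
    if (gap > config$superoperon_gap_nt) break
    walked <- c(walked, nxt)
    pid <- g$protein_id[nxt]
    d <- if (is.na(pid)) character(0) else idx[[pid]] %||% character(0)
    if (TAG_CARF %in% d) { carf_at <- nxt; break }
    j <- nxt
  }
  if (is.na(carf_at)) return(NULL)
  members <- rev(walked)   # transcription order: CARF gene first
  embedded <- character(0)
  for (k in setdiff(walked, carf_at)) {
    pid <- g$protein_id[k]
    d <- if (is.na(pid)) character(0) else idx[[pid]] %||% character(0)
    embedded <- c(embedded, unname(EMBEDDED_SYSTEM_TAGS[
      names(EMBEDDED_SYSTEM_TAGS) %in% d]))
  }
  span <- abs(max(g$end[c(carf_at, i)]) - min(g$start[c(carf_at, i)]))
  list(carf_gene = g$gene_id[carf_at],
       member_genes = g$gene_id[members],
       same_direction = TRUE,
       span_nt = as.integer(span),
       embedded_systems = unique(embedded))
}

#' Assign component roles to the genes of a classified locus
#'
#' Maps each locus gene to exactly one role from its domain evidence:
#' GTPase-bearing gene to CnuB, DUF2357-bearing to CnuC (CnuCD when fused
#' to an Hsp70-like unit), the SF1 helicase to CnuH, the wHTH effector to
#' CnuE, a stand-alone Hsp70-like coiled-coil protein to CnuD, the separate
#' coiled-coil protein to CnuA; anything else becomes accessory with a
#' diagnostic. Non-CoCoNuT systems carry no roles.
#'
#' @param call A `coconut_call` (possibly without components yet).
#' @param system,hits,neighborhood As in [classify_locus()].
#' @param cnuH,cnuE,cnuA Pre-resolved gene IDs (or `NULL`).
#' @return The call with its `components` data frame filled in.
#' @export
assign_roles <- function(call, system, hits, neighborhood,
                         cnuH = NULL, cnuE = NULL, cnuA = NULL) {
  if (!call$label %in% c("I-A", "I-B", "Pseudo-I-B", "I-C", "II",
                         "III-A", "III-B", "III-C")) {
    call$components <- data.frame(gene_id = character(), role = character(),
                                  evidence = character(),
                                  stringsAsFactors = FALSE)
    return(call)
  }
  doms <- island_domains(neighborhood, hits)
  rows <- list()
  add <- function(gene_id, role) {
    if (is.null(gene_id) || is.na(gene_id)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gene_id, role = role,
      evidence = paste(doms[[gene_id]], collapse = ","),
      stringsAsFactors = FALSE)
  }
  add(system$mcrB_gene, "CnuB")
  if (!is.na(system$mcrC_gene)) {
    cdoms <- doms[[system$mcrC_gene]]
    add(system$mcrC_gene, if ("Hsp70" %in% cdoms) "CnuCD" else "CnuC")
  }
  add(cnuH, "CnuH")
  add(cnuE, "CnuE")
  add(cnuA, "CnuA")
  # stand-alone Hsp70-like coiled-coil proteins (Types III-B / III-C)
  taken <- vapply(rows, function(r) r$gene_id, character(1))
  for (gid in neighborhood$genes$gene_id) {
    if (gid %in% taken) next
    d <- doms[[gid]]
    if ("Hsp70" %in% d && !"DUF2357" %in% d && "CC" %in% d)
      add(gid, "CnuD")
  }
  call$components <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(gene_id = character(), role = character(),
               evidence = character(), stringsAsFactors = FALSE)
  call
}
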