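# classification fixtures are generated end-to-end: each subtype locus is
# planted by the simulator, annotated, censused, and classified

classified_fixture <- function(seed = 5L, loci_per_subtype = 1L, ...) {
  cfg <- default_config()
  sim <- sim_config(seed = seed, loci_per_subtype = loci_per_subtype,
                    decoy_count = 0L, ...)
  gen <- generate_genome(sim)
  ad <- mock_profile_adapter(gen$truth$tags)
  ann <- annotate_proteins(gen$bundle, ad, config = cfg)
  cen <- run_census(gen$bundle, ann, config = cfg)
  contig_of <- stats::setNames(
    gen$bundle$contigs,
    vapply(gen$bundle$contigs, `[[`, character(1), "contig_id"))
  calls <- lapply(seq_len(nrow(cen$systems)), function(r) {
    s <- cen$systems[r, ]
    ct <- contig_of[[s$contig_id]]
    n <- extract_neighborhood(ct, s$mcrB_gene, cfg$flank_genes)
    classify_locus(s, ann, n, ct, cfg)
  })
  truth_of <- stats::setNames(gen$truth$loci$label, gen$truth$loci$mcrB_gene)
  list(gen = gen, ann = ann, cen = cen, calls = calls,
       truth_label = unname(truth_of[cen$systems$mcrB_gene]))
}

test_that("the grammar assigns every planted subtype its label", {
  fx <- classified_fixture(seed = 5L)
  got <- vapply(fx$calls, `[[`, character(1), "label")
  expect_identical(got, fx$truth_label)
  expect_setequal(got, c("I-A", "I-B", "Pseudo-I-B", "I-C", "II", "III-A",
                         "III-B", "III-C", "non_CoCoNuT_McrBC"))
  # the grammar is total: every system got exactly one valid label
  expect_true(all(got %in% coconut_labels()))
})

test_that("the NxD signature gates CoCoNuT membership", {
  fx <- classified_fixture(seed = 6L)
  sig <- vapply(fx$calls, `[[`, character(1), "signature")
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  expect_true(all(lab[sig != "NxD"] == "non_CoCoNuT_McrBC"))
  expect_true(all(sig[lab != "non_CoCoNuT_McrBC"] == "NxD"))
})

test_that("component roles follow the domain architecture", {
  fx <- classified_fixture(seed = 5L)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  roles_of <- function(l) sort(fx$calls[[which(lab == l)]]$components$role)
  expect_identical(roles_of("III-A"), c("CnuB", "CnuCD", "CnuE", "CnuH"))
  expect_true(all(c("CnuD", "CnuA", "CnuB", "CnuC", "CnuH") %in%
                    roles_of("III-B")))
  expect_identical(roles_of("I-B"), c("CnuA", "CnuB", "CnuC"))
  # non-CoCoNuT systems carry no component roles
  expect_identical(nrow(fx$calls[[which(lab == "non_CoCoNuT_McrBC")[1]]]$
                          components), 0L)
})

test_that("the Type I-A helical insert is read from the motif spacing", {
  fx <- classified_fixture(seed = 7L)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  ia <- fx$cen$systems[which(lab == "I-A"), ]
  h <- fx$ann[fx$ann$protein_id == ia$mcrB_protein, ]
  expect_true("helical_insert" %in% h$domain_name)
  # the I-C CnuB has the normal spacing and no insert call
  ic <- fx$cen$systems[which(lab == "I-C"), ]
  expect_false("helical_insert" %in%
                 fx$ann$domain_name[fx$ann$protein_id == ic$mcrB_protein])
})

test_that("TerY-P is detected for II/III-A and never for III-B/III-C", {
  fx <- classified_fixture(seed = 8L)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  tery <- vapply(fx$calls, `[[`, logical(1), "tery_p")
  expect_true(all(tery[lab %in% c("II", "III-A")]))
  expect_false(any(tery[lab %in% c("III-B", "III-C")]))
})

test_that("TerY-P needs the complete co-oriented VWA/PP2C/STK+ZnR triad", {
  g <- rbind(mk_gene("v", 0, 300, "+"), mk_gene("p", 350, 540, "+"),
             mk_gene("k", 950, 660, "+"))
  full <- rbind(mk_hit("v_p", "VWA"), mk_hit("p_p", "PP2C"),
                mk_hit("k_p", "STK"), mk_hit("k_p", "ZnR"))
  n <- extract_neighborhood(contig("c1", g, 10000), "v")
  expect_true(detect_tery_p(n, full))
  # reversed reading order is accepted too
  rev_hits <- rbind(mk_hit("k_p", "VWA"), mk_hit("p_p", "PP2C"),
                    mk_hit("v_p", "STK"), mk_hit("v_p", "ZnR"))
  expect_true(detect_tery_p(n, rev_hits))
  # missing ZnR on the kinase -> incomplete
  expect_false(detect_tery_p(n, full[full$domain_name != "ZnR", ]))
  # mixed strands -> no triad
  g2 <- g; g2$strand[2] <- "-"
  n2 <- extract_neighborhood(contig("c1", g2, 10000), "v")
  expect_false(detect_tery_p(n2, full))
})

test_that("extended III-A variants are named by their diagnostic ATPase", {
  fx <- classified_fixture(seed = 9L, loci_per_subtype = 3L,
                           include_superoperons = FALSE)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  ext <- vapply(fx$calls, `[[`, character(1), "extended_IIIA")
  expect_setequal(ext[lab == "III-A"],
                  c("EssC_like", "SpoVK_like", "VirB4_like"))
  expect_true(all(ext[lab != "III-A"] == "none"))
  # MIDAS states: 5' VWA intact, internal VWA degraded
  iiia <- which(lab == "III-A" & ext == "EssC_like")
  s <- fx$cen$systems[iiia, ]
  ctid <- s$contig_id
  ct <- fx$gen$bundle$contigs[[match(
    ctid, vapply(fx$gen$bundle$contigs, `[[`, character(1), "contig_id"))]]
  n <- extract_neighborhood(ct, s$mcrB_gene)
  det <- detect_extended_IIIA(n, fx$ann)
  expect_identical(det$variant, "EssC_like")
  expect_identical(det$midas_first, "intact")
  expect_identical(det$midas_internal, "degraded_no_T")
})

test_that("no inserted ATPase between VWA genes means no extended variant", {
  fx <- classified_fixture(seed = 10L, include_extended_IIIA = FALSE)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  ext <- vapply(fx$calls, `[[`, character(1), "extended_IIIA")
  expect_identical(unique(ext[lab == "III-A"]), "none")
})

test_that("CARF/RtcR superoperons are walked upstream in one direction", {
  fx <- classified_fixture(seed = 11L)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  carf <- fx$calls[[which(lab == "II")]]$carf_association
  expect_false(is.null(carf))
  expect_true(carf$same_direction)
  expect_setequal(carf$embedded_systems, c("TypeI_RM", "BrnT_like"))
  # an opposite-strand gene interrupting the walk kills the association
  s <- fx$cen$systems[which(lab == "II"), ]
  ct <- fx$gen$bundle$contigs[[match(
    s$contig_id,
    vapply(fx$gen$bundle$contigs, `[[`, character(1), "contig_id"))]]
  ct2 <- ct
  flip <- match(paste0(sub("_g.*", "", s$mcrB_gene), "_g5"),
                ct2$genes$gene_id)
  ct2$genes$strand[flip] <- setdiff(c("+", "-"),
                                    ct2$genes$strand[flip])
  expect_null(detect_carf_superoperon(ct2, s, fx$ann))
})

test_that("labels are stable under physical gene reordering in the locus", {
  fx <- classified_fixture(seed = 12L)
  lab <- vapply(fx$calls, `[[`, character(1), "label")
  for (target in c("III-B", "III-C")) {
    s <- fx$cen$systems[which(lab == target), ]
    cti <- match(s$contig_id, vapply(fx$gen$bundle$contigs, `[[`,
                                     character(1), "contig_id"))
    ct <- fx$gen$bundle$contigs[[cti]]
    # swap the coordinates of the CnuH and CnuD genes (strands, gaps kept)
    prefix <- sub("_g.*", "", s$mcrB_gene)
    roles <- fx$gen$truth$roles
    gH <- roles$gene_id[roles$locus_id == prefix & roles$role == "CnuH"]
    gD <- roles$gene_id[roles$locus_id == prefix & roles$role == "CnuD"]
    g <- ct$genes
    iH <- match(gH, g$gene_id); iD <- match(gD, g$gene_id)
    swap <- g[iH, c("start", "end")]
    g[iH, c("start", "end")] <- g[iD, c("start", "end")]
    g[iD, c("start", "end")] <- swap
    ct2 <- contig(ct$contig_id, g, ct$length)
    n2 <- extract_neighborhood(ct2, s$mcrB_gene)
    call2 <- classify_locus(s, fx$ann, n2, ct2)
    expect_identical(call2$label, target)
  }
})
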