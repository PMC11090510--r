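test_that("neighborhood extraction takes up to 10 genes on each side", {
  ct25 <- mk_contig(25)
  n <- extract_neighborhood(ct25, "g13")          # anchor with full flanks
  expect_identical(nrow(n$genes), 21L)
  ct5 <- mk_contig(5)
  expect_identical(nrow(extract_neighborhood(ct5, "g1")$genes), 5L)
  ct30 <- mk_contig(30)
  expect_identical(nrow(extract_neighborhood(ct30, "g4")$genes), 14L)
  expect_error(extract_neighborhood(ct5, "missing"), "not found")
})

test_that("strict filter needs COG1401 or both alias classes", {
  n <- extract_neighborhood(mk_contig(7), "g4")
  expect_true(strict_filter(n, mk_hit("g4_p", "COG1401"))$pass)
  both <- rbind(mk_hit("g4_p", "EVE"), mk_hit("g5_p", "DUF2357"))
  expect_true(strict_filter(n, both)$pass)
  expect_false(strict_filter(n, mk_hit("g4_p", "MoxR"))$pass)
  expect_false(strict_filter(n, empty_hits())$pass)
})

test_that("relaxed filter enforces the 90 nt / size / orientation gates", {
  mk_n <- function(gap, partner_len, partner_strand = "+") {
    g <- rbind(mk_gene("hit", 0, 300, "+", plen = 120),
               mk_gene("prt", 300 + gap, 3 * partner_len, partner_strand,
                       plen = partner_len))
    extract_neighborhood(contig("c1", g, 10000), "hit")
  }
  hits <- mk_hit("hit_p", "EVE")   # one McrB alias: the missing part is McrC
  r <- relaxed_filter(mk_n(60, 250), hits)
  expect_true(r$pass)
  expect_identical(r$missing, "McrC")
  expect_identical(r$partner$gene_id, "prt")
  expect_false(relaxed_filter(mk_n(60, 140), hits)$pass)   # 140 <= 150
  expect_false(relaxed_filter(mk_n(60, 150), hits)$pass)   # strict >
  expect_true(relaxed_filter(mk_n(60, 151), hits)$pass)
  expect_false(relaxed_filter(mk_n(10, 250, "-"), hits)$pass)  # wrong strand
  expect_true(relaxed_filter(mk_n(90, 250), hits)$pass)    # inclusive 90
  expect_false(relaxed_filter(mk_n(91, 250), hits)$pass)   # behavioral sweep
  # overlapping genes always satisfy the gap rule
  expect_true(relaxed_filter(mk_n(-10, 250), hits)$pass)
  # McrC alias present instead: missing component is McrB, gate > 200 aa
  hits_c <- mk_hit("hit_p", "DUF2357")
  expect_false(relaxed_filter(mk_n(60, 200), hits_c)$pass)
  expect_true(relaxed_filter(mk_n(60, 201), hits_c)$pass)
})

test_that("loosening the gap threshold never loses relaxed passes", {
  hits <- mk_hit("hit_p", "EVE")
  set.seed(91)
  gaps <- sample(0:200, 30, replace = TRUE)
  passes <- function(th) {
    cfg <- default_config(gap_nt = th)
    sum(vapply(gaps, function(g) {
      gg <- rbind(mk_gene("hit", 0, 300, "+", plen = 120),
                  mk_gene("prt", 300 + g, 900, "+", plen = 300))
      relaxed_filter(extract_neighborhood(contig("c1", gg, 10000), "hit"),
                     hits, config = cfg)$pass
    }, logical(1)))
  }
  counts <- vapply(c(30, 60, 90, 120, 200), passes, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("rescue filter chains operonic association transitively", {
  raw <- mk_hit("a_p", "McrB_search_hit")
  direct <- rbind(mk_gene("a", 0, 300, "+", plen = 100),
                  mk_gene("b", 320, 900, "+", plen = 300))
  n1 <- extract_neighborhood(contig("c1", direct, 10000), "a")
  expect_true(rescue_filter(n1, raw)$pass)

  opp <- rbind(mk_gene("a", 0, 300, "+", plen = 100),
               mk_gene("b", 320, 900, "-", plen = 300))
  n2 <- extract_neighborhood(contig("c1", opp, 10000), "a")
  expect_false(rescue_filter(n2, raw)$pass)

  # partner reachable through an intermediate same-strand gene
  chain <- rbind(mk_gene("a", 0, 300, "+", plen = 100),
                 mk_gene("mid", 330, 240, "+", plen = 80),
                 mk_gene("b", 610, 900, "+", plen = 300))
  n3 <- extract_neighborhood(contig("c1", chain, 10000), "a")
  expect_true(rescue_filter(n3, raw)$pass)
  # breaking the chain with a > 90 nt gap stops the walk
  chain2 <- chain; chain2$start[3] <- 671 + 240; chain2$end[3] <- chain2$start[3] + 900
  n4 <- extract_neighborhood(contig("c1", chain2, 10000), "a")
  expect_false(rescue_filter(n4, raw)$pass)
})

test_that("pairing is greedy nearest-neighbor and matches the brute force", {
  # McrB upstream of McrC, same strand
  g <- rbind(mk_gene("b1", 0, 300, "+"), mk_gene("c1", 350, 300, "+"))
  n <- extract_neighborhood(contig("c1", g, 10000), "b1")
  hits <- rbind(mk_hit("b1_p", "COG1401"), mk_hit("c1_p", "DUF2357"))
  sys <- pair_mcrbc(n, hits)
  expect_identical(nrow(sys), 1L)
  expect_false(sys$order_reversed)

  # McrC upstream of McrB: reversed operon
  g2 <- rbind(mk_gene("c1", 0, 300, "+"), mk_gene("b1", 350, 300, "+"))
  n2 <- extract_neighborhood(contig("c1", g2, 10000), "b1")
  sys2 <- pair_mcrbc(n2, hits)
  expect_true(sys2$order_reversed)
  # on the minus strand the same coordinate order is NOT reversed
  g3 <- g2; g3$strand <- "-"
  n3 <- extract_neighborhood(contig("c1", g3, 10000), "b1")
  expect_false(pair_mcrbc(n3, hits)$order_reversed)

  # 2 McrB + 2 McrC alternating: two systems by nearest pairing
  g4 <- rbind(mk_gene("b1", 0, 300, "+"), mk_gene("c1", 350, 300, "+"),
              mk_gene("b2", 700, 300, "+"), mk_gene("c2", 1050, 300, "+"))
  n4 <- extract_neighborhood(contig("c1", g4, 10000), "b1")
  hits4 <- rbind(mk_hit("b1_p", "COG1401"), mk_hit("b2_p", "COG1401"),
                 mk_hit("c1_p", "DUF2357"), mk_hit("c2_p", "DUF2357"))
  sys4 <- pair_mcrbc(n4, hits4)
  expect_identical(nrow(sys4), 2L)
  got <- sys4[, c("mcrB_gene", "mcrC_gene")]
  want <- oracle_pairing(b_pos = c(1L, 3L), c_pos = c(2L, 4L))
  b_names <- c("b1", "b2"); c_names <- c("c1", "c2")
  expect_setequal(paste(got$mcrB_gene, got$mcrC_gene),
                  paste(b_names[want[, "b"]], c_names[want[, "c"]]))
  # no gene is reused
  expect_false(anyDuplicated(c(got$mcrB_gene, got$mcrC_gene)) > 0)

  # orphan McrB
  sys5 <- pair_mcrbc(n, mk_hit("b1_p", "COG1401"))
  expect_identical(nrow(sys5), 1L)
  expect_true(is.na(sys5$mcrC_gene))

  # fused gene carrying both classes
  hits6 <- rbind(mk_hit("b1_p", "COG1401"), mk_hit("b1_p", "DUF2357"))
  sys6 <- pair_mcrbc(n, hits6)
  expect_true(sys6$fused[1])
  expect_identical(sys6$mcrB_gene[1], sys6$mcrC_gene[1])
})

test_that("census recovers planted operons and rejects decoys", {
  cfg <- default_config()
  sim <- sim_config(seed = 13L, loci_per_subtype = 1L,
                    non_coconut_count = 2L, decoy_count = 10L)
  gen <- generate_genome(sim)
  ad <- mock_profile_adapter(gen$truth$tags)
  ann <- annotate_proteins(gen$bundle, ad, config = cfg)
  cen <- run_census(gen$bundle, ann, config = cfg)
  expect_identical(nrow(cen$systems), 10L)   # 8 subtypes + 2 canonical
  expect_identical(unname(cen$funnel[["strict_pass"]]), 10L)
  planted_b <- gen$truth$loci$mcrB_gene
  expect_setequal(cen$systems$mcrB_gene, planted_b)
  expect_false(any(grepl("decoy", cen$systems$mcrB_gene)))
  # filter tiers partition the neighborhoods
  f <- cen$funnel
  expect_identical(unname(f[["strict_pass"]] + f[["relaxed_pass"]] +
                          f[["rescued_pass"]] + f[["rejected"]]),
                   unname(f[["input"]]))
})

test_that("empty genomes produce empty censuses", {
  ct <- contig("c1", mk_contig(1)$genes[0, ], 1000)
  bundle <- genome_bundle(list(ct), character(0))
  cen <- run_census(bundle, empty_hits())
  expect_identical(nrow(cen$systems), 0L)
  expect_true(all(cen$funnel == 0))
})

test_that("relaxed-only and rescue-only loci land in the right funnel tiers", {
  sim <- sim_config(seed = 17L, loci_per_subtype = 0L,
                    non_coconut_count = 0L, decoy_count = 0L,
                    include_tier_fixtures = TRUE)
  gen <- generate_genome(sim)
  ad <- mock_profile_adapter(gen$truth$tags)
  ann <- annotate_proteins(gen$bundle, ad)
  cen <- run_census(gen$bundle, ann)
  expect_identical(unname(cen$funnel[["strict_pass"]]), 0L)
  expect_identical(unname(cen$funnel[["relaxed_pass"]]), 1L)
  expect_identical(unname(cen$funnel[["rescued_pass"]]), 1L)
  expect_setequal(cen$systems$tier, c("relaxed_one_alias",
                                      "rescued_no_alias"))
  # the scan of the untagged McrB proteins still reads the NxxD signature
  expect_true(all(cen$systems$signature == "NxxD"))
})
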