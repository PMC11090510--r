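# Synthetic annotated genomes with planted CoCoNuT loci of every subtype,
# ancillary modules, non-CoCoNuT McrBC operons and decoys, plus a
# ground-truth table, so that every pipeline stage is testable without any
# download.
#
# Motif-bearing domains carry real literal motifs embedded in seeded random
# background (so the built-in scanners are exercised on sequence);
# profile-only domains are represented as placeholder tags consumed by the
# mock profile-search adapter. Background residue composition is uniform
# over the 20-aa alphabet.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' All randomness in [generate_genome()] is fixed by `seed`.
#'
#' @param seed Integer RNG seed.
#' @param loci_per_subtype Planted loci per CoCoNuT subtype label (8 labels:
#'   I-A, I-B, Pseudo-I-B, I-C, II, III-A, III-B, III-C).
#' @param non_coconut_count Planted canonical (NxxD) McrBC operons.
#' @param decoy_count Decoy loci (MoxR-like AAA+ singletons, Type I RM
#'   operons, random genes, cycled).
#' @param contig_count Number of contigs to spread loci over.
#' @param mean_intergenic_gap_nt Typical within-operon intergenic gap.
#' @param include_superoperons Attach a CARF/RtcR superoperon (RtcR, Type I
#'   RM, BrnT-like) upstream of Type II loci.
#' @param include_extended_IIIA Insert an extended variant (EssC-like /
#'   SpoVK-like / VirB4-like, cycled) between duplicated VWA genes at the
#'   5' end of Type III-A loci.
#' @param include_tier_fixtures Plant one relaxed-tier locus (single McrB
#'   alias plus an untagged partner) and one rescue-tier locus (raw search
#'   hit only).
#' @param overlap_prob Probability that a within-operon gap is negative
#'   (overlapping reading frames).
#' @param isolation_genes Untagged filler genes between loci (keeps planted
#'   islands outside each other's 10-gene flanks).
#' @param fp_rate False-positive hit rate for [mock_profile_adapter()].
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, loci_per_subtype = 1L,
                       non_coconut_count = 1L, decoy_count = 6L,
                       contig_count = 2L, mean_intergenic_gap_nt = 60L,
                       include_superoperons = TRUE,
                       include_extended_IIIA = TRUE,
                       include_tier_fixtures = FALSE,
                       overlap_prob = 0.15, isolation_genes = 12L,
                       fp_rate = 0) {
  cfg <- list(seed = as.integer(seed),
              loci_per_subtype = as.integer(loci_per_subtype),
              non_coconut_count = as.integer(non_coconut_count),
              decoy_count = as.integer(decoy_count),
              contig_count = max(1L, as.integer(contig_count)),
              mean_intergenic_gap_nt = as.integer(mean_intergenic_gap_nt),
              include_superoperons = include_superoperons,
              include_extended_IIIA = include_extended_IIIA,
              include_tier_fixtures = include_tier_fixtures,
              overlap_prob = overlap_prob,
              isolation_genes = as.integer(isolation_genes),
              fp_rate = fp_rate)
  counts <- unlist(cfg[c("loci_per_subtype", "non_coconut_count",
                         "decoy_count")])
  if (any(counts < 0)) stop("sim_config: counts must be >= 0")
  structure(cfg, class = "sim_config")
}

SUBTYPE_LABELS <- c("I-A", "I-B", "Pseudo-I-B", "I-C", "II", "III-A",
                    "III-B", "III-C")

# ---- protein token system -------------------------------------------------

rand_bg <- function(n, exclude = character()) {
  paste(sample(setdiff(AA20, exclude), n, replace = TRUE), collapse = "")
}

tk <- function(seq, domain = NA_character_, motif = NA_character_,
               motif_offset = NA_integer_) {
  list(seq = seq, domain = domain, motif = motif,
       motif_offset = motif_offset)
}

tk_bg <- function(n) tk(rand_bg(n))
tk_tag <- function(name, len) tk(rand_bg(len), domain = name)

# GTPase token: Walker A, Walker B, then the Nx(xx)D signature. The region
# between Walker B and the signature excludes N and D so the planted motif
# is the first match; a helical-insert spacer uses coiled-coil-ish letters
# (also N/D-free).
tk_gtpase <- function(variant = "NxD", insert = 0L, tag = TRUE) {
  safe <- c("N", "D")
  spacer_len <- if (insert > 0L) insert else 12L
  spacer_alpha <- if (insert > 0L) c("A", "E", "K", "L", "Q", "R", "S")
                  else setdiff(AA20, safe)
  spacer <- paste(sample(spacer_alpha, spacer_len, replace = TRUE),
                  collapse = "")
  motif_seq <- switch(variant, NxD = "NVDE", NxxD = "NSSDE",
                      NxxxD = "NSTADE",
                      stop("unknown variant ", variant))
  pre <- rand_bg(8, exclude = safe)
  mid <- rand_bg(25, exclude = safe)
  seq <- paste0(pre, "GESGSGKS", mid, "ILFIDE", spacer, motif_seq,
                rand_bg(15))
  tk(seq, domain = if (tag) "COG1401" else NA_character_,
     motif = variant,
     motif_offset = nchar(pre) + 8L + nchar(mid) + 6L + spacer_len)
}

tk_cc <- function(heptads = 10L) tk(strrep("IEALEKK", heptads))

tk_hepn <- function(motif = "RxxxxH") {
  lit <- if (motif == "RxxxxH") "RNIAEH" else "RSH"
  pre <- rand_bg(10, exclude = c("R", "H"))
  seq <- paste0(pre, lit, rand_bg(10, exclude = c("R", "H")))
  tk(seq, domain = "HEPN", motif = motif, motif_offset = nchar(pre))
}

tk_vwa <- function(state = "intact") {
  ex <- c("D", "S", "T")
  seq <- paste0(rand_bg(10, ex), "DLSYS", rand_bg(40, ex),
                if (state == "intact") "T" else "A",
                rand_bg(30, ex), "D", rand_bg(10, ex))
  tk(seq, domain = "VWA", motif = paste0("MIDAS_", state),
     motif_offset = 10L)
}

tk_cpxc <- function(k) {
  parts <- character(0)
  for (i in seq_len(k))
    parts <- c(parts, "CPAC", rand_bg(6, exclude = c("C", "P")))
  tk(paste(parts, collapse = ""))
}

tk_raw <- function(len = 80L) tk(rand_bg(len), domain = RAW_SEARCH_TAG)

# concatenate tokens into one protein; returns sequence plus tag and motif
# tables in 0-based aa coordinates
build_protein <- function(pid, tokens) {
  seqs <- vapply(tokens, `[[`, character(1), "seq")
  ends <- cumsum(nchar(seqs))
  starts <- c(0L, ends[-length(ends)])
  tags <- motifs <- list()
  for (i in seq_along(tokens)) {
    t <- tokens[[i]]
    if (!is.na(t$domain))
      tags[[length(tags) + 1L]] <- data.frame(
        protein_id = pid, domain_name = t$domain,
        start_aa = starts[i], end_aa = ends[i], stringsAsFactors = FALSE)
    if (!is.na(t$motif))
      motifs[[length(motifs) + 1L]] <- data.frame(
        protein_id = pid, motif = t$motif,
        position_aa = starts[i] + t$motif_offset, stringsAsFactors = FALSE)
  }
  list(sequence = paste(seqs, collapse = ""),
       tags = if (length(tags) > 0) do.call(rbind, tags) else NULL,
       motifs = if (length(motifs) > 0) do.call(rbind, motifs) else NULL)
}

# ---- locus architectures --------------------------------------------------

cnuc_type1 <- function() list(tk_tag("Ig", 50), tk_tag("DUF2357", 120),
                              tk_cpxc(3), tk_tag("PD_DExK", 80),
                              tk_tag("ZnR", 20))

tery_genes <- function() {
  list(list(role = "TerY_VWA", tokens = list(tk_vwa("intact"))),
       list(role = "TerY_PP2C", tokens = list(tk_tag("PP2C", 180))),
       list(role = "TerY_STK", tokens = list(tk_tag("STK", 200),
                                             tk_tag("ZnR", 20))))
}

# gene spec list (transcription order) for one locus of a given label;
# rep_i cycles the extended III-A variant
locus_spec <- function(label, cfg, rep_i = 1L) {
  genes <- switch(
    label,
    "I-A" = list(
      list(role = "CnuB", tokens = list(tk_tag("CSD", 60), tk_cc(10),
                                        tk_gtpase("NxD", insert = 90L))),
      list(role = "CnuC", tokens = cnuc_type1())),
    "I-B" = list(
      list(role = "CnuA", tokens = list(tk_tag("PYD", 70), tk_cc(12),
                                        tk_tag("REC", 100))),
      list(role = "CnuB", tokens = list(tk_tag("CSD", 60),
                                        tk_tag("YTH", 90),
                                        tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = cnuc_type1())),
    "Pseudo-I-B" = list(
      list(role = "CnuB", tokens = list(tk_tag("CSD", 60),
                                        tk_tag("YTH", 90),
                                        tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = cnuc_type1())),
    "I-C" = list(
      list(role = "CnuB", tokens = list(tk_tag("CSD", 60),
                                        tk_tag("YTH", 90), tk_cc(10),
                                        tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = cnuc_type1())),
    "II" = c(list(
      list(role = "CnuB", tokens = list(tk_cc(10), tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = list(tk_tag("Ig", 40),
                                        tk_tag("DUF2357", 120),
                                        tk_cpxc(2),
                                        tk_tag("iPD_DExK", 80),
                                        tk_tag("ZnR", 20))),
      list(role = "CnuH", tokens = list(tk_tag("SPB", 70),
                                        tk_tag("RTL", 80),
                                        tk_tag("SF1_helicase", 180),
                                        tk_tag("OB_stalk", 70))),
      list(role = "CnuE", tokens = list(tk_tag("wHTH", 80), tk_cc(6),
                                        tk_hepn("RxxxxH")))),
      tery_genes()),
    "III-A" = c(list(
      list(role = "CnuB", tokens = list(tk_cc(10), tk_gtpase("NxD"),
                                        tk_tag("HTH", 40))),
      list(role = "CnuCD", tokens = list(tk_tag("DUF2357", 120),
                                         tk_tag("Hsp70", 200),
                                         tk_tag("HEAT", 80),
                                         tk_tag("CSD", 60))),
      list(role = "CnuH", tokens = list(tk_tag("SPB", 70),
                                        tk_tag("RTL", 80),
                                        tk_tag("SF1_helicase", 180),
                                        tk_tag("OB_stalk", 70))),
      list(role = "CnuE", tokens = list(tk_tag("wHTH", 80), tk_cc(6),
                                        tk_hepn("RxxxxH"),
                                        tk_hepn("RxH")))),
      tery_genes()),
    "III-B" = list(
      list(role = "CnuB", tokens = list(tk_cc(10), tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = list(tk_tag("Ig", 40),
                                        tk_tag("DUF2357", 120),
                                        tk_tag("iPD_DExK", 80))),
      list(role = "CnuH", tokens = list(tk_tag("wHTH", 60),
                                        tk_tag("SF1_helicase", 180),
                                        tk_tag("OB_stalk", 70),
                                        tk_tag("Vsr", 80))),
      list(role = "CnuD", tokens = list(tk_tag("Hsp70", 200), tk_cc(6))),
      list(role = "CnuA", tokens = list(tk_cc(12)))),
    "III-C" = list(
      list(role = "CnuB", tokens = list(tk_cc(10), tk_gtpase("NxD"))),
      list(role = "CnuC", tokens = list(tk_tag("Ig", 40),
                                        tk_tag("DUF2357", 120),
                                        tk_tag("iPD_DExK", 80))),
      list(role = "CnuH", tokens = list(tk_tag("SF1_helicase", 180))),
      list(role = "CnuE", tokens = list(tk_tag("wHTH", 80), tk_cc(6),
                                        tk_tag("PLD", 90),
                                        tk_tag("PLD", 90))),
      list(role = "CnuD", tokens = list(tk_tag("Hsp70", 200), tk_cc(6)))),
    "non_CoCoNuT_McrBC" = list(
      list(role = "McrB", tokens = list(tk_tag("DUF3578", 80),
                                        tk_gtpase("NxxD"))),
      list(role = "McrC", tokens = list(tk_tag("DUF2357", 120),
                                        tk_tag("PD_DExK", 80)))),
    "relaxed_fixture" = list(
      list(role = "McrB", tokens = list(tk_tag("EVE", 80),
                                        tk_gtpase("NxxD", tag = FALSE))),
      list(role = "partner", tokens = list(tk_bg(250)))),
    "rescue_fixture" = list(
      list(role = "McrB", tokens = list(tk_raw(),
                                        tk_gtpase("NxxD", tag = FALSE))),
      list(role = "partner", tokens = list(tk_bg(300)))),
    stop("unknown label ", label))

  extended <- "none"
  if (label == "III-A" && cfg$include_extended_IIIA) {
    variant <- c("EssC_like", "SpoVK_like", "VirB4_like")[
      (rep_i - 1L) %% 3L + 1L]
    block <- switch(variant,
      EssC_like = list(
        list(role = "ext_ATPase", tokens = list(tk_cc(8),
                                                tk_tag("EssC_ATPase", 300))),
        list(role = "ext_WXG100_1", tokens = list(tk_tag("WXG100", 90))),
        list(role = "ext_WXG100_2", tokens = list(tk_tag("WXG100", 90))),
        list(role = "ext_CC_nuclease",
             tokens = list(tk_cc(6), tk_tag("DExK_nuclease", 80)))),
      SpoVK_like = list(
        list(role = "ext_ATPase", tokens = list(tk_tag("SpoVK_ATPase", 300))),
        list(role = "ext_Gly_zip", tokens = list(tk_tag("Gly_zipper", 100)))),
      VirB4_like = list(
        list(role = "ext_ATPase", tokens = list(tk_tag("VirB4_ATPase", 300)))))
    genes <- c(list(list(role = "ext_VWA_5prime",
                         tokens = list(tk_vwa("intact")))),
               block,
               list(list(role = "ext_VWA_internal",
                         tokens = list(tk_vwa("degraded")))),
               genes)
    extended <- variant
  }

  superoperon <- FALSE
  if (label == "II" && cfg$include_superoperons) {
    genes <- c(list(
      list(role = "CARF_RtcR", tokens = list(tk_tag("CARF_RtcR", 400)),
           super = TRUE),
      list(role = "HsdR", tokens = list(tk_tag("HsdR", 300)), super = TRUE),
      list(role = "HsdM", tokens = list(tk_tag("HsdM", 250)), super = TRUE),
      list(role = "HsdS", tokens = list(tk_tag("HsdS", 150)), super = TRUE),
      list(role = "BrnT", tokens = list(tk_tag("BrnT", 100)), super = TRUE)),
      genes)
    superoperon <- TRUE
  }
  list(genes = genes, extended = extended, superoperon = superoperon)
}

decoy_spec <- function(kind) {
  switch(kind,
    moxr = list(genes = list(list(role = "decoy_MoxR",
                                  tokens = list(tk_tag("MoxR", 250))))),
    rm = list(genes = list(
      list(role = "decoy_HsdR", tokens = list(tk_tag("HsdR", 300))),
      list(role = "decoy_HsdM", tokens = list(tk_tag("HsdM", 250))),
      list(role = "decoy_HsdS", tokens = list(tk_tag("HsdS", 150))))),
    random = list(genes = list(list(role = "decoy_random",
                                    tokens = list(tk_bg(150))))))
}

# ---- genome assembly ------------------------------------------------------

#' Generate an annotated synthetic genome with planted ground truth
#'
#' For each subtype label, operons are assembled from domain tokens: real
#' sequence segments containing the literal motifs (Walker A `GESGSGKS`,
#' Walker B hydrophobics + `DE`, the Nx(xx)D signature, HEPN `R-x4-H` /
#' `R-x-H`, MIDAS, CPxC repeats, heptad repeats for coiled-coils) embedded
#' in seeded random background, plus named placeholder tags for
#' profile-only domains consumed by [mock_profile_adapter()]. Operon
#' geometry: same strand, within-operon gaps drawn in \[0, 90\] nt with
#' occasional negative gaps (overlapping reading frames). Decoys are
#' MoxR-like AAA+ singletons (isolated by > 90 nt gaps), Type I RM operons
#' and random genes.
#'
#' @param cfg A [sim_config()].
#' @return List with `bundle` (a [genome_bundle()], `hits = NULL`) and
#'   `truth`: a list of `loci` (one row per planted locus), `roles` (gene
#'   to component role), `tags` (the planted adapter hit table) and
#'   `motifs` (planted motif coordinates).
#' @export
generate_genome <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  loci <- list()
  for (r in seq_len(cfg$loci_per_subtype))
    for (lab in SUBTYPE_LABELS)
      loci[[length(loci) + 1L]] <- list(label = lab, rep = r)
  for (r in seq_len(cfg$non_coconut_count))
    loci[[length(loci) + 1L]] <- list(label = "non_CoCoNuT_McrBC", rep = r)
  if (cfg$include_tier_fixtures) {
    loci[[length(loci) + 1L]] <- list(label = "relaxed_fixture", rep = 1L)
    loci[[length(loci) + 1L]] <- list(label = "rescue_fixture", rep = 1L)
  }
  decoy_kinds <- rep(c("moxr", "rm", "random"),
                     length.out = cfg$decoy_count)

  proteins <- character(0)
  tags <- motifs <- roles <- truth_rows <- list()
  contig_genes <- rep(list(list()), cfg$contig_count)
  cursors <- rep(0L, cfg$contig_count)
  n_filler <- 0L

  iso_gap <- function() sample(150:400, 1)
  op_gap <- function() {
    if (stats::runif(1) < cfg$overlap_prob) sample(-15:-1, 1)
    else sample(0:min(90L, cfg$mean_intergenic_gap_nt + 30L), 1)
  }

  add_gene <- function(ci, gene_id, pid, aa_len, strand, gap) {
    start <- max(0L, cursors[ci] + as.integer(gap))
    end <- start + 3L * aa_len
    contig_genes[[ci]][[length(contig_genes[[ci]]) + 1L]] <<-
      gene_record(gene_id, paste0("ctg", ci), start, end, strand,
                  protein_id = pid, protein_length = aa_len)
    cursors[ci] <<- end
  }

  add_fillers <- function(ci, k) {
    for (i in seq_len(k)) {
      n_filler <<- n_filler + 1L
      pid <- sprintf("fill_p%04d", n_filler)
      aa <- sample(80:200, 1)
      proteins[[pid]] <<- rand_bg(aa)
      add_gene(ci, sprintf("fill_g%04d", n_filler), pid, aa,
               sample(c("+", "-"), 1), iso_gap())
    }
  }

  place_locus <- function(ci, locus_id, spec, label, rep_i) {
    strand <- sample(c("+", "-"), 1)
    genes <- spec$genes
    n <- length(genes)
    # per-gene protein build (transcription order)
    built <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- paste0(locus_id, "_p", i)
      b <- build_protein(pid, genes[[i]]$tokens)
      proteins[[pid]] <<- b$sequence
      if (!is.null(b$tags)) tags[[length(tags) + 1L]] <<- b$tags
      if (!is.null(b$motifs)) motifs[[length(motifs) + 1L]] <<- b$motifs
      built[[i]] <- list(pid = pid, aa = nchar(b$sequence),
                         role = genes[[i]]$role,
                         super = isTRUE(genes[[i]]$super))
    }
    gaps <- vapply(seq_len(n), function(i) {
      if (i == 1L) iso_gap()
      else if (built[[i]]$super || built[[i - 1L]]$super) sample(95:195, 1)
      else op_gap()
    }, numeric(1))
    order_idx <- if (strand == "+") seq_len(n) else rev(seq_len(n))
    # when reversed, the gap drawn between transcription-consecutive genes
    # i and i+1 must separate placement-consecutive genes
    for (k in seq_len(n)) {
      i <- order_idx[k]
      g <- if (k == 1L) iso_gap() else {
        j <- order_idx[k - 1L]
        gaps[max(i, j)]
      }
      add_gene(ci, paste0(locus_id, "_g", i), built[[i]]$pid,
               built[[i]]$aa, strand, g)
      roles[[length(roles) + 1L]] <<- data.frame(
        locus_id = locus_id, gene_id = paste0(locus_id, "_g", i),
        role = built[[i]]$role, stringsAsFactors = FALSE)
    }
    core <- vapply(built, function(b) b$role, character(1))
    b_idx <- which(core %in% c("CnuB", "McrB"))[1]
    c_idx <- which(core %in% c("CnuC", "CnuCD", "McrC", "partner"))[1]
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      locus_id = locus_id, contig_id = paste0("ctg", ci),
      label = if (label %in% c("relaxed_fixture", "rescue_fixture"))
        "non_CoCoNuT_McrBC" else label,
      tier = switch(label, relaxed_fixture = "relaxed_one_alias",
                    rescue_fixture = "rescued_no_alias", "strict"),
      mcrB_gene = if (is.na(b_idx)) NA_character_ else
        paste0(locus_id, "_g", b_idx),
      mcrC_gene = if (is.na(c_idx)) NA_character_ else
        paste0(locus_id, "_g", c_idx),
      strand = strand,
      signature = if (label %in% c("non_CoCoNuT_McrBC", "relaxed_fixture",
                                   "rescue_fixture")) "NxxD" else "NxD",
      tery_p = label %in% c("II", "III-A"),
      extended_IIIA = spec$extended %||% "none",
      superoperon = isTRUE(spec$superoperon),
      stringsAsFactors = FALSE)
  }

  ci <- 0L
  n_locus <- 0L
  for (lc in loci) {
    ci <- ci %% cfg$contig_count + 1L
    n_locus <- n_locus + 1L
    locus_id <- sprintf("L%03d", n_locus)
    spec <- locus_spec(lc$label, cfg, lc$rep)
    add_fillers(ci, cfg$isolation_genes %/% 2L)
    place_locus(ci, locus_id, spec, lc$label, lc$rep)
    add_fillers(ci, cfg$isolation_genes - cfg$isolation_genes %/% 2L)
  }
  n_decoy <- 0L
  for (kind in decoy_kinds) {
    ci <- ci %% cfg$contig_count + 1L
    n_decoy <- n_decoy + 1L
    spec <- decoy_spec(kind)
    strand <- sample(c("+", "-"), 1)
    add_fillers(ci, cfg$isolation_genes %/% 2L)
    for (i in seq_along(spec$genes)) {
      pid <- sprintf("decoy%02d_p%d", n_decoy, i)
      b <- build_protein(pid, spec$genes[[i]]$tokens)
      proteins[[pid]] <- b$sequence
      if (!is.null(b$tags)) tags[[length(tags) + 1L]] <- b$tags
      add_gene(ci, sprintf("decoy%02d_g%d", n_decoy, i), pid,
               nchar(b$sequence), strand,
               if (i == 1L) iso_gap() else op_gap())
    }
    add_fillers(ci, cfg$isolation_genes - cfg$isolation_genes %/% 2L)
  }

  contigs <- lapply(seq_len(cfg$contig_count), function(i) {
    genes <- if (length(contig_genes[[i]]) > 0)
      do.call(rbind, contig_genes[[i]]) else gene_record("x", "x", 0, 1,
                                                         "+")[0, ]
    contig(paste0("ctg", i), genes, cursors[i] + 500L)
  })
  bundle <- genome_bundle(contigs, proteins)
  truth <- list(
    loci = do.call(rbind, truth_rows),
    roles = do.call(rbind, roles),
    tags = if (length(tags) > 0) do.call(rbind, tags) else
      data.frame(protein_id = character(), domain_name = character(),
                 start_aa = integer(), end_aa = integer(),
                 stringsAsFactors = FALSE),
    motifs = if (length(motifs) > 0) do.call(rbind, motifs) else NULL)
  rownames(truth$loci) <- rownames(truth$tags) <- NULL
  list(bundle = bundle, truth = truth)
}

#' Mock profile-search adapter over planted tags
#'
#' Returns domain hits exactly at the planted placeholder coordinates with
#' E-value 1e-10. Optionally injects reproducible false-positive hits
#' (innocuous domain names, never McrB/McrC aliases) at rate `fp_rate`,
#' fixed by `fp_seed`, for robustness experiments.
#'
#' @param tags Planted tag table (`truth$tags` from [generate_genome()]).
#' @param protein_ids All protein IDs of the bundle (needed when
#'   `fp_rate > 0` so false positives can land on untagged proteins too).
#' @param fp_rate Per-protein false-positive probability.
#' @param fp_seed Seed fixing the false positives.
#' @return A function `(protein_id, sequence) -> domain-hit data frame`,
#'   deterministic for fixed construction arguments.
#' @export
mock_profile_adapter <- function(tags, protein_ids = NULL, fp_rate = 0,
                                 fp_seed = 1L) {
  fp <- NULL
  if (fp_rate > 0 && !is.null(protein_ids)) {
    vocab <- c("DUF9999", "TPR", "MBL_fold", "SWI2_SNF2", "YprA")
    old <- .Random.seed_save()
    set.seed(fp_seed)
    pick <- stats::runif(length(protein_ids)) < fp_rate
    fp <- data.frame(protein_id = protein_ids[pick],
                     domain_name = sample(vocab, sum(pick), replace = TRUE),
                     start_aa = 0L, end_aa = 30L,
                     stringsAsFactors = FALSE)
    .Random.seed_restore(old)
  }
  function(protein_id, sequence) {
    h <- tags[tags$protein_id == protein_id, , drop = FALSE]
    if (!is.null(fp))
      h <- rbind(h, fp[fp$protein_id == protein_id, , drop = FALSE])
    if (nrow(h) == 0) return(empty_hits())
    domain_hit(h$protein_id, h$domain_name,
               pmin(h$start_aa, nchar(sequence) - 1L),
               pmin(h$end_aa, nchar(sequence)),
               evalue = 1e-10, source = "profile")
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a planted-family clustering fixture
#'
#' Families are generated by point-mutating a random family ancestor at a
#' per-site rate; the within-family vs across-family identity margin is
#' checked (on ungapped identity) at generation time.
#'
#' @param n_families,seqs_per_family Family layout.
#' @param divergence Per-site mutation probability in \[0, 0.6\].
#' @param seed RNG seed.
#' @param length_aa Sequence length (default 120).
#' @return Named character vector (`fam<i>_seq<j>`).
#' @export
generate_clustering_fixture <- function(n_families, seqs_per_family,
                                        divergence, seed,
                                        length_aa = 120L) {
  if (divergence < 0 || divergence > 0.6)
    stop("divergence must be in [0, 0.6]")
  set.seed(seed)
  seqs <- character(0)
  fam_of <- character(0)
  for (f in seq_len(n_families)) {
    anc <- sample(AA20, length_aa, replace = TRUE)
    for (s in seq_len(seqs_per_family)) {
      x <- anc
      mut <- stats::runif(length_aa) < divergence
      if (any(mut))
        x[mut] <- vapply(x[mut], function(ch)
          sample(setdiff(AA20, ch), 1), character(1))
      seqs[[sprintf("fam%d_seq%d", f, s)]] <- paste(x, collapse = "")
      fam_of[[sprintf("fam%d_seq%d", f, s)]] <- sprintf("fam%d", f)
    }
  }
  ham <- function(a, b) mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  ids <- names(seqs)
  if (length(ids) > 1 && n_families > 1) {
    within <- 1; across <- 0
    for (i in seq_len(length(ids) - 1L)) for (j in (i + 1L):length(ids)) {
      h <- ham(seqs[[i]], seqs[[j]])
      if (fam_of[[i]] == fam_of[[j]]) within <- min(within, h)
      else across <- max(across, h)
    }
    if (within <= across)
      stop("clustering fixture: family identity margin violated")
  }
  seqs
}
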