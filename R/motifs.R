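# Sequence-level annotation: signature-motif scanners, HEPN/MIDAS/CPxC
# detectors, a heptad coiled-coil heuristic, and the profile-search adapter
# seam with the McrB/McrC alias tables.
#
# Every scanner is a pure function of its inputs.

#' McrB/McrC alias tables
#'
#' Domain names accepted as evidence for the two McrBC components during
#' neighborhood filtering. `COG1401` is the primary McrB GTPase domain; the
#' aliases are domains commonly fused to, or families containing, McrB and
#' McrC homologs.
#'
#' @return List with elements `mcrB` (McrB alias set), `mcrC` (McrC alias
#'   set) and `primary_mcrB` (`"COG1401"`).
#' @export
alias_tables <- function() {
  list(
    mcrB = c("MoxR", "AAA_5", "COG4127", "DUF4357", "Smc", "WEMBL",
             "Myosin_tail_1", "DUF3578", "EVE", "Mrr_N", "pfam01878"),
    mcrC = c("McrBC", "McrC", "PF09823", "DUF2357", "COG1700", "PDDEXK_7",
             "RE_LlaJI"),
    primary_mcrB = "COG1401")
}

# Walker motifs of P-loop NTPases. Hydrophobic class for Walker B is
# {I, L, V, M, F, A}; the motif is four consecutive class members then "DE".
WALKER_A_RE <- "G.{4}GK[ST]"
WALKER_B_RE <- "[ILVMFA]{4}DE"

first_match <- function(seq, re, from = 1L) {
  m <- regexpr(re, substring(seq, from), perl = TRUE)
  if (m < 0) return(NULL)
  list(start = from + as.integer(m) - 1L,
       end = from + as.integer(m) + attr(m, "match.length") - 2L)
}

#' Scan for the Nx(xx)D GTPase signature motif
#'
#' Locates Walker A (`G-x4-G-K-[S/T]`) and Walker B (four hydrophobics then
#' `DE`) inside the GTPase region, then returns the first `N-x{1..3}-D`
#' match downstream of Walker B within `window` amino acids. The variant is
#' named by spacer length (1 = NxD, 2 = NxxD, 3 = NxxxD); candidate
#' positions are scanned left to right and, at a given position, the
#' shortest spacer wins. The residue immediately after the D is recorded
#' because in the NxD clade it is usually (not invariably) E or a second D.
#'
#' @param seq Amino-acid sequence (uppercase).
#' @param gtpase_hit Optional one-row domain-hit delimiting the GTPase
#'   domain (internal aa coordinates); defaults to the whole sequence.
#' @param window Search window in aa downstream of Walker B (default 60).
#' @return List with `variant` (`"NxD"`, `"NxxD"`, `"NxxxD"` or `"none"`),
#'   `position_aa` (0-based index of the N; `NA` when absent), `spacer_aa`
#'   (distance from the end of Walker B to the N), `following` (residue
#'   after the D) and `diagnostic` (`NA` or `"no_walker"`).
#' @export
scan_signature_motif <- function(seq, gtpase_hit = NULL, window = 60L) {
  lo <- 1L; hi <- nchar(seq)
  if (!is.null(gtpase_hit)) {
    lo <- gtpase_hit$start_aa + 1L
    hi <- gtpase_hit$end_aa
  }
  region_none <- list(variant = "none", position_aa = NA_integer_,
                      spacer_aa = NA_integer_, following = NA_character_,
                      diagnostic = NA_character_)
  wa <- first_match(substr(seq, lo, hi), WALKER_A_RE)
  wb <- if (!is.null(wa))
    first_match(substr(seq, lo, hi), WALKER_B_RE, from = wa$end + 1L)
  if (is.null(wa) || is.null(wb)) {
    region_none$diagnostic <- "no_walker"
    return(region_none)
  }
  wb_end <- lo + wb$end - 1L            # absolute 1-based end of Walker B
  last_n <- min(hi, wb_end + window)    # last allowed position for the N
  chars <- strsplit(substr(seq, wb_end + 1L, min(hi, last_n + 4L)), "")[[1]]
  for (p in seq_len(min(length(chars), last_n - wb_end))) {
    if (chars[p] != "N") next
    for (k in 1:3) {
      if (p + k + 1L <= length(chars) && chars[p + k + 1L] == "D") {
        abs_n <- wb_end + p               # 1-based position of N
        fol <- substr(seq, abs_n + k + 2L, abs_n + k + 2L)
        return(list(variant = c("NxD", "NxxD", "NxxxD")[k],
                    position_aa = abs_n - 1L,
                    spacer_aa = p - 1L,
                    following = if (nzchar(fol)) fol else NA_character_,
                    diagnostic = NA_character_))
      }
    }
  }
  region_none
}

#' Scan for HEPN ribonuclease motifs
#'
#' All non-overlapping `R-x4-H` matches are reported. Shortened `R-x-H`
#' matches are only trusted inside regions annotated as HEPN (by the profile
#' adapter or fixture tags), because `R-x-H` alone is uninformative.
#'
#' @param seq Amino-acid sequence.
#' @param hepn_regions Optional data frame with `start_aa`, `end_aa`
#'   (internal aa coordinates) of HEPN-annotated regions.
#' @return Data frame with columns `motif` (`"RxxxxH"`/`"RxH"`) and
#'   `position_aa` (0-based index of the R), sorted by position.
#' @export
scan_hepn <- function(seq, hepn_regions = NULL) {
  out <- data.frame(motif = character(), position_aa = integer(),
                    stringsAsFactors = FALSE)
  m <- gregexpr("R.{4}H", seq, perl = TRUE)[[1]]
  long_pos <- integer()
  if (m[1] > 0) {
    long_pos <- as.integer(m)
    out <- rbind(out, data.frame(motif = "RxxxxH",
                                 position_aa = long_pos - 1L,
                                 stringsAsFactors = FALSE))
  }
  if (!is.null(hepn_regions) && nrow(hepn_regions) > 0) {
    m2 <- gregexpr("R.H", seq, perl = TRUE)[[1]]
    if (m2[1] > 0) {
      for (p in as.integer(m2)) {
        inside <- any(p - 1L >= hepn_regions$start_aa &
                      p + 1L <= hepn_regions$end_aa)
        overlaps_long <- any(p >= long_pos & p <= long_pos + 5L)
        if (inside && !overlaps_long)
          out <- rbind(out, data.frame(motif = "RxH", position_aa = p - 1L,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  out[order(out$position_aa), , drop = FALSE]
}

#' Classify the MIDAS motif state of a VWA region
#'
#' The Mg2+-coordinating MIDAS motif is `DxSxS ... T ... D`. The region is
#' `intact` when a `D-x-S-x-S` match is followed by a threonine within the
#' first spacing window and by an aspartate within the second window after
#' that threonine; `degraded_no_T` when the motif and the downstream D are
#' present but the middle threonine is missing from its window; `absent`
#' otherwise. The spacing windows are configurable defaults (in aa,
#' measured from the D of the motif and from the T, respectively).
#'
#' @param seq Amino-acid sequence of a VWA-annotated region.
#' @param t_window,d_window Integer length-2 spacing windows.
#' @return `"intact"`, `"degraded_no_T"` or `"absent"`.
#' @export
scan_midas <- function(seq, t_window = c(20L, 80L), d_window = c(10L, 60L)) {
  m <- gregexpr("D.S.S", seq, perl = TRUE)[[1]]
  if (m[1] < 0) return("absent")
  chars <- strsplit(seq, "")[[1]]
  degraded <- FALSE
  for (p in as.integer(m)) {
    t_lo <- p + t_window[1]; t_hi <- min(length(chars), p + t_window[2])
    if (t_lo > length(chars)) next
    t_pos <- which(chars[t_lo:t_hi] == "T") + t_lo - 1L
    for (q in t_pos) {
      d_lo <- q + d_window[1]; d_hi <- min(length(chars), q + d_window[2])
      if (d_lo <= length(chars) && any(chars[d_lo:d_hi] == "D"))
        return("intact")
    }
    # no qualifying T: is the terminal D still there in the combined window?
    d_lo <- p + t_window[1] + d_window[1]
    d_hi <- min(length(chars), p + t_window[2] + d_window[2])
    if (length(t_pos) == 0 && d_lo <= length(chars) &&
        any(chars[d_lo:d_hi] == "D"))
      degraded <- TRUE
  }
  if (degraded) "degraded_no_T" else "absent"
}

#' Count Zn-binding CPxC motifs
#'
#' Non-overlapping `C-P-x-C` matches, counted left to right.
#'
#' @param seq Amino-acid sequence.
#' @return Integer count.
#' @export
count_cpxc <- function(seq) {
  m <- gregexpr("CP.C", seq, perl = TRUE)[[1]]
  if (m[1] < 0) 0L else length(m)
}

# Heptad propensity tables for the coiled-coil heuristic. Positions a/d
# favour the hydrophobic seam; b,c,e,f,g favour charged/polar residues.
# The contrasts are sharpened (literature-style hydrophobicity propensities,
# cubed) so that an ideal heptad repeat scores ~0.73 while shuffled and
# random controls stay below ~0.36, well clear of the 0.5 threshold.
CC_PROP_AD <- local({
  v <- c(L = 0.857, I = 0.857, M = 0.857, V = 0.857, F = 0.857,
         A = 0.125, W = 0.064, Y = 0.064, C = 0.064,
         E = 5.1e-04, K = 5.1e-04, Q = 5.1e-04, R = 5.1e-04, D = 5.1e-04,
         N = 5.1e-04, S = 5.1e-04, T = 5.1e-04, H = 5.1e-04, G = 5.1e-04,
         P = 6.4e-05)
  v
})
CC_PROP_BEFG <- local({
  v <- c(E = 0.729, K = 0.729, Q = 0.729, R = 0.729,
         D = 0.512, N = 0.512, S = 0.512, T = 0.512, A = 0.512,
         H = 0.091, G = 0.091,
         L = 0.0156, I = 0.0156, M = 0.0156, V = 0.0156, F = 0.0156,
         W = 0.0156, Y = 0.0156, C = 0.0156,
         P = 5.1e-04)
  v
})

#' Predict coiled-coil segments with a heptad-propensity sliding window
#'
#' For each window the score is the best, over the seven possible heptad
#' frames, of the geometric mean of per-position propensities (an embedded
#' constant table favouring hydrophobics at heptad positions a/d and
#' polar/charged residues elsewhere), which lies in \[0, 1\]. Maximal runs of
#' windows scoring at or above the threshold are merged into segments. This
#' is a deterministic, dependency-free heuristic standing behind an adapter
#' seam: any external coiled-coil predictor can replace it by supplying
#' `coiled_coil` domain hits directly.
#'
#' @param seq Amino-acid sequence.
#' @param window Window length in aa (default 28, i.e. four heptads).
#' @param threshold Segment-calling threshold on the window score.
#' @return Data frame of segments with `start_aa`, `end_aa` (0-based
#'   half-open) and `score` (maximum window score inside the segment).
#'   Sequences shorter than `window` give zero rows.
#' @export
predict_coiled_coil <- function(seq, window = 28L, threshold = 0.5) {
  empty <- data.frame(start_aa = integer(), end_aa = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
  n <- nchar(seq)
  if (n < window) return(empty)
  x <- strsplit(seq, "")[[1]]
  lad <- log(ifelse(x %in% names(CC_PROP_AD), CC_PROP_AD[x], 1e-4))
  lbe <- log(ifelse(x %in% names(CC_PROP_BEFG), CC_PROP_BEFG[x], 1e-4))
  nw <- n - window + 1L
  best <- rep(-Inf, nw)
  for (f in 0:6) {
    pos <- (seq_len(n) - 1L + f) %% 7L
    l <- ifelse(pos == 0L | pos == 3L, lad, lbe)
    cs <- c(0, cumsum(l))
    best <- pmax(best, (cs[(window + 1L):(n + 1L)] - cs[1L:nw]) / window)
  }
  score <- exp(best)
  ok <- score >= threshold
  if (!any(ok)) return(empty)
  # merge qualifying windows into maximal runs
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  data.frame(
    start_aa = starts[segs] - 1L,
    end_aa = ends[segs] + window - 1L,
    score = vapply(segs, function(i) max(score[starts[i]:ends[i]]),
                   numeric(1)),
    stringsAsFactors = FALSE)
}

#' Annotate all proteins of a bundle
#'
#' Union of (E-value-filtered, de-duplicated) adapter hits and the built-in
#' motif and coiled-coil annotations:
#' * coiled-coil segments (`domain_name = "CC"`, `source = "coiled_coil"`);
#' * the GTPase signature variant, scanned inside each `COG1401` hit
#'   (`source = "motif"`, domain named by the variant);
#' * HEPN catalytic motifs inside HEPN-annotated regions;
#' * the MIDAS state of each VWA-annotated region
#'   (`MIDAS_intact` / `MIDAS_degraded_no_T`).
#'
#' An adapter failure on one protein is recorded as a diagnostic (attribute
#' `"diagnostics"` of the result), not an error.
#'
#' @param bundle A [genome_bundle()].
#' @param adapter A profile-search adapter: `function(protein_id, sequence)`
#'   returning a domain-hit data frame (deterministic for fixed inputs), or
#'   `NULL` to use only `bundle$hits` and built-in scanners.
#' @param alias Alias tables (unused by the scanners themselves; carried for
#'   interface symmetry with the census stage).
#' @param config Pipeline configuration (E-value threshold, coiled-coil
#'   window/threshold, signature window).
#' @return Domain-hit data frame ordered by (protein_id, start_aa,
#'   domain_name), with a `"diagnostics"` attribute (character vector).
#' @export
annotate_proteins <- function(bundle, adapter = NULL,
                              alias = alias_tables(),
                              config = default_config()) {
  diags <- character()
  pids <- sort(names(bundle$proteins))
  parts <- vector("list", length(pids))
  base_hits <- if (is.null(bundle$hits)) empty_hits() else bundle$hits
  for (i in seq_along(pids)) {
    pid <- pids[i]
    seq <- bundle$proteins[[pid]]
    h <- base_hits[base_hits$protein_id == pid, , drop = FALSE]
    if (!is.null(adapter)) {
      ah <- tryCatch(adapter(pid, seq), error = function(e) {
        diags <<- c(diags, paste0(pid, ": adapter error: ",
                                  conditionMessage(e)))
        empty_hits()
      })
      if (nrow(ah) > 0) h <- rbind(h, ah)
    }
    keep <- is.na(h$evalue) | h$evalue <= config$evalue
    h <- unique(h[keep, , drop = FALSE])
    # built-in scanners
    cc <- predict_coiled_coil(seq, config$coiled_coil_window,
                              config$coiled_coil_threshold)
    if (nrow(cc) > 0)
      h <- rbind(h, domain_hit(pid, "CC", cc$start_aa, cc$end_aa,
                               source = "coiled_coil"))
    gt <- h[h$domain_name == "COG1401", , drop = FALSE]
    if (nrow(gt) > 0) {
      sig <- scan_signature_motif(seq, gt[1, ], config$signature_window)
      if (sig$variant == "none" && is.na(sig$diagnostic)) {
        # re-scan with the extended window to catch helical-insert variants
        sig2 <- scan_signature_motif(seq, gt[1, ], config$insert_scan_window)
        if (sig2$variant != "none") sig <- sig2
      }
      if (sig$variant != "none") {
        k <- match(sig$variant, c("NxD", "NxxD", "NxxxD"))
        h <- rbind(h, domain_hit(pid, sig$variant, sig$position_aa,
                                 sig$position_aa + k + 2L,
                                 source = "motif"))
        if (!is.na(sig$spacer_aa) &&
            sig$spacer_aa >= config$helical_insert_min_aa)
          h <- rbind(h, domain_hit(pid, "helical_insert",
                                   gt$start_aa[1], sig$position_aa,
                                   source = "motif"))
      }
    }
    hepn_reg <- h[h$domain_name == "HEPN", c("start_aa", "end_aa"),
                  drop = FALSE]
    if (nrow(hepn_reg) > 0) {
      hm <- scan_hepn(seq, hepn_reg)
      if (nrow(hm) > 0)
        h <- rbind(h, domain_hit(pid, hm$motif, hm$position_aa,
                                 hm$position_aa +
                                   ifelse(hm$motif == "RxxxxH", 6L, 3L),
                                 source = "motif"))
    }
    vwa <- h[h$domain_name == "VWA", , drop = FALSE]
    if (nrow(vwa) > 0) {
      for (j in seq_len(nrow(vwa))) {
        st <- scan_midas(substr(seq, vwa$start_aa[j] + 1L, vwa$end_aa[j]),
                         config$midas_t_window, config$midas_d_window)
        if (st != "absent")
          h <- rbind(h, domain_hit(pid, paste0("MIDAS_", st),
                                   vwa$start_aa[j], vwa$end_aa[j],
                                   source = "motif"))
      }
    }
    parts[[i]] <- h
  }
  out <- unique(do.call(rbind, c(list(empty_hits()), parts)))
  out <- out[order(out$protein_id, out$start_aa, out$domain_name), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "diagnostics") <- diags
  out
}
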