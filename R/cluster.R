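# Iterative cluster-align-merge of protein families:
# greedy incremental clustering at an identity threshold, center-star
# alignment around the cluster centroid, per-column frequency profiles,
# profile-profile merging at a score-to-self-score ratio > 0.1, and
# representative selection at a 0.9 identity threshold for tree building.

PROFILE_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

new_cluster <- function(members, centroid, alignment = NULL,
                        profile = NULL) {
  structure(list(members = members, centroid = centroid,
                 alignment = alignment, profile = profile),
            class = "seq_cluster")
}

#' @export
print.seq_cluster <- function(x, ...) {
  cat("<seq_cluster> ", length(x$members), " member(s), centroid ",
      x$centroid, "\n", sep = "")
  invisible(x)
}

# deterministic processing order: longest first, ties by ID
cluster_order <- function(seqs) {
  names(seqs)[order(-nchar(seqs), names(seqs))]
}

#' Greedy incremental clustering at an identity threshold
#'
#' Sequences are processed longest-first (ties broken by ID); each sequence
#' joins the first existing cluster (in founding order) whose centroid
#' identity is at or above the threshold, otherwise it founds a new cluster.
#' The result is a partition of the input and, because the processing order
#' is a function of the sequences only, is invariant to input order.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @return List of `seq_cluster` objects (members, centroid; no alignment).
#' @export
greedy_cluster <- function(seqs, threshold) {
  if (threshold <= 0 || threshold > 1)
    stop("greedy_cluster: threshold must be in (0, 1]")
  if (length(seqs) == 0) return(list())
  clusters <- list()
  for (id in cluster_order(seqs)) {
    placed <- FALSE
    for (k in seq_along(clusters)) {
      if (pairwise_identity(seqs[[id]],
                            seqs[[clusters[[k]]$centroid]]) >= threshold) {
        clusters[[k]]$members <- c(clusters[[k]]$members, id)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- new_cluster(id, id)
  }
  clusters
}

#' Center-star alignment of a cluster
#'
#' Aligns every member to the centroid pairwise and merges the pairwise
#' alignments with the once-a-gap-always-a-gap rule. All rows have equal
#' length and de-gapping any row reproduces the member's input sequence.
#'
#' @param cl A `seq_cluster`.
#' @param seqs Named character vector resolving the members.
#' @return The cluster with its `alignment` filled in (named character
#'   vector of equal-length aligned rows, centroid first).
#' @export
align_cluster <- function(cl, seqs) {
  cen <- seqs[[cl$centroid]]
  others <- setdiff(cl$members, cl$centroid)
  if (length(others) == 0) {
    cl$alignment <- stats::setNames(cen, cl$centroid)
    return(cl)
  }
  L <- nchar(cen)
  pair <- lapply(others, function(id) nw_align(cen, seqs[[id]]))
  names(pair) <- others
  # insertions relative to the centroid, keyed by the number of centroid
  # residues consumed before the insertion point (slot 0..L)
  ins_of <- function(al) {
    ca <- strsplit(al$aligned_a, "")[[1]]
    ins <- integer(L + 1L)
    consumed <- 0L
    for (ch in ca) {
      if (ch == "-") ins[consumed + 1L] <- ins[consumed + 1L] + 1L
      else consumed <- consumed + 1L
    }
    ins
  }
  member_ins <- lapply(pair, ins_of)
  max_ins <- Reduce(pmax, member_ins)
  project <- function(al, ins) {
    ca <- strsplit(al$aligned_a, "")[[1]]
    cb <- strsplit(al$aligned_b, "")[[1]]
    out <- character(0)
    consumed <- 0L; k <- 1L
    emit_slot <- function(slot_chars, slot) {
      pad <- max_ins[slot + 1L] - length(slot_chars)
      c(slot_chars, rep("-", pad))
    }
    slot_chars <- character(0)
    for (idx in seq_along(ca)) {
      if (ca[idx] == "-") {
        slot_chars <- c(slot_chars, cb[idx])
      } else {
        out <- c(out, emit_slot(slot_chars, consumed), cb[idx])
        slot_chars <- character(0)
        consumed <- consumed + 1L
      }
    }
    out <- c(out, emit_slot(slot_chars, consumed))
    paste(out, collapse = "")
  }
  cen_chars <- strsplit(cen, "")[[1]]
  cen_row <- character(0)
  for (k in 0:L) {
    cen_row <- c(cen_row, rep("-", max_ins[k + 1L]),
                 if (k < L) cen_chars[k + 1L])
  }
  rows <- c(stats::setNames(paste(cen_row, collapse = ""), cl$centroid),
            stats::setNames(
              vapply(others,
                     function(id) project(pair[[id]], member_ins[[id]]),
                     character(1)),
              others))
  stopifnot(length(unique(nchar(rows))) == 1)
  cl$alignment <- rows
  cl
}

#' Build a per-column frequency profile from an alignment
#'
#' Column frequencies over the 20-aa alphabet plus gap, with a pseudocount
#' added to every cell before normalisation, so each column sums to 1.
#'
#' @param alignment Character vector of equal-length aligned rows.
#' @param pseudocount Pseudocount per cell (default 0.01).
#' @return Object of class `seq_profile`: list with `mat` (21 x L frequency
#'   matrix) and `length`.
#' @export
build_profile <- function(alignment, pseudocount = 0.01) {
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("build_profile: rows of unequal length")
  chars <- do.call(rbind, strsplit(alignment, ""))
  mat <- vapply(seq_len(L), function(j) {
    cnt <- table(factor(chars[, j], levels = PROFILE_ALPHABET))
    v <- as.numeric(cnt) + pseudocount
    v / sum(v)
  }, numeric(length(PROFILE_ALPHABET)))
  rownames(mat) <- PROFILE_ALPHABET
  structure(list(mat = mat, length = L), class = "seq_profile")
}

#' Profile-profile similarity scores
#'
#' `cross_score` is the best, over all ungapped sliding offsets, of the sum
#' of column-wise dot products between the two frequency profiles;
#' `self_score(p)` is `cross_score(p, p)`. The score is symmetric in its
#' arguments.
#'
#' @param p,q `seq_profile` objects.
#' @return A non-negative real number.
#' @export
cross_score <- function(p, q) {
  # S[i, j] = dot product of column i of p with column j of q; the score at
  # offset o is the sum over the diagonal j - i = o
  S <- crossprod(p$mat, q$mat)
  off <- col(S) - row(S)
  max(rowsum(as.vector(S), as.vector(off)))
}

#' @rdname cross_score
#' @export
self_score <- function(p) cross_score(p, p)

ensure_profiles <- function(clusters, seqs, pseudocount = 0.01) {
  lapply(clusters, function(cl) {
    if (is.null(cl$alignment)) cl <- align_cluster(cl, seqs)
    if (is.null(cl$profile)) cl$profile <- build_profile(cl$alignment,
                                                         pseudocount)
    cl
  })
}

#' One profile-merging round
#'
#' For each unordered pair of clusters the similarity ratio is
#' `cross_score / max(self_score_A, self_score_B)` (denominator
#' configurable as `"max"` or `"min"`); pairs with ratio strictly greater
#' than the threshold are merged via single-linkage connected components,
#' and merged clusters are re-aligned and re-profiled. The cluster count
#' never increases.
#'
#' @param clusters List of `seq_cluster` objects (profiles are computed if
#'   absent, which requires `seqs`).
#' @param seqs Named character vector resolving members.
#' @param ratio_threshold Merge threshold (strict inequality; default 0.1).
#' @param denominator `"max"` (conservative, default) or `"min"`.
#' @return List of `seq_cluster` objects after merging.
#' @export
merge_round <- function(clusters, seqs, ratio_threshold = 0.1,
                        denominator = c("max", "min")) {
  denominator <- match.arg(denominator)
  n <- length(clusters)
  if (n < 2) return(clusters)
  clusters <- ensure_profiles(clusters, seqs)
  selfs <- vapply(clusters, function(cl) self_score(cl$profile), numeric(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    cs <- cross_score(clusters[[i]]$profile, clusters[[j]]$profile)
    den <- if (denominator == "max") max(selfs[i], selfs[j])
           else min(selfs[i], selfs[j])
    if (cs / den > ratio_threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (r in sort(unique(roots))) {
    grp <- which(roots == r)
    if (length(grp) == 1L) {
      out[[length(out) + 1L]] <- clusters[[grp]]
    } else {
      members <- unlist(lapply(clusters[grp], `[[`, "members"))
      lens <- nchar(seqs[members])
      centroid <- members[order(-lens, members)][1]
      merged <- align_cluster(new_cluster(members, centroid), seqs)
      merged$profile <- build_profile(merged$alignment)
      out[[length(out) + 1L]] <- merged
    }
  }
  out
}

#' Iterative cluster-align-merge
#'
#' Greedy clustering at the initial identity threshold, then alignment,
#' profile construction and profile-based merging, repeated for the
#' configured number of iterations (default 3) with early stop as soon as a
#' round merges nothing. Deterministic for fixed input.
#'
#' @param seqs Named character vector of sequences.
#' @param config Pipeline configuration (`cluster_threshold`,
#'   `ratio_threshold`, `ratio_denominator`, `iterations`).
#' @return List of `seq_cluster` objects with alignments and profiles; the
#'   number of merge rounds actually executed is attached as attribute
#'   `"rounds"`.
#' @export
iterate_clustering <- function(seqs, config = default_config()) {
  clusters <- greedy_cluster(seqs, config$cluster_threshold)
  clusters <- ensure_profiles(clusters, seqs)
  rounds <- 0L
  for (it in seq_len(config$iterations)) {
    before <- length(clusters)
    clusters <- merge_round(clusters, seqs, config$ratio_threshold,
                            config$ratio_denominator)
    rounds <- rounds + 1L
    if (length(clusters) == before) break
  }
  attr(clusters, "rounds") <- rounds
  clusters
}

#' Select cluster representatives
#'
#' Greedy clustering at the representative threshold (default 0.9); the
#' centroid of each cluster is returned, sorted.
#'
#' @param seqs Named character vector of sequences.
#' @param threshold Identity threshold in (0, 1].
#' @return Sorted character vector of representative sequence IDs.
#' @export
select_representatives <- function(seqs, threshold = 0.9) {
  sort(vapply(greedy_cluster(seqs, threshold), `[[`, character(1),
              "centroid"))
}

#' Neighbor-joining tree of representative sequences
#'
#' Distances are `1 - pairwise_identity`; the tree is the unrooted NJ tree,
#' which recovers any additive distance matrix exactly. This is the
#' desk-scale tree builder behind an adapter seam: any external
#' maximum-likelihood program can replace it downstream of the exported
#' distance matrix.
#'
#' @param seqs Named character vector (>= 2 sequences), or a precomputed
#'   `dist`/square matrix with row/column names.
#' @return An `ape` `phylo` object.
#' @export
nj_tree <- function(seqs) {
  if (is.matrix(seqs) || inherits(seqs, "dist")) {
    d <- as.matrix(seqs)
  } else {
    n <- length(seqs)
    if (n < 2) stop("nj_tree: need at least 2 sequences")
    d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- 1 - pairwise_identity(seqs[[i]], seqs[[j]])
    }
  }
  if (nrow(d) < 2) stop("nj_tree: need at least 2 leaves")
  if (nrow(d) == 2) {
    lab <- rownames(d)
    return(structure(list(
      edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
      edge.length = rep(d[1, 2] / 2, 2),
      tip.label = lab, Nnode = 1L), class = "phylo"))
  }
  ape::nj(stats::as.dist(d))
}
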