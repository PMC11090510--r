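# Independent oracles used by the tests. These re-derive expected values by
# brute force and stay independent of the package's implementation paths.

AA_ALPHA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PROFILE_ALPHABET_TEST <- c(AA_ALPHA, "-")

# plain-loop affine-gap Needleman-Wunsch with the same scoring conventions
# (BLOSUM62, gap of length L costs open + L*extend) and the same traceback
# preference (aligned pair > gap-in-b > gap-in-a); written independently of
# nw_align's vectorised recurrences
oracle_nw <- function(a, b, open = 11, ext = 1) {
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  sm <- e$BLOSUM62
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- sm[av[i], bv[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
  }
  finals <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  st <- which.max(finals)
  i <- n + 1; j <- m + 1
  ra <- rb <- character(0)
  while (i > 1 || j > 1) {
    if (st == 1) {
      s <- sm[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      st <- which(prev + s == M[i, j])[1]
      ra <- c(av[i - 1], ra); rb <- c(bv[j - 1], rb)
      i <- i - 1; j <- j - 1
    } else if (st == 2) {
      from_m <- M[i - 1, j] - open - ext == X[i, j]
      ra <- c(av[i - 1], ra); rb <- c("-", rb)
      i <- i - 1
      st <- if (from_m) 1 else 2
    } else {
      from_m <- M[i, j - 1] - open - ext == Y[i, j]
      ra <- c("-", ra); rb <- c(bv[j - 1], rb)
      j <- j - 1
      st <- if (from_m) 1 else 3
    }
  }
  list(score = finals[which.max(finals)],
       identity = sum(ra == rb & ra != "-") / length(ra))
}

# quadratic left-to-right non-overlapping CPxC counter
oracle_cpxc <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  n <- length(s); i <- 1; count <- 0
  while (i <= n - 3) {
    if (s[i] == "C" && s[i + 1] == "P" && s[i + 3] == "C") {
      count <- count + 1; i <- i + 4
    } else i <- i + 1
  }
  count
}

# brute-force minimal-total-distance matching of McrB/McrC gene indices
# (enumerates all injective assignments; feasible for <= 4 genes per side)
oracle_pairing <- function(b_pos, c_pos, max_intervening = 2L) {
  k <- min(length(b_pos), length(c_pos))
  best <- NULL; best_cost <- Inf
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  csubsets <- utils::combn(seq_along(c_pos), k, simplify = FALSE)
  for (bsel in utils::combn(seq_along(b_pos), k, simplify = FALSE)) {
    for (csub in csubsets) {
      for (cperm in perms(csub)) {
        interv <- abs(b_pos[bsel] - c_pos[cperm]) - 1L
        if (any(interv > max_intervening)) next
        cost <- sum(abs(b_pos[bsel] - c_pos[cperm]))
        if (cost < best_cost) {
          best_cost <- cost
          best <- cbind(b = bsel, c = cperm)
        }
      }
    }
  }
  best
}

# quick gene-table builders ---------------------------------------------------

mk_gene <- function(id, start, len = 300L, strand = "+", plen = 100L,
                    contig = "c1", pid = paste0(id, "_p")) {
  gene_record(id, contig, start, start + len, strand,
              protein_id = pid, protein_length = plen)
}

# evenly spaced genes: n genes of length `len` nt separated by `gap` nt
mk_contig <- function(n, gap = 50L, len = 300L, strand = "+",
                      plen = 100L, contig = "c1") {
  rows <- lapply(seq_len(n), function(i)
    mk_gene(paste0("g", i), (i - 1L) * (len + gap), len,
            if (length(strand) == 1) strand else strand[i],
            if (length(plen) == 1) plen else plen[i], contig))
  contig(contig, do.call(rbind, rows), n * (len + gap) + 100L)
}

mk_hit <- function(pid, dom, start = 0L, end = 10L) {
  data.frame(protein_id = pid, domain_name = dom, start_aa = start,
             end_aa = end, evalue = 1e-10, source = "profile",
             stringsAsFactors = FALSE)
}

rand_seq <- function(n, alphabet = AA_ALPHA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
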