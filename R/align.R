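# Global pairwise alignment with affine gaps (BLOSUM62, gap open 11,
# extend 1; a gap of length L costs open + L * extend). The dynamic program
# is vectorised row-wise; the within-row horizontal-gap recurrence is solved
# with a running cummax over M[i, k] + k * extend. Tie-breaks during
# traceback are fixed (match state > vertical gap > horizontal gap) so the
# reported alignment, and hence the identity, is deterministic.

.pkgenv <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkgenv$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgenv$blosum62 <- e$BLOSUM62
  }
  .pkgenv$blosum62
}

#' Global alignment of two protein sequences
#'
#' Needleman--Wunsch with affine gap penalties and BLOSUM62 scoring.
#'
#' @param a,b Non-empty amino-acid sequences.
#' @param gap_open,gap_extend Gap penalties (positive numbers; a gap of
#'   length L costs `gap_open + L * gap_extend`).
#' @return List with `score`, `aligned_a`, `aligned_b` (equal-length strings
#'   with `-` for gaps).
#' @export
nw_align <- function(a, b, gap_open = 11, gap_extend = 1) {
  sm <- blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  av[!av %in% rownames(sm)] <- "*"; bv[!bv %in% rownames(sm)] <- "*"
  n <- length(av); m <- length(bv)
  if (n == 0 || m == 0) stop("nw_align: empty sequence")
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)  # ends in aligned pair
  X <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in b (a residue over gap)
  Y <- matrix(NEG, n + 1L, m + 1L)  # ends in gap in a
  M[1, 1] <- 0
  X[2:(n + 1L), 1] <- -(gap_open + seq_len(n) * gap_extend)
  Y[1, 2:(m + 1L)] <- -(gap_open + seq_len(m) * gap_extend)
  S <- sm[av, bv, drop = FALSE]
  jm <- seq_len(m)
  for (i in seq_len(n)) {
    prevM <- M[i, ]; prevX <- X[i, ]; prevY <- Y[i, ]
    best_prev <- pmax(prevM, prevX, prevY)
    M[i + 1L, jm + 1L] <- best_prev[jm] + S[i, ]
    X[i + 1L, ] <- pmax(prevM - gap_open - gap_extend, prevX - gap_extend)
    # Y[i+1, j] = max_{k < j} M[i+1, k] - open - (j - k) * extend
    mrow <- M[i + 1L, ]
    run <- cummax(mrow[jm] + jm * gap_extend)
    Y[i + 1L, jm + 1L] <- run - gap_open - (jm + 1L) * gap_extend
  }
  # traceback; state preference M > X > Y throughout
  i <- n + 1L; j <- m + 1L
  finals <- c(M[i, j], X[i, j], Y[i, j])
  state <- which.max(finals)
  score <- finals[state]
  ra <- character(0); rb <- character(0)
  eps <- 1e-6
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      s <- S[i - 1L, j - 1L]
      prev <- c(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L])
      state <- which(abs(prev + s - M[i, j]) < eps)[1]
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb)
      i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      from_m <- abs(M[i - 1L, j] - gap_open - gap_extend - X[i, j]) < eps
      ra <- c(av[i - 1L], ra); rb <- c("-", rb)
      i <- i - 1L
      state <- if (from_m) 1L else 2L
    } else {
      from_m <- abs(M[i, j - 1L] - gap_open - gap_extend - Y[i, j]) < eps
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb)
      j <- j - 1L
      state <- if (from_m) 1L else 3L
    }
  }
  list(score = score,
       aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""))
}

#' Fractional identity under global alignment
#'
#' Identical matches divided by the number of alignment columns (gap columns
#' included) of the optimal global alignment returned by [nw_align()].
#'
#' @param a,b Non-empty amino-acid sequences.
#' @inheritParams nw_align
#' @return A real number in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  if (identical(a, b)) return(1)
  al <- nw_align(a, b, gap_open, gap_extend)
  xa <- strsplit(al$aligned_a, "")[[1]]
  xb <- strsplit(al$aligned_b, "")[[1]]
  sum(xa == xb & xa != "-") / length(xa)
}
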