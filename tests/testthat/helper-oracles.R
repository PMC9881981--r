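# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain dense matrices and
# exhaustive enumeration at tiny problem sizes.

# full (unbanded) affine-gap global alignment score
r_affine_global <- function(q, t, match = 2, mismatch = -4, gap_open = -4,
                            gap_ext = -2) {
  lq <- length(q); lt <- length(t)
  NEG <- -1e18
  M <- matrix(NEG, lq + 1, lt + 1)
  X <- matrix(NEG, lq + 1, lt + 1) # gap in target (consumes query)
  Y <- matrix(NEG, lq + 1, lt + 1) # gap in query (consumes target)
  M[1, 1] <- 0
  for (i in seq_len(lq)) X[i + 1, 1] <- gap_open + gap_ext * i
  for (j in seq_len(lt)) Y[1, j + 1] <- gap_open + gap_ext * j
  for (i in seq_len(lq)) {
    for (j in seq_len(lt)) {
      s <- if (q[i] >= 0 && q[i] == t[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_ext,
                             X[i, j + 1] + gap_ext,
                             Y[i, j + 1] + gap_open + gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_ext,
                             X[i + 1, j] + gap_open + gap_ext,
                             Y[i + 1, j] + gap_ext)
    }
  }
  max(M[lq + 1, lt + 1], X[lq + 1, lt + 1], Y[lq + 1, lt + 1])
}

# full extension score: best over match-state cells reachable from (0,0)
r_affine_extend <- function(q, t, match = 2, mismatch = -4, gap_open = -4,
                            gap_ext = -2) {
  lq <- length(q); lt <- length(t)
  NEG <- -1e18
  M <- matrix(NEG, lq + 1, lt + 1)
  X <- matrix(NEG, lq + 1, lt + 1)
  Y <- matrix(NEG, lq + 1, lt + 1)
  M[1, 1] <- 0
  for (i in seq_len(lq)) X[i + 1, 1] <- gap_open + gap_ext * i
  for (j in seq_len(lt)) Y[1, j + 1] <- gap_open + gap_ext * j
  for (i in seq_len(lq)) {
    for (j in seq_len(lt)) {
      s <- if (q[i] >= 0 && q[i] == t[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_ext,
                             X[i, j + 1] + gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_ext,
                             Y[i + 1, j] + gap_ext)
    }
  }
  max(M, 0)
}

# plain recursive Levenshtein with memoisation (tiny inputs only)
r_levenshtein <- function(a, b) {
  la <- length(a); lb <- length(b)
  memo <- matrix(NA_integer_, la + 1, lb + 1)
  rec <- function(i, j) {
    if (i == 0) return(j)
    if (j == 0) return(i)
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- min(rec(i - 1, j) + 1L, rec(i, j - 1) + 1L,
             rec(i - 1, j - 1) + (a[i] != b[j]))
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(la, lb)
}

# chaining objective shared with the package contract
r_link_penalty <- function(dq, dt, cap = 15) {
  g <- abs(dq - dt)
  min(0.01 * g + 0.5 * log2(g + 1), cap)
}

# best chain score by exhaustive enumeration of increasing subsequences
r_best_chain_score <- function(qp, tp, max_gap = 12000, cap = 15) {
  n <- length(qp)
  best <- -Inf
  score_of <- function(idx) {
    s <- 1
    if (length(idx) > 1) {
      for (x in 2:length(idx)) {
        dq <- qp[idx[x]] - qp[idx[x - 1]]
        dt <- tp[idx[x]] - tp[idx[x - 1]]
        if (dq <= 0 || dt <= 0 || dq > max_gap || dt > max_gap) return(-Inf)
        s <- s + 1 - r_link_penalty(dq, dt, cap)
      }
    }
    s
  }
  extend <- function(idx) {
    s <- score_of(idx)
    if (s > best) best <<- s
    last <- idx[length(idx)]
    for (nx in seq_len(n)) {
      if (qp[nx] > qp[last] && tp[nx] > tp[last]) extend(c(idx, nx))
    }
  }
  for (i in seq_len(n)) extend(i)
  best
}

# brute-force minimizer positions from per-position k-mer hashes
r_minimizer_positions <- function(hashes, w) {
  nk <- length(hashes)
  W <- min(w, nk)
  sel <- logical(nk)
  for (j in seq_len(nk - W + 1)) {
    win <- hashes[j:(j + W - 1)]
    m <- min(win)
    if (!is.finite(m)) next
    sel[j:(j + W - 1)][win == m] <- TRUE
  }
  which(sel) - 1L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
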