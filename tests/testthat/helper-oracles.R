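# Independent oracles used to validate the package's computational paths.

# ---- pair-HMM likelihood oracles ------------------------------------------
# Model conventions (mirroring the documented mapper model, implemented
# independently of the C++ bottom-up DP):
#   states M / X (read insertion) / Y (genome deletion); Begin->M = 1-2g,
#   Begin->X = g; M->M = 1-2g, M->X = M->Y = g; X->X = Y->Y = gext,
#   X->M = Y->M = 1-gext; no X<->Y; M emits (1-e_j) on match else e_j/3,
#   X emits 1/4, Y silent; paths start and end in M or X; read global,
#   window local with free unscored flanks.

oracle_emit <- function(rb, wb, e) {
  if (rb == wb && rb %in% c("A", "C", "G", "T")) 1 - e else e / 3
}

# Exhaustive sum over all alignments, computed top-down with memoisation.
oracle_forward <- function(read, window, e, g, gext) {
  r <- strsplit(read, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(r); n <- length(w)
  tr <- list(
    M = c(M = 1 - 2 * g, X = g, Y = g),
    X = c(M = 1 - gext, X = gext, Y = 0),
    Y = c(M = 1 - gext, X = 0, Y = gext)
  )
  memo <- new.env(parent = emptyenv())
  # probability of consuming read bases (i+1)..m given genome pointer j and
  # the state of the last move
  cont <- function(i, j, state) {
    if (i == m) return(1)  # free end after the last read base
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    tot <- 0
    if (j < n) {
      tot <- tot + tr[[state]]["M"] * oracle_emit(r[i + 1], w[j + 1], e[i + 1]) *
        cont(i + 1, j + 1, "M")
    }
    tot <- tot + tr[[state]]["X"] * 0.25 * cont(i + 1, j, "X")
    if (j < n && state != "X") {
      tot <- tot + tr[[state]]["Y"] * cont(i, j + 1, "Y")
    }
    tot <- unname(tot)
    memo[[key]] <- tot
    tot
  }
  tot <- 0
  for (j0 in 0:n) {
    if (j0 < n) {
      tot <- tot + (1 - 2 * g) * oracle_emit(r[1], w[j0 + 1], e[1]) *
        cont(1, j0 + 1, "M")
    }
    tot <- tot + g * 0.25 * cont(1, j0, "X")
  }
  log(unname(tot))
}

# Literal path enumeration (no memoisation): multiplies probabilities along
# every complete alignment path. Only feasible for tiny reads/windows; used
# to validate oracle_forward itself.
oracle_forward_paths <- function(read, window, e, g, gext) {
  r <- strsplit(read, "")[[1]]
  w <- strsplit(window, "")[[1]]
  m <- length(r); n <- length(w)
  tr <- list(
    M = c(M = 1 - 2 * g, X = g, Y = g),
    X = c(M = 1 - gext, X = gext, Y = 0),
    Y = c(M = 1 - gext, X = 0, Y = gext)
  )
  total <- 0
  walk <- function(i, j, state, prob) {
    if (i == m) {
      total <<- total + prob
      return(invisible())
    }
    if (j < n) {
      walk(i + 1, j + 1, "M",
           prob * tr[[state]]["M"] * oracle_emit(r[i + 1], w[j + 1], e[i + 1]))
    }
    walk(i + 1, j, "X", prob * tr[[state]]["X"] * 0.25)
    if (j < n && state != "X") walk(i, j + 1, "Y", prob * tr[[state]]["Y"])
    invisible()
  }
  for (j0 in 0:n) {
    if (j0 < n) {
      walk(1, j0 + 1, "M", (1 - 2 * g) * oracle_emit(r[1], w[j0 + 1], e[1]))
    }
    walk(1, j0, "X", g * 0.25)
  }
  log(unname(total))
}

# ---- exact conditional NB test oracle -------------------------------------
# Conditional masses computed from dnbinom products at an arbitrary mean
# (the mean cancels under the conditioning), dbinom for phi = 0.
oracle_exact_test <- function(a, b, phi) {
  s <- a + b
  if (s == 0) return(1)
  x <- 0:s
  w <- if (phi == 0) {
    stats::dbinom(x, s, 0.5)
  } else {
    m <- stats::dnbinom(x, size = 1 / phi, mu = 1) *
      stats::dnbinom(s - x, size = 1 / phi, mu = 1)
    m / sum(m)
  }
  sum(w[w <= w[a + 1] * (1 + 1e-9)])
}

# ---- BH step-up oracle -----------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# ---- brute-force interval assignment oracle -------------------------------
# Largest same-strand >= 1 bp overlap wins, ties to the lowest feature start.
oracle_assign <- function(aln, ann, stranded = TRUE) {
  vapply(seq_len(nrow(aln)), function(i) {
    best <- NA_character_
    best_w <- 0L
    best_start <- Inf
    for (f in seq_len(nrow(ann))) {
      if (ann$contig[f] != aln$contig[i]) next
      if (stranded && ann$strand[f] != aln$strand[i]) next
      w <- min(aln$end[i], ann$end[f]) - max(aln$start[i], ann$start[f])
      if (w < 1) next
      if (w > best_w || (w == best_w && ann$start[f] < best_start)) {
        best <- ann$feature_id[f]
        best_w <- w
        best_start <- ann$start[f]
      }
    }
    best
  }, character(1))
}
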