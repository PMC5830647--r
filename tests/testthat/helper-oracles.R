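# Independent brute-force oracles for the evaluation metrics, written as
# plain nested loops so they share no code with the package implementation.

bf_dice <- function(a, b) {
  inter <- 0L
  na <- 0L
  nb <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j]) na <- na + 1L
      if (b[i, j]) nb <- nb + 1L
      if (a[i, j] && b[i, j]) inter <- inter + 1L
    }
  }
  if (na + nb == 0L) return(1)
  2 * inter / (na + nb)
}

bf_accuracy <- function(p, t) {
  good <- 0L
  for (i in seq_len(nrow(p)))
    for (j in seq_len(ncol(p)))
      if (p[i, j] == t[i, j]) good <- good + 1L
  good / length(p)
}

# 8-connected labelling by repeated scanning flood fill
bf_label8 <- function(x) {
  lab <- matrix(0L, nrow(x), ncol(x))
  nxt <- 0L
  for (sj in seq_len(ncol(x))) {
    for (si in seq_len(nrow(x))) {
      if (!x[si, sj] || lab[si, sj] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(si, sj))
      lab[si, sj] <- nxt
      while (length(queue)) {
        cur <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) {
          for (dj in -1:1) {
            ni <- cur[1] + di
            nj <- cur[2] + dj
            if (ni >= 1 && ni <= nrow(x) && nj >= 1 && nj <= ncol(x) &&
                x[ni, nj] && lab[ni, nj] == 0L) {
              lab[ni, nj] <- nxt
              queue[[length(queue) + 1]] <- c(ni, nj)
            }
          }
        }
      }
    }
  }
  lab
}

# detection counts by the containment-of-predicted-centroid rule
bf_detect <- function(pred, truth) {
  lp <- bf_label8(pred == 2)
  lt <- bf_label8(truth == 2)
  nt <- max(lt)
  hits <- rep(0L, max(nt, 1L))
  fp <- 0L
  if (max(lp) > 0) {
    for (id in seq_len(max(lp))) {
      rs <- c()
      cs <- c()
      for (i in seq_len(nrow(pred)))
        for (j in seq_len(ncol(pred)))
          if (lp[i, j] == id) { rs <- c(rs, i); cs <- c(cs, j) }
      r <- min(max(round(mean(rs)), 1), nrow(truth))
      co <- min(max(round(mean(cs)), 1), ncol(truth))
      owner <- lt[r, co]
      if (owner == 0L) fp <- fp + 1L else hits[owner] <- hits[owner] + 1L
    }
  }
  tp <- if (nt > 0) sum(hits >= 1L) else 0L
  fp <- fp + if (nt > 0) sum(pmax(hits - 1L, 0L)) else 0L
  fn <- nt - tp
  list(TP = tp, FP = fp, FN = fn,
       sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn),
       precision = if (tp + fp == 0) 0 else tp / (tp + fp))
}

# random 3-class mask with a few blobby objects
random_mask_pair <- function(n = 32, seed = 1) {
  set.seed(seed)
  make <- function() {
    m <- matrix(0L, n, n)
    for (k in seq_len(sample(2:5, 1))) {
      r <- runif(1, 3, n - 3)
      co <- runif(1, 3, n - 3)
      rad <- runif(1, 1.5, 4)
      d2 <- outer((seq_len(n) - r)^2, (seq_len(n) - co)^2, `+`)
      m[d2 <= (rad / 0.6)^2] <- 1L
      m[d2 <= rad^2] <- 2L
    }
    m
  }
  list(pred = make(), truth = make())
}
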