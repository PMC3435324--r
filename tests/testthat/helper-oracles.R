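# Independent brute-force oracles, kept deliberately naive.

# Direct double-summation normalized cross-correlation.
ncc_oracle <- function(f, t) {
  M <- nrow(f); N <- ncol(f); P <- nrow(t); Q <- ncol(t)
  g <- matrix(0, M - P + 1, N - Q + 1)
  tb <- mean(t)
  for (u in seq_len(M - P + 1)) {
    for (v in seq_len(N - Q + 1)) {
      w <- f[u:(u + P - 1), v:(v + Q - 1)]
      fb <- mean(w)
      num <- sum((w - fb) * (t - tb))
      den <- sqrt(sum((w - fb)^2) * sum((t - tb)^2))
      g[u, v] <- if (den > 0) num / den else 0
    }
  }
  g
}

# Exhaustive Otsu: maximize between-class variance over all 256 cuts.
otsu_oracle <- function(v) {
  b <- floor(pmin(pmax(v, 0), 255))
  best <- -1; bk <- 0L
  for (k in 0:254) {
    c0 <- b[b <= k]; c1 <- b[b > k]
    if (!length(c0) || !length(c1)) next
    bcv <- as.numeric(length(c0)) * length(c1) * (mean(c0) - mean(c1))^2
    if (bcv > best) { best <- bcv; bk <- k }
  }
  bk
}

# Queue-based 3D flood fill labelling.
flood_fill_oracle <- function(vol, connectivity = 6L) {
  d <- dim(vol)
  lab <- array(0L, d)
  if (connectivity == 6L) {
    nb <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    nb <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
    nb <- nb[rowSums(abs(nb)) > 0, ]
  }
  cur <- 0L
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (!vol[i, j, k] || lab[i, j, k] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j, k)); lab[i, j, k] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(nb))) {
        q <- p + nb[r, ]
        if (any(q < 1) || any(q > d)) next
        if (vol[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# Map labels to a canonical partition signature for comparison.
partition_signature <- function(lab) {
  ids <- lab[lab > 0]
  split(which(lab > 0), ids)[order(vapply(split(which(lab > 0), ids), min, 1))]
}
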