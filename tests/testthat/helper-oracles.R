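# Independent pure-R oracles, deliberately distinct from the package's
# compiled implementation: breadth-first flood fill over explicit queues.

r_label_components <- function(m, connectivity) {
  nr <- nrow(m); nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  if (connectivity == 8) {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  }
  n <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!m[i, j] || lab[i, j] != 0L) next
      n <- n + 1L
      queue <- list(c(i, j))
      lab[i, j] <- n
      while (length(queue) > 0) {
        cur <- queue[[1]]; queue <- queue[-1]
        for (k in seq_along(dr)) {
          ni <- cur[1] + dr[k]; nj <- cur[2] + dc[k]
          if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
              m[ni, nj] && lab[ni, nj] == 0L) {
            lab[ni, nj] <- n
            queue[[length(queue) + 1]] <- c(ni, nj)
          }
        }
      }
    }
  }
  list(labels = lab, n = n)
}

r_betti <- function(m) {
  b0 <- r_label_components(m, 8)$n
  comp <- r_label_components(!m, 4)
  border <- unique(c(comp$labels[1, ], comp$labels[nrow(m), ],
                     comp$labels[, 1], comp$labels[, ncol(m)]))
  b1 <- length(setdiff(seq_len(comp$n), border))
  c(b0 = b0, b1 = b1)
}

# exact McNemar by full enumeration of the 2^(b+c) equally likely
# discordant-outcome sequences under H0
enum_mcnemar <- function(b, c) {
  n <- b + c
  counts <- vapply(0:(2^n - 1), function(bits) {
    sum(bitwAnd(bits, bitwShiftL(1L, 0:(n - 1))) != 0)
  }, numeric(1))
  observed <- min(b, c)
  min(1, 2 * sum(counts <= observed) / 2^n)
}

# decode integer 0..65535 into a 4x4 logical grid
int_to_grid <- function(k, nr = 4, nc = 4) {
  matrix(as.logical(intToBits(k)[seq_len(nr * nc)]), nr, nc)
}

random_grid <- function(nr, nc, p = 0.5) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
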