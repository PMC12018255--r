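# Independent oracles used to cross-check the package implementations.

# Replication-expansion weighted quantile: expand each value into ceil(w*K)
# copies and take the type-1 empirical quantile of the expanded sample.
oracle_weighted_quantile <- function(values, weights, q, K = 5000) {
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  reps <- ceiling(weights / sum(weights) * K)
  x <- sort(rep(values, reps))
  n <- length(x)
  x[max(1L, ceiling(q * n))]
}

# Breadth-first flood fill, structurally different from the package's
# two-pass union-find labelling.
oracle_label <- function(m, connectivity = 8) {
  nr <- nrow(m)
  nc <- ncol(m)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      if (m[r0, c0] > 0 && lab[r0, c0] == 0L) {
        nxt <- nxt + 1L
        queue <- list(c(r0, c0))
        lab[r0, c0] <- nxt
        while (length(queue) > 0) {
          cur <- queue[[length(queue)]]
          queue[[length(queue)]] <- NULL
          for (off in offs) {
            r <- cur[1] + off[1]
            cc <- cur[2] + off[2]
            if (r >= 1 && r <= nr && cc >= 1 && cc <= nc &&
                m[r, cc] > 0 && lab[r, cc] == 0L) {
              lab[r, cc] <- nxt
              queue[[length(queue) + 1]] <- c(r, cc)
            }
          }
        }
      }
    }
  }
  lab
}

# Cell-area oracle: numerical integration of the spherical surface element.
oracle_cell_area <- function(lat_center, resolution) {
  R <- 6371.0088
  f <- function(phi) cos(phi)
  top <- (lat_center + resolution / 2) * pi / 180
  bot <- (lat_center - resolution / 2) * pi / 180
  R^2 * (resolution * pi / 180) *
    stats::integrate(f, bot, top, rel.tol = 1e-12)$value
}
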