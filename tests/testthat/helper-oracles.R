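# Independent oracles used across tests. These deliberately share no code
# with the package: shortest paths by exhaustive simple-path enumeration,
# bivariate normal probabilities by one-dimensional adaptive quadrature.

# All-pairs distances, fractional-credit betweenness and closeness on the
# 1/|w| distance graph, by enumerating every simple path (feasible <= 8 nodes).
brute_force_centrality <- function(A, tol = 1e-9) {
  p <- ncol(A)
  L <- 1 / abs(A)
  L[A == 0] <- Inf
  paths_st <- function(s, t) {
    res <- list()
    recurse <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        res[[length(res) + 1L]] <<- list(path = path, len = len)
        return(invisible())
      }
      for (nxt in seq_len(p)) {
        if (is.finite(L[last, nxt]) && !(nxt %in% path)) {
          recurse(c(path, nxt), len + L[last, nxt])
        }
      }
    }
    recurse(s, 0)
    res
  }
  D <- matrix(Inf, p, p); diag(D) <- 0
  btw <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      ps <- paths_st(s, t)
      if (!length(ps)) next
      lens <- vapply(ps, `[[`, numeric(1), "len")
      dmin <- min(lens)
      D[s, t] <- D[t, s] <- dmin
      geo <- ps[lens <= dmin + tol * (1 + dmin)]
      for (g in geo) {
        inner <- setdiff(g$path, c(s, t))
        btw[inner] <- btw[inner] + 1 / length(geo)
      }
    }
  }
  clo <- vapply(seq_len(p), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    if (!length(d)) 0 else 1 / sum(d)
  }, numeric(1))
  list(distance = D, betweenness = btw, closeness = clo)
}

# Bivariate normal CDF by integrating the conditional univariate CDF.
bvn_quadrature <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  stats::integrate(function(x) {
    dnorm(x) * pnorm((k - rho * x) / sqrt(1 - rho^2))
  }, -Inf, h, rel.tol = 1e-10)$value
}

# Symmetric small test network with mixed-sign weights.
toy_graph <- function() {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.5
  A[2, 3] <- A[3, 2] <- -0.4
  A[3, 4] <- A[4, 3] <- 0.25
  A[1, 4] <- A[4, 1] <- 0.1
  network_graph(c("a", "b", "c", "d"), A)
}
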