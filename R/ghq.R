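# Gauss-Hermite quadrature rules (physicists' convention: weight exp(-x^2)).
# Nodes/weights via Golub-Welsch on the symmetric Jacobi matrix.

gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# E[plogis(m + u)] with u ~ N(0, sd^2), vectorised over m.
logistic_normal_mean <- function(m, sd, n_nodes = 21L) {
  if (sd <= 0) return(stats::plogis(m))
  gh <- gauss_hermite(n_nodes)
  u <- sqrt(2) * sd * gh$nodes
  w <- gh$weights / sqrt(pi)
  p <- vapply(seq_along(u),
              function(k) stats::plogis(m + u[k]),
              numeric(length(m)))
  if (length(m) == 1L) sum(p * w) else as.numeric(p %*% w)
}
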