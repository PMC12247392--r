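# Shared fixtures and independent oracles for the test suite.

# Brute-force IPF oracle on a k-dimensional array, written independently of
# the package internals: margins are (dims, target) pairs, updates use
# apply/sweep, fixed iteration count, no convergence shortcuts.
bf_ipf <- function(seed_arr, margins, iters = 10000L) {
  W <- seed_arr
  for (it in seq_len(iters)) {
    for (m in margins) {
      fitted <- apply(W, m$dims, sum)
      ratio <- ifelse(fitted > 0, m$target / fitted, 0)
      W <- sweep(W, m$dims, ratio, "*")
    }
  }
  W
}

# flatten an array into the package's canonical cell order (last factor
# varies fastest = last array dimension fastest)
canon_order <- function(W) as.vector(aperm(W, rev(seq_along(dim(W)))))

# random raking fixture: a strictly positive joint on a random small
# scheme, margins derived exactly from it (so the system is feasible)
random_rake_fixture <- function(seed, n_factors = sample(2:3, 1L)) {
  set.seed(seed)
  dims <- sample(2:4, n_factors, replace = TRUE)
  fnames <- paste0("f", seq_len(n_factors))
  lv <- lapply(seq_len(n_factors),
               function(i) paste0("l", seq_len(dims[i])))
  names(lv) <- fnames
  scheme <- do.call(strat_scheme, lv)
  J <- array(runif(prod(dims), 0.5, 10), dim = dims)
  # one-way margins for every factor plus, when 3 factors, one two-way
  subsets <- as.list(seq_len(n_factors))
  if (n_factors == 3L) subsets <- c(list(c(1L, 2L)), list(3L))
  margins_pkg <- list()
  margins_bf <- list()
  for (si in seq_along(subsets)) {
    dd <- subsets[[si]]
    tg <- apply(J, dd, sum)
    margins_bf[[si]] <- list(dims = dd, target = tg)
    combo <- expand.grid(lv[dd], stringsAsFactors = FALSE)
    pos <- vapply(seq_along(dd),
                  function(k) match(combo[[k]], lv[[dd[k]]]),
                  integer(nrow(combo)))
    cnt <- if (length(dd) == 1L) as.vector(tg)[pos[, 1L]]
           else tg[pos]
    df <- cbind(data.frame(area_id = "A", stringsAsFactors = FALSE),
                combo, count = cnt)
    margins_pkg[[si]] <- df
  }
  names(margins_pkg) <- paste0("m", seq_along(margins_pkg))
  seed_arr <- array(runif(prod(dims), 0.2, 3), dim = dims)
  list(scheme = scheme, dims = dims, joint = J,
       margins_pkg = margins_pkg, margins_bf = margins_bf,
       seed_arr = seed_arr)
}

# direct post-stratification against a known joint (independent of the
# poststratify/rake code path)
direct_poststrat <- function(preds, joint_df) {
  key <- paste(joint_df$area_id, joint_df$cell)
  cnt <- joint_df$count[match(paste(preds$area_id, preds$cell), key)]
  out <- tapply(cnt * preds$p, preds$area_id, sum) /
    tapply(cnt, preds$area_id, sum)
  out <- out[sort(names(out))]
  stats::setNames(as.numeric(out), names(out))
}

# textbook correlation implementations (independent of stats::cor)
textbook_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
textbook_spearman <- function(x, y)
  textbook_pearson(rank(x), rank(y))

# small deterministic survey for io tests
tiny_study <- function(seed = 1) {
  cfg <- tiny_generator_config(seed = seed)
  simulate_study(cfg)
}
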