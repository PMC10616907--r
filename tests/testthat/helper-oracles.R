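# Independent oracles, deliberately written against the definitions rather
# than the package internals: exhaustive joint-histogram TE/SLTE, naive
# k-core peeling, brute-force feedback vertex sets, and full
# rank-assignment Mann-Whitney enumeration.

# Plug-in TE (or SLTE) by explicit tabulation of every (i_t, i_{t-1},
# j_{t-d}) configuration over t = max(1, d) .. T-1 (0-based).
oracle_te <- function(i, j, d, sorted = FALSE) {
  T <- length(i)
  t <- seq(max(2, d + 1), T)          # 1-based bins
  a <- i[t]; b <- i[t - 1]; cc <- j[t - d]
  N <- length(t)
  idx <- a * 4 + b * 2 + cc
  n <- tabulate(idx + 1, 8)
  tot <- 0
  for (av in 0:1) for (bv in 0:1) for (cv in 0:1) {
    nk <- n[av * 4 + bv * 2 + cv + 1]
    if (nk == 0) next
    nbc <- n[bv * 2 + cv + 1] + n[4 + bv * 2 + cv + 1]
    nab <- n[av * 4 + bv * 2 + 1] + n[av * 4 + bv * 2 + 2]
    nb <- sum(n[c(bv * 2 + 1, bv * 2 + 2, 4 + bv * 2 + 1, 4 + bv * 2 + 2)])
    term <- (nk / N) * log((nk / nbc) / (nab / nb))
    tot <- tot + if (sorted && av != cv) -term else term
  }
  tot
}

# k-core numbers by literal iterative deletion on the undirected simple
# graph, one k at a time.
oracle_kcore <- function(edges, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(x) character())
  for (r in seq_len(nrow(edges))) {
    u <- edges$src[r]; v <- edges$dst[r]
    if (u == v) next
    adj[[u]] <- union(adj[[u]], v)
    adj[[v]] <- union(adj[[v]], u)
  }
  core <- setNames(rep(0L, length(nodes)), nodes)
  k <- 1L
  alive <- nodes
  repeat {
    repeat {
      deg <- vapply(alive, function(v) length(intersect(adj[[v]], alive)),
                    numeric(1))
      drop <- alive[deg < k]
      if (length(drop) == 0) break
      alive <- setdiff(alive, drop)
    }
    if (length(alive) == 0) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# acyclicity by repeated removal of nodes with no remaining out-edges
oracle_is_acyclic <- function(edges, nodes) {
  alive <- nodes
  e <- edges[edges$src != edges$dst, , drop = FALSE]
  repeat {
    if (length(alive) == 0) return(TRUE)
    ee <- e[e$src %in% alive & e$dst %in% alive, , drop = FALSE]
    sink_free <- setdiff(alive, unique(ee$src))
    if (length(sink_free) == 0) return(FALSE)
    alive <- setdiff(alive, sink_free)
  }
}

# all minimum feedback vertex sets by subset enumeration in order of size
oracle_min_fvs <- function(edges, nodes) {
  if (oracle_is_acyclic(edges, nodes)) return(list(character()))
  for (k in seq_along(nodes)) {
    sets <- combn(nodes, k, simplify = FALSE)
    hits <- Filter(function(s) {
      keep <- setdiff(nodes, s)
      oracle_is_acyclic(edges[edges$src %in% keep & edges$dst %in% keep, ,
                              drop = FALSE], keep)
    }, sets)
    if (length(hits)) return(hits)
  }
}

# exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups (tie-free samples)
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  w_obs <- sum(outer(x, y, ">"))
  picks <- combn(n1 + n2, n1, simplify = FALSE)
  ws <- vapply(picks, function(ix) {
    sum(outer(pool[ix], pool[-ix], ">"))
  }, numeric(1))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# quick random-digraph edge frame
random_digraph <- function(n, p, seed, weights = FALSE) {
  set.seed(seed)
  nodes <- paste0("v", seq_len(n))
  m <- matrix(runif(n * n) < p, n, n)
  diag(m) <- FALSE
  e <- data.frame(src = nodes[row(m)[m]], dst = nodes[col(m)[m]],
                  stringsAsFactors = FALSE)
  if (weights && nrow(e)) e$weight <- round(runif(nrow(e), 0.1, 2), 3)
  list(nodes = nodes, edges = e)
}

# small Bernoulli raster with planted edges; plain R, independent of the
# package simulator; 1-based spike bins
tiny_coupled_raster <- function(T, p_base, edges = NULL, seed = 1) {
  set.seed(seed)
  n <- length(p_base)
  m <- matrix(rbinom(n * T, 1, rep(p_base, T)), n, T)
  if (!is.null(edges)) {
    for (r in seq_len(nrow(edges))) {
      j <- edges$src[r]; i <- edges$dst[r]; d <- edges$delay[r]
      src_t <- which(m[j, ] == 1)
      tgt_t <- src_t + d
      tgt_t <- tgt_t[tgt_t <= T]
      if (edges$sign[r] > 0) m[i, tgt_t] <- 1L else m[i, tgt_t] <- 0L
    }
  }
  m
}
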