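# shared fixtures and independent oracles for the test suite

# fast simulation config: coarser grid, same physics
tiny_config <- function(..., grid = c(0, 12, 4096)) {
  simulation_config(grid = grid, ...)
}

# independent minimal PLS1 reference: one predictive component, no
# orthogonal deflation (the five-line textbook NIPALS step)
pls1_oracle_scores <- function(X, y) {
  yc <- y - mean(y)
  w <- drop(crossprod(X, yc))
  w <- w / sqrt(sum(w^2))
  drop(X %*% w)
}

# random z-scored dataset with some y-correlated structure
rand_xy <- function(seed, n = 12, p = 8, signal = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  X[, 1] <- X[, 1] + signal * y
  X <- scale(X)
  attr(X, "scaled:center") <- attr(X, "scaled:scale") <- NULL
  list(X = X, y = y)
}

# brute-force relative betweenness via exhaustive shortest-path counting
brute_betweenness <- function(compounds, edges) {
  n <- length(compounds)
  adj <- matrix(FALSE, n, n, dimnames = list(compounds, compounds))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  # all simple paths between u and v by DFS; count the shortest ones
  paths <- function(u, v) {
    found <- list()
    walk <- function(cur, visited) {
      if (cur == v) { found[[length(found) + 1L]] <<- visited; return() }
      for (nxt in which(adj[cur, ]))
        if (!(nxt %in% visited)) walk(nxt, c(visited, nxt))
    }
    walk(u, u)
    if (!length(found)) return(NULL)
    len <- vapply(found, length, integer(1))
    found[len == min(len)]
  }
  btw <- setNames(numeric(n), compounds)
  for (u in seq_len(n - 1)) for (v in (u + 1):n) {
    sp <- paths(u, v)
    if (is.null(sp)) next
    for (pp in sp) {
      inner <- setdiff(pp, c(u, v))
      for (k in inner) btw[k] <- btw[k] + 1 / length(sp)
    }
  }
  btw / ((n - 1) * (n - 2) / 2)  # relative (normalized) centrality
}

# a few clean, well-separated singlet metabolites for targeted tests
toy_library <- function() {
  list(
    metabolite_spec("fumarate", mk_mult_df(6.50, 1, 0, 1),
                    base_concentration = 1, is_reference = TRUE),
    metabolite_spec("alpha", mk_mult_df(2.0, 1, 0, 1), base_concentration = 2),
    metabolite_spec("beta", mk_mult_df(7.5, 1, 0, 1), base_concentration = 1),
    metabolite_spec("gamma", mk_mult_df(9.0, 1, 0, 1), base_concentration = 1.5)
  )
}

mk_mult_df <- function(...) {
  m <- matrix(c(...), ncol = 4, byrow = TRUE)
  data.frame(center = m[, 1], n_lines = as.integer(m[, 2]),
             j_hz = m[, 3], relative_area = m[, 4])
}

# set built directly from an intensity matrix (descending ppm)
set_from_matrix <- function(ppm, mat, groups = NULL) {
  n <- nrow(mat)
  if (is.null(groups)) groups <- rep("g", n)
  nmr_spectrum_set(lapply(seq_len(n), function(i)
    nmr_spectrum(ppm, mat[i, ], paste0("s", i), groups[i])))
}
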