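# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation they check.

# Pearson correlation of manually averaged ranks, written out longhand.
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    }
    r
  }
  a <- avg_rank(x)
  b <- avg_rank(y)
  n <- length(a)
  num <- sum(a * b) - n * mean(a) * mean(b)
  den <- sqrt((sum(a^2) - n * mean(a)^2) * (sum(b^2) - n * mean(b)^2))
  num / den
}

# Naive all-pairs Spearman: one spearman computation per pair via stats::cor.
oracle_all_pairs <- function(mat, prefilter) {
  ids <- rownames(mat)
  out <- list()
  for (i in seq_len(nrow(mat) - 1L)) {
    for (j in (i + 1L):nrow(mat)) {
      if (stats::sd(mat[i, ]) == 0 || stats::sd(mat[j, ]) == 0) next
      r <- stats::cor(mat[i, ], mat[j, ], method = "spearman")
      if (abs(r) >= prefilter) {
        a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
        out[[length(out) + 1L]] <- data.frame(
          feature_a = a, feature_b = b, rho = r, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      rho = numeric(0)))
  }
  do.call(rbind, out)
}

# Sort an edge table canonically so two edge sets can be compared.
canon_edges <- function(e) {
  e <- data.frame(feature_a = e$feature_a, feature_b = e$feature_b,
                  rho = e$rho, stringsAsFactors = FALSE)
  e <- e[order(e$feature_a, e$feature_b), ]
  rownames(e) <- NULL
  e
}

# Exhaustive shortest paths on a small weighted graph given as an edge list
# (data.frame from_i, to_i, d). Enumerates all simple paths; returns the
# distance matrix and, per ordered pair, the shortest-path counts through
# each vertex -- enough to recompute closeness and betweenness from scratch.
oracle_paths <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from_i[k]; j <- edges$to_i[k]; d <- edges$d[k]
    adj[[i]] <- rbind(adj[[i]], c(j, d))
    adj[[j]] <- rbind(adj[[j]], c(i, d))
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw <- numeric(n)
  eps <- 1e-9
  for (s in seq_len(n - 1L)) {
    for (t in (s + 1L):n) {
      paths <- list()
      walk <- function(v, seen, len) {
        if (v == t) {
          paths[[length(paths) + 1L]] <<- list(len = len, via = seen)
          return()
        }
        if (is.null(adj[[v]])) return()
        for (k in seq_len(nrow(adj[[v]]))) {
          w <- adj[[v]][k, 1L]
          if (w %in% seen || w == s) next
          walk(w, c(seen, w), len + adj[[v]][k, 2L])
        }
      }
      walk(s, integer(0), 0)
      if (!length(paths)) next
      lens <- vapply(paths, `[[`, numeric(1), "len")
      dmin <- min(lens)
      dist[s, t] <- dist[t, s] <- dmin
      short <- paths[lens <= dmin + eps]
      sigma <- length(short)
      for (p in short) {
        inner <- setdiff(p$via, t)
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  clo <- numeric(n)
  for (v in seq_len(n)) {
    d <- dist[v, -v]
    reach <- sum(is.finite(d))
    clo[v] <- if (reach > 0) reach / sum(d[is.finite(d)]) else 0
  }
  list(dist = dist, betweenness = btw, closeness = clo)
}

# Exhaustive one-sample Wilcoxon signed-rank: enumerate all 2^n sign
# patterns of the observed |differences| ranks.
oracle_signed_rank_p <- function(values, mu) {
  d <- values - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  Ws <- numeric(2^n)
  for (code in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(code))[1:n]
    Ws[code + 1L] <- sum(r[signs == 1L])
  }
  lo <- mean(Ws <= W_obs + 1e-9)
  hi <- mean(Ws >= W_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# All permutations of 1..n (recursive; used only for small n).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# A random connected-ish weighted graph as a correlation edge table.
random_edge_table <- function(n_vertices, p_edge = 0.5) {
  ids <- sprintf("v%02d", seq_len(n_vertices))
  rows <- list()
  for (i in seq_len(n_vertices - 1L)) {
    for (j in (i + 1L):n_vertices) {
      if (stats::runif(1) < p_edge) {
        rho <- stats::runif(1, 0.05, 1) * sample(c(-1, 1), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_a = ids[i], feature_b = ids[j], rho = rho,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(feature_a = ids[1], feature_b = ids[2], rho = 0.5,
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
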