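# Independent oracles used to cross-check the package's persistence engine
# and landscape evaluator. Deliberately separate implementations: a full
# boundary-matrix reduction over GF(2) on the complete simplex list (all
# dimensions at once, plain R), an igraph minimum spanning tree for the
# dimension-0 deaths, and a direct sort-all-tents landscape evaluator.

# Full-reduction Rips persistence oracle, dimensions 0 and 1.
# Edges are unrestricted (dimension 0 uses the full filtration); triangles
# are restricted to filtration value <= threshold; dimension-1 bars are
# reported only for births <= threshold, matching compute_diagram().
oracle_rips <- function(xy, threshold) {
  n <- nrow(xy)
  dm <- as.matrix(stats::dist(xy))

  verts <- lapply(seq_len(n), function(i) list(v = i, dim = 0L, filt = 0))
  edges <- list()
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    edges[[length(edges) + 1]] <- list(v = c(i, j), dim = 1L, filt = dm[i, j])
  }
  tris <- list()
  if (n >= 3) {
    for (i in seq_len(n - 2)) for (j in seq.int(i + 1, n - 1)) {
      for (k in seq.int(j + 1, n)) {
        f <- max(dm[i, j], dm[i, k], dm[j, k])
        if (f <= threshold) {
          tris[[length(tris) + 1]] <- list(v = c(i, j, k), dim = 2L, filt = f)
        }
      }
    }
  }
  simps <- c(verts, edges, tris)

  # global order: (filtration, dimension, lexicographic vertex tuple)
  filts <- vapply(simps, `[[`, numeric(1), "filt")
  dims <- vapply(simps, `[[`, integer(1), "dim")
  vkeys <- vapply(simps, function(s)
    paste(sprintf("%06d", s$v), collapse = ","), character(1))
  ord <- order(filts, dims, vkeys, method = "radix")
  simps <- simps[ord]
  pos_of <- new.env(hash = TRUE)
  for (idx in seq_along(simps)) {
    assign(paste(simps[[idx]]$v, collapse = "-"), idx, envir = pos_of)
  }

  boundary <- function(s) {
    if (s$dim == 0L) return(integer(0))
    faces <- utils::combn(s$v, length(s$v) - 1, simplify = FALSE)
    sort(vapply(faces, function(f)
      get(paste(f, collapse = "-"), envir = pos_of), integer(1)))
  }

  m <- length(simps)
  pivots <- vector("list", m)      # pivot row -> reduced column
  killer <- rep(NA_integer_, m)    # pivot row -> column index that kills it
  for (j in seq_len(m)) {
    col <- boundary(simps[[j]])
    while (length(col) > 0) {
      low <- col[length(col)]
      if (is.null(pivots[[low]])) break
      other <- pivots[[low]]
      col <- sort(c(setdiff(col, other), setdiff(other, col)))
    }
    if (length(col) > 0) {
      low <- col[length(col)]
      pivots[[low]] <- col
      killer[low] <- j
    }
  }

  bars <- list()
  killed <- !is.na(killer)
  has_killer_col <- logical(m)
  has_killer_col[killer[killed]] <- TRUE
  for (i in seq_len(m)) {
    s <- simps[[i]]
    if (has_killer_col[i]) next            # negative simplex: kills, no bar
    if (killed[i]) {
      d <- simps[[killer[i]]]$filt
      if (d > s$filt) {
        bars[[length(bars) + 1]] <- c(s$dim, s$filt, d)
      }
    } else if (s$dim <= 1L) {
      bars[[length(bars) + 1]] <- c(s$dim, s$filt, Inf)
    }
  }
  out <- do.call(rbind, bars)
  out <- tibble::tibble(dimension = as.integer(out[, 1]),
                        birth = out[, 2], death = out[, 3])
  out <- out[!(out$dimension == 1 & out$birth > threshold), ]
  dplyr::arrange(out, .data$dimension, .data$birth, .data$death)
}

# Euclidean MST edge weights via igraph (independent of the union-find path).
oracle_mst_weights <- function(xy) {
  dm <- as.matrix(stats::dist(xy))
  g <- igraph::graph_from_adjacency_matrix(dm, mode = "undirected",
                                           weighted = TRUE)
  sort(igraph::E(igraph::mst(g))$weight)
}

# Brute-force landscape evaluator: all tent values at each t, sorted.
oracle_landscape <- function(bars, k, t) {
  vapply(t, function(tt) {
    vals <- pmax(0, pmin(tt - bars$birth, bars$death - tt))
    vals <- sort(vals, decreasing = TRUE)
    if (length(vals) < k) 0 else vals[k]
  }, numeric(1))
}

# Sorted comparison of two diagrams up to floating-point tolerance.
expect_same_bars <- function(a, b, tol = 1e-9) {
  for (d in 0:1) {
    ba <- dplyr::arrange(a[a$dimension == d, ], .data$birth, .data$death)
    bb <- dplyr::arrange(b[b$dimension == d, ], .data$birth, .data$death)
    expect_equal(nrow(ba), nrow(bb),
                 info = sprintf("bar count mismatch in dim %d", d))
    expect_equal(ba$birth, bb$birth, tolerance = tol)
    expect_equal(ba$death, bb$death, tolerance = tol)
  }
}

random_cloud <- function(n, seed, scale = 1) {
  set.seed(seed)
  tibble::tibble(x = runif(n) * scale, y = runif(n) * scale)
}
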