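# Independent brute-force oracles used across the suite.  These deliberately
# use naive algorithms (path walking, exhaustive enumeration, double loops)
# so they share no code with the implementations they check.

# per-cell upstream counts by walking every cell's downstream path
oracle_accumulation <- function(d8) {
  nr <- nrow(d8); nc <- ncol(d8)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  acc <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(d8[r, c])) next
    rr <- r; cc <- c
    repeat {
      acc[rr, cc] <- acc[rr, cc] + 1L
      k <- d8[rr, cc]
      if (is.na(k) || k == 0L) break
      rr2 <- rr + dr[k]; cc2 <- cc + dc[k]
      rr <- rr2; cc <- cc2
    }
  }
  acc[is.na(d8)] <- NA_integer_
  acc
}

# cells whose downstream walk passes through `point`
oracle_catchment <- function(d8, point) {
  nr <- nrow(d8); nc <- ncol(d8)
  dr <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dc <- c(0, 1, 1, 1, 0, -1, -1, -1)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(d8[r, c])) next
    rr <- r; cc <- c
    repeat {
      if (rr == point[1] && cc == point[2]) { out[r, c] <- TRUE; break }
      k <- d8[rr, cc]
      if (is.na(k) || k == 0L) break
      rr2 <- rr + dr[k]; cc2 <- cc + dc[k]
      rr <- rr2; cc <- cc2
    }
  }
  out
}

# naive queue flood fill, 4-connected, over an eligibility mask
oracle_flood_fill <- function(eligible, seed_cell) {
  nr <- nrow(eligible); nc <- ncol(eligible)
  out <- matrix(FALSE, nr, nc)
  if (!eligible[seed_cell[1], seed_cell[2]]) return(out)
  queue <- list(seed_cell)
  out[seed_cell[1], seed_cell[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      q <- p + d
      if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
          eligible[q[1], q[2]] && !out[q[1], q[2]]) {
        out[q[1], q[2]] <- TRUE
        queue <- c(queue, list(q))
      }
    }
  }
  out
}

random_dem <- function(nr, nc, seed) {
  set.seed(seed)
  z <- matrix(cumsum(rnorm(nr * nc, 0, 1)), nr, nc)
  z <- z + 2 * (row(z) + col(z))     # mild overall tilt, still with pits
  grid_raster(z + matrix(rnorm(nr * nc, 0, 3), nr, nc))
}

# random single-outlet basin tree with areas
random_basin_tree <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  ids <- sprintf("b%02d", seq_len(n))
  basin_set(ids, ifelse(is.na(parent), NA, ids[parent]),
            area = runif(n, 1, 10))
}

oracle_ancestors <- function(bs, s0) {
  out <- character(0)
  for (id in bs$id) {
    if (id == s0) next
    j <- id
    repeat {
      j <- bs$downstream[match(j, bs$id)]
      if (is.na(j)) break
      if (j == s0) { out <- c(out, id); break }
    }
  }
  out
}

# random dam-node river network in to_tree() input form: dams sit between
# river nodes on a random tree of confluences
random_dam_network <- function(n_dams, seed) {
  set.seed(seed)
  dam_ids <- sprintf("d%02d", seq_len(n_dams))
  nodes <- data.frame(id = c("outlet", dam_ids, paste0("r_", dam_ids)),
                      type = c("outlet", rep("dam", n_dams),
                               rep("river", n_dams)),
                      stringsAsFactors = FALSE)
  down <- vapply(seq_len(n_dams), function(i) {
    if (i == 1L) "outlet" else paste0("r_", dam_ids[sample.int(i - 1L, 1L)])
  }, character(1))
  edges <- data.frame(from = c(down, dam_ids),
                      to = c(dam_ids, paste0("r_", dam_ids)),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

random_assets <- function(ids, seed, p_existing = 0.3) {
  set.seed(seed)
  n <- length(ids)
  asset_metrics(data.frame(
    id = ids, type = sample(c("reservoir", "ror"), n, TRUE, c(0.8, 0.2)),
    energy = runif(n, 1, 100), firm = runif(n, 0.5, 20),
    emissions_model = runif(n, 0, 5000), emissions_ef = runif(n, 0, 5000),
    cropland_loss = 0, forest_loss = 0,
    existing = runif(n) < p_existing, stringsAsFactors = FALSE))
}

# exhaustive portfolio enumeration: realised objective matrix (2^n x p)
enumerate_portfolios <- function(assets, edge_assets, objectives,
                                 forced = character(0)) {
  n <- length(edge_assets)
  vals <- vapply(objectives, function(o)
    assets[[o$metric]][match(edge_assets, assets$id)], numeric(n))
  vals <- matrix(vals, nrow = n)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  if (length(forced)) {
    keep <- rowSums(subsets[, match(forced, edge_assets), drop = FALSE]) ==
      length(forced)
    subsets <- subsets[keep, , drop = FALSE]
  }
  t(apply(subsets, 1L, function(sel) {
    vapply(seq_along(objectives), function(j) {
      v <- vals[sel, j]
      if (objectives[[j]]$aggregation == "sum") sum(v)
      else if (length(v)) mean(v) else 0
    }, numeric(1))
  }))
}

# independent O(m^2) Pareto filter on a max-sense matrix; returns the
# unique non-dominated vectors, lexicographically sorted
oracle_pareto_vectors <- function(M) {
  M <- unique(M)
  m <- nrow(M)
  keep <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (!keep[i]) next
    dom <- rowSums(M >= rep(M[i, ], each = m)) == ncol(M) &
      rowSums(M > rep(M[i, ], each = m)) > 0
    if (any(dom)) keep[i] <- FALSE
  }
  out <- M[keep, , drop = FALSE]
  out[do.call(order, lapply(seq_len(ncol(out)), function(j) out[, j])), ,
      drop = FALSE]
}

# orientation/normalisation used for epsilon-dominance checks, recomputed
# independently from single-asset extrema
scale_objectives <- function(M, assets, edge_assets, objectives) {
  for (j in seq_along(objectives)) {
    o <- objectives[[j]]
    v <- assets[[o$metric]][match(edge_assets, assets$id)]
    w <- diff(range(v)); if (w == 0) w <- 1
    s <- if (o$sense == "max") 1 else -1
    M[, j] <- M[, j] * s / w
  }
  M
}

expect_same_vector_set <- function(A, B, tol = 1e-9) {
  A <- round(A / tol) * tol
  B <- round(B / tol) * tol
  key <- function(M) sort(apply(M, 1L, paste, collapse = "|"))
  expect_equal(key(unique(A)), key(unique(B)))
}

small_fleet <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(seed = 7, grid_size = 28L, n_dams = 10L)
      ls <- synth_landscape(cfg)
      cache <<- list(cfg = cfg, landscape = ls,
                     fleet = synth_fleet(cfg, ls))
    }
    cache
  }
})
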