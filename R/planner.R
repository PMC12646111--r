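#' Asset metrics tables
#'
#' One row per candidate hydropower asset: annual energy and firm power,
#' annual emissions under each estimation method, impounded cropland and
#' forest areas, and whether the asset already exists.  Run-of-river (RoR)
#' assets inundate no land, so their cropland and forest losses are zero.
#'
#' @param df Data frame with columns `id`, `type` (`"reservoir"` or
#'   `"ror"`), `energy` (GWh/yr), `firm` (GWh/yr), `emissions_model`,
#'   `emissions_ef` (tCO2e/yr), `cropland_loss`, `forest_loss` (km2),
#'   `existing` (logical).
#' @return The validated table (class `asset_metrics`).
#' @export
asset_metrics <- function(df) {
  need <- c("id", "type", "energy", "firm", "emissions_model",
            "emissions_ef", "cropland_loss", "forest_loss", "existing")
  check_columns(df, need, "asset")
  if (anyDuplicated(df$id)) row_fail("asset", which(duplicated(df$id)),
                                     "duplicated asset id")
  num <- c("energy", "firm", "emissions_model", "emissions_ef",
           "cropland_loss", "forest_loss")
  for (cn in num) {
    bad <- which(!is.finite(df[[cn]]))
    if (length(bad)) row_fail("asset", bad, sprintf("non-finite %s", cn))
  }
  bad <- which(df$type == "ror" & (df$cropland_loss != 0 | df$forest_loss != 0))
  if (length(bad)) row_fail("asset", bad, "RoR assets must have zero land loss")
  class(df) <- unique(c("asset_metrics", class(df)))
  df
}

#' Build the dam-as-edge tree network
#'
#' River planning networks describe dams as nodes on a river graph.  The
#' planner instead works on the line-graph-style representation in which
#' nodes are contiguous dam-free river regions and dams are directed edges
#' oriented from the downstream region (outlet side) to the upstream region
#' (source side).  Consecutive dam-free stretches merge into a single node;
#' the root is the region containing the outlet.
#'
#' @param nodes Data frame with columns `id` and `type`; dams carry type
#'   `"dam"`, all other types are river/junction/outlet nodes.
#' @param edges Data frame with columns `from`, `to`, each edge oriented
#'   from the downstream node to the upstream node.
#' @return A list of class `tree_network`: `regions` (character ids),
#'   `root`, and `edges` (data frame `asset`, `downstream`, `upstream`).
#' @section Errors: `resghg_cyclic_input` for cyclic or disconnected
#'   inputs; `resghg_multiple_outlets` when more than one node lacks a
#'   downstream link.
#' @export
to_tree <- function(nodes, edges) {
  check_columns(nodes, c("id", "type"), "node")
  check_columns(edges, c("from", "to"), "edge")
  ids <- as.character(nodes$id)
  if (anyDuplicated(ids)) abort("duplicated node ids", "resghg_bad_argument")
  from <- as.character(edges$from); to <- as.character(edges$to)
  if (!all(c(from, to) %in% ids)) {
    abort("edge endpoints must be declared nodes", "resghg_schema_error")
  }
  roots <- setdiff(ids, to)
  if (length(roots) != 1L) {
    abort(sprintf("expected a single outlet node, found %d", length(roots)),
          "resghg_multiple_outlets")
  }
  if (any(table(to) > 1L) || nrow(edges) != length(ids) - 1L) {
    abort("input graph is not a tree oriented away from the outlet",
          "resghg_cyclic_input")
  }
  is_dam <- nodes$type[match(ids, ids)] == "dam"
  names(is_dam) <- ids

  # union-find over river (non-dam) nodes joined by dam-free edges
  parent_uf <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent_uf[[x]] != x) {
      parent_uf[[x]] <<- parent_uf[[parent_uf[[x]]]]
      x <- parent_uf[[x]]
    }
    x
  }
  for (k in seq_along(from)) {
    if (!is_dam[[from[k]]] && !is_dam[[to[k]]]) {
      parent_uf[[find(from[k])]] <- find(to[k])
    }
  }
  region_of <- vapply(ids, find, character(1))

  dams <- ids[is_dam]
  down_nb <- stats::setNames(from[match(ids, to)], ids)  # downstream neighbour
  out_edges <- lapply(dams, function(d) {
    dn <- down_nb[[d]]
    if (is.na(dn) || is_dam[[dn]]) {
      abort(sprintf("dam '%s' must sit between river nodes", d),
            "resghg_schema_error")
    }
    ups <- to[from == d]
    ups <- ups[!is_dam[ups]]
    if (length(ups) > 1L) {
      abort(sprintf("dam '%s' has multiple upstream branches", d),
            "resghg_schema_error")
    }
    up_region <- if (length(ups)) region_of[[ups]] else paste0(d, ".headwater")
    data.frame(asset = d, downstream = region_of[[dn]],
               upstream = up_region, stringsAsFactors = FALSE)
  })
  ed <- do.call(rbind, c(out_edges,
                         list(data.frame(asset = character(0),
                                         downstream = character(0),
                                         upstream = character(0)))))
  regions <- unique(c(region_of[!is_dam[ids]], ed$upstream))
  if (nrow(ed) && anyDuplicated(ed$upstream)) {
    abort("a region has more than one downstream dam", "resghg_cyclic_input")
  }
  structure(list(regions = regions, root = region_of[[roots]], edges = ed),
            class = "tree_network")
}

#' @export
print.tree_network <- function(x, ...) {
  cat(sprintf("tree_network: %d regions, %d dams, root '%s'\n",
              length(x$regions), nrow(x$edges), x$root))
  invisible(x)
}

#' Objective specifications
#'
#' @param name Display name of the objective.
#' @param metric Column of the [asset_metrics()] table supplying per-asset
#'   values.
#' @param sense `"max"` or `"min"`.
#' @param aggregation `"sum"` or `"mean"` across selected assets (means are
#'   0 for the empty portfolio).
#' @return A list of class `objective_spec`.
#' @export
objective_spec <- function(name, metric, sense = c("max", "min"),
                           aggregation = c("sum", "mean")) {
  structure(list(name = name, metric = metric, sense = match.arg(sense),
                 aggregation = match.arg(aggregation)),
            class = "objective_spec")
}

#' Default planning objectives
#'
#' Total annual hydropower production and firm power are maximised (sums);
#' GHG emissions, cropland loss and forest loss are minimised.  Emissions
#' default to the sum aggregation (total portfolio emissions); land losses
#' default to means across selected assets, with sum variants available by
#' building the specs directly.
#'
#' @param emission_method `"model"` (empirical pathway model) or `"ef"`
#'   (Tier 1 emission factors).
#' @param emission_aggregation `"sum"` or `"mean"`.
#' @return A list of [objective_spec()]s.
#' @export
default_objectives <- function(emission_method = c("model", "ef"),
                               emission_aggregation = c("sum", "mean")) {
  emission_method <- match.arg(emission_method)
  emission_aggregation <- match.arg(emission_aggregation)
  list(
    objective_spec("hydropower", "energy", "max", "sum"),
    objective_spec("firm power", "firm", "max", "sum"),
    objective_spec("ghg emissions", paste0("emissions_", emission_method),
                   "min", emission_aggregation),
    objective_spec("cropland loss", "cropland_loss", "min", "mean"),
    objective_spec("forest loss", "forest_loss", "min", "mean")
  )
}

#' Firm power from a generation time series
#'
#' The dependable generation level: the 5th percentile of the series,
#' computed with the linear-interpolation quantile convention (R type 7).
#' The series is assumed to be expressed as an annualised rate (e.g.
#' GWh/yr-equivalent per timestep); `annualize` rescales otherwise (use
#' 365.25/7 for weekly energy totals).
#'
#' @param series Numeric generation series (length >= 20).
#' @param probability Percentile defining firmness (default 0.05).
#' @param annualize Multiplier applied to the percentile.
#' @return Firm power in the annualised unit.
#' @export
firm_power <- function(series, probability = 0.05, annualize = 1) {
  if (length(series) < 20L) {
    abort("generation series too short (need >= 20 values)",
          "resghg_series_too_short")
  }
  stats::quantile(series, probability, names = FALSE, type = 7) * annualize
}

# ---- epsilon-Pareto dynamic program ----------------------------------------

# Per-objective orientation (+1 max, -1 min) and normalisation width from
# single-asset extrema.
objective_scaling <- function(assets, objectives) {
  sgn <- vapply(objectives, function(o) if (o$sense == "max") 1 else -1,
                numeric(1))
  w <- vapply(objectives, function(o) {
    v <- assets[[o$metric]]
    r <- diff(range(v))
    if (r > 0) r else 1
  }, numeric(1))
  list(sign = sgn, width = w)
}

# Pareto filter on a max-sense matrix; returns indices of non-dominated
# rows (duplicates keep their first occurrence).
pareto_filter <- function(M) {
  m <- nrow(M)
  if (m <= 1L) return(seq_len(m))
  if (ncol(M) == 2L) {
    # sort by decreasing first objective; keep strictly increasing second
    o <- order(-M[, 1], -M[, 2])
    best <- cummax(c(-Inf, M[o, 2]))[seq_len(m)]
    keep <- M[o, 2] > best
    keep[1] <- TRUE
    dup <- duplicated(M[o, , drop = FALSE])
    return(sort(o[keep & !dup]))
  }
  o <- do.call(order, c(lapply(seq_len(ncol(M)), function(j) -M[, j])))
  keep <- integer(0)
  Mo <- M[o, , drop = FALSE]
  for (i in seq_len(m)) {
    x <- Mo[i, ]
    if (length(keep)) {
      K <- Mo[keep, , drop = FALSE]
      dominated <- any(rowSums(K >= rep(x, each = length(keep))) == ncol(M) &
                         rowSums(K > rep(x, each = length(keep))) > 0)
      if (dominated) next
      dup <- any(rowSums(K == rep(x, each = length(keep))) == ncol(M))
      if (dup) next
    }
    keep <- c(keep, i)
  }
  sort(o[keep])
}

# Prune a DP state set.  acc: m x p matrix of scaled (max-sense, normalised)
# objective accumulators; n: selected-asset counts; cell: grid width (0 =
# exact).  Mean-aggregated objectives make states with different n
# incomparable, so dominance is applied within equal-n groups only.
prune_states <- function(acc, n, ports, cell, need_n_groups) {
  if (cell > 0) {
    key <- apply(floor(acc / cell + 1e-9), 1L, paste, collapse = ",")
    if (need_n_groups) key <- paste(key, n)
    first <- !duplicated(key)
    acc <- acc[first, , drop = FALSE]
    n <- n[first]; ports <- ports[first]
  }
  groups <- if (need_n_groups) split(seq_along(n), n) else list(seq_along(n))
  keep <- unlist(lapply(groups, function(ix) {
    ix[pareto_filter(acc[ix, , drop = FALSE])]
  }), use.names = FALSE)
  keep <- sort(keep)
  list(acc = acc[keep, , drop = FALSE], n = n[keep], ports = ports[keep])
}

# worst-case number of prune events any state passes through, used to split
# the epsilon budget across DP merges
prune_depth <- function(children_of, root) {
  depth <- function(r) {
    kids <- children_of[[r]]
    if (is.null(kids) || !nrow(kids)) return(0L)
    p <- vapply(kids$upstream, depth, integer(1))
    p <- sort(p)
    max(p + rev(seq_along(p)))
  }
  depth(root)
}

#' Approximate the Pareto frontier of dam portfolios
#'
#' Bottom-up dynamic program over the rooted region tree.  Each subtree
#' carries a set of (partial portfolio, objective accumulator) states;
#' child branches merge by accumulator addition (mean-aggregated objectives
#' are carried as sums plus a selected-asset count, so merging stays
#' exact).  States are pruned by dominance, and -- for `epsilon > 0` -- by
#' an accumulator grid whose cell width divides the epsilon budget across
#' the merge depth, so that every feasible portfolio ends within
#' `epsilon/2` (normalised, additively) of a surviving state.  The root
#' set is then reduced with a final greedy `epsilon/2`-thinning.  Every
#' feasible objective vector is therefore epsilon-dominated by some
#' returned point; returned vectors are exact, recomputed from the
#' portfolio.  With `epsilon = 0` the result is the exact Pareto set.
#'
#' Normalisation ranges per objective come from single-asset extrema and
#' are recorded in the result.
#'
#' @param net A [to_tree()] network.
#' @param assets An [asset_metrics()] table covering every edge asset.
#' @param objectives List of [objective_spec()]s.
#' @param epsilon Approximation precision in normalised objective units
#'   (>= 0).
#' @param scenario `"not_built"` leaves every asset free; `"built"` forces
#'   existing assets into every portfolio.
#' @return A list of class `pareto_frontier`: `points` (data frame of
#'   objective values, one column per objective), `portfolios` (list of
#'   asset-id vectors), plus the run metadata.
#' @export
epsilon_pareto <- function(net, assets, objectives, epsilon = 0,
                           scenario = c("not_built", "built")) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(net, "tree_network"))
  assets <- asset_metrics(assets)
  stopifnot_number(epsilon, "epsilon", min = 0)
  if (!nrow(net$edges)) abort("empty tree network", "resghg_empty_tree")
  if (!all(net$edges$asset %in% assets$id)) {
    abort("every dam edge needs a row in the asset table",
          "resghg_schema_error")
  }
  p <- length(objectives)
  sc <- objective_scaling(assets, objectives)
  vals <- vapply(objectives, function(o) {
    assets[[o$metric]][match(net$edges$asset, assets$id)]
  }, numeric(nrow(net$edges)))
  vals <- matrix(vals, nrow = nrow(net$edges), ncol = p)
  scaled_vals <- sweep(vals, 2L, sc$sign / sc$width, `*`)
  forced <- scenario == "built" &
    assets$existing[match(net$edges$asset, assets$id)]
  need_n <- any(vapply(objectives, function(o) o$aggregation == "mean",
                       logical(1)))

  children_of <- split(cbind(net$edges,
                             edge_i = seq_len(nrow(net$edges))),
                       factor(net$edges$downstream, levels = net$regions))
  D <- max(1L, prune_depth(children_of, net$root))
  cell <- if (epsilon > 0) epsilon / (2 * D) else 0

  solve_region <- function(region) {
    acc <- matrix(0, 1L, p); n <- 0L; ports <- list(integer(0))
    kids <- children_of[[region]]
    if (!is.null(kids) && nrow(kids)) {
      # merge deeper branches last: minimises the prune depth bound
      ord <- order(vapply(kids$upstream, function(u)
        prune_depth(children_of, u), integer(1)))
      for (k in ord) {
        e <- kids$edge_i[k]
        sub <- solve_region(kids$upstream[k])
        # extend child states with the include/exclude choice for this dam
        inc_acc <- sweep(sub$acc, 2L, scaled_vals[e, ], `+`)
        inc_n <- sub$n + 1L
        inc_ports <- lapply(sub$ports, function(ix) c(ix, e))
        if (forced[e]) {
          br <- list(acc = inc_acc, n = inc_n, ports = inc_ports)
        } else {
          br <- list(acc = rbind(sub$acc, inc_acc),
                     n = c(sub$n, inc_n),
                     ports = c(sub$ports, inc_ports))
        }
        # cross-sum with the accumulated states of earlier branches
        m1 <- nrow(acc); m2 <- nrow(br$acc)
        i1 <- rep(seq_len(m1), times = m2)
        i2 <- rep(seq_len(m2), each = m1)
        acc <- acc[i1, , drop = FALSE] + br$acc[i2, , drop = FALSE]
        n <- n[i1] + br$n[i2]
        ports <- mapply(function(a, b) c(ports[[a]], br$ports[[b]]),
                        i1, i2, SIMPLIFY = FALSE)
        pruned <- prune_states(acc, n, ports, cell, need_n)
        acc <- pruned$acc; n <- pruned$n; ports <- pruned$ports
      }
    }
    list(acc = acc, n = n, ports = ports)
  }

  root_states <- solve_region(net$root)

  # realise exact objective vectors from the portfolios
  realise <- function(ix) {
    vapply(seq_len(p), function(j) {
      v <- vals[ix, j]
      if (objectives[[j]]$aggregation == "sum") sum(v)
      else if (length(ix)) mean(v) else 0
    }, numeric(1))
  }
  pts <- t(vapply(root_states$ports, realise, numeric(p)))
  scaled_pts <- sweep(pts, 2L, sc$sign / sc$width, `*`)
  nd <- pareto_filter(scaled_pts)
  pts <- pts[nd, , drop = FALSE]
  scaled_pts <- scaled_pts[nd, , drop = FALSE]
  ports <- root_states$ports[nd]

  if (epsilon > 0 && nrow(pts) > 1L) {
    o <- order(-rowSums(scaled_pts))
    keep <- integer(0)
    half <- epsilon / 2
    for (i in o) {
      if (!length(keep)) { keep <- i; next }
      K <- scaled_pts[keep, , drop = FALSE]
      covered <- any(rowSums(K >= rep(scaled_pts[i, ] - half,
                                      each = length(keep))) == p)
      if (!covered) keep <- c(keep, i)
    }
    keep <- sort(keep)
    pts <- pts[keep, , drop = FALSE]
    ports <- ports[keep]
  }

  colnames(pts) <- vapply(objectives, `[[`, character(1), "name")
  structure(list(points = as.data.frame(pts),
                 portfolios = lapply(ports, function(ix)
                   net$edges$asset[sort(ix)]),
                 objectives = objectives, epsilon = epsilon,
                 scenario = scenario,
                 normalization = data.frame(
                   objective = colnames(pts), sign = sc$sign,
                   width = sc$width)),
            class = "pareto_frontier")
}

#' @export
print.pareto_frontier <- function(x, ...) {
  cat(sprintf("epsilon-Pareto frontier: %d points, epsilon = %g, scenario %s\n",
              nrow(x$points), x$epsilon, x$scenario))
  print(utils::head(x$points, 10L))
  if (nrow(x$points) > 10L) cat("...\n")
  invisible(x)
}

#' @export
plot.pareto_frontier <- function(x, objectives = c(1L, 3L), ...) {
  pts <- x$points[, objectives, drop = FALSE]
  graphics::plot(pts[[1]], pts[[2]], xlab = names(pts)[1],
                 ylab = names(pts)[2],
                 main = sprintf("Pareto frontier (epsilon = %g)", x$epsilon),
                 pch = 19, ...)
  invisible(x)
}

#' Tabular frontier report
#'
#' One row per frontier point: portfolio size, total hydropower and firm
#' power, total emissions under both methods, emission intensity (g/kWh),
#' firm-power ratio and land losses, sorted by increasing hydropower.
#'
#' @param frontier A [epsilon_pareto()] result.
#' @param assets The [asset_metrics()] table used to build it.
#' @return A data frame.
#' @export
frontier_report <- function(frontier, assets) {
  stopifnot(inherits(frontier, "pareto_frontier"))
  if (!nrow(frontier$points)) abort("empty frontier", "resghg_bad_argument")
  rows <- lapply(frontier$portfolios, function(ids) {
    a <- assets[match(ids, assets$id), , drop = FALSE]
    energy <- sum(a$energy)
    em_model <- sum(a$emissions_model)
    em_ef <- sum(a$emissions_ef)
    data.frame(
      n_assets = length(ids),
      energy = energy,
      firm = sum(a$firm),
      firm_ratio = if (energy > 0) sum(a$firm) / energy else NA_real_,
      emissions_model = em_model,
      emissions_ef = em_ef,
      ei_model = if (energy > 0) em_model / energy else NA_real_,
      ei_ef = if (energy > 0) em_ef / energy else NA_real_,
      cropland_loss = sum(a$cropland_loss),
      forest_loss = sum(a$forest_loss))
  })
  out <- do.call(rbind, rows)
  out$portfolio <- vapply(frontier$portfolios, paste, character(1),
                          collapse = ";")
  out[order(out$energy), , drop = FALSE]
}
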