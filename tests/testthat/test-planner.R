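test_that("dam-node graphs become dam-as-edge trees", {
  # single dam on a single river
  net1 <- to_tree(data.frame(id = c("out", "d1", "up"),
                             type = c("outlet", "dam", "river")),
                  data.frame(from = c("out", "d1"), to = c("d1", "up")))
  expect_equal(length(net1$regions), 2L)
  expect_equal(nrow(net1$edges), 1L)
  # Y-shaped network with three dams: four regions, three edges
  nodes <- data.frame(
    id = c("out", "d1", "j", "d2", "s1", "d3", "s2"),
    type = c("outlet", "dam", "river", "dam", "river", "dam", "river"))
  edges <- data.frame(from = c("out", "d1", "j", "d2", "j", "d3"),
                      to = c("d1", "j", "d2", "s1", "d3", "s2"))
  netY <- to_tree(nodes, edges)
  expect_equal(length(netY$regions), 4L)
  expect_equal(nrow(netY$edges), 3L)
  expect_equal(netY$root, "out")
  # random trees: edge count equals dam count, all dams present
  for (seed in 1:15) {
    n <- sample(2:50, 1)
    g <- random_dam_network(n, seed)
    net <- to_tree(g$nodes, g$edges)
    expect_equal(nrow(net$edges), n)
    expect_setequal(net$edges$asset, g$nodes$id[g$nodes$type == "dam"])
  }
  # cycles and multiple outlets are rejected
  expect_error(to_tree(data.frame(id = c("a", "b"), type = c("river", "river")),
                       data.frame(from = c("a", "b"), to = c("b", "a"))),
               class = "resghg_multiple_outlets")
})

test_that("firm power is the order-free interpolated 5th percentile", {
  expect_equal(firm_power(rep(7.5, 30)), 7.5)
  s <- 1:100
  # independent sort/interpolation oracle for the type-7 convention
  h <- (100 - 1) * 0.05 + 1
  oracle <- sort(s)[floor(h)] + (h - floor(h)) *
    (sort(s)[ceiling(h)] - sort(s)[floor(h)])
  expect_equal(firm_power(s), oracle)
  set.seed(1)
  expect_equal(firm_power(sample(s)), firm_power(s))
  expect_equal(firm_power(rep(2, 52), annualize = 365.25 / 7),
               2 * 365.25 / 7)
  expect_error(firm_power(1:5), class = "resghg_series_too_short")
})

test_that("a single dam yields the two-point frontier", {
  g <- random_dam_network(1, 3)
  net <- to_tree(g$nodes, g$edges)
  assets <- random_assets("d01", seed = 3, p_existing = 0)
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"))
  fr <- epsilon_pareto(net, assets, obj, epsilon = 0)
  expect_equal(nrow(fr$points), 2L)
  expect_setequal(vapply(fr$portfolios, length, integer(1)), c(0L, 1L))
})

test_that("exact frontiers equal brute-force enumeration on random trees", {
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"),
              objective_spec("land", "forest_loss", "min", "mean"))
  for (seed in 1:40) {
    n <- sample(4:10, 1)
    g <- random_dam_network(n, seed)
    net <- to_tree(g$nodes, g$edges)
    set.seed(seed + 1000)
    assets <- asset_metrics(data.frame(
      id = net$edges$asset, type = "reservoir",
      energy = runif(n, 1, 100), firm = runif(n, 1, 10),
      emissions_model = runif(n, 0, 1000), emissions_ef = runif(n, 0, 1000),
      cropland_loss = runif(n, 0, 5), forest_loss = runif(n, 0, 5),
      existing = FALSE))
    fr <- epsilon_pareto(net, assets, obj, epsilon = 0)
    enum <- enumerate_portfolios(assets, net$edges$asset, obj)
    sc_enum <- scale_objectives(enum, assets, net$edges$asset, obj)
    oracle <- oracle_pareto_vectors(sc_enum)
    got <- scale_objectives(as.matrix(fr$points), assets, net$edges$asset,
                            obj)
    expect_same_vector_set(got, oracle)
  }
})

test_that("epsilon coverage holds against enumeration", {
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"),
              objective_spec("firm", "firm", "max", "sum"))
  for (seed in 101:115) {
    n <- sample(8:12, 1)
    g <- random_dam_network(n, seed)
    net <- to_tree(g$nodes, g$edges)
    assets <- random_assets(net$edges$asset, seed, p_existing = 0)
    enum <- enumerate_portfolios(assets, net$edges$asset, obj)
    sc_enum <- scale_objectives(enum, assets, net$edges$asset, obj)
    for (eps in c(0.01, 0.05)) {
      fr <- epsilon_pareto(net, assets, obj, epsilon = eps)
      got <- scale_objectives(as.matrix(fr$points), assets,
                              net$edges$asset, obj)
      # every feasible vector is epsilon-dominated by a returned point
      covered <- rep(FALSE, nrow(sc_enum))
      for (k in seq_len(nrow(got))) {
        covered <- covered |
          (rowSums(rep(got[k, ] + eps + 1e-12, each = nrow(sc_enum)) >=
                     sc_enum) == ncol(sc_enum))
      }
      expect_true(all(covered))
    }
  }
})

test_that("frontier size shrinks with epsilon and epsilon zero is exact", {
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"))
  for (seed in 201:215) {
    g <- random_dam_network(10, seed)
    net <- to_tree(g$nodes, g$edges)
    assets <- random_assets(net$edges$asset, seed, p_existing = 0)
    sizes <- vapply(c(0, 0.02, 0.04, 0.08, 0.16), function(eps)
      nrow(epsilon_pareto(net, assets, obj, epsilon = eps)$points),
      numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("the built scenario forces existing assets into every portfolio", {
  g <- random_dam_network(8, 77)
  net <- to_tree(g$nodes, g$edges)
  assets <- random_assets(net$edges$asset, 77, p_existing = 0.4)
  forced <- assets$id[assets$existing]
  fr <- epsilon_pareto(net, assets, default_objectives(), epsilon = 0,
                       scenario = "built")
  for (p in fr$portfolios) expect_true(all(forced %in% p))
  # every asset existing: the full portfolio is the only point
  assets2 <- assets; assets2$existing <- TRUE
  obj2 <- list(objective_spec("hp", "energy", "max", "sum"),
               objective_spec("ghg", "emissions_model", "min", "sum"))
  fr2 <- epsilon_pareto(net, assets2, obj2, epsilon = 0, scenario = "built")
  expect_equal(nrow(fr2$points), 1L)
  expect_setequal(fr2$portfolios[[1]], assets2$id)
  # built-scenario frontier matches enumeration restricted to forced sets
  obj3 <- list(objective_spec("hp", "energy", "max", "sum"),
               objective_spec("ghg", "emissions_model", "min", "sum"))
  frb <- epsilon_pareto(net, assets, obj3, epsilon = 0, scenario = "built")
  enum <- enumerate_portfolios(assets, net$edges$asset, obj3, forced = forced)
  oracle <- oracle_pareto_vectors(
    scale_objectives(enum, assets, net$edges$asset, obj3))
  got <- scale_objectives(as.matrix(frb$points), assets, net$edges$asset,
                          obj3)
  expect_same_vector_set(got, oracle)
})

test_that("not-built frontiers weakly dominate built frontiers", {
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"))
  for (seed in 301:310) {
    g <- random_dam_network(9, seed)
    net <- to_tree(g$nodes, g$edges)
    assets <- random_assets(net$edges$asset, seed, p_existing = 0.4)
    nb <- epsilon_pareto(net, assets, obj, epsilon = 0)
    b <- epsilon_pareto(net, assets, obj, epsilon = 0, scenario = "built")
    # for every built point there is a not-built point at least as good
    for (i in seq_len(nrow(b$points))) {
      ok <- any(nb$points[[1]] >= b$points[i, 1] - 1e-9 &
                  nb$points[[2]] <= b$points[i, 2] + 1e-9)
      expect_true(ok)
    }
  }
})

test_that("frontier reports recompute intensities per portfolio", {
  g <- random_dam_network(5, 55)
  net <- to_tree(g$nodes, g$edges)
  set.seed(55)
  energy <- runif(5, 10, 50)
  assets <- asset_metrics(data.frame(
    id = net$edges$asset, type = "ror", energy = energy, firm = energy / 5,
    emissions_model = 3 * energy, emissions_ef = 3 * energy,
    cropland_loss = 0, forest_loss = 0, existing = FALSE))
  obj <- list(objective_spec("hp", "energy", "max", "sum"),
              objective_spec("ghg", "emissions_model", "min", "sum"))
  fr <- epsilon_pareto(net, assets, obj, epsilon = 0)
  rep <- frontier_report(fr, assets)
  expect_equal(nrow(rep), nrow(fr$points))
  expect_true(all(diff(rep$energy) >= 0))
  # an all-RoR portfolio reports the constant biogenic intensity exactly
  nonempty <- rep[rep$n_assets > 0, ]
  expect_equal(nonempty$ei_model, rep(3, nrow(nonempty)))
  # oracle: intensities recompute from per-asset sums
  for (i in seq_len(nrow(rep))) {
    ids <- strsplit(rep$portfolio[i], ";")[[1]]
    if (!length(ids)) next
    a <- assets[match(ids, assets$id), ]
    expect_equal(rep$ei_model[i], sum(a$emissions_model) / sum(a$energy))
  }
})
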