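make_comp <- function(values) {
  # values: genes x samples matrix with rownames
  build_compendium(values, NULL)
}

test_that("empirical_quantile follows the nearest-rank convention", {
  expect_equal(empirical_quantile(5, 0), 5)
  expect_equal(empirical_quantile(5, 73), 5)
  expect_equal(empirical_quantile(1:100, 0), 1)
  expect_equal(empirical_quantile(1:100, 100), 100)
  expect_equal(empirical_quantile(1:100, 50), 50)
  expect_error(empirical_quantile(numeric(0), 50), "empty")
  set.seed(3)
  for (i in 1:50) {
    v <- stats::rnorm(sample(1:40, 1))
    th <- stats::runif(1, 0, 100)
    s <- sort(v)
    expect_equal(empirical_quantile(v, th),
                 s[max(1, ceiling(th / 100 * length(s)))])
  }
})

test_that("compendium assembly pools reference and experiment columns", {
  ref <- matrix(1:12, 4, 3, dimnames = list(paste0("g", 1:4), NULL))
  exp <- matrix(1:8, 4, 2, dimnames = list(paste0("g", 1:4), NULL))
  comp <- build_compendium(ref, exp)
  expect_equal(dim(comp$values), c(4, 5))
  expect_equal(sum(comp$source == "reference"), 3)
  expect_equal(sum(comp$source == "experiment"), 2)

  rownames(exp) <- paste0("h", 1:4)
  expect_error(build_compendium(ref, exp), "no genes")
})

test_that("threshold types pool the right samples", {
  vals <- rbind(g1 = c(1, 2, 3), g2 = c(10, 20, 30))
  comp <- make_comp(vals)
  t2 <- compute_thresholds(comp, type = 2, theta = 50)
  expect_equal(unname(t2$x_g), c(2, 20))
  t1 <- compute_thresholds(comp, type = 1, theta = 50)
  pooled <- sort(c(vals))
  expect_equal(t1$x_global, pooled[ceiling(0.5 * 6)])
  t3 <- compute_thresholds(comp, type = 3, theta = 50)
  expect_equal(unname(t3$x_g), c(2, 20))
  expect_equal(unname(t3$sigma_g), c(sd(c(1, 2, 3)), sd(c(10, 20, 30))))
})

test_that("gene penalties are the thresholded shortfall", {
  spec2 <- structure(list(type = 2L, theta = 50, x_g = c(gA = 3)),
                     class = "threshold_spec")
  expect_equal(compute_gene_penalties(c(gA = 5), spec2)[["gA"]], 0)
  expect_equal(compute_gene_penalties(c(gA = 2), spec2)[["gA"]], 1)
  spec1 <- structure(list(type = 1L, theta = 50, x_global = 3),
                     class = "threshold_spec")
  expect_equal(compute_gene_penalties(c(gA = 2), spec1)[["gA"]], 1)
  spec3 <- structure(list(type = 3L, theta = 50, x_g = c(gA = 3),
                          sigma_g = c(gA = 0.5)),
                     class = "threshold_spec")
  expect_equal(compute_gene_penalties(c(gA = 2), spec3)[["gA"]], 2)
  # genes without expression data are unpenalized
  expect_equal(compute_gene_penalties(c(gB = 1), spec2)[["gA"]], 0)
})

test_that("reaction penalties propagate through GPRs with max/min", {
  m <- stoich_model(
    data.frame(id = c("EX_a", "R1", "R2", "BM"),
               formula = c("a ->", "a -> b", "a -> b", "b ->"),
               lb = 0, ub = 10,
               gpr = c("", "A AND B", "A OR B", "")),
    biomass = "BM")
  ci <- propagate_reaction_penalties(c(A = 1, B = 3), m)
  expect_equal(unname(ci[c("R1", "R2")]), c(3, 1))
  expect_equal(unname(ci[c("EX_a", "BM")]), c(0, 0))
})

test_that("thresholds and penalties are monotone in theta; theta=0 is free", {
  set.seed(9)
  vals <- matrix(stats::rlnorm(5 * 40, sample(0:3, 5, TRUE)), 5, 40,
                 dimnames = list(paste0("g", 1:5), NULL))
  comp <- make_comp(vals)
  grid <- seq(1, 99, by = 7)
  expr <- vals[, 1]
  prev2 <- rep(-Inf, 5); prev1 <- -Inf
  for (th in grid) {
    s2 <- compute_thresholds(comp, 2, th)
    s1 <- compute_thresholds(comp, 1, th)
    expect_true(all(s2$x_g >= prev2))
    expect_gte(s1$x_global, prev1)
    prev2 <- s2$x_g; prev1 <- s1$x_global
  }
  s0 <- compute_thresholds(comp, 2, 0)
  expect_true(all(compute_gene_penalties(expr, s0) == 0))
  s0g <- compute_thresholds(comp, 1, 0)
  expect_true(all(compute_gene_penalties(expr, s0g) == 0))
})

test_that("Type 2 equals Type 1 when genes share one distribution", {
  set.seed(13)
  shared <- stats::rnorm(60, 10, 2)
  vals <- rbind(g1 = shared, g2 = shared, g3 = shared)
  comp <- make_comp(vals)
  for (th in c(10, 50, 90)) {
    t1 <- compute_thresholds(comp, 1, th)
    t2 <- compute_thresholds(comp, 2, th)
    expect_equal(unname(t2$x_g), rep(t1$x_global, 3))
  }
})

test_that("Type 3 penalties are invariant to per-gene rescaling", {
  set.seed(14)
  base <- stats::rlnorm(50, 1, 0.4)
  k <- 37.5
  comp <- make_comp(rbind(g1 = base, g2 = k * base))
  s <- compute_thresholds(comp, 3, 60)
  expect_equal(s$x_g[["g2"]], k * s$x_g[["g1"]])
  expect_equal(s$sigma_g[["g2"]], k * s$sigma_g[["g1"]])
  e <- base[1] * 0.5
  p <- compute_gene_penalties(c(g1 = e, g2 = k * e), s)
  expect_equal(p[["g1"]], p[["g2"]])
})

test_that("interpolation is exact at nodes and linear between", {
  expect_equal(interpolate_timeseries(c(0, 2), c(0, 4), 1), 2)
  expect_equal(interpolate_timeseries(c(0, 2, 5), c(1, 3, 0), c(0, 2, 5)),
               c(1, 3, 0))
  expect_error(interpolate_timeseries(c(0, 2), c(0, 4), 3),
               "outside")
  # construct-then-query: piecewise-linear ground truth recovered exactly
  set.seed(4)
  for (i in 1:20) {
    knots <- sort(stats::runif(6, 0, 10))
    vals <- stats::rnorm(6)
    f <- stats::approxfun(knots, vals)
    q <- stats::runif(10, min(knots), max(knots))
    expect_equal(interpolate_timeseries(knots, vals, q), f(q))
  }
  # matrix form, single and multiple query times keep dimensions
  m <- rbind(g1 = c(0, 2), g2 = c(4, 8))
  out <- interpolate_timeseries(c(0, 1), m, 0.5)
  expect_equal(dim(out), c(2, 1))
  expect_equal(out[, 1], c(g1 = 1, g2 = 6))
})
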