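# Per-step mechanics of the dynamic loop.

batch_media_model <- function() {
  # metabolites named after a minimal aerobic batch medium
  rx <- data.frame(
    id = c("EX_llac", "EX_dlac", "EX_nh4", "EX_o2", "USE", "BM"),
    formula = c("llac ->", "dlac ->", "nh4 ->", "o2 ->",
                "llac + o2 -> x", "x + nh4 ->"),
    lb = c(-1000, -1000, -1000, -1000, 0, 0),
    ub = c(1000, 1000, 1000, 1000, 10, 1000),
    gpr = "", stringsAsFactors = FALSE)
  stoich_model(rx, biomass = "BM")
}

test_that("state initialization reproduces the starting medium", {
  m <- batch_media_model()
  cfg <- team_config(clamp = c(o2 = 10))
  st <- initialize_state(m, c(llac = 36, dlac = 13, nh4 = 9), od0 = 0.1,
                         cfg)
  expect_equal(st$e[["llac"]], 36)
  expect_equal(st$e[["dlac"]], 13)
  expect_equal(st$e[["nh4"]], 9)
  expect_equal(st$e[["o2"]], 10)     # clamped dissolved oxygen
  expect_equal(st$e[["x"]], 0)       # unlisted metabolites start empty
  expect_equal(st$BM, 0.1)

  st0 <- initialize_state(m, c(), od0 = 1, cfg)
  expect_true(all(st0$e[setdiff(names(st0$e), "o2")] == 0))
  expect_error(initialize_state(m, c(llac = 1), od0 = 0, cfg), "positive")
  expect_error(initialize_state(m, c(nope = 1), od0 = 1, cfg), "unknown")
})

test_that("uptake bounds equal the pool that one step can exhaust", {
  m <- batch_media_model()
  cfg <- team_config(clamp = c(o2 = 10))
  st <- initialize_state(m, c(llac = 10), od0 = 1, cfg)
  b <- media_exchange_bounds(m, st, cfg)
  expect_equal(b$lb[m$rxn_ids == "EX_llac"], -10)   # pool / dt
  expect_equal(b$lb[m$rxn_ids == "EX_dlac"], 0)     # empty pool: no uptake
  expect_equal(b$lb[m$rxn_ids == "EX_o2"], -10)     # clamp every step
  # clamp holds regardless of simulated depletion
  st$e[["o2"]] <- 0
  b2 <- media_exchange_bounds(m, st, cfg)
  expect_equal(b2$lb[m$rxn_ids == "EX_o2"], -10)
  # halved dt doubles the admissible rate
  cfg2 <- team_config(dt = 0.5, clamp = c(o2 = 10))
  b3 <- media_exchange_bounds(m, st, cfg2)
  expect_equal(b3$lb[m$rxn_ids == "EX_llac"], -20)
})

test_that("specific bounds scale with biomass; exchange bounds do not", {
  m <- toy_chain_model()
  b <- scale_bounds_to_total(m, 0.5)
  expect_equal(b$lb[m$rxn_ids == "EX_a"], -10)  # exchange untouched
  expect_equal(b$ub[m$rxn_ids == "T_ab"], 5)    # 10 * 0.5
  b1 <- scale_bounds_to_total(m, 1)
  expect_equal(b1$lb, m$lb0)
  expect_equal(b1$ub, m$ub0)
  set.seed(5)
  for (i in 1:10) {
    bm <- stats::runif(1, 0.1, 5)
    b <- scale_bounds_to_total(m, bm)
    bio <- !m$exchange
    expect_equal(b$ub[bio], m$ub0[bio] * bm)
    expect_equal(b$lb[bio], m$lb0[bio] * bm)
  }
})

test_that("the growth requirement follows the measured curve plus death", {
  cfg <- team_config(death_rate = 0)
  flat <- data.frame(time = 0:10, od = rep(1, 11))
  expect_equal(biomass_rmf_bound(flat, 0, BM = 1, cfg), 0)
  cfg6 <- team_config(death_rate = 0.06)
  grow <- data.frame(time = 0:2, od = c(1, 1.1, 1.2))
  expect_equal(biomass_rmf_bound(grow, 0, BM = 1, cfg6), 0.1 + 0.06)
  # shrinking od is floored at zero
  shrink <- data.frame(time = 0:1, od = c(1, 0.2))
  expect_equal(biomass_rmf_bound(shrink, 0, BM = 1, cfg), 0)
  expect_error(biomass_rmf_bound(grow, 5, BM = 1, cfg6), "cover")
})

test_that("fraction-of-max growth requirement matches an FBA oracle", {
  m <- toy_chain_model()
  cfg <- team_config(rmf_mode = "fraction_of_max", rmf_fraction = 0.5)
  lb <- m$lb0; lb[1] <- -4
  oracle <- scipy_lp_batch(list(list(
    S = m$S, lb = lb, ub = m$ub0,
    lin_w = replace(numeric(3), 3, 1), maximize = TRUE)))[[1]]
  vmax <- oracle$V[[3]]
  expect_equal(biomass_rmf_bound(NULL, 0, BM = 1, cfg, model = m,
                                 lb = lb, ub = m$ub0),
               0.5 * vmax)
})

test_that("stage 1 routes flux around penalized reactions", {
  # all-zero penalties: inconsistency 0
  m <- toy_chain_model()
  lb <- m$lb0; lb[3] <- 2  # require biomass flux 2
  s <- solve_min_inconsistency(m, lb, m$ub0, numeric(3))
  expect_equal(s$inconsistency, 0)
  expect_equal(s$status, "optimal")

  # only path to biomass is penalized: inconsistency = c * required flux
  ci <- c(0, 1.5, 0)
  s2 <- solve_min_inconsistency(m, lb, m$ub0, ci)
  expect_equal(s2$inconsistency, 1.5 * 2)

  # two parallel paths, penalties (0, 5): all flux on the free path
  rx <- data.frame(id = c("EX_a", "P1", "P2", "BM"),
                   formula = c("a ->", "a -> b", "a -> b", "b ->"),
                   lb = c(-10, 0, 0, 3), ub = c(10, 10, 10, 10))
  m2 <- stoich_model(rx, biomass = "BM")
  s3 <- solve_min_inconsistency(m2, m2$lb0, m2$ub0, c(0, 0, 5, 0))
  expect_equal(s3$inconsistency, 0)
  expect_equal(unname(s3$V[["P2"]]), 0)
  expect_equal(unname(s3$V[["P1"]]), 3)
})

test_that("stage 2 respects the inconsistency lock", {
  m <- toy_chain_model()
  lb <- m$lb0; lb[3] <- 2
  ci <- c(0, 1.5, 0)
  s1 <- solve_min_inconsistency(m, lb, m$ub0, ci)
  s2 <- solve_min_total_flux(m, lb, m$ub0, ci, s1$inconsistency)
  expect_lte(s2$inconsistency,
             s1$inconsistency + 1e-9 * (1 + s1$inconsistency))
  expect_lte(s2$total_flux, s1$total_flux + 1e-9)
})

test_that("the Euler update moves pools by flux * dt and floors at zero", {
  m <- toy_chain_model()
  cfg <- team_config(death_rate = 0.06)
  st <- initialize_state(m, c(a = 10), od0 = 1, cfg)
  V <- c(EX_a = -4, T_ab = 4, BM = 0.2)
  st2 <- update_state(st, m, V, cfg)
  expect_equal(st2$e[["a"]], 6)
  expect_equal(st2$BM, 1 + 0.2 - 0.06)   # growth minus death
  expect_equal(st2$t, 1)
  # secretion adds to the pool
  st3 <- update_state(st, m, c(EX_a = 2, T_ab = 0, BM = 0), cfg)
  expect_equal(st3$e[["a"]], 12)
  # Euler overshoot is floored and logged
  st4 <- update_state(st, m, c(EX_a = -12, T_ab = 0, BM = 0), cfg)
  expect_equal(st4$e[["a"]], 0)
  expect_equal(attr(st4, "floored"), "a")
})

test_that("plain dFBA on the chain matches a hand-rolled Euler loop", {
  m <- toy_chain_model()
  cfg <- team_config(t_end = 8, death_rate = 0.06, clamp = c())
  od <- data.frame(time = 0:8, od = 1 + 0.1 * (0:8))
  traj <- run_dfba(m, od, c(a = 0.9), cfg)
  # hand iteration: biomass flux pinned at observed growth + death
  # replacement while the pool allows, else relaxed to the pool rate
  e <- 0.9; BM <- 1
  for (k in 1:8) {
    target <- 0.1 + 0.06 * BM
    v <- min(target, e)           # uptake cannot exceed the pool
    e <- e - v
    BM <- BM + v - 0.06 * BM
    expect_equal(unname(traj$conc[k + 1, "a"]), e, tolerance = 1e-9)
    expect_equal(traj$biomass[k + 1], BM, tolerance = 1e-9)
  }
  expect_true(all(traj$status %in% c("optimal", "relaxed")))
})

test_that("a zero-length horizon yields just the initial state", {
  m <- toy_chain_model()
  cfg <- team_config(t_end = 0)
  od <- data.frame(time = 0:1, od = c(1, 1))
  traj <- run_dfba(m, od, c(a = 5), cfg)
  expect_equal(length(traj$times), 1)
  expect_equal(nrow(traj$flux), 0)
  expect_equal(unname(traj$conc[1, "a"]), 5)
})

test_that("team_step enforces the fractional growth requirement", {
  sc <- make_scenario(scenario_spec())
  cfg <- team_config(rmf_mode = "fraction_of_max", rmf_fraction = 0.5,
                     clamp = c(o2 = 10))
  spec <- compute_thresholds(sc$compendium, 2, 50)
  expr <- sc$expression_ts$values[, 10]
  step <- team_step(sc$model, expr, spec, sc$media, cfg)
  bm_flux <- step$solution$V[[sc$model$rxn_ids[sc$model$biomass]]]
  expect_gte(bm_flux, step$rmf - 1e-8)
  expect_gt(step$rmf, 0)
  expect_equal(step$solution$status, "optimal")
})
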