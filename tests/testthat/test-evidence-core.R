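test_that("discretization yields normalized masses that match cdf differences", {
  b <- discretize(example_model(), grid_size = 2000)
  expect_equal(sum(b$prior_mass), 1, tolerance = 1e-6)
  expect_equal(sum(b$posterior_mass), 1, tolerance = 1e-6)
  # single-cell posterior mass agrees with an exact cdf-difference oracle
  i <- 700
  expect_equal(b$posterior_mass[i],
               pbeta(b$edges[i + 1], 12, 16) - pbeta(b$edges[i], 12, 16),
               tolerance = 1e-9)
  # posterior mass on (0.45, 0.55) accumulates to the cdf difference
  sel <- b$grid > 0.45 & b$grid < 0.55
  expect_equal(sum(b$posterior_mass[sel]),
               pbeta(max(b$edges[-1][sel]), 12, 16) -
                 pbeta(min(b$edges[-(length(b$edges))][sel]), 12, 16),
               tolerance = 1e-9)
})

test_that("a model without data discretizes to identical prior and posterior", {
  b <- discretize(beta_bernoulli(4, 4), grid_size = 256)
  expect_equal(b$prior_mass, b$posterior_mass, tolerance = 1e-12)
  rbf <- relative_belief(b)
  expect_true(all(abs(rbf$rb[rbf$defined] - 1) < 1e-9))
})

test_that("narrow bounds are flagged as capturing too little mass", {
  expect_warning(discretize(example_model(), grid_size = 64, bounds = c(0.45, 0.55)),
                 "capture")
})

test_that("the relative belief function is the cellwise mass ratio", {
  # forced two-cell arithmetic
  b <- make_belief(grid = c(0.25, 0.75), prior = c(0.5, 0.5), post = c(0.75, 0.25),
                   width = 0.5)
  rbf <- relative_belief(b)
  expect_equal(rbf$rb, c(1.5, 0.5))
  # posterior mass where the prior has none violates absolute continuity
  bad <- make_belief(grid = c(0.25, 0.75), prior = c(1, 0), post = c(0.75, 0.25),
                     width = 0.5)
  expect_error(relative_belief(bad), "zero prior mass")
  # normalization invariant on a constructed function
  b <- discretize(beta_bernoulli(2, 5, n = 30, s = 4), grid_size = 1024)
  rbf <- relative_belief(b)
  expect_equal(sum(rbf$rb[rbf$defined] * b$prior_mass[rbf$defined]), 1,
               tolerance = 1e-6)
})

test_that("grid RB at the hypothesized cell reproduces the worked value", {
  b <- discretize(example_model(), grid_size = 4096)
  rbf <- relative_belief(b)
  i <- findInterval(0.5, rbf$edges)
  expect_equal(rbf$rb[i], 1.421, tolerance = 0.002)
})

test_that("the LRSE maximizes the evidence with deterministic tie-breaking", {
  b <- discretize(example_model(), grid_size = 4096)
  rbf <- relative_belief(b)
  est <- lrse(rbf)
  expect_lt(abs(est - 0.400), rbf$width)
  expect_false(attr(est, "tied"))
  # total tie: flat function reports the smallest grid value with a flag
  bflat <- make_belief(grid = c(0.2, 0.5, 0.8), prior = rep(1 / 3, 3),
                       post = rep(1 / 3, 3), width = 0.3)
  eflat <- lrse(relative_belief(bflat))
  expect_equal(as.numeric(eflat), 0.2)
  expect_true(attr(eflat, "tied"))
  # two-cell unique maximum
  b2 <- make_belief(grid = c(0.25, 0.75), prior = c(0.5, 0.5), post = c(0.75, 0.25),
                    width = 0.5)
  expect_equal(as.numeric(lrse(relative_belief(b2))), 0.25)
})

test_that("credible regions are evidence-ordered, contain the LRSE, and nest in gamma", {
  m <- example_model()
  b <- discretize(m, grid_size = 4096)
  rbf <- relative_belief(b)
  reg <- credible_region(rbf, b, 0.95)
  expect_equal(nrow(reg$intervals), 1L)
  expect_gte(reg$content, 0.95)
  est <- as.numeric(lrse(rbf))
  expect_true(reg$intervals[1, 1] <= est && est <= reg$intervals[1, 2])
  # gamma = 0 keeps only the maximal-evidence cell(s); gamma = 1 keeps all
  reg0 <- credible_region(rbf, b, 0)
  expect_equal(sum(reg0$cells), 1L)
  expect_equal(rbf$grid[reg0$cells], est)
  reg1 <- credible_region(rbf, b, 1)
  expect_equal(sum(reg1$cells), sum(rbf$defined))
  # nesting across a gamma ladder
  gammas <- c(0.1, 0.3, 0.5, 0.7, 0.9, 0.99)
  regs <- lapply(gammas, function(g) credible_region(rbf, b, g)$cells)
  for (k in seq_len(length(gammas) - 1)) {
    expect_true(all(regs[[k + 1]][regs[[k]]]))
  }
})

test_that("the worked 0.95-region matches the printed interval at grid resolution", {
  b <- discretize(example_model(), grid_size = 4096)
  rbf <- relative_belief(b)
  reg <- credible_region(rbf, b, 0.95)
  # printed (0.227, 0.593) is a 3-decimal rounding; allow its quantization
  # on top of one cell width
  expect_lt(abs(reg$intervals[1, 1] - 0.227), rbf$width + 5e-4)
  expect_lt(abs(reg$intervals[1, 2] - 0.593), rbf$width + 5e-4)
  expect_lt(abs(unname(reg$intervals[1, 2] - reg$intervals[1, 1]) - 0.366), 0.002)
})

test_that("strength calibrates the evidence and handles ties and boundaries", {
  m <- example_model()
  b <- discretize(m, grid_size = 4096)
  rbf <- relative_belief(b)
  st <- strength(rbf, b, 0.5)
  expect_lt(abs(st$strength - 0.309), 0.003)
  # at the LRSE every value has no more evidence: strength 1
  expect_equal(strength(rbf, b, as.numeric(lrse(rbf)))$strength, 1)
  # forced two-cell arithmetic: psi0 on the weaker cell
  b2 <- make_belief(grid = c(0.25, 0.75), prior = c(0.5, 0.5), post = c(0.75, 0.25),
                    width = 0.5)
  rbf2 <- relative_belief(b2)
  st2 <- strength(rbf2, b2, 0.75)
  expect_equal(st2$strength, 0.25)
  expect_equal(st2$tie_mass, 0.25)
  expect_error(strength(rbf, b, 2), "outside")
})

test_that("exact ties from symmetry are counted into strength once each", {
  # symmetric posterior: psi0 = 0.3 and 0.7 have exactly equal RB
  m <- beta_bernoulli(4, 4, n = 20, s = 10)
  b <- discretize(m, grid_size = 1000, bounds = c(0, 1))
  rbf <- relative_belief(b)
  st <- strength(rbf, b, 0.3)
  i <- st$cell
  j <- which.min(abs(b$grid - (1 - b$grid[i])))  # mirror cell
  expect_equal(rbf$rb[j], rbf$rb[i], tolerance = 1e-12)
  expect_gte(st$tie_mass,
             b$posterior_mass[i] + b$posterior_mass[j] - 1e-12)
})

test_that("the inequality chain tie-mass <= strength <= RB(psi0) holds over random configurations", {
  cfgs <- random_configs(200)
  for (k in seq_len(nrow(cfgs))) {
    m <- beta_bernoulli(cfgs$a0[k], cfgs$b0[k], n = cfgs$n[k], s = cfgs$s[k])
    b <- discretize(m, grid_size = 256)
    rbf <- relative_belief(b)
    st <- tryCatch(strength(rbf, b, cfgs$psi0[k]), error = function(e) NULL)
    if (is.null(st)) next  # psi0 outside the discretized support
    expect_lte(st$tie_mass, st$strength + 1e-12)
    expect_lte(st$strength, st$rb_at_psi0 + 1e-9)
  }
})

test_that("Bayes factors are posterior-to-prior odds with undefined boundaries flagged", {
  b2 <- make_belief(grid = c(0.25, 0.75), prior = c(0.5, 0.5), post = c(0.75, 0.25),
                    width = 0.5)
  expect_equal(bayes_factor(b2, c(TRUE, FALSE)), 3)
  expect_true(is.na(bayes_factor(b2, c(TRUE, TRUE))))
  # worked example: cells in (0.45, 0.55) against exact beta cdfs
  b <- discretize(example_model(), grid_size = 4096)
  sel <- b$grid > 0.45 & b$grid < 0.55
  lo <- min(b$edges[-length(b$edges)][sel]); hi <- max(b$edges[-1][sel])
  q <- pbeta(hi, 12, 16) - pbeta(lo, 12, 16)
  p <- pbeta(hi, 4, 4) - pbeta(lo, 4, 4)
  oracle <- (q / (1 - q)) / (p / (1 - p))
  expect_equal(bayes_factor(b, sel), oracle, tolerance = 1e-6)
})

test_that("grid refinement converges at first order (Cauchy check)", {
  # endpoints move by at most the coarser cell width; interpolated RB at a
  # fixed point converges second order; strength moves by no more than the
  # swept boundary mass (two boundaries times the posterior density bound)
  m <- example_model()
  res <- lapply(c(1024, 2048, 4096), function(gs) {
    b <- discretize(m, grid_size = gs)
    rbf <- relative_belief(b)
    st <- strength(rbf, b, 0.5)
    reg <- credible_region(rbf, b, 0.95)
    list(w = rbf$width,
         rb = stats::approx(rbf$grid, rbf$rb, xout = 0.5)$y,
         s = st$strength, fmax = max(b$posterior_mass) / rbf$width,
         lo = unname(reg$intervals[1, 1]), hi = unname(reg$intervals[1, 2]))
  })
  for (k in 1:2) {
    w_prev <- res[[k]]$w
    expect_lt(abs(res[[k + 1]]$rb - res[[k]]$rb), w_prev)
    expect_lt(abs(res[[k + 1]]$s - res[[k]]$s), 2 * w_prev * res[[k]]$fmax)
    expect_lt(abs(res[[k + 1]]$lo - res[[k]]$lo), w_prev)
    expect_lt(abs(res[[k + 1]]$hi - res[[k]]$hi), w_prev)
  }
})

test_that("RB is invariant under smooth monotone reparameterization at corresponding points", {
  # psi = g(theta) = theta^2; discretize uniformly in the psi scale and
  # compare the ratio at g(psi0) with the theta-scale ratio at psi0
  m <- example_model()
  g <- function(t) t^2
  ginv <- function(p) sqrt(p)
  b_th <- discretize(m, grid_size = 4096, bounds = c(1e-4, 1 - 1e-4))
  rb_th <- relative_belief(b_th)
  edges_psi <- seq(g(1e-4), g(1 - 1e-4), length.out = 4097)
  Fp <- function(q) pbeta(ginv(q), 4, 4)
  Fq <- function(q) pbeta(ginv(q), 12, 16)
  b_psi <- make_belief(grid = (edges_psi[-1] + edges_psi[-4097]) / 2,
                       prior = diff(Fp(edges_psi)), post = diff(Fq(edges_psi)),
                       width = diff(edges_psi)[1])
  b_psi$edges <- edges_psi
  rb_psi <- relative_belief(b_psi)
  for (psi0 in c(0.3, 0.5, 0.7)) {
    i_th <- findInterval(psi0, rb_th$edges)
    i_psi <- findInterval(g(psi0), rb_psi$edges)
    # Jacobians cancel in the ratio; allow a little discretization drift
    expect_equal(rb_psi$rb[i_psi], rb_th$rb[i_th], tolerance = 0.01)
  }
})

test_that("the Monte Carlo path reproduces the closed form within Monte Carlo error", {
  m <- example_model()
  draws <- 4e5
  b <- mc_marginal_belief(
    prior_sampler = function(k) rbeta(k, 4, 4),
    likelihood = function(th) th^8 * (1 - th)^12,
    bins = 128, draws = draws, seed = 2718)
  rbf <- relative_belief(b)
  i <- findInterval(0.5, rbf$edges)
  expect_equal(rbf$rb[i], 1.421, tolerance = 0.05)
  # determinism at fixed seed
  b2 <- mc_marginal_belief(
    prior_sampler = function(k) rbeta(k, 4, 4),
    likelihood = function(th) th^8 * (1 - th)^12,
    bins = 128, draws = draws, seed = 2718)
  expect_identical(b$posterior_mass, b2$posterior_mass)
  # constant likelihood carries no evidence
  bc <- mc_marginal_belief(
    prior_sampler = function(k) rbeta(k, 4, 4),
    likelihood = function(th) rep(1, length(th)),
    bins = 64, draws = 2e5, seed = 11)
  rbc <- relative_belief(bc)
  mid <- bc$grid > 0.2 & bc$grid < 0.8
  expect_lt(max(abs(rbc$rb[mid] - 1)), 0.12)
})

test_that("the Monte Carlo path mirrors under psi = 1 - theta with swapped counts", {
  b_id <- mc_marginal_belief(
    prior_sampler = function(k) rbeta(k, 4, 4),
    likelihood = function(th) th^8 * (1 - th)^12,
    psi_map = identity, bins = 64, draws = 2e5, seed = 99)
  b_mir <- mc_marginal_belief(
    prior_sampler = function(k) rbeta(k, 4, 4),
    likelihood = function(th) th^12 * (1 - th)^8,  # s and n - s swapped
    psi_map = function(th) 1 - th, bins = 64, draws = 2e5, seed = 99)
  rb_id <- relative_belief(b_id)
  rb_mir <- relative_belief(b_mir)
  i_id <- findInterval(0.35, rb_id$edges)
  i_mir <- findInterval(0.35, rb_mir$edges)
  expect_equal(rb_mir$rb[i_mir], rb_id$rb[i_id], tolerance = 0.08)
})

test_that("degenerate importance weights trigger the effective-sample-size warning", {
  expect_warning(
    mc_marginal_belief(
      prior_sampler = function(k) rbeta(k, 4, 4),
      likelihood = function(th) as.numeric(abs(th - 0.5) < 2e-4),
      bins = 16, draws = 2e4, seed = 5),
    "effective sample size")
})
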