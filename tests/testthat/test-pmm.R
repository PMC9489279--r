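test_that("design bundles encode fixed, incidence and covariance pieces", {
  tr <- readNewick("((A:1,B:1):1,C:2);")
  rel <- relatednessMatrix(tr)
  d <- data.frame(species = rep(c("A", "B", "C"), each = 2),
                  strain = paste0("s", 1:6),
                  n_infected = c(3, 2, 1, 0, 0, 0), n_replicates = 3,
                  focal_distance = rep(c(0, 2, 4), each = 2))
  des <- buildDesign(d, fixed = character(), random = "species", rel = rel,
                     family = "binomial")
  expect_equal(unname(des$X), matrix(1, 6, 1))

  des2 <- buildDesign(d, fixed = "focal_distance",
                      random = c("phylo", "species"), rel = rel,
                      family = "binomial")
  Zp <- des2$Z[, seq_len(des2$term_sizes[["phylo"]])]
  expect_equal(dim(Zp), c(6, 3))
  expect_true(all(rowSums(Zp) == 1))
  expect_error(buildDesign(transform(d, species = "Z"), rel = rel,
                           family = "binomial"), "not on the tree")
})

test_that("design reproduces the generator's linear predictor", {
  tr <- simulateYuleTree(12, seed = 21)
  obs <- simulateSusceptibility(tr, simulationConfig(nSpecies = 12),
                                seed = 22)
  truth <- attr(obs, "truth")
  rel <- relatednessMatrix(tr)
  des <- buildDesign(obs, fixed = "focal_distance",
                     random = c("phylo", "species"), rel = rel,
                     family = "binomial")
  qp <- des$term_sizes[["phylo"]]
  eta <- des$X %*% c(truth$beta0, truth$beta1) +
    des$Z[, seq_len(qp)] %*% truth$u_phylo[colnames(des$Z)[seq_len(qp)]] +
    des$Z[, qp + seq_len(des$term_sizes[["species"]])] %*%
      truth$u_species[colnames(des$Z)[qp + seq_len(des$term_sizes[["species"]])]]
  # what remains is exactly the strain-level residual draw
  expect_equal(unname(truth$liability - as.numeric(eta)), truth$residual,
               tolerance = 1e-10)
})

test_that("Gaussian sampler matches the conjugate closed form", {
  set.seed(42)
  n <- 10
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n)
  d <- data.frame(species = "A", strain = letters[1:n], score = y, x = x)
  fit <- fitPMM(d, fixed = "x", random = character(), family = "gaussian",
                chain = chainSettings(22000, 2000, 10, seed = 7),
                fixResidual = 1)
  X <- cbind(1, x)
  P <- crossprod(X) / 1 + diag(2) / 1e8
  m <- solve(P, crossprod(X, y) / 1)
  V <- solve(P)
  draws <- posteriorSamples(fit)$beta
  S <- nrow(draws)
  for (j in 1:2) {
    mc_se <- sd(draws[, j]) / sqrt(S)
    expect_lt(abs(mean(draws[, j]) - m[j]), 3 * mc_se)
    expect_equal(sd(draws[, j]), sqrt(V[j, j]), tolerance = 0.1)
  }
})

test_that("posterior summaries follow the pMCMC and HPD conventions", {
  expect_equal(pMCMC(rep(1, 1000)), 0.002)
  expect_equal(pMCMC(c(rep(1, 3), rep(-1, 2))), 0.8)
  set.seed(9)
  sym <- rnorm(2000)
  expect_gt(pMCMC(sym), 0.9)
  expect_lte(pMCMC(sym), 1)

  h <- hpdInterval(1:100, 0.9)
  expect_equal(unname(h[2] - h[1]), 89)
  set.seed(10)
  skew <- rexp(5000)
  hs <- hpdInterval(skew, 0.95)
  expect_lt(hs[1], hs[2])
  expect_lt(hs[1], 0.05)  # HPD of an exponential hugs zero
})

test_that("DIC reduces to the plug-in deviance for constant draws", {
  # Gaussian toy: y = {0, 1}, fitted 0, sigma2_e = 1
  samples <- list(deviance = rep(2 * log(2 * pi) + 1, 5),
                  fitted = matrix(0, 5, 2), sigma2_e = rep(1, 5),
                  beta = matrix(0, 5, 1))
  design <- list(family = "gaussian", y = c(0, 1))
  expect_equal(OrsayHostRange:::.pmm_dic(samples, design),
               2 * log(2 * pi) + 1)
  expect_error(OrsayHostRange:::.pmm_dic(
    list(deviance = 1, fitted = matrix(0, 1, 2), sigma2_e = 1),
    design), "at least 2")
})

test_that("adding a strongly generating covariate lowers DIC", {
  wins <- 0L
  n_rep <- 12L
  for (r in seq_len(n_rep)) {
    tr <- simulateYuleTree(25, seed = 500 + r)
    obs <- simulateSusceptibility(
      tr, simulationConfig(nSpecies = 25, sigma2Phylo = 0.25,
                           sigma2Species = 0.25), seed = 600 + r)
    rel <- relatednessMatrix(tr)
    with_cov <- fitPMM(obs, fixed = "focal_distance", random = "species",
                       rel = rel, family = "binomial",
                       chain = test_chain(700 + r))
    without <- fitPMM(obs, fixed = character(), random = "species",
                      rel = rel, family = "binomial",
                      chain = test_chain(800 + r))
    wins <- wins + (dic(with_cov) < dic(without))
  }
  expect_gte(wins, n_rep - 1L)
})

test_that("liability Metropolis acceptance lands in the adapted band", {
  tr <- simulateYuleTree(20, seed = 31)
  obs <- simulateSusceptibility(tr, simulationConfig(nSpecies = 20),
                                seed = 32)
  rel <- relatednessMatrix(tr)
  fit <- fitPMM(obs, fixed = "focal_distance",
                random = c("phylo", "species"), rel = rel,
                family = "binomial", chain = test_chain(33))
  acc <- posteriorSamples(fit)$accept_rate
  expect_gt(acc, 0.2)
  expect_lt(acc, 0.7)
})

test_that("doubling branch lengths halves the phylogenetic variance", {
  tr <- simulateYuleTree(40, seed = 41)
  rel <- relatednessMatrix(tr)
  set.seed(42)
  u <- as.numeric(MASS::mvrnorm(1, rep(0, 40), 2 * relMatrix(rel)))
  d <- data.frame(species = rep(tr$tip.label, each = 3),
                  strain = paste0(rep(tr$tip.label, each = 3), "_",
                                  rep(1:3, 40)),
                  score = rep(u, each = 3) + rnorm(120, 0, 0.5))
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  rel2 <- relatednessMatrix(tr2)
  f1 <- fitPMM(d, random = c("phylo", "species"), rel = rel,
               family = "gaussian", response = "score",
               chain = test_chain(43, 20000, 4000))
  f2 <- fitPMM(d, random = c("phylo", "species"), rel = rel2,
               family = "gaussian", response = "score",
               chain = test_chain(44, 20000, 4000))
  m1 <- mean(posteriorSamples(f1)$sigma2[, "phylo"])
  m2 <- mean(posteriorSamples(f2)$sigma2[, "phylo"])
  expect_gt(m2 / m1, 0.3)
  expect_lt(m2 / m1, 0.75)
  # fitted probabilities statistically unchanged
  p1 <- colMeans(posteriorSamples(f1)$fitted)
  p2 <- colMeans(posteriorSamples(f2)$fitted)
  expect_gt(cor(p1, p2), 0.98)
})

test_that("posterior draws serialize to tidy TSV", {
  set.seed(90)
  d <- data.frame(species = rep(c("A", "B"), each = 6),
                  strain = paste0("s", 1:12), score = rnorm(12))
  fit <- fitPMM(d, random = "species", family = "gaussian",
                response = "score", chain = test_chain(91))
  path <- withr::local_tempfile(fileext = ".tsv")
  writePosteriorDraws(fit, path)
  df <- read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), nrow(posteriorSamples(fit)$beta))
  expect_true(all(c("intercept", "sigma2_species", "sigma2_residual",
                    "deviance") %in% names(df)))
  expect_equal(df$sigma2_residual, posteriorSamples(fit)$sigma2_e,
               tolerance = 1e-8)
})

test_that("stationarity diagnostics separate stationary from drifting chains", {
  set.seed(1)
  ok <- heidelbergerWelch(rnorm(1000))
  expect_true(ok$passed)
  expect_equal(ok$retainedFraction, 1)

  bad <- heidelbergerWelch(seq_len(1000))
  expect_false(bad$passed)

  # affine invariance of the verdict
  set.seed(2)
  x <- rnorm(500) + cumsum(rnorm(500, 0, 0.05))
  v1 <- heidelbergerWelch(x)
  v2 <- heidelbergerWelch(5 - 3 * x)
  expect_identical(v1$passed, v2$passed)
  expect_equal(v1$pvalue, v2$pvalue, tolerance = 1e-8)

  const <- heidelbergerWelch(rep(2, 200))
  expect_false(const$passed)
  expect_match(const$reason, "degenerate")
})
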