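test_that("Yule trees are deterministic, ultrametric and round-trip", {
  t1 <- simulateYuleTree(10, seed = 5)
  t2 <- simulateYuleTree(10, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_false(identical(ape::write.tree(t1),
                         ape::write.tree(simulateYuleTree(10, seed = 6))))

  for (n in c(2, 10, 100)) {
    tr <- simulateYuleTree(n, seed = n)
    expect_equal(validateUltrametric(tr, tol = 1e-9), 1, tolerance = 1e-9)
  }

  # write -> parse round-trip preserves topology and branch lengths
  tr <- simulateYuleTree(10, seed = 8)
  back <- readNewick(ape::write.tree(tr, digits = 17))
  expect_setequal(back$tip.label, tr$tip.label)
  for (a in tr$tip.label) for (b in tr$tip.label)
    expect_equal(copheneticDistance(back, a, b),
                 copheneticDistance(tr, a, b), tolerance = 1e-12)

  expect_error(simulateYuleTree(1), "at least 2")
})

test_that("susceptibility generator obeys its degenerate and trend contracts", {
  tr <- simulateYuleTree(15, seed = 12)
  cfg0 <- simulationConfig(nSpecies = 15, trueBeta1 = 0, sigma2Phylo = 0,
                           sigma2Species = 0, sigma2Residual = 0)
  obs0 <- simulateSusceptibility(tr, cfg0, seed = 13)
  truth0 <- attr(obs0, "truth")
  expect_true(all(truth0$liability == cfg0$trueBeta0))

  # infection decreases with distance when beta1 = -2 (rank correlation)
  neg <- 0L
  n_rep <- 40L
  for (r in seq_len(n_rep)) {
    tr <- simulateYuleTree(40, seed = 4000 + r)
    obs <- simulateSusceptibility(tr, simulationConfig(), seed = 4100 + r)
    rho <- suppressWarnings(
      cor(obs$focal_distance, obs$n_infected / obs$n_replicates,
          method = "spearman"))
    neg <- neg + (!is.na(rho) && rho < 0)
  }
  expect_gte(neg, round(0.95 * n_rep))
})

test_that("phylogenetic liabilities covary according to A", {
  tr <- simulateYuleTree(12, seed = 30)
  rel <- relatednessMatrix(tr)
  cfg <- simulationConfig(nSpecies = 12, strainsPerSpecies = 1,
                          trueBeta1 = 0, sigma2Phylo = 1,
                          sigma2Species = 0, sigma2Residual = 0)
  set.seed(31)
  L <- t(replicate(400, attr(simulateSusceptibility(tr, cfg), "truth")$liability))
  emp <- cov(L)
  A <- unname(relMatrix(rel))
  off <- row(A) != col(A)
  expect_gt(cor(emp[off], A[off]), 0.7)
  # the closest pair covaries more than the most distant pair
  expect_gt(emp[off][which.max(A[off])], emp[off][which.min(A[off])])
})

test_that("Ct assay generator respects the domain and role moments", {
  status <- data.frame(strain = c("S1", "S2"), species = c("S1", "S2"),
                       p_infected = c(1, 0))
  cfg <- simulationConfig(nBlocks = 100, replicatesPerStrain = 3)
  tab <- simulateCtAssay(status, cfg, seed = 50)
  rec <- ctRecords(tab)
  ct <- rec$ct[!is.na(rec$ct)]
  expect_true(all(ct > 0 & ct <= 40))

  # benchmark 5 sits far from the detection limit: moments ~ (22.0, 0.6)
  b5 <- rec$ct[rec$role == "benchmark5" & !is.na(rec$ct)]
  expect_gt(length(b5), 280)
  expect_equal(mean(b5), 22.0, tolerance = 0.15)
  expect_equal(sd(b5), 0.6, tolerance = 0.15)

  # benchmark 4 straddles the limit: detected wells follow the
  # upper-truncated normal closed form
  b4 <- rec$ct[rec$role == "benchmark4" & !is.na(rec$ct)]
  a <- (40 - 38.4) / 2.6
  lam <- dnorm(a) / pnorm(a)
  expect_equal(mean(b4), 38.4 - 2.6 * lam, tolerance = 0.5)
  expect_equal(sd(b4), 2.6 * sqrt(1 - lam * (lam + a)), tolerance = 0.5)

  # the negative control is always undetected
  expect_true(all(is.na(rec$ct[rec$role == "control1_neg"])))

  # probability-1 strain with zero spread pins every replicate at the mean
  cfg0 <- simulationConfig(ctInfectedSd = 1e-12, nBlocks = 1)
  tab0 <- simulateCtAssay(status[1, ], cfg0, seed = 51)
  exp_ct <- ctRecords(tab0)
  exp_ct <- exp_ct$ct[exp_ct$role == "experimental"]
  expect_equal(exp_ct, rep(cfg0$ctInfectedMean, 3), tolerance = 1e-6)
})

test_that("threshold calling recovers the generated infection status", {
  tr <- simulateYuleTree(40, seed = 60)
  obs <- simulateSusceptibility(tr, simulationConfig(), seed = 61)
  tab <- simulateCtAssay(obs, simulationConfig(), seed = 62)
  thr <- deriveThreshold(tab, suppressMessages(withinStrainSd(tab)))
  calls <- callSusceptibility(tab, thr)
  merged <- merge(calls, obs, by = c("strain", "species"))
  accuracy <- mean(merged$susceptible == (merged$n_infected.y >= 1))
  expect_gte(accuracy, 0.95)
})

test_that("passage trajectories respect their limiting regimes", {
  lines <- data.frame(line_id = paste0("L", 1:30),
                      strain = paste0("S", 1:30),
                      passage0_ct = c(runif(25, 16, 28), rep(NA, 5)))
  # persistence probability 1: every exposed line reaches passage 5
  cfg3 <- simulationConfig(passageA = 50, passageB = 0)
  tr3 <- simulatePassageTrajectories(lines, cfg3, seed = 70)
  sc3 <- scoreTransmissionTable(tr3)
  expect_true(all(sc3$score[!is.na(sc3$passage0_ct)] == 3))
  expect_true(all(sc3$score[is.na(sc3$passage0_ct)] == 0))

  # persistence probability 0: every detected line loses the virus at once
  cfg1 <- simulationConfig(passageA = -50, passageB = 0)
  sc1 <- scoreTransmissionTable(
    simulatePassageTrajectories(lines, cfg1, seed = 71))
  expect_true(all(sc1$score[!is.na(sc1$passage0_ct)] == 1))

  # mean score decreases with passage-0 Ct under the default loss model
  many <- data.frame(line_id = paste0("L", 1:1000),
                     strain = paste0("S", 1:1000),
                     passage0_ct = runif(1000, 15, 29))
  scm <- scoreTransmissionTable(
    simulatePassageTrajectories(many, simulationConfig(), seed = 72))
  expect_lt(cor(scm$passage0_ct, scm$score, method = "spearman"), -0.2)
})
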