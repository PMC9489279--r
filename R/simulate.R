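#' Default configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator with defaults that mirror the
#' study design the pipeline analyses: a pure-birth species tree of unit
#' height; three strains per species assayed in three replicate populations;
#' a logit liability model for susceptibility with a distance-from-focal
#' slope and phylogenetic, species and residual variance components;
#' per-role Ct moments for the plate controls and benchmarks; and a
#' passage-persistence model whose per-passage retention probability falls
#' with the passage-0 Ct.
#'
#' Role Ct moments (mean, sd) default to the plate-design values: negative
#' control undetected; positive controls (15.7, 2.0) and (12.7, 2.2);
#' benchmark 4 (38.4, 2.6); benchmark 5 (22.0, 0.6). Raw role draws at or
#' above 40 cycles are recorded as undetected (the qPCR detection limit).
#'
#' @param nSpecies number of species tips (default 40)
#' @param birthRate Yule birth rate (default 1; height is rescaled to 1)
#' @param strainsPerSpecies strains assayed per species (default 3)
#' @param replicatesPerStrain replicate populations per strain (default 3)
#' @param trueBeta0 liability intercept (default 0)
#' @param trueBeta1 liability slope on distance from the focal host
#'   (default -2)
#' @param sigma2Phylo,sigma2Species,sigma2Residual variance components of
#'   the liability (defaults 1, 0.5, 1)
#' @param ctInfectedMean,ctInfectedSd Ct moments of infected replicates
#'   (defaults 20, 4; drawn truncated to (0, 40))
#' @param ctRoles named list of c(mean, sd) per non-experimental role
#' @param nBlocks number of experimental blocks (default 8)
#' @param passageA,passageB persistence model: per-passage retention
#'   probability \code{plogis(passageA - passageB * (passage0_ct - 20))}
#'   (defaults 1.5, 0.2)
#' @param ... overrides for any of the above
#' @return named list of generator settings
#' @export
simulationConfig <- function(nSpecies = 40, birthRate = 1,
                             strainsPerSpecies = 3, replicatesPerStrain = 3,
                             trueBeta0 = 0, trueBeta1 = -2,
                             sigma2Phylo = 1, sigma2Species = 0.5,
                             sigma2Residual = 1,
                             ctInfectedMean = 20, ctInfectedSd = 4,
                             ctRoles = list(
                               control2_N2 = c(15.7, 2.0),
                               control3_JU1580 = c(12.7, 2.2),
                               benchmark4 = c(38.4, 2.6),
                               benchmark5 = c(22.0, 0.6)),
                             nBlocks = 8,
                             passageA = 1.5, passageB = 0.2, ...) {
  cfg <- c(as.list(environment()), list(...))
  stopifnot(cfg$sigma2Phylo >= 0, cfg$sigma2Species >= 0,
            cfg$sigma2Residual >= 0, cfg$nSpecies >= 2,
            cfg$replicatesPerStrain >= 1)
  cfg
}

#' Simulate an ultrametric pure-birth (Yule) species tree
#'
#' Wraps [ape::rphylo()] with zero extinction and rescales the tree to unit
#' height, so distances are directly comparable across simulated trees.
#' Tips are labelled \code{sp01, sp02, ...} in the tree's tip order.
#' Deterministic for a given seed.
#'
#' @param nSpecies number of tips (at least 2)
#' @param birthRate speciation rate (default 1; only shapes node spacing
#'   before rescaling)
#' @param seed RNG seed; if NULL the current RNG state is used
#' @return an ultrametric \code{phylo} of height 1
#' @export
simulateYuleTree <- function(nSpecies, birthRate = 1, seed = NULL) {
  if (nSpecies < 2) stop("need at least 2 species")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(nSpecies, birth = birthRate, death = 0)
  H <- max(.tip_depths(tree))
  tree$edge.length <- tree$edge.length / H
  tree$tip.label <- sprintf("sp%02d", seq_len(nSpecies))
  tree
}

#' Simulate strain-level susceptibility data on a tree
#'
#' Draws a phylogenetic species effect from \eqn{N(0, \sigma^2_p A)}, an
#' i.i.d. species effect, and a strain-level residual; forms the liability
#' \eqn{\ell = \beta_0 + \beta_1 d + u_{phylo} + u_{species} + e} where
#' \eqn{d} is the cophenetic distance from the focal tip; and draws the
#' number of infected replicates \eqn{k \sim Binom(n, \mathrm{logit}^{-1}
#' \ell)} per strain. The generating parameters and latent effects are
#' attached as attribute \code{"truth"}.
#'
#' @param tree ultrametric \code{phylo}
#' @param config from [simulationConfig()]
#' @param focal focal tip label (default: first tip)
#' @param seed RNG seed; NULL uses the current state
#' @return data.frame with columns species, strain, n_infected,
#'   n_replicates, focal_distance; attribute \code{truth}
#' @export
simulateSusceptibility <- function(tree, config = simulationConfig(),
                                   focal = tree$tip.label[1], seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rel <- relatednessMatrix(tree)
  d <- distanceFromFocal(tree, focal)
  nsp <- length(tree$tip.label)
  u_phylo <- if (config$sigma2Phylo > 0)
    as.numeric(MASS::mvrnorm(1, mu = rep(0, nsp),
                             Sigma = config$sigma2Phylo * relMatrix(rel)))
  else rep(0, nsp)
  u_species <- stats::rnorm(nsp, 0, sqrt(config$sigma2Species))
  names(u_phylo) <- names(u_species) <- tree$tip.label

  rows <- list()
  liab <- numeric(0)
  resid <- numeric(0)
  for (sp in tree$tip.label) {
    for (j in seq_len(config$strainsPerSpecies)) {
      e <- stats::rnorm(1, 0, sqrt(config$sigma2Residual))
      resid <- c(resid, e)
      l <- config$trueBeta0 + config$trueBeta1 * d[sp] +
        u_phylo[sp] + u_species[sp] + e
      k <- stats::rbinom(1, config$replicatesPerStrain, stats::plogis(l))
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, strain = paste0(sp, "_s", j),
        n_infected = k, n_replicates = config$replicatesPerStrain,
        focal_distance = unname(d[sp]))
      liab <- c(liab, l)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    beta0 = config$trueBeta0, beta1 = config$trueBeta1,
    sigma2Phylo = config$sigma2Phylo, sigma2Species = config$sigma2Species,
    sigma2Residual = config$sigma2Residual,
    focal = focal, u_phylo = u_phylo, u_species = u_species,
    liability = liab, residual = resid, config = config)
  out
}

# normal draw censored at the 40-cycle detection limit: >= 40 -> NA
# (undetected); non-positive raw values redrawn (never in practice for the
# role moments used)
.draw_role_ct <- function(n, mean, sd) {
  ct <- stats::rnorm(n, mean, sd)
  bad <- ct <= 0
  while (any(bad)) {
    ct[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- ct <= 0
  }
  ifelse(ct >= 40, NA_real_, ct)
}

#' Simulate a plate-style qPCR Ct table
#'
#' Emits experimental replicate rows per strain plus the full set of
#' control/benchmark rows in triplicate per block. Infected replicates draw
#' Ct from a normal truncated to (0, 40); uninfected replicates draw from
#' the benchmark-4 (carry-over) regime, with raw values at or above 40
#' recorded as undetected. The negative control is always undetected.
#'
#' @param status data.frame with columns strain, species, and either
#'   \code{p_infected} (per-replicate infection probability) or
#'   \code{n_infected} + \code{n_replicates} (exact counts, as produced by
#'   [simulateSusceptibility()])
#' @param config from [simulationConfig()]
#' @param seed RNG seed; NULL uses the current state
#' @return a [CtTable-class]
#' @export
simulateCtAssay <- function(status, config = simulationConfig(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nrep <- config$replicatesPerStrain
  blocks <- rep(seq_len(config$nBlocks), length.out = nrow(status))
  rows <- list()
  for (i in seq_len(nrow(status))) {
    if (!is.null(status$n_infected)) {
      nr <- status$n_replicates[i]
      infected <- seq_len(nr) <= status$n_infected[i]
      infected <- sample(infected)
    } else {
      nr <- nrep
      infected <- stats::runif(nr) < status$p_infected[i]
    }
    ct <- numeric(nr)
    for (j in seq_len(nr)) {
      if (infected[j]) {
        repeat {
          v <- stats::rnorm(1, config$ctInfectedMean, config$ctInfectedSd)
          if (v > 0 && v < 40) break
        }
        ct[j] <- v
      } else {
        b4 <- config$ctRoles$benchmark4
        ct[j] <- .draw_role_ct(1, b4[1], b4[2])
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      strain = status$strain[i], species = status$species[i],
      block = blocks[i], replicate = seq_len(nr),
      role = "experimental", ct = ct)
  }
  for (b in seq_len(config$nBlocks)) {
    rows[[length(rows) + 1]] <- data.frame(
      strain = "N2", species = "C.elegans", block = b, replicate = 1:3,
      role = "control1_neg", ct = NA_real_)
    for (role in names(config$ctRoles)) {
      m <- config$ctRoles[[role]]
      strain <- switch(role, control2_N2 = "N2",
                       control3_JU1580 = "JU1580", "none")
      rows[[length(rows) + 1]] <- data.frame(
        strain = strain, species = if (strain == "none") "none" else "C.elegans",
        block = b, replicate = 1:3, role = role,
        ct = .draw_role_ct(3, m[1], m[2]))
    }
  }
  ctTable(do.call(rbind, rows))
}

#' Simulate serial-passage trajectories
#'
#' Virus is detected at passage 0 iff the line's passage-0 Ct is below the
#' susceptibility threshold; thereafter the virus persists through each
#' passage independently with probability
#' \code{plogis(passageA - passageB * (passage0_ct - 20))}, so lines with
#' strong primary amplification (low Ct) transmit longer. A line is
#' truncated at its first loss; at most passages 0-5 are recorded.
#'
#' @param lines data.frame with columns line_id, strain, passage0_ct
#'   (NA = undetected)
#' @param config from [simulationConfig()]
#' @param threshold passage-0 detection threshold tau (default 29.5)
#' @param seed RNG seed; NULL uses the current state
#' @return long-format data.frame: line_id, strain, passage, detected,
#'   passage0_ct
#' @export
simulatePassageTrajectories <- function(lines, config = simulationConfig(),
                                        threshold = 29.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(lines))) {
    ct <- lines$passage0_ct[i]
    det0 <- !is.na(ct) && ct < threshold
    det <- det0
    passage <- 0L
    traj <- logical(0)
    repeat {
      traj <- c(traj, det)
      if (!det || passage == 5L) break
      p <- stats::plogis(config$passageA -
                           config$passageB * (ct - 20))
      det <- stats::runif(1) < p
      passage <- passage + 1L
    }
    rows[[length(rows) + 1]] <- data.frame(
      line_id = lines$line_id[i], strain = lines$strain[i],
      passage = seq_along(traj) - 1L, detected = traj,
      passage0_ct = ct)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
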