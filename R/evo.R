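## Forward Monte Carlo simulation of a two-sex diploid population under
## stabilizing selection on expression. Each individual carries three
## additive loci (shared, male-specific, female-specific; two alleles
## each); the phenotype is the sum of the shared-locus alleles, the
## own-sex-locus alleles and a standard-normal environmental deviate.
## Gaussian stabilizing selection w = exp(-s * P^2) acts on viability with
## a sex-specific strength; generations are non-overlapping.

#' Parameters of the stabilizing-selection simulation
#'
#' Defaults follow the studied regime: census size 500, 100 breeding
#' pairs of 5 offspring, per-locus per-individual mutation rate 5e-3
#' (standard-normal increments to one allele), 2000 generations recorded
#' every 10, 30 replicates. The equal-selection condition uses
#' `sMale = sFemale = 0.005`; the sex-specific condition raises
#' `sFemale` to 0.05.
#'
#' @param popSize census size after reproduction.
#' @param sMale,sFemale selection strengths (Gaussian fitness
#'   `exp(-s * P^2)`).
#' @param mutRate mutation probability per locus per individual per
#'   generation.
#' @param nParentPairs breeding pairs per generation.
#' @param offspringPerPair offspring per pair
#'   (`nParentPairs * offspringPerPair` must equal `popSize`).
#' @param nGenerations generations per replicate.
#' @param recordEvery recording interval (generations).
#' @param nReplicates independent replicates.
#' @param seed integer seed.
#' @return List of class `"EvoParams"`.
#' @export
evoParams <- function(popSize = 500L, sMale = 0.005, sFemale = 0.005,
                      mutRate = 5e-3, nParentPairs = 100L,
                      offspringPerPair = 5L, nGenerations = 2000L,
                      recordEvery = 10L, nReplicates = 30L, seed = 1L) {
  stopifnot(sMale >= 0, sFemale >= 0, mutRate >= 0, mutRate <= 1,
            nParentPairs * offspringPerPair == popSize,
            nGenerations >= 1, recordEvery >= 1, nReplicates >= 1)
  structure(list(popSize = as.integer(popSize), sMale = sMale,
                 sFemale = sFemale, mutRate = mutRate,
                 nParentPairs = as.integer(nParentPairs),
                 offspringPerPair = as.integer(offspringPerPair),
                 nGenerations = as.integer(nGenerations),
                 recordEvery = as.integer(recordEvery),
                 nReplicates = as.integer(nReplicates),
                 seed = as.integer(seed)), class = "EvoParams")
}

## Population representation: list with
##   alleles: popSize x 6 matrix (columns: shared.1, shared.2, male.1,
##            male.2, female.1, female.2)
##   sex:     logical, TRUE = male
##   E:       environmental deviates
.newPopulation <- function(popSize) {
  list(alleles = matrix(rnorm(popSize * 6), popSize, 6,
                        dimnames = list(NULL, c("shared.1", "shared.2",
                                                "male.1", "male.2",
                                                "female.1", "female.2"))),
       sex = rep(c(TRUE, FALSE), length.out = popSize),
       E = rnorm(popSize))
}

#' Phenotypes of all individuals
#'
#' `P = G + E` where G sums both alleles at the shared locus and both
#' alleles at the individual's own-sex locus; the opposite-sex locus is
#' carried silently.
#'
#' @param pop population list (`alleles`, `sex`, `E`).
#' @return Numeric phenotype per individual.
#' @export
evoPhenotype <- function(pop) {
  shared <- pop$alleles[, "shared.1"] + pop$alleles[, "shared.2"]
  own <- ifelse(pop$sex,
                pop$alleles[, "male.1"] + pop$alleles[, "male.2"],
                pop$alleles[, "female.1"] + pop$alleles[, "female.2"])
  shared + own + pop$E
}

#' Gaussian stabilizing-selection fitness
#'
#' @param s selection strength (>= 0).
#' @param P phenotype.
#' @return `exp(-s * P^2)` in (0, 1].
#' @export
evoFitness <- function(s, P) {
  stopifnot(all(s >= 0))
  exp(-s * P^2)
}

## One generation: viability selection (sex-specific s), then 100 males
## and 100 females drawn with replacement from the survivors, Mendelian
## transmission with free recombination, random offspring sex, fresh E,
## then mutation. If either sex has no survivors the viability draw is
## repeated (up to maxRedraws, then an error).
.nextGeneration <- function(pop, params, maxRedraws = 100L) {
  P <- evoPhenotype(pop)
  s <- ifelse(pop$sex, params$sMale, params$sFemale)
  w <- evoFitness(s, P)
  for (try in seq_len(maxRedraws + 1L)) {
    alive <- runif(length(w)) <= w
    if (any(alive & pop$sex) && any(alive & !pop$sex)) break
    if (try > maxRedraws)
      stop("population extinct: one sex had no survivors in ",
           maxRedraws, " consecutive viability draws")
  }
  maleIds <- which(alive & pop$sex)
  femaleIds <- which(alive & !pop$sex)
  # sample.int avoids sample()'s scalar surprise when only one survivor
  fathers <- rep(maleIds[sample.int(length(maleIds), params$nParentPairs,
                                    replace = TRUE)],
                 each = params$offspringPerPair)
  mothers <- rep(femaleIds[sample.int(length(femaleIds),
                                      params$nParentPairs,
                                      replace = TRUE)],
                 each = params$offspringPerPair)
  n <- params$popSize
  A <- matrix(0, n, 6, dimnames = dimnames(pop$alleles))
  for (locus in 0:2) {
    c1 <- 2 * locus + 1
    fromDad <- c1 + (runif(n) < 0.5)        # one allele from each parent,
    fromMom <- c1 + (runif(n) < 0.5)        # chosen independently per locus
    A[, c1] <- pop$alleles[cbind(fathers, fromDad)]
    A[, c1 + 1] <- pop$alleles[cbind(mothers, fromMom)]
  }
  newPop <- list(alleles = A, sex = runif(n) < 0.5, E = rnorm(n))
  evoMutate(newPop, params$mutRate)
}

#' Mutate allelic effects
#'
#' For every individual x locus, with probability `mutRate` one of the
#' two alleles (chosen uniformly) receives an independent standard-normal
#' increment.
#'
#' @param pop population list.
#' @param mutRate per-locus per-individual mutation probability.
#' @return The mutated population.
#' @export
evoMutate <- function(pop, mutRate) {
  if (mutRate <= 0) return(pop)
  n <- nrow(pop$alleles)
  for (locus in 0:2) {
    hit <- which(runif(n) < mutRate)
    if (length(hit) == 0) next
    col <- 2 * locus + 1 + (runif(length(hit)) < 0.5)
    idx <- cbind(hit, col)
    pop$alleles[idx] <- pop$alleles[idx] + rnorm(length(hit))
  }
  pop
}

#' Run replicate simulations of sex-specific stabilizing selection
#'
#' Each replicate initializes all allelic effects and environmental
#' deviates as standard-normal draws, then iterates viability selection,
#' random pairing with replacement, Mendelian reproduction and mutation.
#' Every `recordEvery` generations the phenotypic variance among males
#' and among females and the variance of the shared-locus allelic
#' effects (over all `2 * popSize` alleles) are recorded.
#'
#' @param params an [evoParams()] object.
#' @param sharedVarOver `"alleles"` (default: variance over the 2N
#'   shared-locus allelic effects) or `"individuals"` (variance of the
#'   per-individual shared-locus sums).
#' @return data.frame with columns `replicate`, `generation`,
#'   `var_pheno_male`, `var_pheno_female`, `var_shared_locus`.
#' @export
runEvoSim <- function(params, sharedVarOver = c("alleles", "individuals")) {
  stopifnot(inherits(params, "EvoParams"))
  sharedVarOver <- match.arg(sharedVarOver)
  set.seed(params$seed)
  repSeeds <- sample.int(2^31 - 1, params$nReplicates)
  rows <- list()
  for (r in seq_len(params$nReplicates)) {
    set.seed(repSeeds[r])
    pop <- .newPopulation(params$popSize)
    for (gen in seq_len(params$nGenerations)) {
      pop <- .nextGeneration(pop, params)
      if (gen %% params$recordEvery == 0) {
        P <- evoPhenotype(pop)
        sharedVar <- if (sharedVarOver == "alleles")
          var(c(pop$alleles[, "shared.1"], pop$alleles[, "shared.2"]))
        else var(pop$alleles[, "shared.1"] + pop$alleles[, "shared.2"])
        rows[[length(rows) + 1]] <- data.frame(
          replicate = r, generation = gen,
          var_pheno_male = var(P[pop$sex]),
          var_pheno_female = var(P[!pop$sex]),
          var_shared_locus = sharedVar)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
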