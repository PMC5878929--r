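#' Configuration for Balding-Nichols genotype simulation
#'
#' The island model used throughout for testable ground truth: ancestral
#' allele frequencies at each locus are Dirichlet-distributed; each
#' population's frequencies are then drawn from
#' \eqn{\mathrm{Dirichlet}(p (1-F)/F)}, so F is the expected F_ST between
#' a population and the ancestral pool; genotypes are two independent
#' draws per locus (Hardy-Weinberg and linkage equilibrium).
#'
#' @param n_populations number of populations (>= 1).
#' @param n_individuals individuals per population: scalar or vector of
#'   length \code{n_populations}.
#' @param n_loci number of loci.
#' @param alleles_min,alleles_max range of allele counts per locus
#'   (each locus draws its allele number uniformly from this range;
#'   microsatellite panels typically span 2-20).
#' @param f Balding-Nichols differentiation parameter in (0, 1): scalar
#'   or one value per locus.
#' @param concentration Dirichlet concentration for ancestral frequencies
#'   (1 = uniform over the simplex).
#' @param missing_rate per-genotype missingness probability in [0, 1).
#' @param seed integer seed.
#' @return list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_populations = 3, n_individuals = 30,
                              n_loci = 29, alleles_min = 2, alleles_max = 20,
                              f = 0.05, concentration = 1,
                              missing_rate = 0, seed = 1) {
  if (any(f <= 0) || any(f >= 1)) stop("f must be in (0, 1)")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_populations < 1 || n_loci < 1) stop("counts must be >= 1")
  if (alleles_min < 2 || alleles_max < alleles_min)
    stop("need alleles_max >= alleles_min >= 2")
  n_individuals <- rep_len(n_individuals, n_populations)
  if (any(n_individuals < 1)) stop("counts must be >= 1")
  if (!length(f) %in% c(1L, n_loci)) stop("f must be scalar or per-locus")
  structure(list(n_populations = as.integer(n_populations),
                 n_individuals = as.integer(n_individuals),
                 n_loci = as.integer(n_loci),
                 alleles_min = as.integer(alleles_min),
                 alleles_max = as.integer(alleles_max),
                 f = as.numeric(f), concentration = concentration,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  while (sum(x) == 0) x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

## Draw population frequencies around ancestral p with Balding-Nichols F.
bn_draw <- function(p, f) {
  rdirichlet(p * (1 - f) / f)
}

## Sample m diploid genotypes (allele code pairs) from frequency vector.
draw_genotypes <- function(freq, m, codes) {
  a1 <- sample(codes, m, replace = TRUE, prob = freq)
  a2 <- sample(codes, m, replace = TRUE, prob = freq)
  cbind(a1, a2)
}

#' Simulate a multi-population microsatellite-like dataset
#'
#' Balding-Nichols island model (see \code{\link{simulation_config}}).
#' A locus whose ancestral draw would leave fewer than 2 alleles with
#' appreciable frequency is resampled, so every locus is polymorphic in
#' the ancestral pool. Allele codes are arbitrary integers starting at
#' 101 (fragment-size-like, but carrying no size semantics).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list with \code{table} (a \code{genotype_table}, populations
#'   named \code{"P1"}, \code{"P2"}, ...) and \code{truth} (list holding
#'   the config plus, per locus, the ancestral and per-population latent
#'   allele frequencies).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    P <- config$n_populations
    L <- config$n_loci
    fvec <- rep_len(config$f, L)
    pops <- paste0("P", seq_len(P))
    n_ind <- config$n_individuals
    total <- sum(n_ind)
    ids <- sprintf("ind%03d", seq_len(total))
    labels <- rep(pops, n_ind)
    a1 <- a2 <- matrix(NA_integer_, total, L)
    truth_loci <- vector("list", L)
    for (l in seq_len(L)) {
      k <- sample(config$alleles_min:config$alleles_max, 1)
      repeat {
        anc <- rdirichlet(rep(config$concentration, k))
        if (sum(anc > 0.01) >= 2) break
      }
      codes <- 101L + seq_len(k) - 1L
      pop_freq <- lapply(seq_len(P), function(p) bn_draw(anc, fvec[l]))
      row0 <- 0L
      for (p in seq_len(P)) {
        g <- draw_genotypes(pop_freq[[p]], n_ind[p], codes)
        a1[row0 + seq_len(n_ind[p]), l] <- g[, 1]
        a2[row0 + seq_len(n_ind[p]), l] <- g[, 2]
        row0 <- row0 + n_ind[p]
      }
      truth_loci[[l]] <- list(k = k, codes = codes, ancestral = anc,
                              pop_freq = stats::setNames(pop_freq, pops))
    }
    if (config$missing_rate > 0) {
      miss <- matrix(stats::runif(total * L) < config$missing_rate, total, L)
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
    }
    locus_names <- sprintf("L%02d", seq_len(L))
    names(truth_loci) <- locus_names
    table <- genotype_table(ids, labels, locus_names, a1, a2,
                            metadata = list(simulated = TRUE,
                                            seed = config$seed))
    list(table = table,
         truth = list(config = config, loci = truth_loci,
                      dispersers = data.frame(individual = character(0),
                                              source = character(0),
                                              labelled = character(0),
                                              stringsAsFactors = FALSE)))
  })
}

#' Plant true dispersers into a simulated dataset
#'
#' Appends individuals whose genotypes are drawn from one population's
#' latent allele frequencies but who are labelled as sampled in another:
#' ground-truth first-generation dispersers for power estimation.
#'
#' @param sim result of \code{\link{simulate_dataset}} (list with
#'   \code{table} and \code{truth}).
#' @param plan data.frame with columns \code{source}, \code{labelled},
#'   \code{count}: how many dispersers to draw from \code{source} and
#'   label as \code{labelled} (source != labelled).
#' @param seed integer seed.
#' @return list like \code{sim}, with the planted individuals appended to
#'   \code{table} and recorded in \code{truth$dispersers}.
#' @export
plant_dispersers <- function(sim, plan, seed = 1) {
  stopifnot(is.list(sim), inherits(sim$table, "genotype_table"))
  if (nrow(plan) == 0) return(sim)
  if (!all(c("source", "labelled", "count") %in% names(plan)))
    stop("plan needs columns source, labelled, count")
  pops <- populations(sim$table)
  bad <- setdiff(c(plan$source, plan$labelled), pops)
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  if (any(plan$source == plan$labelled))
    stop("planted dispersers must have source != labelled")
  with_seed(seed, {
    L <- length(sim$table$locus_names)
    total_new <- sum(plan$count)
    a1 <- a2 <- matrix(NA_integer_, total_new, L)
    ids <- sprintf("disp%03d", seq_len(total_new))
    labels <- character(total_new)
    rec <- data.frame(individual = ids, source = NA_character_,
                      labelled = NA_character_, stringsAsFactors = FALSE)
    row0 <- 0L
    for (i in seq_len(nrow(plan))) {
      m <- plan$count[i]
      if (m == 0) next
      rows <- row0 + seq_len(m)
      for (l in seq_len(L)) {
        tl <- sim$truth$loci[[l]]
        g <- draw_genotypes(tl$pop_freq[[plan$source[i]]], m, tl$codes)
        a1[rows, l] <- g[, 1]
        a2[rows, l] <- g[, 2]
      }
      labels[rows] <- plan$labelled[i]
      rec$source[rows] <- plan$source[i]
      rec$labelled[rows] <- plan$labelled[i]
      row0 <- row0 + m
    }
    tb <- sim$table
    table <- genotype_table(c(tb$individual_ids, ids),
                            c(tb$population_labels, labels),
                            tb$locus_names,
                            rbind(tb$allele1, a1), rbind(tb$allele2, a2),
                            tb$metadata)
    # keep original population order (appended rows may interleave labels)
    ord <- order(match(table$population_labels, pops))
    table <- gt_subset(table, individuals = table$individual_ids[ord])
    truth <- sim$truth
    truth$dispersers <- rbind(truth$dispersers, rec)
    list(table = table, truth = truth)
  })
}

#' Starling-like synthetic preset
#'
#' Three populations of 32, 32 and 30 individuals typed at 29
#' microsatellite-like loci (2-20 alleles each), with a hierarchical
#' two-level Balding-Nichols structure: populations P2 and P3 diverge
#' mildly from a shared pool that is itself well separated from P1, so
#' that pairwise theta spans roughly 0.026 (P2-P3) to 0.08 (P1-P2,
#' P1-P3) — one genetically distinct population and two similar ones.
#'
#' @param seed integer seed.
#' @param missing_rate per-genotype missingness (default 0.02, a typical
#'   microsatellite panel dropout level).
#' @param f_far Balding-Nichols divergence of the distinct population
#'   from the ancestral pool.
#' @param f_near divergence of each of the two similar populations from
#'   their shared intermediate pool.
#' @return list with \code{table} and \code{truth}, as
#'   \code{\link{simulate_dataset}}.
#' @export
simulate_starling_panel <- function(seed = 1, missing_rate = 0.02,
                                    f_far = 0.068, f_near = 0.026) {
  with_seed(derive_seed(seed, "starling"), {
    L <- 29L
    n_ind <- c(32L, 32L, 30L)
    pops <- c("P1", "P2", "P3")
    total <- sum(n_ind)
    ids <- sprintf("ind%03d", seq_len(total))
    labels <- rep(pops, n_ind)
    a1 <- a2 <- matrix(NA_integer_, total, L)
    truth_loci <- vector("list", L)
    for (l in seq_len(L)) {
      k <- sample(2:20, 1)
      repeat {
        anc <- rdirichlet(rep(1, k))
        if (sum(anc > 0.01) >= 2) break
      }
      codes <- 101L + seq_len(k) - 1L
      mid <- bn_draw(anc, f_far)              # shared pool of P2/P3
      pop_freq <- list(P1 = bn_draw(anc, f_far),
                       P2 = bn_draw(mid, f_near),
                       P3 = bn_draw(mid, f_near))
      row0 <- 0L
      for (p in seq_len(3)) {
        g <- draw_genotypes(pop_freq[[p]], n_ind[p], codes)
        a1[row0 + seq_len(n_ind[p]), l] <- g[, 1]
        a2[row0 + seq_len(n_ind[p]), l] <- g[, 2]
        row0 <- row0 + n_ind[p]
      }
      truth_loci[[l]] <- list(k = k, codes = codes, ancestral = anc,
                              pop_freq = pop_freq)
    }
    if (missing_rate > 0) {
      miss <- matrix(stats::runif(total * L) < missing_rate, total, L)
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
    }
    locus_names <- sprintf("L%02d", seq_len(L))
    names(truth_loci) <- locus_names
    table <- genotype_table(ids, labels, locus_names, a1, a2,
                            metadata = list(simulated = TRUE, seed = seed,
                                            preset = "starling"))
    cfg <- simulation_config(3, n_ind, L, 2, 20, f = f_far,
                             missing_rate = missing_rate, seed = seed)
    list(table = table,
         truth = list(config = cfg, loci = truth_loci,
                      dispersers = data.frame(individual = character(0),
                                              source = character(0),
                                              labelled = character(0),
                                              stringsAsFactors = FALSE)))
  })
}
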