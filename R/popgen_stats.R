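#' Per-population allele counts and the global allele inventory
#'
#' Builds the frequency model every downstream statistic and the
#' assignment likelihood consume: for each locus, the global inventory of
#' distinct alleles observed across all populations pooled (its size k is
#' the prior dimension of the partial-Bayesian likelihood), and for each
#' population the vector of allele counts and the total number of called
#' alleles. Missing genotypes contribute nothing.
#'
#' @param table a \code{genotype_table}.
#' @return an object of class \code{freq_model}: list with \code{pops},
#'   \code{loci}, \code{inventory} (per locus, sorted allele codes),
#'   \code{counts} (per locus, populations x alleles count matrix) and
#'   \code{n} (populations x loci matrix of called allele totals).
#'   Population-locus cells with zero called alleles are recorded with
#'   \code{n = 0} (their frequencies are undefined, not zero).
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- populations(table)
  loci <- table$locus_names
  pop_idx <- match(table$population_labels, pops)
  inventory <- vector("list", length(loci))
  counts <- vector("list", length(loci))
  n <- matrix(0L, length(pops), length(loci), dimnames = list(pops, loci))
  for (l in seq_along(loci)) {
    a <- c(table$allele1[, l], table$allele2[, l])
    p <- rep(pop_idx, 2L)
    keep <- !is.na(a)
    inv <- sort(unique(a[keep]))
    if (length(inv) == 0) inv <- integer(0)
    cm <- matrix(0L, length(pops), max(1L, length(inv)),
                 dimnames = list(pops, if (length(inv)) as.character(inv) else "NA"))
    if (length(inv)) {
      tab <- table(factor(p[keep], levels = seq_along(pops)),
                   factor(a[keep], levels = inv))
      cm <- matrix(as.integer(tab), length(pops), length(inv),
                   dimnames = list(pops, as.character(inv)))
    }
    inventory[[l]] <- inv
    counts[[l]] <- cm
    n[, l] <- rowSums(cm)
  }
  names(inventory) <- names(counts) <- loci
  structure(list(pops = pops, loci = loci, inventory = inventory,
                 counts = counts, n = n),
            class = "freq_model")
}

#' @export
print.freq_model <- function(x, ...) {
  cat("freq_model: ", length(x$pops), " populations, ", length(x$loci),
      " loci, ", sum(lengths(x$inventory)), " alleles total\n", sep = "")
  invisible(x)
}

#' Polymorphic information content (PIC)
#'
#' Botstein et al.'s informativeness measure for a co-dominant locus:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#' A monomorphic locus scores 0; the supremum over frequency vectors is
#' below 1. Always bounded above by the expected heterozygosity
#' \eqn{1 - \sum_i p_i^2}.
#'
#' @param p numeric vector of allele frequencies summing to 1.
#' @return PIC value in [0, 1).
#' @export
pic <- function(p) {
  if (length(p) == 0) stop("empty frequency vector")
  if (any(p < 0)) stop("negative frequency")
  s <- sum(p)
  if (abs(s - 1) > 1e-8) stop("frequencies must sum to 1 (got ", s, ")")
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p_i^2)^2 - sum p_i^4
  1 - s2 - (s2^2 - sum(p^4))
}

#' Per-locus summary statistics
#'
#' PIC and expected heterozygosity are computed from allele frequencies
#' pooled over all individuals (population structure ignored), observed
#' heterozygosity from the pooled genotypes. Optionally adds a pooled
#' Hardy-Weinberg Monte Carlo p-value per locus.
#'
#' @param table a \code{genotype_table}.
#' @param hwe if \code{TRUE}, add a pooled-per-locus HWE p-value column.
#' @param n_permutations Monte Carlo sample size for the HWE test.
#' @param seed integer seed for the HWE permutations.
#' @return data.frame with one row per locus: \code{locus}, \code{n_alleles},
#'   \code{pic}, \code{het_obs}, \code{het_exp}, \code{n_typed} (individuals
#'   with a called genotype) and optionally \code{hwe_p}.
#' @export
locus_stats <- function(table, hwe = FALSE, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(table, "genotype_table"))
  loci <- table$locus_names
  out <- data.frame(locus = loci, n_alleles = NA_integer_, pic = NA_real_,
                    het_obs = NA_real_, het_exp = NA_real_,
                    n_typed = NA_integer_, stringsAsFactors = FALSE)
  for (l in seq_along(loci)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    ok <- !is.na(a1)
    out$n_typed[l] <- sum(ok)
    a <- c(a1[ok], a2[ok])
    if (length(a) == 0) next
    p <- as.numeric(table(a)) / length(a)
    out$n_alleles[l] <- length(p)
    out$pic[l] <- pic(p)
    out$het_exp[l] <- 1 - sum(p^2)
    out$het_obs[l] <- mean(a1[ok] != a2[ok])
  }
  if (hwe) {
    out$hwe_p <- vapply(seq_along(loci), function(l) {
      hwe_test_genotypes(table$allele1[, l], table$allele2[, l],
                         n_permutations, seed + l)
    }, numeric(1))
  }
  out
}

## Weir & Cockerham (1984) variance components for one allele at one locus.
## n_i: sample sizes (individuals with calls), p_i: allele frequency per pop,
## h_i: observed heterozygote frequency (for this allele) per pop.
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Pairwise Weir-Cockerham F_ST (theta)
#'
#' Multi-locus method-of-moments estimate
#' \eqn{\hat\theta = \sum a / \sum (a + b + c)}, variance components
#' summed over all alleles at all shared typed loci. Small negative values
#' are possible for undifferentiated populations.
#'
#' @param table a \code{genotype_table}.
#' @param popA,popB population labels present in the table.
#' @return scalar theta estimate.
#' @export
pairwise_fst <- function(table, popA, popB) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- populations(table)
  if (!popA %in% pops || !popB %in% pops)
    stop("unknown population label")
  if (popA == popB) stop("popA and popB must differ")
  iA <- table$population_labels == popA
  iB <- table$population_labels == popB
  num <- den <- 0
  used <- 0L
  for (l in seq_along(table$locus_names)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    okA <- iA & !is.na(a1); okB <- iB & !is.na(a1)
    nA <- sum(okA); nB <- sum(okB)
    if (nA < 2 || nB < 2) next
    alleles <- sort(unique(c(a1[okA | okB], a2[okA | okB])))
    for (al in alleles) {
      p_i <- c(sum(a1[okA] == al) + sum(a2[okA] == al),
               sum(a1[okB] == al) + sum(a2[okB] == al)) / (2 * c(nA, nB))
      h_i <- c(sum((a1[okA] == al) != (a2[okA] == al)),
               sum((a1[okB] == al) != (a2[okB] == al))) / c(nA, nB)
      comp <- wc_components(c(nA, nB), p_i, h_i)
      num <- num + comp[["a"]]
      den <- den + sum(comp)
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no locus typed in >= 2 individuals in both populations")
  num / den
}

#' Pairwise Shannon mutual information (I)
#'
#' Information shared between allele identity and population label,
#' \deqn{I = H(\mathrm{pooled}) - \sum_s w_s H_s,}
#' with natural logarithms, weights \eqn{w_s} proportional to called allele
#' counts, averaged (unweighted) over loci typed in both populations.
#' Zero iff the per-locus allele distributions coincide; an alternative to
#' F_ST that is more robust across population sizes and dispersal rates.
#'
#' @param table a \code{genotype_table}.
#' @param popA,popB population labels present in the table.
#' @return mean per-locus mutual information, in nats.
#' @export
mutual_information <- function(table, popA, popB) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- populations(table)
  if (!popA %in% pops || !popB %in% pops)
    stop("unknown population label")
  if (popA == popB) stop("popA and popB must differ")
  iA <- table$population_labels == popA
  iB <- table$population_labels == popB
  entropy <- function(counts) {
    p <- counts[counts > 0]
    p <- p / sum(p)
    -sum(p * log(p))
  }
  vals <- numeric(0)
  for (l in seq_along(table$locus_names)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    aA <- c(a1[iA], a2[iA]); aA <- aA[!is.na(aA)]
    aB <- c(a1[iB], a2[iB]); aB <- aB[!is.na(aB)]
    if (length(aA) == 0 || length(aB) == 0) next
    inv <- sort(unique(c(aA, aB)))
    cA <- as.numeric(table(factor(aA, levels = inv)))
    cB <- as.numeric(table(factor(aB, levels = inv)))
    wA <- length(aA) / (length(aA) + length(aB))
    I_l <- entropy(cA + cB) - wA * entropy(cA) - (1 - wA) * entropy(cB)
    vals <- c(vals, max(0, I_l))
  }
  if (length(vals) == 0) stop("no locus typed in both populations")
  mean(vals)
}

#' All pairwise differentiation statistics
#'
#' @param table a \code{genotype_table}.
#' @return data.frame with one row per unordered population pair:
#'   \code{popA}, \code{popB}, \code{theta_fst}, \code{mutual_information}.
#' @export
pairwise_differentiation <- function(table) {
  pops <- populations(table)
  if (length(pops) < 2) stop("need >= 2 populations")
  prs <- utils::combn(pops, 2)
  out <- data.frame(popA = prs[1, ], popB = prs[2, ],
                    theta_fst = NA_real_, mutual_information = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    out$theta_fst[i] <- pairwise_fst(table, out$popA[i], out$popB[i])
    out$mutual_information[i] <- mutual_information(table, out$popA[i], out$popB[i])
  }
  out
}

## log conditional probability (up to the shared allele-count constant) of a
## genotype array given its allele counts: proportional to 2^h / prod(g_ij!).
hwe_log_prob <- function(het_count, geno_counts) {
  het_count * log(2) - sum(lgamma(geno_counts + 1))
}

hwe_test_genotypes <- function(a1, a2, n_permutations, seed) {
  ok <- !is.na(a1)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) return(1)
  alleles <- c(a1, a2)
  if (length(unique(alleles)) < 2) return(1)  # monomorphic
  key <- function(x, y) paste(pmin(x, y), pmax(x, y))
  obs_tab <- table(key(a1, a2))
  obs_lp <- hwe_log_prob(sum(a1 != a2), as.numeric(obs_tab))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample(alleles)
    p1 <- perm[seq_len(n)]; p2 <- perm[n + seq_len(n)]
    lp <- hwe_log_prob(sum(p1 != p2), as.numeric(table(key(p1, p2))))
    if (lp <= obs_lp + 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_permutations)
}

#' Monte Carlo exact test for Hardy-Weinberg equilibrium
#'
#' Conditional exact test: the probability of the observed genotype array
#' given its allele counts is compared with arrays obtained by randomly
#' re-pairing the observed alleles. The p-value uses the
#' \eqn{(r+1)/(N+1)} estimator, so it lies in (0, 1]; a monomorphic locus
#' returns 1.
#'
#' @param table a \code{genotype_table}.
#' @param pop population label to test within.
#' @param locus locus name.
#' @param n_permutations number of Monte Carlo re-pairings (>= 1).
#' @param seed integer seed.
#' @return Monte Carlo p-value.
#' @export
hwe_test <- function(table, pop, locus, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(table, "genotype_table"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (!pop %in% populations(table)) stop("unknown population: ", pop)
  l <- match(locus, table$locus_names)
  if (is.na(l)) stop("unknown locus: ", locus)
  rows <- table$population_labels == pop
  if (sum(rows & !is.na(table$allele1[, l])) < 2)
    stop("fewer than 2 called genotypes for ", pop, " at ", locus)
  hwe_test_genotypes(table$allele1[rows, l], table$allele2[rows, l],
                     n_permutations, seed)
}

#' Hardy-Weinberg screening report across populations and loci
#'
#' Runs the Monte Carlo exact test per (population, locus), applies a
#' Bonferroni correction across all tests, and flags loci that depart from
#' equilibrium in two or more populations after correction — candidates
#' for exclusion (the decision is left to the user).
#'
#' @param table a \code{genotype_table}.
#' @param alpha family-wise significance level (default 0.05).
#' @param n_permutations Monte Carlo sample size per test.
#' @param seed integer seed.
#' @return list with \code{tests} (data.frame pop x locus p-values, raw and
#'   Bonferroni-adjusted, significance flag) and \code{flagged_loci}
#'   (character vector of loci significant in >= 2 populations).
#' @export
hwe_screen <- function(table, alpha = 0.05, n_permutations = 1000, seed = 1) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- populations(table)
  grid <- expand.grid(pop = pops, locus = table$locus_names,
                      stringsAsFactors = FALSE)
  grid$p <- NA_real_
  for (i in seq_len(nrow(grid))) {
    l <- match(grid$locus[i], table$locus_names)
    rows <- table$population_labels == grid$pop[i]
    if (sum(rows & !is.na(table$allele1[, l])) < 2) next
    grid$p[i] <- hwe_test_genotypes(table$allele1[rows, l],
                                    table$allele2[rows, l],
                                    n_permutations, seed + i)
  }
  grid$p_bonferroni <- pmin(1, grid$p * sum(!is.na(grid$p)))
  grid$significant <- !is.na(grid$p_bonferroni) & grid$p_bonferroni < alpha
  fails <- tapply(grid$significant, grid$locus, sum)
  flagged <- names(fails)[!is.na(fails) & fails >= 2]
  list(tests = grid, flagged_loci = as.character(flagged))
}

#' Rank loci by polymorphic information content
#'
#' @param stats data.frame with columns \code{locus} and \code{pic}
#'   (as returned by \code{\link{locus_stats}}).
#' @param direction \code{"highest_first"} (most informative first) or
#'   \code{"lowest_first"}. Ties preserve input order.
#' @return character vector of locus names in rank order.
#' @export
rank_loci <- function(stats, direction = c("highest_first", "lowest_first")) {
  direction <- match.arg(direction)
  if (!all(c("locus", "pic") %in% names(stats)))
    stop("stats must have 'locus' and 'pic' columns")
  if (anyNA(stats$pic)) stop("all loci must have PIC values")
  ord <- order(if (direction == "highest_first") -stats$pic else stats$pic)
  as.character(stats$locus[ord])
}
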