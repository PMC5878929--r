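#' Construct a genotype table
#'
#' The canonical in-memory container for co-dominant diploid multi-locus
#' genotypes with population labels. Alleles are stored as two integer
#' matrices (individuals x loci); a missing genotype has \code{NA} in both.
#' Allele codes are opaque non-negative integers (for microsatellites they
#' are usually fragment sizes, but no size semantics are assumed).
#'
#' A genotype is either fully missing at a locus or has both alleles
#' present: if only one allele of a pair is \code{NA} (a half-call), the
#' genotype is conservatively set to fully missing.
#'
#' @param individual_ids character vector of unique individual identifiers.
#' @param population_labels character vector, one label per individual;
#'   must form at least one non-empty group.
#' @param locus_names character vector of unique locus names.
#' @param allele1,allele2 integer matrices of dimension
#'   \code{length(individual_ids) x length(locus_names)} holding the two
#'   allele codes per genotype (\code{NA} = missing).
#' @param metadata free-form named list of provenance information.
#'
#' @return An object of class \code{genotype_table} with fields
#'   \code{individual_ids}, \code{population_labels}, \code{locus_names},
#'   \code{allele1}, \code{allele2}, \code{metadata}.
#' @export
genotype_table <- function(individual_ids, population_labels, locus_names,
                           allele1, allele2, metadata = list()) {
  individual_ids <- as.character(individual_ids)
  population_labels <- as.character(population_labels)
  locus_names <- as.character(locus_names)
  allele1 <- as.matrix(allele1)
  allele2 <- as.matrix(allele2)
  storage.mode(allele1) <- "integer"
  storage.mode(allele2) <- "integer"

  n <- length(individual_ids)
  L <- length(locus_names)
  if (anyDuplicated(individual_ids))
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]), collapse = ", "))
  if (anyDuplicated(locus_names))
    stop("duplicate locus names")
  if (length(population_labels) != n)
    stop("population_labels must have one entry per individual")
  if (n > 0 && L == 0)
    stop("at least one locus is required")
  if (!all(dim(allele1) == c(n, L)) || !all(dim(allele2) == c(n, L)))
    stop("allele matrices must be ", n, " x ", L)
  if (any(allele1 < 0, na.rm = TRUE) || any(allele2 < 0, na.rm = TRUE))
    stop("allele codes must be non-negative integers")
  if (n == 0)
    stop("empty table: no individuals")

  # half-calls collapse to fully missing
  half <- xor(is.na(allele1), is.na(allele2))
  if (any(half)) {
    allele1[half] <- NA_integer_
    allele2[half] <- NA_integer_
  }
  dimnames(allele1) <- dimnames(allele2) <- list(individual_ids, locus_names)

  structure(
    list(individual_ids = individual_ids,
         population_labels = population_labels,
         locus_names = locus_names,
         allele1 = allele1,
         allele2 = allele2,
         metadata = metadata),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  tab <- table(x$population_labels)
  cat("genotype_table: ", length(x$individual_ids), " individuals, ",
      length(x$locus_names), " loci, ", length(tab), " populations\n", sep = "")
  cat("  populations: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  miss <- mean(is.na(x$allele1))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Population names of a genotype table
#'
#' @param table a \code{genotype_table}.
#' @return character vector of population labels in order of first appearance.
#' @export
populations <- function(table) {
  stopifnot(inherits(table, "genotype_table"))
  unique(table$population_labels)
}

#' Subset a genotype table by loci and/or individuals
#'
#' Locus selection order is respected in the result, which is what nested
#' PIC-ranked panel construction relies on.
#'
#' @param table a \code{genotype_table}.
#' @param loci character vector of locus names to keep, in the requested
#'   order (default: all, original order).
#' @param individuals character vector of individual ids to keep
#'   (default: all).
#' @return a \code{genotype_table} restricted to the selection.
#' @export
gt_subset <- function(table, loci = NULL, individuals = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.null(loci)) loci <- table$locus_names
  if (is.null(individuals)) individuals <- table$individual_ids
  bad <- setdiff(loci, table$locus_names)
  if (length(bad)) stop("unknown locus name(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(individuals, table$individual_ids)
  if (length(bad)) stop("unknown individual id(s): ", paste(bad, collapse = ", "))
  li <- match(loci, table$locus_names)
  ii <- match(individuals, table$individual_ids)
  genotype_table(table$individual_ids[ii],
                 table$population_labels[ii],
                 loci,
                 table$allele1[ii, li, drop = FALSE],
                 table$allele2[ii, li, drop = FALSE],
                 table$metadata)
}

#' Relabel individuals into other populations
#'
#' Simulated dispersal is implemented as relabelling: the individual's
#' genotype is untouched, only its population label changes, so downstream
#' allele counts treat it as sampled in the target population.
#'
#' @param table a \code{genotype_table}.
#' @param map named character vector: names are individual ids, values are
#'   target population labels (which must already exist in the table).
#' @return a relabelled \code{genotype_table}.
#' @export
gt_relabel <- function(table, map) {
  stopifnot(inherits(table, "genotype_table"))
  if (length(map) == 0) return(table)
  if (is.null(names(map)) || any(names(map) == ""))
    stop("map must be a named vector (individual id -> population)")
  bad <- setdiff(names(map), table$individual_ids)
  if (length(bad)) stop("unknown individual id(s): ", paste(bad, collapse = ", "))
  pops <- populations(table)
  bad <- setdiff(unname(map), pops)
  if (length(bad)) stop("unknown target population(s): ", paste(bad, collapse = ", "))
  labels <- table$population_labels
  labels[match(names(map), table$individual_ids)] <- unname(map)
  genotype_table(table$individual_ids, labels, table$locus_names,
                 table$allele1, table$allele2, table$metadata)
}
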