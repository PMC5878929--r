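# Shared fixture builders; all randomness is locally seeded.

# A random but valid genotype table: useful for round-trip properties.
random_table <- function(seed, n_pops = 2, n_per_pop = 4, n_loci = 3,
                         max_allele = 99, missing_rate = 0.1) {
  set.seed(seed)
  n <- n_pops * n_per_pop
  a1 <- matrix(sample.int(max_allele, n * n_loci, replace = TRUE), n, n_loci)
  a2 <- matrix(sample.int(max_allele, n * n_loci, replace = TRUE), n, n_loci)
  miss <- matrix(runif(n * n_loci) < missing_rate, n, n_loci)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  genotype_table(sprintf("i%02d", seq_len(n)),
                 rep(sprintf("pop%d", seq_len(n_pops)), each = n_per_pop),
                 sprintf("loc%d", seq_len(n_loci)), a1, a2)
}

tables_equal <- function(x, y) {
  identical(x$individual_ids, y$individual_ids) &&
    identical(x$population_labels, y$population_labels) &&
    identical(x$locus_names, y$locus_names) &&
    identical(unname(x$allele1), unname(y$allele1)) &&
    identical(unname(x$allele2), unname(y$allele2))
}

# Small two-population table with known counts, for likelihood hand checks.
toy_two_pop <- function() {
  # popA: aa, ab  (counts a=3, b=1); popB: bb, bb (counts b=4)
  genotype_table(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"), "L1",
                 matrix(c(1L, 1L, 2L, 2L), 4, 1),
                 matrix(c(1L, 2L, 2L, 2L), 4, 1))
}
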