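#' Read a GENEPOP file
#'
#' Parses the de-facto interchange format for co-dominant population
#' genotypes. Both 2- and 3-digit allele encodings are accepted (the width
#' must be consistent within the file), individual ids may be separated
#' from genotypes by a comma and/or whitespace, and locus names may be
#' listed one per line or comma-separated on a single line. An all-zero
#' genotype string (\code{"0000"} / \code{"000000"}) is missing data; a
#' half-called genotype (one allele zero) is conservatively treated as
#' fully missing.
#'
#' @param path path to a GENEPOP text file.
#' @param pop_names optional character vector naming the populations in
#'   file order; defaults to \code{"pop1"}, \code{"pop2"}, ...
#' @return a \code{genotype_table}. The file title line is kept in
#'   \code{metadata$title}.
#' @export
read_genepop <- function(path, pop_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s+$", "", lines)
  if (length(lines) < 3) stop("not a GENEPOP file (fewer than 3 lines): ", path)
  title <- lines[[1]]

  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop) || first_pop < 3)
    stop("no POP record found (or it precedes the locus list): ", path)

  locus_lines <- trimws(lines[2:(first_pop - 1)])
  locus_lines <- locus_lines[nzchar(locus_lines)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (anyDuplicated(loci)) stop("duplicate locus names in header")
  L <- length(loci)

  ids <- character(0); pops <- integer(0)
  geno_rows <- list()
  pop_idx <- 0L
  pop_sizes <- integer(0)
  width <- NA_integer_

  for (k in seq(from = first_pop, to = length(lines))) {
    line <- lines[[k]]
    if (!nzchar(trimws(line))) next
    if (toupper(trimws(line)) == "POP") {
      if (pop_idx > 0L && pop_sizes[pop_idx] == 0L)
        stop("empty population (POP record ", pop_idx, ") in ", path)
      pop_idx <- pop_idx + 1L
      pop_sizes[pop_idx] <- 0L
      next
    }
    # "id , 0101 0202 ..." — comma optional, whitespace tolerated
    parts <- strsplit(line, ",", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      id <- trimws(parts[[1]])
      rest <- paste(parts[-1], collapse = ",")
    } else {
      toks0 <- strsplit(trimws(line), "\\s+")[[1]]
      id <- toks0[[1]]
      rest <- paste(toks0[-1], collapse = " ")
    }
    toks <- strsplit(trimws(rest), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L)
      stop("line ", k, ": expected ", L, " genotypes, found ", length(toks),
           " (individual '", id, "')")
    wid <- unique(nchar(toks))
    if (length(wid) != 1 || !wid %in% c(4L, 6L))
      stop("line ", k, ": genotype strings must be uniformly 4 or 6 characters")
    wid <- wid / 2L
    if (is.na(width)) width <- wid
    else if (width != wid)
      stop("line ", k, ": inconsistent allele digit width (", wid,
           " vs ", width, ")")
    a1 <- as.integer(substr(toks, 1L, width))
    a2 <- as.integer(substr(toks, width + 1L, 2L * width))
    if (anyNA(a1) || anyNA(a2))
      stop("line ", k, ": non-numeric genotype string")
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    ids <- c(ids, id)
    pops <- c(pops, pop_idx)
    pop_sizes[pop_idx] <- pop_sizes[pop_idx] + 1L
    geno_rows[[length(geno_rows) + 1L]] <- rbind(a1, a2)
  }
  if (pop_idx == 0L || pop_sizes[pop_idx] == 0L)
    stop("empty population at end of ", path)
  if (anyDuplicated(ids))
    stop("duplicate individual ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  if (is.null(pop_names)) pop_names <- paste0("pop", seq_len(pop_idx))
  if (length(pop_names) != pop_idx)
    stop("pop_names has length ", length(pop_names), " but file has ",
         pop_idx, " populations")

  allele1 <- do.call(rbind, lapply(geno_rows, function(g) g[1, ]))
  allele2 <- do.call(rbind, lapply(geno_rows, function(g) g[2, ]))
  genotype_table(ids, pop_names[pops], loci, allele1, allele2,
                 metadata = list(title = title, source = path,
                                 allele_digits = width))
}

#' Write a genotype table to a GENEPOP file
#'
#' @param table a \code{genotype_table}.
#' @param path output path.
#' @param digits allele encoding width, 2 or 3 (default 3, the widest
#'   interchange dialect). All allele codes must fit the width.
#' @param title title line for the file.
#' @return \code{path}, invisibly.
#' @export
write_genepop <- function(table, path, digits = 3,
                          title = "dispersim genotype export") {
  stopifnot(inherits(table, "genotype_table"))
  digits <- as.integer(digits)
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  maxcode <- 10L^digits - 1L
  mx <- max(c(table$allele1, table$allele2), na.rm = TRUE)
  if (mx > maxcode)
    stop("allele code ", mx, " does not fit ", digits, "-digit encoding")

  fmt <- function(a) {
    out <- formatC(a, width = digits, flag = "0")
    out[is.na(a)] <- strrep("0", digits)
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(table$locus_names, con)
  for (p in populations(table)) {
    writeLines("POP", con)
    rows <- which(table$population_labels == p)
    for (i in rows) {
      g <- paste0(fmt(table$allele1[i, ]), fmt(table$allele2[i, ]))
      writeLines(paste0(table$individual_ids[i], " , ",
                        paste(g, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a tabular (CSV/TSV) genotype file
#'
#' Expected layout: header \code{id,pop,<locus>_1,<locus>_2,...} with two
#' allele columns per locus; missing alleles coded as empty or 0.
#'
#' @param path path to a delimited text file.
#' @param sep field separator (default \code{","}).
#' @return a \code{genotype_table}.
#' @export
read_genotype_table <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 4) stop("expected id, pop and at least one locus pair")
  if (!all(tolower(names(df)[1:2]) == c("id", "pop")))
    stop("first two columns must be 'id' and 'pop'")
  acols <- names(df)[-(1:2)]
  if (length(acols) %% 2 != 0) stop("odd number of allele columns")
  base1 <- sub("_1$", "", acols[seq(1, length(acols), 2)])
  base2 <- sub("_2$", "", acols[seq(2, length(acols), 2)])
  if (!identical(base1, base2))
    stop("allele columns must come in <locus>_1,<locus>_2 pairs")
  to_int <- function(x) {
    x <- suppressWarnings(as.integer(x))
    x[!is.na(x) & x == 0L] <- NA_integer_
    x
  }
  a1 <- sapply(df[acols[seq(1, length(acols), 2)]], to_int)
  a2 <- sapply(df[acols[seq(2, length(acols), 2)]], to_int)
  if (nrow(df) == 1) { a1 <- t(a1); a2 <- t(a2) }
  genotype_table(df[[1]], df[[2]], base1, a1, a2,
                 metadata = list(source = path))
}

#' Write a genotype table to CSV
#'
#' Inverse of \code{\link{read_genotype_table}}; missing alleles are
#' written as 0.
#'
#' @param table a \code{genotype_table}.
#' @param path output path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
write_genotype_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "genotype_table"))
  L <- length(table$locus_names)
  out <- data.frame(id = table$individual_ids, pop = table$population_labels,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (l in seq_len(L)) {
    a1 <- table$allele1[, l]; a2 <- table$allele2[, l]
    a1[is.na(a1)] <- 0L; a2[is.na(a2)] <- 0L
    out[[paste0(table$locus_names[l], "_1")]] <- a1
    out[[paste0(table$locus_names[l], "_2")]] <- a2
  }
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
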