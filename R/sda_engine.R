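#' Select one simulated-disperser candidate per population
#'
#' Candidates are drawn uniformly (seeded) from the individuals of each
#' population whose membership p-value in the baseline detection run is at
#' least \code{exclusion_threshold} — individuals with low membership
#' probability are excluded because they may be real dispersers.
#'
#' @param table the unmodified \code{genotype_table}.
#' @param baseline result of \code{\link{detect_migrants}} on \code{table}.
#' @param seed integer seed for the random draw.
#' @param exclusion_threshold individuals with baseline p-value below this
#'   are ineligible (default 0.05).
#' @param override optional character vector of individual ids (one per
#'   population) to use verbatim instead of random selection.
#' @return named character vector: population label -> candidate id.
#' @export
select_candidates <- function(table, baseline, seed = 1,
                              exclusion_threshold = 0.05, override = NULL) {
  stopifnot(inherits(table, "genotype_table"))
  pops <- populations(table)
  if (!is.null(override)) {
    bad <- setdiff(override, table$individual_ids)
    if (length(bad)) stop("unknown individual id(s): ", paste(bad, collapse = ", "))
    homes <- table$population_labels[match(override, table$individual_ids)]
    if (anyDuplicated(homes) || !setequal(homes, pops))
      stop("override must name exactly one individual per population")
    return(stats::setNames(override[match(pops, homes)], pops))
  }
  out <- stats::setNames(character(length(pops)), pops)
  for (p in pops) {
    eligible <- baseline$individual[baseline$home == p &
                                    baseline$p_value >= exclusion_threshold]
    if (!length(eligible))
      stop("population ", p, ": no individual with membership p >= ",
           exclusion_threshold)
    out[p] <- with_seed(derive_seed(seed, "candidate", p),
                        sample(eligible, 1))
  }
  out
}

#' Enumerate disperser-placement treatments
#'
#' With one candidate per each of k populations, every placement function
#' (candidate -> population) is a treatment: k^k in total, including the
#' identity placement (no movement), which is treatment 0. More generally,
#' m candidates over k populations give k^m plans.
#'
#' @param candidates named character vector: home population -> candidate
#'   individual id.
#' @param populations_ character vector of population labels.
#' @return list of plans; each plan is a list with \code{id} (integer,
#'   identity = 0) and \code{placement} (named character vector:
#'   candidate id -> population it is placed in).
#' @export
enumerate_treatments <- function(candidates, populations_) {
  if (is.null(names(candidates)) || !all(names(candidates) %in% populations_))
    stop("candidates must be named by their home populations")
  homes <- names(candidates)
  m <- length(candidates)
  k <- length(populations_)
  if (k < 1) stop("need at least one population")
  grids <- expand.grid(rep(list(populations_), m), stringsAsFactors = FALSE)
  names(grids) <- unname(candidates)
  # identity plan first (id 0)
  is_identity <- apply(grids, 1, function(r) all(r == homes))
  ord <- order(!is_identity)
  grids <- grids[ord, , drop = FALSE]
  lapply(seq_len(nrow(grids)), function(i) {
    list(id = i - 1L,
         placement = stats::setNames(as.character(grids[i, ]),
                                     unname(candidates)))
  })
}

#' Nested locus panels from a ranked locus list
#'
#' The highest-first direction yields all L prefixes of the ranking
#' (sizes 1..L, the full panel included); the lowest-first direction
#' yields sizes 1..L-1 only, because its full panel duplicates the
#' highest-first one — 2L - 1 panels in total (57 for 29 loci).
#'
#' @param ranked_loci character vector of locus names ranked highest-PIC
#'   first.
#' @return list of panels; each is a list with \code{direction}
#'   (\code{"highest_first"}/\code{"lowest_first"}), \code{size}, and
#'   \code{loci} (the panel, in ranking order).
#' @export
prefix_series <- function(ranked_loci) {
  L <- length(ranked_loci)
  if (L < 1) stop("empty locus list")
  hi <- lapply(seq_len(L), function(m)
    list(direction = "highest_first", size = m, loci = ranked_loci[seq_len(m)]))
  if (L == 1) return(hi)
  lo_rank <- rev(ranked_loci)
  lo <- lapply(seq_len(L - 1), function(m)
    list(direction = "lowest_first", size = m, loci = lo_rank[seq_len(m)]))
  c(hi, lo)
}

classify_outcome <- function(placed_at_home, flagged, source_correct) {
  if (placed_at_home) {
    if (flagged) "false_positive" else "correct_resident"
  } else if (!flagged) {
    "false_negative"
  } else if (source_correct) {
    "correct_disperser"
  } else {
    "wrong_source"
  }
}

#' Run the Simulated Disperser Analysis grid
#'
#' For every (treatment plan, locus panel) cell: relabel the candidates
#' according to the plan, restrict to the panel's loci, re-run migrant
#' detection on the modified table, and classify each candidate:
#' \itemize{
#'   \item placed at home, not flagged: \code{correct_resident};
#'   \item placed at home, flagged: \code{false_positive};
#'   \item placed away, not flagged: \code{false_negative};
#'   \item placed away, flagged, assigned to its true home:
#'     \code{correct_disperser};
#'   \item placed away, flagged, assigned elsewhere: \code{wrong_source}.
#' }
#' Null distributions are recomputed for every (plan, panel) because
#' relabelling changes home-population allele counts; non-candidate
#' individuals are scored as part of each run but do not enter the grid.
#'
#' @param table the unmodified \code{genotype_table}.
#' @param candidates named character vector (home population ->
#'   candidate id), e.g. from \code{\link{select_candidates}}.
#' @param plans list of treatment plans from
#'   \code{\link{enumerate_treatments}}.
#' @param panels list of locus panels from \code{\link{prefix_series}}.
#' @param config an \code{\link{assignment_config}}.
#' @return data.frame of class \code{sda_grid}, one row per
#'   (treatment, candidate, panel): \code{treatment}, \code{disperser},
#'   \code{home}, \code{placed_in}, \code{direction}, \code{panel_size},
#'   \code{p_value}, \code{assigned_source}, \code{outcome},
#'   \code{correct} (logical). Cells whose detection run fails carry
#'   outcome \code{"error"} rather than being dropped.
#' @export
run_grid <- function(table, candidates, plans, panels,
                     config = assignment_config()) {
  stopifnot(inherits(table, "genotype_table"),
            inherits(config, "assignment_config"))
  pops <- populations(table)
  homes <- names(candidates)
  rows <- list()
  for (plan in plans) {
    relabelled <- gt_relabel(table, plan$placement)
    fm <- allele_frequencies(relabelled)
    home_idx <- match(relabelled$population_labels, fm$pops)
    arr <- try(locus_loglik_array(relabelled, fm, config$leave_one_out),
               silent = TRUE)
    null_arrs <- NULL
    if (!inherits(arr, "try-error")) {
      null_arrs <- lapply(seq_along(fm$pops), function(p)
        simulate_null_lls(fm, fm$pops[p], config$n_simulated,
                          derive_seed(config$seed, "grid", plan$id, fm$pops[p])))
    }
    cand_rows <- match(unname(candidates), relabelled$individual_ids)
    for (panel in panels) {
      keep <- fm$loci %in% panel$loci
      for (ci in seq_along(candidates)) {
        cand <- unname(candidates)[ci]
        home_pop <- homes[ci]                 # true collection locality
        placed <- plan$placement[[cand]]
        rec <- list(treatment = plan$id, disperser = cand, home = home_pop,
                    placed_in = placed, direction = panel$direction,
                    panel_size = panel$size, p_value = NA_real_,
                    assigned_source = NA_character_, outcome = "error",
                    correct = NA)
        if (!inherits(arr, "try-error")) {
          p <- match(placed, fm$pops)        # labelled (placement) population
          keep_p <- keep & fm$n[p, ] > 0
          if (any(keep_p)) {
            i <- cand_rows[ci]
            cs <- collapse_statistic(arr[i, , , drop = FALSE], keep_p, p,
                                     config$statistic)
            null_cs <- collapse_statistic(null_arrs[[p]], keep_p,
                                          rep(p, config$n_simulated),
                                          config$statistic)
            pv <- mc_pvalue(sort(null_cs$stat10), cs$stat10)
            flagged <- pv < config$alpha
            src <- fm$pops[cs$best]
            rec$p_value <- pv
            rec$assigned_source <- src
            rec$outcome <- classify_outcome(placed == home_pop, flagged,
                                            src == home_pop)
            rec$correct <- rec$outcome %in% c("correct_resident",
                                              "correct_disperser")
          }
        }
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(out) <- c("sda_grid", class(out))
  out
}

#' Minimal panel size for reliable classification
#'
#' For each (disperser, direction): the smallest panel size m such that
#' the disperser is classified correctly at every panel size >= m in every
#' treatment. \code{Inf} if no such size exists within the grid.
#'
#' @param grid an \code{sda_grid} from \code{\link{run_grid}}.
#' @return data.frame with columns \code{disperser}, \code{direction},
#'   \code{minimal_size}.
#' @export
minimal_panel <- function(grid) {
  if (!nrow(grid)) stop("empty grid")
  combos <- unique(grid[c("disperser", "direction")])
  combos$minimal_size <- NA_real_
  for (i in seq_len(nrow(combos))) {
    g <- grid[grid$disperser == combos$disperser[i] &
              grid$direction == combos$direction[i], ]
    sizes <- sort(unique(g$panel_size))
    ok_at <- vapply(sizes, function(m)
      all(g$correct[g$panel_size == m] %in% TRUE), logical(1))
    # smallest m such that every size >= m is fully correct
    good_from <- rev(cumprod(rev(ok_at))) == 1
    combos$minimal_size[i] <- if (any(good_from))
      sizes[which(good_from)[1]] else Inf
  }
  rownames(combos) <- NULL
  combos
}

#' Worst-case treatment plan
#'
#' The most stringent single validation scenario: each candidate is
#' placed in the population most genetically similar to its home
#' (minimum pairwise mutual information; Weir-Cockerham theta as a
#' fallback when mutual information is unavailable), and panels are
#' grown lowest-PIC-first. Similarity ties are broken lexicographically
#' (with a message).
#'
#' @param candidates named character vector (home population ->
#'   candidate id).
#' @param differentiation data.frame from
#'   \code{\link{pairwise_differentiation}} (columns \code{popA},
#'   \code{popB}, \code{mutual_information} and/or \code{theta_fst}).
#' @return list with \code{plan} (a treatment plan, id -1) and
#'   \code{direction} (\code{"lowest_first"}).
#' @export
worst_case_plan <- function(candidates, differentiation) {
  metric <- if ("mutual_information" %in% names(differentiation) &&
                !anyNA(differentiation$mutual_information))
    "mutual_information" else "theta_fst"
  homes <- names(candidates)
  placement <- stats::setNames(character(length(candidates)),
                               unname(candidates))
  for (ci in seq_along(candidates)) {
    h <- homes[ci]
    rows <- differentiation[differentiation$popA == h |
                            differentiation$popB == h, ]
    if (!nrow(rows)) stop("no pairwise statistics for population ", h)
    other <- ifelse(rows$popA == h, rows$popB, rows$popA)
    val <- rows[[metric]]
    best <- which(val <= min(val) + 1e-15)
    if (length(best) > 1) {
      message("similarity tie for ", h, "; breaking lexicographically")
      best <- best[order(other[best])][1]
    }
    placement[ci] <- other[best]
  }
  list(plan = list(id = -1L, placement = placement),
       direction = "lowest_first")
}

#' Heatmap of SDA outcomes
#'
#' One tile per (treatment, panel size) per disperser and ranking
#' direction; colours distinguish correct classification, undetected
#' dispersal/false positives, and detection with a wrong source.
#'
#' @param grid an \code{sda_grid}.
#' @return a ggplot object (facets: disperser x direction).
#' @export
plot_sda_heatmap <- function(grid) {
  grid$outcome <- factor(grid$outcome,
                         levels = c("correct_resident", "correct_disperser",
                                    "false_positive", "false_negative",
                                    "wrong_source", "error"))
  ggplot2::ggplot(grid,
                  ggplot2::aes(x = .data$panel_size,
                               y = factor(.data$treatment),
                               fill = .data$outcome)) +
    ggplot2::geom_tile(colour = "grey90", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = c(
      correct_resident = "#2166ac", correct_disperser = "#4393c3",
      false_positive = "#b2182b", false_negative = "#d6604d",
      wrong_source = "#f4a582", error = "grey50"), drop = FALSE) +
    ggplot2::facet_grid(disperser ~ direction) +
    ggplot2::labs(x = "panel size (loci)", y = "treatment",
                  fill = "outcome") +
    ggplot2::theme_minimal()
}

#' Export an SDA grid as tidy CSV
#'
#' @param grid an \code{sda_grid}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE)
  invisible(path)
}
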