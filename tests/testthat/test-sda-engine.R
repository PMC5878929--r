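test_that("treatment enumeration covers every placement combination", {
  pops3 <- c("X", "Y", "Z")
  cand3 <- setNames(c("a", "b", "c"), pops3)
  plans <- enumerate_treatments(cand3, pops3)
  expect_equal(length(plans), 27)                      # 3^3
  expect_equal(plans[[1]]$id, 0L)
  expect_equal(plans[[1]]$placement, setNames(pops3, c("a", "b", "c")))
  keys <- vapply(plans, function(p) paste(p$placement, collapse = "|"),
                 character(1))
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(length(enumerate_treatments(setNames("a", "X"), "X")), 1)
  plans2 <- enumerate_treatments(setNames(c("a", "b"), c("X", "Y")),
                                 c("X", "Y"))
  expect_equal(length(plans2), 4)                      # brute force: 2^2
  expect_error(enumerate_treatments(c("a", "b"), c("X", "Y")), "named")
})

test_that("nested panel series has 2L - 1 members with the right sizes", {
  loci29 <- sprintf("m%02d", 1:29)
  panels <- prefix_series(loci29)
  expect_equal(length(panels), 57)                     # 29 + 28
  expect_equal(length(prefix_series("solo")), 1)
  p5 <- prefix_series(letters[1:5])
  expect_equal(length(p5), 9)
  hi <- Filter(function(p) p$direction == "highest_first", p5)
  lo <- Filter(function(p) p$direction == "lowest_first", p5)
  expect_equal(vapply(hi, `[[`, numeric(1), "size"), 1:5)
  expect_equal(vapply(lo, `[[`, numeric(1), "size"), 1:4)
  # prefixes nest and follow the ranking / its reverse
  expect_equal(hi[[3]]$loci, c("a", "b", "c"))
  expect_equal(lo[[2]]$loci, c("e", "d"))
  expect_error(prefix_series(character(0)), "empty")
})

test_that("candidate selection excludes low-membership individuals", {
  sim <- simulate_starling_panel(seed = 2)
  cfg <- assignment_config(n_simulated = 200, seed = 3)
  baseline <- detect_migrants(sim$table, cfg)
  cand <- select_candidates(sim$table, baseline, seed = 5)
  expect_equal(names(cand), c("P1", "P2", "P3"))
  # deterministic under the seed
  expect_identical(cand, select_candidates(sim$table, baseline, seed = 5))
  # eligibility respects the membership threshold
  for (p in names(cand)) {
    pv <- baseline$p_value[baseline$individual == cand[[p]]]
    expect_gte(pv, 0.05)
  }
  # explicit override returned verbatim
  ids <- vapply(c("P1", "P2", "P3"), function(p)
    sim$table$individual_ids[sim$table$population_labels == p][1],
    character(1))
  expect_equal(select_candidates(sim$table, baseline, override = unname(ids)),
               ids)
  # impossible threshold: no eligible individual
  expect_error(select_candidates(sim$table, baseline,
                                 exclusion_threshold = 2), "no individual")
})

test_that("the SDA grid is complete, exclusive and sane on easy data", {
  sim <- simulate_dataset(simulation_config(2, 20, 10, f = 0.25,
                                            alleles_max = 8, seed = 14))
  cfg <- assignment_config(n_simulated = 150, seed = 21)
  baseline <- detect_migrants(sim$table, cfg)
  cand <- select_candidates(sim$table, baseline, seed = 1)
  plans <- enumerate_treatments(cand, populations(sim$table))
  ranked <- rank_loci(locus_stats(sim$table), "highest_first")
  panels <- prefix_series(ranked)
  grid <- run_grid(sim$table, cand, plans, panels, cfg)
  # one record per (plan, panel, candidate); nothing dropped
  expect_equal(nrow(grid), length(plans) * length(panels) * length(cand))
  expect_false(any(grid$outcome == "error"))
  # outcome classes are a function of (placement, flag, source): exhaustive
  expect_true(all(grid$outcome %in% c("correct_resident", "correct_disperser",
                                      "false_positive", "false_negative",
                                      "wrong_source")))
  at_home <- grid$placed_in == grid$home
  expect_true(all(grid$outcome[at_home] %in% c("correct_resident",
                                               "false_positive")))
  expect_true(all(grid$outcome[!at_home] %in% c("correct_disperser",
                                                "false_negative",
                                                "wrong_source")))
  # identity treatment with the full, strongly differentiated panel:
  # every candidate is a correct resident
  full <- grid[grid$treatment == 0 & grid$panel_size == 10, ]
  expect_true(all(full$outcome == "correct_resident"))
  # moved dispersers flagged with the right source are correct_disperser
  moved_ok <- grid[!at_home & grid$p_value < cfg$alpha &
                     grid$assigned_source == grid$home, ]
  expect_true(all(moved_ok$outcome == "correct_disperser"))
  # correct-rate roughly improves with panel size (strong differentiation)
  rate <- tapply(grid$correct, grid$panel_size, mean)
  expect_gt(cor(as.numeric(names(rate)), rate, method = "spearman"), 0)
})

test_that("minimal panel size is the smallest size with no later failure", {
  mk <- function(sizes, correct) data.frame(
    treatment = 0, disperser = "d", home = "A", placed_in = "B",
    direction = "highest_first", panel_size = sizes, p_value = NA,
    assigned_source = "A", outcome = ifelse(correct, "correct_disperser",
                                            "false_negative"),
    correct = correct)
  expect_equal(minimal_panel(mk(1:10, rep(TRUE, 10)))$minimal_size, 1)
  expect_equal(minimal_panel(mk(1:10, c(rep(FALSE, 6), rep(TRUE, 4))))$minimal_size, 7)
  # a late failure pushes the minimal size past it
  cor <- rep(TRUE, 10); cor[c(3, 8)] <- FALSE
  expect_equal(minimal_panel(mk(1:10, cor))$minimal_size, 9)
  expect_equal(minimal_panel(mk(1:10, rep(FALSE, 10)))$minimal_size, Inf)
  expect_error(minimal_panel(mk(1, TRUE)[0, ]), "empty")
  # the two directions are summarised independently
  g <- rbind(mk(1:5, rep(TRUE, 5)),
             transform(mk(1:5, c(FALSE, TRUE, TRUE, TRUE, TRUE)),
                       direction = "lowest_first"))
  mp <- minimal_panel(g)
  expect_equal(mp$minimal_size[mp$direction == "highest_first"], 1)
  expect_equal(mp$minimal_size[mp$direction == "lowest_first"], 2)
})

test_that("the worst case moves candidates to their most similar population", {
  cand <- setNames(c("a", "b"), c("X", "Y"))
  diffs <- data.frame(popA = "X", popB = "Y",
                      theta_fst = 0.05, mutual_information = 0.1)
  wc <- worst_case_plan(cand, diffs)
  expect_equal(wc$direction, "lowest_first")
  expect_equal(wc$plan$placement, setNames(c("Y", "X"), c("a", "b")))
  # argmin over a random similarity matrix equals a brute-force scan
  set.seed(19)
  pops <- c("P", "Q", "R", "S")
  prs <- t(combn(pops, 2))
  diffs4 <- data.frame(popA = prs[, 1], popB = prs[, 2],
                       theta_fst = runif(6), mutual_information = runif(6))
  cand4 <- setNames(paste0("c", 1:4), pops)
  wc4 <- worst_case_plan(cand4, diffs4)
  for (p in pops) {
    rows <- diffs4[diffs4$popA == p | diffs4$popB == p, ]
    other <- ifelse(rows$popA == p, rows$popB, rows$popA)
    expect_equal(unname(wc4$plan$placement[cand4[[p]]]),
                 other[which.min(rows$mutual_information)])
  }
  # ties break lexicographically
  tie <- data.frame(popA = c("X", "X", "Y"), popB = c("Y", "Z", "Z"),
                    mutual_information = c(0.2, 0.2, 0.3),
                    theta_fst = c(0.1, 0.1, 0.2))
  cand3 <- setNames(c("a", "b", "c"), c("X", "Y", "Z"))
  expect_message(wc3 <- worst_case_plan(cand3, tie), "tie")
  expect_equal(unname(wc3$plan$placement[["a"]]), "Y")
})

test_that("heatmap and CSV export run on a small grid", {
  g <- data.frame(treatment = rep(0:1, each = 2), disperser = "d",
                  home = "A", placed_in = c("A", "B"),
                  direction = "highest_first", panel_size = rep(1:2, 2),
                  p_value = 0.5,
                  assigned_source = "A",
                  outcome = c("correct_resident", "false_negative",
                              "correct_resident", "correct_disperser"),
                  correct = c(TRUE, FALSE, TRUE, TRUE))
  class(g) <- c("sda_grid", class(g))
  plt <- plot_sda_heatmap(g)
  expect_s3_class(plt, "ggplot")
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 4)
  expect_equal(back$outcome, g$outcome)
})
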