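test_that("coordination function is exact full-assignment match", {
  expect_equal(coordination_function("LLRR", "LLRR"), 1)
  expect_equal(coordination_function("LLRR", "LLRL"), 0)
  for (a in c("L", "RL", "LLRRL")) expect_equal(coordination_function(a, a), 1)
  expect_error(coordination_function("LL", "LLR"), "length")
})

test_that("coordination index matches its definition and bounds", {
  expect_equal(coordination_index(rep("LLR", 7))$value, 1)
  expect_equal(coordination_index(c("LL", "LR", "RL", "RR"))$value, 0)
  # counts (3, 1) over N = 4: 3 coinciding pairs of 6
  expect_equal(coordination_index(c("LR", "LR", "LR", "RL"))$value, 0.5)
  expect_error(coordination_index("LR"), "at least 2")
  expect_error(coordination_index(c("LR", "LRR")), "length")
})

test_that("coordination index equals the pair-enumeration oracle", {
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(2:8, 1)
    len <- sample(1:4, 1)
    choices <- replicate(n, paste(sample(c("L", "R"), len, replace = TRUE),
                                  collapse = ""))
    ci <- coordination_index(choices)
    expect_equal(ci$value, ci_oracle(choices))
    expect_equal(sum(ci$solution_counts), n)
    expect_gte(ci$value, 0); expect_lte(ci$value, 1)
  }
})

test_that("random-picking CI is 1/2^n by enumeration", {
  expect_equal(random_picking_ci(mk_board(list(c(1, 1)))), 0.5)
  expect_equal(random_picking_ci(random_test_board(4, 5)), 1 / 16)
  expect_equal(random_picking_ci(random_test_board(5, 6)), 1 / 32)
})

mk_small_rm <- function(choices, n_boards_circles = NULL, t_predef = NULL) {
  k <- ncol(choices)
  boards <- lapply(seq_len(k), function(j) {
    n <- nchar(choices[1, j])
    b <- random_test_board(n, seed = 77 + j)
    b$board_id <- paste0("g", j)
    b
  })
  colnames(choices) <- paste0("g", seq_len(k))
  response_matrix(choices, boards,
                  t_predef = if (is.null(t_predef)) k else t_predef)
}

test_that("iCA matches hand-computed pairwise coordination", {
  # 3 players, 2 games; player 1 matches player 2 in game 1 only
  ch <- rbind(p1 = c("LL", "LR"), p2 = c("LL", "RL"), p3 = c("RR", "RR"))
  m <- mk_small_rm(ch)
  s <- ica(m)
  expect_equal(unname(s["p1"]), 1 / 4)  # 1 match of (N-1)*t = 4 slots
  expect_equal(ica(m, player = "p1"), c(p1 = 1 / 4))
  # all identical -> 1; loner -> 0
  m1 <- mk_small_rm(rbind(a = c("LL", "LR"), b = c("LL", "LR"),
                          c = c("LL", "LR")))
  expect_equal(unname(ica(m1)), rep(1, 3))
  m0 <- mk_small_rm(rbind(a = c("LL", "LR"), b = c("LL", "LR"),
                          c = c("RR", "RL")))
  expect_equal(unname(ica(m0, player = "c")), 0)
})

test_that("iCA only uses the predefined board subset by default", {
  ch <- rbind(p1 = c("LL", "LR"), p2 = c("LL", "RR"))
  m <- mk_small_rm(ch, t_predef = 1)
  expect_equal(unname(ica(m)), c(1, 1))          # agree on the predefined game
  expect_equal(unname(ica(m, predefined_only = FALSE)), c(0.5, 0.5))
})

test_that("iCA is invariant to player and game relabeling", {
  set.seed(31)
  ch <- matrix(replicate(5 * 3, paste(sample(c("L", "R"), 2, replace = TRUE),
                                      collapse = "")), nrow = 5)
  rownames(ch) <- paste0("p", 1:5)
  m <- mk_small_rm(ch)
  s <- ica(m)
  perm_p <- sample(5); perm_g <- sample(3)
  ch2 <- ch[perm_p, perm_g]
  boards2 <- m$boards[perm_g]
  m2 <- response_matrix(ch2, boards2)
  expect_equal(ica(m2)[m$players], s)
})

test_that("duplicating a player's answers cannot decrease their iCA", {
  set.seed(32)
  for (rep in 1:10) {
    ch <- matrix(replicate(4 * 2, paste(sample(c("L", "R"), 2, replace = TRUE),
                                        collapse = "")), nrow = 4)
    rownames(ch) <- paste0("p", 1:4)
    m <- mk_small_rm(ch)
    base <- unname(ica(m, player = "p1"))
    ch2 <- rbind(ch, p5 = ch["p1", ])
    m2 <- mk_small_rm(ch2)
    expect_gte(unname(ica(m2, player = "p1")), base)
  }
})

test_that("game tags follow the availability/usage coding", {
  b <- mk_board(list(c(1, 0), c(9, 0)))
  r <- closeness_rule(b)
  expect_equal(game_tag("LR", r), 1L)
  expect_equal(game_tag("RL", r), -1L)
  r0 <- closeness_rule(mk_board(list(c(5, 0))))
  expect_equal(game_tag("L", r0), 0L)
  # two rules implying the same assignment both tag +1
  b2 <- mk_board(list(c(1, 1), c(2, 3), c(8, 1), c(9, 3)), sl = c(0, 2),
                 sr = c(10, 2), w = 12, h = 8)
  rc <- closeness_rule(b2); re <- equality_rule(b2)
  expect_equal(rc$assignment, re$assignment)
  expect_equal(game_tag(rc$assignment, rc), 1L)
  expect_equal(game_tag(re$assignment, re), 1L)
})

test_that("strategy rate follows the +1 / nonzero ratio with NA when empty", {
  expect_equal(round_half_up(strategy_rate(c(1, 1, 1, 1, 1, -1, -1, -1)), 2),
               0.63)  # 5 of 8
  expect_equal(strategy_rate(c(1, 1, 1, 1, -1, -1, -1, -1, -1, -1)), 0.40)
  expect_equal(strategy_rate(c(1, 0, 1, 0)), 1)
  expect_true(is.na(strategy_rate(c(0, 0, 0))))
  expect_error(strategy_rate(c(2, 0)), "game tags")
  # games where the rule is unavailable do not affect the rate
  gt <- c(1, -1, 1, 0, 0)
  expect_equal(strategy_rate(gt), strategy_rate(gt[gt != 0]))
})

test_that("utilization ratio counts rule-followers and flags inapplicable", {
  boards <- list(predefined_boards()[[1]], predefined_boards()[[7]])
  boards[[1]]$board_id <- "g1"; boards[[2]]$board_id <- "g2"
  ch <- rbind(p1 = c("LR", "L"), p2 = c("LR", "R"), p3 = c("RL", "L"))
  colnames(ch) <- c("g1", "g2")
  m <- response_matrix(ch, boards)
  expect_equal(utilization_ratio(m, "g1", "closeness"), 2 / 3)
  expect_true(is.na(utilization_ratio(m, "g2", "closeness")))
  gs <- game_summary(m)
  expect_equal(gs$util_closeness, c(2 / 3, NA))
  expect_equal(gs$random_ci, c(0.25, 0.5))
})

test_that("utilization-CI regression recovers exact linear relations", {
  ci <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  util <- 0.2 + 0.8 * ci
  r <- suppressWarnings(utilization_vs_ci_regression(ci, util))  # exact fit
  expect_equal(r$slope, 0.8, tolerance = 1e-10)
  expect_equal(r$intercept, 0.2, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-8)
  expect_error(utilization_vs_ci_regression(rep(0.5, 5), util), "constant")
})

test_that("the slope test holds its size under independence", {
  set.seed(41)
  rejections <- 0
  for (rep in 1:200) {
    ci <- runif(10)
    util <- runif(10)  # independent of ci
    r <- utilization_vs_ci_regression(ci, util)
    if (r$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 200, 0.10)  # non-significant in >= 90% of draws
})

test_that("strategy-rate ANOVA flags a shifted dimension via Tukey", {
  set.seed(51)
  n <- 40
  prof <- data.frame(player = paste0("p", 1:n),
                     sr_closeness = runif(n, 0.4, 0.6),
                     sr_equality = runif(n, 0.4, 0.6),
                     sr_accession = runif(n, 0.4, 0.6))
  same <- compare_strategy_rates(prof)
  expect_gt(same$p_value, 0.05)
  prof2 <- prof
  prof2$sr_accession <- prof2$sr_accession - 0.35
  diff <- compare_strategy_rates(prof2)
  expect_lt(diff$p_value, 0.001)
  acc_rows <- grepl("accession", diff$tukey$comparison)
  expect_true(all(diff$tukey$p_adj[acc_rows] < 0.001))
  expect_true(all(diff$tukey$p_adj[!acc_rows] > 0.05))
})

test_that("identical strategy-rate columns give F near zero", {
  prof <- data.frame(sr_closeness = seq(0.1, 0.9, length.out = 15),
                     sr_equality = seq(0.1, 0.9, length.out = 15),
                     sr_accession = seq(0.1, 0.9, length.out = 15))
  r <- compare_strategy_rates(prof)
  expect_equal(r$f_stat, 0, tolerance = 1e-10)
  expect_true(all(r$tukey$p_adj > 0.99))
})

test_that("permutation p-values agree with the F test on Gaussian rates", {
  set.seed(61)
  n <- 30
  prof <- data.frame(sr_closeness = pmin(pmax(rnorm(n, 0.55, 0.1), 0), 1),
                     sr_equality = pmin(pmax(rnorm(n, 0.5, 0.1), 0), 1),
                     sr_accession = pmin(pmax(rnorm(n, 0.45, 0.1), 0), 1))
  a <- compare_strategy_rates(prof)
  p <- compare_strategy_rates(prof, method = "permutation", n_perm = 2000,
                              seed = 62)
  expect_equal(p$f_stat, a$f_stat)
  se <- sqrt(a$p_value * (1 - a$p_value) / 2000)
  expect_lt(abs(p$p_value - a$p_value), 4 * se + 0.01)
})

test_that("players with undefined rates are excluded with a warning", {
  prof <- data.frame(sr_closeness = c(0.5, 0.6, NA, 0.7),
                     sr_equality = c(0.4, 0.5, 0.6, 0.7),
                     sr_accession = c(0.3, 0.2, 0.1, 0.4))
  expect_warning(r <- compare_strategy_rates(prof), "excluded")
  expect_equal(r$n_players, 3)
})
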