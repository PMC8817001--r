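#' Coordination function
#'
#' Indicator of successful coordination between two full assignments of the
#' same board: 1 when both players attached every circle to the same square,
#' 0 otherwise.
#'
#' @param a,b L/R assignment strings of equal length.
#' @return 0 or 1.
#' @export
coordination_function <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop_("assignments '%s' and '%s' differ in length", a, b)
  as.integer(a == b)
}

#' Coordination index of a game
#'
#' The probability that two distinct players, drawn at random without
#' replacement, chose the same solution:
#' \deqn{c = \sum_j m_j (m_j - 1) / (N (N - 1))}
#' where \eqn{m_j} counts the players who chose solution \eqn{j}. The index
#' is 1 when all players coincide and 0 when all differ; under uniform
#' random picking its expectation is 1/2^n for an n-circle board.
#'
#' @param choices character vector of assignment strings for one board
#'   (length at least 2, all the same string length).
#' @param board_id optional board label.
#' @return an object of class \code{coordination_index}: list with
#'   \code{board_id}, \code{value}, \code{n_players} and
#'   \code{solution_counts}.
#' @export
coordination_index <- function(choices, board_id = NA_character_) {
  n <- length(choices)
  if (n < 2) stop_("the coordination index needs at least 2 choices")
  if (length(unique(nchar(choices))) != 1)
    stop_("choices differ in assignment length")
  m <- table(choices)
  value <- sum(m * (m - 1)) / (n * (n - 1))
  structure(list(board_id = board_id, value = value, n_players = n,
                 solution_counts = c(m)),
            class = "coordination_index")
}

#' @export
print.coordination_index <- function(x, ...) {
  cat(sprintf("<coordination_index%s> c = %.4f (N = %d, %d distinct solutions)\n",
              if (is.na(x$board_id)) "" else paste0(" '", x$board_id, "'"),
              x$value, x$n_players, length(x$solution_counts)))
  invisible(x)
}

#' Random-picking coordination index of a board
#'
#' Expected coordination index when every player chooses uniformly at random
#' over the full solution space, computed by enumerating all 2^n assignments
#' (the probability that two independent uniform picks coincide, i.e. 1/2^n).
#'
#' @param board a [game_board()].
#' @return numeric scalar.
#' @export
random_picking_ci <- function(board) {
  sols <- enumerate_assignments(board)
  p <- rep(1 / length(sols), length(sols))
  sum(p^2)
}

#' Individual coordination ability
#'
#' A player's mean pairwise coordination rate against every other player
#' over the predefined boards:
#' \deqn{iCA(i) = \sum_{j \ne i} \sum_{k=1}^{t} CF(i,j,k) / ((N-1) t).}
#' By default only the first \code{t_predef} boards of the response matrix
#' enter the computation, since only those are shared by all players.
#'
#' @param matrix a [response_matrix()] with at least 2 players.
#' @param player a player identifier, or \code{NULL} for all players.
#' @param predefined_only restrict to the predefined board subset
#'   (default \code{TRUE}).
#' @return a named numeric vector of iCA scores in [0, 1] (length 1 when
#'   \code{player} is given).
#' @export
ica <- function(matrix, player = NULL, predefined_only = TRUE) {
  stopifnot(inherits(matrix, "response_matrix"))
  ch <- matrix$choices
  N <- nrow(ch)
  if (N < 2) stop_("iCA needs at least 2 players")
  cols <- if (predefined_only) seq_len(matrix$t_predef) else seq_len(ncol(ch))
  t <- length(cols)
  agree <- numeric(N)
  for (k in cols) {
    same <- outer(ch[, k], ch[, k], "==")
    agree <- agree + rowSums(same) - 1  # drop self-match
  }
  scores <- agree / ((N - 1) * t)
  names(scores) <- matrix$players
  if (!is.null(player)) {
    if (!player %in% matrix$players) stop_("unknown player '%s'", player)
    scores <- scores[player]
  }
  scores
}

#' Game tag of a choice under a rule
#'
#' Per player, game and rule: 0 when the rule is not applicable on the
#' board; +1 when the player's choice equals the rule's implied assignment;
#' -1 when the rule was available but not followed.
#'
#' @param choice an assignment string.
#' @param rule_result a \code{rule_result} from the rule engine.
#' @return -1, 0 or 1.
#' @export
game_tag <- function(choice, rule_result) {
  stopifnot(inherits(rule_result, "rule_result"))
  if (!rule_result$applicable) return(0L)
  if (nchar(choice) != nchar(rule_result$assignment))
    stop_("choice length does not match the rule's implied assignment")
  if (choice == rule_result$assignment) 1L else -1L
}

#' Game-tag array of a response matrix
#'
#' @param matrix a [response_matrix()].
#' @return a named list with one players-by-boards integer matrix per rule
#'   (\code{closeness}, \code{equality}, \code{accession}).
#' @export
game_tags <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  profs <- lapply(matrix$boards, profile_board)
  rules <- c("closeness", "equality", "accession")
  out <- lapply(rules, function(rule) {
    m <- sapply(seq_along(matrix$boards), function(k) {
      rr <- profs[[k]]$results[[rule]]
      if (!rr$applicable) return(rep(0L, nrow(matrix$choices)))
      ifelse(matrix$choices[, k] == rr$assignment, 1L, -1L)
    })
    m <- matrix(m, nrow = nrow(matrix$choices),
                dimnames = list(matrix$players,
                                colnames(matrix$choices)))
    m
  })
  names(out) <- rules
  out
}

#' Strategy rate from a game-tag row
#'
#' The fraction of rule-available games in which the player followed the
#' rule: \eqn{SR = \#\{GT = 1\} / \#\{GT \ne 0\}}. Games where the rule is
#' unavailable (GT = 0) do not affect the rate. When the rule was never
#' available the rate is undefined and \code{NA} is returned.
#'
#' @param gt_row integer vector over games with values in {-1, 0, 1}.
#' @return numeric in [0, 1], or \code{NA}.
#' @export
strategy_rate <- function(gt_row) {
  if (!all(gt_row %in% c(-1L, 0L, 1L))) stop_("game tags must be -1, 0 or 1")
  denom <- sum(gt_row != 0)
  if (denom == 0) return(NA_real_)
  sum(gt_row == 1) / denom
}

#' Strategic profiles of all players
#'
#' Computes the per-player strategy rate of each selection rule over all
#' boards of the response matrix (predefined and random alike).
#'
#' @param matrix a [response_matrix()].
#' @return data frame with columns \code{player}, \code{sr_closeness},
#'   \code{sr_equality}, \code{sr_accession} (each in [0, 1] or \code{NA}
#'   when the rule was never applicable).
#' @export
strategy_rates <- function(matrix) {
  gt <- game_tags(matrix)
  data.frame(player = matrix$players,
             sr_closeness = apply(gt$closeness, 1, strategy_rate),
             sr_equality = apply(gt$equality, 1, strategy_rate),
             sr_accession = apply(gt$accession, 1, strategy_rate),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rule utilization ratio on one board
#'
#' Share of players whose choice equals the rule's implied assignment;
#' \code{NA} when the rule is inapplicable on the board.
#'
#' @param matrix a [response_matrix()].
#' @param board a \code{game_board} (or a board id present in the matrix).
#' @param rule one of "closeness", "equality", "accession".
#' @return numeric in [0, 1] or \code{NA}.
#' @export
utilization_ratio <- function(matrix, board, rule) {
  stopifnot(inherits(matrix, "response_matrix"))
  rule <- match.arg(rule, c("closeness", "equality", "accession"))
  if (is.character(board)) {
    k <- match(board, colnames(matrix$choices))
    if (is.na(k)) stop_("board '%s' not in response matrix", board)
    board <- matrix$boards[[k]]
  } else {
    k <- match(board$board_id, colnames(matrix$choices))
    if (is.na(k)) stop_("board '%s' not in response matrix", board$board_id)
  }
  rr <- switch(rule, closeness = closeness_rule(board),
               equality = equality_rule(board),
               accession = accession_rule(board))
  if (!rr$applicable) return(NA_real_)
  mean(matrix$choices[, k] == rr$assignment)
}

#' Per-game summary table: CI, random-picking CI and rule utilization
#'
#' @param matrix a [response_matrix()].
#' @return data frame with one row per board: observed coordination index,
#'   the uniform random-picking benchmark, and the utilization ratio of each
#'   rule (NA where inapplicable).
#' @export
game_summary <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  rows <- lapply(seq_along(matrix$boards), function(k) {
    b <- matrix$boards[[k]]
    data.frame(board_id = b$board_id,
               predefined = k <= matrix$t_predef,
               n_circles = n_circles(b),
               ci = coordination_index(matrix$choices[, k])$value,
               random_ci = random_picking_ci(b),
               util_closeness = utilization_ratio(matrix, b, "closeness"),
               util_equality = utilization_ratio(matrix, b, "equality"),
               util_accession = utilization_ratio(matrix, b, "accession"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression of rule utilization on game difficulty
#'
#' Ordinary least squares of per-game utilization ratios on per-game
#' coordination indices, with the usual two-sided t test on the slope.
#' Easier games (higher CI) are expected to show higher rule utilization.
#'
#' @param ci numeric vector of per-game coordination indices.
#' @param utilization numeric vector of matching utilization ratios
#'   (\code{NA} pairs are dropped).
#' @return list with \code{slope}, \code{intercept}, \code{p_value},
#'   \code{r_squared}, \code{n} and the underlying \code{lm} fit.
#' @export
utilization_vs_ci_regression <- function(ci, utilization) {
  keep <- is.finite(ci) & is.finite(utilization)
  ci <- ci[keep]
  utilization <- utilization[keep]
  if (length(ci) < 3) stop_("need at least 3 complete (CI, utilization) pairs")
  if (stats::var(ci) == 0) stop_("CI values are constant; slope is undefined")
  fit <- stats::lm(utilization ~ ci)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       p_value = s$coefficients[2, 4],
       r_squared = s$r.squared,
       n = length(ci),
       fit = fit)
}

#' Compare the three strategy rates across players
#'
#' One-way analysis of variance of strategy rate against selection rule
#' (three groups: closeness, equality, accession), with Tukey HSD pairwise
#' comparisons via the studentized range distribution. A permutation test of
#' the F statistic is available as a small-sample alternative.
#'
#' @param profiles data frame as returned by [strategy_rates()].
#' @param method "anova" (default) or "permutation".
#' @param n_perm permutation count when \code{method = "permutation"}.
#' @param seed optional seed for the permutation draw.
#' @return list with \code{f_stat}, \code{df}, \code{p_value},
#'   \code{tukey} (data frame of pairwise comparisons) and \code{n_players}.
#' @export
compare_strategy_rates <- function(profiles, method = c("anova", "permutation"),
                                   n_perm = 2000, seed = NULL) {
  method <- match.arg(method)
  cols <- c("sr_closeness", "sr_equality", "sr_accession")
  stopifnot(all(cols %in% names(profiles)))
  complete <- stats::complete.cases(profiles[, cols])
  if (!all(complete))
    warning(sprintf("%d player(s) with undefined strategy rates excluded",
                    sum(!complete)))
  profiles <- profiles[complete, ]
  if (nrow(profiles) < 2) stop_("need at least 2 players with complete profiles")
  long <- data.frame(
    value = c(profiles$sr_closeness, profiles$sr_equality,
              profiles$sr_accession),
    rule = factor(rep(c("closeness", "equality", "accession"),
                      each = nrow(profiles)),
                  levels = c("closeness", "equality", "accession")))
  fit <- stats::aov(value ~ rule, data = long)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  df <- c(an[["Df"]][1], an[["Df"]][2])
  p_value <- an[["Pr(>F)"]][1]
  if (method == "permutation") {
    obs <- f_stat
    f_perm <- with_seed(seed, replicate(n_perm, {
      perm <- long
      perm$value <- sample(perm$value)
      a <- summary(stats::aov(value ~ rule, data = perm))[[1]]
      a[["F value"]][1]
    }))
    p_value <- (1 + sum(f_perm >= obs)) / (n_perm + 1)
  }
  tk <- stats::TukeyHSD(fit)$rule
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(f_stat = f_stat, df = df, p_value = p_value, tukey = tukey,
       n_players = nrow(profiles), method = method)
}
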