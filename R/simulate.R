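#' Built-in predefined game boards
#'
#' Ten fixed "Assign Circles" boards on a 12 x 8 grid, synthesized so that
#' the applicability pattern of the three selection rules across boards
#' matches the classical predefined battery: boards where all rules agree,
#' boards where only one rule applies, boards where closeness/accession
#' disagree with equality, and boards where no rule applies at all. The
#' exact coordinates are this package's own constructions (the historical
#' layouts are not machine-readable); see the methods vignette.
#'
#' @return list of 10 \code{game_board}s with ids \code{predef_01} ..
#'   \code{predef_10}.
#' @export
predefined_boards <- function() {
  sq <- function(circles, id, sl = c(1, 3), sr = c(9, 3))
    game_board(circles, sl, sr, 12, 8, id)
  list(
    # 2 circles, all three rules imply LR
    sq(list(c(2, 3), c(8, 3)), "predef_01"),
    # 4 circles, all three rules imply LLRR
    sq(list(c(2, 2), c(3, 4), c(7, 2), c(8, 4)), "predef_02"),
    # 3 circles: only accession applies (LLR); one circle equidistant
    sq(list(c(4, 5), c(5, 5), c(6, 1)), "predef_03"),
    # 4 circles: only equality applies (LLRR); middle circle equidistant
    sq(list(c(2, 2), c(3, 2), c(5, 1), c(7, 2)), "predef_04"),
    # 3 circles: closeness and accession imply LLR, equality inapplicable
    sq(list(c(2, 3), c(3, 5), c(8, 2)), "predef_05"),
    # 4 circles: accession LRRR vs equality LLRR; closeness tied
    sq(list(c(2, 3), c(5, 1), c(6, 1), c(7, 1)), "predef_06"),
    # 1 circle, equidistant: no rule applies
    sq(list(c(5, 1)), "predef_07"),
    # 2 circles on the midline: no rule applies
    sq(list(c(5, 1), c(5, 6)), "predef_08"),
    # 4 circles: closeness/accession LRRR vs equality LLRR (slanted squares)
    sq(list(c(2, 5), c(4, 0), c(6, 2), c(8, 3)), "predef_09",
       sl = c(1, 5), sr = c(9, 2)),
    # 5 circles: closeness LLRRR vs accession LLLRR; equality inapplicable
    sq(list(c(3, 5), c(4, 5), c(5, 5), c(6, 2), c(7, 5)), "predef_10",
       sl = c(1, 3), sr = c(8, 3))
  )
}

#' Generate a random game board
#'
#' Places two squares (left third / right third of the grid) and
#' \code{n_circles} distinct circles uniformly at random, optionally
#' rejection-sampling until named rules are applicable or inapplicable.
#'
#' @param n_circles number of circles.
#' @param grid c(width, height) of the grid (default c(12, 8)).
#' @param constraints named logical vector, e.g.
#'   \code{c(equality = FALSE, closeness = TRUE)}: required applicability
#'   per rule; unnamed rules are unconstrained.
#' @param seed optional seed.
#' @param board_id label for the board.
#' @param max_tries rejection-sampling cap (default 1000).
#' @return a \code{game_board}.
#' @export
generate_board <- function(n_circles, grid = c(12, 8), constraints = NULL,
                           seed = NULL, board_id = "random", max_tries = 1000) {
  w <- grid[1]; h <- grid[2]
  if (w < 4 || h < 1 || n_circles + 2 > w * h)
    stop_("grid too small for %d circles and 2 squares", n_circles)
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      sl <- c(sample(0:(max(1, w %/% 3) - 1), 1), sample(0:(h - 1), 1))
      sr <- c(sample((w - max(1, w %/% 3)):(w - 1), 1), sample(0:(h - 1), 1))
      cells <- setdiff(seq_len(w * h) - 1L,
                       c(sl[1] * h + sl[2], sr[1] * h + sr[2]))
      pick <- sample(cells, n_circles)
      circles <- cbind(pick %/% h, pick %% h)
      b <- game_board(circles, sl, sr, w, h, board_id)
      if (is.null(constraints) || length(constraints) == 0) return(b)
      prof <- profile_board(b)
      ok <- TRUE
      for (rule in names(constraints)) {
        if (prof$results[[rule]]$applicable != constraints[[rule]]) {
          ok <- FALSE; break
        }
      }
      if (ok) return(b)
    }
    stop_("could not satisfy board constraints within %d tries", max_tries)
  })
}

#' Agent specification
#'
#' A synthetic player is a two-level mixture: with probability \code{noise}
#' it picks a full assignment uniformly at random over all 2^n solutions;
#' otherwise it samples among the assignments implied by the applicable
#' selection rules, with probability proportional to the summed propensity
#' weights of the rules implying each assignment (rules that imply the same
#' assignment pool their mass). If no rule applies, the choice is uniform.
#'
#' @param w_closeness,w_equality,w_accession non-negative propensity
#'   weights.
#' @param noise probability of a uniform random assignment, in [0, 1].
#' @param id optional agent label.
#' @return an object of class \code{agent_spec}.
#' @export
agent_spec <- function(w_closeness = 1, w_equality = 1, w_accession = 1,
                       noise = 0, id = NULL) {
  w <- c(closeness = unname(w_closeness), equality = unname(w_equality),
         accession = unname(w_accession))
  if (any(w < 0)) stop_("propensity weights must be non-negative")
  if (noise < 0 || noise > 1) stop_("noise must lie in [0, 1]")
  if (sum(w) == 0 && noise < 1)
    stop_("all-zero propensities require noise = 1")
  structure(list(weights = w, noise = noise, id = id), class = "agent_spec")
}

random_assignment <- function(n) {
  paste(sample(c("L", "R"), n, replace = TRUE), collapse = "")
}

#' Simulate one agent's choice on a board
#'
#' @param agent an [agent_spec()].
#' @param board a [game_board()].
#' @param seed optional seed.
#' @param rule_profile optional precomputed [profile_board()] result for
#'   \code{board} (avoids recomputation in population loops).
#' @return an assignment string.
#' @export
simulate_agent <- function(agent, board, seed = NULL, rule_profile = NULL) {
  stopifnot(inherits(agent, "agent_spec"), inherits(board, "game_board"))
  if (is.null(rule_profile)) rule_profile <- profile_board(board)
  with_seed(seed, {
    n <- n_circles(board)
    if (stats::runif(1) < agent$noise) return(random_assignment(n))
    mass <- list()
    for (rule in names(agent$weights)) {
      rr <- rule_profile$results[[rule]]
      if (rr$applicable && agent$weights[[rule]] > 0) {
        key <- rr$assignment
        mass[[key]] <- (if (is.null(mass[[key]])) 0 else mass[[key]]) +
          agent$weights[[rule]]
      }
    }
    if (length(mass) == 0) return(random_assignment(n))
    opts <- names(mass)
    p <- unlist(mass)
    opts[sample.int(length(opts), 1, prob = p / sum(p))]
  })
}

#' Population specification
#'
#' Bundles the boards, the agents and a master seed from which independent
#' per-agent choice streams are derived, so that any agent's responses can
#' be regenerated without simulating the others.
#'
#' @param agents list of [agent_spec()]s (at least 2).
#' @param boards list of [game_board()]s; the first \code{t_predef} are
#'   flagged predefined.
#' @param t_predef number of predefined boards (default: all).
#' @param seed master seed.
#' @return an object of class \code{population_spec}.
#' @export
population_spec <- function(agents, boards, t_predef = length(boards),
                            seed = 1L) {
  if (length(agents) < 2) stop_("need at least 2 agents")
  if (length(boards) < 1) stop_("need at least 1 board")
  structure(list(agents = agents, boards = boards,
                 t_predef = as.integer(t_predef), seed = as.integer(seed)),
            class = "population_spec")
}

#' Simulate a full response matrix from a population specification
#'
#' @param spec a [population_spec()].
#' @return a [response_matrix()] (reproducible: same spec and seed give the
#'   identical matrix).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n_a <- length(spec$agents)
  profs <- lapply(spec$boards, profile_board)
  agent_seeds <- split_seed(spec$seed, n_a)
  ch <- matrix(NA_character_, nrow = n_a, ncol = length(spec$boards))
  ids <- vapply(seq_len(n_a), function(i) {
    id <- spec$agents[[i]]$id
    if (is.null(id)) sprintf("agent_%03d", i) else id
  }, character(1))
  for (i in seq_len(n_a)) {
    ch[i, ] <- with_seed(agent_seeds[i], {
      vapply(seq_along(spec$boards), function(k)
        simulate_agent(spec$agents[[i]], spec$boards[[k]],
                       rule_profile = profs[[k]]),
        character(1))
    })
  }
  rownames(ch) <- ids
  colnames(ch) <- vapply(spec$boards, function(b) b$board_id, character(1))
  response_matrix(ch, spec$boards, t_predef = spec$t_predef)
}

#' Study-like synthetic population
#'
#' Builds a population specification emulating the statistical structure of
#' the behavioural study the pipeline is designed for: 93 agents playing 14
#' boards (the 10 built-in predefined boards plus 4 random ones), with
#' three latent ability strata that yield a multimodal distribution of
#' individual coordination ability -- a tight high-ability group (low
#' choice noise), a tight intermediate group, and a broad low-ability group
#' (high, variable noise). Propensity weights favour closeness and equality
#' over accession, so strategy-rate profiles correlate with ability.
#'
#' @param seed master seed (also drives the random boards and agent draws).
#' @param n_agents number of agents (default 93).
#' @param strata stratum proportions (high, mid, low ability); must sum
#'   to 1.
#' @param noise_ranges list of length-2 noise ranges per stratum.
#' @return a [population_spec()].
#' @export
study_population_spec <- function(seed = 1L, n_agents = 93,
                                  strata = c(high = 0.30, mid = 0.40,
                                             low = 0.30),
                                  noise_ranges = list(high = c(0, 0.08),
                                                      mid = c(0.18, 0.32),
                                                      low = c(0.45, 0.95))) {
  if (abs(sum(strata) - 1) > 1e-8) stop_("stratum proportions must sum to 1")
  seeds <- split_seed(seed, 6)
  board_seeds <- split_seed(seeds[1], 8)
  boards <- predefined_boards()
  for (i in 1:4) {
    nc <- with_seed(board_seeds[i], sample(2:5, 1))
    boards[[10 + i]] <- generate_board(
      n_circles = nc, seed = board_seeds[4 + i],
      board_id = sprintf("random_%02d", i))
  }
  counts <- round(n_agents * strata)
  counts[1] <- n_agents - sum(counts[-1])
  labels <- rep(names(strata), counts)
  agents <- with_seed(seeds[2], {
    lapply(seq_len(n_agents), function(i) {
      rng <- noise_ranges[[labels[i]]]
      agent_spec(w_closeness = stats::runif(1, 0.6, 1.0),
                 w_equality = stats::runif(1, 0.5, 1.0),
                 w_accession = stats::runif(1, 0.05, 0.30),
                 noise = stats::runif(1, rng[1], rng[2]),
                 id = sprintf("agent_%03d_%s", i, labels[i]))
    })
  })
  population_spec(agents, boards, t_predef = 10L, seed = seeds[3])
}
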