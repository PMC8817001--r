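#' Focal-point selection rules
#'
#' The three selection rules classically studied for "Assign Circles"
#' boards. Each rule is applicable on a board only when it implies a single
#' unique full assignment; any distance tie makes a rule inapplicable.
#'
#' \describe{
#'   \item{closeness}{assign each circle to the strictly nearer square
#'     (Euclidean distance between grid points).}
#'   \item{accession}{partition circles into coherent groups (4-connected:
#'     horizontally or vertically adjacent grid cells) and assign each whole
#'     group to the square nearer to the group, where the group-square
#'     distance is the minimum over the group's circles.}
#'   \item{equality}{median-line refinement of equal division: applicable
#'     when the circle count n is even and some vertical line has exactly
#'     n/2 circles strictly on each side; circles left of the line go to the
#'     left square.}
#' }
#'
#' @param board a [game_board()].
#' @return an object of class \code{rule_result}: a list with \code{rule},
#'   \code{applicable} (logical) and \code{assignment} (L/R string, or
#'   \code{NA} when inapplicable).
#' @name selection_rules
NULL

rule_result <- function(rule, applicable, assignment = NA_character_) {
  structure(list(rule = rule, applicable = applicable,
                 assignment = if (applicable) assignment else NA_character_),
            class = "rule_result")
}

#' @export
print.rule_result <- function(x, ...) {
  cat(sprintf("<rule_result> %s: %s\n", x$rule,
              if (x$applicable) x$assignment else "not applicable"))
  invisible(x)
}

sq_dists <- function(board) {
  # n x 2 matrix of squared distances of each circle to (left, right) square
  d2 <- function(sq) (board$circles[, 1] - sq[1])^2 +
    (board$circles[, 2] - sq[2])^2
  cbind(left = d2(board$square_left), right = d2(board$square_right))
}

#' @rdname selection_rules
#' @export
closeness_rule <- function(board) {
  stopifnot(inherits(board, "game_board"))
  d <- sq_dists(board)
  if (any(d[, 1] == d[, 2])) return(rule_result("closeness", FALSE))
  lab <- ifelse(d[, 1] < d[, 2], "L", "R")
  rule_result("closeness", TRUE, paste(lab, collapse = ""))
}

# Connected components of the circle set under 4-adjacency
# (Manhattan distance 1). Returns an integer component label per circle.
circle_components <- function(board) {
  pts <- board$circles
  n <- nrow(pts)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      adj <- which(comp == 0L &
                     abs(pts[, 1] - pts[v, 1]) + abs(pts[, 2] - pts[v, 2]) == 1)
      comp[adj] <- cur
      queue <- c(queue, adj)
    }
  }
  comp
}

#' @rdname selection_rules
#' @export
accession_rule <- function(board) {
  stopifnot(inherits(board, "game_board"))
  comp <- circle_components(board)
  d <- sq_dists(board)
  lab <- character(nrow(d))
  for (k in unique(comp)) {
    idx <- comp == k
    dl <- min(d[idx, 1])
    dr <- min(d[idx, 2])
    if (dl == dr) return(rule_result("accession", FALSE))
    lab[idx] <- if (dl < dr) "L" else "R"
  }
  rule_result("accession", TRUE, paste(lab, collapse = ""))
}

#' @rdname selection_rules
#' @export
equality_rule <- function(board) {
  stopifnot(inherits(board, "game_board"))
  n <- n_circles(board)
  if (n %% 2 != 0) return(rule_result("equality", FALSE))
  xs <- sort(board$circles[, 1])
  h <- n %/% 2
  if (xs[h] >= xs[h + 1]) return(rule_result("equality", FALSE))
  # circles are canonically ordered by ascending x, so the first n/2 are the
  # left half whenever a strict vertical gap exists at the median
  lab <- rep(c("L", "R"), each = h)
  rule_result("equality", TRUE, paste(lab, collapse = ""))
}

#' Profile a board under all three selection rules
#'
#' Evaluates closeness, accession and equality on a board and collects the
#' set of distinct predicted responses (the union of implied assignments of
#' the applicable rules).
#'
#' @param board a [game_board()].
#' @return an object of class \code{board_rule_profile}: list with
#'   \code{board_id}, \code{results} (named list of \code{rule_result}) and
#'   \code{predicted} (character vector of distinct implied assignments,
#'   possibly empty).
#' @export
profile_board <- function(board) {
  res <- list(closeness = closeness_rule(board),
              equality = equality_rule(board),
              accession = accession_rule(board))
  implied <- vapply(res, function(r) r$assignment, character(1))
  structure(list(board_id = board$board_id, results = res,
                 predicted = unique(implied[!is.na(implied)])),
            class = "board_rule_profile")
}

#' @export
print.board_rule_profile <- function(x, ...) {
  cat(sprintf("<board_rule_profile '%s'>\n", x$board_id))
  for (r in x$results)
    cat(sprintf("  %-9s %s\n", r$rule,
                if (r$applicable) r$assignment else "None"))
  cat("  predicted:",
      if (length(x$predicted)) paste(x$predicted, collapse = " or ")
      else "None", "\n")
  invisible(x)
}

#' Tabulate rule applicability for a set of boards
#'
#' @param boards list of \code{game_board}s.
#' @return data frame with one row per board and per-rule implied
#'   assignments (\code{NA} when inapplicable).
#' @export
rules_table <- function(boards) {
  rows <- lapply(boards, function(b) {
    p <- profile_board(b)
    data.frame(board_id = b$board_id,
               closeness = p$results$closeness$assignment,
               equality = p$results$equality$assignment,
               accession = p$results$accession$assignment,
               n_predicted = length(p$predicted),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
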