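#' Canonical circle ordering
#'
#' Circles on a board are kept in canonical reading order for assignment
#' strings: ascending x (left to right), ties broken by ascending y (top to
#' bottom, with the origin at the top-left corner and y growing downward).
#'
#' @param points integer matrix with two columns (x, y), one row per circle,
#'   or a list of length-2 integer vectors.
#' @return an integer matrix with columns \code{x}, \code{y}, rows sorted in
#'   canonical order.
#' @export
canonicalize_circles <- function(points) {
  pts <- as_point_matrix(points)
  if (anyDuplicated(pts)) stop_("duplicate circle positions are not allowed")
  pts[order(pts[, 1], pts[, 2]), , drop = FALSE]
}

as_point_matrix <- function(points) {
  if (is.list(points)) points <- do.call(rbind, points)
  pts <- matrix(as.numeric(points), ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  if (any(!is.finite(pts))) stop_("non-finite point coordinates")
  if (any(pts != round(pts))) stop_("point coordinates must be integers")
  pts
}

#' Construct an "Assign Circles" game board
#'
#' A board is a rectangular integer grid (origin top-left, x rightward,
#' y downward) holding one left square, one right square and at least one
#' circle. Players assign every circle to one of the two squares. Circles are
#' stored in canonical order (see [canonicalize_circles()]); positions are
#' grid cell centers.
#'
#' @param circles two-column matrix (or list of (x, y) pairs) of circle
#'   positions.
#' @param square_left,square_right length-2 integer vectors (x, y); the left
#'   square must have strictly smaller x than the right square.
#' @param grid_width,grid_height grid dimensions in cells; coordinates run
#'   from 0 to width-1 / height-1.
#' @param board_id character label.
#' @return an object of class \code{game_board}.
#' @export
game_board <- function(circles, square_left, square_right,
                       grid_width = 12L, grid_height = 8L,
                       board_id = "board") {
  circles <- canonicalize_circles(circles)
  square_left <- as.numeric(square_left)
  square_right <- as.numeric(square_right)
  b <- structure(
    list(board_id = as.character(board_id)[1],
         grid = c(width = as.integer(grid_width),
                  height = as.integer(grid_height)),
         circles = circles,
         square_left = square_left,
         square_right = square_right),
    class = "game_board")
  validate_game_board(b)
}

validate_game_board <- function(b) {
  g <- b$grid
  if (any(g < 1)) stop_("grid dimensions must be positive")
  if (length(b$square_left) != 2 || length(b$square_right) != 2)
    stop_("squares must be (x, y) points")
  if (b$square_left[1] >= b$square_right[1])
    stop_("left square must lie strictly left of the right square")
  n <- nrow(b$circles)
  if (n < 1) stop_("a board needs at least one circle")
  in_grid <- function(p) all(p >= 0) && p[1] < g[1] && p[2] < g[2]
  if (!in_grid(b$square_left) || !in_grid(b$square_right))
    stop_("squares must lie within the grid")
  for (i in seq_len(n)) {
    p <- b$circles[i, ]
    if (!in_grid(p)) stop_("circle %d lies outside the grid", i)
    if (all(p == b$square_left) || all(p == b$square_right))
      stop_("circle %d coincides with a square", i)
  }
  b
}

#' @export
print.game_board <- function(x, ...) {
  cat(sprintf("<game_board '%s'> %dx%d grid, %d circle(s)\n", x$board_id,
              x$grid[1], x$grid[2], nrow(x$circles)))
  cat(sprintf("  squares: L=(%g,%g) R=(%g,%g)\n",
              x$square_left[1], x$square_left[2],
              x$square_right[1], x$square_right[2]))
  cat("  circles:", paste(sprintf("(%g,%g)", x$circles[, 1], x$circles[, 2]),
                          collapse = " "), "\n")
  invisible(x)
}

#' Number of circles on a board
#' @param board a \code{game_board}.
#' @return integer circle count.
#' @export
n_circles <- function(board) nrow(board$circles)

#' Size of the solution space of a board
#'
#' Every full assignment sends each circle to one of the two squares, so a
#' board with n circles has 2^n possible solutions.
#'
#' @param board a \code{game_board}.
#' @return \code{2^n_circles(board)}.
#' @export
solution_space_size <- function(board) 2^n_circles(board)

#' Enumerate all assignments of a board
#'
#' @param board a \code{game_board} (at most 20 circles).
#' @return character vector of all 2^n L/R assignment strings, in
#'   lexicographic order.
#' @export
enumerate_assignments <- function(board) {
  n <- n_circles(board)
  if (n > 20) stop_("refusing to enumerate more than 2^20 assignments")
  g <- expand.grid(rep(list(c("L", "R")), n), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(g))
  sort(out)
}

#' Validate an assignment string against a board
#'
#' An assignment is a string over {L, R} whose i-th character gives the
#' square of the i-th canonical circle.
#'
#' @param assignment character scalar.
#' @param board a \code{game_board} (or an integer circle count).
#' @return the assignment, invisibly, if valid; otherwise an error.
#' @export
validate_assignment <- function(assignment, board) {
  n <- if (inherits(board, "game_board")) n_circles(board) else as.integer(board)
  if (!is.character(assignment) || length(assignment) != 1 || is.na(assignment))
    stop_("assignment must be a single character string")
  if (nchar(assignment) != n)
    stop_("assignment '%s' has length %d but the board has %d circles",
          assignment, nchar(assignment), n)
  if (grepl("[^LR]", assignment))
    stop_("assignment '%s' contains characters outside {L, R}", assignment)
  invisible(assignment)
}

# ---- response matrices -----------------------------------------------------

#' Construct a response matrix
#'
#' Holds the full choice of every player on every board: one L/R assignment
#' string per (player, board) cell. The first \code{t_predef} boards are
#' flagged as the predefined subset over which individual coordination
#' ability is computed; the remaining boards (e.g. randomly generated ones)
#' still enter the strategy-rate denominators.
#'
#' @param choices character matrix, rows = players, columns = boards; row
#'   names are player identifiers, column names must equal the board ids.
#' @param boards list of \code{game_board}s in column order.
#' @param t_predef number of leading boards regarded as predefined
#'   (default: all).
#' @return an object of class \code{response_matrix}.
#' @export
response_matrix <- function(choices, boards, t_predef = length(boards)) {
  if (!is.matrix(choices) || !is.character(choices))
    stop_("choices must be a character matrix")
  if (length(boards) != ncol(choices))
    stop_("got %d boards for %d choice columns", length(boards), ncol(choices))
  ids <- vapply(boards, function(b) b$board_id, character(1))
  if (anyDuplicated(ids)) stop_("duplicate board ids")
  if (is.null(colnames(choices))) colnames(choices) <- ids
  if (!identical(colnames(choices), ids))
    stop_("choice column names do not match board ids")
  if (is.null(rownames(choices)))
    rownames(choices) <- paste0("p", seq_len(nrow(choices)))
  t_predef <- as.integer(t_predef)
  if (t_predef < 1 || t_predef > length(boards))
    stop_("t_predef must be between 1 and the number of boards")
  for (j in seq_along(boards)) {
    for (i in seq_len(nrow(choices))) {
      if (is.na(choices[i, j]))
        stop_("missing choice for player '%s' on board '%s'",
              rownames(choices)[i], ids[j])
      tryCatch(validate_assignment(choices[i, j], boards[[j]]),
               error = function(e)
                 stop_("player '%s', board '%s': %s",
                       rownames(choices)[i], ids[j], conditionMessage(e)))
    }
  }
  structure(list(players = rownames(choices), boards = boards,
                 t_predef = t_predef, choices = choices),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d players x %d boards (%d predefined)\n",
              length(x$players), length(x$boards), x$t_predef))
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

#' Read / write board JSON files
#'
#' Boards are serialized as JSON objects
#' \code{{"board_id", "grid": [w,h], "squares": {"left": [x,y],
#' "right": [x,y]}, "circles": [[x,y], ...]}}. Circles may be stored in any
#' order; they are canonicalized on load.
#'
#' @param path file path.
#' @return \code{read_board} returns a \code{game_board};
#'   \code{write_board} returns \code{path} invisibly.
#' @export
read_board <- function(path) {
  if (!file.exists(path)) stop_("board file not found: %s", path)
  j <- tryCatch(jsonlite::fromJSON(path, simplifyMatrix = TRUE),
                error = function(e)
                  stop_("malformed board JSON '%s': %s", path,
                        conditionMessage(e)))
  for (f in c("board_id", "grid", "squares", "circles"))
    if (is.null(j[[f]])) stop_("board file '%s' lacks field '%s'", path, f)
  circ <- j$circles
  if (is.list(circ)) circ <- do.call(rbind, circ)
  game_board(circles = circ,
             square_left = j$squares$left, square_right = j$squares$right,
             grid_width = j$grid[1], grid_height = j$grid[2],
             board_id = j$board_id)
}

#' @param board a \code{game_board}.
#' @rdname read_board
#' @export
write_board <- function(board, path) {
  stopifnot(inherits(board, "game_board"))
  j <- list(board_id = board$board_id,
            grid = as.integer(board$grid),
            squares = list(left = as.integer(board$square_left),
                           right = as.integer(board$square_right)),
            circles = matrix(as.integer(board$circles), ncol = 2))
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read / write response-matrix CSV files
#'
#' The CSV has a header \code{player,<board_id_1>,...,<board_id_k>}; each
#' cell holds the player's full L/R assignment string for that board.
#'
#' @param path CSV file path.
#' @param boards list of \code{game_board}s matching the file's columns.
#' @param t_predef number of leading predefined boards (default: all).
#' @return \code{read_responses} returns a \code{response_matrix};
#'   \code{write_responses} returns \code{path} invisibly.
#' @export
read_responses <- function(path, boards, t_predef = length(boards)) {
  if (!file.exists(path)) stop_("response file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2 || names(df)[1] != "player")
    stop_("response CSV '%s' must start with a 'player' column", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$player
  response_matrix(m, boards, t_predef = t_predef)
}

#' @param matrix a \code{response_matrix}.
#' @rdname read_responses
#' @export
write_responses <- function(matrix, path) {
  stopifnot(inherits(matrix, "response_matrix"))
  df <- data.frame(player = matrix$players, matrix$choices,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
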