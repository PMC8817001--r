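# Shared builders and independent brute-force oracles for the rule engine.

mk_board <- function(circles, sl = c(0, 0), sr = c(10, 0), w = 16, h = 12,
                     id = "test") {
  game_board(circles, sl, sr, w, h, id)
}

# distance of every circle to each square (squared, exact in integers)
d2_to <- function(board, sq) {
  (board$circles[, 1] - sq[1])^2 + (board$circles[, 2] - sq[2])^2
}

# Oracle: enumerate all 2^n assignments, keep those in which every circle
# sits at a square of minimal distance; applicable iff exactly one survives
# and no circle is tied.
closeness_oracle <- function(board) {
  dl <- d2_to(board, board$square_left)
  dr <- d2_to(board, board$square_right)
  keep <- character(0)
  for (a in enumerate_assignments(board)) {
    lab <- strsplit(a, "")[[1]]
    d <- ifelse(lab == "L", dl, dr)
    if (all(d <= pmin(dl, dr))) keep <- c(keep, a)
  }
  if (length(keep) == 1) keep else NA_character_
}

# Oracle: connected components via igraph over 4-adjacency, then the
# min-distance group criterion; ties make it inapplicable.
accession_oracle <- function(board) {
  pts <- board$circles
  n <- nrow(pts)
  adj <- which(outer(pts[, 1], pts[, 1], function(a, b) abs(a - b)) +
                 outer(pts[, 2], pts[, 2], function(a, b) abs(a - b)) == 1,
               arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = adj[, 1], to = adj[, 2]), directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership[as.character(seq_len(n))]
  dl <- d2_to(board, board$square_left)
  dr <- d2_to(board, board$square_right)
  lab <- character(n)
  for (k in unique(comp)) {
    idx <- comp == k
    if (min(dl[idx]) == min(dr[idx])) return(NA_character_)
    lab[idx] <- if (min(dl[idx]) < min(dr[idx])) "L" else "R"
  }
  paste(lab, collapse = "")
}

# Oracle: enumerate equal-split assignments induced by a vertical line
# (all L circles strictly left of all R circles); applicable iff exactly
# one such assignment exists.
equality_oracle <- function(board) {
  n <- n_circles(board)
  if (n %% 2 != 0) return(NA_character_)
  xs <- board$circles[, 1]
  keep <- character(0)
  for (a in enumerate_assignments(board)) {
    lab <- strsplit(a, "")[[1]]
    if (sum(lab == "L") != n / 2) next
    if (max(xs[lab == "L"]) < min(xs[lab == "R"])) keep <- c(keep, a)
  }
  if (length(keep) == 1) keep else NA_character_
}

random_test_board <- function(n_circles, seed) {
  set.seed(seed)
  repeat {
    w <- 10L; h <- 8L
    sl <- c(sample(0:3, 1), sample(0:(h - 1), 1))
    sr <- c(sample(6:9, 1), sample(0:(h - 1), 1))
    cells <- setdiff(0:(w * h - 1), c(sl[1] * h + sl[2], sr[1] * h + sr[2]))
    pick <- sample(cells, n_circles)
    circles <- cbind(pick %/% h, pick %% h)
    b <- try(game_board(circles, sl, sr, w, h, "rnd"), silent = TRUE)
    if (!inherits(b, "try-error")) return(b)
  }
}

# Pair-enumeration oracle for the coordination index.
ci_oracle <- function(choices) {
  n <- length(choices)
  pairs <- utils::combn(n, 2)
  mean(choices[pairs[1, ]] == choices[pairs[2, ]])
}
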