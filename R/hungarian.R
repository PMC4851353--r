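# Kuhn-Munkres (Hungarian) assignment via shortest augmenting paths with
# dual potentials, O(n^3). Written here because no installed package
# provides a linear-assignment solver; validated in the test suite against
# exhaustive permutation enumeration.

# Solve the square assignment problem for cost matrix C (finite entries).
# Returns an integer vector a with a[i] = column assigned to row i.
solve_lsap_square <- function(C) {
  n <- nrow(C)
  INF <- Inf
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)      # p[j] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 1L                # columns are offset by 1: j0 = 1 is the virtual column
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in 2L:(n + 1L)) {
        if (!used[j]) {
          cur <- C[i0, j - 1L] - u[i0 + 1L] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2L:(n + 1L)) if (p[j] > 0L) ans[p[j]] <- j - 1L
  ans
}

#' One-to-one assignment by the Kuhn-Munkres algorithm
#'
#' Solves the minimum-total-cost one-to-one assignment between the rows
#' (trackers) and columns (measurements) of a cost matrix. Rectangular
#' problems are padded with dummy rows/columns; infinite entries mark
#' forbidden pairs and are never realized: a row or column whose cheapest
#' option is forbidden comes back unassigned.
#'
#' @param C numeric cost matrix (entries positive or `Inf`); may have zero
#'   rows or columns.
#' @return A list with `pairs` (2-column matrix of assigned row/col index
#'   pairs), `unassigned_rows`, `unassigned_cols`, and `total_cost` (sum of
#'   realized finite costs).
#' @export
associate <- function(C) {
  n <- nrow(C)
  m <- ncol(C)
  if (n == 0L || m == 0L) {
    return(list(pairs = matrix(integer(0), ncol = 2L,
                               dimnames = list(NULL, c("row", "col"))),
                unassigned_rows = seq_len(n), unassigned_cols = seq_len(m),
                total_cost = 0))
  }
  k <- max(n, m)
  finite <- C[is.finite(C)]
  BIG <- if (length(finite)) sum(abs(finite)) + max(abs(finite), 1) + 1 else 1
  Cs <- matrix(BIG, k, k)
  Cs[seq_len(n), seq_len(m)] <- ifelse(is.finite(C), C, BIG)
  a <- solve_lsap_square(Cs)
  pairs <- matrix(integer(0), ncol = 2L)
  for (i in seq_len(n)) {
    j <- a[i]
    if (j <= m && is.finite(C[i, j])) pairs <- rbind(pairs, c(i, j))
  }
  colnames(pairs) <- c("row", "col")
  list(pairs = pairs,
       unassigned_rows = setdiff(seq_len(n), pairs[, 1]),
       unassigned_cols = setdiff(seq_len(m), pairs[, 2]),
       total_cost = if (nrow(pairs)) sum(C[pairs]) else 0)
}
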