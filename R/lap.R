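#' @include AllGenerics.R
NULL

#' Solve a linear assignment problem
#'
#' Minimum-cost one-to-one assignment of rows to columns of a square cost
#' matrix, solved exactly by shortest augmenting paths with dual
#' potentials. `Inf` entries mark forbidden assignments; they are replaced
#' internally by a cost large enough that they are never chosen when a
#' feasible alternative exists.
#'
#' @param cost numeric square matrix; `Inf` allowed.
#' @return list with `assignment` (integer vector: column assigned to each
#'   row) and `cost` (total cost of the assignment, `Inf` if any forbidden
#'   pair had to be used).
#' @examples
#' solveAssignment(matrix(c(4, 2, 1, 3), 2, 2))
#' @export
solveAssignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0L) return(list(assignment = integer(0), cost = 0))
  storage.mode(cost) <- "double"
  finite <- cost[is.finite(cost)]
  if (!length(finite)) stop("cost matrix has no finite entries")
  big <- (max(abs(finite)) + 1) * (n + 1)
  work <- cost
  work[!is.finite(work)] <- big
  a <- lap_solve_cpp(work)
  tot <- sum(cost[cbind(seq_len(n), a)])
  list(assignment = a, cost = tot)
}

## Frame-to-frame linking cost model (Jaqaman-style augmented LAP).
##
## Square matrix of size n1 + n2:
##   [ D^2 | death ]   D^2  : squared displacement, Inf beyond the gate
##   [birth|   0  ]   death/birth: diagonal cost b = maxLinkDist^2
## Minimizing total cost trades a link (d^2) against a death plus a birth
## (2b), so links are accepted when d^2 < 2b and never beyond the gate.
.linkCostMatrix <- function(xy1, xy2, maxLinkDist) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  b <- maxLinkDist^2
  M <- matrix(Inf, n1 + n2, n1 + n2)
  if (n1 && n2) {
    d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
    d2[d2 > b] <- Inf
    M[seq_len(n1), seq_len(n2)] <- d2
  }
  if (n1) M[cbind(seq_len(n1), n2 + seq_len(n1))] <- b
  if (n2) M[cbind(n1 + seq_len(n2), seq_len(n2))] <- b
  if (n1 && n2) M[n1 + seq_len(n2), n2 + seq_len(n1)] <- 0
  M
}

## Returns an integer vector: for each spot in frame 1, the index of the
## linked spot in frame 2, or NA.
.linkFramePair <- function(xy1, xy2, maxLinkDist) {
  n1 <- nrow(xy1); n2 <- nrow(xy2)
  if (n1 == 0L) return(integer(0))
  if (n2 == 0L) return(rep(NA_integer_, n1))
  a <- solveAssignment(.linkCostMatrix(xy1, xy2, maxLinkDist))$assignment
  link <- a[seq_len(n1)]
  link[link > n2] <- NA_integer_
  link
}
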