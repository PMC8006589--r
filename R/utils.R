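## small internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise cosine similarity between two sets of vectors
#'
#' @param X,Y numeric matrices with the same number of columns.
#' @return `nrow(X)` x `nrow(Y)` similarity matrix; rows that are all zero
#'   get similarity 0 against everything (cosine is undefined there).
#' @keywords internal
cosine_similarity <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  nx <- sqrt(rowSums(X^2))
  ny <- sqrt(rowSums(Y^2))
  S <- X %*% t(Y)
  denom <- outer(nx, ny)
  out <- ifelse(denom > 0, S / ifelse(denom > 0, denom, 1), 0)
  dimnames(out) <- list(rownames(X), rownames(Y))
  out
}

#' Cosine distance matrix (1 - similarity), zero rows at maximal distance
#' @keywords internal
cosine_distance <- function(X, Y = X) {
  nx <- sqrt(rowSums(as.matrix(X)^2))
  ny <- sqrt(rowSums(as.matrix(Y)^2))
  D <- 1 - cosine_similarity(X, Y)
  # cosine is undefined for zero vectors: map to the maximal distance
  if (any(nx == 0) || any(ny == 0)) {
    D[nx == 0, ] <- 1
    D[, ny == 0] <- 1
    warning("zero vectors present; their cosine distances set to 1")
  }
  D
}

#' Scale each nonzero row of a matrix to unit Euclidean norm
#' @keywords internal
unit_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  zero <- n == 0
  if (any(zero)) warning(sum(zero), " zero rows left unnormalized")
  X[!zero, ] <- X[!zero, , drop = FALSE] / n[!zero]
  X
}

frob <- function(X) sqrt(sum(X^2))

stop_tf <- function(...) stop(..., call. = FALSE)
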