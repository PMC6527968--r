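## Lawson-Hanson active-set non-negative least squares:
## minimise ||A x - b||^2 subject to x >= 0.
## Returns list(x, passive) where passive flags unconstrained coefficients.
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  n <- ncol(A)
  if (is.null(max_iter)) max_iter <- 10L * n
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b))            # gradient at x = 0
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(w), 1) * n
  iter <- 0L
  repeat {
    w <- drop(crossprod(A, b - A %*% x))
    cand <- which(!passive & w > tol)
    if (length(cand) == 0L) break
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) break
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      Q <- P[z[P] <= tol]
      alpha <- min(x[Q] / (x[Q] - z[Q]))
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    if (iter > max_iter) break
  }
  x[x < 0] <- 0
  list(x = x, passive = passive)
}
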