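#' Invert the CAE sub-feature matrices
#'
#' The encoder output W' (m x m x p) is a stack of p square sub-feature
#' matrices W_sub. Each channel is inverted exactly when its 2-norm
#' condition number stays below `condThreshold`; otherwise the Moore-Penrose
#' pseudo-inverse is used and the channel is flagged in the report. (An
#' ideal encoder never produces singular channels; the gate is a
#' robustness extension for learned outputs.)
#'
#' @param Wp numeric array m x m x p.
#' @param condThreshold condition-number gate for exact inversion.
#' @return list with `inv` (m x m x p array of inverses) and `report`
#'   (data.frame: channel, cond, method).
#' @export
invertSubfeatures <- function(Wp, condThreshold = 1e8) {
  if (!is.array(Wp) || length(dim(Wp)) != 3L || dim(Wp)[1] != dim(Wp)[2])
    stopf("Wp must be an m x m x p array")
  if (any(!is.finite(Wp))) stopf("Wp contains non-finite entries")
  m <- dim(Wp)[1]; p <- dim(Wp)[3]
  inv <- array(0, dim(Wp))
  cond <- numeric(p)
  method <- character(p)
  for (j in seq_len(p)) {
    A <- Wp[, , j]
    d <- svd(A, nu = 0, nv = 0)$d
    cond[j] <- if (min(d) > 0) max(d) / min(d) else Inf
    if (is.finite(cond[j]) && cond[j] <= condThreshold) {
      inv[, , j] <- solve(A)
      method[j] <- "exact"
    } else {
      inv[, , j] <- pseudoInverse(A)
      method[j] <- "pinv"
    }
  }
  list(inv = inv,
       report = data.frame(channel = seq_len(p), cond = cond, method = method))
}

# SVD pseudo-inverse with a relative singular-value cutoff.
pseudoInverse <- function(A, tol = 1e-12) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Data-domain transformation: voltages to velocity-domain features
#'
#' Maps each measurement vector from the voltage domain into the velocity
#' domain channel by channel, `v_sub^(j) = W_sub^(j)^-1 U`, and stacks the
#' p columns into an m x p feature matrix v' in channel order.
#'
#' @param U measurement vector (length m) or matrix of samples (N x m).
#' @param Wp encoder feature tensor m x m x p (ignored when `inv` given).
#' @param inv precomputed result of [invertSubfeatures()] (list or array).
#' @param condThreshold passed to [invertSubfeatures()] when inverting here.
#' @return for a vector U, an m x p matrix; for a matrix U, an N x m x p
#'   array. The inversion report is attached as attribute `report`.
#' @export
domainTransform <- function(U, Wp = NULL, inv = NULL, condThreshold = 1e8) {
  if (is.null(inv)) {
    if (is.null(Wp)) stopf("either Wp or inv must be supplied")
    inv <- invertSubfeatures(Wp, condThreshold)
  }
  report <- NULL
  if (is.list(inv)) { report <- inv$report; inv <- inv$inv }
  m <- dim(inv)[1]; p <- dim(inv)[3]
  vec <- is.null(dim(U))
  Um <- if (vec) matrix(U, nrow = 1) else U
  if (ncol(Um) != m)
    stopf("measurement length %d does not match channel order m = %d", ncol(Um), m)
  out <- array(0, c(nrow(Um), m, p))
  for (j in seq_len(p)) out[, , j] <- Um %*% t(inv[, , j])
  res <- if (vec) matrix(out[1, , ], m, p) else out
  attr(res, "report") <- report
  res
}
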