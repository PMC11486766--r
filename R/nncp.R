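# Non-negative CANDECOMP/PARAFAC decomposition by alternating non-negative
# least squares. Each ALS subproblem is solved exactly with the block
# principal pivoting active-set method of Kim & Park (2011), vectorized over
# right-hand sides; full exchange rules fall back to single-variable
# exchanges to guarantee termination.

#' Non-negative least squares by block principal pivoting
#'
#' Solves `min ||A X - B||_F` subject to `X >= 0` column by column through
#' the normal equations, given the cross-products `AtA = A'A` (R x R) and
#' `AtB = A'B` (R x K). Columns sharing a passive set are solved in one
#' linear solve.
#'
#' @param AtA R x R positive semi-definite matrix.
#' @param AtB R x K matrix.
#' @param max_iter safeguard on pivoting iterations.
#' @return R x K non-negative matrix.
#' @export
nnls_bpp <- function(AtA, AtB, max_iter = NULL) {
  r <- nrow(AtA)
  k <- ncol(AtB)
  if (is.null(max_iter)) max_iter <- 5L * r + 50L
  tol <- 1e-12 * max(abs(AtB), 1)

  X <- matrix(0, r, k)
  Y <- -AtB
  Fset <- matrix(FALSE, r, k)          # passive (unconstrained) variables
  p <- rep(3L, k)
  ninf <- rep(r + 1L, k)

  pow2 <- 2^(seq_len(r) - 1)        # exact pattern key for r <= 53
  solve_passive <- function(X, Y, Fset, cols) {
    keys <- as.vector(pow2 %*% Fset[, cols, drop = FALSE])
    for (key in unique(keys)) {
      jj <- cols[keys == key]
      fk <- Fset[, jj[1]]
      if (!any(fk)) {
        X[, jj] <- 0
      } else {
        sub <- AtA[fk, fk, drop = FALSE]
        rhs <- AtB[fk, jj, drop = FALSE]
        xk <- tryCatch(solve(sub, rhs), error = function(e) {
          solve(sub + diag(1e-10 * mean(diag(sub)) + 1e-300, sum(fk)), rhs)
        })
        X[, jj] <- 0
        X[fk, jj] <- xk
      }
      Y[, jj] <- AtA %*% X[, jj, drop = FALSE] - AtB[, jj, drop = FALSE]
      Y[fk, jj] <- 0
    }
    list(X = X, Y = Y)
  }

  live <- seq_len(k)
  res <- solve_passive(X, Y, Fset, live)
  X <- res$X; Y <- res$Y
  for (it in seq_len(max_iter)) {
    V <- (Fset & X < -tol) | (!Fset & Y < -tol)
    nV <- colSums(V)
    live <- which(nV > 0L)
    if (length(live) == 0L) break
    for (j in live) {
      if (nV[j] < ninf[j]) {
        ninf[j] <- nV[j]; p[j] <- 3L
        Fset[, j] <- xor(Fset[, j], V[, j])
      } else if (p[j] > 0L) {
        p[j] <- p[j] - 1L
        Fset[, j] <- xor(Fset[, j], V[, j])
      } else {
        i <- max(which(V[, j]))
        Fset[i, j] <- !Fset[i, j]
      }
    }
    res <- solve_passive(X, Y, Fset, live)
    X <- res$X; Y <- res$Y
  }
  X[X < 0] <- 0
  X
}

#' Fit a non-negative CP decomposition to a group FC tensor
#'
#' Decomposes a non-negative 3-way tensor `G` (ROIs x ROIs x windows) into
#' `rank` rank-one brain patterns \eqn{G \approx \sum_r \lambda_r \, x_r
#' \circ y_r \circ z_r} with all factors non-negative and unit-norm columns,
#' by alternating non-negative least squares with the block principal
#' pivoting solver. The best of `n_restarts` random initializations (by
#' reconstruction fit) is kept. Because FC slices are symmetric, the two ROI
#' modes are averaged after fitting ("symmetrized"); the pre-symmetrization
#' discrepancy is recorded as `asymmetry`.
#'
#' @param G a `group_fc_tensor` or a non-negative numeric 3-way array.
#' @param rank number of components R (1 <= R <= min(N, W)).
#' @param n_restarts number of initializations (default 10). The first uses
#'   the deterministic "nvecs" scheme — absolute values of the leading
#'   singular vectors of the mode unfoldings — which usually lands near the
#'   global optimum; the rest are random.
#' @param max_iter ALS iteration cap per restart (default 500).
#' @param tol relative change in fit declaring convergence (default 1e-8).
#' @param seed integer seed for the restarts (optional but recommended).
#' @param symmetrize average the two ROI modes after fitting (default TRUE).
#' @return an object of class `nncp` with components `lambdas` (descending),
#'   `spatial`, `spatial_b`, `temporal` (unit-norm columns), `fit` (relative
#'   reconstruction fit in `[0, 1]`), `asymmetry`, `rank`, `converged`,
#'   `iterations`, and the data tensor `G` (for residuals).
#' @seealso [core_consistency()], [select_rank()], [brain_patterns()]
#' @export
nncp <- function(G, rank, n_restarts = 10L, max_iter = 500L, tol = 1e-8,
                 seed = NULL, symmetrize = TRUE) {
  gobj <- if (inherits(G, "group_fc_tensor")) G else NULL
  Ga <- if (is.null(gobj)) G else gobj$G
  d <- dim(Ga)
  if (length(d) != 3L) fcp_stop("fcp_shape_error", "G must be a 3-way array")
  if (any(Ga < 0)) fcp_stop("fcp_value_error", "G must be entrywise >= 0")
  normG <- fnorm(Ga)
  if (normG == 0) fcp_stop("fcp_degenerate_input_error", "G is the zero tensor")
  if (!(rank >= 1L && rank <= min(d))) {
    fcp_stop("fcp_config_error", sprintf(
      "rank must be between 1 and %d", min(d)))
  }
  rank <- as.integer(rank)

  X1 <- unfold(Ga, 1); X2 <- unfold(Ga, 2); X3 <- unfold(Ga, 3)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1L)

  nvecs_init <- function(X, k) {
    # abs of leading singular vectors of an unfolding; pad with uniform
    # columns when the rank exceeds what the SVD supplies usefully
    nv <- min(k, min(dim(X)))
    u <- abs(svd(X, nu = nv, nv = 0L)$u)
    if (nv < k) u <- cbind(u, matrix(stats::runif(nrow(X) * (k - nv)),
                                     nrow(X), k - nv))
    u + 1e-9
  }

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    init <- with_seed(derive_seed(seed, rs), {
      if (rs == 1L) {
        list(B = nvecs_init(X2, rank), C = nvecs_init(X3, rank))
      } else {
        list(B = matrix(stats::runif(d[2] * rank), d[2], rank),
             C = matrix(stats::runif(d[3] * rank), d[3], rank))
      }
    })
    B <- init$B; C <- init$C
    A <- NULL
    fit_prev <- -Inf; fit <- NA_real_
    converged <- FALSE
    it <- 0L
    while (it < max_iter) {
      it <- it + 1L
      BtB <- crossprod(B); CtC <- crossprod(C)
      A <- t(nnls_bpp(BtB * CtC, t(X1 %*% khatri_rao(C, B))))
      AtA <- crossprod(A)
      B <- t(nnls_bpp(AtA * CtC, t(X2 %*% khatri_rao(C, A))))
      BtB <- crossprod(B)
      W3 <- X3 %*% khatri_rao(B, A)
      C <- t(nnls_bpp(AtA * BtB, t(W3)))
      err2 <- normG^2 - 2 * sum(C * W3) + sum(crossprod(C) * (AtA * BtB))
      fit <- 1 - sqrt(max(err2, 0)) / normG
      if (is.finite(fit_prev) && abs(fit - fit_prev) < tol) {
        converged <- TRUE
        break
      }
      fit_prev <- fit
    }
    if (is.null(best) || fit > best$fit) {
      best <- list(A = A, B = B, C = C, fit = fit, converged = converged,
                   iterations = it, restart = rs)
    }
  }

  # normalize columns into lambdas
  na <- sqrt(colSums(best$A^2)); nb <- sqrt(colSums(best$B^2))
  nc <- sqrt(colSums(best$C^2))
  lam <- na * nb * nc
  sc <- function(m, nrm) sweep(m, 2, pmax(nrm, .Machine$double.xmin), `/`)
  A <- sc(best$A, na); B <- sc(best$B, nb); C <- sc(best$C, nc)

  square <- d[1] == d[2]
  asym <- if (square) {
    max(sqrt(colSums((A - B)^2)) /
          pmax(sqrt(colSums(A^2)), .Machine$double.xmin))
  } else NA_real_
  if (symmetrize && square) {
    M <- (A + B) / 2
    nm <- sqrt(colSums(M^2))
    lam <- lam * nm^2           # preserve the rank-one tensor's scale
    Mh <- sc(M, nm)
    A <- Mh; B <- Mh
  }
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; A <- A[, ord, drop = FALSE]; B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  fit_final <- cp_fit_value(Ga, normG, lam, A, B, C)
  warn <- if (!best$converged) {
    sprintf("ALS did not converge within %d iterations (best restart %d)",
            max_iter, best$restart)
  } else NULL

  structure(
    list(lambdas = lam, spatial = A, spatial_b = B, temporal = C,
         fit = fit_final, fit_raw = best$fit, asymmetry = asym,
         rank = rank, dims = d, converged = best$converged,
         iterations = best$iterations, n_restarts = n_restarts,
         seed = seed, warnings = warn, G = Ga, group = gobj$group),
    class = "nncp"
  )
}

# Relative fit of a CP model without forming the dense reconstruction.
cp_fit_value <- function(Ga, normG, lam, A, B, C) {
  Al <- sweep(A, 2, lam, `*`)
  cross <- sum(Al * (unfold(Ga, 1) %*% khatri_rao(C, B)))
  gram <- sum((crossprod(Al, Al)) * (crossprod(B) * crossprod(C)))
  err2 <- normG^2 - 2 * cross + gram
  1 - sqrt(max(err2, 0)) / normG
}

#' @export
print.nncp <- function(x, ...) {
  cat(sprintf(
    "Non-negative CP decomposition%s\n  %d x %d x %d tensor, rank %d, fit %.4f\n",
    if (is.null(x$group)) "" else paste0(" [", x$group, "]"),
    x$dims[1], x$dims[2], x$dims[3], x$rank, x$fit))
  cat("  lambda:", paste(signif(x$lambdas, 4), collapse = ", "), "\n")
  if (!is.null(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' @export
summary.nncp <- function(object, ...) {
  roi_sets <- apply(object$spatial, 2, threshold_pattern, simplify = FALSE)
  out <- list(
    rank = object$rank, fit = object$fit, asymmetry = object$asymmetry,
    converged = object$converged, lambdas = object$lambdas,
    pattern_sizes = vapply(roi_sets, length, integer(1)),
    dims = object$dims)
  class(out) <- "summary.nncp"
  out
}

#' @export
print.summary.nncp <- function(x, ...) {
  cat(sprintf("Non-negative CP model: rank %d, fit %.4f, asymmetry %.2e\n",
              x$rank, x$fit, x$asymmetry))
  tab <- data.frame(pattern = seq_len(x$rank), lambda = signif(x$lambdas, 4),
                    rois_above_threshold = x$pattern_sizes)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.nncp <- function(object, ...) {
  list(lambdas = object$lambdas, spatial = object$spatial,
       temporal = object$temporal)
}

#' @export
fitted.nncp <- function(object, ...) {
  cp_tensor(object$lambdas, object$spatial, object$spatial_b, object$temporal)
}

#' @export
residuals.nncp <- function(object, ...) {
  if (is.null(object$G)) {
    fcp_stop("fcp_value_error", "model was fitted without storing the tensor")
  }
  object$G - fitted(object)
}

#' Plot temporal loadings and component weights of a CP model
#'
#' @param x an `nncp` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.nncp <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$temporal, type = "l", lty = 1,
                    xlab = "window", ylab = "temporal loading",
                    main = "Temporal loadings", ...)
  graphics::barplot(x$lambdas, names.arg = seq_along(x$lambdas),
                    xlab = "pattern", ylab = expression(lambda),
                    main = "Component weights")
  invisible(x)
}
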