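#' Soft-thresholding operator
#'
#' Proximal operator of `lam * ||.||_1`:
#' `sign(v) * pmax(abs(v) - lam, 0)`.
#'
#' @param v Numeric vector.
#' @param lam Nonnegative threshold.
#' @return Thresholded vector.
#' @export
soft_threshold <- function(v, lam) {
  stopifnot(lam >= 0)
  sign(v) * pmax(abs(v) - lam, 0)
}

#' Largest squared singular value of the forward matrix
#'
#' Estimates the Lipschitz building block `||A||_2^2` by power iteration on
#' `t(A) %*% A` to a relative tolerance. The FISTA step size applies a
#' safety factor `(1 + 10 * tol)` on top of the estimate so the step never
#' exceeds `1/L` even though power iteration approaches the true value from
#' below.
#'
#' @param model A `sparsus_model` or plain matrix.
#' @param tol Relative convergence tolerance of the power iteration.
#' @param max_sweeps Maximum number of iterations.
#' @return The estimate of `||A||_2^2` (scalar).
#' @export
lipschitz_estimate <- function(model, tol = 1e-7, max_sweeps = 1000) {
  is_model <- inherits(model, "sparsus_model")
  A <- if (is_model) model$A else model
  G <- if (is_model) model$cache$G else NULL
  if (is_model && !is.null(model$cache$smax2)) return(model$cache$smax2)
  n <- ncol(A)
  v <- rep(1 / sqrt(n), n)
  lam_old <- 0
  for (i in seq_len(max_sweeps)) {
    w <- if (!is.null(G)) as.vector(G %*% v) else as.vector(crossprod(A, A %*% v))
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(0)
    v <- w / lam
    if (abs(lam - lam_old) <= tol * lam) {
      if (is_model) model$cache$smax2 <- lam
      return(lam)
    }
    lam_old <- lam
  }
  rlang::abort(
    sprintf("Power iteration did not converge in %d sweeps (last estimate %.6g).",
            max_sweeps, lam_old),
    class = "sparsus_error_power"
  )
}

#' Solver settings for the l1-regularized inversion
#'
#' @param alpha Regularization weight; the objective is
#'   `||S - A T||_2^2 + alpha^2 * ||T||_1`, exactly as used throughout the
#'   package.
#' @param max_iters Iteration cap.
#' @param tolerance Relative objective-change stopping criterion.
#' @param step_rule `"fixed_1_over_L"` (the only rule implemented; kept as a
#'   field for forward compatibility).
#' @param nonnegativity If `TRUE`, the proximal step is one-sided and the
#'   solution is constrained to `T >= 0`.
#' @return A `sparsus_solver_config` list.
#' @export
solver_config <- function(alpha, max_iters = 2000, tolerance = 1e-8,
                          step_rule = "fixed_1_over_L", nonnegativity = FALSE) {
  stopifnot(alpha >= 0, max_iters >= 1, tolerance > 0)
  structure(
    list(alpha = alpha, max_iters = as.integer(max_iters),
         tolerance = tolerance, step_rule = step_rule,
         nonnegativity = isTRUE(nonnegativity)),
    class = "sparsus_solver_config"
  )
}

# smallest number of cells carrying 95% of the l1 mass
effective_support <- function(v, mass = 0.95) {
  a <- sort(abs(v[v != 0]), decreasing = TRUE)
  if (length(a) == 0) return(0L)
  as.integer(which(cumsum(a) >= mass * sum(a))[1])
}

# gram-vector product exploiting iterate sparsity
gram_mv <- function(G, v) {
  nz <- which(v != 0)
  if (length(nz) == 0) return(numeric(nrow(G)))
  if (length(nz) < ncol(G) / 4) {
    as.vector(G[, nz, drop = FALSE] %*% v[nz])
  } else {
    as.vector(G %*% v)
  }
}

#' Solve the l1-regularized least-squares problem with (monotone) FISTA
#'
#' Minimizes `F(T) = ||S - A T||_2^2 + alpha^2 * ||T||_1` with the monotone
#' variant of the fast iterative shrinkage-thresholding algorithm: gradient
#' step on the quadratic term at the momentum point, soft-thresholding with
#' threshold `alpha^2 * step` (the exact proximal map for this objective
#' scaling, whose gradient is `2 t(A) (A T - S)` and Lipschitz constant
#' `L = 2 ||A||_2^2`), momentum `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2`,
#' and a monotonicity safeguard so the objective trace is non-increasing.
#'
#' When the model carries a cached Gram matrix (see [precompute_gram()])
#' all iterations run in the n-dimensional grid space.
#'
#' @param model A `sparsus_model` or plain `m x n` matrix.
#' @param S Data vector of length `m` (vectorized RF record, element-major
#'   blocks with time fastest — `as.vector(rf$samples)`).
#' @param config A [solver_config()].
#' @param x0 Optional warm-start vector.
#' @return A `sparsus_recon`: list with `T_hat`, `objective_trace`,
#'   `n_iters`, `converged`, `residual_norm`, `alpha`, `support` (indices of
#'   nonzero entries), `grid` (when the model carries one).
#' @export
fista_solve <- function(model, S, config, x0 = NULL) {
  is_model <- inherits(model, "sparsus_model")
  A <- if (is_model) model$A else model
  if (length(S) != nrow(A)) {
    rlang::abort(sprintf("length(S) = %d does not match nrow(A) = %d.",
                         length(S), nrow(A)),
                 class = "sparsus_error_dimension")
  }
  alpha2 <- config$alpha^2
  G <- if (is_model) model$cache$G else NULL
  b <- as.vector(crossprod(A, S))
  sts <- sum(S^2)
  smax2 <- lipschitz_estimate(model)
  L <- 2 * smax2 * (1 + 1e-6)
  step <- if (L > 0) 1 / L else 1
  thr <- alpha2 * step

  n <- ncol(A)
  x <- if (is.null(x0)) numeric(n) else as.numeric(x0)
  stopifnot(length(x) == n)
  objective <- function(v, Gv = NULL) {
    if (!is.null(G)) {
      if (is.null(Gv)) Gv <- gram_mv(G, v)
      sts - 2 * sum(b * v) + sum(v * Gv) + alpha2 * sum(abs(v))
    } else {
      r <- S - A %*% v
      sum(r^2) + alpha2 * sum(abs(v))
    }
  }
  prox <- if (config$nonnegativity) {
    function(v) pmax(v - thr, 0)
  } else {
    function(v) soft_threshold(v, thr)
  }

  # G-path: one gram_mv per iteration. The momentum point is a linear
  # combination of the current and previous iterates, so its Gram product
  # is derived from the cached products instead of a second multiply.
  Gx <- if (!is.null(G)) gram_mv(G, x) else NULL
  f_x <- objective(x, Gx)
  y <- x
  Gy <- Gx
  tk <- 1
  trace <- numeric(config$max_iters)
  converged <- FALSE
  n_iters <- 0L
  for (k in seq_len(config$max_iters)) {
    grad <- if (!is.null(G)) 2 * (Gy - b) else {
      as.vector(2 * crossprod(A, A %*% y - S))
    }
    z <- prox(y - step * grad)
    if (anyNA(z)) {
      rlang::abort(sprintf("FISTA iterates contain NaN (step size %.3g).", step),
                   class = "sparsus_error_divergence")
    }
    Gz <- if (!is.null(G)) gram_mv(G, z) else NULL
    f_z <- objective(z, Gz)
    # monotone safeguard with adaptive restart: a rejected step resets the
    # momentum instead of stalling the objective trace
    if (f_z <= f_x) {
      t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
      beta <- (tk - 1) / t_next
      y <- z + beta * (z - x)
      if (!is.null(G)) Gy <- (1 + beta) * Gz - beta * Gx
      x <- z
      Gx <- Gz
      rel <- abs(f_x - f_z) / max(abs(f_x), .Machine$double.eps)
      f_x <- f_z
      tk <- t_next
      trace[k] <- f_x
      n_iters <- k
      if (k > 1 && rel < config$tolerance) {
        converged <- TRUE
        break
      }
    } else {
      y <- x
      Gy <- Gx
      tk <- 1
      trace[k] <- f_x
      n_iters <- k
    }
  }
  resid <- sqrt(sum((S - A %*% x)^2))
  structure(
    list(
      T_hat = as.vector(x),
      objective_trace = trace[seq_len(n_iters)],
      n_iters = n_iters, converged = converged,
      residual_norm = resid, alpha = config$alpha,
      support = which(x != 0),
      grid = if (is_model) model$grid else NULL
    ),
    class = "sparsus_recon"
  )
}

#' @export
print.sparsus_recon <- function(x, ...) {
  cat(sprintf(
    "<sparsus_recon> support %d, %d iters (%s), objective %.4g, residual %.4g\n",
    length(x$support), x$n_iters,
    if (x$converged) "converged" else "max iters", utils::tail(x$objective_trace, 1),
    x$residual_norm
  ))
  invisible(x)
}

#' Heuristic choice of the regularization weight
#'
#' Scans `alpha^2` over a logarithmic grid of fractions of
#' `alpha_max^2 = 2 * max(abs(t(A) %*% S))` — the smallest `alpha^2` for
#' which the all-zero solution is optimal under this objective scaling
#' (subgradient condition `|2 t(A) S|_inf <= alpha^2`). Solutions are
#' warm-started from large to small `alpha`; the selected value is the
#' smallest `alpha` whose solution support does not exceed
#' `support_budget` cells — the programmatic counterpart of tuning
#' `alpha` until the image looks like a plausible sparse scene.
#'
#' The budget is enforced on the *effective* support — the smallest number
#' of cells carrying 95% of the solution's l1 mass — rather than on the
#' raw nonzero count, which is dominated by near-zero noise cells and
#' oscillates between realizations.
#'
#' @param model A `sparsus_model` or matrix.
#' @param S Data vector.
#' @param fractions Candidate `alpha^2` values as fractions of
#'   `alpha_max^2`, scanned in decreasing order.
#' @param support_budget Largest acceptable effective support size.
#' @param max_iters,tolerance,nonnegativity Solver settings per candidate.
#' @return A list with `alpha`, `result` (the `sparsus_recon` at the chosen
#'   alpha), `scan` (tibble: alpha, fraction, support, eff_support,
#'   residual_norm, objective, n_iters), and `flag` (`"ok"`,
#'   `"all_above_budget"`, or `"all_empty"`).
#' @export
choose_alpha <- function(model, S,
                         fractions = 10^seq(log10(0.5), -2, length.out = 8),
                         support_budget = 25,
                         max_iters = 500, tolerance = 1e-7,
                         nonnegativity = FALSE) {
  stopifnot(all(fractions > 0))
  fractions <- sort(fractions, decreasing = TRUE)
  A <- if (inherits(model, "sparsus_model")) model$A else model
  alpha2_max <- 2 * max(abs(crossprod(A, S)))
  fits <- vector("list", length(fractions))
  x0 <- NULL
  for (i in seq_along(fractions)) {
    a <- sqrt(alpha2_max * fractions[i])
    fits[[i]] <- fista_solve(
      model, S,
      solver_config(a, max_iters = max_iters, tolerance = tolerance,
                    nonnegativity = nonnegativity),
      x0 = x0
    )
    x0 <- fits[[i]]$T_hat
  }
  scan <- tibble::tibble(
    fraction = fractions,
    alpha = sqrt(alpha2_max * fractions),
    support = vapply(fits, function(f) length(f$support), integer(1)),
    eff_support = vapply(fits, function(f) effective_support(f$T_hat),
                         integer(1)),
    residual_norm = vapply(fits, function(f) f$residual_norm, numeric(1)),
    objective = vapply(fits, function(f) utils::tail(f$objective_trace, 1), numeric(1)),
    n_iters = vapply(fits, function(f) f$n_iters, integer(1))
  )
  ok <- which(scan$eff_support > 0 & scan$eff_support <= support_budget)
  if (length(ok) > 0) {
    pick <- max(ok) # fractions are decreasing, so max index = smallest alpha
    flag <- "ok"
  } else if (all(scan$support == 0)) {
    pick <- length(fractions)
    flag <- "all_empty"
  } else {
    pick <- which.min(scan$eff_support)
    flag <- "all_above_budget"
  }
  list(alpha = scan$alpha[pick], result = fits[[pick]], scan = scan, flag = flag)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sparse reconstruction into its nonzero grid cells
#'
#' @param x A `sparsus_recon`.
#' @param ... Unused.
#' @return A tibble with `point`, `x`, `z` (when a grid is attached) and
#'   `value`, one row per nonzero cell.
#' @export
tidy.sparsus_recon <- function(x, ...) {
  out <- tibble::tibble(point = x$support, value = x$T_hat[x$support])
  if (!is.null(x$grid)) {
    co <- grid_coords(x$grid)
    out$x <- co$x[out$point]
    out$z <- co$z[out$point]
    out <- out[, c("point", "x", "z", "value")]
  }
  out
}

#' One-row summary of a sparse reconstruction
#'
#' @param x A `sparsus_recon`.
#' @param ... Unused.
#' @return A tibble with `alpha`, `support_size`, `n_iters`, `converged`,
#'   `objective`, `residual_norm`.
#' @export
glance.sparsus_recon <- function(x, ...) {
  tibble::tibble(
    alpha = x$alpha,
    support_size = length(x$support),
    n_iters = x$n_iters,
    converged = x$converged,
    objective = utils::tail(x$objective_trace, 1),
    residual_norm = x$residual_norm
  )
}
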