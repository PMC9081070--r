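# Shared low-level numerics: lattice index shifts, sparse operator assembly,
# trilinear interpolation and a small bounded Nelder-Mead.

# linear indices of the +/-1 neighbour along `axis`; NA where out of domain
.shifted_index <- function(dims, axis, dir) {
  lin <- array(seq_len(prod(dims)), dims)
  nb <- array(NA_integer_, dims)
  n <- dims[axis]
  if (n < 2L) return(nb)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (a in 1:3) { src[[a]] <- seq_len(dims[a]); dst[[a]] <- seq_len(dims[a]) }
  if (dir > 0) { dst[[axis]] <- 1:(n - 1L); src[[axis]] <- 2:n }
  else         { dst[[axis]] <- 2:n;        src[[axis]] <- 1:(n - 1L) }
  nb[dst[[1]], dst[[2]], dst[[3]]] <- lin[src[[1]], src[[2]], src[[3]]]
  nb
}

# Assemble and solve  L u = rhs  on the free (non-Dirichlet) nodes of a
# lattice, where L is described by per-node stencil coefficients:
#   terms: list of list(nb = full-grid neighbour index (NA = out of domain),
#                       coef = per-node coefficient,
#                       boundary = "reflect" (redirect to `opposite`) or
#                                  "drop" (omit coefficient and its diagonal
#                                          counterpart `diag_pair`),
#                       opposite = neighbour index used for reflection,
#                       diag_pair = per-node diagonal contribution tied to
#                                   this term (dropped together with it))
#   diag: per-node diagonal contribution independent of the terms
# Dirichlet nodes carry known values `dirvals`; their contributions move to
# the right-hand side. Returns the full-grid solution array.
.solve_lattice <- function(dims, dirichlet, dirvals, terms, diag, rhs_full,
                           label = "lattice solve") {
  N <- prod(dims)
  free <- which(!dirichlet)
  nf <- length(free)
  if (nf == 0L) {
    u <- array(0, dims); u[dirichlet] <- dirvals[dirichlet]; return(u)
  }
  fmap <- integer(N); fmap[free] <- seq_len(nf)
  diag_acc <- rep(0, N) + diag
  rows <- list(); cols <- list(); vals <- list()
  rhs <- rhs_full[free]
  ti <- 1L
  for (tm in terms) {
    nb <- tm$nb; coef <- tm$coef
    out <- is.na(nb)
    if (identical(tm$boundary, "reflect")) {
      nb[out] <- tm$opposite[out]
      diag_acc <- diag_acc + tm$diag_pair
    } else { # drop
      keepd <- !out
      diag_acc[keepd] <- diag_acc[keepd] + tm$diag_pair[keepd]
      coef[out] <- 0
    }
    nbf <- nb[free]; cf <- coef[free]
    act <- which(!is.na(nbf) & cf != 0)
    if (length(act)) {
      nbv <- nbf[act]
      isd <- dirichlet[nbv]
      if (any(isd)) {
        ii <- act[isd]
        rhs[ii] <- rhs[ii] - cf[ii] * dirvals[nbf[ii]]
      }
      ii <- act[!isd]
      if (length(ii)) {
        rows[[ti]] <- ii
        cols[[ti]] <- fmap[nbf[ii]]
        vals[[ti]] <- cf[ii]
        ti <- ti + 1L
      }
    }
  }
  rows[[ti]] <- seq_len(nf); cols[[ti]] <- seq_len(nf)
  vals[[ti]] <- diag_acc[free]
  A <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                            x = unlist(vals), dims = c(nf, nf))
  sol <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                  error = function(e)
                    stop(sprintf("%s: linear solve failed (%s)", label,
                                 conditionMessage(e))))
  res <- sqrt(sum((as.numeric(A %*% sol) - rhs)^2)) /
    max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (!all(is.finite(sol)) || res > 1e-6)
    stop(sprintf("%s: solution not converged (relative residual %.3g)",
                 label, res))
  u <- array(0, dims)
  u[dirichlet] <- dirvals[dirichlet]
  u[free] <- sol
  u
}

# Laplace-type stencil terms (zero normal gradient via second-order ghost
# reflection on non-Dirichlet boundary faces)
.laplace_terms <- function(dims, hs, dcoef = 1) {
  terms <- list()
  diag <- 0
  for (axis in 1:3) {
    c_ax <- dcoef / hs[axis]^2
    nb_m <- .shifted_index(dims, axis, -1L)
    nb_p <- .shifted_index(dims, axis, +1L)
    cvec <- rep(c_ax, prod(dims))
    terms[[length(terms) + 1L]] <-
      list(nb = nb_m, coef = cvec, boundary = "reflect", opposite = nb_p,
           diag_pair = rep(0, prod(dims)))
    terms[[length(terms) + 1L]] <-
      list(nb = nb_p, coef = cvec, boundary = "reflect", opposite = nb_m,
           diag_pair = rep(0, prod(dims)))
    diag <- diag - 2 * c_ax
  }
  list(terms = terms, diag = diag)
}

# vectorised trilinear interpolation on a regular (rectilinear) lattice;
# points outside the lattice return `outside`
.trilinear <- function(xc, yc, zc, values, pts, outside = 0) {
  n <- nrow(pts)
  res <- rep(outside, n)
  eps <- 1e-9
  inside <- pts[, 1] >= xc[1] - eps & pts[, 1] <= xc[length(xc)] + eps &
    pts[, 2] >= yc[1] - eps & pts[, 2] <= yc[length(yc)] + eps &
    pts[, 3] >= zc[1] - eps & pts[, 3] <= zc[length(zc)] + eps
  if (!any(inside)) return(res)
  p <- pts[inside, , drop = FALSE]
  loc <- function(coords, v) {
    i <- findInterval(v, coords, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(coords) - 1L)
    f <- (v - coords[i]) / (coords[i + 1L] - coords[i])
    list(i = i, f = pmin(pmax(f, 0), 1))
  }
  lx <- loc(xc, p[, 1]); ly <- loc(yc, p[, 2]); lz <- loc(zc, p[, 3])
  nx <- length(xc); ny <- length(yc)
  id <- function(i, j, k) i + (j - 1L) * nx + (k - 1L) * nx * ny
  v <- values
  g <- function(di, dj, dk) v[id(lx$i + di, ly$i + dj, lz$i + dk)]
  wx0 <- 1 - lx$f; wy0 <- 1 - ly$f; wz0 <- 1 - lz$f
  out <- g(0L, 0L, 0L) * wx0 * wy0 * wz0 + g(1L, 0L, 0L) * lx$f * wy0 * wz0 +
    g(0L, 1L, 0L) * wx0 * ly$f * wz0 + g(1L, 1L, 0L) * lx$f * ly$f * wz0 +
    g(0L, 0L, 1L) * wx0 * wy0 * lz$f + g(1L, 0L, 1L) * lx$f * wy0 * lz$f +
    g(0L, 1L, 1L) * wx0 * ly$f * lz$f + g(1L, 1L, 1L) * lx$f * ly$f * lz$f
  res[inside] <- out
  res
}

#' Bounded Nelder-Mead downhill simplex
#'
#' Small downhill-simplex minimiser with box constraints enforced by clamping
#' every candidate vertex into the bounds, and a full log of evaluated
#' points. Standard coefficients: reflection 1, expansion 2, contraction 0.5,
#' shrink 0.5. Convergence is declared when the relative simplex diameter
#' falls below `tol` or after `maxeval` objective evaluations.
#'
#' @param fn Objective, `fn(x) -> numeric(1)`; may return `Inf`.
#' @param x0 Numeric start vector.
#' @param lower,upper Bounds (recycled); default unbounded.
#' @param step Initial simplex step per coordinate (default 10\% of the
#'   coordinate magnitude, or 0.1 where it is zero).
#' @param tol Relative simplex-diameter tolerance (default 1e-3).
#' @param maxeval Evaluation budget (default 200).
#' @return List with `par`, `value`, `evals` and `trace` (a data frame of all
#'   evaluated points and values, in evaluation order).
#' @export
nelder_mead <- function(fn, x0, lower = -Inf, upper = Inf, step = NULL,
                        tol = 1e-3, maxeval = 200) {
  n <- length(x0)
  lower <- rep_len(lower, n); upper <- rep_len(upper, n)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  if (is.null(step)) step <- ifelse(x0 == 0, 0.1, 0.1 * abs(x0))
  step <- rep_len(step, n)
  trace_x <- list(); trace_f <- numeric(0)
  evals <- 0L
  f <- function(x) {
    evals <<- evals + 1L
    val <- suppressWarnings(fn(x))
    if (!is.finite(val)) val <- Inf
    trace_x[[length(trace_x) + 1L]] <<- x
    trace_f[length(trace_f) + 1L] <<- val
    val
  }
  V <- matrix(rep(clamp(x0), n + 1L), nrow = n + 1L, byrow = TRUE)
  for (i in seq_len(n)) {
    v <- V[i + 1L, ]; v[i] <- v[i] + step[i]
    if (v[i] > upper[i]) v[i] <- x0[i] - step[i]
    V[i + 1L, ] <- clamp(v)
  }
  fv <- apply(V, 1L, f)
  repeat {
    ord <- order(fv)
    V <- V[ord, , drop = FALSE]; fv <- fv[ord]
    scale <- max(1, max(abs(V[1L, ])))
    diam <- max(sqrt(rowSums((V[-1L, , drop = FALSE] -
                                matrix(V[1L, ], n, n, byrow = TRUE))^2)))
    if (diam / scale < tol || evals >= maxeval) break
    centroid <- colMeans(V[seq_len(n), , drop = FALSE])
    xr <- clamp(centroid + 1 * (centroid - V[n + 1L, ]))
    fr <- f(xr)
    if (fr < fv[1L]) {
      xe <- clamp(centroid + 2 * (centroid - V[n + 1L, ]))
      fe <- f(xe)
      if (fe < fr) { V[n + 1L, ] <- xe; fv[n + 1L] <- fe }
      else { V[n + 1L, ] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      V[n + 1L, ] <- xr; fv[n + 1L] <- fr
    } else {
      xc <- clamp(centroid + 0.5 * (V[n + 1L, ] - centroid))
      fc <- f(xc)
      if (fc < fv[n + 1L]) { V[n + 1L, ] <- xc; fv[n + 1L] <- fc }
      else {
        for (i in 2:(n + 1L)) {
          V[i, ] <- clamp(V[1L, ] + 0.5 * (V[i, ] - V[1L, ]))
          fv[i] <- f(V[i, ])
        }
      }
    }
    if (evals >= maxeval) break
  }
  best <- which.min(fv)
  list(par = V[best, ], value = fv[best], evals = evals,
       trace = data.frame(do.call(rbind, trace_x), value = trace_f))
}
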