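#' Distance-geometry reconstruction of the average granule structure
#'
#' Five labeled particles (the granule-protein center plus four mRNA cluster
#' centers) are embedded in 3D from their 10 average pairwise distances by
#' least-squares minimization of `sum_{i<j} (||x_i - x_j|| - d_ij)^2` with
#' quasi-Newton (BFGS) iterations from random starts, polished by
#' Levenberg-Marquardt. Distances cannot tell a structure from its mirror
#' image; a noise-bootstrap ensemble therefore splits into two chirality
#' classes, kept distinct by registering every solution with proper
#' rotations only (no reflections) and separated by k-means.
#'
#' @name triangulate
NULL

.pair_index <- function(n) t(utils::combn(n, 2))

.distance_loss <- function(par, d, w, prs) {
  X <- matrix(par, ncol = 3)
  dv <- sqrt(rowSums((X[prs[, 1], ] - X[prs[, 2], ])^2))
  sum(w * (dv - d)^2)
}

.distance_grad <- function(par, d, w, prs) {
  X <- matrix(par, ncol = 3)
  diffs <- X[prs[, 1], ] - X[prs[, 2], ]
  dv <- pmax(sqrt(rowSums(diffs^2)), 1e-12)
  coef <- 2 * w * (dv - d) / dv
  G <- matrix(0, nrow(X), 3)
  for (k in seq_len(nrow(prs))) {
    G[prs[k, 1], ] <- G[prs[k, 1], ] + coef[k] * diffs[k, ]
    G[prs[k, 2], ] <- G[prs[k, 2], ] - coef[k] * diffs[k, ]
  }
  as.vector(G)
}

## Levenberg-Marquardt polish in a gauge-fixed parameterization: the rigid
## motion is removed (point 1 at the origin, point 2 on +x, point 3 in the
## xy-plane), leaving 3n-6 free parameters against n(n-1)/2 residuals so the
## least-squares system is well posed. Falls back to the input when the
## leading points are (near) collinear.
.lm_polish <- function(par, dv, w, prs, n) {
  X <- matrix(par, ncol = 3)
  X <- sweep(X, 2, X[1, ])
  e1 <- X[2, ]; n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) return(par)
  e1 <- e1 / n1
  v2 <- X[3, ] - sum(X[3, ] * e1) * e1; n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-9) return(par)
  e2 <- v2 / n2
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  Xg <- X %*% cbind(e1, e2, e3)
  to_free <- function(Xg) {
    fr <- c(Xg[2, 1], Xg[3, 1:2])
    if (n > 3L) fr <- c(fr, as.vector(t(Xg[4:n, , drop = FALSE])))
    fr
  }
  from_free <- function(p) {
    Xr <- matrix(0, n, 3)
    Xr[2, 1] <- p[1]; Xr[3, 1:2] <- p[2:3]
    if (n > 3L)
      Xr[4:n, ] <- matrix(p[-(1:3)], ncol = 3, byrow = TRUE)
    Xr
  }
  pol <- tryCatch(
    minpack.lm::nls.lm(
      par = to_free(Xg),
      fn = function(p) {
        Xr <- from_free(p)
        sqrt(w) * (sqrt(rowSums((Xr[prs[, 1], ] - Xr[prs[, 2], ])^2)) - dv)
      },
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15, gtol = 0)),
    error = function(e) NULL)
  if (is.null(pol)) return(par)
  Xr <- from_free(pol$par)
  if (.distance_loss(as.vector(Xr), dv, w, prs) <
      .distance_loss(par, dv, w, prs)) as.vector(Xr) else par
}

#' Embed labeled points from a pairwise distance matrix
#'
#' @param d symmetric distance matrix (nm) with zero diagonal; rownames are
#'   the particle labels.
#' @param seed RNG seed for the random starts.
#' @param n_starts number of random starts; the best (lowest loss) wins.
#' @param weights optional per-pair weights (same shape as `d`), e.g.
#'   `1/sigma^2`; default unweighted.
#' @return A `granule_structure`: `coords` (labeled n x 3 matrix, centered
#'   at the origin), `loss`, `deviation_nm` (see [mean_deviation()]),
#'   `seed`, `class_label` (NA until classified).
#' @export
solve_coordinates <- function(d, seed = 1L, n_starts = 5L, weights = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n >= 3L, ncol(d) == n, all(abs(d - t(d)) < 1e-9),
            all(diag(d) == 0), all(d >= 0))
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  prs <- .pair_index(n)
  dv <- d[prs]
  w <- if (is.null(weights)) rep(1, nrow(prs)) else as.matrix(weights)[prs]
  scale <- max(dv) / 2
  set.seed(seed)
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    par0 <- stats::runif(3 * n, -scale, scale)
    fit <- tryCatch(
      stats::optim(par0, .distance_loss, .distance_grad, d = dv, w = w,
                   prs = prs, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    par <- .lm_polish(fit$par, dv, w, prs, n)
    loss <- .distance_loss(par, dv, w, prs)
    if (is.null(best) || loss < best$loss) best <- list(par = par, loss = loss)
  }
  if (is.null(best)) stop("solver error: no start converged")
  X <- matrix(best$par, ncol = 3)
  X <- sweep(X, 2, colMeans(X))
  rownames(X) <- labels
  colnames(X) <- c("x", "y", "z")
  st <- structure(list(coords = X, loss = best$loss, seed = seed,
                       class_label = NA_integer_),
                  class = "granule_structure")
  st$deviation_nm <- mean_deviation(st, d)
  st
}

#' @export
print.granule_structure <- function(x, ...) {
  cat("granule_structure of", nrow(x$coords), "points; mean deviation",
      signif(x$deviation_nm, 4), "nm\n")
  print(round(x$coords, 2))
  invisible(x)
}

#' Mean deviation of implied from measured distances
#'
#' The mean over all unique pairs of `|implied - measured|` distance, the
#' goodness-of-fit figure of a triangulated structure (nm).
#'
#' @param s a `granule_structure` or a labeled coordinate matrix.
#' @param d the measured distance matrix.
#' @return Mean absolute deviation in nm.
#' @export
mean_deviation <- function(s, d) {
  X <- if (inherits(s, "granule_structure")) s$coords else as.matrix(s)
  d <- as.matrix(d)
  stopifnot(nrow(X) == nrow(d))
  if (!is.null(rownames(X)) && !is.null(rownames(d)))
    stopifnot(all(rownames(X) == rownames(d)))
  prs <- .pair_index(nrow(X))
  implied <- sqrt(rowSums((X[prs[, 1], ] - X[prs[, 2], ])^2))
  mean(abs(implied - d[prs]))
}

## Kabsch alignment restricted to proper rotations (det = +1)
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  t_vec <- cq - as.vector(R %*% cp)
  list(R = R, t = t_vec)
}

#' Register a structure onto a reference (proper rotations only)
#'
#' Finds the rigid transform (rotation with determinant +1, plus
#' translation) minimizing label-wise RMSD, robustly: candidate transforms
#' are fitted on minimal 3-point subsets, scored by consensus (inliers
#' within twice the median residual of the all-point fit), and the winner
#' is refitted on its inliers. Reflections are excluded, so a mirror-image
#' structure keeps a strictly positive RMSD - this is what keeps the two
#' chirality classes distinct.
#'
#' @param s structure to register (`granule_structure` or coordinate
#'   matrix).
#' @param ref reference structure with the same labels.
#' @param inlier_mult inlier threshold as a multiple of the all-point fit's
#'   median residual.
#' @return List: `coords` (registered), `R`, `t`, `rmsd_nm`, `inliers`.
#' @export
register_structure <- function(s, ref, inlier_mult = 2) {
  P <- if (inherits(s, "granule_structure")) s$coords else as.matrix(s)
  Q <- if (inherits(ref, "granule_structure")) ref$coords else as.matrix(ref)
  stopifnot(nrow(P) == nrow(Q))
  n <- nrow(P)
  resid_of <- function(tr) {
    Pt <- sweep(P %*% t(tr$R), 2, tr$t, "+")
    sqrt(rowSums((Pt - Q)^2))
  }
  full <- .kabsch(P, Q)
  thr <- inlier_mult * stats::median(resid_of(full))
  best <- list(tr = full, inl = resid_of(full) <= max(thr, 1e-9))
  if (n > 3L && thr > 0) {
    for (tri in utils::combn(n, 3, simplify = FALSE)) {
      tr <- .kabsch(P[tri, , drop = FALSE], Q[tri, , drop = FALSE])
      inl <- resid_of(tr) <= thr
      if (sum(inl) > sum(best$inl)) best <- list(tr = tr, inl = inl)
    }
  }
  if (sum(best$inl) >= 3L)
    best$tr <- .kabsch(P[best$inl, , drop = FALSE], Q[best$inl, , drop = FALSE])
  Pt <- sweep(P %*% t(best$tr$R), 2, best$tr$t, "+")
  dimnames(Pt) <- dimnames(Q)
  list(coords = Pt, R = best$tr$R, t = best$tr$t,
       rmsd_nm = sqrt(mean(rowSums((Pt - Q)^2))), inliers = best$inl)
}

## draw one noisy distance matrix around d (sd scalar or matrix), redraw negatives
.draw_distances <- function(d, sd) {
  up <- upper.tri(d)
  sdv <- if (length(sd) == 1L) rep(sd, sum(up)) else as.matrix(sd)[up]
  vals <- d[up] + stats::rnorm(sum(up), 0, sdv)
  while (any(vals < 0)) {
    neg <- which(vals < 0)
    vals[neg] <- d[up][neg] + stats::rnorm(length(neg), 0, sdv[neg])
  }
  out <- d
  out[up] <- vals
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Noise-bootstrap ensemble of triangulated structures
#'
#' Repeats the embedding `n` times, each time from a distance set drawn from
#' a normal distribution centered on the measured means with s.d. equal to
#' the measurement uncertainty; every solution is registered onto the
#' noise-free reference solution by proper rotations.
#'
#' @param d_mean measured mean distance matrix (nm).
#' @param d_sd measurement uncertainty: scalar or per-entry matrix (nm).
#' @param n ensemble size (default 1000).
#' @param seed RNG seed.
#' @param n_starts random starts per bootstrap solve.
#' @return A `structure_ensemble`: `coords` (n x npoints x 3 registered
#'   array), `deviations_nm`, `rmsd_nm`, `reference`, `n_requested`,
#'   `n_achieved`, `seed`.
#' @export
bootstrap_ensemble <- function(d_mean, d_sd, n = 1000L, seed = 1L,
                               n_starts = 2L) {
  d_mean <- as.matrix(d_mean)
  if (n < 2) stop("ensemble size must be >= 2")
  reference <- solve_coordinates(d_mean, seed = seed, n_starts = 5L)
  npt <- nrow(d_mean)
  set.seed(seed)
  draw_seeds <- sample.int(.Machine$integer.max, n)
  coords <- array(NA_real_, c(n, npt, 3))
  devs <- rmsds <- rep(NA_real_, n)
  ok <- logical(n)
  for (k in seq_len(n)) {
    set.seed(draw_seeds[k])
    dk <- .draw_distances(d_mean, d_sd)
    st <- tryCatch(
      solve_coordinates(dk, seed = draw_seeds[k], n_starts = n_starts),
      error = function(e) NULL)
    if (is.null(st)) next
    reg <- register_structure(st, reference)
    coords[k, , ] <- reg$coords
    devs[k] <- st$deviation_nm
    rmsds[k] <- reg$rmsd_nm
    ok[k] <- TRUE
  }
  if (sum(ok) < n)
    message(n - sum(ok), " bootstrap solves failed and were dropped")
  structure(list(coords = coords[ok, , , drop = FALSE],
                 deviations_nm = devs[ok], rmsd_nm = rmsds[ok],
                 reference = reference, labels = rownames(d_mean),
                 n_requested = n, n_achieved = sum(ok), seed = seed),
            class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("structure_ensemble:", x$n_achieved, "of", x$n_requested,
      "structures; mean deviation",
      signif(mean(x$deviations_nm), 4), "nm\n")
  invisible(x)
}

#' Signed volume of a labeled structure
#'
#' Scalar triple product of three edge vectors (points 2..5 define the
#' simplex), divided by 6. Its sign is the structure's chirality; near-zero
#' magnitude means a (nearly) planar, achiral configuration.
#'
#' @param coords labeled n x 3 coordinate matrix (n >= 4; rows 2..5 used).
#' @return Signed volume in nm^3.
#' @export
signed_volume <- function(coords) {
  X <- if (inherits(coords, "granule_structure")) coords$coords else
    as.matrix(coords)
  stopifnot(nrow(X) >= 4L)
  i <- if (nrow(X) >= 5L) 2:5 else 1:4
  v1 <- X[i[2], ] - X[i[1], ]; v2 <- X[i[3], ] - X[i[1], ]
  v3 <- X[i[4], ] - X[i[1], ]
  det(rbind(v1, v2, v3)) / 6
}

#' Classify a registered ensemble into chirality classes
#'
#' Seeded k-means (k = 2, multiple initializations) on the flattened
#' registered coordinates. As an interpretable sanity channel each
#' structure's signed volume is reported: for a non-planar geometry the two
#' k-means classes should coincide with the two signs (mirror-image
#' families). Planar geometries are achiral; they are flagged and the
#' class split is not chirality-driven.
#'
#' @param ensemble a `structure_ensemble`.
#' @param k number of classes (default 2).
#' @param seed RNG seed for k-means.
#' @param planar_tol relative volume below which the reference is deemed
#'   planar (fraction of max pairwise distance cubed).
#' @return List: `labels`, `counts`, `signed_volumes`, `sign_agreement`
#'   (fraction of structures whose k-means class matches the majority sign
#'   of that class), `flag_planar`, `centers`.
#' @export
classify_chirality <- function(ensemble, k = 2L, seed = 1L,
                               planar_tol = 1e-3) {
  stopifnot(inherits(ensemble, "structure_ensemble"))
  n <- ensemble$n_achieved
  X <- matrix(ensemble$coords, nrow = n)
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = 10, iter.max = 100)
  vols <- apply(ensemble$coords, 1, function(m) signed_volume(m))
  scale3 <- max(stats::dist(ensemble$reference$coords))^3
  flag_planar <- abs(signed_volume(ensemble$reference)) < planar_tol * scale3
  agree <- NA_real_
  if (!flag_planar) {
    sgn <- sign(vols)
    maj <- vapply(seq_len(k), function(cl) {
      s <- sgn[km$cluster == cl]
      if (!length(s)) return(0)
      as.numeric(names(which.max(table(s))))
    }, numeric(1))
    agree <- mean(sgn == maj[km$cluster])
  }
  counts <- as.integer(tabulate(km$cluster, k))
  list(labels = km$cluster, counts = counts, signed_volumes = vols,
       sign_agreement = agree, flag_planar = flag_planar,
       centers = km$centers)
}
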