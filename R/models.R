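#' Parameters for the convexity-preserving evolution
#'
#' Coefficients of the proposed evolution
#' \deqn{\phi_t = s(\kappa)\,[\lambda_1 (I-c_1)^2 - \lambda_2 (I-c_2)^2]\,
#'   \delta_\epsilon(\phi) + \alpha\,\kappa\,\delta_\epsilon(\phi) +
#'   \mu\,g\,\delta_\epsilon(\phi) + \beta\,(1-s(\kappa))\,\kappa\,
#'   \delta_\epsilon(\phi)}
#' under the inside-negative convention, where positive `mu` drives the
#' contour inward.  Published working regime: `alpha = 1`, `mu = 10`,
#' `lambda2 = 1`, `lambda1` in `[1, 5]` (larger values pull the contour
#' inward harder; too large leaks through weak boundaries), `beta = 1` for
#' images with clear boundaries.
#'
#' @param lambda1 inside data weight (>= 0).
#' @param lambda2 outside data weight (>= 0).
#' @param alpha length-term coefficient (> 0).
#' @param mu area (balloon) coefficient; positive shrinks, negative expands.
#' @param beta curvature-term coefficient (> 0).
#' @param eps smoothed Heaviside/Dirac band half-width (px).
#' @param sigma Gaussian sd for the edge indicator (px).
#' @param edge_scale gradient scale for the edge indicator (see
#'   [edge_indicator()]).
#' @param csi_sigma Gaussian sd for smoothing curvature before the CSI sign.
#' @param dt explicit time step; `NULL` (default) picks it from the CFL
#'   bound via [suggest_time_step()] on a trial evaluation.
#' @param max_iterations iteration budget.
#' @param tolerance convergence tolerance on the mean per-iteration change
#'   of `phi` within the contour band.
#' @param checkpoint_stride iterations between convergence checks.
#' @param snapshot_stride iterations between stored contour snapshots
#'   (0 disables).
#' @param reinit_every redistance `phi` every this many iterations (5 Godunov
#'   upwind sweeps of the sign-preserving redistancing equation; 0 disables).
#'   The default is 5: the smoothed Dirac is compactly supported, so without
#'   periodic redistancing no force ever reaches pixels with `|phi| > eps`
#'   and the contour stalls after about `eps` px of travel (the CPLSE model
#'   refreshes its distance profile through its own regularizer instead).
#' @return an `evolution_params` object.
#' @export
evolution_params <- function(lambda1 = 3.5, lambda2 = 1, alpha = 1, mu = 10,
                             beta = 1, eps = 1.5, sigma = 1.5,
                             edge_scale = 255, csi_sigma = 1, dt = NULL,
                             max_iterations = 1500L, tolerance = 1e-4,
                             checkpoint_stride = 20L, snapshot_stride = 200L,
                             reinit_every = 5L) {
  p <- list(lambda1 = lambda1, lambda2 = lambda2, alpha = alpha, mu = mu,
            beta = beta, eps = eps, sigma = sigma, edge_scale = edge_scale,
            csi_sigma = csi_sigma, dt = dt,
            max_iterations = as.integer(max_iterations),
            tolerance = tolerance,
            checkpoint_stride = as.integer(checkpoint_stride),
            snapshot_stride = as.integer(snapshot_stride),
            reinit_every = as.integer(reinit_every))
  if (p$lambda1 < 0 || p$lambda2 < 0)
    stop_osg("lambda1 and lambda2 must be nonnegative", "osg_param_error")
  if (p$alpha <= 0 || p$beta <= 0)
    stop_osg("alpha and beta must be positive", "osg_param_error")
  check_eps(p$eps)
  if (p$max_iterations < 1L)
    stop_osg("max_iterations must be >= 1", "osg_param_error")
  if (!is.null(p$dt) && p$dt <= 0)
    stop_osg("dt must be positive", "osg_param_error")
  if (p$tolerance < 0)
    stop_osg("tolerance must be nonnegative", "osg_param_error")
  if (p$checkpoint_stride < 1L)
    stop_osg("checkpoint_stride must be >= 1", "osg_param_error")
  structure(p, class = "evolution_params")
}

#' Parameters for the Chan-Vese baseline
#'
#' @param mu_cv length weight (>= 0).  Note the scale: with intensities
#'   normalized to `[0, 1]` the data forces are O(0.1), so useful length
#'   weights are O(0.01-0.1).
#' @param v area weight (any sign; positive shrinks).  May also be a matrix
#'   for a spatially weighted area force.
#' @param lambda1,lambda2 region weights (>= 0).
#' @inheritParams evolution_params
#' @return a `cv_params` object.
#' @export
cv_params <- function(mu_cv = 0.02, v = 0, lambda1 = 1, lambda2 = 1,
                      eps = 1.5, dt = NULL, max_iterations = 1500L,
                      tolerance = 1e-4, checkpoint_stride = 20L,
                      snapshot_stride = 200L, reinit_every = 5L) {
  p <- list(mu_cv = mu_cv, v = v, lambda1 = lambda1, lambda2 = lambda2,
            eps = eps, dt = dt, max_iterations = as.integer(max_iterations),
            tolerance = tolerance,
            checkpoint_stride = as.integer(checkpoint_stride),
            snapshot_stride = as.integer(snapshot_stride),
            reinit_every = as.integer(reinit_every))
  if (p$mu_cv < 0) stop_osg("mu_cv must be nonnegative", "osg_param_error")
  if (p$lambda1 < 0 || p$lambda2 < 0)
    stop_osg("lambda1 and lambda2 must be nonnegative", "osg_param_error")
  check_eps(p$eps)
  structure(p, class = "cv_params")
}

#' Parameters for the CPLSE baseline
#'
#' Distance-regularized convexity-preserving evolution: DRLSE's double-well
#' regularizer plus edge-weighted length and area forces, both gated by the
#' curvature-sign indicator, plus the concavity-repair curvature force.
#' Canonical DRLSE defaults for an initial contour placed well away from
#' the object (the situation after rectangle initialization): `dt = 5`,
#' `mu_reg = 0.04` (keeping `dt * mu_reg < 1/4`, the stability bound of the
#' double-well diffusion), `lambda_len = 5`, `alpha_area = 3` (positive
#' shrinks an inside-negative contour).  The front speed of this model is
#' limited by how fast the regularizer rebuilds the distance profile ahead
#' of the front, i.e. by `mu_reg * dt`, so the large-step small-`mu_reg`
#' regime travels markedly faster at equal stability.
#'
#' @param mu_reg distance-regularization weight (> 0).
#' @param lambda_len weighted-length coefficient.
#' @param alpha_area weighted-area coefficient.
#' @inheritParams evolution_params
#' @return a `cplse_params` object.
#' @export
cplse_params <- function(mu_reg = 0.04, lambda_len = 5, alpha_area = 3,
                         eps = 1.5, sigma = 1.5, edge_scale = 255,
                         csi_sigma = 1, dt = 5, max_iterations = 1500L,
                         tolerance = 1e-4, checkpoint_stride = 20L,
                         snapshot_stride = 200L) {
  p <- list(mu_reg = mu_reg, lambda_len = lambda_len,
            alpha_area = alpha_area, eps = eps, sigma = sigma,
            edge_scale = edge_scale, csi_sigma = csi_sigma, dt = dt,
            max_iterations = as.integer(max_iterations),
            tolerance = tolerance,
            checkpoint_stride = as.integer(checkpoint_stride),
            snapshot_stride = as.integer(snapshot_stride))
  if (p$mu_reg <= 0) stop_osg("mu_reg must be positive", "osg_param_error")
  if (p$dt * p$mu_reg >= 0.25)
    stop_osg("dt * mu_reg must be < 1/4 for the double-well diffusion",
             "osg_param_error")
  check_eps(p$eps)
  structure(p, class = "cplse_params")
}

#' Double-well distance-regularization factor
#'
#' `dp(s) = p'(s)/s` for the DRLSE double-well potential
#' \deqn{p(s) = \frac{1}{(2\pi)^2}(1 - \cos 2\pi s) \ (s \le 1), \qquad
#'   p(s) = \tfrac12 (s-1)^2 \ (s > 1),}
#' i.e. `sin(2 pi s)/(2 pi s)` for `s <= 1` and `(s - 1)/s` for `s > 1`;
#' continuous at `s = 1` (both branches vanish) with limit 1 as `s -> 0`
#' (returned at `s = 0`).
#'
#' @param s nonnegative gradient magnitude (vector or matrix).
#' @return same shape as `s`.
#' @export
drlse_dp <- function(s) {
  if (any(s < 0)) stop_osg("`s` must be nonnegative", "osg_contract_error")
  out <- s
  lo <- s < 1          # s = 1 uses the upper branch: (s-1)/s is exactly 0
  sl <- s[lo]
  out[lo] <- ifelse(sl == 0, 1, sin(2 * pi * sl) / (2 * pi * sl))
  sh <- s[!lo]
  out[!lo] <- (sh - 1) / sh
  out
}

#' CFL-limited time step
#'
#' Returns the explicit time step satisfying both the advective bound
#' `dt * max|R| <= 0.5` px per step and the parabolic bound
#' `dt * alpha <= 0.25` at unit spacing; the stricter bound wins.  With a
#' zero speed field only the parabolic bound applies.
#'
#' @param params an `evolution_params` / `cv_params` / `cplse_params` object,
#'   or directly the diffusive (length-term) coefficient as a scalar.
#' @param max_speed maximum absolute per-pixel value of a trial right-hand
#'   side evaluation.
#' @return time step `dt`.
#' @export
suggest_time_step <- function(params, max_speed) {
  alpha <- if (is.numeric(params)) params
  else if (inherits(params, "cv_params")) max(params$mu_cv, 1e-8)
  else if (inherits(params, "cplse_params")) max(params$lambda_len, 1e-8)
  else params$alpha
  parabolic <- 0.25 / alpha
  if (!is.finite(max_speed) || max_speed <= 0) return(parabolic)
  min(0.5 / max_speed, parabolic)
}

#' Right-hand side of the convexity-preserving evolution
#'
#' Per-pixel update field
#' `delta_eps(phi) * (s * (lambda1 (I-c1)^2 - lambda2 (I-c2)^2) +
#'  alpha * kappa + mu * g + beta * (1-s) * kappa)`.
#' Where the contour is locally convex (`s = 1`) the data-driven force
#' dominates; where it turns concave (`s = 0`) the data force is switched
#' off and the curvature force pulls the contour back toward convexity.
#'
#' @param phi level-set field.
#' @param grid [image_grid()].
#' @param stats `region_stats` from [compute_region_means()] on the current
#'   `phi`.
#' @param edges edge-indicator matrix from [edge_indicator()].
#' @param curv `curvature_field` from [compute_curvature()] on the current
#'   `phi`.
#' @param params [evolution_params()].
#' @return update matrix, zero outside the `eps` band.
#' @export
proposed_rhs <- function(phi, grid, stats, edges, curv, params) {
  grid <- as_image_grid(grid)
  check_levelset(phi, grid)
  if (!identical(dim(edges), dim(phi)) || !identical(dim(curv$kappa), dim(phi)))
    stop_osg("field shapes do not match", "osg_contract_error")
  I <- grid$intensities
  data_term <- params$lambda1 * (I - stats$c1)^2 -
    params$lambda2 * (I - stats$c2)^2
  d <- smoothed_dirac(phi, params$eps)
  d * (curv$s * data_term + params$alpha * curv$kappa +
         params$mu * edges + params$beta * (1 - curv$s) * curv$kappa)
}

#' Right-hand side of the Chan-Vese gradient flow
#'
#' Under the inside-negative convention the descent direction of the
#' Chan-Vese energy is
#' `delta_eps(phi) * (mu_cv * kappa + v + lambda1 (I-c1)^2 -
#'  lambda2 (I-c2)^2)`; `v` may be a matrix for a spatially weighted area
#' force.
#'
#' @inheritParams proposed_rhs
#' @param params [cv_params()].
#' @export
cv_rhs <- function(phi, grid, stats, params) {
  grid <- as_image_grid(grid)
  check_levelset(phi, grid)
  I <- grid$intensities
  kappa <- cpp_curvature(phi, 1e-8)
  d <- smoothed_dirac(phi, params$eps)
  d * (params$mu_cv * kappa + params$v +
         params$lambda1 * (I - stats$c1)^2 -
         params$lambda2 * (I - stats$c2)^2)
}

#' Right-hand side of the CPLSE evolution
#'
#' `mu_reg * div(dp(|grad phi|) grad phi) + s * (lambda_len * delta *
#'  div(g grad phi/|grad phi|) + alpha_area * g * delta) + (1-s) * kappa *
#'  delta`.
#'
#' @inheritParams proposed_rhs
#' @param params [cplse_params()].
#' @export
cplse_rhs <- function(phi, grid, edges, curv, params) {
  grid <- as_image_grid(grid)
  check_levelset(phi, grid)
  gr <- cpp_grad(phi)
  nrm <- sqrt(gr$gx^2 + gr$gy^2)
  dp <- drlse_dp(nrm)
  reg <- params$mu_reg * cpp_divergence(dp * gr$gx, dp * gr$gy)
  nrm_f <- pmax(nrm, 1e-8)
  len <- cpp_divergence(edges * gr$gx / nrm_f, edges * gr$gy / nrm_f)
  d <- smoothed_dirac(phi, params$eps)
  reg + curv$s * (params$lambda_len * d * len + params$alpha_area * edges * d) +
    (1 - curv$s) * curv$kappa * d
}

# Shared explicit time-stepping loop.  `rhs_fun(phi)` returns the update
# field for the current phi.
evolve_loop <- function(phi0, grid, params, rhs_fun, model) {
  check_levelset(phi0, grid)
  if (all(phi0 >= 0) || all(phi0 <= 0))
    stop_osg("initial level-set field must have both signs", "osg_param_error")
  phi <- phi0
  dt <- params$dt
  if (is.null(dt)) {
    trial <- rhs_fun(phi)
    dt <- suggest_time_step(params, max(abs(trial)))
  }
  snapshots <- list()
  prev <- phi
  reason <- "budget"
  iters <- params$max_iterations
  for (k in seq_len(params$max_iterations)) {
    r <- rhs_fun(phi)
    phi <- phi + dt * r
    if (!all(is.finite(phi)))
      stop_osg(sprintf("numerical instability: non-finite phi at iteration %d (reduce dt)", k),
               "osg_numeric_error")
    if (!is.null(params$reinit_every) && params$reinit_every > 0L &&
        k %% params$reinit_every == 0L)
      phi <- redistance(phi, sweeps = 5L)
    if (all(phi > 0) || all(phi < 0)) {
      reason <- "contour_vanished"
      iters <- k
      break
    }
    if (params$snapshot_stride > 0L && k %% params$snapshot_stride == 0L)
      snapshots[[as.character(k)]] <- phi < 0
    if (k %% params$checkpoint_stride == 0L) {
      band <- abs(phi) <= params$eps
      if (any(band)) {
        change <- mean(abs(phi - prev)[band]) / params$checkpoint_stride
        if (change < params$tolerance) {
          reason <- "converged"
          iters <- k
          break
        }
      }
      prev <- phi
    }
  }
  structure(list(phi = phi, mask = phi < 0, iterations = iters,
                 reason = reason, dt = dt, model = model,
                 snapshots = snapshots, params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> model=%s, %d iterations (%s), dt=%.4g, inside area=%d px\n",
              x$model, x$iterations, x$reason, x$dt, sum(x$mask)))
  invisible(x)
}

#' Run the convexity-preserving evolution
#'
#' Explicit iteration `phi_{k+1} = phi_k + dt * R(phi_k)` of the proposed
#' model, refreshing the region means and the curvature/CSI fields every
#' iteration.  Stops on the iteration budget, on contour vanishing (all of
#' `phi` one sign; reported as a termination reason, not an error), or when
#' the mean absolute per-iteration change of `phi` within the contour band
#' falls below `tolerance`.
#'
#' @param phi0 initial level-set field (inside-negative; both signs present).
#'   Typically from [rectangle_to_levelset()] or [auto_initialize()].
#' @param grid [image_grid()].
#' @param params [evolution_params()].
#' @return a `segmentation_result`: final `phi`, binary `mask`
#'   (`phi < 0`), `iterations`, termination `reason`
#'   (`converged` / `budget` / `contour_vanished`), `dt`, contour
#'   `snapshots`.
#' @export
evolve_proposed <- function(phi0, grid, params = evolution_params()) {
  grid <- as_image_grid(grid)
  g <- edge_indicator(grid, params$sigma, params$edge_scale)
  I <- grid$intensities
  rhs <- function(phi) {
    rm <- cpp_region_means(I, phi, params$eps)
    if (rm[3] < 1e-12 || rm[4] < 1e-12)
      stop_osg("degenerate region: the contour has collapsed or filled the image",
               "osg_degenerate_region")
    cpp_proposed_step(phi, I, g, rm[1], rm[2], params$lambda1,
                      params$lambda2, params$alpha, params$mu, params$beta,
                      params$eps, params$csi_sigma)
  }
  evolve_loop(phi0, grid, params, rhs, "proposed")
}

#' Run the Chan-Vese evolution
#'
#' @inheritParams evolve_proposed
#' @param params [cv_params()].
#' @export
cv_evolve <- function(phi0, grid, params = cv_params()) {
  grid <- as_image_grid(grid)
  I <- grid$intensities
  vmat <- if (is.matrix(params$v)) params$v
  else matrix(params$v, grid$height, grid$width)
  rhs <- function(phi) {
    rm <- cpp_region_means(I, phi, params$eps)
    if (rm[3] < 1e-12 || rm[4] < 1e-12)
      stop_osg("degenerate region: the contour has collapsed or filled the image",
               "osg_degenerate_region")
    cpp_cv_step(phi, I, vmat, rm[1], rm[2], params$lambda1, params$lambda2,
                params$mu_cv, params$eps)
  }
  evolve_loop(phi0, grid, params, rhs, "cv")
}

#' Run the CPLSE evolution
#'
#' @inheritParams evolve_proposed
#' @param params [cplse_params()].
#' @export
cplse_evolve <- function(phi0, grid, params = cplse_params()) {
  grid <- as_image_grid(grid)
  g <- edge_indicator(grid, params$sigma, params$edge_scale)
  rhs <- function(phi) {
    cpp_cplse_step(phi, g, params$mu_reg, params$lambda_len,
                   params$alpha_area, params$eps, params$csi_sigma)
  }
  evolve_loop(phi0, grid, params, rhs, "cplse")
}

#' Sign-preserving redistancing
#'
#' A few explicit Godunov-upwind sweeps of
#' `phi_tau = sign(phi) (1 - |grad phi|)` that nudge `phi` back toward a
#' signed distance function without moving the zero level set appreciably.
#' The proposed and Chan-Vese evolutions apply this periodically
#' (`reinit_every`): their smoothed Dirac is compactly supported, so without
#' redistancing no force reaches pixels with `|phi| > eps` and the contour
#' would stall after about `eps` px of travel.
#'
#' @param phi level-set field.
#' @param sweeps number of pseudo-time steps.
#' @param dtau pseudo time step (stability requires `< 0.5`).
#' @return redistanced field.
#' @export
redistance <- function(phi, sweeps = 5L, dtau = 0.3) {
  check_levelset(phi)
  cpp_redistance(phi, as.integer(sweeps), dtau)
}
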