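# Quasi-potential landscape estimation for 2D vector fields: the potential
# is accumulated along deterministic trajectories (dU/dt = -|f|^2, so U is
# non-increasing and stationary exactly at fixed points), curves are
# aligned within and across basins, and the surface interpolated from all
# trajectory points.

#' Quasi-potential along a single trajectory
#'
#' Integrates the model together with the potential accumulator
#' `dU/dt = -[(dx1/dt)^2 + (dx2/dt)^2]`, starting from `U = 0` (the offset
#' is arbitrary).  `U` is non-increasing and converges to a constant as the
#' trajectory reaches an attractor.
#'
#' @param model `"toggle_input"` (states `Ra`, `Pa`; `input` is the
#'   constant `LRa`) or `"gradient"` (the analytic gradient test field).
#' @param params matching parameter object (`toggle_params`, or numeric
#'   `c(a, b, c)` for the gradient field `U = a (x^2-1)^2 + b y^2 + c x y`).
#' @param init numeric length-2 initial state.
#' @param input constant input value.
#' @param horizon integration horizon in model time units.
#' @param n_out number of output samples.
#' @param rtol,atol integrator tolerances.
#' @return Data frame `time`, the two states, `U`.
#' @export
trajectory_potential <- function(model = c("toggle_input", "gradient"),
                                 params, init, input = 0, horizon = 2e4,
                                 n_out = 400, rtol = 1e-10, atol = 1e-12) {
  model <- match.arg(model)
  pv <- if (model == "gradient") as.numeric(params)
        else as_param_vector(params)
  # geometric-ish output grid: dense early where the potential drops fast
  ts <- unique(c(0, exp(seq(log(horizon * 1e-5), log(horizon),
                            length.out = n_out - 1))))
  st <- .ode_drive_cpp(model_id(model), pv, as.numeric(init),
                       horizon, input, ts, rtol, atol, 2L)
  nm <- model_state_names(model)
  out <- data.frame(time = ts, st)
  names(out) <- c("time", nm, "U")
  out
}

model_fixed_points_2d <- function(model, params, input = 0) {
  if (model == "toggle_input") {
    fp <- toggle_fixed_points(params, LRa = input)
    list(points = cbind(fp$Ra, fp$Pa), stability = fp$stability)
  } else { # gradient field: Newton from a coarse grid of starts
    pv <- as.numeric(params)
    f <- function(y) .model_rhs_cpp(4L, pv, y, 0)
    starts <- as.matrix(expand.grid(seq(-1.5, 1.5, length.out = 7),
                                    seq(-1.5, 1.5, length.out = 7)))
    sols <- NULL
    for (i in seq_len(nrow(starts))) {
      y <- starts[i, ]
      ok <- TRUE
      for (it in 1:50) {
        r <- f(y)
        if (max(abs(r)) < 1e-12) break
        J <- numeric_jacobian(f, y)
        dy <- tryCatch(solve(J, r), error = function(e) NULL)
        if (is.null(dy)) { ok <- FALSE; break }
        y <- y - dy
      }
      if (ok && max(abs(f(y))) < 1e-10) sols <- rbind(sols, y)
    }
    sols <- unique(round(sols, 8))
    stab <- apply(sols, 1, function(y)
      classify_stability(eigen(numeric_jacobian(f, y))$values))
    list(points = sols, stability = stab)
  }
}

#' Assemble a quasi-potential landscape
#'
#' Integrates trajectories from a grid of initial conditions, classifies
#' each by the attractor it reaches, and assembles a global landscape:
#' (i) within a basin, curves are aligned at the common attractor level;
#' (ii) across basins, levels are estimated from separatrix pairs --
#' neighbouring initial conditions whose trajectories reach different
#' attractors -- each pair weighted by `(1 - cos(theta))/2` of the angle
#' between the pair's initial velocities, which concentrates weight on
#' pairs straddling the saddle; (iii) the basin levels solve the weighted
#' least-squares alignment over all pairs; (iv) the surface is
#' interpolated from all aligned trajectory points by local weighted
#' linear fits.
#'
#' @inheritParams trajectory_potential
#' @param n_grid grid resolution of initial conditions per axis; the
#'   surface is reported on the same grid (each node carries the exact
#'   aligned potential of the trajectory started there, which is the
#'   scattered interpolation evaluated at the trajectory initial points).
#' @param lims domain limits `c(x_min, x_max, y_min, y_max)`.
#' @param horizon integration horizon (model time units); trajectories
#'   whose terminal speed exceeds `speed_tol` are flagged.
#' @param speed_tol terminal-speed threshold for convergence.
#' @param match_tol attractor matching distance.
#' @return A `ghost_landscape`: list with `x`, `y`, `U` (matrix),
#'   `attractors`, `levels`, `trajectories` (aligned point cloud),
#'   `n_unclassified`.
#' @export
assemble_landscape <- function(model = c("toggle_input", "gradient"),
                               params, input = 0, n_grid = 40,
                               lims = c(0, 1, 0, 1),
                               horizon = 2e4, speed_tol = 1e-8,
                               match_tol = 1e-4, n_out = 300) {
  model <- match.arg(model)
  fps <- model_fixed_points_2d(model, params, input)
  att <- fps$points[fps$stability == "stable", , drop = FALSE]
  gx <- seq(lims[1], lims[2], length.out = n_grid)
  gy <- seq(lims[3], lims[4], length.out = n_grid)
  ics <- as.matrix(expand.grid(x = gx, y = gy))
  pv <- if (model == "gradient") as.numeric(params)
        else as_param_vector(params)
  f0 <- function(y) .model_rhs_cpp(model_id(model), pv, y, input)

  basin <- integer(nrow(ics))
  curves <- vector("list", nrow(ics))
  u0 <- numeric(nrow(ics))      # aligned potential at the initial point
  v0 <- matrix(0, nrow(ics), 2) # initial velocity
  n_uncl <- 0
  for (i in seq_len(nrow(ics))) {
    tp <- trajectory_potential(model, params, ics[i, ], input, horizon,
                               n_out = n_out)
    term <- as.numeric(tp[nrow(tp), 2:3])
    speed <- sqrt(sum(f0(term)^2))
    d <- sqrt(colSums((t(att) - term)^2))
    # a trajectory must actually reach a stable attractor; separatrix
    # points converge to the saddle (small terminal speed but far from
    # every attractor) and are excluded along with unconverged runs
    if (min(d) > match_tol || speed > max(speed_tol, 1e-6)) {
      basin[i] <- NA
      n_uncl <- n_uncl + 1
      next
    }
    basin[i] <- which.min(d)
    # align the curve so the attractor sits at (basin level) + 0
    tp$U <- tp$U - tp$U[nrow(tp)]
    curves[[i]] <- tp
    u0[i] <- tp$U[1]
    v0[i, ] <- f0(ics[i, ])
  }
  if (n_uncl > 0)
    warning(n_uncl, " trajectories did not reach an attractor and were ",
            "excluded")

  nb <- nrow(att)
  levels <- numeric(nb)
  if (nb > 1) {
    # separatrix pairs: neighbouring grid nodes with different basins;
    # when the node in between was excluded (e.g. it sat exactly on the
    # separatrix) the next classified node in the same direction is used
    idx <- function(ix, iy) (iy - 1) * n_grid + ix
    pairs <- NULL
    for (iy in seq_len(n_grid)) for (ix in seq_len(n_grid)) {
      i <- idx(ix, iy)
      if (is.na(basin[i])) next
      for (dir in list(c(1, 0), c(0, 1))) {
        for (step in 1:2) {
          jx <- ix + dir[1] * step; jy <- iy + dir[2] * step
          if (jx > n_grid || jy > n_grid) break
          j <- idx(jx, jy)
          if (is.na(basin[j])) next
          if (basin[i] != basin[j]) pairs <- rbind(pairs, c(i, j))
          break # nearest classified node in this direction found
        }
      }
    }
    if (is.null(pairs))
      warning("no separatrix pairs found; basin levels left at 0")
    else {
      ct <- function(i, j) {
        a <- v0[i, ]; b <- v0[j, ]
        na <- sqrt(sum(a^2)); nbn <- sqrt(sum(b^2))
        if (na == 0 || nbn == 0) return(0)
        sum(a * b) / (na * nbn)
      }
      w <- apply(pairs, 1, function(p) 0.5 * (1 - ct(p[1], p[2])))
      # weighted least squares for levels L_b, L_1 = 0:
      # L_{b(i)} + u0_i = L_{b(j)} + u0_j
      A <- matrix(0, nrow(pairs), nb)
      rhs <- numeric(nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        i <- pairs[k, 1]; j <- pairs[k, 2]
        A[k, basin[i]] <- A[k, basin[i]] + 1
        A[k, basin[j]] <- A[k, basin[j]] - 1
        rhs[k] <- u0[j] - u0[i]
      }
      A <- A[, -1, drop = FALSE] # gauge: level of basin 1 fixed to 0
      W <- sqrt(w)
      fit <- tryCatch(qr.solve(A * W, rhs * W), error = function(e) NULL)
      if (!is.null(fit)) levels[-1] <- fit
    }
  }

  pts <- do.call(rbind, lapply(which(!is.na(basin)), function(i) {
    tp <- curves[[i]]
    cbind(tp[[2]], tp[[3]], tp$U + levels[basin[i]])
  }))
  # the grid nodes are trajectory initial points, so the interpolated
  # surface at the nodes is their exact aligned potential
  U <- matrix(NA_real_, n_grid, n_grid)
  U[cbind((seq_len(nrow(ics)) - 1) %% n_grid + 1,
          (seq_len(nrow(ics)) - 1) %/% n_grid + 1)] <-
    ifelse(is.na(basin), NA_real_, u0 + levels[ifelse(is.na(basin), 1,
                                                      basin)])
  structure(list(x = gx, y = gy, U = U, attractors = att,
                 levels = levels, basin = basin, trajectories = pts,
                 n_unclassified = n_uncl, model = model),
            class = "ghost_landscape")
}

# Local weighted linear interpolation of scattered (x, y, value) points
# onto a regular grid: for each node, the k nearest points (found through
# a coarse spatial bin) enter a Gaussian-weighted plane fit.  Trajectory
# clouds are strongly anisotropic (points concentrate along flow lines),
# so the fitted value is clamped to the local value range to keep the
# plane from extrapolating across sparse directions.
interp_scattered <- function(pts, ox, oy, k = 36) {
  nx <- length(ox); ny <- length(oy)
  rx <- range(pts[, 1]); ry <- range(pts[, 2])
  nbin <- max(4, ceiling(sqrt(nrow(pts) / 50)))
  bx <- pmin(pmax(findInterval(pts[, 1], seq(rx[1], rx[2],
                                             length.out = nbin + 1),
                               all.inside = TRUE), 1), nbin)
  by <- pmin(pmax(findInterval(pts[, 2], seq(ry[1], ry[2],
                                             length.out = nbin + 1),
                               all.inside = TRUE), 1), nbin)
  bins <- split(seq_len(nrow(pts)), (by - 1) * nbin + bx)
  binkey <- function(ix, iy) as.character((iy - 1) * nbin + ix)
  U <- matrix(NA_real_, nx, ny)
  sx <- diff(rx) / nbin; sy <- diff(ry) / nbin
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    cx <- min(max(1 + floor((ox[i] - rx[1]) / sx), 1), nbin)
    cy <- min(max(1 + floor((oy[j] - ry[1]) / sy), 1), nbin)
    cand <- integer(0); ring <- 0
    while (length(cand) < k && ring <= nbin) {
      sel <- expand.grid(ix = max(1, cx - ring):min(nbin, cx + ring),
                         iy = max(1, cy - ring):min(nbin, cy + ring))
      cand <- unlist(bins[binkey(sel$ix, sel$iy)], use.names = FALSE)
      ring <- ring + 1
    }
    if (!length(cand)) next
    d2 <- (pts[cand, 1] - ox[i])^2 + (pts[cand, 2] - oy[j])^2
    ordk <- order(d2)[seq_len(min(k, length(cand)))]
    sel <- cand[ordk]
    h2 <- max(d2[ordk][length(ordk)], 1e-12)
    w <- sqrt(exp(-d2[ordk] / h2))
    dx <- pts[sel, 1] - ox[i]
    dy <- pts[sel, 2] - oy[j]
    X <- cbind(1, dx, dy)
    fit <- tryCatch(solve(crossprod(X * w),
                          crossprod(X * w, pts[sel, 3] * w)),
                    error = function(e) NULL)
    v <- if (is.null(fit)) sum(w^2 * pts[sel, 3]) / sum(w^2) else fit[1]
    U[i, j] <- min(max(v, min(pts[sel, 3])), max(pts[sel, 3]))
  }
  U
}

#' Wells (persistent local minima) of a landscape surface
#'
#' Local minima of the interpolated surface, filtered by topographic
#' persistence: sweeping the surface from low to high values with a
#' union-find merge, a minimum that joins a deeper basin before rising by
#' at least `min_persistence` above its own level is interpolation noise
#' and is absorbed into that basin.  The survivors are the genuine wells
#' (attractor basins).
#'
#' @param land a `ghost_landscape`.
#' @param min_persistence minimal barrier height separating distinct
#'   wells; default 0.1% of the surface range (the far-from-attractor
#'   potential dominates the range, so genuine inter-well barriers can be
#'   small on this scale).
#' @return Data frame `x`, `y`, `U`, `persistence` (Inf for the global
#'   minimum), ordered by `U`.
#' @export
landscape_minima <- function(land, min_persistence = NULL) {
  U <- land$U
  nx <- nrow(U); ny <- ncol(U)
  if (is.null(min_persistence))
    min_persistence <- 0.001 * diff(range(U, na.rm = TRUE))
  ord <- order(U, na.last = NA) # nodes by ascending level
  comp <- integer(nx * ny)      # 0 = not yet flooded
  root_min <- integer(0)        # component id -> node of its minimum
  died_at <- numeric(0)         # level at which a minimum was absorbed
  parent <- integer(0)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (node in ord) {
    i <- (node - 1) %% nx + 1
    j <- (node - 1) %/% nx + 1
    nb <- c(if (i > 1) node - 1, if (i < nx) node + 1,
            if (j > 1) node - nx, if (j < ny) node + nx,
            if (i > 1 && j > 1) node - nx - 1,
            if (i < nx && j > 1) node - nx + 1,
            if (i > 1 && j < ny) node + nx - 1,
            if (i < nx && j < ny) node + nx + 1)
    roots <- unique(vapply(nb[comp[nb] != 0], function(m) find(comp[m]),
                           1L))
    if (!length(roots)) { # a fresh local minimum
      id <- length(parent) + 1L
      parent[id] <- id
      root_min[id] <- node
      died_at[id] <- NA_real_
      comp[node] <- id
    } else {
      # attach to the deepest neighbouring basin; shallower basins that
      # meet here die (their persistence is fixed at this level)
      depth <- U[root_min[roots]]
      keep <- roots[which.min(depth)]
      comp[node] <- keep
      for (r in roots[roots != keep]) {
        died_at[r] <- U[node]
        parent[r] <- keep
      }
    }
  }
  lvl <- U[root_min]
  pers <- ifelse(is.na(died_at), Inf, died_at - lvl)
  sel <- which(pers >= min_persistence)
  ij <- root_min[sel]
  out <- data.frame(x = land$x[(ij - 1) %% nx + 1],
                    y = land$y[(ij - 1) %/% nx + 1],
                    U = U[ij], persistence = pers[sel])
  out[order(out$U), ]
}

#' @export
print.ghost_landscape <- function(x, ...) {
  cat(sprintf(
    "Quasi-potential landscape (%s): %d x %d surface, %d attractor(s)\n",
    x$model, length(x$x), length(x$y), nrow(x$attractors)))
  invisible(x)
}
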