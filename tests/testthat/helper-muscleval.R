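# Shared fixtures: load the packaged model once per test run.
the_model <- load_default_model()

# Named coordinate vector of zeros in chain order.
zero_coords <- function(model = the_model) {
  stats::setNames(numeric(nrow(model$coords)), model$coords$name)
}

# Rhythm-consistent coordinate map at a given elevation (deg).
rhythm_pose <- function(elv, model = the_model, ...) {
  q <- zero_coords(model)
  q["shoulder_elv"] <- elv
  for (cn in names(model$regression$rhythm)) {
    rc <- model$regression$rhythm[[cn]]
    q[cn] <- rc$intercept + rc$slope * elv
  }
  extra <- list(...)
  q[names(extra)] <- unlist(extra)
  q
}

# Small exercise profile for fast pipeline tests.
small_profile <- function(name, n_reps = 2, rep_duration = 2) {
  exercise_profile(name, n_sets = 1, n_reps = n_reps,
                   rep_duration = rep_duration, rest_duration = 0,
                   lead_in = 1.2)
}

# Exhaustive-grid oracle for the static-optimization box QP
#   min sum(a^2) + w ||M - A a||^2, 0 <= a <= 1   (step 0.001)
# Two muscles: full grid. Three muscles: box-walk lattice search (full
# 0.001-step search over a radius-0.04 box, re-centred on the incumbent
# until it stops moving), which converges to the lattice optimum of this
# convex objective. Returns the evaluated lattice points and objectives of
# the final (or full) grid so callers can also inspect the near-optimal set.
so_grid_oracle <- function(A, M, w = 1000, step = 0.001) {
  nm <- ncol(A)
  obj_of <- function(gg) {
    rowSums(gg^2) + w * rowSums((gg %*% t(A) -
                                   matrix(M, nrow(gg), length(M),
                                          byrow = TRUE))^2)
  }
  if (nm == 2) {
    g <- seq(0, 1, by = step)
    gg <- as.matrix(expand.grid(g, g))
    obj <- obj_of(gg)
    i <- which.min(obj)
    return(list(best = gg[i, ], obj = obj, points = gg, obj_min = obj[i], M = M))
  }
  # 3 muscles: walk
  g <- seq(0, 1, by = 0.01)
  gg <- as.matrix(expand.grid(g, g, g))
  best <- gg[which.min(obj_of(gg)), ]
  repeat {
    rng <- lapply(best, function(b) {
      lo <- max(0, b - 0.04); hi <- min(1, b + 0.04)
      seq(lo, hi, by = step)
    })
    gg <- as.matrix(expand.grid(rng))
    obj <- obj_of(gg)
    i <- which.min(obj)
    nb <- gg[i, ]
    if (max(abs(nb - best)) < step / 2) {
      return(list(best = nb, obj = obj, points = gg, obj_min = obj[i], M = M))
    }
    best <- nb
  }
}

# Activation-space agreement with the exhaustive lattice: the smallest
# max-abs distance from `a` to a lattice point whose objective lies within
# the curvature-implied band of the global lattice minimum (largest Hessian
# eigenvalue x 3/4 step^2 -- the provable gap of the lattice point nearest
# any continuous point). Evaluated on the lattice restricted to a small box
# around `a`; returns Inf when no qualifying point exists there.
so_grid_near_dist <- function(oracle, a, A, w = 1000, step = 0.001,
                              radius = 0.005) {
  lam_max <- 2 + 2 * w * max(eigen(crossprod(A), symmetric = TRUE,
                                   only.values = TRUE)$values)
  eps <- lam_max * 3 * step^2 / 4
  rng <- lapply(a, function(ai) {
    ctr <- round(ai / step) * step
    pmin(pmax(seq(ctr - radius, ctr + radius, by = step), 0), 1)
  })
  gg <- as.matrix(expand.grid(rng))
  obj <- rowSums(gg^2) + w * rowSums((gg %*% t(A) -
                                        matrix(oracle$M, nrow(gg),
                                               length(oracle$M),
                                               byrow = TRUE))^2)
  ok <- obj <= oracle$obj_min + eps
  if (!any(ok)) return(Inf)
  dev <- abs(gg[ok, , drop = FALSE] -
               matrix(a, sum(ok), length(a), byrow = TRUE))
  min(apply(dev, 1, max))
}

# Random small static-optimization instance in the solver's native units.
so_random_instance <- function(nm, nc) {
  arms <- matrix(stats::runif(nm * nc, -0.03, 0.05), nm, nc,
                 dimnames = list(paste0("M", 1:nm), paste0("q", 1:nc)))
  fmax <- stats::setNames(stats::runif(nm, 50, 500), paste0("M", 1:nm))
  M <- stats::setNames(stats::runif(nc, -2, 6), paste0("q", 1:nc))
  geo <- list(state = tibble::tibble(muscle = rownames(arms), length = 1,
                                     fiber = 1, lnorm = 1, f_L = 1,
                                     flagged = FALSE),
              moment_arms = arms)
  mdl <- list(muscles = tibble::tibble(name = names(fmax),
                                       f_max_iso = unname(fmax),
                                       alpha_penn = 0))
  list(arms = arms, fmax = fmax, M = M, geo = geo, mdl = mdl,
       A = t(arms * fmax))
}

# Zero-rhythm regression (constant scapula/clavicle) used where exactness
# against forward kinematics is asserted.
flat_rhythm <- function(model = the_model) {
  regression_coefficients(
    model,
    rhythm = lapply(model$regression$rhythm, function(x)
      list(slope = 0, intercept = 0)))
}
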