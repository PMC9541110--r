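#' Load the default shoulder-elbow musculoskeletal model
#'
#' Builds the generic model used throughout the pipeline: a tree-structured
#' kinematic chain (fixed thorax root, prescribed clavicle and scapula,
#' 3-coordinate glenohumeral joint, elbow flexion, forearm pronation, rigid
#' wrist), the 33-entry muscle parameter registry (maximum isometric force,
#' optimal fiber length, tendon slack length, pennation angle), straight-line
#' muscle path geometry, segment inertia defaults, and the virtual-marker maps
#' for the dense marker stream and the sparse camera joint-centre stream.
#'
#' At load, each muscle's final path point is slid along its last path leg so
#' that the neutral-pose musculotendon length equals
#' `l_ts + l_opt * cos(alpha_penn)`, i.e. fibers sit at optimal length in the
#' neutral pose (`calibrate = TRUE`). The shipped path anchors are editable
#' plausible offsets, not a published geometry.
#'
#' @param asset path to a model asset JSON file; `NULL` uses the packaged
#'   default.
#' @param calibrate logical; calibrate neutral musculotendon lengths to
#'   `l_ts + l_opt * cos(alpha)`.
#' @return an object of class `msk_model`: a list with elements `muscles`
#'   (tibble), `coords` (tibble of generalized coordinates), `joints`,
#'   `geometry`, `inertia` (tibble), `virtual_markers`, `regression`,
#'   `scale_pairs`, `report_groups` and a precompiled kinematic core.
#' @examples
#' model <- load_default_model()
#' dplyr::filter(model$muscles, name == "Deltoideus middle")
#' @export
load_default_model <- function(asset = NULL, calibrate = TRUE) {
  if (is.null(asset)) {
    asset <- system.file("extdata", "default_model.json", package = "muscleval")
  }
  if (!nzchar(asset) || !file.exists(asset)) {
    stop("model asset not found: ", asset %||% "<packaged default_model.json>")
  }
  def <- tryCatch(
    jsonlite::read_json(asset, simplifyVector = FALSE),
    error = function(e) stop("corrupt model asset '", asset, "': ", conditionMessage(e))
  )
  for (key in c("joints", "muscles", "geometry", "inertia", "virtual_markers")) {
    if (is.null(def[[key]])) stop("model asset '", asset, "' is missing field '", key, "'")
  }
  model <- build_model(def)
  if (calibrate) model <- calibrate_muscle_lengths(model)
  model
}

# Assemble and validate an msk_model from a parsed asset definition.
build_model <- function(def) {
  muscles <- dplyr::bind_rows(lapply(def$muscles, function(m) {
    tibble::tibble(name = m$name, base = m$base, group = m$group,
                   f_max_iso = m$f_max_iso, l_opt = m$l_opt, l_ts = m$l_ts,
                   alpha_penn = m$alpha_penn, bundle_ids = m$bundle_ids)
  }))
  stopifnot(all(muscles$f_max_iso > 0), all(muscles$l_opt > 0),
            all(muscles$l_ts >= 0),
            all(muscles$alpha_penn >= 0 & muscles$alpha_penn < 90))
  if (anyDuplicated(muscles$name)) stop("duplicate muscle names in asset")

  joints <- lapply(def$joints, function(j) {
    list(name = j$name, parent = j$parent, child = j$child,
         offset = as.numeric(unlist(j$offset)),
         coords = lapply(j$coords, function(cc) {
           list(name = cc$name, axis = as.numeric(unlist(cc$axis)),
                range = as.numeric(unlist(cc$range)),
                prescribed = isTRUE(cc$prescribed))
         }))
  })
  segments <- vapply(joints, `[[`, "", "child")
  parents <- vapply(joints, `[[`, "", "parent")
  if (anyDuplicated(segments)) stop("chain is not a tree: a segment has two parents")
  if (!all(parents %in% c("ground", segments))) stop("chain parent refers to unknown segment")

  coords <- dplyr::bind_rows(lapply(joints, function(j) {
    if (!length(j$coords)) return(NULL)
    tibble::tibble(
      name = vapply(j$coords, `[[`, "", "name"),
      joint = j$name, segment = j$child,
      lo = vapply(j$coords, function(cc) cc$range[1], 0),
      hi = vapply(j$coords, function(cc) cc$range[2], 0),
      prescribed = vapply(j$coords, `[[`, TRUE, "prescribed"))
  }))
  if (anyDuplicated(coords$name)) stop("coordinate names are not unique")

  geometry <- stats::setNames(
    lapply(def$geometry, function(g) {
      path <- lapply(g$path, function(p)
        list(segment = p$segment, offset = as.numeric(unlist(p$offset))))
      list(muscle = g$muscle, path = path,
           spanned = as.character(unlist(g$spanned)))
    }),
    vapply(def$geometry, `[[`, "", "muscle"))
  missing_geom <- setdiff(muscles$name, names(geometry))
  if (length(missing_geom)) stop("muscles without geometry: ",
                                 paste(missing_geom, collapse = ", "))
  for (g in geometry) {
    if (length(g$path) < 2) stop("muscle '", g$muscle, "' needs >= 2 path points")
    if (g$path[[1]]$segment == g$path[[length(g$path)]]$segment)
      stop("muscle '", g$muscle, "' origin and insertion attach to one segment")
    bad <- setdiff(g$spanned, coords$name)
    if (length(bad)) stop("muscle '", g$muscle, "' spans unknown coordinate ", bad[1])
    segs <- vapply(g$path, `[[`, "", "segment")
    if (!all(segs %in% segments)) stop("muscle '", g$muscle, "' path on unknown segment")
  }

  inertia <- dplyr::bind_rows(lapply(def$inertia, function(i) {
    tibble::tibble(segment = i$segment, mass = i$mass,
                   com_x = i$com_offset[[1]], com_y = i$com_offset[[2]],
                   com_z = i$com_offset[[3]],
                   i_x = i$inertia_diag[[1]], i_y = i$inertia_diag[[2]],
                   i_z = i$inertia_diag[[3]])
  }))
  stopifnot(all(inertia$mass >= 0),
            all(inertia$i_x >= 0 & inertia$i_y >= 0 & inertia$i_z >= 0))

  vm <- lapply(def$virtual_markers, function(m)
    lapply(m, function(x) list(segment = x$segment,
                               offset = as.numeric(unlist(x$offset)))))
  required <- list(
    marker = c("Incisura Jugularis", "Processus Xiphoideus", "Cervical Vertebrae 7",
               "Thoracic Vertebrae 10", "Acromion", "Epicondylus Medialis",
               "Epicondylus Lateralis", "Upper arm", "Head of Ulna",
               "Styloid Radius", "Lower arm", "Hand"),
    camera = c("Mid Spine", "Mid Thorax", "Shoulder joint center",
               "Elbow joint center", "Wrist joint center"))
  for (kind in names(required)) {
    miss <- setdiff(required[[kind]], names(vm[[kind]]))
    if (length(miss)) stop("virtual marker map '", kind, "' lacks labels: ",
                           paste(miss, collapse = ", "))
  }

  model <- structure(list(
    name = def$name %||% "msk model",
    joints = joints, segments = segments, coords = coords,
    muscles = muscles, geometry = geometry, inertia = inertia,
    virtual_markers = vm,
    regression = def$regression,
    scale_pairs = def$scale_pairs,
    report_groups = def$report_groups,
    scale_set = NULL,
    definition = def
  ), class = "msk_model")
  model$core <- compile_core(model)
  # derive default shoulder-centre regression offset from the generic
  # geometry if the asset leaves it unset (see estimate_joint_centers)
  sco <- model$regression$shoulder_center_offset
  if (is.null(sco) || !length(sco)) {
    model$regression$shoulder_center_offset <- default_shoulder_regression(model)
  } else {
    model$regression$shoulder_center_offset <- as.numeric(unlist(sco))
  }
  rhy <- model$regression$rhythm
  if (!is.null(rhy)) {
    model$regression$rhythm <- lapply(rhy, function(x)
      list(slope = as.numeric(x$slope), intercept = as.numeric(x$intercept)))
  }
  model$regression$elevation_map <- elevation_coordinate_map(model)
  model
}

# Precompile the chain into index-based structures for fast FK.
compile_core <- function(model) {
  seg_index <- stats::setNames(seq_along(model$segments), model$segments)
  qnames <- model$coords$name
  joints <- lapply(model$joints, function(j) {
    list(child = seg_index[[j$child]],
         parent = if (j$parent == "ground") 0L else seg_index[[j$parent]],
         offset = j$offset,
         axes = lapply(j$coords, `[[`, "axis"),
         qi = match(vapply(j$coords, `[[`, "", "name"), qnames))
  })
  list(joints = joints, seg_index = seg_index, qnames = qnames,
       nseg = length(model$segments))
}

# Forward kinematics on the compiled core. q: radians, in core$qnames order.
# Returns list(R = list of 3x3, p = 3 x nseg matrix, axes = 3 x nq global
# coordinate axes, jpos = 3 x nq global joint positions) -- the last two only
# when want_axes = TRUE (used by inverse dynamics).
fk_core <- function(core, q, want_axes = FALSE) {
  nseg <- core$nseg
  Rs <- vector("list", nseg)
  ps <- matrix(0, 3, nseg)
  if (want_axes) {
    nq <- length(core$qnames)
    axes <- matrix(0, 3, nq)
    jpos <- matrix(0, 3, nq)
  }
  for (j in core$joints) {
    if (j$parent == 0L) { Rp <- diag(3); pp <- c(0, 0, 0) }
    else { Rp <- Rs[[j$parent]]; pp <- ps[, j$parent] }
    p <- pp + Rp %*% j$offset
    R <- Rp
    if (length(j$qi)) {
      for (k in seq_along(j$qi)) {
        if (want_axes) {
          axes[, j$qi[k]] <- R %*% j$axes[[k]]
          jpos[, j$qi[k]] <- p
        }
        R <- R %*% rot_axis(j$axes[[k]], q[j$qi[k]])
      }
    }
    Rs[[j$child]] <- R
    ps[, j$child] <- p
  }
  out <- list(R = Rs, p = ps)
  if (want_axes) { out$axes <- axes; out$jpos <- jpos }
  out
}

# named coordinate map (deg, possibly partial) -> radian vector in core order
coord_vector <- function(model, coords) {
  q <- stats::setNames(numeric(length(model$core$qnames)), model$core$qnames)
  if (length(coords)) {
    bad <- setdiff(names(coords), names(q))
    if (length(bad)) stop("unknown coordinate: ", paste(bad, collapse = ", "))
    q[names(coords)] <- as.numeric(coords)
  }
  deg2rad(q)
}

#' Forward kinematics of the kinematic chain
#'
#' Computes the global pose (position and orientation) of every segment at a
#' given set of generalized coordinate values.
#'
#' @param model an `msk_model`.
#' @param coords named numeric vector of coordinate values in degrees.
#'   Coordinates omitted from the map must be supplied; a missing coordinate
#'   is an error (all coordinates default to 0 only if `coords` is a complete
#'   map or `partial = TRUE`).
#' @param partial logical; allow unspecified coordinates to default to zero.
#' @return tibble with one row per segment: `segment`, global origin `x`,
#'   `y`, `z` (m) and a list-column `rotation` of 3x3 matrices.
#' @export
chain_forward_kinematics <- function(model, coords, partial = FALSE) {
  stopifnot(inherits(model, "msk_model"))
  if (!partial) {
    missing <- setdiff(model$core$qnames, names(coords))
    if (length(missing)) stop("missing coordinate value: ",
                              paste(missing, collapse = ", "))
  }
  qn <- intersect(names(coords), model$coords$name)
  rng <- model$coords[match(qn, model$coords$name), ]
  out_of_range <- coords[qn] < rng$lo - 1e-9 | coords[qn] > rng$hi + 1e-9
  if (any(out_of_range)) {
    warning("coordinate value outside range: ", paste(qn[out_of_range], collapse = ", "))
  }
  fk <- fk_core(model$core, coord_vector(model, coords))
  tibble::tibble(segment = model$segments,
                 x = fk$p[1, ], y = fk$p[2, ], z = fk$p[3, ],
                 rotation = fk$R)
}

# Global positions of a set of virtual markers for a given fk result.
marker_points_fk <- function(model, fk, labels, kind = "marker") {
  vm <- model$virtual_markers[[kind]]
  si <- model$core$seg_index
  out <- matrix(NA_real_, 3, length(labels))
  for (i in seq_along(labels)) {
    m <- vm[[labels[i]]]
    if (is.null(m)) stop("no virtual marker for label '", labels[i], "'")
    k <- si[[m$segment]]
    out[, i] <- fk$p[, k] + fk$R[[k]] %*% m$offset
  }
  colnames(out) <- labels
  out
}

#' Virtual-marker positions at a pose
#'
#' @param model an `msk_model`.
#' @param coords named coordinate values in degrees (partial maps allowed;
#'   unspecified coordinates are 0).
#' @param kind `"marker"` or `"camera"` stream label set, or `"centers"` for
#'   the three arm joint centres.
#' @param labels optional subset of labels.
#' @return tibble `label`, `x`, `y`, `z` (m).
#' @export
marker_positions <- function(model, coords = NULL, kind = "marker", labels = NULL) {
  labels <- labels %||% names(model$virtual_markers[[kind]])
  fk <- fk_core(model$core, coord_vector(model, coords))
  pts <- marker_points_fk(model, fk, labels, kind)
  tibble::tibble(label = labels, x = pts[1, ], y = pts[2, ], z = pts[3, ])
}

#' Summed maximum isometric force over the heads of a muscle
#'
#' Table-style report rows aggregate multi-head muscles (e.g. the rotator
#' cuff) by summing head forces; the matching %Fmax normalizer is the sum of
#' the heads' maximum isometric forces.
#'
#' @param model an `msk_model`.
#' @param muscle_base_name base muscle name, e.g. `"Infraspinatus"`, or a
#'   full head name.
#' @return total maximum isometric force in N.
#' @examples
#' model <- load_default_model()
#' group_f_max(model, "Infraspinatus") # 967.4 + 1037.4
#' @export
group_f_max <- function(model, muscle_base_name) {
  stopifnot(inherits(model, "msk_model"))
  hit <- model$muscles$base == muscle_base_name | model$muscles$name == muscle_base_name
  if (!any(hit)) {
    stop("unknown muscle base name '", muscle_base_name, "'; valid names: ",
         paste(unique(model$muscles$base), collapse = ", "))
  }
  sum(model$muscles$f_max_iso[hit])
}

# Slide each muscle's final path point along the last leg so the
# musculotendon length at a mid-range calibration pose equals
# l_ts + l_opt*cos(alpha), keeping fibers near optimal length over the
# exercise range. Calibration pose: 45 deg elevation (with rhythm),
# 60 deg elbow flexion.
calibrate_muscle_lengths <- function(model) {
  qn <- model$core$qnames
  qcal <- stats::setNames(numeric(length(qn)), qn)
  qcal["shoulder_elv"] <- deg2rad(45)
  qcal["shoulder_elv_plane"] <- deg2rad(15)
  qcal["elbow_flexion"] <- deg2rad(60)
  for (cn in names(model$regression$rhythm)) {
    rc <- model$regression$rhythm[[cn]]
    qcal[cn] <- deg2rad(rc$intercept + rc$slope * 45)
  }
  fk <- fk_core(model$core, qcal)
  si <- model$core$seg_index
  for (nm in names(model$geometry)) {
    g <- model$geometry[[nm]]
    mp <- model$muscles[model$muscles$name == nm, ]
    target <- mp$l_ts + mp$l_opt * cos(deg2rad(mp$alpha_penn))
    pts <- vapply(g$path, function(p) {
      k <- si[[p$segment]]
      as.numeric(fk$p[, k] + fk$R[[k]] %*% p$offset)
    }, numeric(3))
    legs <- sqrt(colSums((pts[, -1, drop = FALSE] - pts[, -ncol(pts), drop = FALSE])^2))
    L <- sum(legs)
    np <- length(g$path)
    # elbow-crossing muscles keep their distal lever: adjust the origin leg;
    # all others adjust the insertion leg
    move_first <- g$path[[np]]$segment == "forearm"
    if (move_first) {
      new_leg <- legs[1] + (target - L)
      if (new_leg < 0.005) {
        stop("cannot calibrate muscle '", nm, "': required origin path leg ",
             signif(new_leg, 3), " m is degenerate")
      }
      d <- (pts[, 1] - pts[, 2]) / legs[1]
      new_global <- pts[, 2] + d * new_leg
      k <- si[[g$path[[1]]$segment]]
      model$geometry[[nm]]$path[[1]]$offset <-
        as.numeric(t(fk$R[[k]]) %*% (new_global - fk$p[, k]))
    } else {
      new_leg <- legs[np - 1] + (target - L)
      if (new_leg < 0.005) {
        stop("cannot calibrate muscle '", nm, "': required last path leg ",
             signif(new_leg, 3), " m is degenerate")
      }
      d <- (pts[, np] - pts[, np - 1]) / legs[np - 1]
      new_global <- pts[, np - 1] + d * new_leg
      k <- si[[g$path[[np]]$segment]]
      model$geometry[[nm]]$path[[np]]$offset <-
        as.numeric(t(fk$R[[k]]) %*% (new_global - fk$p[, k]))
    }
  }
  model
}

#' Apply segment scale factors to a model
#'
#' Scales joint offsets (by the parent segment's factors, since they are
#' expressed in the parent frame), virtual-marker offsets, muscle path points
#' and centre-of-mass offsets (by their own segment's factors). Principal
#' inertia moments scale with the squared mean factor.
#'
#' @param model an `msk_model`.
#' @param scales a `scale_set` tibble (see [compute_scales()]) or a tibble
#'   with columns `segment`, `sx`, `sy`, `sz`.
#' @return a scaled `msk_model` with `scale_set` recorded.
#' @export
apply_scales <- function(model, scales) {
  stopifnot(inherits(model, "msk_model"))
  fac <- function(seg) {
    i <- match(seg, scales$segment)
    if (is.na(i)) c(1, 1, 1) else c(scales$sx[i], scales$sy[i], scales$sz[i])
  }
  for (j in seq_along(model$joints)) {
    p <- model$joints[[j]]$parent
    if (p != "ground") model$joints[[j]]$offset <- model$joints[[j]]$offset * fac(p)
  }
  for (kind in names(model$virtual_markers)) {
    for (lb in names(model$virtual_markers[[kind]])) {
      m <- model$virtual_markers[[kind]][[lb]]
      model$virtual_markers[[kind]][[lb]]$offset <- m$offset * fac(m$segment)
    }
  }
  for (nm in names(model$geometry)) {
    for (i in seq_along(model$geometry[[nm]]$path)) {
      p <- model$geometry[[nm]]$path[[i]]
      model$geometry[[nm]]$path[[i]]$offset <- p$offset * fac(p$segment)
    }
  }
  for (i in seq_len(nrow(model$inertia))) {
    f <- fac(model$inertia$segment[i])
    model$inertia$com_x[i] <- model$inertia$com_x[i] * f[1]
    model$inertia$com_y[i] <- model$inertia$com_y[i] * f[2]
    model$inertia$com_z[i] <- model$inertia$com_z[i] * f[3]
    s2 <- mean(f)^2
    model$inertia$i_x[i] <- model$inertia$i_x[i] * s2
    model$inertia$i_y[i] <- model$inertia$i_y[i] * s2
    model$inertia$i_z[i] <- model$inertia$i_z[i] * s2
  }
  model$core <- compile_core(model)
  model$scale_set <- scales
  model
}

#' Uniformly scale whole segments
#'
#' Convenience wrapper for subject generation: one scalar factor per segment.
#' @param model an `msk_model`.
#' @param factors named numeric vector, `segment -> factor`.
#' @return scaled `msk_model`.
#' @export
scale_segments <- function(model, factors) {
  scales <- tibble::tibble(segment = names(factors),
                           sx = unname(factors), sy = unname(factors),
                           sz = unname(factors))
  apply_scales(model, scales)
}

#' Serialize / reload a model asset
#'
#' `write_model()` writes the model's definition back to JSON;
#' `read_model()` is `load_default_model()` with a mandatory path. A
#' write-read round trip reproduces every registry value exactly.
#'
#' @param model an `msk_model`.
#' @param path file path.
#' @param calibrate see [load_default_model()].
#' @return `read_model()` returns an `msk_model`; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(model$definition, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path, calibrate = TRUE) {
  load_default_model(asset = path, calibrate = calibrate)
}

# Default shoulder-centre regression: an affine map from the acromion
# position (in the thorax frame reconstructed from the four thorax
# landmarks, relative to their centroid) to the acromion->glenohumeral
# offset. Calibrated on the generic model over the elevation range with the
# model's scapulohumeral rhythm, because the acromion-to-centre vector
# rotates with the scapula as the arm elevates.
default_shoulder_regression <- function(model, elevations = seq(0, 120, by = 5)) {
  qn <- model$core$qnames
  rhy <- model$regression$rhythm
  fk0 <- fk_core(model$core, numeric(length(qn)))
  th <- marker_points_fk(model, fk0,
                         c("Incisura Jugularis", "Cervical Vertebrae 7",
                           "Processus Xiphoideus", "Thoracic Vertebrae 10"),
                         "marker")
  Rth <- thorax_frame(th[, 1], th[, 2], th[, 3], th[, 4])
  cen <- rowMeans(th)
  acrs <- matrix(0, length(elevations), 3)
  offs <- matrix(0, length(elevations), 3)
  for (i in seq_along(elevations)) {
    q <- stats::setNames(numeric(length(qn)), qn)
    for (cn in names(rhy)) {
      q[cn] <- deg2rad(rhy[[cn]]$intercept + rhy[[cn]]$slope * elevations[i])
    }
    fk <- fk_core(model$core, q)
    acr <- marker_points_fk(model, fk, "Acromion", "marker")[, 1]
    gh <- fk$p[, model$core$seg_index[["humerus"]]]
    acrs[i, ] <- as.numeric(t(Rth) %*% (acr - cen))
    offs[i, ] <- as.numeric(t(Rth) %*% (gh - acr))
  }
  # minimum-norm least-squares fit offset ~ 1 + acr (acromion samples lie on
  # a curve, so use a pseudo-inverse)
  X <- cbind(1, acrs)
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-8
  coef <- sv$v[, keep, drop = FALSE] %*%
    (diag(1 / sv$d[keep], sum(keep)) %*% (t(sv$u[, keep, drop = FALSE]) %*% offs))
  list(type = "affine_acromion", intercept = as.numeric(coef[1, ]),
       gain = t(coef[-1, , drop = FALSE]))
}

# Map from the shoulder elevation coordinate (humerus relative to scapula)
# to the measured humero-thoracic elevation angle (humerus long axis from
# the downward vertical) under the model's scapulohumeral rhythm. Purely
# rotational, hence invariant to segment scaling. Used to convert measured
# elevation into the rhythm regression's input.
elevation_coordinate_map <- function(model, grid = seq(0, 180, by = 2)) {
  qn <- model$core$qnames
  rhy <- model$regression$rhythm
  hum <- model$core$seg_index[["humerus"]]
  ht <- vapply(grid, function(e) {
    q <- stats::setNames(numeric(length(qn)), qn)
    q["shoulder_elv"] <- deg2rad(e)
    for (cn in names(rhy)) {
      q[cn] <- deg2rad(rhy[[cn]]$intercept + rhy[[cn]]$slope * e)
    }
    fk <- fk_core(model$core, q)
    axis <- fk$R[[hum]] %*% c(0, -1, 0)
    rad2deg(acos(pmin(pmax(-axis[2], -1), 1)))
  }, 0)
  # keep the strictly increasing prefix: the measured angle folds back once
  # combined glenohumeral + scapular elevation passes 180 degrees
  keep <- c(TRUE, diff(ht) > 0)
  first_bad <- which(!keep)[1]
  if (!is.na(first_bad)) keep[first_bad:length(keep)] <- FALSE
  list(coord = grid[keep], thoracic = ht[keep])
}

# Orthonormal thorax frame from the four thorax landmarks (columns: x,y,z
# axes). Y: mid(IJ,C7)->mid(PX,T10) reversed (up); Z: anterior component.
thorax_frame <- function(ij, c7, px, t10) {
  yv <- (ij + c7) / 2 - (px + t10) / 2
  y <- yv / vnorm(yv)
  zv <- (ij + px) / 2 - (c7 + t10) / 2
  zv <- zv - sum(zv * y) * y
  z <- zv / vnorm(zv)
  x <- vcross(y, z)
  cbind(x, y, z)
}

#' @export
print.msk_model <- function(x, ...) {
  cat("<msk_model>", x$name, "\n")
  cat("  segments:", paste(x$segments, collapse = ", "), "\n")
  cat("  coordinates:", nrow(x$coords),
      sprintf("(%d prescribed)", sum(x$coords$prescribed)), "\n")
  cat("  muscles:", nrow(x$muscles), "entries,",
      length(unique(x$muscles$base)), "muscle groups\n")
  if (!is.null(x$scale_set)) cat("  scaled: yes\n")
  invisible(x)
}
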