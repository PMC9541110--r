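# Builds inst/extdata/default_model.json, the packaged model asset:
# kinematic chain, muscle parameter registry, straight-line muscle path
# anchors, segment inertia defaults, virtual marker maps, regression and
# scaling configuration. Run from the package root:
#   Rscript data-raw/model_asset.R

muscles <- list(
  # name (full), base, group, f_max_iso N, l_opt m, l_ts m, alpha_penn deg, bundle_ids
  list("Trapezius scapula superior", "Trapezius", "Scapula superior", 1043,   0.1127, 0.027, 0, "1-6"),
  list("Trapezius scapula middle",   "Trapezius", "Scapula middle",   470.4,  0.0832, 0.032, 0, "7-9"),
  list("Trapezius scapula inferior", "Trapezius", "Scapula inferior", 414.4,  0.1264, 0.035, 0, "10-12"),
  list("Trapezius clavicle",         "Trapezius", "Clavicle",         201.6,  0.1116, 0.027, 0, "C1-C2"),
  list("Serratus anterior superior", "Serratus anterior", "Superior", 387.8,  0.0945, 0.000, 0, "9-12"),
  list("Serratus anterior middle",   "Serratus anterior", "Middle",   508,    0.1538, 0.012, 0, "5-8"),
  list("Serratus anterior inferior", "Serratus anterior", "Inferior", 430,    0.1587, 0.000, 0, "1-4"),
  list("Rhomboideus superior", "Rhomboideus", "Superior", 200.2, 0.0986, 0.015, 0, "1-2"),
  list("Rhomboideus inferior", "Rhomboideus", "Inferior", 407.4, 0.1152, 0.028, 0, "3-4"),
  list("Levator scapulae",   "Levator scapulae",   "", 280,   0.1578, 0.019, 0, "All"),
  list("Coracobrachialis",   "Coracobrachialis",   "", 648.2, 0.0683, 0.104, 0, "All"),
  list("Deltoideus anterior",  "Deltoideus", "Anterior",  707.7,  0.0940, 0.088, 5, "C1-C4"),
  list("Deltoideus middle",    "Deltoideus", "Middle",    2597.8, 0.0748, 0.064, 5, "4-11"),
  list("Deltoideus posterior", "Deltoideus", "Posterior", 1324.4, 0.0949, 0.076, 5, "1-3"),
  list("Latissimus dorsi superior", "Latissimus dorsi", "Superior", 201.6, 0.2109, 0.081, 0, "1-2"),
  list("Latissimus dorsi middle",   "Latissimus dorsi", "Middle",   315,   0.2656, 0.095, 0, "3-4"),
  list("Latissimus dorsi inferior", "Latissimus dorsi", "Inferior", 270.2, 0.3062, 0.062, 0, "5-6"),
  list("Pectoralis major clavicle",        "Pectoralis major", "Clavicle",        408.8, 0.1087, 0.014, 0, "C1-C2"),
  list("Pectoralis major thorax middle",   "Pectoralis major", "Thorax middle",   683.2, 0.1500, 0.026, 0, "4-6"),
  list("Pectoralis major thorax inferior", "Pectoralis major", "Thorax inferior", 571.2, 0.1830, 0.043, 0, "1-3"),
  list("Teres major", "Teres major", "", 851.2, 0.1410, 0.006, 0, "All"),
  list("Infraspinatus superior", "Infraspinatus", "Superior", 967.4,  0.0698, 0.050, 0, "4-6"),
  list("Infraspinatus inferior", "Infraspinatus", "Inferior", 1037.4, 0.0677, 0.084, 0, "1-3"),
  list("Pectoralis minor", "Pectoralis minor", "", 429.8, 0.1183, 0.032, 0, "All"),
  list("Teres minor", "Teres minor", "", 695.8, 0.0550, 0.051, 0, "All"),
  list("Subscapularis superior", "Subscapularis", "Superior", 540.4, 0.0676, 0.059, 5, "1-3"),
  list("Subscapularis middle",   "Subscapularis", "Middle",   609,   0.0744, 0.055, 5, "4-5, 10"),
  list("Subscapularis inferior", "Subscapularis", "Inferior", 854,   0.0721, 0.059, 0, "6-9, 11"),
  list("Supraspinatus anterior",  "Supraspinatus", "Anterior",  543.2, 0.0554, 0.031, 0, "3-4"),
  list("Supraspinatus posterior", "Supraspinatus", "Posterior", 326.2, 0.0591, 0.025, 0, "1-2"),
  list("Triceps long", "Triceps", "Long", 1580.6, 0.0969, 0.241, 10, "All"),
  list("Biceps long",   "Biceps", "Long",   485.8, 0.1412, 0.257, 0, "All"),
  list("Biceps brevis", "Biceps", "Brevis", 693,   0.1264, 0.212, 0, "All")
)
muscles <- lapply(muscles, function(m) {
  names(m) <- c("name", "base", "group", "f_max_iso", "l_opt", "l_ts",
                "alpha_penn", "bundle_ids")
  m
})

shoulder_coords <- c("shoulder_elv_plane", "shoulder_elv", "shoulder_rot")

joints <- list(
  list(name = "ground_thorax", parent = "ground", child = "thorax",
       offset = c(0, 0, 0), coords = list()),
  list(name = "sternoclavicular", parent = "thorax", child = "clavicle",
       offset = c(0.02, 0.24, 0.06),
       coords = list(
         list(name = "clav_prot", axis = c(0, 1, 0), range = c(-30, 30), prescribed = TRUE),
         list(name = "clav_elev", axis = c(0, 0, 1), range = c(-30, 60), prescribed = TRUE))),
  list(name = "acromioclavicular", parent = "clavicle", child = "scapula",
       offset = c(0.17, 0.02, -0.02),
       coords = list(
         list(name = "scap_prot", axis = c(0, 1, 0), range = c(-30, 60), prescribed = TRUE),
         list(name = "scap_upward_rot", axis = c(0, 0, 1), range = c(-20, 70), prescribed = TRUE),
         list(name = "scap_tilt", axis = c(1, 0, 0), range = c(-30, 30), prescribed = TRUE))),
  list(name = "glenohumeral", parent = "scapula", child = "humerus",
       offset = c(0.01, -0.04, 0),
       coords = list(
         list(name = "shoulder_elv_plane", axis = c(0, 1, 0), range = c(-95, 130), prescribed = FALSE),
         list(name = "shoulder_elv", axis = c(0, 0, 1), range = c(-10, 180), prescribed = FALSE),
         list(name = "shoulder_rot", axis = c(0, 1, 0), range = c(-120, 120), prescribed = FALSE))),
  list(name = "elbow", parent = "humerus", child = "forearm",
       offset = c(0, -0.30, 0),
       coords = list(
         list(name = "elbow_flexion", axis = c(-1, 0, 0), range = c(0, 150), prescribed = FALSE),
         list(name = "pro_sup", axis = c(0, 1, 0), range = c(-90, 90), prescribed = FALSE))),
  list(name = "wrist", parent = "forearm", child = "hand",
       offset = c(0, -0.26, 0), coords = list())
)

virtual_markers <- list(
  marker = list(
    "Incisura Jugularis"    = list(segment = "thorax",  offset = c(0.00,  0.24,  0.09)),
    "Processus Xiphoideus"  = list(segment = "thorax",  offset = c(0.00,  0.02,  0.11)),
    "Cervical Vertebrae 7"  = list(segment = "thorax",  offset = c(0.00,  0.28, -0.08)),
    "Thoracic Vertebrae 10" = list(segment = "thorax",  offset = c(0.00,  0.02, -0.11)),
    "Acromion"              = list(segment = "scapula", offset = c(0.02,  0.02, -0.01)),
    "Epicondylus Medialis"  = list(segment = "humerus", offset = c(-0.035, -0.30, 0.00)),
    "Epicondylus Lateralis" = list(segment = "humerus", offset = c(0.035, -0.30, 0.00)),
    "Upper arm"             = list(segment = "humerus", offset = c(0.035, -0.15, 0.005)),
    "Head of Ulna"          = list(segment = "forearm", offset = c(-0.025, -0.26, 0.00)),
    "Styloid Radius"        = list(segment = "forearm", offset = c(0.025, -0.26, 0.00)),
    "Lower arm"             = list(segment = "forearm", offset = c(0.025, -0.13, 0.01)),
    "Hand"                  = list(segment = "hand",    offset = c(0.00, -0.10, 0.01))
  ),
  camera = list(
    "Mid Spine"             = list(segment = "thorax",  offset = c(0.00,  0.26, -0.09)),
    "Mid Thorax"            = list(segment = "thorax",  offset = c(0.00,  0.02, -0.10)),
    "Shoulder joint center" = list(segment = "humerus", offset = c(0, 0, 0)),
    "Elbow joint center"    = list(segment = "forearm", offset = c(0, 0, 0)),
    "Wrist joint center"    = list(segment = "hand",    offset = c(0, 0, 0))
  ),
  centers = list(
    "Shoulder joint center" = list(segment = "humerus", offset = c(0, 0, 0)),
    "Elbow joint center"    = list(segment = "forearm", offset = c(0, 0, 0)),
    "Wrist joint center"    = list(segment = "hand",    offset = c(0, 0, 0))
  )
)

# Straight-line muscle path anchors in segment-local frames (m).
# X lateral (dominant/right side), Y up, Z anterior. At model load one path
# end is slid along its leg so the musculotendon length at a mid-range
# calibration pose equals l_ts + l_opt * cos(pennation).
pp <- function(segment, offset) list(segment = segment, offset = offset)
geometry <- list(
  list(muscle = "Trapezius scapula superior", spanned = character(),
       path = list(pp("thorax", c(0.00, 0.30, -0.05)), pp("scapula", c(0.00, 0.02, -0.02)))),
  list(muscle = "Trapezius scapula middle", spanned = character(),
       path = list(pp("thorax", c(-0.02, 0.20, -0.10)), pp("scapula", c(-0.02, 0.00, -0.03)))),
  list(muscle = "Trapezius scapula inferior", spanned = character(),
       path = list(pp("thorax", c(-0.02, 0.08, -0.12)), pp("scapula", c(-0.03, -0.02, -0.03)))),
  list(muscle = "Trapezius clavicle", spanned = character(),
       path = list(pp("thorax", c(0.00, 0.30, -0.04)), pp("clavicle", c(0.12, 0.01, -0.01)))),
  list(muscle = "Serratus anterior superior", spanned = character(),
       path = list(pp("thorax", c(0.08, 0.20, 0.05)), pp("scapula", c(-0.04, 0.00, -0.02)))),
  list(muscle = "Serratus anterior middle", spanned = character(),
       path = list(pp("thorax", c(0.10, 0.12, 0.06)), pp("scapula", c(-0.04, -0.02, -0.02)))),
  list(muscle = "Serratus anterior inferior", spanned = character(),
       path = list(pp("thorax", c(0.09, 0.04, 0.05)), pp("scapula", c(-0.04, -0.04, -0.02)))),
  list(muscle = "Rhomboideus superior", spanned = character(),
       path = list(pp("thorax", c(-0.01, 0.24, -0.09)), pp("scapula", c(-0.04, 0.00, -0.03)))),
  list(muscle = "Rhomboideus inferior", spanned = character(),
       path = list(pp("thorax", c(-0.01, 0.16, -0.11)), pp("scapula", c(-0.05, -0.03, -0.03)))),
  list(muscle = "Levator scapulae", spanned = character(),
       path = list(pp("thorax", c(0.00, 0.32, -0.03)), pp("scapula", c(-0.03, 0.01, -0.02)))),
  list(muscle = "Coracobrachialis", spanned = shoulder_coords,
       path = list(pp("scapula", c(0.00, -0.01, 0.03)), pp("humerus", c(0.005, -0.13, 0.005)))),
  list(muscle = "Deltoideus anterior", spanned = shoulder_coords,
       path = list(pp("clavicle", c(0.13, 0.01, 0.01)), pp("humerus", c(0.03, -0.03, 0.02)),
                   pp("humerus", c(0.01, -0.12, 0.01)))),
  list(muscle = "Deltoideus middle", spanned = shoulder_coords,
       path = list(pp("scapula", c(0.02, 0.02, -0.005)), pp("humerus", c(0.04, -0.03, 0.00)),
                   pp("humerus", c(0.012, -0.12, 0.005)))),
  list(muscle = "Deltoideus posterior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.02, 0.01, -0.02)), pp("humerus", c(0.03, -0.03, -0.02)),
                   pp("humerus", c(0.01, -0.12, -0.005)))),
  list(muscle = "Latissimus dorsi superior", spanned = shoulder_coords,
       path = list(pp("thorax", c(-0.02, 0.12, -0.10)), pp("humerus", c(0.005, -0.03, 0.01)))),
  list(muscle = "Latissimus dorsi middle", spanned = shoulder_coords,
       path = list(pp("thorax", c(-0.02, 0.06, -0.10)), pp("humerus", c(0.005, -0.035, 0.012)))),
  list(muscle = "Latissimus dorsi inferior", spanned = shoulder_coords,
       path = list(pp("thorax", c(-0.01, 0.00, -0.09)), pp("humerus", c(0.005, -0.04, 0.014)))),
  list(muscle = "Pectoralis major clavicle", spanned = shoulder_coords,
       path = list(pp("clavicle", c(0.06, 0.00, 0.01)), pp("humerus", c(0.01, -0.04, 0.02)))),
  list(muscle = "Pectoralis major thorax middle", spanned = shoulder_coords,
       path = list(pp("thorax", c(0.02, 0.16, 0.10)), pp("humerus", c(0.012, -0.045, 0.02)))),
  list(muscle = "Pectoralis major thorax inferior", spanned = shoulder_coords,
       path = list(pp("thorax", c(0.02, 0.08, 0.10)), pp("humerus", c(0.012, -0.05, 0.018)))),
  list(muscle = "Teres major", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.04, -0.05, -0.02)), pp("humerus", c(0.005, -0.045, 0.01)))),
  list(muscle = "Infraspinatus superior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.03, -0.01, -0.03)), pp("humerus", c(0.025, -0.01, -0.015)))),
  list(muscle = "Infraspinatus inferior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.035, -0.03, -0.03)), pp("humerus", c(0.025, -0.012, -0.015)))),
  list(muscle = "Pectoralis minor", spanned = character(),
       path = list(pp("thorax", c(0.04, 0.18, 0.08)), pp("scapula", c(0.00, -0.01, 0.03)))),
  list(muscle = "Teres minor", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.03, -0.035, -0.025)), pp("humerus", c(0.022, -0.015, -0.018)))),
  list(muscle = "Subscapularis superior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.02, -0.01, -0.015)), pp("humerus", c(0.015, -0.01, 0.02)))),
  list(muscle = "Subscapularis middle", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.025, -0.02, -0.015)), pp("humerus", c(0.015, -0.012, 0.02)))),
  list(muscle = "Subscapularis inferior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.025, -0.03, -0.015)), pp("humerus", c(0.015, -0.015, 0.02)))),
  list(muscle = "Supraspinatus anterior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.015, 0.01, -0.02)), pp("humerus", c(0.02, 0.005, 0.005)))),
  list(muscle = "Supraspinatus posterior", spanned = shoulder_coords,
       path = list(pp("scapula", c(-0.025, 0.005, -0.025)), pp("humerus", c(0.02, 0.004, 0.00)))),
  list(muscle = "Triceps long", spanned = c(shoulder_coords, "elbow_flexion"),
       path = list(pp("scapula", c(0.00, -0.05, -0.005)), pp("humerus", c(0.005, -0.27, -0.035)),
                   pp("humerus", c(0.002, -0.30, -0.032)), pp("forearm", c(0.00, -0.025, -0.04)))),
  list(muscle = "Biceps long", spanned = c(shoulder_coords, "elbow_flexion", "pro_sup"),
       path = list(pp("scapula", c(0.008, 0.000, 0.012)), pp("humerus", c(0.018, -0.02, 0.018)),
                   pp("humerus", c(0.012, -0.25, 0.028)), pp("forearm", c(0.012, -0.045, 0.012)))),
  list(muscle = "Biceps brevis", spanned = c(shoulder_coords, "elbow_flexion", "pro_sup"),
       path = list(pp("scapula", c(0.00, -0.01, 0.03)), pp("humerus", c(0.014, -0.25, 0.03)),
                   pp("forearm", c(0.014, -0.055, 0.016))))
)

# de Leva-style inertial defaults for a 75 kg, 1.75 m male; proximal-origin
# local frames, principal moments about the COM (kg m^2).
inertia <- list(
  list(segment = "thorax",   mass = 0,    com_offset = c(0, 0.12, 0),   inertia_diag = c(0, 0, 0)),
  list(segment = "clavicle", mass = 0,    com_offset = c(0.085, 0, 0),  inertia_diag = c(0, 0, 0)),
  list(segment = "scapula",  mass = 0,    com_offset = c(-0.02, -0.02, -0.02), inertia_diag = c(0, 0, 0)),
  list(segment = "humerus",  mass = 2.03, com_offset = c(0, -0.173, 0), inertia_diag = c(0.0132, 0.0023, 0.0124)),
  list(segment = "forearm",  mass = 1.22, com_offset = c(0, -0.119, 0), inertia_diag = c(0.0065, 0.0009, 0.0067)),
  list(segment = "hand",     mass = 0.46, com_offset = c(0, -0.079, 0), inertia_diag = c(0.0009, 0.0003, 0.0010))
)

regression <- list(
  # constant acromion->glenohumeral offset, expressed in the thorax frame
  # that estimate_joint_centers() reconstructs from the four thorax markers;
  # NULL means "derive from the generic model at load" (kept exact there).
  shoulder_center_offset = NULL,
  provenance = "configurable stand-in (source regressions not printed)",
  # linear scapulohumeral rhythm: prescribed coordinate = intercept + slope *
  # humero-thoracic elevation (deg). 1:2 upward-rotation ratio by default.
  rhythm = list(
    scap_upward_rot = list(slope = 0.5,  intercept = 0),
    scap_prot       = list(slope = 0.2,  intercept = 0),
    scap_tilt       = list(slope = 0.1,  intercept = 0),
    clav_elev       = list(slope = 0.2,  intercept = 0),
    clav_prot       = list(slope = 0.1,  intercept = 0)
  )
)

scale_pairs <- list(
  marker = list(
    list(segment = "thorax",  axis = "y",   a = "Incisura Jugularis", b = "Processus Xiphoideus"),
    list(segment = "thorax",  axis = "z",   a = "Incisura Jugularis", b = "Cervical Vertebrae 7"),
    list(segment = "humerus", axis = "all", a = "Acromion",           b = "Epicondylus Lateralis"),
    list(segment = "forearm", axis = "all", a = "Epicondylus Lateralis", b = "Styloid Radius")
  ),
  camera = list(
    # sparse stream: one up-down distance only, applied uniformly (thorax rule)
    list(segment = "thorax",  axis = "all", a = "Mid Spine",             b = "Mid Thorax"),
    list(segment = "humerus", axis = "all", a = "Shoulder joint center", b = "Elbow joint center"),
    list(segment = "forearm", axis = "all", a = "Elbow joint center",    b = "Wrist joint center")
  ),
  inherit = list(clavicle = "thorax", scapula = "thorax", hand = "forearm")
)

# Report rows (Table-3 style): row label -> member muscles; %Fmax normalizer
# is the summed Fmax over members. Bold prime movers get Bland-Altman plots.
report_groups <- list(
  lateral_fly = list(
    "Deltoid middle"    = "Deltoideus middle",
    "Deltoid anterior"  = "Deltoideus anterior",
    "Deltoid posterior" = "Deltoideus posterior",
    "Trapezius scapula superior" = "Trapezius scapula superior",
    "Trapezius scapula middle"   = "Trapezius scapula middle",
    "Trapezius scapula inferior" = "Trapezius scapula inferior",
    "Infraspinatus" = c("Infraspinatus superior", "Infraspinatus inferior"),
    "Teres minor"   = "Teres minor",
    "Subscapularis" = c("Subscapularis superior", "Subscapularis middle", "Subscapularis inferior"),
    "Supraspinatus" = c("Supraspinatus anterior", "Supraspinatus posterior")
  ),
  biceps_curl = list(
    "Biceps brevis" = "Biceps brevis",
    "Biceps long"   = "Biceps long",
    "Triceps"       = "Triceps long",
    "Infraspinatus" = c("Infraspinatus superior", "Infraspinatus inferior"),
    "Teres minor"   = "Teres minor",
    "Subscapularis" = c("Subscapularis superior", "Subscapularis middle", "Subscapularis inferior"),
    "Supraspinatus" = c("Supraspinatus anterior", "Supraspinatus posterior")
  ),
  prime_movers = list(
    lateral_fly = c("Deltoid middle", "Deltoid anterior", "Trapezius scapula superior"),
    biceps_curl = c("Biceps brevis", "Biceps long")
  )
)

asset <- list(
  name = "simplified thoracoscapular shoulder-elbow model",
  units = list(length = "m", angle = "deg", force = "N", mass = "kg"),
  joints = joints,
  muscles = muscles,
  geometry = geometry,
  inertia = inertia,
  virtual_markers = virtual_markers,
  regression = regression,
  scale_pairs = scale_pairs,
  report_groups = report_groups
)

jsonlite::write_json(asset, file.path("inst", "extdata", "default_model.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote inst/extdata/default_model.json\n")
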