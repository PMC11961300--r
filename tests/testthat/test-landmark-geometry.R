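## Geometry of arch traits from 3D landmarks.

mk <- function(arch, pts, stage = "primary") landmark_set("s1", stage, arch, pts)

test_that("intra-arch widths are 3D Euclidean distances with symmetric labels", {
  lms <- mk("maxillary", rbind(
    canine_cusp_R = c(-14.25, 0, 0), canine_cusp_L = c(14.25, 0, 0),
    molar_mb_cusp_R = c(-20.45, 0, 0), molar_mb_cusp_L = c(20.45, 0, 0)
  ))
  expect_equal(intercanine_width(lms), 28.5)
  expect_equal(intermolar_width(lms), 40.9)

  ## Pythagorean 3-4-12 triple and the coincident-point identity
  lms2 <- mk("maxillary", rbind(
    canine_cusp_R = c(0, 0, 0), canine_cusp_L = c(3, 4, 12),
    molar_mb_cusp_R = c(1, 2, 3), molar_mb_cusp_L = c(1, 2, 3)
  ))
  expect_equal(intercanine_width(lms2), 13)
  expect_equal(intermolar_width(lms2), 0)

  ## swapping R/L labels leaves the width unchanged
  pts <- lms$points
  rownames(pts) <- c("canine_cusp_L", "canine_cusp_R",
                     "molar_mb_cusp_L", "molar_mb_cusp_R")
  expect_equal(intercanine_width(mk("maxillary", pts)), 28.5)

  ## random pairs against the plain norm
  withr::with_seed(11, for (i in 1:20) {
    p <- matrix(rnorm(6, sd = 10), 2, 3)
    l <- mk("maxillary", rbind(canine_cusp_R = p[1, ], canine_cusp_L = p[2, ]))
    expect_equal(intercanine_width(l), sqrt(sum((p[1, ] - p[2, ])^2)),
                 tolerance = 1e-12)
  })
})

test_that("missing landmarks raise errors naming the absent landmark", {
  lms <- mk("maxillary", rbind(canine_cusp_R = c(0, 0, 0)))
  expect_error(intercanine_width(lms), "canine_cusp_L")
  expect_error(arch_length(lms), "incisor_mesial_R")
})

test_that("arch length is the point-to-line distance, matching the cross-product oracle", {
  lms <- mk("maxillary", rbind(
    incisor_mesial_R = c(-2, 25.9, 0), incisor_mesial_L = c(2, 25.9, 0),
    molar_distal_contact_R = c(-20, 0, 0), molar_distal_contact_L = c(20, 0, 0)
  ))
  expect_equal(arch_length(lms), 25.9)

  ## collinear incisal midpoint
  lms0 <- mk("maxillary", rbind(
    incisor_mesial_R = c(4, 0, 0), incisor_mesial_L = c(6, 0, 0),
    molar_distal_contact_R = c(-20, 0, 0), molar_distal_contact_L = c(20, 0, 0)
  ))
  expect_equal(arch_length(lms0), 0)

  ## degenerate line
  lmsd <- mk("maxillary", rbind(
    incisor_mesial_R = c(0, 1, 0), incisor_mesial_L = c(0, 1, 0),
    molar_distal_contact_R = c(1, 2, 3), molar_distal_contact_L = c(1, 2, 3)
  ))
  expect_error(arch_length(lmsd), "degenerate")

  ## 1000 random skew configurations against the vector-algebra oracle
  withr::with_seed(12, for (i in 1:1000) {
    pr <- rnorm(3, sd = 10); pl <- rnorm(3, sd = 10)
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    l <- mk("maxillary", rbind(incisor_mesial_R = pr, incisor_mesial_L = pl,
                               molar_distal_contact_R = a,
                               molar_distal_contact_L = b))
    expect_equal(arch_length(l), oracle_point_line((pr + pl) / 2, a, b),
                 tolerance = 1e-10)
  })
})

max_pts <- rbind(
  incisor_mesial_R = c(-2, 30, 0), incisor_mesial_L = c(2, 30, 0),
  molar_mb_cusp_R = c(-25, 0, 0), molar_mb_cusp_L = c(25, 0, 0),
  molar_distal_contact_R = c(-26, -1, 0), molar_distal_contact_L = c(26, -1, 0)
)
mand_pts <- rbind(
  incisor_mesial_R = c(-2, 27.6, 1.1), incisor_mesial_L = c(2, 27.6, 1.1),
  molar_distal_contact_R = c(-24, -1, 2), molar_distal_contact_L = c(24, -1, 2)
)

test_that("occlusal plane passes through its three defining points with an anterior AP axis", {
  mx <- mk("maxillary", max_pts)
  md <- mk("mandibular", mand_pts)
  pl <- occlusal_plane(mx, md)
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-9)
  expect_equal(sum(pl$normal * pl$ap_axis), 0, tolerance = 1e-9)
  expect_equal(pl$normal, c(0, 0, 1), ignore_attr = TRUE)   # towards the mandible
  expect_equal(pl$ap_axis, c(0, 1, 0), ignore_attr = TRUE)

  ## translation invariance of the orientation
  sh <- c(5, -3, 7)
  pl2 <- occlusal_plane(apply_rigid(mx, diag(3), sh), apply_rigid(md, diag(3), sh))
  expect_equal(pl2$normal, pl$normal, tolerance = 1e-12)
  expect_equal(pl2$ap_axis, pl$ap_axis, tolerance = 1e-12)

  ## tilted configuration: normal orthogonal to both in-plane edges
  withr::with_seed(13, {
    rot <- random_rotation()
    mxr <- apply_rigid(mx, rot, c(1, 2, 3))
    mdr <- apply_rigid(md, rot, c(1, 2, 3))
    plr <- occlusal_plane(mxr, mdr)
    im <- (mxr$points["incisor_mesial_R", ] + mxr$points["incisor_mesial_L", ]) / 2
    e1 <- mxr$points["molar_mb_cusp_R", ] - im
    e2 <- mxr$points["molar_mb_cusp_L", ] - im
    expect_lt(abs(sum(plr$normal * e1)), 1e-10)
    expect_lt(abs(sum(plr$normal * e2)), 1e-10)
  })

  ## collinear defining points
  bad <- mk("maxillary", rbind(
    incisor_mesial_R = c(-1, 0, 0), incisor_mesial_L = c(1, 0, 0),
    molar_mb_cusp_R = c(-25, 0, 0), molar_mb_cusp_L = c(25, 0, 0)
  ))
  expect_error(occlusal_plane(bad), "collinear")
})

test_that("overjet and overbite follow the stated sign conventions", {
  mx <- mk("maxillary", max_pts)
  md <- mk("mandibular", mand_pts)
  pl <- occlusal_plane(mx, md)
  expect_equal(overjet(mx, md, pl), 2.4)
  expect_equal(overbite(mx, md, pl), 1.1)

  ## identical projected points give zero overjet; in-plane mandibular
  ## reference gives zero overbite
  md0 <- mk("mandibular", rbind(
    incisor_mesial_R = c(-2, 30, 0), incisor_mesial_L = c(2, 30, 0),
    molar_distal_contact_R = c(-24, -1, 2), molar_distal_contact_L = c(24, -1, 2)
  ))
  expect_equal(overjet(mx, md0, pl), 0)
  expect_equal(overbite(mx, md0, pl), 0)

  ## mandibular incisors 1 mm anterior -> overjet -1; open bite -> overbite < 0
  mdo <- mk("mandibular", rbind(
    incisor_mesial_R = c(-2, 31, -0.5), incisor_mesial_L = c(2, 31, -0.5),
    molar_distal_contact_R = c(-24, -1, 2), molar_distal_contact_L = c(24, -1, 2)
  ))
  expect_equal(overjet(mx, mdo, pl), -1)
  expect_lt(overbite(mx, mdo, pl), 0)
})

test_that("molar relationship is positive for distocclusion and negative for mesiocclusion", {
  mx <- mk("maxillary", max_pts, stage = "mixed")
  pl <- occlusal_plane(mx)
  groove <- function(y) mk("mandibular", rbind(
    molar_buccal_groove_R = c(-25, y, 2), molar_buccal_groove_L = c(25, y, 2)
  ), stage = "mixed")
  ## maxillary MB cusp at y = 0: groove directly below -> neutral
  expect_equal(molar_relationship(mx, groove(0), pl, "right"), 0)
  ## groove 2 mm distal (posterior, -y) -> +2 distocclusion
  expect_equal(molar_relationship(mx, groove(-2), pl, "right"), 2)
  expect_equal(molar_relationship(mx, groove(-2), pl, "left"), 2)
  ## groove 2 mm mesial -> -2 mesiocclusion
  expect_equal(molar_relationship(mx, groove(2), pl, "right"), -2)

  ## primary stage uses distal contact points of both arches
  mxp <- mk("maxillary", max_pts, stage = "primary")
  plp <- occlusal_plane(mxp)
  mdp <- mk("mandibular", rbind(
    molar_distal_contact_R = c(-26, -2.5, 2), molar_distal_contact_L = c(26, -2.5, 2)
  ), stage = "primary")
  ## maxillary distal contacts at y = -1; mandibular 1.5 mm distal of that
  expect_equal(molar_relationship(mxp, mdp, plp, "right"), 1.5)
})

test_that("all traits are invariant under joint rigid motions", {
  lm <- simulate_landmarks(example_target("permanent"))
  ref <- extract_all_traits(lm$maxilla, lm$mandible)
  withr::with_seed(14, for (i in 1:25) {
    rot <- random_rotation()
    tr <- rnorm(3, sd = 50)
    moved <- extract_all_traits(apply_rigid(lm$maxilla, rot, tr),
                                apply_rigid(lm$mandible, rot, tr))
    for (cc in setdiff(names(ref), c("subject_id", "stage"))) {
      expect_equal(moved[[cc]], ref[[cc]], tolerance = 1e-9)
    }
  })
})

test_that("extract_all_traits degrades to NA with a warning on missing landmarks", {
  lm <- simulate_landmarks(example_target("permanent"))
  pts <- lm$mandible$points
  pts <- pts[rownames(pts) != "canine_cusp_R", ]
  md <- landmark_set("synthetic", "permanent", "mandibular", pts)
  expect_warning(tr <- extract_all_traits(lm$maxilla, md), "canine_cusp_R")
  expect_true(is.na(tr$mandibular_intercanine_width))
  expect_false(is.na(tr$overjet))
})

test_that("landmark CSV round-trips through read_landmarks and landmarks_to_traits", {
  lm <- simulate_landmarks(example_target("primary"))
  rows <- do.call(rbind, lapply(lm, function(l) {
    data.frame(subject_id = l$subject_id, stage = l$stage, arch = l$arch,
               landmark = rownames(l$points), x = l$points[, 1],
               y = l$points[, 2], z = l$points[, 3])
  }))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  tab <- landmarks_to_traits(read_landmarks(path))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$maxillary_intercanine_width, 28.5, tolerance = 1e-9)
  expect_equal(tab$overjet, 2.4, tolerance = 1e-9)
})
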