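## Landmark geometry: arch traits from 3D coordinates digitized on dental
## models. Intra-arch distances are true 3D distances; inter-arch measures
## (overjet, overbite, molar relationships) are referred to the maxillary
## occlusal plane.

#' Controlled landmark vocabulary
#'
#' Landmark names accepted by [landmark_set()]. Names are functional rather
#' than tooth-numbered: the same name refers to the stage-appropriate tooth
#' (e.g. `canine_cusp_R` is the primary canine cusp tip in the primary and
#' mixed dentitions and the permanent canine cusp tip in the permanent
#' dentition; `molar_mb_cusp_*` is the second primary molar mesiobuccal cusp
#' in the primary dentition and the first permanent molar mesiobuccal cusp
#' otherwise).
#'
#' @return Character vector of valid landmark names.
#' @export
landmark_vocabulary <- function() {
  c(
    "incisor_mesial_R", "incisor_mesial_L",   # central incisor mesial incisal edges
    "canine_cusp_R", "canine_cusp_L",
    "molar_mb_cusp_R", "molar_mb_cusp_L",     # mesiobuccal cusp tips
    "molar_distal_contact_R", "molar_distal_contact_L",
    "molar_buccal_groove_R", "molar_buccal_groove_L"  # mandibular, mixed/permanent
  )
}

#' Construct a landmark set for one subject, arch and dentition stage
#'
#' @param subject_id Subject identifier.
#' @param stage Dentition stage: `"primary"`, `"mixed"` or `"permanent"`.
#' @param arch `"maxillary"` or `"mandibular"`.
#' @param points Numeric matrix with 3 columns (x, y, z in mm, right-handed
#'   axes) and row names drawn from [landmark_vocabulary()], or a named list
#'   of length-3 numeric vectors.
#'
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, stage, arch, points) {
  stage <- match.arg(stage, .STAGES)
  arch <- match.arg(arch, .ARCHES)
  if (is.list(points)) {
    points <- do.call(rbind, points)
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) {
    stop("`points` must have 3 columns (x, y, z)")
  }
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y", "z")
  nm <- rownames(points)
  if (is.null(nm)) {
    stop("`points` rows must be named with landmark names")
  }
  bad <- setdiff(nm, landmark_vocabulary())
  if (length(bad)) {
    stop("unknown landmark name(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(nm)) {
    stop("duplicated landmark name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (!all(is.finite(points))) {
    stop("all landmark coordinates must be finite")
  }
  structure(
    list(subject_id = subject_id, stage = stage, arch = arch, points = points),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> subject %s, %s %s dentition: %d landmarks\n",
              x$subject_id, x$arch, x$stage, nrow(x$points)))
  invisible(x)
}

## Fetch one landmark, erroring with the absent landmark's name.
.lm_point <- function(lms, name) {
  i <- match(name, rownames(lms$points))
  if (is.na(i)) {
    stop(sprintf("missing landmark '%s' (%s arch, subject %s)",
                 name, lms$arch, lms$subject_id), call. = FALSE)
  }
  lms$points[i, ]
}

.norm3 <- function(v) sqrt(sum(v^2))

## Midpoint of the two central-incisor mesial incisal landmarks: the incisal
## reference point used for arch length, the occlusal plane, overjet and
## overbite.
.incisal_midpoint <- function(lms) {
  (.lm_point(lms, "incisor_mesial_R") + .lm_point(lms, "incisor_mesial_L")) / 2
}

#' Intercanine width
#'
#' 3D Euclidean distance between right and left canine cusp tips (primary
#' canines in primary/mixed dentition, permanent canines in permanent
#' dentition).
#'
#' @param lms A [landmark_set()].
#' @return Width in mm.
#' @export
intercanine_width <- function(lms) {
  .norm3(.lm_point(lms, "canine_cusp_R") - .lm_point(lms, "canine_cusp_L"))
}

#' Intermolar width
#'
#' 3D Euclidean distance between right and left molar mesiobuccal cusp tips
#' (second primary molars in primary dentition, first permanent molars in
#' mixed/permanent dentition).
#'
#' @inheritParams intercanine_width
#' @return Width in mm.
#' @export
intermolar_width <- function(lms) {
  .norm3(.lm_point(lms, "molar_mb_cusp_R") - .lm_point(lms, "molar_mb_cusp_L"))
}

#' Arch length
#'
#' Perpendicular (point-to-line) distance in 3D from the midpoint of the two
#' central-incisor mesial incisal landmarks to the infinite line joining the
#' right and left molar distal contact points (second primary molars in
#' primary dentition, first permanent molars otherwise).
#'
#' @inheritParams intercanine_width
#' @return Length in mm.
#' @export
arch_length <- function(lms) {
  p <- .incisal_midpoint(lms)
  a <- .lm_point(lms, "molar_distal_contact_R")
  b <- .lm_point(lms, "molar_distal_contact_L")
  d <- b - a
  len <- .norm3(d)
  if (len < 1e-9) {
    stop("degenerate distal-contact line: the two distal contact points coincide")
  }
  u <- d / len
  w <- p - a
  .norm3(w - sum(w * u) * u)
}

#' Maxillary occlusal plane
#'
#' Plane through the midpoint of the maxillary central-incisor mesial incisal
#' landmarks and the right and left maxillary molar mesiobuccal cusp tips.
#' Used as the reference for all inter-arch measures.
#'
#' The anteroposterior (AP) axis is the in-plane unit vector from the midpoint
#' of the two molar cusps towards the incisal midpoint (pointing anteriorly).
#' The plane normal is oriented towards the mandibular arch when `mandible` is
#' supplied (so normal vertical incisor overlap gives a positive overbite);
#' otherwise its sign is fixed deterministically by making its largest
#' component positive.
#'
#' @param maxilla Maxillary [landmark_set()].
#' @param mandible Optional mandibular [landmark_set()] used only to orient
#'   the plane normal towards the mandible.
#'
#' @return An object of class `occlusal_plane` with fields `origin` (the
#'   incisal midpoint), unit `normal` and unit in-plane `ap_axis`.
#' @export
occlusal_plane <- function(maxilla, mandible = NULL) {
  if (maxilla$arch != "maxillary") {
    stop("occlusal plane must be constructed from the maxillary arch")
  }
  im <- .incisal_midpoint(maxilla)
  mr <- .lm_point(maxilla, "molar_mb_cusp_R")
  ml <- .lm_point(maxilla, "molar_mb_cusp_L")
  n <- c(
    (mr[2] - im[2]) * (ml[3] - im[3]) - (mr[3] - im[3]) * (ml[2] - im[2]),
    (mr[3] - im[3]) * (ml[1] - im[1]) - (mr[1] - im[1]) * (ml[3] - im[3]),
    (mr[1] - im[1]) * (ml[2] - im[2]) - (mr[2] - im[2]) * (ml[1] - im[1])
  )
  nn <- .norm3(n)
  if (nn < 1e-9) {
    stop("occlusal plane undefined: incisal midpoint and molar cusps are collinear")
  }
  n <- n / nn
  if (!is.null(mandible)) {
    cen <- colMeans(mandible$points)
    if (sum((cen - im) * n) < 0) n <- -n
  } else if (n[which.max(abs(n))] < 0) {
    n <- -n
  }
  ap <- im - (mr + ml) / 2
  ap <- ap - sum(ap * n) * n
  ap <- ap / .norm3(ap)
  structure(list(origin = im, normal = n, ap_axis = ap),
            class = "occlusal_plane")
}

#' @export
print.occlusal_plane <- function(x, ...) {
  cat(sprintf("<occlusal_plane> normal (%.3f, %.3f, %.3f), AP axis (%.3f, %.3f, %.3f)\n",
              x$normal[1], x$normal[2], x$normal[3],
              x$ap_axis[1], x$ap_axis[2], x$ap_axis[3]))
  invisible(x)
}

## Orthogonal projection of a point into the occlusal plane.
.project_plane <- function(p, plane) {
  p - sum((p - plane$origin) * plane$normal) * plane$normal
}

#' Overjet
#'
#' Horizontal (anteroposterior) overlap between maxillary and mandibular
#' central incisors: the signed AP component of the maxillary minus the
#' mandibular incisal reference point after projecting both into the
#' maxillary occlusal plane. Positive when the maxillary incisors lie
#' anterior to the mandibular incisors.
#'
#' @param maxilla,mandible [landmark_set()] objects for the two arches.
#' @param plane The maxillary [occlusal_plane()].
#' @return Overjet in mm (signed).
#' @export
overjet <- function(maxilla, mandible, plane) {
  pmx <- .project_plane(.incisal_midpoint(maxilla), plane)
  pmd <- .project_plane(.incisal_midpoint(mandible), plane)
  sum((pmx - pmd) * plane$ap_axis)
}

#' Overbite
#'
#' Vertical overlap between maxillary and mandibular central incisors: the
#' signed component of the mandibular minus the maxillary incisal reference
#' point along the occlusal-plane normal (oriented towards the mandible).
#' Positive for normal vertical overlap, negative for an open bite.
#'
#' @inheritParams overjet
#' @return Overbite in mm (signed).
#' @export
overbite <- function(maxilla, mandible, plane) {
  d <- .incisal_midpoint(mandible) - .incisal_midpoint(maxilla)
  sum(d * plane$normal)
}

#' Molar relationship
#'
#' Signed anteroposterior relation of the mandibular to the maxillary molar
#' on one side, measured along the occlusal-plane AP axis after projecting
#' both reference landmarks into the plane. In the primary dentition the
#' reference landmarks are the distal contact points of the second primary
#' molars of each arch; in the mixed/permanent dentition they are the
#' maxillary first permanent molar mesiobuccal cusp tip and the mandibular
#' first permanent molar buccal groove. Positive values indicate
#' distocclusion (mandibular landmark distal to the maxillary landmark),
#' negative values mesiocclusion.
#'
#' @inheritParams overjet
#' @param side `"right"` or `"left"`.
#' @return Molar relationship in mm (signed).
#' @export
molar_relationship <- function(maxilla, mandible, plane, side = c("right", "left")) {
  side <- match.arg(side)
  sfx <- if (side == "right") "R" else "L"
  if (maxilla$stage == "primary") {
    mx <- .lm_point(maxilla, paste0("molar_distal_contact_", sfx))
    md <- .lm_point(mandible, paste0("molar_distal_contact_", sfx))
  } else {
    mx <- .lm_point(maxilla, paste0("molar_mb_cusp_", sfx))
    md <- .lm_point(mandible, paste0("molar_buccal_groove_", sfx))
  }
  pmx <- .project_plane(mx, plane)
  pmd <- .project_plane(md, plane)
  sum((pmx - pmd) * plane$ap_axis)
}

#' Extract all ten arch traits for one subject and stage
#'
#' Applies every trait operation with stage-appropriate landmark choices.
#' A missing landmark makes the affected trait `NA` (with a warning naming
#' it) rather than aborting the subject.
#'
#' @param maxilla,mandible Maxillary and mandibular [landmark_set()] objects
#'   for the same subject and stage.
#'
#' @return A one-row data frame of class `arch_traits` with `subject_id`,
#'   `stage` and the ten trait columns (mm).
#' @export
extract_all_traits <- function(maxilla, mandible) {
  stopifnot(inherits(maxilla, "landmark_set"), inherits(mandible, "landmark_set"))
  if (maxilla$stage != mandible$stage) {
    stop("maxillary and mandibular landmark sets are from different stages")
  }
  grab <- function(expr, trait) {
    tryCatch(expr, error = function(e) {
      warning(sprintf("subject %s, %s: %s", maxilla$subject_id, trait,
                      conditionMessage(e)), call. = FALSE)
      NA_real_
    })
  }
  plane <- grab(occlusal_plane(maxilla, mandible), "occlusal_plane")
  inter <- function(expr, trait) {
    if (!inherits(plane, "occlusal_plane")) return(NA_real_)
    grab(expr, trait)
  }
  out <- data.frame(
    subject_id = maxilla$subject_id,
    stage = maxilla$stage,
    maxillary_intercanine_width = grab(intercanine_width(maxilla), "maxillary_intercanine_width"),
    maxillary_intermolar_width = grab(intermolar_width(maxilla), "maxillary_intermolar_width"),
    maxillary_arch_length = grab(arch_length(maxilla), "maxillary_arch_length"),
    mandibular_intercanine_width = grab(intercanine_width(mandible), "mandibular_intercanine_width"),
    mandibular_intermolar_width = grab(intermolar_width(mandible), "mandibular_intermolar_width"),
    mandibular_arch_length = grab(arch_length(mandible), "mandibular_arch_length"),
    overjet = inter(overjet(maxilla, mandible, plane), "overjet"),
    overbite = inter(overbite(maxilla, mandible, plane), "overbite"),
    molar_relationship_right = inter(molar_relationship(maxilla, mandible, plane, "right"),
                                     "molar_relationship_right"),
    molar_relationship_left = inter(molar_relationship(maxilla, mandible, plane, "left"),
                                    "molar_relationship_left"),
    stringsAsFactors = FALSE
  )
  class(out) <- c("arch_traits", class(out))
  out
}

#' Read landmark coordinates from CSV
#'
#' Expects columns `subject_id, stage, arch, landmark, x, y, z` (one row per
#' landmark, coordinates in mm).
#'
#' @param path CSV file path.
#' @return A list of [landmark_set()] objects, one per subject/stage/arch.
#' @export
read_landmarks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "stage", "arch", "landmark", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("landmark CSV is missing column(s): ", paste(miss, collapse = ", "))
  }
  key <- interaction(df$subject_id, df$stage, df$arch, drop = TRUE)
  lapply(split(df, key), function(d) {
    pts <- as.matrix(d[, c("x", "y", "z")])
    rownames(pts) <- d$landmark
    landmark_set(d$subject_id[1], d$stage[1], d$arch[1], pts)
  })
}

#' Compute the trait table for a collection of landmark sets
#'
#' Pairs maxillary and mandibular [landmark_set()]s by subject and stage and
#' extracts the ten arch traits for each pair.
#'
#' @param landmark_sets List of [landmark_set()] objects, e.g. from
#'   [read_landmarks()].
#' @return Data frame with one row per subject and stage.
#' @export
landmarks_to_traits <- function(landmark_sets) {
  key <- vapply(landmark_sets, function(l) paste(l$subject_id, l$stage, sep = "\r"),
                character(1))
  rows <- lapply(split(landmark_sets, key), function(pair) {
    arches <- vapply(pair, `[[`, character(1), "arch")
    if (!all(c("maxillary", "mandibular") %in% arches)) {
      warning(sprintf("subject %s, %s stage: need both arches, skipping",
                      pair[[1]]$subject_id, pair[[1]]$stage), call. = FALSE)
      return(NULL)
    }
    extract_all_traits(pair[[which(arches == "maxillary")[1]]],
                       pair[[which(arches == "mandibular")[1]]])
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
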