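## Rigid domains, flexible linker and spin-label geometry.
##
## A system is two rigid bodies (one "stationary", one "moving") connected by
## a pseudo-linker: a chain of fixed-length virtual bonds (default 3.8 A per
## residue, the Calpha-Calpha spacing) with bounded deflection pseudo-angles
## and free pseudo-torsions. The moving body's pose is parameterized THROUGH
## the linker: the chain starts at an anchor atom on the stationary body and
## ends at the moving body's anchor atom, so the chain is never broken and
## the translation is a derived quantity (rotation stays free).

#' Construct a rigid body
#'
#' @param atoms data.frame with columns `name`, `resi`, `element`, `x`, `y`,
#'   `z` (Angstrom; arbitrary frame; optionally `resname`).
#' @param rigid_ranges list of integer pairs `c(first, last)` of residue
#'   indices declared rigid; defaults to the full residue range.
#' @param role `"stationary"` or `"moving"`.
#' @return A `rigid_body`; coordinates are stored body-locally, translated so
#'   the geometric centre of the rigid-range atoms is at the origin.
#' @export
rigid_body <- function(atoms, rigid_ranges = NULL, role = c("stationary", "moving")) {
  role <- match.arg(role)
  need <- c("name", "resi", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms must have columns ", paste(need, collapse = ", "))
  if (is.null(rigid_ranges)) rigid_ranges <- list(range(atoms$resi))
  if (!is.list(rigid_ranges)) rigid_ranges <- list(rigid_ranges)
  in_range <- rep(FALSE, nrow(atoms))
  for (rg in rigid_ranges) {
    missing <- setdiff(seq(rg[1], rg[2]), unique(atoms$resi))
    if (length(missing)) {
      stop("residue(s) missing from declared rigid range ", rg[1], "-", rg[2],
           ": ", paste(missing, collapse = ", "))
    }
    in_range <- in_range | (atoms$resi >= rg[1] & atoms$resi <= rg[2])
  }
  ctr <- colMeans(atoms[in_range, c("x", "y", "z")])
  atoms$x <- atoms$x - ctr[1]
  atoms$y <- atoms$y - ctr[2]
  atoms$z <- atoms$z - ctr[3]
  structure(list(atoms = atoms, rigid_ranges = rigid_ranges, role = role),
            class = "rigid_body")
}

#' Load a rigid body from a PDB file
#'
#' @param pdb_path PDB file path (ATOM records; first model; altloc 'A').
#' @param chain chain identifier, or `NULL` for all chains.
#' @param rigid_ranges list of residue-index intervals declared rigid; a
#'   residue absent from the file inside a declared range is a hard error
#'   naming the residue.
#' @param role `"stationary"` or `"moving"`.
#' @return A [rigid_body()] with body-local (rigid-range-centred) coordinates.
#' @export
load_rigid_body <- function(pdb_path, chain = NULL, rigid_ranges = NULL,
                            role = c("stationary", "moving")) {
  df <- read_pdb(pdb_path)
  if (!is.null(chain) && nzchar(chain)) df <- df[df$chain == chain, , drop = FALSE]
  if (!nrow(df)) stop("no atoms for chain '", chain, "' in ", pdb_path)
  rigid_body(df, rigid_ranges = rigid_ranges, role = match.arg(role))
}

body_xyz <- function(body) as.matrix(body$atoms[, c("x", "y", "z")])

element_radius <- function(el) {
  radii <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8)
  r <- radii[toupper(el)]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Collision spheres of a body: coarse = one sphere per residue at the Calpha
# (radius 3.0 A, the default for speed), atom = every atom with per-element
# contact radii.
body_spheres <- function(body, mode = c("coarse", "atom")) {
  mode <- match.arg(mode)
  a <- body$atoms
  if (mode == "coarse") {
    ca <- a[a$name == "CA", , drop = FALSE]
    if (!nrow(ca)) ca <- a   # bodies without explicit CA atoms
    list(xyz = as.matrix(ca[, c("x", "y", "z")]), radii = rep(3.0, nrow(ca)))
  } else {
    list(xyz = as.matrix(a[, c("x", "y", "z")]), radii = element_radius(a$element))
  }
}

radius_of_gyration <- function(body) {
  xyz <- body_xyz(body)
  in_rigid <- rep(FALSE, nrow(xyz))
  for (rg in body$rigid_ranges)
    in_rigid <- in_rigid | (body$atoms$resi >= rg[1] & body$atoms$resi <= rg[2])
  xyz <- xyz[in_rigid, , drop = FALSE]
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

#' Declare a spin-label site
#'
#' The paramagnetic centre of a nitroxide label is represented by a virtual
#' point: either given explicitly, or placed at a fixed offset from the
#' labelled residue along the Calpha->Cbeta direction (falling back to the
#' radial direction from the body centre for Calpha-only models). A point
#' cloud of alternative positions may be supplied; it collapses to its
#' weighted mean for distance evaluation.
#'
#' @param body `"stationary"` or `"moving"`: which body carries the label.
#' @param residue labelled residue index.
#' @param position optional explicit body-frame xyz (Angstrom).
#' @param cloud optional list of `list(xyz =, weight =)` entries; weights must
#'   sum to 1.
#' @param offset length of the virtual side-chain extension in Angstrom
#'   (default 7, approximating the Calpha to N-O bond-centre distance).
#' @return A `label_site` (position resolved when the system is assembled).
#' @export
label_site <- function(body = c("stationary", "moving"), residue,
                       position = NULL, cloud = NULL, offset = 7) {
  body <- match.arg(body)
  if (!is.null(cloud)) {
    w <- vapply(cloud, `[[`, 1, "weight")
    if (abs(sum(w) - 1) > 1e-9) stop("cloud weights must sum to 1")
    position <- colSums(do.call(rbind, lapply(cloud, `[[`, "xyz")) * w)
  }
  structure(list(body = body, residue = as.integer(residue),
                 position = position, cloud = cloud, offset = offset),
            class = "label_site")
}

#' Declare the flexible linker
#'
#' @param n_res number of flexible linker residues; the pseudo-chain has
#'   `n_res + 1` virtual bonds.
#' @param bond_length pseudo-bond length (Angstrom, default 3.8).
#' @param delta_max maximum deflection angle between consecutive pseudo-bonds
#'   in degrees (default 110, i.e. pseudo bond angles of at least 70 degrees).
#' @param anchor_stationary residue index on the stationary body whose Calpha
#'   anchors the chain.
#' @param anchor_moving residue index on the moving body whose Calpha the
#'   chain ends at.
#' @return A `linker_spec`.
#' @export
linker_spec <- function(n_res, bond_length = 3.8, delta_max = 110,
                        anchor_stationary, anchor_moving) {
  stopifnot(n_res >= 0, bond_length > 0, delta_max > 0, delta_max <= 180)
  structure(list(n_res = as.integer(n_res), bond_length = bond_length,
                 delta_max = deg2rad(delta_max),
                 anchor_stationary = as.integer(anchor_stationary),
                 anchor_moving = as.integer(anchor_moving)),
            class = "linker_spec")
}

resolve_atom <- function(body, residue, name = "CA") {
  a <- body$atoms
  i <- which(a$resi == residue & a$name == name)
  if (!length(i)) i <- which(a$resi == residue)
  if (!length(i)) stop("residue ", residue, " not found in ", body$role, " body")
  as.numeric(a[i[1], c("x", "y", "z")])
}

resolve_label_position <- function(body, site) {
  if (!is.null(site$position)) return(as.numeric(site$position))
  ca <- resolve_atom(body, site$residue, "CA")
  cb <- tryCatch(resolve_atom(body, site$residue, "CB"), error = function(e) NULL)
  has_cb <- any(body$atoms$resi == site$residue & body$atoms$name == "CB")
  dir <- if (has_cb) cb - ca else ca
  if (vnorm(dir) < 1e-9) dir <- c(1, 0, 0)
  ca + site$offset * unit(dir)
}

#' Assemble a two-body system
#'
#' @param stationary,moving [rigid_body()] objects with the matching roles.
#' @param linker a [linker_spec()].
#' @param labels named list of [label_site()]s.
#' @param pairs data.frame with columns `label` (restraint name), `a`, `b`
#'   (names of label sites, which must sit on different bodies).
#' @return A `conf_system` with label positions and linker anchors resolved
#'   to body-frame coordinates.
#' @export
conf_system <- function(stationary, moving, linker, labels, pairs) {
  stopifnot(inherits(stationary, "rigid_body"), inherits(moving, "rigid_body"),
            inherits(linker, "linker_spec"))
  if (stationary$role != "stationary" || moving$role != "moving")
    stop("body roles must be 'stationary' and 'moving'")
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("labels must be a named list")
  pos <- lapply(labels, function(s) {
    b <- if (s$body == "stationary") stationary else moving
    resolve_label_position(b, s)
  })
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "a", "b") %in% names(pairs)))
  for (i in seq_len(nrow(pairs))) {
    for (nm in c(pairs$a[i], pairs$b[i]))
      if (!nm %in% names(labels))
        stop("restraint '", pairs$label[i], "' references undeclared label '", nm, "'")
    if (labels[[pairs$a[i]]]$body == labels[[pairs$b[i]]]$body)
      stop("restraint '", pairs$label[i], "' must connect labels on different bodies")
  }
  structure(list(
    stationary = stationary, moving = moving, linker = linker,
    labels = labels, label_positions = pos, pairs = pairs,
    anchor_stationary = resolve_atom(stationary, linker$anchor_stationary),
    anchor_moving = resolve_atom(moving, linker$anchor_moving)
  ), class = "conf_system")
}

n_bonds <- function(system) system$linker$n_res + 1L

## ---- pseudo-chain geometry -------------------------------------------------

# Unit direction from polar angle alpha (from +z) and azimuth beta.
dir_from_angles <- function(alpha, beta) {
  c(sin(alpha) * cos(beta), sin(alpha) * sin(beta), cos(alpha))
}

# Deflect unit direction d by angle delta, torsion phi (both radians),
# using the deterministic perpendicular frame of perp_frame().
deflect_dir <- function(d, delta, phi) {
  fr <- perp_frame(d)
  cos(delta) * d + sin(delta) * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
}

# Chain nodes p_1..p_nb from the stationary anchor; the last node is the
# world position of the moving body's anchor atom.
chain_points <- function(anchor, chain, nb, bond_length) {
  pts <- matrix(0, nb, 3)
  d <- dir_from_angles(chain$alpha, chain$beta)
  p <- anchor + bond_length * d
  pts[1, ] <- p
  if (nb > 1) {
    for (i in 2:nb) {
      d <- deflect_dir(d, chain$delta[i - 1], chain$phi[i - 1])
      p <- p + bond_length * d
      pts[i, ] <- p
    }
  }
  pts
}

#' Create a conformer from sampling parameters
#'
#' Derives the moving body's translation from the pseudo-chain (so the linker
#' is closed by construction), stores the pose, and computes all pair
#' distances.
#'
#' @param system a [conf_system()].
#' @param quat unit quaternion (w, x, y, z) rotating the moving body.
#' @param chain list with `alpha`, `beta` (first-bond direction, radians),
#'   `delta`, `phi` (deflections in `[0, delta_max]` and torsions, radians,
#'   length `n_bonds - 1` each).
#' @return A `conformer` with fields `quat`, `translation`, `chain`,
#'   `pair_distances`, `target_value` (NA until evaluated) and
#'   `relative_probability` (NA until weighted).
#' @export
make_conformer <- function(system, quat, chain) {
  quat <- quat_normalize(quat)
  nb <- n_bonds(system)
  pts <- chain_points(system$anchor_stationary, chain, nb, system$linker$bond_length)
  R <- quat_to_mat(quat)
  translation <- pts[nb, ] - as.numeric(R %*% system$anchor_moving)
  cf <- structure(list(quat = quat, translation = translation, chain = chain,
                       pair_distances = NULL, target_value = NA_real_,
                       relative_probability = NA_real_),
                  class = "conformer")
  cf$pair_distances <- conformer_distances(system, cf)
  cf
}

#' Create a conformer from an explicit pose
#'
#' Bypasses the linker parameterization; used for tests and for placing
#' externally defined poses. No linker nodes are available for such a
#' conformer and chain closure is not guaranteed.
#'
#' @inheritParams make_conformer
#' @param translation xyz translation (Angstrom) of the moving body.
#' @return A `conformer`.
#' @export
pose_conformer <- function(system, quat, translation) {
  cf <- structure(list(quat = quat_normalize(quat),
                       translation = as.numeric(translation), chain = NULL,
                       pair_distances = NULL, target_value = NA_real_,
                       relative_probability = NA_real_),
                  class = "conformer")
  cf$pair_distances <- conformer_distances(system, cf)
  cf
}

#' World coordinates of a placed conformer
#'
#' @param system a [conf_system()].
#' @param conformer a `conformer`.
#' @return List with matrices `stationary` (unchanged body-local coordinates,
#'   which define the world frame), `moving` (rotated + translated) and
#'   `linker` (pseudo-chain nodes, `NULL` for pose-only conformers).
#' @export
place_conformer <- function(system, conformer) {
  R <- quat_to_mat(conformer$quat)
  mv <- body_xyz(system$moving) %*% t(R)
  mv <- sweep(mv, 2, conformer$translation, `+`)
  lk <- NULL
  if (!is.null(conformer$chain)) {
    pts <- chain_points(system$anchor_stationary, conformer$chain,
                        n_bonds(system), system$linker$bond_length)
    # interior nodes only: the last node is the moving anchor itself
    lk <- pts[-nrow(pts), , drop = FALSE]
    if (!nrow(lk)) lk <- NULL
  }
  list(stationary = body_xyz(system$stationary), moving = mv, linker = lk)
}

#' World positions of all label sites for a conformer
#'
#' @inheritParams place_conformer
#' @return Matrix (one row per label, named) of xyz positions; cloud labels
#'   are represented by their weighted-mean point.
#' @export
label_positions <- function(system, conformer) {
  R <- quat_to_mat(conformer$quat)
  out <- t(vapply(names(system$labels), function(nm) {
    s <- system$labels[[nm]]
    p <- system$label_positions[[nm]]
    if (s$body == "moving") as.numeric(R %*% p) + conformer$translation else p
  }, numeric(3)))
  rownames(out) <- names(system$labels)
  out
}

#' Distance between two label sites in a placed conformer
#'
#' @inheritParams place_conformer
#' @param a,b label-site names.
#' @return Euclidean distance in Angstrom.
#' @export
label_distance <- function(system, conformer, a, b) {
  lp <- label_positions(system, conformer)
  vnorm(lp[a, ] - lp[b, ])
}

conformer_distances <- function(system, conformer) {
  lp <- label_positions(system, conformer)
  d <- vapply(seq_len(nrow(system$pairs)), function(i) {
    vnorm(lp[system$pairs$a[i], ] - lp[system$pairs$b[i], ])
  }, 0)
  stats::setNames(d, system$pairs$label)
}

#' Soft-sphere steric overlap score between two bodies
#'
#' Sum over inter-body sphere pairs of `k * max(0, d_min - d)^2` with `d_min`
#' the sum of the two contact radii; zero iff no pair is closer than contact.
#'
#' @param xyz_a,xyz_b coordinate matrices (rows = spheres) of the two bodies.
#' @param radii_a,radii_b contact radii (Angstrom).
#' @param k stiffness (Angstrom^-2 * Angstrom^2, default 1).
#' @return Score in Angstrom^2.
#' @export
steric_score <- function(xyz_a, xyz_b, radii_a, radii_b, k = 1) {
  xyz_a <- rbind(xyz_a); xyz_b <- rbind(xyz_b)
  d2 <- outer(rowSums(xyz_a^2), rowSums(xyz_b^2), `+`) - 2 * xyz_a %*% t(xyz_b)
  dmin <- outer(radii_a, radii_b, `+`)
  ov <- dmin - sqrt(pmax(0, d2))
  k * sum(pmax(0, ov)^2)
}

# Steric score of a placed conformer (inter-body only; the pseudo-linker
# carries no spheres).
conformer_steric <- function(system, conformer, mode = "coarse", k = 1) {
  sa <- body_spheres(system$stationary, mode)
  sb <- body_spheres(system$moving, mode)
  R <- quat_to_mat(conformer$quat)
  mb <- sweep(sb$xyz %*% t(R), 2, conformer$translation, `+`)
  steric_score(sa$xyz, mb, sa$radii, sb$radii, k = k)
}
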