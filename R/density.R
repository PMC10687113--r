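## Conformation-space density maps.
##
## With all conformers expressed in the stationary body's frame, the moving
## body's occupancy is rendered as isotropic 3D Gaussians (one per conformer
## at the moving body's geometric centre, or one per residue/atom), with peak
## amplitude equal to the conformer's relative probability, evaluated on an
## evenly spaced grid (default 1 A) within a truncation radius and merged by
## taking the maximum at each grid point.

#' Least-squares rigid superposition (Kabsch)
#'
#' @param P,Q n x 3 coordinate matrices; `P` is moved onto `Q`.
#' @return List with rotation `R` (3x3, proper), translation `t`, and the
#'   post-fit `rmsd`; apply as `sweep(P %*% t(R), 2, t, "+")`... see
#'   `$transform(X)`.
#' @export
kabsch <- function(P, Q) {
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  s <- svd(t(P0) %*% Q0)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  transform <- function(X) sweep(sweep(X, 2, cp) %*% t(R), 2, cq, `+`)
  rmsd <- sqrt(mean(rowSums((transform(P) - Q)^2)))
  list(R = R, t = cq - as.numeric(R %*% cp), rmsd = rmsd, transform = transform)
}

#' Superpose conformer models on the stationary body
#'
#' Each model's stationary-body atoms are least-squares fitted onto the
#' reference body coordinates and the fitted rigid transform is applied to
#' all of the model's coordinates, bringing the whole ensemble into the
#' stationary frame. For models produced by [place_conformer()] this is the
#' identity (they are already in that frame); the post-fit stationary RMSD is
#' ~0 in all cases because the rigid body is internally identical.
#'
#' @param models list of coordinate sets as returned by [place_conformer()]
#'   (each a list with `stationary`, `moving`, optionally `linker`).
#' @param stationary the reference [rigid_body()].
#' @return The superposed models, each with an `rmsd_stationary` element.
#' @export
superpose_on_stationary <- function(models, stationary) {
  ref <- body_xyz(stationary)
  lapply(models, function(m) {
    fit <- kabsch(m$stationary, ref)
    out <- list(stationary = fit$transform(m$stationary),
                moving = fit$transform(m$moving),
                linker = if (!is.null(m$linker)) fit$transform(m$linker),
                rmsd_stationary = fit$rmsd)
    out
  })
}

#' Build the max-merged density grid of the moving body
#'
#' @param ensemble a weighted `conf_ensemble` (conformers in the stationary
#'   frame, `relative_probability` set; see [assign_relative()]).
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param sigma_density Gaussian sd in Angstrom; default is the radius of
#'   gyration of the moving body's rigid part (single mode) or 2.2 Angstrom
#'   (per-residue mode).
#' @param truncation evaluation radius in multiples of sigma (default 3).
#' @param mode `"single"` (one Gaussian at the moving body's geometric
#'   centre; default) or `"per_residue"` (one Gaussian per collision sphere,
#'   for non-globular bodies).
#' @return A `density_grid`: `origin`, `spacing`, `shape`, and `values`
#'   (3D array, all in `[0, 1]`).
#' @export
build_density_grid <- function(ensemble, spacing = 1.0, sigma_density = NULL,
                               truncation = 3, mode = c("single", "per_residue")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "conf_ensemble"), spacing > 0, truncation > 0)
  if (!is.null(sigma_density) && sigma_density <= 0) stop("sigma_density must be > 0")
  sigma <- sigma_density %||%
    if (mode == "single") radius_of_gyration(ensemble$system$moving) else 2.2
  amp <- vapply(ensemble$conformers, `[[`, 0, "relative_probability")
  if (all(is.na(amp))) amp <- rep(1, length(amp))
  amp[is.na(amp)] <- 0

  # Gaussian centres per conformer: the moving body's local frame is centred
  # on its rigid part, so the single-mode centre is just the translation.
  centres <- lapply(seq_along(ensemble$conformers), function(i) {
    cf <- ensemble$conformers[[i]]
    if (mode == "single") {
      matrix(cf$translation, 1, 3)
    } else {
      sp <- body_spheres(ensemble$system$moving, "coarse")
      R <- quat_to_mat(cf$quat)
      sweep(sp$xyz %*% t(R), 2, cf$translation, `+`)
    }
  })
  all_c <- do.call(rbind, centres)
  pad <- truncation * sigma + spacing
  origin <- floor((apply(all_c, 2, min) - pad) / spacing) * spacing
  upper <- apply(all_c, 2, max) + pad
  shape <- pmax(2L, as.integer(ceiling((upper - origin) / spacing)) + 1L)
  ax <- lapply(1:3, function(k) origin[k] + spacing * (seq_len(shape[k]) - 1L))
  values <- array(0, dim = shape)
  tr2 <- (truncation * sigma)^2

  for (i in seq_along(centres)) {
    if (amp[i] <= 0) next
    cm <- centres[[i]]
    for (j in seq_len(nrow(cm))) {
      ctr <- cm[j, ]
      ix <- which(abs(ax[[1]] - ctr[1]) <= truncation * sigma)
      iy <- which(abs(ax[[2]] - ctr[2]) <= truncation * sigma)
      iz <- which(abs(ax[[3]] - ctr[3]) <= truncation * sigma)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ax[[1]][ix] - ctr[1])^2
      dy2 <- (ax[[2]][iy] - ctr[2])^2
      dz2 <- (ax[[3]][iz] - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
      g <- amp[i] * exp(-d2 / (2 * sigma^2))
      g[d2 > tr2] <- 0
      sub <- values[ix, iy, iz, drop = FALSE]
      values[ix, iy, iz] <- array(pmax(sub, g), dim = dim(g))
    }
  }
  structure(list(origin = origin, spacing = spacing, shape = shape,
                 values = values, sigma = sigma, truncation = truncation,
                 mode = mode),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid: %d x %d x %d at %.2f A, max %.3f>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing, max(x$values)))
  invisible(x)
}

#' Write a density grid as a volume file
#'
#' Writes either an OpenDX scalar field (text) or a CCP4/MRC-2000 map (mode 2
#' float, little-endian), both loadable by PyMOL and ChimeraX in the same
#' frame as ensembles written by [write_ensemble_pdb()].
#'
#' @param grid a [build_density_grid()] object.
#' @param path output path.
#' @param format `"dx"` or `"mrc"`; default guessed from the file extension.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path, format = c("auto", "dx", "mrc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(mrc|map|ccp4)$", path, ignore.case = TRUE)) "mrc" else "dx"
  }
  if (format == "dx") write_dx(grid, path) else write_mrc(grid, path)
  invisible(path)
}

write_dx <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- grid$shape
  writeLines(c(
    "# OpenDX density written by confspace",
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]),
    sprintf("delta %.6f 0 0", grid$spacing),
    sprintf("delta 0 %.6f 0", grid$spacing),
    sprintf("delta 0 0 %.6f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))
  ), con)
  # DX data order: z varies fastest (column-major over the permuted array)
  vals <- as.numeric(aperm(grid$values, c(3, 2, 1)))
  pad <- (3 - length(vals) %% 3) %% 3
  vv <- c(vals, rep(NA_real_, pad))
  m <- matrix(vv, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(row) {
    paste(sprintf("%.6e", row[!is.na(row)]), collapse = " ")
  })
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
}

write_mrc <- function(grid, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- grid$shape
  v <- grid$values
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(n)                              # NX NY NZ (columns, rows, sections)
  wi(2)                              # MODE 2 = float32
  wi(c(0, 0, 0))                     # NXSTART NYSTART NZSTART
  wi(n)                              # MX MY MZ
  wf(n * grid$spacing)               # CELLA
  wf(c(90, 90, 90))                  # CELLB
  wi(c(1, 2, 3))                     # MAPC MAPR MAPS
  wf(c(min(v), max(v), mean(v)))     # DMIN DMAX DMEAN
  wi(1)                              # ISPG
  wi(0)                              # NSYMBT
  wi(rep(0, 25))                     # EXTRA (words 26-50)
  wf(grid$origin)                    # ORIGIN (MRC2000, words 50-52)
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.numeric(v)))       # RMS
  wi(0)                              # NLABL
  writeBin(raw(800), con)            # labels
  # data: column (x) fastest, section (z) slowest = R's native array order
  writeBin(as.numeric(v), con, size = 4, endian = "little")
}

#' Read a volume file written by [write_volume()]
#'
#' @param path file path.
#' @param format `"dx"`, `"mrc"`, or `"auto"` (extension-based).
#' @return A `density_grid` (values as stored; float precision for MRC).
#' @export
read_volume <- function(path, format = c("auto", "dx", "mrc")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(mrc|map|ccp4)$", path, ignore.case = TRUE)) "mrc" else "dx"
  }
  if (format == "dx") read_dx(path) else read_mrc(path)
}

read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cnt <- as.integer(strsplit(sub(".*counts ", "", grep("gridpositions", lines, value = TRUE)[1]), " +")[[1]])
  origin <- as.numeric(strsplit(sub("^origin ", "", grep("^origin", lines, value = TRUE)[1]), " +")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  spacing <- as.numeric(strsplit(sub("^delta ", "", deltas[1]), " +")[[1]])[1]
  i0 <- grep("data follows", lines)[1]
  i1 <- grep("attribute", lines)[1]
  vals <- as.numeric(unlist(strsplit(trimws(lines[(i0 + 1):(i1 - 1)]), " +")))
  v <- aperm(array(vals, dim = rev(cnt)), c(3, 2, 1))
  structure(list(origin = origin, spacing = spacing, shape = cnt, values = v),
            class = "density_grid")
}

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  rf <- function(k) readBin(con, "numeric", n = k, size = 4, endian = "little")
  n <- ri(3)
  mode <- ri(1)
  if (mode != 2) stop("unsupported MRC mode ", mode)
  ri(3)            # nstart
  ri(3)            # mx my mz
  cella <- rf(3)
  rf(3)            # cellb
  ri(3)            # mapc mapr maps
  rf(3)            # dmin dmax dmean
  ri(2)            # ispg nsymbt
  ri(25)           # extra
  origin <- rf(3)
  seek(con, 1024)
  v <- array(rf(prod(n)), dim = n)
  structure(list(origin = origin, spacing = cella[1] / n[1], shape = n,
                 values = v),
            class = "density_grid")
}
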