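## Minimal PDB reading/writing (ATOM records only, first model, altloc 'A'
## preferred). No pre-installed R package in this stack parses PDB, so the
## fixed-column format is handled here directly.

#' Read ATOM records from a PDB file
#'
#' @param path PDB file path.
#' @return data.frame with columns `name`, `altloc`, `resname`, `chain`,
#'   `resi`, `x`, `y`, `z`, `element`. Only the first MODEL is kept; where
#'   alternate locations exist, blank or 'A' is preferred.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # first model only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (!length(atom)) stop("no ATOM records in ", path)
  sub_field <- function(a, b) trimws(substring(atom, a, b))
  df <- data.frame(
    name    = sub_field(13, 16),
    altloc  = sub_field(17, 17),
    resname = sub_field(18, 20),
    chain   = sub_field(22, 22),
    resi    = as.integer(sub_field(23, 26)),
    x       = as.numeric(sub_field(31, 38)),
    y       = as.numeric(sub_field(39, 46)),
    z       = as.numeric(sub_field(47, 54)),
    element = sub_field(77, 78),
    stringsAsFactors = FALSE
  )
  df <- df[df$altloc %in% c("", "A"), , drop = FALSE]
  # fall back to first character of the atom name when element is absent
  noel <- !nzchar(df$element)
  df$element[noel] <- substring(gsub("[0-9]", "", df$name[noel]), 1, 1)
  rownames(df) <- NULL
  df
}

format_atom_line <- function(serial, name, resname, chain, resi, xyz,
                             occ = 1, b = 0, element = "C") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else substr(name, 1, 4)
  sprintf("ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm, " ", substr(resname, 1, 3), chain, resi %% 10000L,
          xyz[1], xyz[2], xyz[3], occ, b, element)
}

#' Write a conformer ensemble as a multi-model PDB
#'
#' One MODEL/ENDMDL block per conformer: the stationary body (chain A),
#' linker pseudo-atoms (chain L) and the moving body (chain B), all in the
#' stationary body's frame so the file shares coordinates with density maps
#' written by [write_volume()]. The relative probability, if assigned, is
#' stored in the occupancy column.
#'
#' @param ensemble a `conf_ensemble` from [run_protocol()].
#' @param path output path.
#' @param system the `conf_system`; defaults to the one stored in `ensemble`.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, system = ensemble$system) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("REMARK   confspace ensemble (stationary chain A, linker chain L, moving chain B)", con)
  body_lines <- function(df, chain, xyz, occ, serial0) {
    resname <- df$resname
    if (is.null(resname)) resname <- rep("ALA", nrow(df))
    vapply(seq_len(nrow(df)), function(i) {
      format_atom_line(serial0 + i, df$name[i], resname[i], chain,
                       df$resi[i], xyz[i, ], occ = occ,
                       element = df$element[i])
    }, "")
  }
  for (m in seq_along(ensemble$conformers)) {
    cf <- ensemble$conformers[[m]]
    coords <- place_conformer(system, cf)
    occ <- cf$relative_probability
    if (is.na(occ)) occ <- 1
    writeLines(sprintf("MODEL     %4d", m), con)
    s <- system$stationary$atoms
    writeLines(body_lines(s, "A", coords$stationary, occ, 0L), con)
    serial <- nrow(s)
    if (!is.null(coords$linker)) {
      lk <- coords$linker
      writeLines(vapply(seq_len(nrow(lk)), function(i) {
        format_atom_line(serial + i, "CA", "GLY", "L", i, lk[i, ], occ = occ)
      }, ""), con)
      serial <- serial + nrow(lk)
    }
    mv <- system$moving$atoms
    writeLines(body_lines(mv, "B", coords$moving, occ, serial), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
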