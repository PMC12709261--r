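#' Load a trajectory from disk
#'
#' Reads a multi-model PDB, a (possibly multi-frame) GRO file, or a
#' structure file (PDB/GRO) paired with a DCD coordinate trajectory.
#' Coordinates are converted to nanometres (PDB is Angstrom-native; GRO and
#' DCD-with-GRO are taken as nm, DCD paired with a PDB as Angstrom).
#'
#' @param structure_path Path to a PDB or GRO file (topology; for PDB, may
#'   itself hold multiple MODELs).
#' @param trajectory_path Optional DCD file supplying the frames.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(structure_path, trajectory_path = NULL) {
  ext <- tolower(tools::file_ext(structure_path))
  base <- switch(ext,
    pdb = .read_pdb_trajectory(structure_path),
    gro = .read_gro_trajectory(structure_path),
    abort(sprintf("unrecognized structure format: .%s (use PDB or GRO)", ext))
  )
  if (is.null(trajectory_path)) return(base)
  dext <- tolower(tools::file_ext(trajectory_path))
  if (dext != "dcd") {
    abort(sprintf("unrecognized trajectory format: .%s (use DCD)", dext))
  }
  xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
  if (ncol(xyz) != 3L * n_atoms(base)) {
    abort(sprintf(
      "atom-count mismatch: topology has %d atoms, DCD frames have %d",
      n_atoms(base), ncol(xyz) / 3L
    ))
  }
  scale <- if (ext == "pdb") 0.1 else 1.0  # DCD carries the writer's units
  coords <- array(NA_real_, c(nrow(xyz), n_atoms(base), 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, ncol(xyz), by = 3L)] * scale
  trajectory(coords, base$topology, box = base$box[1, ])
}

.read_pdb_trajectory <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- pdb$atom
  elem <- atoms$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- .element_from_atom_name(atoms$elety)
  } else {
    blank <- is.na(elem) | elem == ""
    elem[blank] <- .element_from_atom_name(atoms$elety[blank])
  }
  chains <- atoms$chain
  chains[is.na(chains) | chains == ""] <- "A"
  topology <- tibble(
    chain_id = chains,
    residue_index = .renumber_within_chain(chains, atoms$resno),
    residue_name = atoms$resid,
    atom_name = atoms$elety,
    element = elem
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  coords <- array(NA_real_, c(nrow(xyz), nrow(topology), 3L))
  for (d in 1:3) coords[, , d] <- xyz[, seq(d, ncol(xyz), by = 3L)] * 0.1
  trajectory(coords, topology)
}

# residue indices 1-based and contiguous within each chain, preserving order
.renumber_within_chain <- function(chains, resno) {
  key <- paste(chains, resno, sep = "\r")
  out <- integer(length(key))
  for (ch in unique(chains)) {
    sel <- chains == ch
    out[sel] <- match(key[sel], unique(key[sel]))
  }
  out
}

.read_gro_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); topology <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    natoms <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(natoms)) abort("malformed GRO file: bad atom count line")
    atom_lines <- lines[i + 1L + seq_len(natoms)]
    box_line <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]),
                                    "\\s+")[[1]])
    resno <- as.integer(substr(atom_lines, 1, 5))
    resnm <- trimws(substr(atom_lines, 6, 10))
    atnm <- trimws(substr(atom_lines, 11, 15))
    x <- as.numeric(substr(atom_lines, 21, 28))
    y <- as.numeric(substr(atom_lines, 29, 36))
    z <- as.numeric(substr(atom_lines, 37, 44))
    if (is.null(topology)) {
      # GRO has no chain field: a drop in residue numbering starts a new chain
      reset <- c(FALSE, diff(resno) < 0)
      chain_idx <- cumsum(reset) + 1L
      chains <- LETTERS[pmin(chain_idx, 26L)]
      topology <- tibble(
        chain_id = chains,
        residue_index = .renumber_within_chain(chains, resno),
        residue_name = resnm,
        atom_name = atnm,
        element = .element_from_atom_name(atnm)
      )
    }
    frames[[length(frames) + 1L]] <- cbind(x, y, z)
    boxes[[length(boxes) + 1L]] <- box_line[1:3]
    i <- i + 3L + natoms
  }
  coords <- array(NA_real_, c(length(frames), nrow(topology), 3L))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, topology, box = do.call(rbind, boxes))
}

#' Write a trajectory to disk
#'
#' Multi-model PDB (coordinates written in Angstrom at 1e-3 A precision,
#' i.e. 1e-4 nm) or multi-frame GRO (nm, 1e-3 nm precision).
#'
#' @param traj A [trajectory()].
#' @param path Output path; format chosen by extension (.pdb or .gro).
#' @export
write_trajectory <- function(traj, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pdb = .write_pdb_trajectory(traj, path),
    gro = .write_gro_trajectory(traj, path),
    abort(sprintf("unsupported output format: .%s", ext))
  )
  invisible(path)
}

.write_pdb_trajectory <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  nm <- ifelse(nchar(top$atom_name) < 4,
               sprintf(" %-3s", top$atom_name), top$atom_name)
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- frame_coords(traj, f) * 10  # nm -> Angstrom
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(top)) %% 100000L, nm, top$residue_name,
      substr(top$chain_id, 1, 1), top$residue_index %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, toupper(top$element)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
}

.write_gro_trajectory <- function(traj, path) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  # global residue numbering restarting per chain, as GROMACS writes it
  for (f in seq_len(n_frames(traj))) {
    writeLines(sprintf("synthetic trajectory, frame %d", f), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    xyz <- frame_coords(traj, f)
    lines <- sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      top$residue_index %% 100000L, top$residue_name, top$atom_name,
      seq_len(nrow(top)) %% 100000L, xyz[, 1], xyz[, 2], xyz[, 3]
    )
    writeLines(lines, con)
    box <- if (is.null(traj$box)) c(0, 0, 0) else traj$box[f, ]
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
}

# ---------------------------------------------------------------------------

# 8-state DSSP -> 3-state reduction: helices (H,G,I) -> H; strands (E,B) -> E;
# everything else (T,S,C,~,blank) -> C
.reduce_dssp <- function(chars) {
  out <- rep("C", length(chars))
  out[chars %in% c("H", "G", "I")] <- "H"
  out[chars %in% c("E", "B")] <- "E"
  out
}

#' Load a secondary-structure series from DSSP output
#'
#' Two dialects are supported. Plain per-frame strings: each frame is
#' `n_chains` lines of `n_residues` 8-state characters (lines starting with
#' `#` and blank lines are ignored). GROMACS `do_dssp` `.xpm`: the matrix is
#' parsed with its embedded legend, chain-separator rows are dropped, and
#' rows are mapped back to residues. In both cases the 8-state alphabet is
#' reduced to {H, E, C}: (H, G, I) -> H, (E, B) -> E, rest -> C.
#'
#' @param path DSSP strings file or GROMACS `.xpm` file.
#' @param n_chains,n_residues Expected dimensions.
#' @return An [ss_series()] with `source = "dssp_file"`.
#' @export
load_dssp_table <- function(path, n_chains, n_residues) {
  if (tolower(tools::file_ext(path)) == "xpm") {
    return(.load_dssp_xpm(path, n_chains, n_residues))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) %% n_chains != 0L) {
    abort(sprintf(
      "DSSP file has %d record lines, not a multiple of n_chains = %d",
      length(lines), n_chains
    ))
  }
  nf <- length(lines) %/% n_chains
  bad <- nchar(lines) != n_residues
  if (any(bad)) {
    abort(sprintf(
      "DSSP line length %d does not match n_residues = %d",
      nchar(lines[which(bad)[1]]), n_residues
    ))
  }
  arr <- array("C", c(nf, n_chains, n_residues))
  for (f in seq_len(nf)) {
    for (ch in seq_len(n_chains)) {
      chars <- strsplit(lines[(f - 1L) * n_chains + ch], "")[[1]]
      arr[f, ch, ] <- .reduce_dssp(toupper(chars))
    }
  }
  ss_series(arr, source = "dssp_file")
}

.load_dssp_xpm <- function(path, n_chains, n_residues) {
  lines <- readLines(path)
  qlines <- regmatches(lines, regexpr('"[^"]*"', lines))
  qlines <- substr(qlines, 2, nchar(qlines) - 1)
  hdr <- as.integer(strsplit(trimws(qlines[1]), "\\s+")[[1]])
  n_cols <- hdr[1]; n_rows <- hdr[2]; n_colors <- hdr[3]; cpp <- hdr[4]
  if (cpp != 1L) abort("only 1 character-per-pixel xpm matrices are supported")
  is_legend <- grepl('^. +c #', qlines)
  legend_idx <- which(is_legend)[seq_len(n_colors)]
  code <- substr(qlines[legend_idx], 1, 1)
  # the state label sits in the /* "..." */ comment on the same source line
  src <- lines[regexpr('"[^"]*"', lines) > 0]
  legend_src <- src[match(qlines[legend_idx], substr(
    regmatches(src, regexpr('"[^"]*"', src)), 2,
    nchar(regmatches(src, regexpr('"[^"]*"', src))) - 1))]
  label <- sub('.*\\/\\*\\s*"([^"]*)"\\s*\\*\\/.*', "\\1", legend_src)
  map <- setNames(vapply(label, function(lb) {
    switch(toupper(substr(lb, 1, 3)),
      "A-H" = "H", "3-H" = "G", "5-H" = "I",
      "B-S" = "E", "B-B" = "B",
      "TUR" = "T", "BEN" = "S", "COI" = "C", "CHA" = "=", "~")
  }, ""), code)
  data_rows <- tail(qlines, n_rows)
  # xpm rows run top-to-bottom = last y value (residue) first
  mat <- do.call(rbind, lapply(rev(data_rows), function(s) strsplit(s, "")[[1]]))
  ss8 <- matrix(map[mat], nrow(mat), ncol(mat))
  keep <- ss8[, 1] != "="  # drop chain-separator rows
  ss8 <- ss8[keep, , drop = FALSE]
  if (nrow(ss8) != n_chains * n_residues) {
    abort(sprintf(
      "xpm matrix has %d residue rows, expected %d chains x %d residues",
      nrow(ss8), n_chains, n_residues
    ))
  }
  arr <- array("C", c(n_cols, n_chains, n_residues))
  for (ch in seq_len(n_chains)) {
    rows <- (ch - 1L) * n_residues + seq_len(n_residues)
    for (r in seq_len(n_residues)) {
      arr[, ch, r] <- .reduce_dssp(ss8[rows[r], ])
    }
  }
  ss_series(arr, source = "dssp_file")
}

#' Write a secondary-structure series as per-frame strings
#'
#' Inverse of the plain-string dialect read by [load_dssp_table()].
#'
#' @param series An [ss_series()].
#' @param path Output file.
#' @export
write_ss_series <- function(series, path) {
  d <- dim(series)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(d[1])) {
    writeLines(sprintf("# frame %d", f), con)
    for (ch in seq_len(d[2])) {
      writeLines(paste(series[f, ch, ], collapse = ""), con)
    }
  }
  invisible(path)
}

#' Write a result table to CSV or JSON
#'
#' @param records Data frame of results (non-empty).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @export
write_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (!nrow(records)) abort("refusing to write an empty table")
  if (format == "csv") {
    readr::write_csv(records, path)
  } else {
    jsonlite::write_json(records, path, digits = NA, auto_unbox = FALSE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a result table written by [write_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from extension.
#' @return A tibble.
#' @export
read_table_file <- function(path, format = NULL) {
  format <- format %||% tolower(tools::file_ext(path))
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE)
  } else {
    as_tibble(jsonlite::fromJSON(path))
  }
}
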