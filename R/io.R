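# Plain-text interchange formats: photon tables (CSV), ground-truth tables
# (CSV), spectra (two-column CSV), multi-frame XYZ trajectories + group maps.

#' Write / read a cohort of photon streams as a CSV photon table
#'
#' Columns: `molecule_id`, `macro_time_s`, `micro_time_ns`. TCSPC metadata
#' (window and period, identical across the cohort) is stored in a `#`
#' header comment.
#'
#' @param streams list of [PhotonStream-class] objects.
#' @param path output file.
#' @return `writePhotonTable`: invisibly, the path.
#' @export
writePhotonTable <- function(streams, path) {
  .stopIfNot(length(streams) > 0, "no streams to write")
  w <- streams[[1]]@tcspcWindow
  p <- streams[[1]]@excitationPeriod
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tcspc_window_ns=%.17g excitation_period_ns=%.17g", w, p), con)
  writeLines("molecule_id,macro_time_s,micro_time_ns", con)
  for (s in streams) {
    if (!length(s@macroTime)) next
    writeLines(sprintf("%s,%.9g,%.9g", s@moleculeId, s@macroTime, s@microTime), con)
  }
  invisible(path)
}

#' @rdname writePhotonTable
#' @return `readPhotonTable`: list of [PhotonStream-class] objects.
#' @export
readPhotonTable <- function(path) {
  .stopIfNot(file.exists(path), "file not found: %s", path)
  hdr <- readLines(path, n = 1L)
  .stopIfNot(grepl("^# tcspc_window_ns=", hdr),
             "missing TCSPC metadata header in %s", path)
  nums <- c(as.numeric(sub(".*tcspc_window_ns=([^ ]+).*", "\\1", hdr)),
            as.numeric(sub(".*excitation_period_ns=([^ ]+).*", "\\1", hdr)))
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .stopIfNot(all(c("molecule_id", "macro_time_s", "micro_time_ns") %in% names(tab)),
             "photon table %s lacks the documented columns", path)
  lapply(split(tab, tab$molecule_id), function(d) {
    d <- d[order(d$macro_time_s), ]
    PhotonStream(d$molecule_id[1], d$macro_time_s, d$micro_time_ns,
                 tcspcWindow = nums[1], excitationPeriod = nums[2])
  })
}

#' Write / read a two-column spectrum table
#'
#' @param spectrum data.frame with `wavelength_nm`, `value`.
#' @param path file path.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.csv(spectrum[, c("wavelength_nm", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
  .stopIfNot(file.exists(path), "file not found: %s", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  .stopIfNot(all(c("wavelength_nm", "value") %in% names(tab)),
             "spectrum %s lacks columns wavelength_nm, value", path)
  .stopIfNot(all(diff(tab$wavelength_nm) > 0),
             "wavelength grid in %s must be strictly increasing", path)
  tab
}

#' Write a trajectory as multi-frame XYZ plus a group map
#'
#' The XYZ file holds standard frame blocks (atom count line, comment line,
#' then `label x y z` with coordinates in nm, the element field reused as the
#' pseudo-atom group label). The group map is a CSV with columns
#' `atom_index` (0-based), `group`, `bp_index` (-1 for non-duplex atoms) and
#' `tip` (0/1 flag for the 5'-terminal nucleotide).
#'
#' @param traj a [TrajectoryFrameSet-class].
#' @param xyzPath,groupsPath output paths.
#' @export
writeTrajectory <- function(traj, xyzPath, groupsPath) {
  g <- traj@groups
  con <- file(xyzPath, "w")
  on.exit(close(con))
  for (f in seq_along(traj@frames)) {
    fr <- traj@frames[[f]]
    writeLines(as.character(nrow(fr)), con)
    writeLines(sprintf("frame %d", f), con)
    writeLines(sprintf("%s %.9f %.9f %.9f", g$group, fr[, 1], fr[, 2], fr[, 3]), con)
  }
  utils::write.csv(g, groupsPath, row.names = FALSE, quote = FALSE)
  invisible(xyzPath)
}

#' Read a multi-frame XYZ trajectory plus group map
#'
#' @param xyzPath multi-frame XYZ file (coordinates in nm).
#' @param groupsPath group-map CSV (`atom_index,group,bp_index,tip`); a file
#'   without the tip flag column, or one not covering every atom, is
#'   rejected.
#' @param cylinderRadius,nBp optional metadata to attach.
#' @return a [TrajectoryFrameSet-class].
#' @export
readTrajectory <- function(xyzPath, groupsPath,
                           cylinderRadius = NA_real_, nBp = NA_real_) {
  .stopIfNot(file.exists(xyzPath), "file not found: %s", xyzPath)
  .stopIfNot(file.exists(groupsPath), "file not found: %s", groupsPath)
  g <- utils::read.csv(groupsPath, stringsAsFactors = FALSE)
  need <- c("atom_index", "group", "bp_index", "tip")
  .stopIfNot(all(need %in% names(g)),
             "group map %s must have columns %s (tip flag required)",
             groupsPath, paste(need, collapse = ","))

  lines <- readLines(xyzPath)
  frames <- list()
  i <- 1L; f <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    na <- suppressWarnings(as.integer(trimws(lines[i])))
    f <- f + 1L
    .stopIfNot(!is.na(na) && na > 0,
               "frame %d: malformed atom-count line %d in %s", f, i, xyzPath)
    .stopIfNot(i + 1L + na <= length(lines),
               "frame %d: truncated frame block in %s", f, xyzPath)
    block <- lines[(i + 2L):(i + 1L + na)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    bad <- which(lengths(parts) < 4L)
    .stopIfNot(!length(bad), "frame %d, atom %d: malformed XYZ line", f, bad[1])
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3, byrow = TRUE)
    .stopIfNot(!anyNA(xyz), "frame %d: non-numeric coordinates", f)
    frames[[f]] <- `dimnames<-`(xyz, list(NULL, c("x", "y", "z")))
    i <- i + 2L + na
  }
  .stopIfNot(length(frames) >= 1, "no frames in %s", xyzPath)
  nAtoms <- nrow(frames[[1]])
  for (f in seq_along(frames))
    .stopIfNot(nrow(frames[[f]]) == nAtoms,
               "frame %d has %d atoms, expected %d", f, nrow(frames[[f]]), nAtoms)
  .stopIfNot(nrow(g) == nAtoms && setequal(g$atom_index, seq_len(nAtoms) - 1L),
             "group map does not cover all %d atom indices (0-based)", nAtoms)
  g <- g[order(g$atom_index), ]
  new("TrajectoryFrameSet", frames = frames, groups = g,
      cylinderRadius = cylinderRadius, nBp = nBp)
}
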