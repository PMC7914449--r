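# Plain-text readers and writers for every exchange format the pipeline
# uses: thermogram/pattern/spectrum CSV, NOESY volume matrix CSV with a
# mixing-time header, multi-frame XYZ (comment line carries the box) and a
# minimal GRO dialect.

#' Write / read a thermogram CSV (columns T_degC, Cp)
#' @param t a [thermogram()]; @param path file path.
#' @return `read_thermogram_csv` returns a [thermogram()].
#' @export
write_thermogram_csv <- function(t, path) {
  stopifnot(inherits(t, "thermogram"))
  utils::write.csv(data.frame(T_degC = t$temperature, Cp = t$cp),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_thermogram_csv
#' @export
read_thermogram_csv <- function(path) {
  d <- utils::read.csv(path)
  thermogram(d$T_degC, d$Cp)
}

#' Write / read a diffraction pattern CSV (columns s_invA, intensity)
#'
#' The angular region tag is carried in a `# region=` header line.
#' @param p a [diffraction_pattern()]; @param path file path.
#' @return `read_pattern_csv` returns a [diffraction_pattern()].
#' @export
write_pattern_csv <- function(p, path) {
  stopifnot(inherits(p, "diffraction_pattern"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# region=%s", attr(p, "region")), con)
  writeLines("s_invA,intensity", con)
  writeLines(sprintf("%.10g,%.10g", p$s, p$intensity), con)
  invisible(path)
}

#' @rdname write_pattern_csv
#' @export
read_pattern_csv <- function(path) {
  first <- readLines(path, n = 1L)
  region <- if (grepl("^# *region=", first))
    sub("^# *region=", "", first) else "SAXD"
  d <- utils::read.csv(path, comment.char = "#")
  diffraction_pattern(d$s_invA, d$intensity, region)
}

#' Write / read a spectrum CSV (columns ppm, intensity)
#' @param sp a [spectrum31p()]; @param path file path.
#' @return `read_spectrum_csv` returns a [spectrum31p()].
#' @export
write_spectrum_csv <- function(sp, path) {
  stopifnot(inherits(sp, "spectrum31p"))
  utils::write.csv(data.frame(ppm = sp$ppm, intensity = sp$intensity),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  spectrum31p(d$ppm, d$intensity)
}

#' Write / read a NOESY volume CSV matrix
#'
#' First line `tm_s=<value>`; then a matrix with rows = lipid groups, one
#' `diagonal` column, and one column per ligand proton.
#' @param t a [noesy_volumes()]; @param path file path.
#' @return `read_noesy_csv` returns a [noesy_volumes()].
#' @export
write_noesy_csv <- function(t, path) {
  stopifnot(inherits(t, "noesy_volumes"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("tm_s=%.10g", t$tm), con)
  rows <- rownames(t$cross)
  header <- paste(c("group", "diagonal", colnames(t$cross)), collapse = ",")
  writeLines(header, con)
  for (r in rows)
    writeLines(paste(c(r, sprintf("%.10g", c(t$diagonal[r], t$cross[r, ]))),
                     collapse = ","), con)
  invisible(path)
}

#' @rdname write_noesy_csv
#' @export
read_noesy_csv <- function(path) {
  lines <- readLines(path)
  if (!grepl("^tm_s=", lines[1L])) stop("missing tm_s= header line")
  tm <- as.numeric(sub("^tm_s=", "", lines[1L]))
  d <- utils::read.csv(text = paste(lines[-1L], collapse = "\n"),
                       check.names = FALSE)
  diag_v <- stats::setNames(d$diagonal, d$group)
  cross <- as.matrix(d[, setdiff(names(d), c("group", "diagonal")),
                       drop = FALSE])
  rownames(cross) <- d$group
  noesy_volumes(tm, diag_v, cross)
}

#' Write / read a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (`n`, comment, `label x y z`); the comment line
#' carries `box Lx Ly Lz nm frame i`. Masses are not part of XYZ, so
#' `read_xyz_frames` takes a named `masses` map (Da per group, default 1).
#' @param t a [group_trajectory()]; @param path file path.
#' @param masses named numeric, mass per group label (Da).
#' @return `read_xyz_frames` returns a [group_trajectory()].
#' @export
write_xyz_frames <- function(t, path) {
  stopifnot(inherits(t, "group_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(t$frames)) {
    f <- t$frames[[i]]
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("box %.6f %.6f %.6f nm frame %d",
                       t$box[1], t$box[2], t$box[3], i), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", f$group, f$x, f$y, f$z), con)
  }
  invisible(path)
}

#' @rdname write_xyz_frames
#' @export
read_xyz_frames <- function(path, masses = NULL) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cm <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (cm[1] != "box") stop("XYZ comment line must start with 'box'")
    box <- as.numeric(cm[2:4])
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    lab <- vapply(parts, `[[`, character(1), 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    m <- if (is.null(masses)) rep(1, n) else {
      mm <- masses[lab]
      if (any(is.na(mm))) stop("masses map missing a group label")
      as.numeric(mm)
    }
    frames[[length(frames) + 1L]] <-
      data.frame(group = lab, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 mass = m, stringsAsFactors = FALSE)
    i <- i + 2L + n
  }
  group_trajectory(frames, box)
}

#' Write / read a minimal GRO-dialect trajectory
#'
#' Fixed-width GRO records (resname = group label, atom name = group
#' label), one block per frame, box line in nm. Velocities are not written.
#' @param t a [group_trajectory()]; @param path file path.
#' @param masses named numeric, mass per group label (Da).
#' @return `read_gro_frames` returns a [group_trajectory()].
#' @export
write_gro_frames <- function(t, path) {
  stopifnot(inherits(t, "group_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(t$frames)) {
    f <- t$frames[[i]]
    writeLines(sprintf("frame %d", i), con)
    writeLines(sprintf("%5d", nrow(f)), con)
    for (j in seq_len(nrow(f)))
      writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                         j %% 100000L, substr(f$group[j], 1, 5),
                         substr(f$group[j], 1, 5), j %% 100000L,
                         f$x[j], f$y[j], f$z[j]), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f",
                       t$box[1], t$box[2], t$box[3]), con)
  }
  invisible(path)
}

#' @rdname write_gro_frames
#' @export
read_gro_frames <- function(path, masses = NULL) {
  lines <- readLines(path)
  frames <- list()
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i + 1L])
    block <- lines[(i + 2L):(i + 1L + n)]
    lab <- trimws(substr(block, 6L, 10L))
    x <- as.numeric(substr(block, 21L, 28L))
    y <- as.numeric(substr(block, 29L, 36L))
    z <- as.numeric(substr(block, 37L, 44L))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    m <- if (is.null(masses)) rep(1, n) else {
      mm <- masses[lab]
      if (any(is.na(mm))) stop("masses map missing a group label")
      as.numeric(mm)
    }
    frames[[length(frames) + 1L]] <-
      data.frame(group = lab, x = x, y = y, z = z, mass = m,
                 stringsAsFactors = FALSE)
    i <- i + 3L + n
  }
  group_trajectory(frames, box)
}

#' Write a transitions TSV (one row per composition and transition)
#' @param rows list of `list(label =, molar_ratio =, transition =)`.
#' @param path file path.
#' @export
write_transitions_tsv <- function(rows, path) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(label = r$label, molar_ratio = r$molar_ratio,
               t_onset = r$transition$t_onset, t_end = r$transition$t_end,
               t_max = r$transition$t_max, dH = r$transition$dH,
               fwhm = r$transition$fwhm, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a structural-parameter TSV (Table-2-style columns)
#' @param fits named list of [lamellar_fit()] objects.
#' @param path file path.
#' @export
write_structure_tsv <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(sample = nm, d = f$d, zH = f$zH, sigmaH = f$sigmaH,
               sigmaC = f$sigmaC, dHH = f$dHH, dB = f$dB, dw = f$dw,
               residual = f$fit_residual, stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
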