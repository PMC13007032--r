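#' Trajectory container
#'
#' @param frames List of `configuration` frames with consistent atom count
#'   and ordering.
#' @param metadata Named list (source format, timestep, ...).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(frames, metadata = list()) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n0 <- nrow(frames[[1]]$positions)
  for (f in frames) {
    stopifnot(inherits(f, "configuration"))
    if (nrow(f$positions) != n0) stop("inconsistent atom count across frames")
  }
  structure(list(frames = frames, metadata = metadata), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms (%s)\n", length(x$frames),
              nrow(x$frames[[1]]$positions),
              if (!is.null(x$metadata$format)) x$metadata$format else "in-memory"))
  invisible(x)
}

#' Write a trajectory as extended XYZ or LAMMPS dump text
#'
#' Extended XYZ: per frame, an atom count line, a comment line
#' `box Lx Ly Lz`, then columns `species x y z mass charge mol_id`.
#' LAMMPS dump: standard `ITEM:` blocks with bounds [-L/2, L/2] and columns
#' `id mol type x y z q`. Atom ids are 1-based in both formats.
#'
#' @param traj A `trajectory` or single `configuration`.
#' @param path Output file path.
#' @param format `"xyz_extended"` (default) or `"lammps_dump"`.
#' @param digits Coordinate precision.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xyz_extended", "lammps_dump"),
                             digits = 8) {
  format <- match.arg(format)
  frames <- if (inherits(traj, "configuration")) list(traj) else traj$frames
  con <- file(path, "w"); on.exit(close(con))
  fmt <- paste0("%.", digits, "g")
  for (t in seq_along(frames)) {
    f <- frames[[t]]
    n <- nrow(f$positions)
    if (format == "xyz_extended") {
      writeLines(as.character(n), con)
      writeLines(sprintf(paste("box", fmt, fmt, fmt),
                         f$box[1], f$box[2], f$box[3]), con)
      writeLines(sprintf(paste("%s", fmt, fmt, fmt, fmt, fmt, "%d"),
                         f$species, f$positions[, 1], f$positions[, 2],
                         f$positions[, 3], f$mass, f$charge, f$mol_id), con)
    } else {
      writeLines(c("ITEM: TIMESTEP", as.character(t - 1L),
                   "ITEM: NUMBER OF ATOMS", as.character(n),
                   "ITEM: BOX BOUNDS pp pp pp",
                   sprintf(paste(fmt, fmt), -f$box / 2, f$box / 2),
                   "ITEM: ATOMS id mol type x y z q"), con)
      writeLines(sprintf(paste("%d %d %s", fmt, fmt, fmt, fmt),
                         seq_len(n), f$mol_id, f$species, f$positions[, 1],
                         f$positions[, 2], f$positions[, 3], f$charge), con)
    }
  }
  invisible(path)
}

.parse_error <- function(line, msg) stop("parse error at line ", line, ": ", msg)

#' Read a trajectory from extended XYZ or LAMMPS dump text
#'
#' The LAMMPS reader maps columns by the `ITEM: ATOMS` header: coordinates
#' may be unwrapped (`xu yu zu`), wrapped (`x y z`) or scaled (`xs ys zs`;
#' unscaled by the box), and `id`, `mol`, `type`, `q`, `mass` columns are
#' honored when present. Atoms are reordered by id. Missing masses default
#' to 1 (analysis steps that need real masses should supply them via the
#' writer).
#'
#' @param path Input file.
#' @param format `"xyz_extended"` or `"lammps_dump"`.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, format = c("xyz_extended", "lammps_dump")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (length(lines) == 0) stop("empty trajectory file: ", path)
  frames <- list()
  i <- 1L
  if (format == "xyz_extended") {
    while (i <= length(lines)) {
      if (!grepl("^\\s*\\d+\\s*$", lines[i]))
        .parse_error(i, "expected atom count")
      n <- as.integer(lines[i])
      if (i + 1L > length(lines) || !grepl("^box\\s", lines[i + 1L]))
        .parse_error(i + 1L, "expected 'box Lx Ly Lz' comment line")
      box <- as.numeric(strsplit(trimws(lines[i + 1L]), "\\s+")[[1]][2:4])
      if (i + 1L + n > length(lines))
        .parse_error(i, sprintf("truncated frame %d (need %d atom lines)",
                                length(frames) + 1L, n))
      rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
      if (any(lengths(rows) < 7L))
        .parse_error(i + 1L + which(lengths(rows) < 7L)[1], "expected 7 columns")
      m <- matrix(unlist(lapply(rows, `[`, 2:7)), ncol = 6, byrow = TRUE)
      num <- suppressWarnings(matrix(as.numeric(m), ncol = 6))
      if (any(is.na(num)))
        .parse_error(i + 1L + which(rowSums(is.na(num)) > 0)[1], "non-numeric field")
      frames[[length(frames) + 1L]] <-
        configuration(num[, 1:3], vapply(rows, `[`, "", 1L), num[, 4],
                      num[, 5], as.integer(num[, 6]), box = box)
      i <- i + 2L + n
    }
  } else {
    while (i <= length(lines)) {
      if (!grepl("^ITEM: TIMESTEP", lines[i])) .parse_error(i, "expected ITEM: TIMESTEP")
      n <- as.integer(lines[i + 3L])
      if (is.na(n)) .parse_error(i + 3L, "bad atom count")
      bounds <- do.call(rbind, lapply(strsplit(trimws(lines[(i + 5L):(i + 7L)]), "\\s+"),
                                      function(x) as.numeric(x[1:2])))
      if (any(is.na(bounds))) .parse_error(i + 5L, "bad box bounds")
      box <- bounds[, 2] - bounds[, 1]
      hdr <- strsplit(trimws(sub("^ITEM: ATOMS\\s*", "", lines[i + 8L])), "\\s+")[[1]]
      if (length(hdr) == 0) .parse_error(i + 8L, "expected ITEM: ATOMS header")
      if (i + 8L + n > length(lines))
        .parse_error(i + 8L, sprintf("truncated frame %d", length(frames) + 1L))
      rows <- strsplit(trimws(lines[(i + 9L):(i + 8L + n)]), "\\s+")
      if (any(lengths(rows) != length(hdr)))
        .parse_error(i + 9L, "row/column mismatch")
      tab <- as.data.frame(matrix(unlist(rows), ncol = length(hdr), byrow = TRUE),
                           stringsAsFactors = FALSE)
      names(tab) <- hdr
      col <- function(names_try, default = NULL) {
        hit <- intersect(names_try, hdr)
        if (length(hit)) suppressWarnings(as.numeric(tab[[hit[1]]])) else default
      }
      x <- col(c("x", "xu")); y <- col(c("y", "yu")); z <- col(c("z", "zu"))
      if (is.null(x)) { xs <- col("xs"); x <- bounds[1, 1] + xs * box[1] }
      if (is.null(y)) { ys <- col("ys"); y <- bounds[2, 1] + ys * box[2] }
      if (is.null(z)) { zs <- col("zs"); z <- bounds[3, 1] + zs * box[3] }
      if (is.null(x) || is.null(y) || is.null(z))
        .parse_error(i + 8L, "no usable coordinate columns")
      if (any(is.na(c(x, y, z)))) .parse_error(i + 9L, "non-numeric coordinate")
      id <- col("id", seq_len(n))
      ord <- order(id)
      frames[[length(frames) + 1L]] <-
        configuration(cbind(x, y, z)[ord, , drop = FALSE],
                      (if ("type" %in% hdr) tab$type else rep("1", n))[ord],
                      (col("mass", rep(1, n)))[ord],
                      (col("q", rep(0, n)))[ord],
                      as.integer(col("mol", seq_len(n)))[ord], box = box)
      i <- i + 9L + n
    }
  }
  trajectory(frames, metadata = list(format = format, path = path))
}

#' Read a reaction-coordinate window time series
#'
#' Parses colvars-style plain-text output: whitespace-separated numeric
#' columns, `#` comment lines tolerated; by default column 1 is the step and
#' column 2 the reaction coordinate.
#'
#' @param path Input file.
#' @param column 1-based index of the coordinate column (default 2).
#' @return Data frame with `step` and `xi`.
#' @export
read_window_series <- function(path, column = 2L) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no numeric rows in ", path)
  rows <- strsplit(trimws(lines[keep]), "\\s+")
  if (any(lengths(rows) < column))
    .parse_error(keep[which(lengths(rows) < column)[1]], "too few columns")
  step <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 1L)))
  xi <- suppressWarnings(as.numeric(vapply(rows, `[`, "", column)))
  bad <- which(is.na(step) | is.na(xi))
  if (length(bad)) .parse_error(keep[bad[1]], "non-numeric cell")
  data.frame(step = step, xi = xi)
}

#' Write a window series as two-column plain text
#'
#' @param samples A `window_samples` or numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_series <- function(samples, path) {
  xi <- if (inherits(samples, "window_samples")) samples$samples else samples
  con <- file(path, "w"); on.exit(close(con))
  if (inherits(samples, "window_samples"))
    writeLines(sprintf("# center %.6f k %.6f T %.2f", samples$bias$center,
                       samples$bias$k, samples$temperature), con)
  writeLines(sprintf("%d %.10g", seq_along(xi), xi), con)
  invisible(path)
}

# Kahan compensated summation
.kahan_sum <- function(x) {
  s <- 0; c <- 0
  for (v in x) {
    y <- v - c
    t <- s + y
    c <- (t - s) - y
    s <- t
  }
  s
}

#' Enforce an exact net charge by minimal uniform correction
#'
#' Partial-charge assignments rounded to finite precision rarely sum to the
#' intended formal charge; a uniform shift of (target - sum)/n is applied to
#' every charge. The shift is computed with compensated (Kahan) summation
#' and any remaining few-ulp residual is folded into the last charge so
#' that the compensated sum of the corrected charges equals the target
#' exactly.
#'
#' @param charges Nonempty numeric vector of charges (e).
#' @param target Required net charge (e), e.g. -1 for an anionic solute.
#' @return Corrected charges, same length.
#' @export
correct_net_charge <- function(charges, target = -1) {
  if (length(charges) == 0) stop("charges must be nonempty")
  stopifnot(is.numeric(charges), all(is.finite(charges)), is.finite(target))
  q <- charges + (target - .kahan_sum(charges)) / length(charges)
  for (i in 1:5) {
    r <- .kahan_sum(q) - target
    if (r == 0) break
    q[length(q)] <- q[length(q)] - r
  }
  q
}
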