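#' Construct a labeled multi-frame trajectory
#'
#' @param labels Character vector of atom labels (unique per atom, e.g.
#'   `"MG"`, `"O6"`, `"O8"`).
#' @param coords Numeric array `n_frames x n_atoms x 3`, Angstrom.
#' @param box Optional orthorhombic box lengths `c(Lx, Ly, Lz)`, Angstrom.
#' @param timestep Time between frames, ps.
#' @return An object of class `phos_trajectory`.
#' @export
phos_trajectory <- function(labels, coords, box = NULL, timestep = 1) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("atom labels must be unique", call. = FALSE)
  }
  if (length(dim(coords)) != 3L || dim(coords)[2] != length(labels) ||
      dim(coords)[3] != 3L) {
    stop("coords must be an n_frames x n_atoms x 3 array", call. = FALSE)
  }
  if (any(!is.finite(coords))) {
    stop("coordinates must be finite", call. = FALSE)
  }
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) == 1L) box <- rep(box, 3)
    if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive lengths (Angstrom)", call. = FALSE)
    }
  }
  if (!is.numeric(timestep) || timestep <= 0) {
    stop("timestep must be positive (ps)", call. = FALSE)
  }
  structure(list(labels = labels, coords = coords, box = box,
                 timestep = timestep),
            class = "phos_trajectory")
}

#' @export
print.phos_trajectory <- function(x, ...) {
  cat(sprintf("<phos_trajectory> %d frames, %d atoms (%s)%s, dt = %g ps\n",
              dim(x$coords)[1], length(x$labels),
              paste(utils::head(x$labels, 6), collapse = ", "),
              if (is.null(x$box)) "" else
                sprintf(", box %g x %g x %g A", x$box[1], x$box[2], x$box[3]),
              x$timestep))
  invisible(x)
}

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ blocks (atom count line, comment line, then one
#' `label x y z` line per atom). An orthorhombic box may be declared on
#' the comment line as `box=Lx,Ly,Lz`; the first frame's value is used and
#' all frames must share the atom label set in the same order.
#'
#' @param path XYZ file path.
#' @param timestep Time between frames, ps.
#' @return A [phos_trajectory()].
#' @export
read_xyz_trajectory <- function(path, timestep = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop("empty trajectory file: ", path, call. = FALSE)
  frames <- list()
  box <- NULL
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n <= 0L) {
      stop("malformed XYZ: bad atom count at line ", i, call. = FALSE)
    }
    if (i + 1L + n > length(lines)) {
      stop("malformed XYZ: truncated frame starting at line ", i, call. = FALSE)
    }
    comment <- lines[i + 1L]
    if (is.null(box)) {
      m <- regmatches(comment, regexec("box=([0-9.eE+-]+),([0-9.eE+-]+),([0-9.eE+-]+)",
                                       comment))[[1]]
      if (length(m) == 4L) box <- as.numeric(m[2:4])
    }
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    if (any(lengths(rows) < 4L)) {
      stop("malformed XYZ: atom line with fewer than 4 fields in frame at line ",
           i, call. = FALSE)
    }
    labs <- vapply(rows, `[[`, character(1), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- list(labels = labs, xyz = xyz)
    i <- i + 2L + n
  }
  labs0 <- frames[[1]]$labels
  same <- vapply(frames, function(f) identical(f$labels, labs0), logical(1))
  if (!all(same)) {
    stop("all frames must share the same atom labels in the same order",
         call. = FALSE)
  }
  coords <- array(NA_real_, c(length(frames), length(labs0), 3L))
  for (k in seq_along(frames)) coords[k, , ] <- frames[[k]]$xyz
  phos_trajectory(labs0, coords, box = box, timestep = timestep)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj A [phos_trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "phos_trajectory"))
  n_frames <- dim(traj$coords)[1]
  n_atoms <- length(traj$labels)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(n_frames)) {
    writeLines(as.character(n_atoms), con)
    comment <- sprintf("t=%.6g", (k - 1) * traj$timestep)
    if (!is.null(traj$box)) {
      comment <- sprintf("box=%.10g,%.10g,%.10g %s",
                         traj$box[1], traj$box[2], traj$box[3], comment)
    }
    writeLines(comment, con)
    writeLines(sprintf("%s %.10g %.10g %.10g", traj$labels,
                       traj$coords[k, , 1], traj$coords[k, , 2],
                       traj$coords[k, , 3]), con)
  }
  invisible(path)
}

# displacement with minimum-image convention when a box is present;
# d: n x 3 matrix of raw differences
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (j in 1:3) d[, j] <- d[, j] - box[j] * round(d[, j] / box[j])
  d
}

atom_index <- function(traj, label) {
  i <- match(label, traj$labels)
  if (is.na(i)) stop("unknown atom label: ", label, call. = FALSE)
  i
}

#' Per-frame distance between two labeled atoms
#'
#' Euclidean distance in each frame, under the minimum-image convention
#' when the trajectory carries a periodic box.
#'
#' @param traj A [phos_trajectory()].
#' @param a,b Atom labels.
#' @return An object of class `distance_trace`: a data.frame with columns
#'   `time` (ps) and `distance` (Angstrom) and a `pair` attribute.
#' @export
distance_trace <- function(traj, a, b) {
  stopifnot(inherits(traj, "phos_trajectory"))
  ia <- atom_index(traj, a)
  ib <- atom_index(traj, b)
  d <- traj$coords[, ia, , drop = FALSE][, 1, ] - traj$coords[, ib, , drop = FALSE][, 1, ]
  if (is.null(dim(d))) d <- matrix(d, nrow = 1)
  d <- min_image(d, traj$box)
  dist <- sqrt(rowSums(d^2))
  n <- length(dist)
  structure(
    data.frame(time = (seq_len(n) - 1) * traj$timestep, distance = dist),
    pair = c(a, b),
    class = c("distance_trace", "data.frame")
  )
}

#' Radial distribution function between two atom selections
#'
#' Histogram of reference-target pair distances over all frames,
#' normalized by spherical shell volume, target number density and the
#' number of reference atoms and frames, so that g(r) -> 1 for a
#' homogeneous fluid:
#' \deqn{g(r) = \frac{n_{pairs}(r)}{N_{frames}\, N_{ref}\, \rho_{target}\,
#'       4\pi r^2\, dr}}
#' Self-pairs (an atom appearing in both selections) are excluded; when
#' the selections overlap the target density uses the per-reference count
#' of distinct targets.
#'
#' @param traj A [phos_trajectory()] with a periodic box (the density is
#'   undefined otherwise).
#' @param ref Character vector of reference atom labels.
#' @param target Character vector of target atom labels.
#' @param dr Bin width, Angstrom.
#' @param r_max Histogram range, Angstrom; at most half the smallest box
#'   length (minimum-image distances beyond that are ambiguous).
#' @return An object of class `rdf_result`: a data.frame with columns
#'   `r_center` (Angstrom) and `g` plus attributes `n_frames`, `n_ref`,
#'   `rho_target`, `pair_spec`.
#' @export
radial_distribution <- function(traj, ref, target, dr = 0.05, r_max = 10) {
  stopifnot(inherits(traj, "phos_trajectory"))
  if (is.null(traj$box)) {
    stop("RDF requires a periodic box (number density undefined)", call. = FALSE)
  }
  if (!is.numeric(dr) || dr <= 0) stop("dr must be positive", call. = FALSE)
  if (r_max > min(traj$box) / 2 + 1e-9) {
    stop("r_max exceeds half the smallest box length", call. = FALSE)
  }
  iref <- vapply(ref, atom_index, integer(1), traj = traj)
  itar <- vapply(target, atom_index, integer(1), traj = traj)
  n_frames <- dim(traj$coords)[1]
  edges <- seq(0, r_max, by = dr)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, edges[length(edges)] + dr)
  counts <- numeric(length(edges) - 1L)
  n_pairs_per_frame <- 0L
  for (k in seq_len(n_frames)) {
    for (ir in iref) {
      jt <- setdiff(itar, ir)
      if (length(jt) == 0L) next
      d <- matrix(traj$coords[k, jt, , drop = FALSE][1, , ], ncol = 3) -
        matrix(traj$coords[k, ir, ], nrow = length(jt), ncol = 3, byrow = TRUE)
      d <- min_image(d, traj$box)
      r <- sqrt(rowSums(d^2))
      r <- r[r < edges[length(edges)]]
      if (length(r) > 0L) {
        h <- findInterval(r, edges, rightmost.closed = FALSE)
        tb <- tabulate(h, nbins = length(counts))
        counts <- counts + tb
      }
      if (k == 1L) n_pairs_per_frame <- n_pairs_per_frame + length(jt)
    }
  }
  vol <- prod(traj$box)
  # distinct targets per reference (constant across refs for label sets)
  n_tar_eff <- n_pairs_per_frame / length(iref)
  rho <- n_tar_eff / vol
  centers <- edges[-length(edges)] + dr / 2
  shell <- 4 * pi * centers^2 * dr
  g <- counts / (n_frames * length(iref) * rho * shell)
  keep <- centers <= r_max
  structure(
    data.frame(r_center = centers[keep], g = g[keep]),
    n_frames = n_frames, n_ref = length(iref), rho_target = rho,
    pair_spec = list(ref = ref, target = target), dr = dr,
    class = c("rdf_result", "data.frame")
  )
}

#' Coordination-stability summary of a distance trace
#'
#' Formalizes the tight-versus-diffuse comparison of ion coordination:
#' a tightly coordinated ion (Mg2+-like) shows a narrow distance
#' distribution, a loosely coordinated one (Na+-like) a broad one with
#' excursions.
#'
#' @param trace A [distance_trace()].
#' @param cutoff Coordination cutoff, Angstrom.
#' @return A list with `mean` (Angstrom), `sd` (Angstrom, sample sd; 0 for
#'   a single frame) and `fraction_within` (fraction of frames with
#'   distance <= cutoff).
#' @export
coordination_stability <- function(trace, cutoff = 2.5) {
  stopifnot(inherits(trace, "distance_trace"))
  d <- trace$distance
  if (length(d) == 0L) stop("empty distance trace", call. = FALSE)
  if (!is.numeric(cutoff) || cutoff <= 0) {
    stop("cutoff must be positive (Angstrom)", call. = FALSE)
  }
  s <- if (length(d) > 1L) stats::sd(d) else 0
  list(mean = mean(d), sd = s, fraction_within = mean(d <= cutoff))
}
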