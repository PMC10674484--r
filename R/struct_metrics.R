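# Aggregate-shape descriptors from coordinates: radius of gyration,
# Kirkwood hydrodynamic radius, sphere volumes, and per-residue C-alpha
# RMSF over multi-model PDB trajectories.

#' Construct a coordinate trajectory
#'
#' @param frames List of N x 3 coordinate matrices (angstrom), all with the
#'   same atom count and order.
#' @param elements Per-atom element symbols.
#' @param masses Per-atom masses in amu (> 0).
#' @param atom_names Per-atom names (e.g. "CA") for selections.
#' @param resno Per-atom residue numbers.
#' @return A `trajectory` object.
#' @export
trajectory <- function(frames, elements, masses, atom_names = NULL,
                       resno = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1)
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    stopifnot(ncol(f) == 3)
    if (!all(is.finite(f))) stop("coordinates must be finite")
    f
  })
  n <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, integer(1)) == n))
    stop("all frames must have the same atom count")
  stopifnot(length(elements) == n, length(masses) == n)
  if (any(masses <= 0)) stop("masses must be > 0")
  if (is.null(atom_names)) atom_names <- elements
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(frames = frames, elements = elements, masses = masses,
                 atom_names = atom_names, resno = resno),
            class = "trajectory")
}

#' Read a PDB file as a trajectory
#'
#' Multiple MODEL records become multiple frames, in file order.  Element
#' symbols come from the element column when present, falling back to
#' atom-name heuristics; masses are looked up from a standard table.
#'
#' @param path Path to a PDB file.
#' @return A [trajectory()].
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  if (any(!is.finite(as.matrix(at[, c("x", "y", "z")]))))
    stop("missing or non-numeric coordinates in ", path)
  el <- at$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(at))
  el <- trimws(el)
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # atom-name heuristics for files without an element column
    fb <- suppressWarnings(tryCatch(
      bio3d::atom2ele(at$elety[miss], rescue = TRUE),
      error = function(e) {
        nm <- sub("^[0-9]*", "", at$elety[miss])
        ifelse(substr(nm, 1, 2) %in% c("CL", "BR", "NA", "MG", "ZN", "FE"),
               substr(nm, 1, 2), substr(nm, 1, 1))
      }))
    el[miss] <- fb
  }
  el <- paste0(toupper(substr(el, 1, 1)),
               tolower(substr(el, 2, nchar(el))))
  ptable <- new.env()
  utils::data("elements", package = "bio3d", envir = ptable)
  ptable <- ptable$elements
  masses <- ptable$mass[match(el, as.character(ptable$symb))]
  masses[!is.finite(masses) | masses <= 0] <- 12.011  # unknowns as carbon
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  frames <- lapply(seq_len(nrow(xyz)), function(i)
    matrix(xyz[i, ], ncol = 3, byrow = TRUE))
  trajectory(frames = frames, elements = el, masses = masses,
             atom_names = at$elety, resno = at$resno)
}

#' Radius of gyration of a coordinate frame
#'
#' Rg = sqrt( sum m_i |r_i - r_com|^2 / sum m_i ), mass-weighted by default
#' (the GROMACS `gyrate` convention); `mass_weighted = FALSE` sets all
#' masses to 1.
#'
#' @param frame N x 3 coordinate matrix (angstrom).
#' @param masses Per-atom masses; ignored when `mass_weighted = FALSE`.
#' @param mass_weighted Use the masses (default TRUE).
#' @return Radius of gyration in angstrom.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(10, 0, 0)))  # 5
#' @export
radius_of_gyration <- function(frame, masses = NULL, mass_weighted = TRUE) {
  frame <- as.matrix(frame)
  stopifnot(ncol(frame) == 3, nrow(frame) >= 1)
  m <- if (mass_weighted && !is.null(masses)) masses else rep(1, nrow(frame))
  stopifnot(length(m) == nrow(frame))
  com <- colSums(frame * m) / sum(m)
  d2 <- rowSums(sweep(frame, 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Kirkwood hydrodynamic radius of a coordinate frame
#'
#' Rh = [ mean over unordered atom pairs of 1/|r_i - r_j| ]^-1, the Kirkwood
#' inverse-mean-inverse-distance approximation to the hydrodynamic size of a
#' rigid particle.  By default the average runs over carbon atoms.
#'
#' @param frame N x 3 coordinate matrix (angstrom).
#' @param elements Per-atom element symbols (needed unless
#'   `selection = NULL`).
#' @param selection Element symbol to select (default `"C"`), or `NULL` for
#'   all atoms, or an integer/logical index vector.
#' @return Kirkwood hydrodynamic radius in angstrom.
#' @examples
#' kirkwood_rh(rbind(c(0, 0, 0), c(10, 0, 0)), selection = NULL)  # 10
#' @export
kirkwood_rh <- function(frame, elements = NULL, selection = "C") {
  frame <- as.matrix(frame)
  stopifnot(ncol(frame) == 3)
  idx <- if (is.null(selection)) {
    seq_len(nrow(frame))
  } else if (is.character(selection)) {
    if (is.null(elements)) stop("element selection requires `elements`")
    which(toupper(elements) == toupper(selection))
  } else {
    seq_len(nrow(frame))[selection]
  }
  if (length(idx) < 2) stop("need at least 2 selected atoms")
  d <- stats::dist(frame[idx, , drop = FALSE])
  if (any(d == 0)) {
    pair <- which(as.matrix(d) == 0 & upper.tri(as.matrix(d)),
                  arr.ind = TRUE)[1, ]
    stop(sprintf("coincident selected atoms (pair %d, %d): 1/r undefined",
                 idx[pair[1]], idx[pair[2]]))
  }
  1 / mean(1 / d)
}

#' Gyration volume from a radius of gyration
#'
#' Vg = (4/3) pi (Rg/10)^3, the sphere volume at the gyration radius
#' (radius in angstrom, volume in nm^3).
#'
#' @param Rg_A Radius of gyration in angstrom (> 0).
#' @return Volume in nm^3.
#' @examples
#' gyration_volume(13.9)  # 11.3 nm^3
#' @export
gyration_volume <- function(Rg_A) {
  if (any(Rg_A <= 0)) stop("Rg_A must be > 0")
  volume_from_radius(Rg_A)
}

# Kabsch least-squares superposition: rotation + translation mapping
# `mobile` onto `ref` (both N x 3), minimizing RMSD.
kabsch_superpose <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- sweep(mobile, 2, cm)
  B <- sweep(ref, 2, cr)
  s <- svd(crossprod(A, B))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = R, translation = cr - as.numeric(R %*% cm),
       apply = function(x) sweep(as.matrix(x) %*% t(R), 2,
                                 cr - as.numeric(R %*% cm), `+`))
}

#' Root mean square fluctuation per atom over a trajectory
#'
#' rmsf_i = sqrt( mean over frames of |r_i - <r_i>|^2 ), optionally after
#' least-squares rigid superposition of every frame onto the selection's
#' mean structure (the mean is recomputed once after the first fit).
#'
#' @param traj A [trajectory()].
#' @param selection Atom-name filter (default `"CA"`), or `NULL` for all
#'   atoms, or an integer index vector.
#' @param superpose Rigidly superpose frames before averaging (default
#'   TRUE).
#' @return Data frame with `atom`, `resno`, `rmsf_A` for the selected atoms.
#' @export
rmsf <- function(traj, selection = "CA", superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  if (length(traj$frames) < 2) stop("rmsf needs at least 2 frames")
  idx <- if (is.null(selection)) seq_along(traj$atom_names)
         else if (is.character(selection)) which(traj$atom_names == selection)
         else as.integer(selection)
  if (length(idx) == 0) stop("selection matches no atoms")
  if (superpose && length(idx) < 3)
    stop("superposition needs at least 3 selected atoms")
  sel <- lapply(traj$frames, function(f) f[idx, , drop = FALSE])

  if (superpose) {
    mean_str <- Reduce(`+`, sel) / length(sel)
    for (pass in 1:2) {   # mean -> fit -> recompute mean, iterated once
      sel <- lapply(sel, function(f) kabsch_superpose(f, mean_str)$apply(f))
      mean_str <- Reduce(`+`, sel) / length(sel)
    }
  } else {
    mean_str <- Reduce(`+`, sel) / length(sel)
  }
  dev2 <- Reduce(`+`, lapply(sel, function(f)
    rowSums((f - mean_str)^2))) / length(sel)
  data.frame(atom = traj$atom_names[idx], resno = traj$resno[idx],
             rmsf_A = sqrt(dev2))
}

#' Per-frame and aggregate structural metrics of a trajectory
#'
#' Computes per-frame radius of gyration and Kirkwood hydrodynamic radius,
#' their means and standard deviations across frames, the corresponding
#' sphere volumes Vg and Vh from the MEAN radii, and (when the trajectory
#' has >= 2 frames) the per-atom RMSF table.
#'
#' @param traj A [trajectory()].
#' @param rh_selection Element filter for the Kirkwood radius (default
#'   `"C"`, all carbons).
#' @param rmsf_selection Atom-name filter for the RMSF (default `"CA"`).
#' @param mass_weighted Mass-weight the radius of gyration (default TRUE).
#' @param superpose Superpose frames before the RMSF (default TRUE).
#' @return A `structure_metrics` list: `per_frame` (data frame of `frame`,
#'   `Rg_A`, `Rh_A`), `Rg_mean_A`, `Rg_sd_A`, `Rh_mean_A`, `Rh_sd_A`,
#'   `Vg_nm3`, `Vh_nm3`, `rmsf` (data frame or NULL).
#' @export
trajectory_summary <- function(traj, rh_selection = "C",
                               rmsf_selection = "CA",
                               mass_weighted = TRUE, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  rg <- vapply(traj$frames, radius_of_gyration, numeric(1),
               masses = traj$masses, mass_weighted = mass_weighted)
  rh <- vapply(traj$frames, kirkwood_rh, numeric(1),
               elements = traj$elements, selection = rh_selection)
  rmsf_tab <- NULL
  if (length(traj$frames) >= 2) {
    rmsf_tab <- tryCatch(
      rmsf(traj, selection = rmsf_selection, superpose = superpose),
      error = function(e) NULL)
  }
  structure(list(
    per_frame = data.frame(frame = seq_along(traj$frames),
                           Rg_A = rg, Rh_A = rh),
    Rg_mean_A = mean(rg), Rg_sd_A = stats::sd(rg),
    Rh_mean_A = mean(rh), Rh_sd_A = stats::sd(rh),
    Vg_nm3 = gyration_volume(mean(rg)),
    Vh_nm3 = volume_from_radius(mean(rh)),
    rmsf = rmsf_tab),
    class = "structure_metrics")
}

#' Write structural metrics as JSON plus delimited tables
#'
#' @param metrics A `structure_metrics` object.
#' @param json_path Output path for the JSON report.
#' @param per_frame_path Optional path for the per-frame metric table.
#' @param rmsf_path Optional path for the per-atom RMSF table.
#' @return `json_path`, invisibly.
#' @export
write_structure_metrics <- function(metrics, json_path,
                                    per_frame_path = NULL,
                                    rmsf_path = NULL) {
  jsonlite::write_json(
    list(Rg_mean_A = metrics$Rg_mean_A, Rg_sd_A = metrics$Rg_sd_A,
         Rh_mean_A = metrics$Rh_mean_A, Rh_sd_A = metrics$Rh_sd_A,
         Vg_nm3 = metrics$Vg_nm3, Vh_nm3 = metrics$Vh_nm3,
         n_frames = nrow(metrics$per_frame)),
    json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(per_frame_path))
    utils::write.table(metrics$per_frame, per_frame_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (!is.null(rmsf_path) && !is.null(metrics$rmsf))
    utils::write.table(metrics$rmsf, rmsf_path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(json_path)
}
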