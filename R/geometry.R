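# Geometric measurements on tetrameric channel coordinate models:
# opposing-subunit diagonal distances, rigid superposition, domain
# rotation angles, segment displacements.

#' Read a channel coordinate model
#'
#' Parses a PDB or mmCIF file (via bio3d) into a light atom table used by
#' the geometry operations.
#'
#' @param path path to a .pdb or .cif file.
#' @return object of class `channel_model`: data frame with columns
#'   chain, resno, atom, elety, x, y, z.
#' @export
read_channel_model <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path)
  a <- pdb$atom
  as_channel_model(data.frame(chain = a$chain, resno = a$resno,
                              atom = a$elety, x = a$x, y = a$y, z = a$z))
}

#' Build a channel model from an atom table
#'
#' @param df data frame with columns chain, resno, atom, x, y, z.
#' @return object of class `channel_model`.
#' @export
as_channel_model <- function(df) {
  need <- c("chain", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(df))) stop("missing columns: ",
                                      paste(setdiff(need, names(df)),
                                            collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop("non-finite coordinates")
  structure(df[need], class = c("channel_model", "data.frame"))
}

#' @export
print.channel_model <- function(x, ...) {
  cat(sprintf("Channel model: %d atoms, chains %s\n", nrow(x),
              paste(sort(unique(x$chain)), collapse = " ")))
  invisible(x)
}

# Select atoms: chains (NULL = all), residue numbers (NULL = all), atom
# names (NULL = all). Returns the subset in chain/resno/atom order.
select_atoms <- function(model, chains = NULL, resno = NULL, atom = NULL) {
  m <- as.data.frame(model)
  if (!is.null(chains)) m <- m[m$chain %in% chains, ]
  if (!is.null(resno)) m <- m[m$resno %in% resno, ]
  if (!is.null(atom)) m <- m[m$atom %in% atom, ]
  m[order(m$chain, m$resno, match(m$atom, unique(m$atom))), ]
}

# Parse a "chain:resno_range:atom" selection string, e.g. "A:700-830:CA",
# "A,B:785:CA", "::CA" (all chains, all residues).
parse_selection <- function(sel) {
  parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
  parts <- c(parts, rep("", 3 - length(parts)))
  chains <- if (nzchar(parts[1])) strsplit(parts[1], ",")[[1]] else NULL
  resno <- if (nzchar(parts[2])) {
    unlist(lapply(strsplit(parts[2], ",")[[1]], function(r) {
      if (grepl("-", r)) {
        ab <- as.integer(strsplit(r, "-")[[1]])
        seq(ab[1], ab[2])
      } else as.integer(r)
    }))
  } else NULL
  atom <- if (nzchar(parts[3])) strsplit(parts[3], ",")[[1]] else NULL
  list(chains = chains, resno = resno, atom = atom)
}

apply_selection <- function(model, sel) {
  s <- if (is.character(sel)) parse_selection(sel) else sel
  select_atoms(model, s$chains, s$resno, s$atom)
}

#' Opposing-subunit diagonal distances
#'
#' In a tetramer, measures the distance between the named atom of the
#' given residue in each of the two pairs of opposing subunits (the two
#' diagonals of the ring) and their absolute difference. Opposing pairs
#' are identified as the chain pairing that maximizes inter-chain centroid
#' distance, so arbitrary chain naming is handled.
#'
#' @param model a `channel_model` with 4 chains.
#' @param resno residue number.
#' @param atom atom name (default "CA").
#' @return list(d1, d2, diff, pairs) — the two diagonal distances (A),
#'   their absolute difference, and the chain pairing used.
#' @export
diagonal_distances <- function(model, resno, atom = "CA") {
  m <- as.data.frame(model)
  chains <- sort(unique(m$chain))
  if (length(chains) != 4) stop("expected 4 chains, found ", length(chains))
  sel <- m[m$resno == resno & m$atom == atom, ]
  missing <- setdiff(chains, unique(sel$chain))
  if (length(missing) > 0)
    stop("residue ", resno, " ", atom, " missing in chain(s): ",
         paste(missing, collapse = ", "))
  # centroid-based opposing-pair assignment over whole chains
  cent <- t(vapply(chains, function(ch) {
    colMeans(m[m$chain == ch, c("x", "y", "z")])
  }, numeric(3)))
  d12 <- sum((cent[1, ] - cent[2, ])^2)
  d13 <- sum((cent[1, ] - cent[3, ])^2)
  d14 <- sum((cent[1, ] - cent[4, ])^2)
  partner <- chains[which.max(c(d12, d13, d14)) + 1]
  pair1 <- c(chains[1], partner)
  pair2 <- setdiff(chains, pair1)
  at <- function(ch) {
    r <- sel[sel$chain == ch, c("x", "y", "z")]
    if (nrow(r) != 1) stop("selection not unique in chain ", ch)
    as.numeric(r)
  }
  d1 <- sqrt(sum((at(pair1[1]) - at(pair1[2]))^2))
  d2 <- sqrt(sum((at(pair2[1]) - at(pair2[2]))^2))
  list(d1 = d1, d2 = d2, diff = abs(d1 - d2),
       pairs = list(pair1, pair2))
}

# Kabsch: optimal rotation (det +1) mapping centred B onto centred A.
kabsch <- function(A, B) {
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  s$v %*% D %*% t(s$u)
}

#' Least-squares rigid superposition
#'
#' Superposes the selected atoms of `model_b` onto those of `model_a`
#' (Kabsch algorithm via SVD). Selections must resolve to equal atom
#' counts in matching order; rows are matched on (chain, resno, atom)
#' when both selections share those keys.
#'
#' @param model_a,model_b `channel_model` objects.
#' @param sel_a,sel_b selection strings ("chain:resno_range:atom") or
#'   lists; default all CA atoms.
#' @return object of class `superposition`: rotation (3x3, det +1),
#'   translation (A), rmsd (A), n atoms, and `transform(xyz)` applying
#'   the fit.
#' @export
superpose <- function(model_a, model_b, sel_a = "::CA", sel_b = sel_a) {
  a <- apply_selection(model_a, sel_a)
  b <- apply_selection(model_b, sel_b)
  key <- function(m) paste(m$chain, m$resno, m$atom)
  common <- intersect(key(a), key(b))
  a <- a[match(common, key(a)), ]
  b <- b[match(common, key(b)), ]
  if (nrow(a) < 3) stop("fewer than 3 matched atoms")
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  ca <- colMeans(A); cb <- colMeans(B)
  R <- kabsch(sweep(A, 2, ca), sweep(B, 2, cb))
  tr <- ca - as.numeric(R %*% cb)
  Bfit <- sweep(B %*% t(R), 2, tr, `+`)
  rmsd <- sqrt(mean(rowSums((A - Bfit)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd,
                 n_atoms = nrow(a),
                 transform = function(xyz) sweep(xyz %*% t(R), 2, tr, `+`)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  ang <- acos(pmin(pmax((sum(diag(x$rotation)) - 1) / 2, -1), 1)) * 180 / pi
  cat(sprintf("Superposition: %d atoms, RMSD %.3f A, rotation %.2f deg\n",
              x$n_atoms, x$rmsd, ang))
  invisible(x)
}

# Apply a rigid transform to a whole model.
transform_model <- function(model, transform) {
  m <- as.data.frame(model)
  xyz <- transform(as.matrix(m[, c("x", "y", "z")]))
  m$x <- xyz[, 1]; m$y <- xyz[, 2]; m$z <- xyz[, 3]
  as_channel_model(m)
}

#' Rotation of one domain between two structures
#'
#' After superposing `model_b` onto `model_a` using `align_sel`, measures
#' the rotation about `axis` that best maps the `measure_sel` atoms of A
#' onto those of B: atom positions (relative to the measured selection's
#' centroid) are projected onto the plane normal to the axis and the
#' radius-squared-weighted mean angular offset is returned (projected-
#' moment method). Antisymmetric: swapping the models negates the angle.
#'
#' @param model_a,model_b `channel_model` objects.
#' @param align_sel selection used for superposition.
#' @param measure_sel selection whose rotation is measured.
#' @param axis rotation axis, "z" (default), "x", "y" or a length-3
#'   vector.
#' @return angle in degrees (counter-clockwise about the axis, A -> B).
#'   A warning reports poor conditioning when the selection is nearly
#'   axial.
#' @export
relative_rotation <- function(model_a, model_b, align_sel, measure_sel,
                              axis = "z") {
  ax <- if (is.character(axis))
    switch(axis, x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1),
           stop("unknown axis")) else axis / sqrt(sum(axis^2))
  fit <- superpose(model_a, model_b, align_sel)
  b_al <- transform_model(model_b, fit$transform)
  a <- apply_selection(model_a, measure_sel)
  b <- apply_selection(b_al, measure_sel)
  key <- function(m) paste(m$chain, m$resno, m$atom)
  common <- intersect(key(a), key(b))
  if (length(common) < 2) stop("measure selection matches fewer than 2 atoms")
  A <- as.matrix(a[match(common, key(a)), c("x", "y", "z")])
  B <- as.matrix(b[match(common, key(b)), c("x", "y", "z")])
  cen <- colMeans((A + B) / 2)
  A <- sweep(A, 2, cen); B <- sweep(B, 2, cen)
  # project out the axial component
  proj <- function(M) M - outer(as.numeric(M %*% ax), ax)
  Ap <- proj(A); Bp <- proj(B)
  r2 <- rowSums(Ap^2)
  if (mean(r2) < 1e-6 || stats::sd(r2) / mean(r2) > 50)
    warning("measure selection nearly axial; rotation poorly conditioned")
  crossz <- function(U, V) {
    # axis component of U x V
    cx <- U[, 2] * V[, 3] - U[, 3] * V[, 2]
    cy <- U[, 3] * V[, 1] - U[, 1] * V[, 3]
    cz <- U[, 1] * V[, 2] - U[, 2] * V[, 1]
    cbind(cx, cy, cz) %*% ax
  }
  dth <- atan2(as.numeric(crossz(Ap, Bp)), rowSums(Ap * Bp))
  sum(r2 * dth) / sum(r2) * 180 / pi
}

#' Displacement of a segment between two structures
#'
#' Distance between the `segment_sel` CA centroids of the two models after
#' superposing on `align_sel`. Invariant to rigid motion applied jointly
#' to both models.
#'
#' @param model_a,model_b `channel_model` objects.
#' @param align_sel selection used for superposition.
#' @param segment_sel selection of the segment (e.g. one helix).
#' @return displacement in Angstrom.
#' @export
segment_displacement <- function(model_a, model_b, align_sel, segment_sel) {
  fit <- superpose(model_a, model_b, align_sel)
  b_al <- transform_model(model_b, fit$transform)
  a <- apply_selection(model_a, segment_sel)
  b <- apply_selection(b_al, segment_sel)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty segment selection")
  sqrt(sum((colMeans(a[, c("x", "y", "z")]) -
            colMeans(b[, c("x", "y", "z")]))^2))
}

#' Synthetic tetramer coordinate model
#'
#' Builds a CA-only tetramer with exact C4 geometry: each subunit is a
#' helical arc of `n_res` residues at ring radius `ring_radius`, related
#' by 90 deg rotations about z. `c2_shift_A` translates two opposing
#' subunits axially (breaking C4 to C2); `diag_offset_A` instead pulls one
#' subunit outward along its diagonal.
#'
#' This is a synthetic stand-in used for verifying the measurement
#' operations and, where deposited coordinates are not available, for
#' demonstrating them; it is not a real channel structure.
#'
#' @param n_res residues per subunit.
#' @param ring_radius ring radius (A).
#' @param c2_shift_A axial shift (A) of chains A and C.
#' @param diag_offset_A radial offset (A) of chain A only.
#' @return a `channel_model` with chains A-D.
#' @export
synthetic_tetramer <- function(n_res = 60, ring_radius = 35, c2_shift_A = 0,
                               diag_offset_A = 0) {
  t <- seq(0, 4 * pi, length.out = n_res)
  base <- cbind(x = ring_radius + 6 * cos(t),
                y = 6 * sin(t),
                z = seq(-20, 20, length.out = n_res))
  out <- list()
  for (i in 0:3) {
    ch <- LETTERS[i + 1]
    a <- i * pi / 2
    Rz <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    xyz <- base %*% t(Rz)
    if (ch %in% c("A", "C")) xyz[, 3] <- xyz[, 3] + c2_shift_A
    if (ch == "A" && diag_offset_A != 0)
      xyz[, 1:2] <- sweep(xyz[, 1:2], 2,
                          diag_offset_A * c(cos(a), sin(a)), `+`)
    out[[ch]] <- data.frame(chain = ch, resno = seq_len(n_res), atom = "CA",
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  as_channel_model(do.call(rbind, out))
}
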