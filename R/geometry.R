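# Backbone geometry: dihedral angles, Kabsch superposition, backbone RMSD
# and ungapped peptide sequence identity.

vunit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(v * NA_real_)
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Dihedral angle of four points
#'
#' IUPAC sign convention, degrees in (-180, 180]. Returns `NA` for
#' degenerate (collinear) geometry, with a warning.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees, or `NA`.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-9 || sqrt(sum(n2^2)) < 1e-9) {
    warning("degenerate (collinear) dihedral geometry; angle undefined")
    return(NA_real_)
  }
  m1 <- vcross(n1, vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

backbone_coords <- function(res_atoms, name) {
  row <- res_atoms[res_atoms$atom == name, , drop = FALSE]
  if (nrow(row) != 1) return(NULL)
  c(row$x, row$y, row$z)
}

#' Backbone phi/psi dihedrals of a chain
#'
#' phi(i) is C(i-1)-N(i)-CA(i)-C(i); psi(i) is N(i)-CA(i)-C(i)-N(i+1).
#' The first residue has no phi and the last no psi. Residues with missing
#' backbone atoms, or across numbering gaps, yield `NA` with a warning.
#'
#' @param structure An atom tibble.
#' @param chain Chain identifier.
#' @return A tibble with columns `chain`, `resno`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(structure, chain) {
  poly <- structure[structure$chain == chain, , drop = FALSE]
  if (nrow(poly) == 0) stop_validation(sprintf("chain '%s' not found", chain))
  resnos <- sort(unique(poly$resno))
  getres <- function(rn) poly[poly$resno == rn, , drop = FALSE]
  n <- length(resnos)
  phi <- psi <- rep(NA_real_, n)
  warned <- FALSE
  for (i in seq_len(n)) {
    res <- getres(resnos[i])
    N <- backbone_coords(res, "N")
    CA <- backbone_coords(res, "CA")
    C <- backbone_coords(res, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) {
      if (!warned) {
        warning(sprintf("residue %d of chain '%s' misses backbone atoms; dihedrals undefined",
                        resnos[i], chain))
        warned <- TRUE
      }
      next
    }
    if (i > 1 && resnos[i] - resnos[i - 1] == 1) {
      Cprev <- backbone_coords(getres(resnos[i - 1]), "C")
      if (!is.null(Cprev)) phi[i] <- dihedral_angle(Cprev, N, CA, C)
    }
    if (i < n && resnos[i + 1] - resnos[i] == 1) {
      Nnext <- backbone_coords(getres(resnos[i + 1]), "N")
      if (!is.null(Nnext)) psi[i] <- dihedral_angle(N, CA, C, Nnext)
    }
  }
  tibble::tibble(chain = chain, resno = resnos, phi = phi, psi = psi)
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation and translation mapping `mobile` onto
#' `reference`, reflection-corrected so the rotation is proper
#' (determinant +1).
#'
#' @param mobile,reference Numeric n x 3 matrices of paired coordinates,
#'   n >= 3.
#' @return An object of class `superposition`: a list with `rotation`
#'   (3 x 3), `translation` (length 3), `rmsd` (Angstrom) and `n_atoms`.
#'   The transform maps a row vector `p` to `(p - mobile centroid) %*%
#'   rotation + reference centroid`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop_validation("mobile and reference must have the same number of points")
  }
  if (nrow(mobile) < 3) stop_validation("superposition needs at least 3 paired points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm)
  Q <- sweep(reference, 2, cr)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  moved <- P %*% R
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(
    list(rotation = R, translation = cr - cm %*% R, rmsd = rmsd,
         n_atoms = nrow(mobile), mobile_centroid = cm, reference_centroid = cr),
    class = "superposition"
  )
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Kabsch superposition over %d atoms: RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition` object.
#' @param coords An n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(sweep(as.matrix(coords), 2, sp$mobile_centroid) %*% sp$rotation,
        2, sp$reference_centroid, `+`)
}

backbone_atom_table <- function(structure, chains = NULL) {
  out <- structure[structure$atom %in% c("N", "CA", "C", "O") & !structure$het, ,
                   drop = FALSE]
  if (!is.null(chains)) out <- out[out$chain %in% chains, , drop = FALSE]
  out
}

#' Backbone RMSD between two structures
#'
#' Pairs backbone atoms (N, CA, C, and O where present in both) of mapped
#' residues, optimally superposes the pairs (Kabsch) and returns the RMSD.
#'
#' @param model,reference Atom tibbles.
#' @param mapping Optional tibble with columns `chain` and `resno` naming
#'   the residues to compare (same numbering in both structures). Default:
#'   all (chain, resno) pairs present in both.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(model, reference, mapping = NULL) {
  bm <- backbone_atom_table(model)
  br <- backbone_atom_table(reference)
  if (is.null(mapping)) {
    mapping <- dplyr::inner_join(
      dplyr::distinct(bm[, c("chain", "resno")]),
      dplyr::distinct(br[, c("chain", "resno")]),
      by = c("chain", "resno")
    )
  }
  if (nrow(mapping) == 0) stop_validation("empty residue mapping for backbone RMSD")
  key <- function(df) paste(df$chain, df$resno, df$atom)
  bm <- bm[paste(bm$chain, bm$resno) %in% paste(mapping$chain, mapping$resno), ]
  br <- br[paste(br$chain, br$resno) %in% paste(mapping$chain, mapping$resno), ]
  shared <- intersect(key(bm), key(br))
  if (length(shared) < 3) stop_validation("fewer than 3 shared backbone atoms in mapping")
  bm <- bm[match(shared, key(bm)), ]
  br <- br[match(shared, key(br)), ]
  superpose(as.matrix(bm[, c("x", "y", "z")]),
            as.matrix(br[, c("x", "y", "z")]))$rmsd
}

#' Ungapped sequence identity of a template against a target peptide
#'
#' Slides the template along the target without gaps and counts the
#' maximum number of matching positions; identity is that count divided by
#' the target length.
#'
#' @param template,target One-letter amino-acid strings;
#'   `nchar(template) <= nchar(target)`.
#' @return A one-row tibble: `template`, `target`, `n_match`, `offset`
#'   (0-based offset of the best placement), `identity` (unrounded %) and
#'   `identity_pct` (rounded to the nearest integer percent).
#' @export
peptide_identity <- function(template, target) {
  assert_aa_string(c(template, target), "peptide sequence")
  lt <- nchar(template)
  lg <- nchar(target)
  if (lt > lg) stop_validation("template must not be longer than the target")
  tpl <- stringr::str_split_1(template, "")
  tgt <- stringr::str_split_1(target, "")
  offsets <- 0:(lg - lt)
  matches <- vapply(offsets, function(o) sum(tpl == tgt[(o + 1):(o + lt)]), integer(1))
  best <- which.max(matches)
  identity <- matches[best] / lg * 100
  tibble::tibble(
    template = template, target = target,
    n_match = matches[best], offset = offsets[best],
    identity = identity, identity_pct = as.integer(round(identity))
  )
}
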