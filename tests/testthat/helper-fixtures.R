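# Shared fixtures and independent oracles used across test files.

P27_PEPTIDE <- "NAGSVEQTPKKPGLR"

anchored_site_fixture <- function() {
  path <- system.file("extdata", "cdk2_sites.tsv", package = "cdk2substrate")
  anchor_sites(parse_site_table(path))
}

reference_peptide <- function() {
  build_peptide(P27_PEPTIDE, c(-120, 120), chain = "A", resno_start = 180L)
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

rotation_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
         byrow = TRUE)
}

euler_rotation <- function(a, b, g) {
  rotation_z(a) %*% rotation_y(b) %*% rotation_z(g)
}

# Brute-force superposition oracle, independent of the SVD route:
# exhaustive Euler-angle grid over centered clouds, refined by
# Nelder-Mead from the best grid point.
grid_superpose_rmsd <- function(mobile, reference, step = 20) {
  P <- sweep(as.matrix(mobile), 2, colMeans(mobile))
  Q <- sweep(as.matrix(reference), 2, colMeans(reference))
  rmsd_for <- function(angles) {
    R <- euler_rotation(angles[1], angles[2], angles[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  grid <- expand.grid(
    a = seq(-180, 180 - step, by = step),
    b = seq(0, 180, by = step),
    g = seq(-180, 180 - step, by = step)
  )
  vals <- apply(grid, 1, rmsd_for)
  best <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(best, rmsd_for, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Apply a rigid transform (rotation about z + y, plus translation) to an
# atom tibble.
rigidly_transform <- function(structure, deg_z = 33, deg_y = 21,
                              shift = c(4, -7, 11)) {
  R <- rotation_z(deg_z) %*% rotation_y(deg_y)
  xyz <- as.matrix(structure[, c("x", "y", "z")]) %*% t(R)
  structure$x <- xyz[, 1] + shift[1]
  structure$y <- xyz[, 2] + shift[2]
  structure$z <- xyz[, 3] + shift[3]
  structure
}

hbond_key <- function(tbl) {
  if (nrow(tbl) == 0) return(character())
  sort(paste(tbl$donor_chain, tbl$donor_resno, tbl$donor_atom,
             tbl$acceptor_chain, tbl$acceptor_resno, tbl$acceptor_atom))
}

salt_key <- function(tbl) {
  if (nrow(tbl) == 0) return(character())
  sort(paste(tbl$basic_chain, tbl$basic_resno, tbl$basic_atom,
             tbl$acidic_chain, tbl$acidic_resno, tbl$acidic_atom))
}
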