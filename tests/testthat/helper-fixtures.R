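# fixtures built in code: PDB record lines, small structures, rigid
# transforms

pdbLine <- function(serial, name, resname, chain, resno, x, y, z,
                    element, alt = " ") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resname, chain, resno, x, y, z, element)
}

# structure from explicit atom rows (equal-mass carbons by default)
simpleStructure <- function(xyz, element = "C", chain = "A",
                            resno = seq_len(nrow(xyz)),
                            elety = paste0("C", seq_len(nrow(xyz))),
                            label = "simple") {
  newStructure(data.frame(
    chain = chain, resno = resno, resid = "TOY", elety = elety,
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    stringsAsFactors = FALSE), label = label)
}

randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigidTransform <- function(s, R = randomRotation(), t = rnorm(3, sd = 10)) {
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")]) %*% t(R)
  s@atoms$x <- xyz[, 1] + t[1]
  s@atoms$y <- xyz[, 2] + t[2]
  s@atoms$z <- xyz[, 3] + t[3]
  s
}

# non-rigid conformer at a target superposed RMSD from s (used to plant
# cluster centers that superposition cannot collapse)
conformerStructure <- function(s, targetRmsd, seed, label = "conformer") {
  set.seed(seed)
  n <- nrow(s@atoms)
  d <- matrix(rnorm(3 * n), ncol = 3)
  scale <- targetRmsd
  out <- s
  for (i in 1:4) {
    out <- s
    out@atoms$x <- s@atoms$x + scale * d[, 1]
    out@atoms$y <- s@atoms$y + scale * d[, 2]
    out@atoms$z <- s@atoms$z + scale * d[, 3]
    r <- superposeRmsd(s, out, atomSelection(filter = "all"))$rmsd
    scale <- scale * targetRmsd / r
  }
  out@label <- label
  out
}

# translate every atom by a fixed offset (used to plant cluster centers)
shiftStructure <- function(s, dx = 0, dy = 0, dz = 0, label = s@label) {
  s@atoms$x <- s@atoms$x + dx
  s@atoms$y <- s@atoms$y + dy
  s@atoms$z <- s@atoms$z + dz
  s@label <- label
  s
}
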