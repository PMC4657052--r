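# Builders for tiny in-memory structures and text fixtures used across
# the suite.

atom_df <- function(chain, resno, resname, atom, element, x, y, z, occ = 1) {
  data.frame(chain = chain, resno = resno, resname = resname, atom = atom,
             element = element, x = x, y = y, z = z, occ = occ,
             stringsAsFactors = FALSE)
}

# a lone MET sulphur atom
sd_atom <- function(resno, xyz, chain = "A") {
  atom_df(chain, resno, "MET", "SD", "S", xyz[1], xyz[2], xyz[3])
}

# idealized PHE six-membered ring centred at `centroid` (xy-plane)
phe_ring <- function(resno, centroid, chain = "A", radius = 1.39,
                     drop_atom = NULL) {
  names6 <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- (seq_len(6) - 1) * pi / 3
  out <- atom_df(chain, resno, "PHE", names6,
                 substr(names6, 1, 1),
                 centroid[1] + radius * cos(ang),
                 centroid[2] + radius * sin(ang),
                 centroid[3])
  if (!is.null(drop_atom)) out <- out[out$atom != drop_atom, ]
  out
}

# TRP with all 9 ring atoms (geometry approximate; membership is what the
# ring finder uses)
trp_rings <- function(resno, centroid, chain = "A") {
  names9 <- c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  ang <- (seq_len(9) - 1) * 2 * pi / 9
  atom_df(chain, resno, "TRP", names9,
          substr(names9, 1, 1),
          centroid[1] + 1.3 * cos(ang), centroid[2] + 1.3 * sin(ang),
          centroid[3])
}

# poly-CA chain for sequence/mapping tests; resno may be offset
ca_chain <- function(seq, chain = "A", resno_start = 1) {
  ch <- strsplit(seq, "")[[1]]
  atom_df(chain, seq_along(ch) + resno_start - 1,
          vapply(ch, bio3d::aa123, character(1)), "CA", "C",
          seq_along(ch) * 3.8, 0, 0)
}

# random SD atoms + PHE rings in a box; returns structure and brute-force
# nearest-ring answers
random_motif_structure <- function(n_met, n_ring, box = 30) {
  sds <- lapply(seq_len(n_met), function(i) {
    sd_atom(i, runif(3, 0, box))
  })
  rings <- lapply(seq_len(n_ring), function(j) {
    phe_ring(n_met + j, runif(3, 0, box))
  })
  structure_model(do.call(rbind, c(sds, rings)))
}

# brute-force nearest ring-centroid distance per MET SD (independent of
# the package's geometry code path)
brute_nearest <- function(s) {
  sds <- s[s$atom == "SD", , drop = FALSE]
  phe <- s[s$resname == "PHE", , drop = FALSE]
  cents <- do.call(rbind, lapply(split(phe, phe$resno), function(g) {
    colMeans(as.matrix(g[, c("x", "y", "z")]))
  }))
  vapply(seq_len(nrow(sds)), function(i) {
    min(sqrt(rowSums(sweep(cents, 2,
      as.numeric(sds[i, c("x", "y", "z")]))^2)))
  }, numeric(1))
}

rigid_transform <- function(s, angle = 0.7, axis = c(1, 2, 3),
                            shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% t(R)
  s$x <- xyz[, 1] + shift[1]
  s$y <- xyz[, 2] + shift[2]
  s$z <- xyz[, 3] + shift[3]
  s
}

write_fasta_tmp <- function(ids, seqs) {
  f <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), f)
  f
}

# minimal fixed-width PDB ATOM line writer for parser tests
pdb_atom_line <- function(serial, name, resn, chain, resno, x, y, z,
                          occ = 1, alt = " ", elem = "") {
  namefmt <- if (nchar(name) < 4) sprintf(" %-3s", name)
              else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s%s%-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, namefmt, alt, resn, chain, resno, x, y, z, occ, 0,
          elem)
}
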