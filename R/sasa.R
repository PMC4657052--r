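# Solvent-accessible surface area by the Shrake-Rupley rolling-probe
# point-sampling method, relative accessibility against Gly-X-Gly
# reference maxima, and exposed/buried stratification of motif calls.

# van der Waals radii (Angstrom) by element; unlisted elements fall back
# to 1.80
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Theoretical maximum residue SASA (Angstrom^2) in a Gly-X-Gly tripeptide
# (Tien et al. 2013, theoretical column)
MAX_SASA_GXG <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

# deterministic quasi-uniform points on the unit sphere (Fibonacci spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each heavy atom is covered with `n_points` quasi-uniform test points at
#' radius `r_atom + probe`; a point is accessible when it lies strictly
#' outside every neighbouring atom's probe-inflated sphere (so exactly
#' coincident spheres do not occlude each other). The atom's accessible
#' area is the accessible fraction of `4 * pi * (r + probe)^2`. Hydrogens
#' are excluded, matching crystal-structure practice.
#'
#' @param s A `structure_model`.
#' @param probe Probe (water) radius in Angstrom, default 1.4.
#' @param n_points Test points per atom, default 960.
#' @return Data frame: the heavy atoms of `s` with an added `area` column
#'   (Angstrom^2).
#' @export
shrake_rupley_sasa <- function(s, probe = 1.4, n_points = 960) {
  stopifnot(inherits(s, "structure_model"))
  at <- s[s$element != "H", , drop = FALSE]
  n <- nrow(at)
  if (n == 0) stop_metox("no heavy atoms in structure")
  r <- unname(VDW_RADII[at$element])
  r[is.na(r)] <- 1.80
  R <- r + probe
  xyz <- as.matrix(at[, c("x", "y", "z")])
  pts <- sphere_points(n_points)
  area <- numeric(n)
  max_reach <- max(R)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (R[i] + max_reach)^2)
    nb <- nb[nb != i]
    nb <- nb[d2[nb] < (R[i] + R[nb])^2]
    p <- sweep(pts * R[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, n_points)
      for (j in nb) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
               (p[, 3] - xyz[j, 3])^2
        # strictly inside occludes; relative slack keeps exact-boundary
        # points (e.g. coincident spheres) accessible despite rounding
        free <- free & dj2 >= R[j]^2 * (1 - 1e-9)
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * R[i]^2
  }
  at$area <- area
  at
}

#' Relative accessibility of a residue
#'
#' Residue SASA divided by its theoretical Gly-X-Gly maximum (e.g. 224.0
#' Angstrom^2 for methionine). Values slightly above 1 can occur for very
#' exposed conformations.
#'
#' @param sasa Residue SASA in Angstrom^2 (vectorised).
#' @param resname Three-letter residue name(s).
#' @return Numeric fraction(s).
#' @export
relative_accessibility <- function(sasa, resname) {
  ref <- MAX_SASA_GXG[toupper(resname)]
  if (any(is.na(ref))) {
    stop_metox("no reference maximum SASA for residue(s): ",
               paste(unique(resname[is.na(ref)]), collapse = ", "))
  }
  unname(sasa / ref)
}

#' Residue-level accessibility records
#'
#' Aggregates [shrake_rupley_sasa()] per residue, computes relative
#' accessibility and the exposed/buried classification at the 5% and 20%
#' thresholds (exposed means relative accessibility strictly above the
#' threshold). Residues without a reference maximum (ligands, waters) are
#' dropped.
#'
#' @param s A `structure_model`.
#' @param probe,n_points Passed to [shrake_rupley_sasa()].
#' @return Data frame with columns `chain`, `resno`, `resname`, `sasa`,
#'   `rel_acc`, `exposed_at_5`, `exposed_at_20`.
#' @export
sasa_records <- function(s, probe = 1.4, n_points = 960) {
  at <- shrake_rupley_sasa(s, probe = probe, n_points = n_points)
  at <- at[toupper(at$resname) %in% names(MAX_SASA_GXG), , drop = FALSE]
  if (nrow(at) == 0) stop_metox("no standard residues in structure")
  key <- paste(at$chain, at$resno, at$resname, sep = "\r")
  agg <- aggregate(list(sasa = at$area), list(key = key), sum)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    chain = vapply(parts, `[`, character(1), 1),
    resno = as.integer(vapply(parts, `[`, character(1), 2)),
    resname = vapply(parts, `[`, character(1), 3),
    sasa = agg$sasa, stringsAsFactors = FALSE)
  out$rel_acc <- relative_accessibility(out$sasa, out$resname)
  out$exposed_at_5 <- out$rel_acc > 0.05
  out$exposed_at_20 <- out$rel_acc > 0.20
  out[order(out$chain, out$resno), ]
}

#' Oxidation-by-motif contingency table among exposed methionines
#'
#' Restricts the methionines to those with relative accessibility strictly
#' above `threshold` and cross-tabulates oxidation status against motif
#' status. Used to show that the S-aromatic association is not an artefact
#' of burial: it should persist after excluding buried residues.
#'
#' @param calls A `motif_calls` object.
#' @param sasa Data frame from [sasa_records()].
#' @param oxidized Data frame with columns `chain`, `resno`, `oxidized`
#'   (logical), in structure numbering.
#' @param threshold Relative-accessibility threshold (0 keeps everything).
#' @return A `contingency_2x2` (rows oxidized yes/no, columns motif
#'   yes/no). Methionines missing from `sasa` or `oxidized` are dropped
#'   with a warning; an empty stratum raises an error.
#' @export
stratify_by_exposure <- function(calls, sasa, oxidized, threshold) {
  stopifnot(inherits(calls, "motif_calls"))
  df <- calls$calls
  k <- function(chain, resno) paste(chain, resno)
  df$rel_acc <- sasa$rel_acc[match(k(df$chain, df$resno),
                                   k(sasa$chain, sasa$resno))]
  df$oxidized <- oxidized$oxidized[match(k(df$chain, df$resno),
                                         k(oxidized$chain, oxidized$resno))]
  drop <- is.na(df$rel_acc) | is.na(df$oxidized)
  if (any(drop)) {
    warning(sum(drop), " methionine(s) without accessibility or oxidation ",
            "record dropped", call. = FALSE)
    df <- df[!drop, , drop = FALSE]
  }
  df <- df[df$rel_acc > threshold, , drop = FALSE]
  if (nrow(df) == 0) {
    stop_metox("no methionine exceeds accessibility threshold ", threshold)
  }
  contingency_2x2(
    a = sum(df$oxidized & df$forms_motif),
    b = sum(df$oxidized & !df$forms_motif),
    c = sum(!df$oxidized & df$forms_motif),
    d = sum(!df$oxidized & !df$forms_motif),
    row_labels = c("oxidized", "not oxidized"),
    col_labels = c("motif", "no motif"))
}
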