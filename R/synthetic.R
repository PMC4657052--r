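# Synthetic data with known ground truth: proteomes with controllable
# residue usage, oxidation labels with planted flanking-composition
# biases, toy structures with a controllable S-aromatic motif fraction,
# and a logistic oxidation model linking labels to motif status and
# accessibility. Every generator is a pure function of (config, seed).

# Average human proteome amino-acid frequencies (UniProt-style background;
# methionine at 0.023, the reported human average usage)
HUMAN_AA_FREQ <- c(
  A = 0.070, C = 0.023, D = 0.047, E = 0.071, F = 0.037, G = 0.066,
  H = 0.026, I = 0.043, K = 0.057, L = 0.099, M = 0.023, N = 0.036,
  P = 0.063, Q = 0.048, R = 0.056, S = 0.083, T = 0.053, V = 0.060,
  W = 0.012, Y = 0.027)

#' Configuration for the synthetic-data generators
#'
#' Defaults emulate the study conditions of the source data: 1646 proteins
#' (the H2O2-sensitive set size), human-like background residue
#' frequencies with methionine usage 0.023, a motif fraction of 0.54
#' (roughly 600 of 1118 methionines forming S-aromatic motifs), a baseline
#' oxidation rate of 0.18 for motif-free methionines and a motif odds
#' ratio of 0.3 (together giving a marginal oxidation rate near 0.12,
#' i.e. 136/1118). The accessibility effect defaults to 0 so that motif
#' effects can be studied unconfounded; set `beta_acc > 0` to plant the
#' burial confounder deliberately.
#'
#' @param n_proteins Number of proteins to simulate.
#' @param mean_length Mean protein length (Poisson, minimum 25).
#' @param aa_freq Named background frequencies over the 20 amino acids,
#'   summing to 1.
#' @param env_effects Planted flanking-composition biases: a list of lists
#'   with elements `residue` (single letter), `offsets` (integer offsets
#'   relative to the methionine) and `delta` (added frequency mass).
#' @param motif_fraction Fraction of methionines placed within 7 Angstrom
#'   of an aromatic ring centroid in toy structures.
#' @param beta0,beta_motif,beta_acc Logistic oxidation model coefficients:
#'   `P(oxidized) = plogis(beta0 + beta_motif * motif + beta_acc *
#'   rel_acc)`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_proteins = 1646, mean_length = 460,
                             aa_freq = HUMAN_AA_FREQ,
                             env_effects = NULL,
                             motif_fraction = 0.54,
                             beta0 = qlogis(0.18),
                             beta_motif = log(0.3),
                             beta_acc = 0) {
  if (!setequal(names(aa_freq), AA20)) {
    stop_metox("aa_freq must be named by the 20 canonical amino acids")
  }
  aa_freq <- aa_freq[AA20]
  if (abs(sum(aa_freq) - 1) > 1e-9 || any(aa_freq < 0)) {
    stop_metox("aa_freq must be non-negative and sum to 1")
  }
  if (motif_fraction < 0 || motif_fraction > 1) {
    stop_metox("motif_fraction must lie in [0, 1]")
  }
  for (eff in env_effects) {
    if (eff$delta < 0 || aa_freq[eff$residue] + eff$delta > 1) {
      stop_metox("planted delta leaves frequencies outside [0, 1]")
    }
  }
  structure(list(n_proteins = n_proteins, mean_length = mean_length,
                 aa_freq = aa_freq, env_effects = env_effects,
                 motif_fraction = motif_fraction, beta0 = beta0,
                 beta_motif = beta_motif, beta_acc = beta_acc),
            class = "synthetic_config")
}

#' Generate a synthetic proteome
#'
#' Residues are drawn i.i.d. from the background frequencies; lengths are
#' Poisson around `mean_length` with a floor of 25; position 1 is forced
#' to methionine (the translation initiator).
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @return Protein set data frame (`id`, `seq`).
#' @export
gen_proteome <- function(cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    lens <- pmax(25L, rpois(cfg$n_proteins, cfg$mean_length))
    seqs <- vapply(lens, function(L) {
      ch <- sample(AA20, L, replace = TRUE, prob = cfg$aa_freq)
      ch[1] <- "M"
      paste(ch, collapse = "")
    }, character(1))
    data.frame(id = sprintf("SYN%05d", seq_len(cfg$n_proteins)),
               seq = seqs, stringsAsFactors = FALSE)
  })
}

#' Plant a flanking-composition bias around oxidized methionines
#'
#' A random half of the eligible methionines (those with a full 10-residue
#' window on both sides) are labelled oxidized. For each oxidized site and
#' each configured effect, the residues at the configured offsets are
#' resampled from the background with the effect residue's frequency
#' increased by `delta` (other frequencies renormalized). Positions that
#' are themselves labelled methionine sites are never overwritten.
#'
#' @param proteome Protein set data frame from [gen_proteome()].
#' @param cfg A `synthetic_config` (its `env_effects` are planted).
#' @param seed Integer seed.
#' @return List with `proteome` (possibly modified sequences) and `sites`
#'   (data frame `protein_id`, `pos`, `oxidized`).
#' @export
plant_env_bias <- function(proteome, cfg, seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    chars <- lapply(proteome$seq, seq_chars)
    sites <- do.call(rbind, lapply(seq_len(nrow(proteome)), function(i) {
      mets <- which(chars[[i]] == "M")
      mets <- mets[mets > 10 & mets + 10 <= length(chars[[i]])]
      if (length(mets) == 0) return(NULL)
      data.frame(protein_id = proteome$id[i], pos = mets, prot = i,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(sites)) {
      return(list(proteome = proteome,
                  sites = data.frame(protein_id = character(),
                                     pos = integer(), oxidized = logical(),
                                     stringsAsFactors = FALSE)))
    }
    n <- nrow(sites)
    sites$oxidized <- FALSE
    sites$oxidized[sample.int(n, floor(n / 2))] <- TRUE
    site_key <- paste(sites$prot, sites$pos)
    for (eff in cfg$env_effects %||% list()) {
      f <- cfg$aa_freq
      boosted <- f
      boosted[eff$residue] <- f[eff$residue] + eff$delta
      others <- setdiff(AA20, eff$residue)
      boosted[others] <- f[others] *
        (1 - boosted[eff$residue]) / (1 - f[eff$residue])
      for (r in which(sites$oxidized)) {
        targets <- sites$pos[r] + eff$offsets
        targets <- targets[!(paste(sites$prot[r], targets) %in% site_key)]
        if (length(targets)) {
          chars[[sites$prot[r]]][targets] <-
            sample(AA20, length(targets), replace = TRUE, prob = boosted)
        }
      }
    }
    proteome$seq <- vapply(chars, paste, character(1), collapse = "")
    list(proteome = proteome,
         sites = sites[, c("protein_id", "pos", "oxidized")])
  })
}

# idealized residue scaffolds, coordinates relative to the site anchor
met_scaffold <- function(resno, origin) {
  offs <- rbind(N  = c(-2.9,  1.2,  0.2),
                CA = c(-2.2,  0.0,  0.0),
                C  = c(-3.0, -1.2,  0.3),
                O  = c(-4.2, -1.4,  0.5),
                CB = c(-1.1, -0.4, -0.9),
                CG = c(-0.8,  0.6, -0.3),
                SD = c( 0.0,  0.0,  0.0),
                CE = c( 1.3,  1.0, -0.6))
  data.frame(chain = "A", resno = resno, resname = "MET",
             atom = rownames(offs),
             element = substr(rownames(offs), 1, 1),
             x = offs[, 1] + origin[1], y = offs[, 2] + origin[2],
             z = offs[, 3] + origin[3], occ = 1,
             stringsAsFactors = FALSE)
}

phe_scaffold <- function(resno, centroid, bond = 1.39) {
  ang <- (seq_len(6) - 1) * pi / 3 + pi / 2
  ring <- cbind(bond * cos(ang), bond * sin(ang), 0)
  rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  extra <- rbind(CB = c(0.0, 2.9, 0.3), CA = c(0.0, 4.1, 0.9),
                 N  = c(1.2, 4.7, 0.7), C  = c(-1.2, 4.8, 1.1),
                 O  = c(-1.9, 5.7, 1.5))
  offs <- rbind(ring, extra)
  data.frame(chain = "A", resno = resno, resname = "PHE",
             atom = rownames(offs),
             element = substr(rownames(offs), 1, 1),
             x = offs[, 1] + centroid[1], y = offs[, 2] + centroid[2],
             z = offs[, 3] + centroid[3], occ = 1,
             stringsAsFactors = FALSE)
}

#' Generate a toy structure with a known S-aromatic motif fraction
#'
#' Methionine/phenylalanine residue pairs are placed on a widely spaced 3D
#' grid (no cross-site contacts possible). For a `round(motif_fraction *
#' n_met)` subset of methionines the phenylalanine ring centroid is placed
#' at a distance drawn uniformly from [4.5, 6.5] Angstrom of the SD
#' sulphur; for the rest, from [8.5, 11.5] Angstrom. The construction
#' leaves a margin around the 7 Angstrom cutoff, so the recovered motif
#' fraction equals the configured one exactly.
#'
#' @param cfg A `synthetic_config` (supplies `motif_fraction`).
#' @param seed Integer seed.
#' @param n_met Number of methionines to place.
#' @param spacing Grid spacing in Angstrom (default 40).
#' @return List with `structure` (a `structure_model`; methionines have
#'   odd residue numbers, their partner phenylalanines the following even
#'   number) and `truth` (data frame `resno`, `forms_motif`, `dist`).
#' @export
gen_toy_structure <- function(cfg = synthetic_config(), seed, n_met = 100,
                              spacing = 40) {
  stopifnot(inherits(cfg, "synthetic_config"), n_met >= 1)
  with_seed(seed, {
    k <- round(cfg$motif_fraction * n_met)
    motif <- rep(FALSE, n_met)
    if (k > 0) motif[sample.int(n_met, k)] <- TRUE
    m <- ceiling(n_met^(1 / 3))
    idx <- seq_len(n_met) - 1
    origin <- cbind((idx %% m), ((idx %/% m) %% m), (idx %/% (m * m))) *
      spacing
    d <- ifelse(motif, runif(n_met, 4.5, 6.5), runif(n_met, 8.5, 11.5))
    atoms <- do.call(rbind, lapply(seq_len(n_met), function(i) {
      rbind(met_scaffold(2L * i - 1L, origin[i, ]),
            phe_scaffold(2L * i, origin[i, ] + c(0, 0, d[i])))
    }))
    list(structure = structure_model(atoms),
         truth = data.frame(resno = 2L * seq_len(n_met) - 1L,
                            forms_motif = motif, dist = d))
  })
}

#' Draw oxidation labels from the logistic oxidation model
#'
#' `P(oxidized) = plogis(beta0 + beta_motif * motif + beta_acc *
#' rel_acc)`: motif-forming methionines are protected when `beta_motif <
#' 0` (the default odds ratio is 0.3) and exposed methionines oxidise more
#' when `beta_acc > 0`.
#'
#' @param motif Logical vector of motif statuses.
#' @param rel_acc Numeric vector of relative accessibilities (default all
#'   0, i.e. no accessibility effect enters).
#' @param cfg A `synthetic_config` (supplies the coefficients).
#' @param seed Integer seed.
#' @return Logical vector of oxidation labels; attribute `prob` holds the
#'   per-site oxidation probabilities.
#' @export
gen_oxidation_labels <- function(motif, rel_acc = NULL,
                                 cfg = synthetic_config(), seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  rel_acc <- rel_acc %||% rep(0, length(motif))
  stopifnot(length(rel_acc) == length(motif))
  p <- plogis(cfg$beta0 + cfg$beta_motif * as.numeric(motif) +
              cfg$beta_acc * rel_acc)
  out <- with_seed(seed, rbinom(length(motif), 1, p) == 1)
  attr(out, "prob") <- p
  out
}
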