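# Flanking-sequence environment statistics: per-offset residue frequencies
# around methionine sites and the standardized frequency-difference
# (z-score) matrix comparing oxidation-prone with oxidation-resistant
# environments.

as_seq_lookup <- function(proteins) {
  if (is.data.frame(proteins)) seq_lookup(proteins) else proteins
}

# retained sites: methionines with >= 10 residues on both sides
env_eligible <- function(sites, lookup) {
  len <- nchar(lookup[sites$protein_id])
  !is.na(len) & sites$pos > 10 & sites$pos + 10 <= len
}

#' Flanking-residue frequency matrix around methionine sites
#'
#' For each offset j in -10..-1, +1..+10 relative to the central
#' methionine, the relative frequency of each of the 20 amino acids is
#' computed over all retained sites. Sites with fewer than 10 neighbours on
#' either side are excluded entirely (windows are never padded), so every
#' retained site contributes one residue at every offset. `X` residues are
#' excluded from both numerator and denominator.
#'
#' @param sites Data frame of methionine sites (`protein_id`, `pos`).
#' @param proteins Protein set data frame or a named `id -> seq` vector.
#' @return A `freq_matrix`: list with `f` (20 x 20 matrix, rows = amino
#'   acids, columns = offsets as character) and `n` (number of retained
#'   sites).
#' @export
env_frequencies <- function(sites, proteins) {
  lookup <- as_seq_lookup(proteins)
  keep <- env_eligible(sites, lookup)
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0) {
    stop_metox("no methionine site has 10 neighbours on both sides")
  }
  counts <- matrix(0, nrow = 20, ncol = length(ENV_OFFSETS),
                   dimnames = list(AA20, as.character(ENV_OFFSETS)))
  denom <- numeric(length(ENV_OFFSETS))
  for (i in seq_len(nrow(sites))) {
    s <- lookup[[sites$protein_id[i]]]
    res <- substring(s, sites$pos[i] + ENV_OFFSETS,
                     sites$pos[i] + ENV_OFFSETS)
    ok <- res %in% AA20
    denom[ok] <- denom[ok] + 1
    idx <- cbind(match(res[ok], AA20), which(ok))
    counts[idx] <- counts[idx] + 1
  }
  f <- sweep(counts, 2, pmax(denom, 1), "/")
  structure(list(f = f, n = nrow(sites)), class = "freq_matrix")
}

#' Pair each oxidized site with a resistant methionine from the same protein
#'
#' For every oxidized site with a full 10-residue window, one non-oxidized
#' methionine from the same protein (itself with a full window) is chosen
#' uniformly at random. Partners are drawn without replacement within a
#' protein, so each resistant methionine backs at most one oxidized site:
#' the z-score null calibration relies on the paired sites being distinct
#' observations. Oxidized sites left without an eligible partner are
#' dropped. Reproducible under a fixed seed.
#'
#' @param oxidized Data frame of oxidized methionine sites.
#' @param proteins Protein set data frame or named lookup vector.
#' @param seed Integer seed.
#' @return List with `oxidized` and `resistant` site data frames of equal
#'   row count (row i of one is paired with row i of the other), plus
#'   `n_dropped`, the number of oxidized sites without an eligible partner.
#' @export
pair_resistant_sites <- function(oxidized, proteins, seed) {
  lookup <- as_seq_lookup(proteins)
  oxidized <- oxidized[env_eligible(oxidized, lookup), , drop = FALSE]
  pick <- rep(NA_integer_, nrow(oxidized))
  with_seed(seed, {
    for (pid in unique(oxidized$protein_id)) {
      rows <- which(oxidized$protein_id == pid)
      s <- lookup[[pid]]
      mets <- which(seq_chars(s) == "M")
      mets <- mets[mets > 10 & mets + 10 <= nchar(s)]
      # candidates: eligible methionines not themselves oxidized
      avail <- setdiff(mets, oxidized$pos[rows])
      for (r in rows) {
        if (length(avail) == 0) break
        j <- avail[sample.int(length(avail), 1)]
        pick[r] <- j
        avail <- setdiff(avail, j)
      }
    }
  })
  ok <- !is.na(pick)
  res <- data.frame(protein_id = oxidized$protein_id[ok],
                    pos = pick[ok], oxidized = rep(FALSE, sum(ok)),
                    stringsAsFactors = FALSE)
  list(oxidized = oxidized[ok, , drop = FALSE], resistant = res,
       n_dropped = sum(!ok))
}

#' Standardized frequency-difference (z-score) matrix
#'
#' For each residue i and offset j, the difference between the
#' oxidation-prone and oxidation-resistant relative frequencies is
#' standardized by its two-proportion null standard error:
#' \deqn{z_{ij} = \frac{f^{ox}_{ij} - f^{res}_{ij}}{
#'   \sqrt{(f^{ox}_{ij}(1-f^{ox}_{ij}) + f^{res}_{ij}(1-f^{res}_{ij}))/n}}}
#' Under the null of identical environments, z is approximately standard
#' normal. Positive z means residue i is more frequent near oxidation-prone
#' methionines. A 0/0 cell (residue absent from both environments) is 0.
#'
#' @param fo,fr `freq_matrix` objects for the oxidation-prone and
#'   oxidation-resistant environments; their `n` must match.
#' @return A `zscore_matrix`: list with `z` (20 x 20) and `n`.
#' @export
zscore_matrix <- function(fo, fr) {
  stopifnot(inherits(fo, "freq_matrix"), inherits(fr, "freq_matrix"))
  if (fo$n != fr$n) {
    stop_metox("frequency matrices built from different site counts: ",
               fo$n, " vs ", fr$n)
  }
  if (fo$n <= 0) stop_metox("site count must be positive")
  se2 <- (fo$f * (1 - fo$f) + fr$f * (1 - fr$f)) / fo$n
  z <- (fo$f - fr$f) / sqrt(se2)
  z[se2 == 0] <- 0
  structure(list(z = z, n = fo$n), class = "zscore_matrix")
}

#' Count z-scores outside symmetric intervals
#'
#' Under the null, the 400 entries behave like standard normals: about
#' `400 * 2 * (1 - pnorm(b))` are expected outside `[-b, b]`. Observed
#' counts far above that indicate distinguishable sequence environments.
#'
#' @param zm A `zscore_matrix`.
#' @param bounds Numeric half-widths (default `c(2, 3)`).
#' @return Data frame with columns `bound`, `n_outside`, `frac_negative`
#'   (fraction of the outside entries that are negative; `NaN` if none)
#'   and `expected_null` (analytic expectation for 400 standard normals).
#' @export
interval_counts <- function(zm, bounds = c(2, 3)) {
  stopifnot(inherits(zm, "zscore_matrix"))
  n_cells <- length(zm$z)
  out <- lapply(bounds, function(b) {
    outside <- zm$z[abs(zm$z) > b]
    data.frame(bound = b, n_outside = length(outside),
               frac_negative = if (length(outside)) mean(outside < 0)
                               else NaN,
               expected_null = n_cells * 2 * (1 - pnorm(b)))
  })
  do.call(rbind, out)
}

#' Per-residue aggregate environment score
#'
#' The contribution of each amino acid to the environmental difference,
#' summarised as the sum of |z| over the 20 offsets.
#'
#' @param zm A `zscore_matrix`.
#' @return Named numeric vector of length 20 (one score per amino acid).
#' @export
aa_aggregate_scores <- function(zm) {
  stopifnot(inherits(zm, "zscore_matrix"))
  rowSums(abs(zm$z))
}
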