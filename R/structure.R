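# S-aromatic motif geometry: aromatic ring centroids, sulphur-to-centroid
# distances, the 7 Angstrom motif call, nearest-distance histograms, chain
# redundancy removal and sequence-separation summaries.

RING_ATOMS <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(pyrrole = c("CG", "CD1", "CD2", "NE1", "CE2"),
             benzene = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")))

#' Aromatic ring centroids of a structure
#'
#' Phe and Tyr contribute one six-membered ring each; Trp contributes two
#' rings, the five-membered pyrrole and the six-membered benzene. The
#' centroid is the unweighted mean of the member-atom coordinates. Rings
#' with missing member atoms are skipped with a warning.
#'
#' @param s A `structure_model`.
#' @return Data frame with columns `chain`, `resno`, `resname`, `ring`,
#'   `cx`, `cy`, `cz`, `n_atoms`.
#' @export
ring_centroids <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  arom <- s[s$resname %in% names(RING_ATOMS), , drop = FALSE]
  if (nrow(arom) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), ring = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  }
  res_key <- paste(arom$chain, arom$resno, arom$resname, sep = "\r")
  out <- list()
  for (k in unique(res_key)) {
    atoms <- arom[res_key == k, , drop = FALSE]
    rings <- RING_ATOMS[[atoms$resname[1]]]
    for (ring_name in names(rings)) {
      members <- rings[[ring_name]]
      got <- atoms[atoms$atom %in% members, , drop = FALSE]
      if (nrow(got) < length(members)) {
        warning(sprintf("skipping %s ring of %s %s%d: missing atom(s) %s",
                        ring_name, atoms$resname[1], atoms$chain[1],
                        atoms$resno[1],
                        paste(setdiff(members, got$atom), collapse = ",")),
                call. = FALSE)
        next
      }
      out[[length(out) + 1]] <- data.frame(
        chain = atoms$chain[1], resno = atoms$resno[1],
        resname = atoms$resname[1], ring = ring_name,
        cx = mean(got$x), cy = mean(got$y), cz = mean(got$z),
        n_atoms = nrow(got), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain = character(), resno = integer(),
                      resname = character(), ring = character(),
                      cx = numeric(), cy = numeric(), cz = numeric(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Sulphur-to-aromatic-ring motif calls
#'
#' For every methionine with a resolved SD sulphur atom, the Euclidean
#' distance to every aromatic ring centroid (all chains; inter-chain
#' contacts count) is computed. A methionine forms an S-aromatic motif when
#' its nearest centroid lies within `cutoff` (7 Angstrom, the first minimum
#' of the bimodal sulphur-aromatic distance distribution). Methionines
#' without an SD atom are skipped with a warning.
#'
#' @param s A `structure_model`.
#' @param cutoff Motif distance threshold in Angstrom (default 7.0).
#' @return A `motif_calls` object: list with `calls` (data frame `chain`,
#'   `resno`, `nearest_dist`, `nearest_chain`, `nearest_resno`,
#'   `nearest_resname`, `nearest_ring`, `forms_motif`), `contacts` (all
#'   ring contacts with distance <= `cutoff`: one row per (methionine,
#'   ring) pair) and `cutoff`.
#' @export
s_aromatic_calls <- function(s, cutoff = 7.0) {
  stopifnot(inherits(s, "structure_model"))
  rings <- ring_centroids(s)
  met <- s[s$resname == "MET", , drop = FALSE]
  met_key <- unique(paste(met$chain, met$resno, sep = "\r"))
  calls <- list(); contacts <- list()
  for (k in met_key) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    ch <- parts[1]; rn <- as.integer(parts[2])
    sd <- met[met$chain == ch & met$resno == rn & met$atom == "SD", ,
              drop = FALSE]
    if (nrow(sd) == 0) {
      warning(sprintf("MET %s%d has no SD atom; skipped", ch, rn),
              call. = FALSE)
      next
    }
    if (nrow(rings) > 0) {
      d <- sqrt((rings$cx - sd$x[1])^2 + (rings$cy - sd$y[1])^2 +
                (rings$cz - sd$z[1])^2)
      near <- which.min(d)
      close_idx <- which(d <= cutoff)
      if (length(close_idx)) {
        contacts[[length(contacts) + 1]] <- data.frame(
          met_chain = ch, met_resno = rn,
          ring_chain = rings$chain[close_idx],
          ring_resno = rings$resno[close_idx],
          ring_resname = rings$resname[close_idx],
          ring = rings$ring[close_idx],
          dist = d[close_idx], stringsAsFactors = FALSE)
      }
      calls[[length(calls) + 1]] <- data.frame(
        chain = ch, resno = rn, nearest_dist = d[near],
        nearest_chain = rings$chain[near],
        nearest_resno = rings$resno[near],
        nearest_resname = rings$resname[near],
        nearest_ring = rings$ring[near],
        forms_motif = d[near] <= cutoff, stringsAsFactors = FALSE)
    } else {
      calls[[length(calls) + 1]] <- data.frame(
        chain = ch, resno = rn, nearest_dist = NA_real_,
        nearest_chain = NA_character_, nearest_resno = NA_integer_,
        nearest_resname = NA_character_, nearest_ring = NA_character_,
        forms_motif = FALSE, stringsAsFactors = FALSE)
    }
  }
  empty_calls <- data.frame(
    chain = character(), resno = integer(), nearest_dist = numeric(),
    nearest_chain = character(), nearest_resno = integer(),
    nearest_resname = character(), nearest_ring = character(),
    forms_motif = logical(), stringsAsFactors = FALSE)
  empty_contacts <- data.frame(
    met_chain = character(), met_resno = integer(),
    ring_chain = character(), ring_resno = integer(),
    ring_resname = character(), ring = character(), dist = numeric(),
    stringsAsFactors = FALSE)
  structure(list(
    calls = if (length(calls)) do.call(rbind, calls) else empty_calls,
    contacts = if (length(contacts)) do.call(rbind, contacts)
               else empty_contacts,
    cutoff = cutoff), class = "motif_calls")
}

#' Histogram of nearest sulphur-to-ring distances
#'
#' Bins the nearest-centroid distance of each methionine over `[0, 20]`
#' Angstrom and locates the first local minimum of the binned counts (the
#' valley between the contact mode near 5 Angstrom and the bulk mode,
#' which motivates the 7 Angstrom cutoff).
#'
#' @param calls A `motif_calls` object.
#' @param binwidth Bin width in Angstrom.
#' @param max_dist Upper limit of the binning range (default 20).
#' @return List with `breaks`, `counts`, `mids` and `first_min` (midpoint
#'   of the first interior local-minimum bin, `NA` if none).
#' @export
distance_histogram <- function(calls, binwidth = 0.5, max_dist = 20) {
  stopifnot(inherits(calls, "motif_calls"), binwidth > 0)
  d <- calls$calls$nearest_dist
  d <- d[is.finite(d) & d >= 0 & d < max_dist]
  breaks <- seq(0, max_dist, by = binwidth)
  if (breaks[length(breaks)] < max_dist) breaks <- c(breaks, max_dist)
  counts <- if (length(d)) {
    tabulate(findInterval(d, breaks, rightmost.closed = FALSE),
             nbins = length(breaks) - 1)
  } else integer(length(breaks) - 1)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  first_min <- NA_real_
  if (length(counts) >= 3) {
    for (i in 2:(length(counts) - 1)) {
      if (counts[i] < counts[i - 1] && counts[i] <= counts[i + 1] &&
          any(counts[seq_len(i - 1)] > 0)) {
        first_min <- mids[i]
        break
      }
    }
  }
  list(breaks = breaks, counts = counts, mids = mids, first_min = first_min)
}

#' Remove redundant (sequence-identical) chains
#'
#' Crystal structures of homo-oligomers duplicate every observation once
#' per protomer. Chains are grouped by identical one-letter sequence and
#' the lexicographically lowest chain identifier of each group is kept.
#'
#' @param s A `structure_model`.
#' @return Character vector of retained chain identifiers.
#' @export
dedup_chains <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  chains <- sort(unique(s$chain))
  seqs <- vapply(chains, function(ch) chain_sequence(s, ch)$seq,
                 character(1))
  chains[!duplicated(seqs)]
}

#' Sequence separations of motif-forming S-aromatic pairs
#'
#' For every (methionine, contacting aromatic residue) pair within the
#' motif cutoff, the absolute difference of their positions in the primary
#' structure. Trp's two rings collapse to one pair per residue. Cross-chain
#' contacts have no linear distance and are excluded (a message reports
#' how many).
#'
#' @param calls A `motif_calls` object.
#' @param map Optional `residue_map` translating author residue numbers to
#'   sequence positions; when `NULL` the author numbering difference is
#'   used directly (valid for sequentially numbered structures).
#' @return List with `pairs` (data frame `met_resno`, `ring_resno`,
#'   `ring_resname`, `separation`) and `summary` (per aromatic type: `n`,
#'   `median`, `mean`, `sd`).
#' @export
linear_separations <- function(calls, map = NULL) {
  stopifnot(inherits(calls, "motif_calls"))
  ct <- calls$contacts
  cross <- ct$met_chain != ct$ring_chain
  if (any(cross)) {
    message(sum(cross), " cross-chain contact(s) excluded from linear ",
            "separations")
  }
  ct <- ct[!cross, , drop = FALSE]
  ct <- ct[!duplicated(paste(ct$met_chain, ct$met_resno, ct$ring_chain,
                             ct$ring_resno, sep = "\r")), , drop = FALSE]
  to_seq <- function(chain, resno) {
    if (is.null(map)) return(resno)
    idx <- match(paste(chain, resno), paste(map$chain, map$resno))
    map$seq_pos[idx]
  }
  sep <- abs(to_seq(ct$met_chain, ct$met_resno) -
             to_seq(ct$ring_chain, ct$ring_resno))
  keep <- !is.na(sep)
  pairs <- data.frame(met_resno = ct$met_resno[keep],
                      ring_resno = ct$ring_resno[keep],
                      ring_resname = ct$ring_resname[keep],
                      separation = sep[keep], stringsAsFactors = FALSE)
  summary <- if (nrow(pairs)) {
    do.call(rbind, lapply(split(pairs, pairs$ring_resname), function(g) {
      data.frame(resname = g$ring_resname[1], n = nrow(g),
                 median = median(g$separation), mean = mean(g$separation),
                 sd = sd(g$separation), stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(resname = character(), n = integer(), median = numeric(),
               mean = numeric(), sd = numeric(), stringsAsFactors = FALSE)
  }
  rownames(summary) <- NULL
  list(pairs = pairs, summary = summary)
}
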