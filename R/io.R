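# Reading and writing of external formats, packaged fixtures, and the
# mapping between UniProt-style sequence numbering and PDB author numbering.

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and trailing `*` stop characters are stripped.
#' Positions are 1-based throughout the package; the N-terminal initiator
#' methionine is position 1. Residues outside the 20 canonical letters
#' (e.g. B, Z, J, U, O) are replaced by `X` with a warning; `X` is excluded
#' from all frequency counts downstream.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first token of the header) and
#'   `seq` (amino-acid string), one row per record. An empty file yields a
#'   zero-row data frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_metox("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  seqs <- toupper(as.character(set))
  seqs <- gsub("\\*+$", "", seqs)
  bad <- !nzchar(seqs)
  if (any(bad)) {
    stop_metox("empty sequence for FASTA record(s): ",
               paste(ids[bad], collapse = ", "))
  }
  nonstd <- grepl(paste0("[^", paste(AA20, collapse = ""), "X]"), seqs)
  if (any(nonstd)) {
    warning("non-canonical residues replaced by X in record(s): ",
            paste(ids[nonstd], collapse = ", "), call. = FALSE)
    seqs <- gsub(paste0("[^", paste(AA20, collapse = ""), "X]"), "X", seqs)
  }
  data.frame(id = unname(ids), seq = unname(seqs), stringsAsFactors = FALSE)
}

#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Only the first MODEL is retained. For alternate locations the highest
#' occupancy conformer is kept, ties resolved towards altloc `A`.
#' Hydrogens are retained here; accessibility routines drop them.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif` file. The dialect is chosen
#'   by extension, falling back to content sniffing (`loop_`/`_atom_site`).
#' @return A `structure_model`: a data frame of atoms with columns `chain`,
#'   `resno`, `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop_metox("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  is_cif <- ext %in% c("cif", "mmcif")
  if (!is_cif && !ext %in% c("pdb", "ent")) {
    head_txt <- readLines(path, n = 50L, warn = FALSE)
    is_cif <- any(grepl("^_atom_site\\.|^loop_", head_txt))
  }
  pdb <- if (is_cif) bio3d::read.cif(path, verbose = FALSE,
                                     rm.alt = FALSE)
         else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE,
                              rm.alt = FALSE)
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop_metox("no atoms found in structure file: ", path)
  }
  at <- at[at$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (nrow(at) == 0) stop_metox("no ATOM records in structure file: ", path)
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  # alternate locations: keep highest occupancy, ties towards 'A'
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  ord <- order(key, -at$o, at$alt)
  keep <- sort(ord[!duplicated(key[ord])])  # original file order
  at <- at[keep, , drop = FALSE]
  elem <- at$elesy
  elem[is.na(elem) | !nzchar(trimws(elem))] <- NA
  miss <- is.na(elem)
  if (any(miss)) {
    # derive element from the atom name: first alphabetic character
    elem[miss] <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                      gsub("^[0-9]+", "", at$elety[miss])),
                                 1, 1))
  }
  structure_model(data.frame(
    chain = at$chain, resno = at$resno, resname = at$resid,
    atom = at$elety, element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z, occ = at$o,
    stringsAsFactors = FALSE))
}

#' Construct a structure model from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `element`, `x`, `y`, `z` and optionally `occ`.
#' @return The validated atom data frame with class `structure_model`.
#' @export
structure_model <- function(atoms) {
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols)) {
    stop_metox("atom table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop_metox("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_metox("non-finite atomic coordinates")
  }
  if (is.null(atoms$occ)) atoms$occ <- 1
  rownames(atoms) <- NULL
  class(atoms) <- c("structure_model", "data.frame")
  atoms
}

#' Write a structure model to a PDB file
#'
#' Coordinates are written with 3 decimal places, so a write/read round trip
#' preserves them to 0.001 Angstrom.
#'
#' @param s A `structure_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "structure_model"))
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(s[, c("x", "y", "z")]))),
                   resno = s$resno, resid = s$resname,
                   eleno = seq_len(nrow(s)), elety = s$atom,
                   chain = s$chain, o = s$occ, elesy = s$element)
  invisible(path)
}

# one-letter chain sequence in order of residue appearance
chain_sequence <- function(s, chain) {
  sub <- s[s$chain == chain, , drop = FALSE]
  if (nrow(sub) == 0) stop_metox("chain not present in structure: ", chain)
  keep <- !duplicated(sub$resno)
  res <- sub[keep, , drop = FALSE]
  lett <- suppressWarnings(bio3d::aa321(res$resname))
  lett[is.na(lett) | !lett %in% AA20] <- "X"
  list(resno = res$resno, letters = lett,
       seq = paste(lett, collapse = ""))
}

#' Map sequence positions onto structure residue numbers
#'
#' PDB author numbering routinely differs from UniProt sequence numbering,
#' so benchmark positions given in sequence space must be translated before
#' any structural lookup. A global pairwise alignment (match +1, mismatch
#' -1, linear gap penalty 2) is computed between the protein sequence and
#' the chain's one-letter sequence; identically aligned residues become map
#' entries.
#'
#' @param p A protein record: either a one-row data frame with columns
#'   `id`/`seq` (as from [read_fasta()]) or a plain sequence string.
#' @param s A `structure_model`.
#' @param chain Chain identifier present in `s`.
#' @return A `residue_map` data frame with columns `seq_pos`, `chain`,
#'   `resno`; attribute `identity` holds the fraction of identical residues
#'   among aligned (gap-free) columns.
#' @details An identity below 0.9 raises an error: it signals a wrong
#'   chain/protein pairing rather than ordinary missing density.
#' @export
map_sequence_to_structure <- function(p, s, chain) {
  seq <- if (is.character(p) && length(p) == 1) p else p$seq[1]
  cs <- chain_sequence(s, chain)
  letters_all <- sort(unique(c(AA20, "X", seq_chars(seq), cs$letters)))
  mat <- matrix(-1, length(letters_all), length(letters_all),
                dimnames = list(letters_all, letters_all))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq), Biostrings::AAString(cs$seq),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 2,
    type = "global")
  pa <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
  ip <- 0L; is <- 0L
  seq_pos <- integer(0); str_idx <- integer(0)
  n_aligned <- 0L; n_ident <- 0L
  for (k in seq_along(pa)) {
    pg <- pa[k] == "-"; sg <- sa[k] == "-"
    if (!pg) ip <- ip + 1L
    if (!sg) is <- is + 1L
    if (!pg && !sg) {
      n_aligned <- n_aligned + 1L
      if (pa[k] == sa[k]) {
        n_ident <- n_ident + 1L
        seq_pos <- c(seq_pos, ip)
        str_idx <- c(str_idx, is)
      }
    }
  }
  identity <- if (n_aligned > 0) n_ident / n_aligned else 0
  if (identity < 0.9) {
    stop_metox(sprintf(
      "sequence/structure identity %.2f < 0.9 for chain %s: wrong pairing?",
      identity, chain))
  }
  out <- data.frame(seq_pos = seq_pos, chain = chain,
                    resno = cs$resno[str_idx], stringsAsFactors = FALSE)
  attr(out, "identity") <- identity
  class(out) <- c("residue_map", "data.frame")
  out
}

#' Packaged in-vitro reactivity benchmark (therapeutic proteins)
#'
#' Thirty-five methionines from eight therapeutic proteins whose in-vitro
#' H2O2 oxidation kinetics are documented in the literature, each assigned
#' to a `low` or `high` empirical reactivity class by a per-protein median
#' split. Positions are sequence positions, not PDB author numbers.
#'
#' @return Data frame with columns `protein_name`, `pdb_id`, `met_pos`,
#'   `reactivity_class`.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "therapeutic_reactivity.tsv",
                      package = "metox", mustWork = TRUE)
  out <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(nrow(out) == 35L,
            all(out$reactivity_class %in% c("low", "high")),
            all(out$met_pos > 0))
  out
}

#' Per-protein confusion counts for the reactivity benchmark
#'
#' The published per-protein outcome of the rule "S-aromatic motif implies
#' low reactivity" applied to the 35 benchmark methionines: true/false
#' positive/negative counts per structure (positive class = low
#' reactivity). Summing rows reproduces the pooled confusion matrix without
#' requiring the structures themselves.
#'
#' @return Data frame with columns `protein_name`, `pdb_id`, `tp`, `tn`,
#'   `fp`, `fn`.
#' @export
load_table2_confusion_fixture <- function() {
  path <- system.file("extdata", "therapeutic_confusion.tsv",
                      package = "metox", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Summary of the prokaryotic (glutamine synthetase) reactivity check
#'
#' For E. coli glutamine synthetase (PDB 2GLS), 15 methionines with
#' empirically characterised H2O2 reactivity were scored against the
#' S-aromatic rule; 13 guesses were correct. Only these summary counts are
#' packaged (the per-residue kinetics live in the primary literature); they
#' feed [binomial_tail()] directly.
#'
#' @return List with elements `pdb_id`, `n_scored`, `n_correct`.
#' @export
load_table4_fixture <- function() {
  path <- system.file("extdata", "glutamine_synthetase_summary.tsv",
                      package = "metox", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  list(pdb_id = df$pdb_id[1], n_scored = as.integer(df$n_scored[1]),
       n_correct = as.integer(df$n_correct[1]))
}

#' Read a methionine site table
#'
#' @param path TSV with header `protein_id`, `pos`, `oxidized`,
#'   `pct_oxidation` (the last may be empty/NA).
#' @return Data frame of methionine sites; `oxidized` is logical,
#'   `pct_oxidation` numeric in `[0, 1]` or `NA`.
#' @export
read_sites <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "pos", "oxidized")
  if (!all(need %in% names(df))) {
    stop_metox("site table must have columns: ", paste(need, collapse = ", "))
  }
  df$oxidized <- as.logical(df$oxidized)
  if (is.null(df$pct_oxidation)) df$pct_oxidation <- NA_real_
  df
}

#' Write a methionine site table
#'
#' @param sites Data frame as returned by [read_sites()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
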