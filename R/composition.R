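# Methionine-content statistics and the bootstrap empirical null used to
# ask whether MetO-containing proteins are unusually methionine-rich.

#' Methionine content of a protein sequence
#'
#' Fraction of residues that are methionine. The N-terminal initiator
#' methionine reflects translation, not composition, so it is dropped by
#' default (position 1 is removed before counting). `X` residues are
#' excluded from the denominator.
#'
#' @param seq Amino-acid string, or a vector of them.
#' @param drop_initiator Drop position 1 before counting (default `TRUE`)?
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
met_content <- function(seq, drop_initiator = TRUE) {
  vapply(seq, function(s) {
    if (drop_initiator) {
      if (nchar(s) < 2) {
        stop_metox("methionine content undefined: length-1 sequence ",
                   "with drop_initiator = TRUE")
      }
      s <- substr(s, 2, nchar(s))
    }
    ch <- seq_chars(s)
    denom <- sum(ch != "X")
    if (denom == 0) return(0)
    sum(ch == "M") / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bootstrap null distribution of mean methionine content
#'
#' Draws `n_samples` random samples of `sample_size` proteins (uniformly,
#' without replacement within a sample, independently across samples) from
#' a background proteome and records the per-sample mean methionine
#' content. The resulting empirical distribution is the sampling null
#' against which an observed group mean is judged.
#'
#' @param proteome Data frame with columns `id`, `seq` (see [read_fasta()]).
#' @param sample_size Proteins per sample.
#' @param n_samples Number of samples (the study-scale choice is `1e4`).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param drop_initiator Passed to [met_content()].
#' @return A `content_distribution`: list with `means`, `n_samples`,
#'   `sample_size`.
#' @export
bootstrap_content_null <- function(proteome, sample_size, n_samples, seed,
                                   drop_initiator = TRUE) {
  n <- nrow(proteome)
  if (sample_size > n) {
    stop_metox("sample_size (", sample_size, ") exceeds proteome size (",
               n, ")")
  }
  if (n_samples < 1) stop_metox("n_samples must be >= 1")
  contents <- met_content(proteome$seq, drop_initiator = drop_initiator)
  means <- with_seed(seed, vapply(seq_len(n_samples), function(i) {
    mean(contents[sample.int(n, sample_size)])
  }, numeric(1)))
  structure(list(means = means, n_samples = n_samples,
                 sample_size = sample_size),
            class = "content_distribution")
}

#' Empirical upper-tail p-value against a bootstrap null
#'
#' Uses the add-one estimator `(1 + #\{means >= observed\}) / (1 + n)`,
#' which never returns 0; when no bootstrap mean reaches the observed
#' value the result is flagged as below the resolution of the null
#' (reported as `< 1/n_samples`).
#'
#' @param dist A `content_distribution` from [bootstrap_content_null()].
#' @param observed Observed mean methionine content.
#' @return List with `p` (add-one estimate), `below_resolution` (logical)
#'   and `bound` (character, e.g. `"< 1e-04"` when below resolution).
#' @export
empirical_pvalue <- function(dist, observed) {
  stopifnot(inherits(dist, "content_distribution"))
  if (length(dist$means) == 0) stop_metox("empty bootstrap distribution")
  n_ge <- sum(dist$means >= observed)
  p <- (1 + n_ge) / (1 + dist$n_samples)
  below <- n_ge == 0
  list(p = p, below_resolution = below,
       bound = if (below) sprintf("< %g", 1 / dist$n_samples) else NA_character_)
}
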