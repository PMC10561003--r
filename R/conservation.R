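#' Per-column conservation profile of an alignment
#'
#' For each alignment column the profile records the counts of the four
#' unambiguous bases, the gap fraction, and a conservation score defined as
#' the modal-base fraction: the count of the most frequent base divided by
#' the number of unambiguous (A/C/G/T) characters in the column. IUPAC
#' ambiguity codes in rows contribute to neither the base counts nor the gap
#' count — ambiguity is treated as ignorance, not evidence. Columns with no
#' unambiguous base score 0.
#'
#' An entropy-based alternative score `1 - H/2` (Shannon entropy in bits over
#' the base frequencies) is also returned for users who prefer it; window
#' extraction uses the modal-base score.
#'
#' @param aln a `gp_alignment` from [read_alignment()] or
#'   [simulate_genus_panel()].
#' @return a `gp_conservation` object: list with `n_cols`, `cons`
#'   (modal-base fraction per column), `cons_entropy`, `gapfrac`, and
#'   `counts` (4 x n_cols matrix, rows A,C,G,T).
#' @export
conservation_profile <- function(aln) {
  stopifnot(inherits(aln, "gp_alignment"))
  m <- alignment_matrix(aln)
  counts <- rbind(A = colSums(m == "A"), C = colSums(m == "C"),
                  G = colSums(m == "G"), T = colSums(m == "T"))
  gaps <- colSums(m == "-")
  tot <- colSums(counts)
  maxc <- apply(counts, 2, max)
  cons <- ifelse(tot > 0, maxc / tot, 0)
  freq <- sweep(counts, 2, pmax(tot, 1L), "/")
  h <- -colSums(ifelse(freq > 0, freq * log2(freq), 0))
  cons_entropy <- ifelse(tot > 0, 1 - h / 2, 0)
  structure(list(n_cols = aln$n_cols, cons = unname(cons),
                 cons_entropy = unname(cons_entropy),
                 gapfrac = unname(gaps / nrow(m)), counts = counts),
            class = "gp_conservation")
}

#' @export
print.gp_conservation <- function(x, ...) {
  cat("<gp_conservation> ", x$n_cols, " columns; mean conservation ",
      sprintf("%.3f", mean(x$cons)), "\n", sep = "")
  invisible(x)
}

#' Extract conserved windows from a conservation profile
#'
#' Returns every maximal run of columns with conservation `>= tau` and gap
#' fraction `<= gamma` that is at least `min_len` columns long, together
#' with its IUPAC consensus (computed from the profile's base counts at
#' `min_freq`). Coordinates are 0-based, half-open alignment columns.
#' Windows are sorted by start and do not overlap.
#'
#' @param profile a `gp_conservation` object.
#' @param min_len minimum window length in columns (a primer must fit).
#' @param tau conservation threshold in (0, 1].
#' @param gamma maximum gap fraction in \[0, 1).
#' @param min_freq minimum base frequency for inclusion in the IUPAC
#'   consensus (see [consensus_iupac()]).
#' @param score which per-column score to threshold: modal-base fraction
#'   (`"modal"`, default) or the entropy alternative (`"entropy"`).
#' @return a `data.frame` with columns `window_id`, `start`, `end`,
#'   `mean_cons`, `consensus`.
#' @export
conserved_windows <- function(profile, min_len = 18L, tau = 0.90,
                              gamma = 0.10, min_freq = 0.70,
                              score = c("modal", "entropy")) {
  stopifnot(inherits(profile, "gp_conservation"))
  score <- match.arg(score)
  if (!(tau > 0 && tau <= 1)) gp_config_error("tau must be in (0, 1]")
  if (!(gamma >= 0 && gamma < 1)) gp_config_error("gamma must be in [0, 1)")
  if (min_len < 1L) gp_config_error("min_len must be >= 1")
  cons <- if (score == "modal") profile$cons else profile$cons_entropy
  ok <- cons >= tau & profile$gapfrac <= gamma
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(
    window_id = character(0), start = integer(0), end = integer(0),
    mean_cons = numeric(0), consensus = character(0),
    stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  s <- starts[keep]; e <- ends[keep]
  data.frame(
    window_id = sprintf("w%02d", seq_along(s)),
    start = s - 1L, end = e,
    mean_cons = vapply(seq_along(s),
                       function(i) mean(cons[s[i]:e[i]]), numeric(1)),
    consensus = vapply(seq_along(s), function(i)
      consensus_from_counts(profile$counts[, s[i]:e[i], drop = FALSE],
                            min_freq), character(1)),
    stringsAsFactors = FALSE)
}

# IUPAC consensus from a 4 x L count matrix (rows A,C,G,T)
consensus_from_counts <- function(counts, min_freq) {
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  vapply(seq_len(ncol(counts)), function(j) {
    cnt <- counts[, j]
    tot <- sum(cnt)
    if (tot == 0L)
      gp_stop("all-gap (or all-ambiguous) column in consensus window",
              "gp_degenerate_column")
    keep <- cnt / tot >= min_freq
    if (!any(keep)) keep <- cnt > 0L   # no base reaches min_freq: all observed
    BITS_IUPAC[sum(bits[keep])]
  }, character(1)) |> paste(collapse = "")
}

#' IUPAC consensus of an alignment slice
#'
#' For each column in `[start, end)` (0-based half-open alignment columns)
#' the consensus letter is the IUPAC code covering exactly the set of bases
#' whose frequency among unambiguous non-gap characters is `>= min_freq`;
#' if no base reaches `min_freq` the code covers all observed bases. Gap
#' characters are never emitted.
#'
#' @param aln a `gp_alignment`.
#' @param start,end 0-based half-open column range.
#' @param min_freq minimum base frequency in (0, 1].
#' @return a consensus string of length `end - start`.
#' @export
consensus_iupac <- function(aln, start, end, min_freq = 0.70) {
  stopifnot(inherits(aln, "gp_alignment"))
  if (!(min_freq > 0 && min_freq <= 1))
    gp_config_error("min_freq must be in (0, 1]")
  if (start < 0L || end > aln$n_cols || start >= end)
    gp_config_error("consensus window outside alignment")
  p <- conservation_profile(aln)
  consensus_from_counts(p$counts[, (start + 1L):end, drop = FALSE], min_freq)
}
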