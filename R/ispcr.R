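#' In-silico PCR: predict amplicons for a primer pair
#'
#' For each template, all qualifying binding sites of both primers are
#' located with [binds()] and every convergent combination — one primer on
#' the plus strand upstream, the other on the minus strand downstream —
#' whose span lies within `[min_len, max_len]` yields one predicted
#' amplicon. Either primer may take either role (the pair is also tried
#' with the roles swapped onto the opposite strands). Amplicon coordinates
#' are 0-based half-open on the template plus strand and include both
#' primer footprints, so `length` is the product size a gel would show.
#'
#' @param fwd,rev the two primer sequences, 5'->3' (IUPAC allowed).
#' @param templates a `data.frame` with columns `id`, `seq` (e.g. from
#'   [read_fasta()]); `genus`/`species` columns are carried through when
#'   present.
#' @param max_mm,three_prime_exact binding-model parameters, see [binds()].
#' @param min_len,max_len product size bounds in bp.
#' @return a `data.frame` of amplicons with columns `template_id`, `start`,
#'   `end`, `length`, `seq`, `fwd_strand`, `fwd_start`, `fwd_mm`,
#'   `rev_strand`, `rev_start`, `rev_mm` (plus `genus`, `species` if
#'   present in `templates`), sorted by (template_id, start, length).
#' @export
simulate_pcr <- function(fwd, rev, templates, max_mm = 2L,
                         three_prime_exact = 3L, min_len = 50L,
                         max_len = 3000L) {
  stopifnot(is.data.frame(templates), all(c("id", "seq") %in% names(templates)))
  out <- vector("list", nrow(templates))
  for (i in seq_len(nrow(templates))) {
    tid <- templates$id[[i]]
    tseq <- templates$seq[[i]]
    sf <- binds(fwd, tseq, max_mm, three_prime_exact, all = TRUE)
    sr <- binds(rev, tseq, max_mm, three_prime_exact, all = TRUE)
    hits <- rbind(
      combine_sites(sf, sr, nchar(fwd), nchar(rev), swapped = FALSE),
      combine_sites(sr, sf, nchar(rev), nchar(fwd), swapped = TRUE))
    if (is.null(hits) || nrow(hits) == 0L) next
    hits <- hits[hits$length >= min_len & hits$length <= max_len, ,
                 drop = FALSE]
    if (nrow(hits) == 0L) next
    hits <- unique(hits)
    hits$template_id <- tid
    hits$seq <- substring(tseq, hits$start + 1L, hits$end)
    if ("genus" %in% names(templates)) hits$genus <- templates$genus[[i]]
    if ("species" %in% names(templates)) hits$species <- templates$species[[i]]
    out[[i]] <- hits
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      seq = character(0), fwd_strand = character(0),
                      fwd_start = integer(0), fwd_mm = integer(0),
                      rev_strand = character(0), rev_start = integer(0),
                      rev_mm = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  front <- c("template_id", "start", "end", "length", "seq")
  res <- res[, c(front, setdiff(names(res), front)), drop = FALSE]
  res <- res[order(res$template_id, res$start, res$length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# convergent combinations: plus-strand sites of primer A x minus-strand
# sites of primer B downstream of them. `swapped` records which pair member
# played the plus-strand role so fwd_* / rev_* always refer to the pair's
# fwd and rev primers.
combine_sites <- function(sites_a, sites_b, len_a, len_b, swapped) {
  pa <- sites_a[sites_a$strand == "+", , drop = FALSE]
  mb <- sites_b[sites_b$strand == "-", , drop = FALSE]
  if (nrow(pa) == 0L || nrow(mb) == 0L) return(NULL)
  g <- expand.grid(ia = seq_len(nrow(pa)), ib = seq_len(nrow(mb)))
  start <- pa$start[g$ia]
  end <- mb$start[g$ib] + len_b
  keep <- mb$start[g$ib] >= pa$start[g$ia]
  if (!any(keep)) return(NULL)
  g <- g[keep, , drop = FALSE]; start <- start[keep]; end <- end[keep]
  a_part <- data.frame(strand = "+", start = pa$start[g$ia],
                       mm = pa$mismatches[g$ia], stringsAsFactors = FALSE)
  b_part <- data.frame(strand = "-", start = mb$start[g$ib],
                       mm = mb$mismatches[g$ib], stringsAsFactors = FALSE)
  fwd_part <- if (swapped) b_part else a_part
  rev_part <- if (swapped) a_part else b_part
  data.frame(start = start, end = end, length = end - start,
             fwd_strand = fwd_part$strand, fwd_start = fwd_part$start,
             fwd_mm = fwd_part$mm, rev_strand = rev_part$strand,
             rev_start = rev_part$start, rev_mm = rev_part$mm,
             stringsAsFactors = FALSE)
}

#' Virtual gel: band report for predicted amplicons
#'
#' Collapses amplicons to distinct band sizes per template, annotates each
#' with the nearest ladder band, and lists templates with no product as
#' "no band" rows.
#'
#' @param amplicons output of [simulate_pcr()].
#' @param ladder sorted numeric vector of ladder band sizes in bp.
#' @param template_ids optional character vector of all templates loaded,
#'   so templates without any amplicon appear as "no band" rows.
#' @return a `data.frame` with columns `template_id`, `band_bp`
#'   (`NA` for no band), `multiplicity`, `nearest_ladder_bp`.
#' @export
virtual_gel <- function(amplicons, ladder = seq(100L, 2000L, by = 100L),
                        template_ids = NULL) {
  rows <- list()
  if (nrow(amplicons) > 0L) {
    agg <- stats::aggregate(list(multiplicity = amplicons$length),
                            by = list(template_id = amplicons$template_id,
                                      band_bp = amplicons$length),
                            FUN = length)
    agg$nearest_ladder_bp <- vapply(agg$band_bp, function(b)
      ladder[which.min(abs(ladder - b))], numeric(1))
    rows[[1L]] <- agg[order(agg$template_id, agg$band_bp), ]
  }
  missing <- setdiff(template_ids, amplicons$template_id)
  if (length(missing) > 0L) {
    rows[[length(rows) + 1L]] <- data.frame(
      template_id = missing, band_bp = NA_integer_, multiplicity = 0L,
      nearest_ladder_bp = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(template_id = character(0), band_bp = integer(0),
                      multiplicity = integer(0),
                      nearest_ladder_bp = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
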