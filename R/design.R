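#' Default design parameters
#'
#' All tunables of the primer-design pipeline in one list. Physical filters
#' follow standard primer-design practice; the binding rule (`max_mm`,
#' `three_prime_exact`) operationalizes genus "homology" as PCR-relevant
#' binding; product bounds bracket typical genus-diagnostic 16S products.
#'
#' @param ... named overrides of any default.
#' @return a named list of parameters.
#' @export
design_params <- function(...) {
  p <- list(
    # candidate physical filters
    Lmin = 18L, Lmax = 25L,
    gc_min = 0.40, gc_max = 0.60,
    tm_min = 55, tm_max = 65,
    max_homopolymer = 4L, max_degenerate = 2L, gc_clamp = TRUE,
    # binding model
    max_mm = 2L, three_prime_exact = 3L,
    # pairing
    prod_min = 300L, prod_max = 1000L, prod_target = 600L,
    pair_cov_min = 0.90, delta_tm_max = 3, cross_dimer_max = 8L,
    # "genus-specific" call
    specific_cov_min = 0.90, specific_outgroup_max = 0.05,
    # thermodynamic conditions
    na_molar = 0.05, oligo_molar = 5e-7,
    # conserved-window extraction
    window_min_len = 18L, tau = 0.90, gamma = 0.10,
    consensus_min_freq = 0.70
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L)
    gp_config_error(paste0("unknown design parameter(s): ",
                           paste(unknown, collapse = ", ")))
  p[names(dots)] <- dots
  p
}

#' Enumerate primer candidates inside conserved windows
#'
#' Every substring of each window's IUPAC consensus with length in
#' `[Lmin, Lmax]` is emitted in both orientations (forward = the consensus
#' substring; reverse = its reverse complement, i.e. the oligo that would
#' be synthesized), then filtered on physical properties: GC fraction
#' within `[gc_min, gc_max]` and Tm within `[tm_min, tm_max]` for every
#' IUPAC expansion (worst case), longest homopolymer `<= max_homopolymer`,
#' at most `max_degenerate` degenerate positions, and — when `gc_clamp` —
#' a G or C (or S) at the candidate's own 3' end. Output order is
#' deterministic: (window, start, length, orientation).
#'
#' @param windows a `data.frame` from [conserved_windows()].
#' @param params a list from [design_params()].
#' @return a `data.frame` of candidates with columns `cand_id`, `seq`,
#'   `window_id`, `aln_start`, `aln_end`, `orientation`, `length`,
#'   `gc_min_frac`, `gc_max_frac`, `tm_celsius`, `max_homopolymer`,
#'   `n_degenerate`, `ingroup_cov`, `outgroup_hit` (the last two `NA`
#'   until scored by [specificity()]).
#' @export
enumerate_candidates <- function(windows, params = design_params()) {
  if (nrow(windows) == 0L) {
    warning("no conserved windows: no candidates enumerated")
    return(empty_candidates())
  }
  rows <- list()
  for (w in seq_len(nrow(windows))) {
    cons <- windows$consensus[[w]]
    wlen <- nchar(cons)
    wstart <- windows$start[[w]]
    for (start in seq_len(wlen)) {
      for (len in params$Lmin:params$Lmax) {
        if (start + len - 1L > wlen) break
        sub <- substr(cons, start, start + len - 1L)
        for (orientation in c("forward", "reverse")) {
          oligo <- if (orientation == "forward") sub else revcomp(sub)
          cand <- candidate_if_valid(oligo, params)
          if (is.null(cand)) next
          rows[[length(rows) + 1L]] <- data.frame(
            cand_id = paste0(windows$window_id[[w]], ":", wstart + start - 1L,
                             ":", len, ":",
                             substr(orientation, 1L, 1L)),
            seq = oligo, window_id = windows$window_id[[w]],
            aln_start = wstart + start - 1L,
            aln_end = wstart + start - 1L + len,
            orientation = orientation, length = len,
            gc_min_frac = cand$gc_min, gc_max_frac = cand$gc_max,
            tm_celsius = cand$tm, max_homopolymer = cand$homo,
            n_degenerate = cand$ndeg,
            ingroup_cov = NA_real_, outgroup_hit = NA_real_,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(empty_candidates())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  data.frame(cand_id = character(0), seq = character(0),
             window_id = character(0), aln_start = integer(0),
             aln_end = integer(0), orientation = character(0),
             length = integer(0), gc_min_frac = numeric(0),
             gc_max_frac = numeric(0), tm_celsius = numeric(0),
             max_homopolymer = integer(0), n_degenerate = integer(0),
             ingroup_cov = numeric(0), outgroup_hit = numeric(0),
             stringsAsFactors = FALSE)
}

# apply the physical filters; NULL if the oligo fails any of them
candidate_if_valid <- function(oligo, params) {
  ndeg <- n_degenerate(oligo)
  if (ndeg > params$max_degenerate) return(NULL)
  if (params$gc_clamp &&
      !substr(oligo, nchar(oligo), nchar(oligo)) %in% c("G", "C", "S"))
    return(NULL)
  exps <- iupac_expansions(oligo)
  gcs <- vapply(exps, gc_fraction, numeric(1))
  if (min(gcs) < params$gc_min || max(gcs) > params$gc_max) return(NULL)
  homo <- max(vapply(exps, max_homopolymer, numeric(1)))
  if (homo > params$max_homopolymer) return(NULL)
  tms <- vapply(exps, tm_nn, numeric(1), na_molar = params$na_molar,
                oligo_molar = params$oligo_molar)
  if (min(tms) < params$tm_min || max(tms) > params$tm_max) return(NULL)
  list(gc_min = min(gcs), gc_max = max(gcs), tm = min(tms), homo = homo,
       ndeg = ndeg)
}

#' Score genus specificity of primer candidates
#'
#' `ingroup_cov` is the fraction of in-group templates on which the
#' candidate has at least one qualifying binding site ([binds()]);
#' `outgroup_hit` is the same fraction over the out-group. An empty
#' out-group yields `outgroup_hit = 0` with a warning.
#'
#' @param candidates a `data.frame` from [enumerate_candidates()].
#' @param ingroup,outgroup `data.frame`s of unaligned templates with
#'   columns `id`, `seq` (out-group may have zero rows).
#' @param params a list from [design_params()].
#' @return `candidates` with `ingroup_cov` and `outgroup_hit` filled in.
#' @export
specificity <- function(candidates, ingroup, outgroup = NULL,
                        params = design_params()) {
  if (nrow(ingroup) == 0L) gp_config_error("in-group must be non-empty")
  no_out <- is.null(outgroup) || nrow(outgroup) == 0L
  if (no_out)
    warning("empty out-group: outgroup_hit reported as 0 for all candidates")
  frac_bound <- function(oligo, seqs) {
    if (length(seqs) == 0L) return(0)
    mean(cpp_binds_any(oligo, seqs, as.integer(params$max_mm),
                       as.integer(params$three_prime_exact)))
  }
  candidates$ingroup_cov <- vapply(candidates$seq, frac_bound, numeric(1),
                                   seqs = ingroup$seq)
  candidates$outgroup_hit <-
    if (no_out) rep(0, nrow(candidates))
    else vapply(candidates$seq, frac_bound, numeric(1), seqs = outgroup$seq)
  candidates
}

#' Pair scored candidates and rank genus-specific primer pairs
#'
#' Forms every convergent (forward, reverse) combination whose members lie
#' in consensus order (forward upstream of reverse on alignment
#' coordinates), passes the pair filters — product length within
#' `[prod_min, prod_max]` on at least `pair_cov_min` of in-group templates
#' (verified per template by in-silico PCR), `|dTm| <= delta_tm_max`,
#' cross-dimer score `<= cross_dimer_max` — and ranks survivors by
#' (pair_outgroup_hit ascending, pair_ingroup_cov descending, |dTm|
#' ascending, |mean product - prod_target| ascending, lexical primer
#' sequences). A pair is flagged `genus_specific` when
#' `pair_ingroup_cov >= specific_cov_min` and
#' `pair_outgroup_hit <= specific_outgroup_max`.
#'
#' `pair_ingroup_cov` counts in-group templates on which BOTH primers bind
#' convergently with an in-bounds product, so it can never exceed either
#' member's coverage. When no pair survives, an empty frame is returned
#' with a `diagnostics` attribute summarizing which filter eliminated most
#' combinations.
#'
#' @param candidates scored candidates from [specificity()].
#' @param ingroup,outgroup unaligned template `data.frame`s (`id`, `seq`).
#' @param params a list from [design_params()].
#' @return a `data.frame` of ranked pairs.
#' @export
pair_and_rank <- function(candidates, ingroup, outgroup = NULL,
                          params = design_params()) {
  diag <- c(orientation_or_order = 0L, consensus_span = 0L, delta_tm = 0L,
            member_coverage = 0L, cross_dimer = 0L, pair_coverage = 0L)
  fwd <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rv <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  # a pair member below pair_cov_min cannot yield a qualifying pair
  n_all <- nrow(fwd) * nrow(rv)
  fwd <- fwd[!is.na(fwd$ingroup_cov) &
               fwd$ingroup_cov >= params$pair_cov_min, , drop = FALSE]
  rv <- rv[!is.na(rv$ingroup_cov) &
             rv$ingroup_cov >= params$pair_cov_min, , drop = FALSE]
  diag[["member_coverage"]] <- n_all - nrow(fwd) * nrow(rv)
  # binding sites are scanned lazily, once per candidate sequence, and
  # reused for every pair it participates in
  in_cache <- site_cache(ingroup$seq, params)
  out_cache <- if (is.null(outgroup) || nrow(outgroup) == 0L) NULL
               else site_cache(outgroup$seq, params)
  # cheap combinatorial prefilters, vectorized over all (fwd, rev) combos
  nf <- nrow(fwd); nr <- nrow(rv)
  rows <- list()
  if (nf > 0L && nr > 0L) {
    span_m <- outer(fwd$aln_start, rv$aln_end, function(a, b) b - a)
    order_ok <- outer(fwd$aln_start, rv$aln_start, "<")
    span_ok <- span_m >= params$prod_min & span_m <= params$prod_max
    dtm_m <- abs(outer(fwd$tm_celsius, rv$tm_celsius, "-"))
    dtm_ok <- dtm_m <= params$delta_tm_max
    diag[["orientation_or_order"]] <- sum(!order_ok)
    diag[["consensus_span"]] <- sum(order_ok & !span_ok)
    diag[["delta_tm"]] <- sum(order_ok & span_ok & !dtm_ok)
    surv <- which(order_ok & span_ok & dtm_ok, arr.ind = TRUE)
    for (s in seq_len(nrow(surv))) {
      i <- surv[s, 1L]; j <- surv[s, 2L]
      fseq <- fwd$seq[[i]]; rseq <- rv$seq[[j]]
      xd <- dimer_score(iupac_expansions(fseq)[[1]],
                        iupac_expansions(rseq)[[1]])
      if (xd > params$cross_dimer_max) {
        diag[["cross_dimer"]] <- diag[["cross_dimer"]] + 1L
        next
      }
      prods <- pair_products(in_cache(fseq), in_cache(rseq),
                             nchar(fseq), nchar(rseq), params$prod_min,
                             params$prod_max)
      cov <- mean(lengths(prods) > 0L)
      if (cov < params$pair_cov_min) {
        diag[["pair_coverage"]] <- diag[["pair_coverage"]] + 1L
        next
      }
      all_lens <- unlist(prods)
      hit <- if (is.null(out_cache)) 0 else {
        mean(lengths(pair_products(out_cache(fseq), out_cache(rseq),
                                   nchar(fseq), nchar(rseq),
                                   params$prod_min, params$prod_max)) > 0L)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        fwd_id = fwd$cand_id[[i]], rev_id = rv$cand_id[[j]],
        fwd_seq = fseq, rev_seq = rseq,
        fwd_window = fwd$window_id[[i]], rev_window = rv$window_id[[j]],
        fwd_aln_start = fwd$aln_start[[i]],
        rev_aln_start = rv$aln_start[[j]],
        tm_f = fwd$tm_celsius[[i]], tm_r = rv$tm_celsius[[j]],
        delta_tm = dtm_m[i, j],
        product_min = min(all_lens), product_max = max(all_lens),
        product_mean = mean(all_lens),
        pair_ingroup_cov = cov, pair_outgroup_hit = hit,
        cross_dimer = xd, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    warning(paste0("no primer pair passed the filters; eliminations: ",
                   paste(names(diag), diag, sep = "=", collapse = ", ")))
    out <- empty_pairs()
    attr(out, "diagnostics") <- diag
    return(out)
  }
  out <- do.call(rbind, rows)
  out$genus_specific <- out$pair_ingroup_cov >= params$specific_cov_min &
    out$pair_outgroup_hit <= params$specific_outgroup_max
  out$score <- out$pair_ingroup_cov - out$pair_outgroup_hit -
    0.01 * out$delta_tm -
    1e-5 * abs(out$product_mean - params$prod_target)
  o <- order(out$pair_outgroup_hit, -out$pair_ingroup_cov, out$delta_tm,
             abs(out$product_mean - params$prod_target), out$fwd_seq,
             out$rev_seq)
  out <- out[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", setdiff(names(out), "rank")), drop = FALSE]
}

# memoized per-oligo site lists over a fixed template set; cache(oligo)
# returns list of site data.frames, one per template
site_cache <- function(template_seqs, params) {
  env <- new.env(parent = emptyenv())
  function(oligo) {
    if (!exists(oligo, envir = env, inherits = FALSE)) {
      assign(oligo, lapply(template_seqs, function(t)
        binds(oligo, t, params$max_mm, params$three_prime_exact,
              all = TRUE)), envir = env)
    }
    get(oligo, envir = env, inherits = FALSE)
  }
}

# per template, the vector of in-bounds convergent product lengths for a
# pair given precomputed site lists; matches simulate_pcr() lengths
pair_products <- function(sites_f, sites_r, len_f, len_r, lo, hi) {
  conv <- function(sa, sb, len_b) {
    a <- sa$start[sa$strand == "+"]
    b <- sb$start[sb$strand == "-"]
    if (length(a) == 0L || length(b) == 0L) return(integer(0))
    spans <- outer(b + len_b, a, "-")
    ok <- outer(b, a, ">=") & spans >= lo & spans <= hi
    as.integer(spans[ok])
  }
  lapply(seq_along(sites_f), function(i)
    c(conv(sites_f[[i]], sites_r[[i]], len_r),
      conv(sites_r[[i]], sites_f[[i]], len_f)))
}

empty_pairs <- function() {
  data.frame(rank = integer(0), fwd_id = character(0), rev_id = character(0),
             fwd_seq = character(0), rev_seq = character(0),
             fwd_window = character(0), rev_window = character(0),
             fwd_aln_start = integer(0), rev_aln_start = integer(0),
             tm_f = numeric(0), tm_r = numeric(0), delta_tm = numeric(0),
             product_min = integer(0), product_max = integer(0),
             product_mean = numeric(0), pair_ingroup_cov = numeric(0),
             pair_outgroup_hit = numeric(0), cross_dimer = integer(0),
             genus_specific = logical(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' One-call genus-specific primer design
#'
#' Convenience wrapper running the full design path: conservation profile
#' of the in-group alignment, conserved-window extraction, candidate
#' enumeration, specificity scoring against the out-group, and pair
#' ranking.
#'
#' @param ingroup_aln a `gp_alignment` of the in-group.
#' @param ingroup unaligned in-group templates (`data.frame` with `id`,
#'   `seq`); defaults to the degapped alignment rows.
#' @param outgroup unaligned out-group templates, may be `NULL`.
#' @param params a list from [design_params()].
#' @return the ranked pair `data.frame` from [pair_and_rank()], with the
#'   windows and scored candidates attached as attributes `windows` and
#'   `candidates`.
#' @export
design_pairs <- function(ingroup_aln, ingroup = NULL, outgroup = NULL,
                         params = design_params()) {
  if (is.null(ingroup)) {
    ingroup <- data.frame(id = ingroup_aln$id,
                          seq = gsub("-", "", ingroup_aln$seq, fixed = TRUE),
                          stringsAsFactors = FALSE)
  }
  prof <- conservation_profile(ingroup_aln)
  wins <- conserved_windows(prof, min_len = params$window_min_len,
                            tau = params$tau, gamma = params$gamma,
                            min_freq = params$consensus_min_freq)
  cands <- enumerate_candidates(wins, params)
  if (nrow(cands) > 0L)
    cands <- specificity(cands, ingroup, outgroup, params)
  pairs <- if (nrow(cands) == 0L) empty_pairs()
           else pair_and_rank(cands, ingroup, outgroup, params)
  attr(pairs, "windows") <- wins
  attr(pairs, "candidates") <- cands
  pairs
}
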