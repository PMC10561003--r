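# Independent oracles, coded against the definitions rather than the
# package internals: brute-force site scanning, product enumeration,
# all-pairs window extraction, and a second nearest-neighbor summation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# --- IUPAC compatibility, re-derived from the code definitions ---------
ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_compat <- function(a, b) {
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0L
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# every qualifying binding site by exhaustive offset x strand scan
oracle_sites <- function(primer, template, max_mm, tpe) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  L <- length(p); n <- length(t)
  pr <- strsplit(oracle_revcomp(primer), "")[[1]]
  out <- list()
  if (n >= L) for (off in 0:(n - L)) {
    win <- t[(off + 1):(off + L)]
    # plus strand: primer 3' end on the right
    mm <- sum(!mapply(oracle_compat, p, win))
    clamp_ok <- tpe == 0 ||
      all(mapply(oracle_compat, p[(L - tpe + 1):L], win[(L - tpe + 1):L]))
    if (mm <= max_mm && clamp_ok)
      out[[length(out) + 1L]] <- data.frame(strand = "+", start = off,
                                            mismatches = mm)
    # minus strand: revcomp(primer) read along the plus strand
    mm <- sum(!mapply(oracle_compat, pr, win))
    clamp_ok <- tpe == 0 ||
      all(mapply(oracle_compat, pr[seq_len(tpe)], win[seq_len(tpe)]))
    if (mm <= max_mm && clamp_ok)
      out[[length(out) + 1L]] <- data.frame(strand = "-", start = off,
                                            mismatches = mm)
  }
  if (length(out) == 0L)
    return(data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

# vectorized variant of oracle_sites for larger templates: same exhaustive
# scan, with compatibility looked up in a matrix precomputed from the
# letter sets above
ORACLE_COMPAT <- outer(names(ORACLE_SETS), names(ORACLE_SETS),
                       Vectorize(oracle_compat))
dimnames(ORACLE_COMPAT) <- list(names(ORACLE_SETS), names(ORACLE_SETS))

oracle_sites_v <- function(primer, template, max_mm, tpe) {
  p <- strsplit(primer, "")[[1]]
  t <- strsplit(template, "")[[1]]
  pr <- strsplit(oracle_revcomp(primer), "")[[1]]
  L <- length(p); n <- length(t)
  out <- list()
  if (n >= L) for (off in 0:(n - L)) {
    win <- t[(off + 1):(off + L)]
    ok_p <- ORACLE_COMPAT[cbind(p, win)]
    if (sum(!ok_p) <= max_mm && (tpe == 0 || all(ok_p[(L - tpe + 1):L])))
      out[[length(out) + 1L]] <- data.frame(strand = "+", start = off,
                                            mismatches = sum(!ok_p))
    ok_m <- ORACLE_COMPAT[cbind(pr, win)]
    if (sum(!ok_m) <= max_mm && (tpe == 0 || all(ok_m[seq_len(tpe)])))
      out[[length(out) + 1L]] <- data.frame(strand = "-", start = off,
                                            mismatches = sum(!ok_m))
  }
  if (length(out) == 0L)
    return(data.frame(strand = character(0), start = integer(0),
                      mismatches = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$strand), , drop = FALSE]
}

# brute-force amplicon enumeration from oracle sites
oracle_amplicons <- function(fwd, rev, template, max_mm, tpe, min_len,
                             max_len, sites_fn = oracle_sites) {
  sf <- sites_fn(fwd, template, max_mm, tpe)
  sr <- sites_fn(rev, template, max_mm, tpe)
  out <- list()
  pairings <- list(list(a = sf, b = sr, len_b = nchar(rev)),
                   list(a = sr, b = sf, len_b = nchar(fwd)))
  for (pg in pairings) {
    ap <- pg$a[pg$a$strand == "+", , drop = FALSE]
    bm <- pg$b[pg$b$strand == "-", , drop = FALSE]
    for (i in seq_len(nrow(ap))) for (j in seq_len(nrow(bm))) {
      if (bm$start[j] < ap$start[i]) next
      len <- bm$start[j] + pg$len_b - ap$start[i]
      if (len >= min_len && len <= max_len)
        out[[length(out) + 1L]] <- data.frame(start = ap$start[i],
                                              end = ap$start[i] + len,
                                              length = len)
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  df <- unique(do.call(rbind, out))
  df <- df[order(df$start, df$length), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# all-(start,end) window extraction oracle for small profiles
oracle_windows <- function(cons, gapfrac, min_len, tau, gamma) {
  n <- length(cons)
  ok <- cons >= tau & gapfrac <= gamma
  out <- list()
  for (s in seq_len(n)) for (e in s:n) {
    if (!all(ok[s:e])) next
    # maximal: cannot extend either side
    if (s > 1 && ok[s - 1]) next
    if (e < n && ok[e + 1]) next
    if (e - s + 1 >= min_len)
      out[[length(out) + 1L]] <- data.frame(start = s - 1L, end = e)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0)))
  do.call(rbind, out)
}

# independent nearest-neighbor summation: full 16-stack table written out,
# summed 5'->3' with terminal initiation and entropy salt correction
oracle_tm <- function(seq, na_molar = 0.05, ct_molar = 5e-7) {
  dh <- c(AA = -7.9, AC = -8.4, AG = -7.8, AT = -7.2,
          CA = -8.5, CC = -8.0, CG = -10.6, CT = -7.8,
          GA = -8.2, GC = -9.8, GG = -8.0, GT = -8.4,
          TA = -7.2, TC = -8.2, TG = -8.5, TT = -7.9)
  ds <- c(AA = -22.2, AC = -22.4, AG = -21.0, AT = -20.4,
          CA = -22.7, CC = -19.9, CG = -27.2, CT = -21.0,
          GA = -22.2, GC = -24.4, GG = -19.9, GT = -22.4,
          TA = -21.3, TC = -22.2, TG = -22.7, TT = -22.2)
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  keys <- paste0(ch[-n], ch[-1])
  H <- sum(dh[keys]); S <- sum(ds[keys])
  for (end in ch[c(1, n)]) {
    if (end %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1) * log(na_molar)
  H * 1000 / (S + 1.987 * log(ct_molar / 4)) - 273.15
}

# longest contiguous complementary run between a and reverse(b), brute force
oracle_dimer <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- rev(strsplit(b, "")[[1]])
  wc <- c(A = "T", T = "A", C = "G", G = "C")
  best <- 0L
  for (off in -(length(bv)):length(av)) {
    run <- 0L
    for (i in seq_along(bv)) {
      j <- i + off
      hit <- j >= 1 && j <= length(av) && av[j] == wc[[bv[i]]]
      run <- if (hit) run + 1L else 0L
      best <- max(best, run)
    }
  }
  best
}

# semi-global (read-global, reference-local) unit-cost distance via
# Biostrings, as an established independent alignment engine
oracle_semiglobal_identity <- function(read, ref) {
  mat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 0
  al <- Biostrings::pairwiseAlignment(read, ref, type = "global-local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 1)
  1 + Biostrings::score(al) / nchar(read)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
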