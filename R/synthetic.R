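#' Configuration for the 16S-like sequence-family simulator
#'
#' The generator emulates the structure that makes genus-specific 16S
#' primer design possible: a shared ~1.5 kb backbone (the gene scaffold),
#' universally conserved windows shared by all genera (the regions
#' universal primers exploit), genus-private conserved signature windows
#' (the regions genus-specific primers exploit), genus-level divergence
#' elsewhere, species-level point variation within each genus, and
#' error-bearing amplicon reads. The mutation model is substitution-only,
#' so the trivial columnwise alignment of the simulated family is exact
#' and conservation ground truth is known.
#'
#' @param seed integer RNG seed; every simulator output is a deterministic
#'   function of the config including this seed.
#' @param backbone_len backbone length in bp.
#' @param n_genera number of genera; the first is the design target.
#' @param n_species_per_genus,n_seqs_per_species panel shape (defaults
#'   give 100 sequences per genus, a typical GenBank panel size).
#' @param signature_windows list (one element per genus) of two-column
#'   matrices / lists of `c(start, len)` giving each genus's private
#'   signature windows (0-based starts). `NULL` auto-places two
#'   non-overlapping windows per genus.
#' @param signature_len length of auto-placed signature windows.
#' @param universal_windows list of `c(start, len)` windows kept identical
#'   in every sequence of every genus (no genus- or species-level
#'   substitutions), emulating universally conserved 16S regions.
#' @param genus_div per-site substitution probability applied per genus to
#'   the backbone outside protected windows (between-genus divergence).
#' @param species_mu per-site substitution probability applied per species
#'   to its genus consensus outside protected and hypervariable positions.
#' @param variable_flank,variable_mu every signature window sits inside a
#'   hypervariable region extending `variable_flank` bp on each side;
#'   within such regions species-level substitutions occur at
#'   `variable_mu` instead of `species_mu` (for every genus, except inside
#'   a genus's own protected signature). This mirrors real 16S structure:
#'   genus-diagnostic signatures are conserved islands inside otherwise
#'   hypervariable regions, so in-group conservation drops off sharply at
#'   the signature boundaries.
#' @param read_error per-base substitution probability applied to
#'   simulated reads.
#' @param composition named genus->fraction vector for read simulation
#'   (must sum to 1); `NULL` defaults to 0.8 for the target genus and the
#'   rest split evenly.
#' @return a validated `gp_sim_config` list.
#' @export
sim_config <- function(seed = 1L, backbone_len = 1500L, n_genera = 2L,
                       n_species_per_genus = 5L, n_seqs_per_species = 20L,
                       signature_windows = NULL, signature_len = 30L,
                       universal_windows = list(c(200L, 30L), c(830L, 30L)),
                       genus_div = 0.02, species_mu = 0.05,
                       variable_flank = 40L, variable_mu = 0.40,
                       read_error = 0.01, composition = NULL) {
  cfg <- list(seed = as.integer(seed), backbone_len = as.integer(backbone_len),
              n_genera = as.integer(n_genera),
              n_species_per_genus = as.integer(n_species_per_genus),
              n_seqs_per_species = as.integer(n_seqs_per_species),
              signature_windows = signature_windows,
              signature_len = as.integer(signature_len),
              universal_windows = universal_windows,
              genus_div = genus_div, species_mu = species_mu,
              variable_flank = as.integer(variable_flank),
              variable_mu = variable_mu,
              read_error = read_error, composition = composition)
  if (is.null(cfg$signature_windows)) {
    # two windows per genus: one in an upstream block, one downstream,
    # staggered across genera so no two windows overlap
    cfg$signature_windows <- lapply(seq_len(cfg$n_genera), function(i) {
      off <- (i - 1L) * (cfg$signature_len + 10L)
      list(c(330L + off, cfg$signature_len),
           c(950L + off, cfg$signature_len))
    })
  }
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) gp_config_error(paste0("invalid sim config field '", field,
                                    "': ", why))
  chk(cfg$backbone_len >= 100L, "backbone_len", "must be >= 100")
  chk(cfg$n_genera >= 1L, "n_genera", "must be >= 1")
  chk(cfg$n_species_per_genus >= 1L, "n_species_per_genus", "must be >= 1")
  chk(cfg$n_seqs_per_species >= 1L, "n_seqs_per_species", "must be >= 1")
  for (p in c("genus_div", "species_mu", "variable_mu", "read_error"))
    chk(cfg[[p]] >= 0 && cfg[[p]] < 1, p, "must be in [0, 1)")
  chk(cfg$variable_flank >= 0L, "variable_flank", "must be >= 0")
  chk(length(cfg$signature_windows) == cfg$n_genera, "signature_windows",
      "need one window list per genus")
  all_wins <- c(do.call(c, cfg$signature_windows), cfg$universal_windows)
  spans <- lapply(all_wins, function(w) {
    chk(length(w) == 2L && w[[2]] >= 1L, "signature_windows",
        "each window is c(start, len)")
    chk(w[[1]] >= 0L && w[[1]] + w[[2]] <= cfg$backbone_len,
        "signature_windows", "window outside backbone")
    c(w[[1]], w[[1]] + w[[2]])
  })
  if (length(spans) > 1L) {
    m <- do.call(rbind, spans)
    m <- m[order(m[, 1]), , drop = FALSE]
    chk(all(m[-1, 1] >= m[-nrow(m), 2]), "signature_windows",
        "windows overlap")
  }
  if (!is.null(cfg$composition)) {
    chk(abs(sum(cfg$composition) - 1) < 1e-9, "composition",
        "fractions must sum to 1")
    chk(all(cfg$composition >= 0), "composition", "fractions must be >= 0")
  }
  structure(cfg, class = "gp_sim_config")
}

genus_names <- function(n) paste0("Genus", LETTERS[seq_len(n)])

BASES <- c("A", "C", "G", "T")

# substitute position i of `ch` with prob p[i] (p recycled); substitutions
# always change the base; protected indices are never touched
mutate_chars <- function(ch, p, protect = integer(0)) {
  if (all(p <= 0)) return(ch)
  idx <- which(runif(length(ch)) < p)
  idx <- setdiff(idx, protect)
  if (length(idx) > 0L) {
    for (i in idx) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  }
  ch
}

# random signature with balanced composition: half the positions drawn from
# {G,C}, half from {A,T}, shuffled — a planted window that admits
# primer-grade (40-60% GC) substrings
random_signature <- function(len) {
  n_gc <- floor(len / 2)
  sample(c(sample(c("G", "C"), n_gc, replace = TRUE),
           sample(c("A", "T"), len - n_gc, replace = TRUE)))
}

window_indices <- function(wins) {
  if (length(wins) == 0L) return(integer(0))
  unlist(lapply(wins, function(w) (w[[1]] + 1L):(w[[1]] + w[[2]])))
}

#' Simulate a labeled 16S-like genus panel with planted signatures
#'
#' Draws a random backbone, then for each genus: plants a fresh GC-balanced
#' genus-private signature in that genus's windows, applies `genus_div`
#' substitutions outside protected windows (the genus consensus), and
#' derives each species from the consensus by per-site substitution —
#' `variable_mu` inside hypervariable regions (any signature window plus
#' flanks), `species_mu` elsewhere, never inside the genus's own protected
#' windows. Sequences within a species are identical
#' (16S gene copies). Universal windows stay identical everywhere;
#' signature windows stay identical within their genus. The output is
#' deterministic for a fixed config.
#'
#' Because the mutation model is substitution-only, the sequences are
#' emitted unaligned and the companion in-group alignment (`aln`) is the
#' exact columnwise alignment.
#'
#' @param cfg a `gp_sim_config` from [sim_config()].
#' @return a list with `ingroup` / `outgroup` / `templates` (labeled
#'   `data.frame`s: id, genus, species, seq), `aln` (a `gp_alignment` of
#'   the in-group), and `truth` (list: `target_genus`, `windows`
#'   data.frame of planted per-genus signature windows with 0-based
#'   half-open coordinates, `universal_windows`, `backbone`).
#' @export
simulate_genus_panel <- function(cfg) {
  stopifnot(inherits(cfg, "gp_sim_config"))
  set.seed(cfg$seed)
  L <- cfg$backbone_len
  backbone <- sample(BASES, L, replace = TRUE)
  uni_idx <- window_indices(cfg$universal_windows)
  genera <- genus_names(cfg$n_genera)
  # hypervariable regions: every signature window plus its flanks
  hv_idx <- integer(0)
  for (wl in cfg$signature_windows) for (w in wl) {
    hv_idx <- c(hv_idx,
                max(1L, w[[1]] + 1L - cfg$variable_flank):
                  min(L, w[[1]] + w[[2]] + cfg$variable_flank))
  }
  hv_idx <- unique(hv_idx)
  recs <- list()
  win_rows <- list()
  for (g in seq_len(cfg$n_genera)) {
    own <- cfg$signature_windows[[g]]
    own_idx <- window_indices(own)
    protect <- c(uni_idx, own_idx)
    gcons <- backbone
    for (w in own) {  # genus-private signature: fresh GC-balanced sequence
      idx <- (w[[1]] + 1L):(w[[1]] + w[[2]])
      gcons[idx] <- random_signature(w[[2]])
    }
    gcons <- mutate_chars(gcons, cfg$genus_div, protect)
    for (w in own) {
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        genus = genera[[g]], start = w[[1]], end = w[[1]] + w[[2]],
        stringsAsFactors = FALSE)
    }
    mu_vec <- rep(cfg$species_mu, L)
    mu_vec[hv_idx] <- cfg$variable_mu
    for (s in seq_len(cfg$n_species_per_genus)) {
      scons <- mutate_chars(gcons, mu_vec, protect)
      species <- sprintf("%s species%02d", genera[[g]], s)
      for (copy in seq_len(cfg$n_seqs_per_species)) {
        recs[[length(recs) + 1L]] <- data.frame(
          id = sprintf("%s_sp%02d_c%02d", genera[[g]], s, copy),
          genus = genera[[g]], species = species,
          seq = paste(scons, collapse = ""), stringsAsFactors = FALSE)
      }
    }
  }
  templates <- do.call(rbind, recs)
  rownames(templates) <- NULL
  ingroup <- templates[templates$genus == genera[[1]], , drop = FALSE]
  outgroup <- templates[templates$genus != genera[[1]], , drop = FALSE]
  rownames(ingroup) <- NULL; rownames(outgroup) <- NULL
  aln <- new_alignment(ingroup$id, ingroup$seq, ingroup$genus,
                       ingroup$species)
  list(ingroup = ingroup, outgroup = outgroup, templates = templates,
       aln = aln,
       truth = list(target_genus = genera[[1]],
                    windows = do.call(rbind, win_rows),
                    universal_windows = cfg$universal_windows,
                    backbone = paste(backbone, collapse = "")))
}

#' Cut a universal primer pair from the simulated universal windows
#'
#' Returns a convergent primer pair lying inside the first and last
#' universal windows (identical in every simulated sequence), the
#' simulator's stand-in for universal 16S primers.
#'
#' @param panel output of [simulate_genus_panel()].
#' @param len primer length.
#' @return a list with `fwd` and `rev` (5'->3' oligo strings).
#' @export
universal_primers <- function(panel, len = 21L) {
  wins <- panel$truth$universal_windows
  if (length(wins) < 2L)
    gp_config_error("need at least two universal windows for a pair")
  bb <- panel$truth$backbone
  w1 <- wins[[1]]; w2 <- wins[[length(wins)]]
  if (len > w1[[2]] || len > w2[[2]])
    gp_config_error("primer length exceeds universal window length")
  fwd <- substr(bb, w1[[1]] + 1L, w1[[1]] + len)
  rev <- revcomp(substr(bb, w2[[1]] + w2[[2]] - len + 1L, w2[[1]] + w2[[2]]))
  list(fwd = fwd, rev = rev)
}

#' Simulate amplicon reads from a mock community
#'
#' Draws reads from the in-silico amplicons of each genus in proportion to
#' the composition, then applies per-base substitution errors. Each read is
#' a full amplicon of a randomly chosen template of its genus (amplicon
#' sequencing of pooled PCR products). Deterministic given the config.
#'
#' @param templates labeled template `data.frame` (id, genus, seq), e.g.
#'   `panel$templates`.
#' @param fwd,rev the amplifying primer pair.
#' @param cfg a `gp_sim_config`; `read_error` and `composition` are used,
#'   and reads are seeded from `cfg$seed + 1000` so that panel and read
#'   draws are decoupled.
#' @param n_reads number of reads to draw.
#' @param params binding/product parameters for the in-silico PCR
#'   ([design_params()]).
#' @return a list with `reads` (data.frame id, seq, qual) and `truth`
#'   (data.frame read_id, genus, template_id).
#' @export
simulate_reads <- function(templates, fwd, rev, cfg, n_reads = 1000L,
                           params = design_params()) {
  stopifnot(inherits(cfg, "gp_sim_config"))
  comp <- cfg$composition
  if (is.null(comp)) {
    genera <- unique(templates$genus)
    comp <- setNames(c(0.8, rep(0.2 / (length(genera) - 1L),
                                length(genera) - 1L)), genera)
    if (length(genera) == 1L) comp <- setNames(1, genera)
  }
  amps <- simulate_pcr(fwd, rev, templates, params$max_mm,
                       params$three_prime_exact, params$prod_min,
                       params$prod_max)
  by_genus <- split(amps, amps$genus)
  for (g in names(comp)) {
    if (comp[[g]] > 0 && (is.null(by_genus[[g]]) || nrow(by_genus[[g]]) == 0L))
      gp_stop(paste0("composition includes genus '", g,
                     "' but the pair amplifies none of its templates"),
              "gp_simulation_error")
  }
  set.seed(cfg$seed + 1000L)
  genus_draw <- sample(names(comp), n_reads, replace = TRUE, prob = comp)
  reads <- vector("list", n_reads)
  truth <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    g <- genus_draw[[i]]
    pool <- by_genus[[g]]
    a <- pool[sample.int(nrow(pool), 1L), ]
    ch <- strsplit(a$seq, "", fixed = TRUE)[[1]]
    ch <- mutate_chars(ch, cfg$read_error)
    rid <- sprintf("read%06d", i)
    reads[[i]] <- data.frame(id = rid, seq = paste(ch, collapse = ""),
                             qual = strrep("I", length(ch)),
                             stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(read_id = rid, genus = g,
                             template_id = a$template_id,
                             stringsAsFactors = FALSE)
  }
  list(reads = do.call(rbind, reads), truth = do.call(rbind, truth))
}
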