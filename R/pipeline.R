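#' Default pipeline configuration
#'
#' The full configuration of the end-to-end pipeline with every tunable at
#' its default. The dump re-loads to an equal config; unknown keys are
#' rejected on load.
#'
#' @return a nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    target_genus = "",   # empty: simulator target / first in-group genus
    simulate = list(
      enabled = TRUE, backbone_len = 1500L, n_genera = 2L,
      n_species_per_genus = 5L, n_seqs_per_species = 20L,
      signature_len = 30L, genus_div = 0.02, species_mu = 0.05,
      variable_flank = 40L, variable_mu = 0.40,
      read_error = 0.01, n_reads = 1000L, target_fraction = 0.8
    ),
    inputs = list(  # used when simulate.enabled is false
      ingroup = "", outgroup = "", msa = "", msa_dialect = "fasta",
      reads = "", refs = ""
    ),
    design = design_params(),
    classify = list(k = 12L, genus_thr = 0.90, species_thr = 0.97,
                    band = 48L, denominator = "all")
  )
}

#' Load a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; keys not in
#' [default_config()] raise a configuration error.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return the merged configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) gp_config_error(paste0("config not found: ", path))
  user <- yaml::read_yaml(path)
  merge_config(cfg, user, "")
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  if (!is.list(user))
    gp_config_error(paste0("config section '", prefix, "' must be a mapping"))
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0L)
    gp_config_error(paste0("unknown config key(s): ",
                           paste0(prefix, unknown, collapse = ", ")))
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Write a configuration to YAML
#'
#' @param config a configuration list.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate (optional) -> conserve -> design -> in-silico PCR ->
#' classify -> rate, writing every artifact under `out_dir` plus a JSON
#' manifest (`manifest.json`) listing artifact names, MD5 checksums,
#' per-stage counts, the seed and the package version. The manifest
#' contains no timestamps or absolute paths, so identical config + seed
#' reproduce it byte-identically.
#'
#' When simulation is enabled, amplicon reads are drawn with a universal
#' primer pair (cut from the simulated universally conserved windows) from
#' a mock community with `target_fraction` of reads from the target genus,
#' and the classification panel holds one representative per simulated
#' species.
#'
#' @param config a configuration list from [load_config()] /
#'   [default_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "gp-out") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  params <- do.call(design_params, config$design)
  art <- list()   # artifact name -> relative file name
  counts <- list()

  # ---- stage: inputs (simulate or load) ----
  if (isTRUE(config$simulate$enabled)) {
    s <- config$simulate
    scfg <- sim_config(seed = seed, backbone_len = s$backbone_len,
                       n_genera = s$n_genera,
                       n_species_per_genus = s$n_species_per_genus,
                       n_seqs_per_species = s$n_seqs_per_species,
                       signature_len = s$signature_len,
                       genus_div = s$genus_div, species_mu = s$species_mu,
                       variable_flank = s$variable_flank,
                       variable_mu = s$variable_mu,
                       read_error = s$read_error)
    panel <- simulate_genus_panel(scfg)
    target <- if (nzchar(config$target_genus)) config$target_genus
              else panel$truth$target_genus
    ingroup <- panel$ingroup; outgroup <- panel$outgroup
    aln <- panel$aln
    write_fasta(ingroup, file.path(out_dir, "ingroup.fasta"))
    write_fasta(outgroup, file.path(out_dir, "outgroup.fasta"))
    art$ingroup <- "ingroup.fasta"; art$outgroup <- "outgroup.fasta"
    refs <- panel$templates[!duplicated(panel$templates$species), ,
                            drop = FALSE]
  } else {
    inp <- config$inputs
    if (!nzchar(inp$ingroup))
      gp_config_error("simulate.enabled is false but inputs.ingroup is empty")
    ingroup <- read_fasta(inp$ingroup)
    outgroup <- if (nzchar(inp$outgroup)) read_fasta(inp$outgroup)
                else ingroup[0, ]
    aln <- if (nzchar(inp$msa)) read_alignment(inp$msa, inp$msa_dialect)
           else new_alignment(ingroup$id, ingroup$seq, ingroup$genus,
                              ingroup$species)
    target <- if (nzchar(config$target_genus)) config$target_genus
              else ingroup$genus[nzchar(ingroup$genus)][1]
    refs <- if (nzchar(inp$refs)) read_fasta(inp$refs)
            else rbind(ingroup, outgroup)
  }
  counts$n_ingroup <- nrow(ingroup); counts$n_outgroup <- nrow(outgroup)

  # ---- stage: conserve ----
  prof <- conservation_profile(aln)
  wins <- conserved_windows(prof, min_len = params$window_min_len,
                            tau = params$tau, gamma = params$gamma,
                            min_freq = params$consensus_min_freq)
  write_table(wins, file.path(out_dir, "windows.tsv"))
  art$windows <- "windows.tsv"
  counts$n_windows <- nrow(wins)

  # ---- stage: design ----
  cands <- suppressWarnings(enumerate_candidates(wins, params))
  if (nrow(cands) > 0L)
    cands <- suppressWarnings(specificity(cands, ingroup, outgroup, params))
  pairs <- if (nrow(cands) > 0L)
    suppressWarnings(pair_and_rank(cands, ingroup, outgroup, params))
  else empty_pairs()
  write_table(pairs, file.path(out_dir, "pairs.tsv"))
  art$pairs <- "pairs.tsv"
  counts$n_candidates <- nrow(cands); counts$n_pairs <- nrow(pairs)
  if (nrow(pairs) == 0L)
    gp_stop("design produced no primer pair (stage: design)",
            "gp_empty_result")
  top <- pairs[1L, ]

  # ---- stage: in-silico PCR of the top pair ----
  templates <- rbind(ingroup, outgroup)
  amps <- simulate_pcr(top$fwd_seq, top$rev_seq, templates, params$max_mm,
                       params$three_prime_exact, params$prod_min,
                       params$prod_max)
  amp_rec <- data.frame(
    id = sprintf("amp%04d|%s|%d-%d|mm%d+%d", seq_len(nrow(amps)),
                 amps$template_id, amps$start, amps$end, amps$fwd_mm,
                 amps$rev_mm),
    seq = amps$seq, stringsAsFactors = FALSE)
  write_fasta(amp_rec, file.path(out_dir, "amplicons.fasta"))
  write_table(virtual_gel(amps, template_ids = templates$id),
              file.path(out_dir, "bands.tsv"))
  art$amplicons <- "amplicons.fasta"; art$bands <- "bands.tsv"
  counts$n_amplicons <- nrow(amps)
  if (nrow(amps) == 0L)
    gp_stop("in-silico PCR produced no amplicon (stage: pcr)",
            "gp_empty_result")

  # ---- stage: classify + rate ----
  if (isTRUE(config$simulate$enabled)) {
    tf <- config$simulate$target_fraction
    genera <- unique(panel$templates$genus)
    others <- setdiff(genera, target)
    comp <- setNames(c(tf, rep((1 - tf) / max(length(others), 1L),
                               length(others))), c(target, others))
    scfg$composition <- comp
    up <- universal_primers(panel)
    rs <- simulate_reads(panel$templates, up$fwd, up$rev, scfg,
                         n_reads = config$simulate$n_reads, params = params)
    reads <- rs$reads
    write_table(rs$truth, file.path(out_dir, "read_truth.tsv"))
    art$read_truth <- "read_truth.tsv"
  } else {
    if (!nzchar(config$inputs$reads))
      gp_config_error("simulate.enabled is false but inputs.reads is empty")
    reads <- read_reads(config$inputs$reads)
  }
  cl <- config$classify
  assignments <- assign_reads(reads, refs, k = cl$k,
                              genus_thr = cl$genus_thr,
                              species_thr = cl$species_thr, band = cl$band)
  write_table(assignments, file.path(out_dir, "assignments.tsv"))
  art$assignments <- "assignments.tsv"
  counts$n_reads <- nrow(reads)
  counts$n_assigned <- sum(assignments$status == "assigned")
  rate <- effective_rate(assignments, target, denominator = cl$denominator)
  write_json_report(unclass(rate), file.path(out_dir, "rate.json"))
  art$rate <- "rate.json"
  counts$effective_rate <- rate$effective_rate

  # ---- manifest ----
  checksums <- vapply(art, function(f)
    unname(tools::md5sum(file.path(out_dir, f))), character(1))
  manifest <- list(
    package = "genusprimer",
    version = as.character(utils::packageVersion("genusprimer")),
    seed = seed, target_genus = target, parameters = config,
    artifacts = as.list(art), checksums = as.list(checksums),
    counts = counts,
    top_pair = list(fwd = top$fwd_seq, rev = top$rev_seq,
                    product_min = top$product_min,
                    product_max = top$product_max,
                    pair_ingroup_cov = top$pair_ingroup_cov,
                    pair_outgroup_hit = top$pair_outgroup_hit,
                    genus_specific = top$genus_specific))
  write_json_report(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
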