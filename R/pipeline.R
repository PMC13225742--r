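#' Construct a demonstration amplicon site
#'
#' Builds a synthetic amplicon whose protospacer carries adenines at
#' positions 1-12 (so the whole canonical editing-window region is
#' observable), a 3'-adjacent AGG PAM, and random flanks.
#'
#' @param site_id Site identifier.
#' @param seed Seed for the random flanks.
#' @param intended_positions Intended edit position(s) (default A5).
#' @param flank Flank length on each side (default 40).
#' @return A [protospacer_site()].
#' @export
example_site <- function(site_id = "demo", seed = 42L,
                         intended_positions = 5L, flank = 40L) {
  set.seed(seed)
  proto <- paste0(strrep("A", 12), "GTCGTCGT")
  left <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  right <- paste(sample(c("A", "C", "G", "T"), flank, TRUE), collapse = "")
  amp <- paste0(left, proto, "AGG", right)
  protospacer_site(site_id, amp, proto_start = flank,
                   intended_positions = intended_positions)
}

#' Default demonstration pipeline configuration
#'
#' A small, fast configuration exercising every stage end-to-end: one
#' amplicon site at 2,000 reads, two GOTI groups (an edited group with
#' deaminase off-targets and a control group with background only) of two
#' embryos each on a 100-kb genome, and three planted guide-similar decoys.
#'
#' @param seed Master seed; every stochastic stage derives its own seed from
#'   it.
#' @param out_dir Output directory for reports.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("run")) {
  list(seed = as.integer(seed), out_dir = out_dir,
       amplicon = list(n_reads = 2000L),
       offtarget = list(genome_len = 1e5, gc = 0.42, depth = 50L,
                        err_rate = 0.001, n_embryos = 2L,
                        groups = list(edited = list(n_deaminase = 60L,
                                                    n_background = 3L,
                                                    ta_weight = 4),
                                      control = list(n_deaminase = 0L,
                                                     n_background = 3L,
                                                     ta_weight = 1)),
                        control_group = "control"),
       predicted = list(spacer = NULL, pam = "NGG",
                        mismatch_list = c(0L, 1L, 2L), max_mm = 3L,
                        flank_bp = 25L))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on simulated inputs
#'
#' Executes simulate -> quantify -> window/purity -> paired SNV calling ->
#' consensus -> spectrum/logo -> predicted-site overlap -> group statistics,
#' writing per-stage TSVs and a machine-readable `summary.json` (stamped
#' with the package version, seed and a config hash) under
#' `config$out_dir`. All stages are deterministic for a fixed seed, so two
#' runs of the same config produce byte-identical reports.
#'
#' @param config A configuration list as produced by [default_run_config()],
#'   or a path to a YAML file with the same structure.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  msg <- function(...) message("[pipeline] ", sprintf(...))

  ## -- amplicon stage ------------------------------------------------------
  msg("amplicon stage")
  site <- example_site(seed = seed)
  acfg <- do.call(amplicon_sim_config,
                  c(list(seed = seed + 10L), config$amplicon))
  sim <- simulate_amplicon_reads(site, acfg)
  aligned <- align_reads(sim$reads, site)
  profile <- quantify_site(aligned, site)
  window <- editing_window(profile$a2g)
  purity <- purity_metrics(profile)
  pd <- perfect_and_dual_fractions(aligned, site)
  write_profile_tsv(profile, file.path(out_dir, "amplicon_profile.tsv"))
  write_window_tsv(list(demo = window), file.path(out_dir, "windows.tsv"))

  ## -- GOTI stage ----------------------------------------------------------
  msg("GOTI stage")
  ocfg <- config$offtarget
  genome <- make_genome(ocfg$genome_len %||% 1e5, ocfg$gc %||% 0.42,
                        seed = seed + 20L)
  profiles3 <- default_caller_profiles()
  counts <- list(); consensus_by_group <- list()
  k <- 0L
  for (g in names(ocfg$groups)) {
    gc_spec <- ocfg$groups[[g]]
    counts[[g]] <- numeric(0)
    group_calls <- list()
    for (e in seq_len(ocfg$n_embryos %||% 2L)) {
      k <- k + 1L
      cfg <- offtarget_sim_config(
        seed = seed + 100L + k,
        genome_len = ocfg$genome_len %||% 1e5, gc = ocfg$gc %||% 0.42,
        n_deaminase = gc_spec$n_deaminase %||% 0L,
        ta_weight = gc_spec$ta_weight %||% 1,
        n_background = gc_spec$n_background %||% 0L,
        n_germline = gc_spec$n_germline %||% 20L,
        depth = ocfg$depth %||% 50L, err_rate = ocfg$err_rate %||% 0.001)
      truth <- simulate_deaminase_snvs(genome, cfg)
      pile <- simulate_paired_pileups(genome, truth, cfg)
      calls <- lapply(profiles3, function(p)
        call_denovo_snvs(pile$edited, pile$control, p))
      cons <- consensus_intersection(calls)
      counts[[g]] <- c(counts[[g]], nrow(cons))
      group_calls[[e]] <- cons
    }
    consensus_by_group[[g]] <- do.call(rbind, lapply(group_calls,
                                                     as.data.frame))
  }
  stats <- group_statistics(counts, ocfg$control_group %||%
                              names(ocfg$groups)[length(ocfg$groups)])
  edited_name <- setdiff(names(ocfg$groups),
                         ocfg$control_group %||% "control")[1]
  edited_calls <- consensus_by_group[[edited_name]]
  spectrum <- mutation_spectrum(edited_calls)
  logo <- context_logo(edited_calls, genome)
  ta_frac <- ta_context_fraction(edited_calls, genome)
  write_snv_tsv(structure(edited_calls,
                          class = c("snv_call_set", "data.frame")),
                file.path(out_dir, "consensus_snvs.tsv"))
  utils::write.table(
    data.frame(class = names(spectrum$counts_12),
               count = spectrum$counts_12),
    file.path(out_dir, "spectrum.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(position = rownames(logo$base_counts), logo$base_counts,
               ic = logo$ic),
    file.path(out_dir, "context_matrix.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  ## -- predicted-site stage ------------------------------------------------
  msg("predicted-site stage")
  pcfg <- config$predicted
  spacer <- pcfg$spacer
  if (is.null(spacer)) {
    set.seed(seed + 30L)
    spacer <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  }
  planted <- plant_predicted_sites(genome, spacer, pcfg$pam %||% "NGG",
                                   pcfg$mismatch_list %||% c(0L, 1L, 2L),
                                   seed = seed + 31L)
  found <- enumerate_predicted_sites(planted$genome, spacer,
                                     pcfg$pam %||% "NGG",
                                     pcfg$max_mm %||% 3L)
  ov <- overlap_with_predicted(edited_calls, found,
                               pcfg$flank_bp %||% 25L)
  write_sites_bed(found, file.path(out_dir, "predicted_sites.bed"))

  ## -- summary -------------------------------------------------------------
  summary <- list(
    provenance = list(
      package = as.character(utils::packageVersion("abequant")),
      seed = seed,
      config_md5 = config_hash(config[setdiff(names(config), "out_dir")])),
    amplicon = list(
      site_id = site$site_id, n_reads = profile$n_reads,
      indel_fraction = profile$indel_fraction,
      peak_position = window$peak_position,
      peak_value = window$peak_value,
      window_positions = window$window_positions,
      a2_over_a5 = purity$a2_over_a5, a8_over_a5 = purity$a8_over_a5,
      bystander_sum = purity$bystander_sum,
      perfect_fraction = pd$perfect_fraction),
    goti = list(
      counts = counts,
      group_stats = stats,
      frac_AG_TC = spectrum$frac_AG_TC,
      ta_context_fraction = ta_frac,
      n_predicted_sites = nrow(found),
      snv_overlap_with_predicted = ov$count))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg("done: %s", out_dir)
  invisible(list(site = site, profile = profile, window = window,
                 purity = purity, perfect_dual = pd, counts = counts,
                 group_stats = stats, spectrum = spectrum, logo = logo,
                 ta_context_fraction = ta_frac, predicted = found,
                 overlap = ov, summary = summary, out_dir = out_dir))
}
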