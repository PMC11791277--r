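# Pipeline orchestration: runs the stages in dependency order from a single
# validated config, with per-stage seeds derived from one global seed and a
# JSON manifest of every artifact produced (with md5 hashes), so identical
# configs reproduce byte-identical outputs.

PIPELINE_STAGES <- c("simulate", "mutpcr", "spectrum", "melt", "select3d",
                     "consequence", "cohort")

#' Default pipeline configuration
#'
#' Returns the full configuration tree with every tunable parameter at its
#' default; pass a partial tree to [run_pipeline()] to override parts of it.
#' Per-stage seeds are derived from the global `seed` by a counter scheme
#' (`seed + stage index`), so each stage is independently reproducible.
#'
#' @return Nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    stages = PIPELINE_STAGES,
    reference = list(length = 183L, gc_target = 0.55, hotspot_template = TRUE),
    reads = list(rate = 0.0072, n_reads = 2000L, read_len = 150L),
    pcr = list(dctp = c(1000, 100, 50, 30, 10),
               delta = c("G>T" = 1e-4, "C>A" = 1e-4),
               cycles = 50L, dup_prob = 0.9, n_products = 200L),
    thermo = list(na_molar = 0.05, sigmoid_width = 0.3,
                  delta_tm_threshold = 0.4),
    melt = list(window_start = 25L, window_len = 30L,
                mutant_position = 34L, mutant_alt = "T"),
    select3d = list(gradient = seq(60, 90, by = 2), n_transitions = 10L),
    composition = list(baseline = c(A = 30, C = 20.5, G = 20.5, T = 29),
                       fold_at = 1.03, genome_bp = 6.2e9),
    consequence = list(variants = data.frame(
      position = c(32L, 34L, 69L), ref = c("C", "G", "G"),
      alt = c("T", "T", "A"), stringsAsFactors = FALSE)),
    cohort = list(n_patients = 135L,
                  prevalence = c(KRAS = 39 / 135, BRAF = 19 / 135,
                                 PI3K = 16 / 135),
                  tm_wt = 78.7, delta_tm_mut = 1.3, noise_sd = 0.1,
                  n_perm = 9999L)
  ), class = "run_config")
}

# Deep-merge a user config into the defaults, rejecting unknown keys.
merge_config <- function(user, defaults = default_config(), path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(sprintf("config%s must be a list", path))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(path, ".", unknown, collapse = ", ")))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.data.frame(defaults[[k]]))
      merge_config(user[[k]], defaults[[k]], paste0(path, ".", k))
    else user[[k]]
  }
  defaults
}

stage_seed <- function(config, stage) {
  as.integer(config$seed) + match(stage, PIPELINE_STAGES)
}

pipeline_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order
#' (simulate, mutpcr, spectrum, melt, select3d, consequence, cohort),
#' writing every artifact under `out_dir` and a `manifest.json` listing each
#' file with its md5 hash plus the fully-resolved config. Re-running with an
#' identical config reproduces byte-identical artifacts.
#'
#' @param config Partial configuration list (see [default_config()]), a path
#'   to a JSON config file, or `NULL` for all defaults.
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly (list with `config`, `stages`, `files`).
#' @export
run_pipeline <- function(config = NULL, out_dir = "mutascope_out",
                         quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- merge_config(config)
  bad <- setdiff(cfg$stages, PIPELINE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% cfg$stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  state <- new.env(parent = emptyenv())

  need <- function(what, from) {
    if (is.null(state[[what]]))
      stop(sprintf("stage '%s' requires the '%s' stage to run first", from, what))
    state[[what]]
  }
  out <- function(name) file.path(out_dir, name)
  emit <- function(path) { files <<- c(files, path); path }
  params <- do.call(thermo_params, cfg$thermo)

  for (stage in stages) {
    pipeline_log(quiet, stage, "starting (seed %d)", stage_seed(cfg, stage))
    switch(stage,
      simulate = {
        s <- stage_seed(cfg, stage)
        ref <- make_reference(reference_spec(
          cfg$reference$length, cfg$reference$gc_target,
          cfg$reference$hotspot_template, seed = s))
        reads <- simulate_reads(ref, rate = cfg$reads$rate,
                                n_reads = cfg$reads$n_reads,
                                read_len = min(cfg$reads$read_len,
                                               nchar(ref$bases)),
                                seed = s + 1L)
        cohort <- do.call(simulate_cohort,
                          c(cfg$cohort[c("n_patients", "prevalence", "tm_wt",
                                         "delta_tm_mut", "noise_sd")],
                            list(seed = s + 2L)))
        pair <- simulate_composition_pair(cfg$composition$baseline,
                                          cfg$composition$fold_at)
        state$reference <- ref; state$reads <- reads
        state$cohort <- cohort; state$composition_pair <- pair
        emit(write_fasta(ref, out("reference.fa")))
        emit(write_fastq(reads, out("reads.fastq")))
        emit(write_tsv(cohort, out("cohort.tsv")))
        emit(write_tsv(data.frame(base = BASES,
                                  before = as.numeric(pair$before[BASES]),
                                  after = as.numeric(pair$after[BASES])),
                       out("composition_pair.tsv")))
        emit(write_json_stable(
          list(reference = cfg$reference, reads = cfg$reads,
               cohort = cfg$cohort[c("n_patients", "prevalence", "tm_wt",
                                     "delta_tm_mut", "noise_sd")],
               composition = cfg$composition, seed = s),
          out("simulate_params.json")))
      },
      mutpcr = {
        ref <- need("reference", stage)
        s <- stage_seed(cfg, stage)
        model <- misincorporation_model(unlist(cfg$pcr$delta))
        pools <- mutpcr_pool_series(cfg$pcr$dctp)
        runs <- lapply(seq_along(pools), function(i) {
          prods <- simulate_pcr(ref, pools[[i]], model,
                                pcr_run(cfg$pcr$cycles, cfg$pcr$dup_prob,
                                        cfg$pcr$n_products, seed = s + i))
          list(pool = pools[[i]], products = prods,
               frequency = mutation_frequency(prods, ref))
        })
        names(runs) <- names(pools)
        state$pcr_runs <- runs
        summary <- data.frame(
          pool = names(runs),
          dCTP_uM = cfg$pcr$dctp,
          ratio = vapply(runs, function(r) dntp_ratio(r$pool), numeric(1)),
          mutation_frequency = vapply(runs, `[[`, numeric(1), "frequency"))
        emit(write_tsv(summary, out("mutpcr_summary.tsv")))
        most <- runs[[which.max(summary$ratio)]]
        emit(write_fasta(stats::setNames(most$products,
                                         sprintf("product_%04d",
                                                 seq_along(most$products))),
                         out("mutpcr_products_maxbias.fa")))
        pipeline_log(quiet, stage, "frequencies: %s",
                     paste(sprintf("%.4g", summary$mutation_frequency),
                           collapse = ", "))
      },
      spectrum = {
        ref <- need("reference", stage)
        reads <- need("reads", stage)
        m <- tally_matrix(reads, ref)
        sf <- site_frequency(reads, ref)
        hot <- hotspot_codon_report(sf)
        pair <- need("composition_pair", stage)
        enr <- at_enrichment(pair$before, pair$after,
                             genome_bp = cfg$composition$genome_bp)
        state$matrix <- m; state$site_freq <- sf; state$hotspot <- hot
        emit(write_tsv(as.data.frame.table(m$counts, responseName = "count"),
                       out("mutation_matrix.tsv")))
        emit(write_tsv(sf, out("site_frequency.tsv")))
        emit(write_json_stable(
          list(overall_frequency = overall_frequency(m),
               hotspots = hot,
               at_enrichment = enr),
          out("spectrum_report.json")))
      },
      melt = {
        ref <- need("reference", stage)
        w0 <- cfg$melt$window_start
        wt_win <- substr(ref$bases, w0, w0 + cfg$melt$window_len - 1L)
        mpos <- cfg$melt$mutant_position
        mut_win <- wt_win
        substr(mut_win, mpos - w0 + 1L, mpos - w0 + 1L) <- cfg$melt$mutant_alt
        wt_tm <- tm_estimate(wt_win, params)
        mut_tm <- tm_estimate(mut_win, params)
        prof_wt <- melt_curve(data.frame(weight = 1, tm = wt_tm), params)
        prof_mut <- melt_curve(data.frame(weight = 1, tm = mut_tm), params)
        calls <- data.frame(
          sample = c("WT_window", "mutant_window"),
          tm_called = c(prof_wt$tm_called, prof_mut$tm_called),
          call = c(classify_sample(prof_wt, wt_tm, params),
                   classify_sample(prof_mut, wt_tm, params)))
        state$melt_calls <- calls
        emit(write_tsv(data.frame(temp = prof_wt$temps,
                                  F_wt = prof_wt$fluorescence,
                                  dF_wt = prof_wt$derivative,
                                  F_mut = prof_mut$fluorescence,
                                  dF_mut = prof_mut$derivative),
                       out("melt_profiles.csv")))
        emit(write_tsv(calls, out("melt_calls.tsv")))
      },
      select3d = {
        ref <- need("reference", stage)
        s <- stage_seed(cfg, stage)
        # mutant carrying n CG>TA transitions at the first G/C positions
        idx <- seq_to_int(ref$bases)
        gcpos <- which(idx %in% c(2L, 3L))[seq_len(cfg$select3d$n_transitions)]
        mut <- idx
        mut[gcpos] <- ifelse(mut[gcpos] == 2L, 4L, 1L) # C>T, G>A
        seqs <- c(wild_type = ref$bases, at_rich_mutant = int_to_seq(mut))
        sel <- td_selection(seqs, cfg$select3d$gradient, params)
        state$selection <- sel
        emit(write_tsv(data.frame(
          temperature = rep(sel$gradient,
                            vapply(sel$recovered, length, integer(1))),
          sequence = unlist(sel$recovered, use.names = FALSE)),
          out("td_selection.tsv")))
        emit(write_json_stable(list(td = as.list(sel$td), seed = s),
                               out("td_values.json")))
      },
      consequence = {
        ref <- need("reference", stage)
        v <- cfg$consequence$variants
        cds_len <- 3L * (nchar(ref$bases) %/% 3L)
        cds <- substr(ref$bases, 1L, cds_len)
        ann <- lapply(seq_len(nrow(v)), function(i)
          annotate(coding_variant(v$position[i], v$ref[i], v$alt[i]), cds))
        tab <- do.call(rbind, lapply(ann, function(a)
          data.frame(position = a$position, ref = a$ref_base,
                     alt = a$alt_base, codon = a$codon_index,
                     ref_codon = a$ref_codon, alt_codon = a$alt_codon,
                     ref_aa = a$ref_aa, alt_aa = a$alt_aa,
                     synonymous = a$synonymous, hotspot = a$hotspot,
                     cg_to_ta = a$cg_to_ta,
                     transforming = is_transforming(a))))
        state$consequences <- tab
        emit(write_tsv(tab, out("consequences.tsv")))
      },
      cohort = {
        cohort <- need("cohort", stage)
        s <- stage_seed(cfg, stage)
        prev <- lapply(genes_of(cohort), function(g) {
          p <- prevalence(cohort, g)
          list(gene = g, n_mutant = p$n_mutant, n_total = p$n_total,
               fraction = p$fraction, percent_display = p$percent_display)
        })
        shift <- tm_shift_test(cohort, gene = genes_of(cohort)[1],
                               n_perm = cfg$cohort$n_perm, seed = s)
        state$prevalence <- prev; state$tm_shift <- shift
        emit(write_json_stable(list(prevalence = prev, tm_shift = shift),
                               out("cohort_report.json")))
      })
    pipeline_log(quiet, stage, "done")
  }

  manifest <- list(
    config = unclass(cfg),
    stages = stages,
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  write_json_stable(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}
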