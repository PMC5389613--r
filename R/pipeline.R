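#' Default pipeline configuration
#'
#' A flat, YAML-serializable list with one block per stage. `run_pipeline()`
#' accepts this list, a modified copy, or a path to a YAML file with the same
#' structure. Stages: `synth` (generate a synthetic dataset; otherwise
#' `input$peaks`/`input$loci` CSVs are read), `freqs` (peak filtering and
#' bulk frequency estimation), `individuals` (pseudo-individual simulation),
#' `diversity`, `distance` (PSA matrix), `nj`, `pcoa`, `structure` (K-scan,
#' delta-K, assignment), `substructure`.
#'
#' @param outdir output directory.
#' @param seed master seed for every stochastic stage.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(outdir = "bulkpop_out", seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = list(synth = TRUE, freqs = TRUE, individuals = TRUE,
                  diversity = TRUE, distance = TRUE, nj = TRUE, pcoa = TRUE,
                  structure = TRUE, substructure = FALSE),
    input = list(peaks = NULL, loci = NULL),
    synth = list(K_true = 3L, n_populations = 20L, n_loci = 28L,
                 drift_F = 0.2, admix_alpha = 0.2, n_individuals = 15L,
                 stutter_rate = 0.12, noise_peak_rate = 0.02),
    peak_filter = list(stutter_ratio = 0.2, noise_floor = 0.05),
    individuals = list(n_individuals = 15L, het_tolerance = 0.05),
    structure = list(k_min = 1L, k_max = 5L, burn_in = 2000L, reps = 2000L,
                     n_runs = 3L),
    substructure = list(k_max = 4L)
  )
}

#' Run the bulked-SSR analysis pipeline
#'
#' Executes the enabled stages in order — peaks -> bulk frequencies ->
#' pseudo-individuals -> (diversity, distances, NJ tree, PCoA) -> admixture
#' K-scan -> delta-K -> threshold assignment -> optional sub-structure — and
#' writes every artifact plus a manifest with md5 content hashes and a run
#' log. Identical configuration and seed reproduce identical outputs.
#'
#' @param config a list as from [pipeline_config()], or a path to a YAML file
#'   with the same structure.
#' @return The manifest `data.frame` (file, md5), invisibly; files are
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- pipeline_config()
  config <- utils::modifyList(base, config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "run.log")
  logmsg <- function(...) cat(format(Sys.time(), "%H:%M:%S"), ...,
                              "\n", file = logfile, append = TRUE)
  cat("bulkpop pipeline\n", file = logfile)
  logmsg("seed:", config$seed)
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  stage <- "init"
  tryCatch({
    stage <- "synth"
    if (isTRUE(config$stages$synth)) {
      gc_ <- do.call(generator_config, c(config$synth, list(seed = config$seed)))
      ds <- generate_dataset(gc_)
      ld <- ds$locus_defs
      peaks <- ds$peaks
      utils::write.csv(as.data.frame(peaks),
                       file.path(config$outdir, "peaks.csv"), row.names = FALSE)
      emit(file.path(config$outdir, "peaks.csv"))
      utils::write.csv(as.data.frame(unclass(ld)),
                       file.path(config$outdir, "loci.csv"), row.names = FALSE)
      emit(file.path(config$outdir, "loci.csv"))
      logmsg("synth: ", length(ds$freqs$pops), " populations")
    } else {
      ld <- read_locus_defs(config$input$loci)
      peaks <- read_peak_table(config$input$peaks, ld)
    }

    stage <- "freqs"
    if (isTRUE(config$stages$freqs)) {
      pf <- do.call(peak_filter_params, config$peak_filter)
      ft <- call_allele_frequencies(peaks, ld, pf)
      write_frequency_table(ft, file.path(config$outdir, "freqs.csv"))
      emit(file.path(config$outdir, "freqs.csv"))
      logmsg("freqs: ", length(ft$pops), " x ", length(ft$loci))
    }

    stage <- "individuals"
    if (isTRUE(config$stages$individuals)) {
      sp <- do.call(sim_params, c(config$individuals, list(seed = config$seed)))
      geno <- simulate_individuals(ft, sp)
      utils::write.csv(geno, file.path(config$outdir, "genotypes.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "genotypes.csv"))
      gfreq <- frequencies_from_genotypes(geno, ld)
    }

    stage <- "diversity"
    if (isTRUE(config$stages$diversity)) {
      all_in_one <- stats::setNames(rep("all", length(gfreq$pops)), gfreq$pops)
      div <- diversity_table(all_in_one, gfreq)
      utils::write.csv(div, file.path(config$outdir, "diversity.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "diversity.csv"))
    }

    stage <- "distance"
    if (isTRUE(config$stages$distance)) {
      d <- distance_matrix(gfreq)
      write_distance_matrix(d, file.path(config$outdir, "dist.csv"))
      emit(file.path(config$outdir, "dist.csv"))
      logmsg("distance: extremes ", signif(attr(d, "min_value"), 3), " - ",
             signif(attr(d, "max_value"), 3))
    }

    stage <- "nj"
    if (isTRUE(config$stages$nj)) {
      tree <- neighbor_joining(d)
      write_newick(tree, file.path(config$outdir, "tree.nwk"))
      emit(file.path(config$outdir, "tree.nwk"))
    }

    stage <- "pcoa"
    if (isTRUE(config$stages$pcoa)) {
      ord <- pcoa_analysis(d)
      co <- data.frame(population = rownames(ord$coordinates),
                       ord$coordinates, check.names = FALSE)
      utils::write.csv(co, file.path(config$outdir, "pcoa.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "pcoa.csv"))
    }

    stage <- "structure"
    asg <- NULL
    if (isTRUE(config$stages$structure)) {
      ap <- admixture_params(burn_in = config$structure$burn_in,
                             reps = config$structure$reps,
                             n_runs = config$structure$n_runs,
                             seed = config$seed)
      scan <- k_scan(geno, config$structure$k_min:config$structure$k_max, ap)
      lnpd_df <- data.frame(run = seq_len(nrow(scan$lnpd)), scan$lnpd,
                            check.names = FALSE)
      utils::write.csv(lnpd_df, file.path(config$outdir, "lnpd.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "lnpd.csv"))
      if (!is.null(scan$delta_k)) {
        utils::write.csv(scan$delta_k, file.path(config$outdir, "deltak.csv"),
                         row.names = FALSE)
        emit(file.path(config$outdir, "deltak.csv"))
      }
      sel <- scan$selected_k
      if (is.na(sel) || sel < 2L) sel <- max(2L, config$structure$k_min)
      best <- which.max(scan$lnpd[, as.character(sel)])
      qbar <- scan$runs[[as.character(sel)]][[best]]$Qbar
      write_q_matrix(qbar, file.path(config$outdir, "qmatrix.csv"))
      emit(file.path(config$outdir, "qmatrix.csv"))
      asg <- assign_groups(qbar, labels = paste0("G", seq_len(ncol(qbar))))
      utils::write.csv(asg, file.path(config$outdir, "assignments.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "assignments.csv"))
      logmsg("structure: selected K = ", scan$selected_k)
    }

    stage <- "substructure"
    if (isTRUE(config$stages$substructure) && !is.null(asg)) {
      ap <- admixture_params(burn_in = config$structure$burn_in,
                             reps = config$structure$reps,
                             n_runs = config$structure$n_runs,
                             seed = config$seed + 1L)
      subres <- hierarchical_substructure(geno, asg,
                                          k_max = config$substructure$k_max,
                                          params = ap)
      utils::write.csv(subres$assignment,
                       file.path(config$outdir, "sub_assignments.csv"),
                       row.names = FALSE)
      emit(file.path(config$outdir, "sub_assignments.csv"))
    }
  }, error = function(e) {
    logmsg("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  logmsg("done: ", nrow(manifest), " artifacts")
  invisible(manifest)
}
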