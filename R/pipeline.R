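## End-to-end orchestration: simulate -> classify -> events -> DE
## (+ permutation) -> usage -> proteomics meta -> sectors -> motility, from
## one plain-text config with explicit per-stage seeds (no hidden global
## RNG), writing delimited outputs and a JSON run manifest.

#' Default pipeline configuration
#'
#' A plain list; persist it with `jsonlite::write_json()` and reload with
#' [read_pipeline_config()]. Every enabled stage has an explicit seed.
#'
#' @param outdir Output directory.
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return Named list of stage toggles, parameters and seeds.
#' @export
pipeline_config <- function(outdir = "isoformshift_run", seed = 7L) {
  list(
    outdir = outdir,
    stages = list(simulate = TRUE, classify = TRUE, events = TRUE,
                  de = TRUE, usage = TRUE, meta = TRUE, sectors = TRUE,
                  motility = TRUE),
    simulate = list(n_genes = 150L, n_obs = 400L, seed = derive_seed(seed, 1)),
    de = list(permutations = 30L, contrast = c("DCM", "CTRL"),
              lfc_guide = 1, seed = derive_seed(seed, 2)),
    usage = list(min_total = 10),
    meta = list(method = "DL", seed = derive_seed(seed, 3)),
    motility = list(seed = derive_seed(seed, 4)),
    inputs = list()   # pre-existing files override simulated ones
  )
}

#' Read a pipeline configuration from JSON
#' @param path JSON file written from a [pipeline_config()]-shaped list.
#' @return Config list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- pipeline_config()
  modifyList(cfg, user)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the pipeline
#'
#' Stages run in dependency order; a stage failure halts its downstream
#' dependents only and is recorded in the manifest. Rerunning with the same
#' config and seeds reproduces identical output checksums.
#'
#' @param config A [pipeline_config()] list or path to a JSON config.
#' @return The manifest (also written to `<outdir>/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  done <- character()
  state <- new.env(parent = emptyenv())

  record <- function(stage, status, outputs = character(),
                     params = list(), seed = NULL, message = NULL) {
    manifest[[stage]] <<- list(
      stage = stage, status = status,
      outputs = as.list(outputs),
      checksum = as.list(unname(tools::md5sum(outputs))),
      parameters = params, seed = seed, message = message)
    if (status == "ok") done <<- c(done, stage)
  }
  run_stage <- function(stage, deps, fn, params = list(), seed = NULL) {
    if (!isTRUE(config$stages[[stage]])) {
      record(stage, "disabled",
             message = if (length(deps)) paste(
               "disabled; dependents of", stage, "will not run") else NULL)
      return(invisible())
    }
    missing_dep <- setdiff(deps, done)
    if (length(missing_dep)) {
      record(stage, "skipped",
             message = paste("upstream stage not available:",
                             paste(missing_dep, collapse = ", ")))
      message("stage '", stage, "' skipped (needs: ",
              paste(missing_dep, collapse = ", "), ")")
      return(invisible())
    }
    out <- tryCatch(fn(), error = function(e) e)
    if (inherits(out, "error"))
      record(stage, "failed", params = params, seed = seed,
             message = conditionMessage(out))
    else record(stage, "ok", outputs = out, params = params, seed = seed)
  }

  run_stage("simulate", character(), function() {
    sc <- config$simulate
    ann <- make_annotation(sc$n_genes, seed = sc$seed)
    obs <- perturb_transcripts(ann, n = sc$n_obs,
                               seed = derive_seed(sc$seed, 11))
    design <- cohort_design(seed = derive_seed(sc$seed, 12))
    cm <- simulate_counts(ann, design, seed = derive_seed(sc$seed, 13))
    prot <- simulate_proteomics(seed = derive_seed(sc$seed, 14))
    mot <- simulate_motility(seed = derive_seed(sc$seed, 15))
    state$ann <- ann; state$obs <- obs; state$cm <- cm
    state$prot <- prot; state$mot <- mot
    paths <- c(
      write_transcripts(ann, file.path(outdir, "reference.gtf")),
      write_transcripts(obs$transcripts, file.path(outdir, "observed.gtf")),
      write_tsv(obs$truth, file.path(outdir, "truth.tsv")),
      write_tsv(cbind(feature_id = rownames(state$cm$counts),
                      as.data.frame(state$cm$counts)),
                file.path(outdir, "counts.tsv")),
      write_tsv(state$cm$samples, file.path(outdir, "samples.tsv")),
      write_tsv(state$mot, file.path(outdir, "motility.tsv")))
    paths
  }, params = config$simulate["n_genes"], seed = config$simulate$seed)

  run_stage("classify", "simulate", function() {
    cb <- classify_batch(state$obs$transcripts, state$ann)
    state$calls <- cb$calls
    c(write_tsv(cb$calls, file.path(outdir, "calls.tsv")),
      write_tsv(cb$summary, file.path(outdir, "calls_summary.tsv")))
  })

  run_stage("events", c("simulate", "classify"), function() {
    mo <- merge_observed(state$ann, state$obs$transcripts, state$calls)
    ev <- enumerate_events(mo$annotation, mo$novel_ids)
    c(write_tsv(ev, file.path(outdir, "events.tsv")),
      write_tsv(count_events(ev), file.path(outdir, "event_counts.tsv")))
  })

  run_stage("de", "simulate", function() {
    dc <- config$de
    de <- de_analysis(state$cm, contrast = dc$contrast,
                      permutations = dc$permutations, seed = dc$seed)
    state$de <- de
    volcano <- de$result
    volcano$lfc_guide <- abs(volcano$log2FoldChange) >= dc$lfc_guide
    c(write_tsv(de$result, file.path(outdir, "de.tsv")),
      write_tsv(volcano, file.path(outdir, "volcano.tsv")),
      write_tsv(data.frame(alpha_star = de$calibration$alpha_star,
                           B = de$calibration$B,
                           min_p = de$calibration$min_p),
                file.path(outdir, "calibration.tsv")))
  }, params = config$de[c("permutations", "contrast")],
     seed = config$de$seed)

  run_stage("usage", c("simulate", "de"), function() {
    keep <- state$cm$samples$condition %in% config$de$contrast
    usage <- dm_usage(state$cm$counts[, keep],
                      stats::setNames(state$cm$features$gene_id,
                                      state$cm$features$feature_id),
                      droplevels(state$cm$samples$condition[keep]),
                      min_total = config$usage$min_total)
    sw <- detect_opposing(state$de$result,
                          stats::setNames(state$cm$features$gene_id,
                                          state$cm$features$feature_id))
    c(write_tsv(usage, file.path(outdir, "usage.tsv")),
      write_tsv(sw, file.path(outdir, "switches.tsv")))
  })

  run_stage("meta", "simulate", function() {
    eff <- do.call(rbind, lapply(state$prot$studies, function(st) {
      gene_tab <- aggregate_protein_groups(st$intensities, st$group2gene)
      study_effect(gene_tab, st$covariates, study_id = st$study_id)
    }))
    meta <- meta_all(eff, method = config$meta$method)
    state$meta <- meta
    c(write_tsv(eff, file.path(outdir, "study_effects.tsv")),
      write_tsv(meta, file.path(outdir, "meta.tsv")))
  })

  run_stage("sectors", c("de", "meta"), function() {
    g <- stats::setNames(state$cm$features$gene_id,
                         state$cm$features$feature_id)
    rna <- state$de$result
    rna_gene <- data.frame(gene = g[rna$feature_id],
                           log2fc = rna$log2FoldChange,
                           significant = rna$significant %||% FALSE)
    ## gene-level RNA flag: strongest isoform per gene
    rna_gene <- do.call(rbind, lapply(split(rna_gene, rna_gene$gene),
      function(d) d[which.max(abs(d$log2fc)), ]))
    prot <- data.frame(gene = state$meta$gene, log2fc = state$meta$mu,
                       significant = state$meta$pvalue < 0.05)
    ns <- nine_sector(rna_gene, prot)
    c(write_tsv(ns$sectors, file.path(outdir, "sectors.tsv")),
      write_tsv(ns$summary, file.path(outdir, "sector_summary.tsv")))
  })

  run_stage("motility", "simulate", function() {
    fit <- fit_hill(state$mot)
    c(write_tsv(data.frame(v_max = fit$v_max, v_min = fit$v_min,
                           pCa50 = fit$pCa50, n_H = fit$n_H,
                           r_squared = fit$r_squared),
                file.path(outdir, "hill_fit.tsv")),
      write_tsv(fit$curve, file.path(outdir, "hill_curve.tsv")))
  }, seed = config$motility$seed)

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(manifest)
}
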