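# End-to-end orchestration: ingest -> burden -> signatures -> neoantigen
# -> survival -> associations, as a plain-files pipeline. Every stage
# writes TSV/JSON into the output directory and the run ends with a
# manifest recording package version, seed and parameters (no timestamps,
# so reruns are byte-identical).

default_run_params <- function() {
  list(kind = "SBS96", k = "auto", k_range = 1:4, n_restarts = 10L,
       seed = 1L, sb_rank = 0.5, wb_rank = 2.0, unpaired_ratio = 15,
       unpaired_mode = "log2_ratio", minprop = 0.1, alpha = 0.05,
       min_mutated = 3L, top_n = 25L, age_threshold = 60)
}

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$inputs)) stop("run config needs an 'inputs' section")
  if (is.null(config$out_dir)) stop("run config needs 'out_dir'")
  stages <- utils::modifyList(
    list(signatures = TRUE, burden = TRUE, neoantigen = TRUE,
         survival = TRUE, associations = TRUE),
    config$stages %||% list())
  params <- utils::modifyList(default_run_params(), config$params %||% list())
  list(inputs = config$inputs, stages = stages, params = params,
       out_dir = config$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order over MAF + clinical
#' (+ optional binding and driver-caller) inputs: cohort ingestion and
#' merge, mutation burden, signature extraction with clinical enrichment,
#' neoantigen scoring with the sharing spectrum, optimal survival
#' cutpoints for every continuous score, and gene-clinical associations
#' (Fisher tests, HMG/LMG, mutual exclusivity, driver consensus). Each
#' stage writes its tables under `out_dir`; `manifest.json` lists the
#' parameters, seed and produced files. Reruns with the same config are
#' byte-identical.
#'
#' @param config a list (or path to a YAML file) with elements `inputs`
#'   (named: `maf` = named character vector/list of MAF paths keyed by
#'   cohort label, `clinical` = clinical TSV path(s), optional `binding` =
#'   peptide TSV, optional `driver_tools` = named list of per-tool result
#'   TSVs), optional `stages` (logical toggles), optional `params`
#'   (`kind`, `k` = "auto" or integer, `k_range`, `n_restarts`, `seed`,
#'   `sb_rank`, `wb_rank`, `unpaired_ratio`, `unpaired_mode`, `minprop`,
#'   `alpha`, `min_mutated`, `top_n`, `age_threshold`) and `out_dir`.
#' @return invisibly, a list of in-memory stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  p <- cfg$params
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  results <- list()
  stages_run <- character(0)

  ## ingest (always on: everything depends on it) -----------------------
  maf_paths <- cfg$inputs$maf
  if (is.null(maf_paths)) stop("stage 'ingest' failed: no MAF inputs configured")
  labels <- names(maf_paths) %||% paste0("cohort", seq_along(maf_paths))
  if (any(labels == "")) labels[labels == ""] <- paste0("cohort", which(labels == ""))
  muts <- mapply(read_maf, unlist(maf_paths), labels, SIMPLIFY = FALSE)
  clin <- lapply(unlist(cfg$inputs$clinical), read_clinical)
  cohort <- merge_cohorts(unname(muts), unname(clin))
  files <- c(files, write_tsv(cohort$mutations,
                              file.path(cfg$out_dir, "mutations.tsv")),
             write_tsv(cohort$clinical,
                       file.path(cfg$out_dir, "clinical_normalized.tsv")))
  results$cohort <- cohort
  stages_run <- c(stages_run, "ingest")
  groupings <- suppressWarnings(build_groupings(cohort$clinical,
                                                age_threshold = p$age_threshold))

  ## burden --------------------------------------------------------------
  scores <- NULL
  if (isTRUE(cfg$stages$burden)) {
    burden <- compute_burden(cohort)
    files <- c(files, write_tsv(burden, file.path(cfg$out_dir, "burden.tsv")))
    conc <- burden_concordance(burden)
    jsonlite::write_json(conc, file.path(cfg$out_dir, "burden_concordance.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(cfg$out_dir, "burden_concordance.json"))
    results$burden <- burden
    results$burden_concordance <- conc
    scores <- burden[, c("sample_id", "aTMB", "fTMB"), with = FALSE]
    stages_run <- c(stages_run, "burden")
  }

  ## signatures -----------------------------------------------------------
  if (isTRUE(cfg$stages$signatures)) {
    catalog <- suppressWarnings(build_catalog(cohort, kind = p$kind))
    files <- c(files, write_catalog(catalog,
                                    file.path(cfg$out_dir, "catalog.tsv")))
    k <- p$k
    if (identical(k, "auto")) {
      sel <- select_k(catalog, k_range = p$k_range, seed = p$seed,
                      n_restarts = p$n_restarts)
      k <- sel$k
      files <- c(files, write_tsv(sel$table,
                                  file.path(cfg$out_dir, "rank_selection.tsv")))
      results$rank_selection <- sel
    }
    sigs <- extract_signatures(catalog, k = as.integer(k),
                               n_restarts = p$n_restarts, seed = p$seed)
    sig_dt <- data.table::data.table(channel = rownames(sigs$signatures))
    for (cn in colnames(sigs$signatures)) {
      data.table::set(sig_dt, j = cn, value = sigs$signatures[, cn])
    }
    expo_dt <- data.table::data.table(sample_id = rownames(sigs$exposures))
    for (cn in colnames(sigs$exposures)) {
      data.table::set(expo_dt, j = cn, value = sigs$exposures[, cn])
    }
    data.table::set(expo_dt, j = "dominant",
                    value = colnames(sigs$exposures)[sigs$dominant])
    files <- c(files,
               write_tsv(sig_dt, file.path(cfg$out_dir, "signatures.tsv")),
               write_tsv(expo_dt, file.path(cfg$out_dir, "exposures.tsv")))
    dom <- stats::setNames(colnames(sigs$exposures)[sigs$dominant],
                           rownames(sigs$exposures))
    sig_assoc <- signature_clinical_tests(dom, groupings[
      !names(groupings) %in% "location"])
    files <- c(files, write_tsv(sig_assoc,
                                file.path(cfg$out_dir, "signature_assoc.tsv")))
    results$signatures <- sigs
    results$signature_assoc <- sig_assoc
    stages_run <- c(stages_run, "signatures")
  }

  ## neoantigen -----------------------------------------------------------
  if (isTRUE(cfg$stages$neoantigen) && !is.null(cfg$inputs$binding)) {
    peptides <- read_binding_table(cfg$inputs$binding)
    neo <- sample_scores(peptides, sb_rank = p$sb_rank, wb_rank = p$wb_rank,
                         unpaired_ratio = p$unpaired_ratio,
                         unpaired_mode = p$unpaired_mode)
    cand <- filter_candidates(peptides, sb_rank = p$sb_rank,
                              wb_rank = p$wb_rank)
    spectrum <- sharing_spectrum(cand)
    files <- c(files,
               write_tsv(neo$scores, file.path(cfg$out_dir, "neoantigen.tsv")),
               write_tsv(neo$gene_scores,
                         file.path(cfg$out_dir, "gene_scores.tsv")),
               write_tsv(spectrum,
                         file.path(cfg$out_dir, "sharing_spectrum.tsv")))
    results$neoantigen <- neo
    results$sharing_spectrum <- spectrum
    if (!is.null(scores)) {
      scores <- merge(scores, neo$scores, by = "sample_id", all.x = TRUE)
    }
    stages_run <- c(stages_run, "neoantigen")
  } else if (isTRUE(cfg$stages$neoantigen)) {
    message("neoantigen stage skipped: no binding table configured")
  }

  ## survival -------------------------------------------------------------
  if (isTRUE(cfg$stages$survival)) {
    if (is.null(scores)) {
      stop("stage 'survival' needs the burden stage (its scores) enabled")
    }
    surv_base <- cohort$clinical[, c("sample_id", "os_time", "os_event"),
                                 with = FALSE]
    data.table::setnames(surv_base, c("sample_id", "time", "event"))
    surv_base <- surv_base[!is.na(time) & !is.na(event) & time > 0]
    cut_rows <- list()
    for (sc in setdiff(names(scores), "sample_id")) {
      rec <- merge(surv_base,
                   scores[, c("sample_id", sc), with = FALSE],
                   by = "sample_id")
      data.table::setnames(rec, sc, "score")
      rec <- rec[!is.na(score)]
      res <- tryCatch(optimal_cutpoint(rec, minprop = p$minprop),
                      error = function(e) NULL)
      if (is.null(res)) next
      cut_rows[[sc]] <- data.table::data.table(
        score = sc, cutpoint = res$cutpoint, statistic = res$statistic,
        n_high = res$n_high, n_low = res$n_low,
        p_unadjusted = res$p_unadjusted, p_adjusted = res$p_adjusted)
    }
    cutpoints <- data.table::rbindlist(cut_rows)
    files <- c(files, write_tsv(cutpoints,
                                file.path(cfg$out_dir, "survival_cutpoints.tsv")))
    results$cutpoints <- cutpoints
    stages_run <- c(stages_run, "survival")
  }

  ## associations ----------------------------------------------------------
  if (isTRUE(cfg$stages$associations)) {
    assoc_all <- list()
    for (g in setdiff(names(groupings), "location")) {
      grp <- groupings[[g]]
      res <- tryCatch(
        gene_group_fisher(cohort, grp, min_mutated = p$min_mutated),
        error = function(e) NULL)
      if (is.null(res) || nrow(res) == 0L) next
      res[, grouping := g]
      assoc_all[[g]] <- res
    }
    assoc <- data.table::rbindlist(assoc_all, fill = TRUE)
    files <- c(files, write_tsv(assoc,
                                file.path(cfg$out_dir, "gene_associations.tsv")))
    results$gene_associations <- assoc
    if ("lymph" %in% names(assoc_all)) {
      hl <- hmg_lmg_classify(assoc_all$lymph, alpha = p$alpha)
      files <- c(files, write_tsv(hl, file.path(cfg$out_dir, "hmg_lmg.tsv")))
      results$hmg_lmg <- hl
    }
    inter <- pairwise_interactions(cohort, top_n = p$top_n, alpha = p$alpha)
    files <- c(files, write_tsv(inter,
                                file.path(cfg$out_dir, "interactions.tsv")))
    results$interactions <- inter
    if (!is.null(cfg$inputs$driver_tools)) {
      tool_tabs <- lapply(cfg$inputs$driver_tools, data.table::fread)
      drivers <- driver_consensus(tool_tabs)
      files <- c(files, write_tsv(drivers,
                                  file.path(cfg$out_dir, "driver_consensus.tsv")))
      results$drivers <- drivers
    }
    stages_run <- c(stages_run, "associations")
  }

  manifest <- list(
    package = "mutscape",
    version = as.character(utils::packageVersion("mutscape")),
    seed = p$seed, parameters = p[order(names(p))],
    stages = stages_run,
    files = sort(basename(files)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
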