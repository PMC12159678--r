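# End-to-end orchestration: regions -> counts -> TPM -> junctions ->
# decomposition -> methylation -> consensus -> single-cell summaries,
# driven by a single YAML (or list) configuration.  Results go to
# files; the machine-readable report carries no timestamps so a run is
# byte-identical under fixed inputs and seed.

.stage_names <- c("regions", "counts", "tpm", "junctions",
                  "decomposition", "methylation", "consensus",
                  "single_cell")

#' Load and validate a pipeline configuration
#'
#' @param config path to a YAML file, or an equivalent nested list.
#'   Recognized sections (all optional except `output_dir` and
#'   `annotation` when counting is requested):
#'   \describe{
#'     \item{output_dir}{directory for all outputs.}
#'     \item{annotation}{`gtf`, `repeat_bed`, `rules` (feature rules as
#'       in [build_quantification_regions()], with `intervals` given as
#'       `chrom:start-end` strings).}
#'     \item{counts}{`block_table`, plus [counting_policy()] fields.}
#'     \item{junctions}{`region_a`, `region_b` (repeat-feature names
#'       from `repeat_bed`), `threshold`, `total_mapped`.}
#'     \item{decomposition}{`samples`, `epsilon`, `scale_outcome`.}
#'     \item{methylation}{`bedmethyl`, `chrom`, `start`, `end`,
#'       `min_cov`, `site_threshold`, `region_threshold`.}
#'     \item{consensus}{`msa`, `query_id`, `min_consensus_freq`,
#'       `min_ref_length`.}
#'     \item{single_cell}{`cells`, `feature`, `features` (vector),
#'       `min_cells_per_type`, `high_threshold`, `type_set`,
#'       `type_col`.}
#'     \item{seed}{master seed echoed into the report.}
#'   }
#' @return validated config list (class `pipeline_config`).
#' @export
load_pipeline_config <- function(config) {
  base <- NULL
  if (is.character(config)) {
    if (!file.exists(config))
      stop("configuration error: config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (!is.null(base)) {
    # resolve input paths relative to the config file's directory
    resolve <- function(p) {
      if (is.null(p) || file.exists(p)) return(p)
      cand <- file.path(base, p)
      if (file.exists(cand)) cand else p
    }
    for (sec in list(c("annotation", "gtf"),
                     c("annotation", "repeat_bed"),
                     c("counts", "block_table"),
                     c("decomposition", "samples"),
                     c("methylation", "bedmethyl"),
                     c("consensus", "msa"),
                     c("single_cell", "cells")))
      if (!is.null(config[[sec[1L]]][[sec[2L]]]))
        config[[sec[1L]]][[sec[2L]]] <-
          resolve(config[[sec[1L]]][[sec[2L]]])
  }
  if (is.null(config$output_dir))
    stop("configuration error: output_dir is required")
  inputs <- c(annotation = config$annotation$gtf,
              repeat_bed = config$annotation$repeat_bed,
              block_table = config$counts$block_table,
              samples = config$decomposition$samples,
              bedmethyl = config$methylation$bedmethyl,
              msa = config$consensus$msa,
              cells = config$single_cell$cells)
  missing <- inputs[!vapply(inputs, file.exists, TRUE)]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)),
               collapse = ", "))
  class(config) <- c("pipeline_config", "list")
  config
}

.parse_rule <- function(rule) {
  if (identical(rule$type, "intervals") && is.character(rule$intervals)) {
    m <- regmatches(rule$intervals,
                    regexec("^([^:]+):([0-9]+)-([0-9]+)$",
                            rule$intervals))
    stopifnot(all(lengths(m) == 4L))
    rule$intervals <- GenomicRanges::GRanges(
      vapply(m, `[`, "", 2L),
      IRanges::IRanges(as.integer(vapply(m, `[`, "", 3L)) + 1L,
                       as.integer(vapply(m, `[`, "", 4L))))
  }
  rule
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order.  Any stage
#' failure aborts with the stage name and cause; outputs written before
#' the failure are kept next to a `FAILED_<stage>` marker file.
#'
#' @param config a path to a YAML config, or a list (see
#'   [load_pipeline_config()]).
#' @return the run report (list), invisibly; also written as
#'   `report.json` and `report.md` under `output_dir`.
#' @export
run_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package = "erviso",
                 version = as.character(packageVersion("erviso")),
                 config = unclass(config),
                 stages = list())
  current_stage <- NULL
  run_stage <- function(name, enabled, fun) {
    if (!enabled) {
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    current_stage <<- name
    res <- tryCatch(fun(), error = function(e) {
      writeLines(conditionMessage(e),
                 file.path(out_dir, paste0("FAILED_", name)))
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    report$stages[[name]] <<- c(list(status = "ok"), res)
  }

  env <- new.env()

  run_stage("regions", !is.null(config$annotation$gtf), function() {
    tx <- read_transcript_gtf(config$annotation$gtf)
    env$transcripts <- tx
    env$repeats <- if (!is.null(config$annotation$repeat_bed))
      read_repeat_features(config$annotation$repeat_bed) else NULL
    rules <- lapply(config$annotation$rules, .parse_rule)
    body <- NULL
    if (!is.null(env$repeats)) {
      bn <- config$annotation$repeat_body_name
      if (is.null(bn)) bn <- "repeat_body"
      body <- env$repeats[env$repeats$name == bn]
    }
    env$regions <- build_quantification_regions(tx, body, rules)
    write_regions_gtf(env$regions, file.path(out_dir, "regions.gtf"))
    list(n_transcripts = length(tx),
         features = as.list(effective_lengths(env$regions)))
  })

  run_stage("counts", !is.null(config$counts$block_table), function() {
    if (is.null(env$regions))
      stop("counting requires the regions stage (annotation section)")
    pol <- do.call(counting_policy,
                   config$counts[intersect(names(config$counts),
                                           names(formals(counting_policy)))])
    env$reads <- read_block_table(config$counts$block_table)
    env$counts <- count_reads(env$reads, env$regions, pol)
    write_count_table(env$counts, file.path(out_dir, "counts.tsv"))
    list(n_samples = ncol(env$counts$counts),
         total_assigned = sum(env$counts$counts),
         skipped = env$counts$skipped)
  })

  run_stage("tpm", !is.null(env$counts), function() {
    tpm <- tpm_normalize(env$counts, env$regions)
    write_count_table(tpm, file.path(out_dir, "tpm.tsv"))
    list(per_sample_sum = as.list(colSums(tpm)))
  })

  run_stage("junctions",
            !is.null(config$junctions) && !is.null(env$reads), function() {
    jc <- config$junctions
    ra <- env$repeats[env$repeats$name == jc$region_a]
    rb <- env$repeats[env$repeats$name == jc$region_b]
    if (length(ra) == 0L || length(rb) == 0L)
      stop("junction regions '", jc$region_a, "'/'", jc$region_b,
           "' not found among repeat features")
    res <- find_junction_reads(env$reads, ra, rb,
                               total_mapped = jc$total_mapped)
    thr <- if (is.null(jc$threshold)) 1L else jc$threshold
    res <- classify_ltr_activity(res, threshold = thr)
    write.table(res, file.path(out_dir, "junctions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    s <- attr(res, "summary")
    list(n_samples = nrow(res), n_active = s$n_active,
         mean_cpm = s$mean_cpm)
  })

  run_stage("decomposition", !is.null(config$decomposition$samples),
            function() {
    dc <- config$decomposition
    samples <- read_sample_table(dc$samples)
    eps <- if (is.null(dc$epsilon)) 0.01 else dc$epsilon
    fit <- fit_contribution_model(
      samples, scale_outcome = isTRUE(dc$scale_outcome))
    contrib <- contribution_log_ratio(fit, samples, epsilon = eps)
    write.table(contrib, file.path(out_dir, "contributions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(unclass(fit), file.path(out_dir, "fit.json"),
                         auto_unbox = TRUE, digits = NA)
    out <- list(fit = unclass(fit))
    if ("group" %in% names(samples)) {
      gs <- summarize_contributions(contrib)
      write.table(gs, file.path(out_dir, "contribution_groups.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out$group_means <- setNames(as.list(gs$mean), gs$group)
    }
    out$spearman_long_gene <- group_compare(
      samples$tpm_long, y = samples$tpm_gene, test = "spearman")$estimate
    out$spearman_short_gene <- group_compare(
      samples$tpm_short, y = samples$tpm_gene, test = "spearman")$estimate
    out
  })

  run_stage("methylation", !is.null(config$methylation$bedmethyl),
            function() {
    mc <- config$methylation
    calls <- read_bedmethyl(mc$bedmethyl)
    if (!is.null(mc$chrom))
      calls <- calls[calls$chrom == mc$chrom, , drop = FALSE]
    args <- list(calls = calls, region = c(mc$start, mc$end))
    for (p in c("min_cov", "site_threshold", "region_threshold"))
      if (!is.null(mc[[p]])) args[[p]] <- mc[[p]]
    s <- do.call(summarize_region_methylation, args)
    jsonlite::write_json(unclass(s),
                         file.path(out_dir, "methylation.json"),
                         auto_unbox = TRUE, digits = NA)
    unclass(s)
  })

  run_stage("consensus", !is.null(config$consensus$msa), function() {
    cc <- config$consensus
    msa <- read_msa(cc$msa)
    if (!is.null(cc$min_ref_length)) {
      refs <- msa[setdiff(names(msa), cc$query_id)]
      kept <- filter_references_by_length(refs, cc$min_ref_length)
      msa <- c(kept[names(kept)], msa[cc$query_id])
    }
    freq <- if (is.null(cc$min_consensus_freq)) 0.8
            else cc$min_consensus_freq
    diffs <- consensus_divergence(msa, cc$query_id,
                                  min_consensus_freq = freq)
    write.table(diffs, file.path(out_dir, "consensus_diffs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_calls = nrow(diffs),
         calls = if (nrow(diffs)) paste0(diffs$consensus_base, ">",
                                         diffs$query_base, "@",
                                         diffs$column) else character())
  })

  run_stage("single_cell", !is.null(config$single_cell$cells),
            function() {
    sc <- config$single_cell
    cells <- read_cell_table(sc$cells)
    type_col <- if (is.null(sc$type_col)) "cell_type" else sc$type_col
    feats <- if (!is.null(sc$features)) sc$features else sc$feature
    out <- list()
    comp_all <- list(); frac_all <- list()
    for (f in feats) {
      comp <- composition_of_expressing_cells(cells, f,
                                              type_col = type_col)
      comp$feature <- f
      comp_all[[f]] <- comp
      mc <- if (is.null(sc$min_cells_per_type)) 600L
            else sc$min_cells_per_type
      fr <- fraction_expressing_by_celltype(cells, f,
                                            min_cells_per_type = mc,
                                            type_col = type_col)
      fr$feature <- f
      frac_all[[f]] <- fr
    }
    write.table(do.call(rbind, comp_all),
                file.path(out_dir, "sc_composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(do.call(rbind, frac_all),
                file.path(out_dir, "sc_fraction_expressing.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out$n_cells <- nrow(cells)
    out$features <- as.list(feats)
    if (!is.null(sc$type_set)) {
      pp <- patient_expressing_type_percentage(cells, sc$type_set,
                                               type_col = type_col)
      write.table(pp$per_patient,
                  file.path(out_dir, "sc_patient_percentage.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      out$patient_comparison <- if (!is.null(pp$comparison))
        unclass(pp$comparison) else NULL
    }
    out
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  .write_report_md(report, file.path(out_dir, "report.md"))
  invisible(report)
}

.write_report_md <- function(report, path) {
  ln <- c(paste0("# erviso run report (v", report$version, ")"), "")
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    ln <- c(ln, paste0("## ", nm, ": ", st$status))
    flat <- st[setdiff(names(st), "status")]
    for (k in names(flat)) {
      v <- flat[[k]]
      if (is.list(v))
        v <- paste(names(v), vapply(v, function(x)
          paste(format(unlist(x), digits = 6), collapse = " "), ""),
          sep = "=", collapse = ", ")
      ln <- c(ln, paste0("- ", k, ": ",
                         paste(format(v, digits = 6), collapse = ", ")))
    }
    ln <- c(ln, "")
  }
  writeLines(ln, path)
  invisible(path)
}
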