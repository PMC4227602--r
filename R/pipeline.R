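#' Pipeline parameter set
#'
#' Collects every tunable threshold of the workflow with its default:
#' promoter window 1000 bp, screen/association alpha 0.05 (strict),
#' one-sided tests toward case enrichment, homopolymer run 5, constraint
#' (GERP) threshold 2, reference-panel size 372 diploids, solid-spine D'
#' threshold 1. Round-trips losslessly through YAML.
#'
#' @param promoter_window,alpha,alternative,min_run,gerp_threshold,
#'   panel_size,dprime_threshold,em_tol,em_max_iter,seed Parameters; see
#'   the stage functions for their meaning.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(promoter_window = 1000, alpha = 0.05,
                            alternative = "enrichment", min_run = 5,
                            gerp_threshold = 2, panel_size = 372,
                            dprime_threshold = 1, em_tol = 1e-10,
                            em_max_iter = 1000, seed = 1) {
  structure(list(
    promoter_window = promoter_window, alpha = alpha,
    alternative = alternative, min_run = min_run,
    gerp_threshold = gerp_threshold, panel_size = panel_size,
    dprime_threshold = dprime_threshold, em_tol = em_tol,
    em_max_iter = em_max_iter, seed = seed
  ), class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file.
#' @return For the reader, a `pipeline_config`; for the writer, `path`
#'   invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the candidate-gene workflow end to end
#'
#' Orchestrates the stages in order — annotate, screen, associate, burden,
#' LD — on whatever inputs are supplied, skipping stages whose inputs are
#' absent. When `out_dir` is given, each stage's table is written as a
#' single-header TSV along with a run log recording package version,
#' parameters and seed, and a YAML summary; re-running with the same inputs
#' and config reproduces the reports byte for byte.
#'
#' @param variants Tibble with `id`, `chrom`, `pos`, `ref`, `alt` and, for
#'   the screen stage, `cohort_alt`, `cohort_total`.
#' @param models Transcript models for annotation (optional).
#' @param target_interval Target intron interval (optional).
#' @param cds_sequences Named list of CDS sequences for coding consequences.
#' @param panel Reference-panel counts for [run_screen()] (optional).
#' @param tracks Optional list with `encode`, `conserved`, `repeats`
#'   interval tibbles.
#' @param flanks Optional named reference flanks for the poly-base rule.
#' @param counts Per-variant genotype counts (`id`, `stratum`, `hom_alt`,
#'   `het`, `hom_ref`) for the association stage (optional).
#' @param genotypes Per-sample genotypes (`sample_id`, `id`, `dosage`, plus
#'   `gene` for burden) (optional).
#' @param phenotypes Tibble `sample_id`, `stratum` for the burden stage.
#' @param marker_order Marker ids in map order; supplying it switches the
#'   LD stage on.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#'
#' @return List of stage results: `annotations`, `screen`, `association`,
#'   `burden`, `ld`, `blocks`, `qc`, plus `config`.
#' @export
run_pipeline <- function(variants, models = NULL, target_interval = NULL,
                         cds_sequences = NULL, panel = NULL, tracks = NULL,
                         flanks = NULL, counts = NULL, genotypes = NULL,
                         phenotypes = NULL, marker_order = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  res <- list(config = config)

  res$qc <- stage("qc", qc_summary(variants, genotypes))

  if (!is.null(models) || !is.null(target_interval)) {
    res$annotations <- stage("annotate", classify_variants(
      variants, models, target_interval,
      promoter_window = config$promoter_window,
      cds_sequences = cds_sequences))
  }
  if (!is.null(panel)) {
    res$screen <- stage("screen", run_screen(
      variants, panel, repeats = tracks$repeats, flanks = flanks,
      panel_size = config$panel_size, alpha = config$alpha,
      min_run = config$min_run, alternative = config$alternative))
  }
  if (!is.null(counts)) {
    res$association <- stage("assoc",
                             associate(counts,
                                       alternative = config$alternative))
  }
  if (!is.null(genotypes) && !is.null(phenotypes) &&
      "gene" %in% names(genotypes)) {
    res$burden <- stage("burden", burden_test(genotypes, phenotypes))
  }
  if (!is.null(genotypes) && !is.null(marker_order) &&
      length(marker_order) >= 2) {
    res$ld <- stage("ld", ld_pairwise(genotypes, marker_order,
                                      tol = config$em_tol,
                                      max_iter = config$em_max_iter))
    res$blocks <- stage("ld", solid_spine_blocks(
      dprime_matrix(res$ld, marker_order),
      threshold = config$dprime_threshold))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$annotations)) {
      write_annotations(res$annotations, file.path(out_dir, "annotations.tsv"))
    }
    for (nm in c("screen", "association", "burden", "ld", "blocks", "qc")) {
      if (!is.null(res[[nm]])) {
        write_report_tsv(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
      }
    }
    writeLines(c(
      paste0("rarescreen ", as.character(utils::packageVersion("rarescreen"))),
      paste0("stages: ", paste(setdiff(names(res), "config"),
                               collapse = ", ")),
      paste0(names(unclass(config)), " = ",
             vapply(unclass(config), format, character(1)))
    ), file.path(out_dir, "run_log.txt"))
    yaml::write_yaml(
      list(parameters = unclass(config),
           stages = setdiff(names(res), "config"),
           n_variants = nrow(variants)),
      file.path(out_dir, "summary.yaml"))
  }
  res
}
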