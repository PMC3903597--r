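# End-to-end orchestration: simulate (or load) -> discover -> nest ->
# date -> classify -> indel -> express -> report, driven by one config.

#' Run the full analysis pipeline
#'
#' Stages run in order on either a simulated genome (when
#' \code{config$simulate} is given) or user-supplied input files; each
#' stage writes its outputs under \code{config$out_dir} so stages can be
#' re-examined independently, and a JSON manifest records the config and
#' completion state. Reruns with the same config and seed are bit-identical
#' for every deterministic stage.
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   \code{seed}, \code{out_dir}, and either \code{simulate} (a list of
#'   [sim_config()] arguments) or paths \code{genome}, \code{proteins},
#'   \code{te_annotations} and optionally \code{ests}; optional
#'   \code{thresholds} overriding \code{min_score}, \code{min_identity}.
#' @return invisibly, a list with all stage outputs.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "simulate", "genome", "proteins",
             "te_annotations", "ests", "thresholds")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(config$out_dir)) stop("config needs out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds %||% list()
  min_score <- th$min_score %||% 80
  min_identity <- th$min_identity %||% 0.75
  manifest <- list(config = config, stages = list())
  out <- list()
  fail <- function(stage, err) {
    manifest$stages[[stage]] <<- list(status = "failed", error = conditionMessage(err))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, null = "null")
    stop("stage ", stage, " failed: ", conditionMessage(err))
  }

  # -- inputs -----------------------------------------------------------
  tryCatch({
    if (!is.null(config$simulate)) {
      cfg <- do.call(sim_config, c(config$simulate,
                                   list(seed = config$seed %||% 1L)))
      sim <- simulate_genome(cfg)
      genome <- sim$genome
      proteins <- c(ref_transposase = sim$ref$protein)
      annotations <- sim$annotations
      out$sim <- sim
      out$ref <- sim$ref
      write_fasta(genome, file.path(config$out_dir, "genome.fa"))
      write_te_annotations(annotations, file.path(config$out_dir, "te_annotations.tsv"))
    } else {
      genome <- parse_fasta(config$genome)
      proteins <- parse_protein_fasta(config$proteins)
      annotations <- parse_te_annotations(config$te_annotations)
      out$ref <- NULL
    }
    manifest$stages$inputs <- list(status = "ok")
  }, error = function(e) fail("inputs", e))

  # -- discovery --------------------------------------------------------
  tryCatch({
    hits <- translated_homology_scan(genome, proteins, min_score = min_score)
    calls <- call_candidate_elements(genome, hits, min_identity = min_identity)
    out$hits <- hits
    out$calls <- calls
    write_gff3(elements_to_gff(calls), file.path(config$out_dir, "calls.gff3"))
    manifest$stages$discovery <- list(status = "ok", n_calls = nrow(calls))
  }, error = function(e) fail("discovery", e))

  # -- nesting + stripping ---------------------------------------------
  tryCatch({
    ins_list <- list()
    stripped <- character()
    for (i in seq_len(nrow(out$calls))) {
      el <- out$calls[i, ]
      ins <- detect_nested_insertions(el, annotations)
      ins_list[[el$id]] <- ins
      eseq <- substr(genome[[el$seq_id]], el$start, el$end)
      stripped[el$id] <- strip_nested(eseq, merge_insertion_intervals(ins))$seq
    }
    out$insertions <- ins_list
    out$stripped <- stripped
    out$nested_summary <- nested_summary(ins_list)
    manifest$stages$nesting <- list(status = "ok")
  }, error = function(e) fail("nesting", e))

  # -- classification ---------------------------------------------------
  tryCatch({
    if (!is.null(out$ref)) {
      anns <- lapply(out$stripped, annotate_transposase, ref = out$ref,
                     min_score = min_score)
      labels <- vapply(anns, function(a) classify_groups(a)$non_redundant, "")
      out$annotations <- anns
      out$group_labels <- labels
      out$group_counts <- group_table(labels)
      manifest$stages$classification <- list(status = "ok")
    } else {
      manifest$stages$classification <- list(status = "skipped",
                                             reason = "no annotated reference transposase")
    }
  }, error = function(e) fail("classification", e))

  # -- size profile -----------------------------------------------------
  tryCatch({
    out$size_profile <- size_profile(nchar(out$stripped))
    manifest$stages$size_profile <- list(status = "ok")
  }, error = function(e) fail("size_profile", e))

  # -- expression -------------------------------------------------------
  if (!is.null(config$ests)) {
    tryCatch({
      ests <- parse_fasta(config$ests)
      out$expression <- match_expression(out$stripped, ests)
      manifest$stages$expression <- list(status = "ok")
    }, error = function(e) fail("expression", e))
  } else {
    manifest$stages$expression <- list(status = "skipped", reason = "no EST file")
  }

  # -- reports ----------------------------------------------------------
  tryCatch({
    build_reports(list(size_profile = out$size_profile,
                       nested_summary = out$nested_summary,
                       group_counts_nonredundant = out$group_counts),
                  file.path(config$out_dir, "reports"))
    manifest$stages$reports <- list(status = "ok")
  }, error = function(e) fail("reports", e))

  manifest$seed <- config$seed %||% 1L
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", force = TRUE)
  invisible(out)
}
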