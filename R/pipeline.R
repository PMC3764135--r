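#' Learn a regulatory PDAG from a perturbation-matrix file
#'
#' The full learning pipeline: read the matrix, derive per-mutant target
#' lists, build (or load) the template, run the TABU structure search,
#' convert the learned DAG to a PDAG using the template's one-way pairs as
#' background orientations, and write the edge list. A resolved-config dump
#' (every parameter, including defaults and the seed) is written next to
#' the output so any run is reproducible from its artifacts alone.
#'
#' @param input path to the perturbation-matrix TSV.
#' @param out path for the PDAG edge-list TSV.
#' @param template \code{"auto"} (build from target lists), \code{"none"}
#'   (fully permissive), or a path to a template TSV.
#' @param config a \code{\link{search_config}}.
#' @param config_out path for the resolved-config dump (default
#'   \code{paste0(out, ".config")}).
#' @param verbose log each search move to stderr.
#' @return the collapsed \code{"dm_pdag"}, invisibly.
#' @export
run_learn <- function(input, out, template = "auto",
                      config = search_config(),
                      config_out = paste0(out, ".config"),
                      verbose = FALSE) {
  m <- read_perturbation_matrix(input)
  targets <- extract_target_lists(m)
  tmpl <- switch(template,
                 auto = build_template(targets),
                 none = permissive_template(colnames(m)),
                 read_template(template))
  if (!setequal(rownames(tmpl), colnames(m)))
    stop("template nodes do not match the matrix mutants")
  net <- tabu_search(m, tmpl, config, verbose = verbose)
  pdag <- to_pdag(net, asymmetric_constraints(tmpl))
  write_pdag(pdag, out)
  dump_config(c(list(subcommand = "learn", input = input, out = out,
                     template = template,
                     score = attr(net, "score"),
                     iterations = attr(net, "iterations")),
                unclass(config)), config_out)
  message(sprintf("learn: %d nodes, %d compelled + %d non-compelled edges (score %.4f)",
                  length(pdag$nodes), nrow(pdag$directed),
                  nrow(pdag$undirected), attr(net, "score")))
  invisible(pdag)
}

#' Evaluate a predicted network against reference interactions
#'
#' Collapses dataset-duplicated regulators, computes precision/recall
#' against the reference interaction file, optionally computes orientation
#' precision against a directed reference-pairs file, and writes a two
#' column (field, value) report TSV.
#'
#' @param net path to a PDAG edge-list TSV (output of
#'   \code{\link{run_learn}}).
#' @param truth path to a reference interaction TSV.
#' @param report output path for the report TSV.
#' @param ref_pairs optional path to a two-column directed reference-pairs
#'   TSV for orientation scoring.
#' @return a list with elements \code{pr} and (optionally)
#'   \code{orientation}, invisibly.
#' @export
run_evaluate <- function(net, truth, report, ref_pairs = NULL) {
  if (!file.exists(truth)) stop(sprintf("truth file not found: %s", truth))
  pdag <- collapse_duplicates(read_pdag(net))
  ref <- read_interaction_set(truth)
  if (!any(c(ref$node_a, ref$node_b) %in% pdag$nodes))
    warning("no reference node appears in the network; zero known pairs")
  pr <- precision_recall(pdag, ref)
  fields <- data.frame(
    field = c("n_pred", "n_known", "n_tp", "precision", "recall"),
    value = c(pr$n_pred, pr$n_known, pr$n_tp, pr$precision, pr$recall),
    stringsAsFactors = FALSE)
  out <- list(pr = pr)
  if (!is.null(ref_pairs)) {
    rp <- as.matrix(utils::read.table(ref_pairs, header = FALSE, sep = "\t",
                                      colClasses = "character"))[, 1:2, drop = FALSE]
    rp[] <- strip_dataset_tag(rp)
    ori <- orientation_precision(pdag, rp)
    out$orientation <- ori
    fields <- rbind(fields, data.frame(
      field = c("orientation_total", "orientation_correct",
                "orientation_precision", "orientation_binom_p"),
      value = c(ori$n_total, ori$n_correct, ori$precision, ori$binom_p)))
  }
  utils::write.table(fields, report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Simulate a planted-model fixture to files
#'
#' Writes the perturbation matrix, the planted truth edge list and the
#' regulator-DEG reference pairs, plus a resolved-config dump.
#'
#' @param out_prefix path prefix; files get suffixes
#'   \code{.matrix.tsv}, \code{.truth.tsv}, \code{.refpairs.tsv},
#'   \code{.config}.
#' @param config a \code{\link{simulation_config}}.
#' @return the simulation list, invisibly.
#' @export
run_simulate <- function(out_prefix, config = simulation_config()) {
  sim <- simulate_planted_model(config)
  write_perturbation_matrix(sim$matrix, paste0(out_prefix, ".matrix.tsv"))
  write_network(sim$truth, paste0(out_prefix, ".truth.tsv"))
  utils::write.table(reference_orientation_pairs(sim$matrix),
                     paste0(out_prefix, ".refpairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  dump_config(c(list(subcommand = "simulate", out_prefix = out_prefix),
                unclass(config)), paste0(out_prefix, ".config"))
  message(sprintf("simulate: %d regulators, %d genes, %d planted edges",
                  config$n_regulators, config$n_genes, nrow(sim$truth$edges)))
  invisible(sim)
}

#' Enrichment of one mutant's targets against a GMT collection
#'
#' @param input path to the perturbation-matrix TSV.
#' @param gmt path to a GMT gene-set file.
#' @param mutant mutant label whose target list is the query.
#' @param report output path for the results TSV.
#' @return the enrichment data.frame, invisibly.
#' @export
run_enrich <- function(input, gmt, mutant, report) {
  m <- read_perturbation_matrix(input)
  if (!mutant %in% colnames(m))
    stop(sprintf("mutant '%s' not found in the matrix", mutant))
  universe <- expression_universe(m)
  sets <- read_gmt(gmt)
  sets <- lapply(sets, intersect, universe)
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) stop("no GMT set overlaps the expression universe")
  res <- enrich_targets(extract_target_lists(m)[[mutant]],
                        gene_set_collection(sets, universe))
  utils::write.table(res, report, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(res)
}

# Resolved-config dump: plain "key: value" lines (YAML-compatible subset).
dump_config <- function(values, path) {
  lines <- vapply(names(values), function(k) {
    v <- values[[k]]
    sprintf("%s: %s", k, paste(format(v, digits = 15), collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
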