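#' Summarize cohort EMR usage
#'
#' Total and median usage-window duration (patient-years) and the
#' distribution of per-bin informative counts.
#'
#' @param windows data.frame from [usage_windows()].
#' @param tensor A \code{presence_tensor} built on those windows.
#' @return List: n_individuals, total_patient_years, median_usage_years,
#'   informative_per_bin (min/median/max).
#' @export
summarize_cohort <- function(windows, tensor) {
  stopifnot(nrow(windows) >= 1, inherits(tensor, "presence_tensor"))
  dur <- windows$max_age - windows$min_age
  per_bin <- colSums(tensor$informative)
  list(
    n_individuals = nrow(windows),
    total_patient_years = sum(dur),
    median_usage_years = stats::median(dur),
    informative_per_bin = c(min = min(per_bin),
                            median = stats::median(per_bin),
                            max = max(per_bin))
  )
}

read_tsv_chr <- function(path, numeric_cols = character()) {
  d <- utils::read.delim(path, colClasses = "character", fill = TRUE,
                         na.strings = character())
  for (cc in intersect(numeric_cols, names(d))) d[[cc]] <- as.numeric(d[[cc]])
  d
}

#' Run the end-to-end association pipeline
#'
#' Executes map -> propagate -> bin -> usage -> associate -> FDR on files
#' in the formats the package reads, and writes the cohort summary, the
#' per-bin term-count matrix, the ranked association table, p-value
#' trajectories of BH-significant pairs, and a machine-readable run
#' manifest recording the configuration, input checksums and every
#' drop/filter count. Rerunning with identical inputs and configuration
#' reproduces the outputs byte for byte.
#'
#' @param ontology Path to an OBO file.
#' @param dictionary Path to the dictionary TSV (source_code, icd_code,
#'   hpo_id).
#' @param encounters Path to the encounter TSV (individual_id, age_years,
#'   source_code, icd_code, ...).
#' @param genotypes Path to the genotype TSV (individual_id, gene).
#' @param out_dir Output directory, created if needed.
#' @param bin_width,max_age Grid parameters, see [bin_grid()].
#' @param min_carriers,fdr_q,modifier_roots Analysis parameters, see
#'   [gxp_scan()].
#' @param extra_codes Additional ICD codes accepted by the neurology
#'   filter (e.g. ICD-9).
#' @param seed Recorded in the manifest for any resampling diagnostics;
#'   the pipeline itself is deterministic.
#' @return Invisibly, a list: \code{summary} (cohort summary),
#'   \code{scan} (the \code{gxp_scan} object), \code{tensor},
#'   \code{drops}, and \code{paths} of the written files. Any stage
#'   failure aborts with the stage name and cause.
#' @export
run_pipeline <- function(ontology, dictionary, encounters, genotypes,
                         out_dir, bin_width = 0.25, max_age = 25,
                         min_carriers = 2, fdr_q = 0.05,
                         modifier_roots = default_modifier_roots(),
                         extra_codes = character(), seed = 1L) {
  for (p in c(ontology, dictionary, encounters, genotypes))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  stopifnot(min_carriers >= 1, fdr_q > 0, fdr_q < 1)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  graph <- stage("ontology", load_ontology(ontology))
  dict <- stage("dictionary", load_dictionary(dictionary, graph))
  raw <- stage("encounters", read_tsv_chr(encounters, "age_years"))
  geno <- stage("genotypes", read_tsv_chr(genotypes))
  grid <- stage("grid", bin_grid(bin_width, max_age))

  mapped <- stage("map", map_encounters(raw, dict, extra_codes))
  windows <- stage("usage", usage_windows(raw))
  tensor <- stage("bin", build_presence(mapped, graph, grid, windows))
  summ <- stage("summary", summarize_cohort(windows, tensor))
  scan <- stage("associate", gxp_scan(tensor, geno, graph,
                                      min_carriers = min_carriers,
                                      fdr_q = fdr_q,
                                      modifier_roots = modifier_roots))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(summary = file.path(out_dir, "cohort_summary.json"),
             counts = file.path(out_dir, "term_counts.tsv"),
             assoc = file.path(out_dir, "associations.tsv"),
             traj = file.path(out_dir, "significant_trajectories.tsv"),
             manifest = file.path(out_dir, "run_manifest.json"))

  drops <- attr(mapped, "drops")
  summ_out <- c(summ,
                list(n_encounter_rows = nrow(raw),
                     n_mapped_term_instances = nrow(mapped),
                     n_bins = grid$n_bins))
  jsonlite::write_json(summ_out, paths["summary"], auto_unbox = TRUE,
                       digits = NA)

  cm <- presence_counts(tensor)
  utils::write.table(data.frame(term = rownames(cm), cm, check.names = FALSE),
                     paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(scan$results, paths["assoc"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sig_keys <- with(scan$results,
                   paste(gene[bh_significant], term[bh_significant], sep = "|"))
  traj <- scan$p_trajectories[sig_keys]
  traj_df <- data.frame(pair = rep(sig_keys, each = grid$n_bins),
                        bin = rep(seq_len(grid$n_bins) - 1L, length(sig_keys)),
                        age_start = rep((seq_len(grid$n_bins) - 1L) * bin_width,
                                        length(sig_keys)),
                        p = unlist(traj, use.names = FALSE))
  utils::write.table(traj_df, paths["traj"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    config = list(bin_width = bin_width, max_age = max_age,
                  min_carriers = min_carriers, fdr_q = fdr_q,
                  modifier_roots = modifier_roots,
                  extra_codes = extra_codes, seed = seed),
    inputs = as.list(tools::md5sum(c(ontology = ontology,
                                     dictionary = dictionary,
                                     encounters = encounters,
                                     genotypes = genotypes))),
    drops = as.list(drops),
    n_pairs_tested = nrow(scan$results),
    n_bh_significant = sum(scan$results$bh_significant)
  )
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)

  invisible(list(summary = summ_out, scan = scan, tensor = tensor,
                 drops = drops, paths = paths))
}
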