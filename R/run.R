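# Orchestration: validated run configuration and one entry point per
# pipeline stage, each writing artifacts plus a machine-readable manifest.

config_schema <- list(
  design = c("positions", "window", "global_exclusions", "overrides",
             "stability", "ddg_threshold", "out_dir"),
  oligos = c("design", "reference", "min_arm_tm", "min_arm_len",
             "max_arm_len", "max_oligo_len", "out_dir"),
  simulate = c("n_codons", "n_positions", "coverage", "error_rate",
               "withheld_fraction", "seed", "out_dir"),
  qc = c("reads", "reference", "min_reads", "out_dir"),
  fit = c("input", "sheet", "out_dir"),
  lod = c("input", "blanks", "range", "out_dir"),
  selectivity = c("input", "on_target", "fold_threshold", "out_dir"),
  panel = c("smiles", "scheme", "linkage", "out_dir"),
  contacts = c("structure", "ligand", "cutoff", "chain", "offset",
               "out_dir")
)

config_defaults <- list(
  design = list(window = 8, global_exclusions = c("C", "P")),
  oligos = list(min_arm_tm = 60, min_arm_len = 15, max_arm_len = 40,
                max_oligo_len = 90),
  simulate = list(n_codons = 100, n_positions = 5, coverage = 30,
                  error_rate = 0, withheld_fraction = 0, seed = 1),
  qc = list(min_reads = 1),
  fit = list(),
  lod = list(),
  selectivity = list(fold_threshold = 10),
  panel = list(scheme = "atompair", linkage = "average"),
  contacts = list(cutoff = 4.5, offset = 0)
)

#' Load and validate a run configuration
#'
#' YAML with a `subcommand` key plus that subcommand's parameters. Unknown
#' keys are a hard error (no silent typos); defaults are resolved into the
#' returned object so the manifest records every effective value.
#'
#' @param path YAML path, or a list already in memory.
#' @return List of class `run_config` with `subcommand` and resolved
#'   parameters.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  sub <- cfg$subcommand
  if (is.null(sub) || !sub %in% names(config_schema)) {
    stop("config needs a `subcommand` among: ",
         paste(names(config_schema), collapse = ", "), call. = FALSE)
  }
  params <- cfg[setdiff(names(cfg), "subcommand")]
  unknown <- setdiff(names(params), config_schema[[sub]])
  if (length(unknown) > 0) {
    stop("unknown config key(s) for `", sub, "`: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  resolved <- utils::modifyList(config_defaults[[sub]], params)
  validate_config_values(sub, resolved)
  structure(c(list(subcommand = sub), resolved), class = "run_config")
}

validate_config_values <- function(sub, p) {
  bad <- function(field, why) {
    stop(sprintf("config field `%s`: %s", field, why), call. = FALSE)
  }
  if (!is.null(p$window) && (!is.numeric(p$window) || p$window < 0)) {
    bad("window", "must be a non-negative number")
  }
  if (!is.null(p$coverage) && p$coverage < 1) bad("coverage", "must be >= 1")
  if (!is.null(p$error_rate) &&
      (p$error_rate < 0 || p$error_rate > 1)) {
    bad("error_rate", "must be in [0, 1]")
  }
  if (!is.null(p$withheld_fraction) &&
      (p$withheld_fraction < 0 || p$withheld_fraction >= 1)) {
    bad("withheld_fraction", "must be in [0, 1)")
  }
  if (!is.null(p$cutoff) && p$cutoff <= 0) bad("cutoff", "must be > 0")
  invisible(TRUE)
}

#' Serialize a run config back to a plain list
#'
#' `load_config(dump_config(x))` is semantically the identity.
#'
#' @param config A `run_config`.
#' @return A plain named list (YAML-ready).
#' @export
dump_config <- function(config) {
  out <- unclass(config)
  out[!vapply(out, is.null, logical(1))]
}

write_manifest <- function(config, out_dir, artifacts, seed = NULL) {
  manifest <- list(
    subcommand = config$subcommand,
    parameters = dump_config(config),
    artifacts = artifacts,
    seed = seed,
    package_version = as.character(utils::packageVersion("dsmkit")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

#' Run one pipeline stage from a configuration
#'
#' Dispatches on `config$subcommand` (`design`, `oligos`, `simulate`, `qc`,
#' `fit`, `lod`, `selectivity`, `panel`, `contacts`), writes the stage's
#' artifacts into `out_dir` together with a JSON manifest recording all
#' resolved parameters, and returns the primary result invisibly.
#'
#' @param config A `run_config`, a YAML path, or a plain list (validated
#'   via [load_config()]).
#' @return The stage's primary result object, invisibly; artifact paths in
#'   attribute `artifacts`.
#' @export
dsm_run <- function(config) {
  if (!inherits(config, "run_config")) config <- load_config(config)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(config$subcommand,
    design = run_design(config, out_dir),
    oligos = run_oligos(config, out_dir),
    simulate = run_simulate(config, out_dir),
    qc = run_qc(config, out_dir),
    fit = run_fit(config, out_dir),
    lod = run_lod(config, out_dir),
    selectivity = run_selectivity(config, out_dir),
    panel = run_panel(config, out_dir),
    contacts = run_contacts(config, out_dir)
  )
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

resolve_design <- function(spec) {
  if (is.null(spec) || identical(spec, "pyr1")) return(pyr1_design())
  if (inherits(spec, "dsm_design")) return(spec)
  design_from_allele_table(read_allele_table(spec))
}

resolve_reference <- function(spec) {
  if (is.null(spec) || identical(spec, "pyr1")) return(pyr1_reference_cds())
  if (inherits(spec, "synthetic_reference")) return(spec$cds)
  if (file.exists(spec)) {
    return(as.character(Biostrings::readDNAStringSet(spec))[1])
  }
  spec
}

run_design <- function(config, out_dir) {
  design <- if (is.null(config$positions)) pyr1_design() else {
    pos <- readr::read_tsv(config$positions, show_col_types = FALSE)
    build_allele_sets(pos, global_exclusions = config$global_exclusions,
                      overrides = config$overrides,
                      window = config$window)
  }
  singles <- enumerate_singles(design)
  doubles <- enumerate_doubles(design)
  report <- library_report(design)
  files <- c(singles = file.path(out_dir, "singles.tsv"),
             doubles = file.path(out_dir, "doubles.tsv"),
             report = file.path(out_dir, "report.tsv"))
  write_variants(singles, files["singles"])
  write_variants(doubles, files["doubles"])
  readr::write_tsv(report, files["report"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(report, artifacts = files))
}

run_oligos <- function(config, out_dir) {
  design <- resolve_design(config$design)
  reference <- resolve_reference(config$reference)
  params <- oligo_params(min_arm_tm = config$min_arm_tm,
                         min_arm_len = config$min_arm_len,
                         max_arm_len = config$max_arm_len,
                         max_oligo_len = config$max_oligo_len)
  oligos <- design_oligos(design, reference, params)
  files <- export_pools(oligos, out_dir)
  write_manifest(config, out_dir, as.list(files$fasta))
  invisible(structure(oligos, artifacts = files))
}

run_simulate <- function(config, out_dir) {
  ref <- make_reference(config$n_codons, seed = config$seed)
  design <- toy_design(ref, n_positions = config$n_positions)
  sim <- simulate_reads(design, ref, coverage = config$coverage,
                        error_rate = config$error_rate,
                        withheld_fraction = config$withheld_fraction,
                        seed = config$seed + 1)
  files <- c(reference = file.path(out_dir, "reference.fasta"),
             reads = file.path(out_dir, "reads.fastq"),
             truth = file.path(out_dir, "truth.tsv"),
             design = file.path(out_dir, "design_singles.tsv"))
  write_reference_fasta(ref, files["reference"])
  write_fastq(sim, files["reads"])
  readr::write_tsv(sim$truth, files["truth"])
  write_variants(enumerate_singles(design), files["design"])
  write_manifest(config, out_dir, as.list(files), seed = config$seed)
  invisible(structure(sim, artifacts = files, design = design,
                      reference = ref))
}

run_qc <- function(config, out_dir) {
  sim <- config$reads
  if (is.character(sim)) sim <- read_fastq(sim)
  if (inherits(sim, "read_simulation")) sim <- sim$reads
  reference <- resolve_reference(config$reference)
  design <- if (inherits(config$design, "dsm_design")) config$design else
    resolve_design(config$design)
  calls <- call_variants(sim, reference, design)
  report <- completeness_report(calls, design,
                                min_reads = config$min_reads)
  files <- c(calls = file.path(out_dir, "calls.tsv"),
             per_variant = file.path(out_dir, "per_variant.tsv"),
             summary = file.path(out_dir, "summary.json"))
  readr::write_tsv(calls, files["calls"])
  write_completeness(report, files["per_variant"], files["summary"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(report, artifacts = files))
}

run_fit <- function(config, out_dir) {
  tab <- read_dose_response(config$input, sheet = config$sheet)
  fit <- fit_4pl(tab)
  files <- c(fit = file.path(out_dir, "fit.tsv"))
  readr::write_tsv(glance.dr_fit(fit), files["fit"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(fit, artifacts = files))
}

run_lod <- function(config, out_dir) {
  tab <- read_dose_response(config$input)
  blanks <- as.numeric(config$blanks)
  res <- estimate_lod(tab, blanks, range = config$range)
  files <- c(lod = file.path(out_dir, "lod.tsv"))
  readr::write_tsv(glance.lod_result(res), files["lod"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(res, artifacts = files))
}

run_selectivity <- function(config, out_dir) {
  tab <- readr::read_csv(config$input, show_col_types = FALSE)
  on_target <- unlist(config$on_target)
  sel <- selectivity_matrix(tab, on_target,
                            fold_threshold = config$fold_threshold)
  files <- c(folds = file.path(out_dir, "selectivity.tsv"))
  write_selectivity(sel, files["folds"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(sel, artifacts = files))
}

run_panel <- function(config, out_dir) {
  panel <- read_smiles(config$smiles)
  sim <- similarity_matrix(panel, scheme = config$scheme)
  cl <- cluster_panel(sim, method = config$linkage)
  files <- c(matrix = file.path(out_dir, "similarity.tsv"),
             tree = file.path(out_dir, "panel.nwk"))
  readr::write_tsv(tidy.similarity_matrix(sim), files["matrix"])
  write_newick(cl, files["tree"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(cl, artifacts = files, similarity = sim))
}

run_contacts <- function(config, out_dir) {
  pos <- contact_positions(config$structure, config$ligand,
                           cutoff = config$cutoff, chain = config$chain,
                           offset = config$offset)
  files <- c(contacts = file.path(out_dir, "contacts.tsv"))
  readr::write_tsv(tibble::tibble(position = pos), files["contacts"])
  write_manifest(config, out_dir, as.list(files))
  invisible(structure(pos, artifacts = files))
}
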