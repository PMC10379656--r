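pipeline_defaults <- list(
  qc = list(
    snp_call_rate = 0.95, subject_call_rate = 0.90, maf = 0.05,
    hwe_p = 1e-6, ptau_transform = "log", exclude_subjects = NULL
  ),
  scan = list(p_threshold = "bonferroni", alpha = 0.05, block_size = 256),
  partition = list(top_n = 10),
  map_genes = NULL
)

validate_pipeline_config <- function(config) {
  if (is.null(config$out_dir)) abort("config must set out_dir")
  if (is.null(config$input)) abort("config must have an input section")
  inp <- config$input
  if (!is.null(inp$simulate)) {
    # simulated input: everything generated in-process
  } else {
    for (key in c("bed", "cohort")) {
      if (is.null(inp[[key]])) abort(paste0("input$", key, " is required"))
      if (!file.exists(inp[[key]])) abort(paste0("input file not found: ", inp[[key]]))
    }
  }
  mg <- config$map_genes
  if (!is.null(mg)) {
    for (key in c("genes_bed", "ad_genes")) {
      if (is.null(mg[[key]])) abort(paste0("map_genes$", key, " is required when the stage is enabled"))
      if (!file.exists(mg[[key]])) abort(paste0("map_genes file not found: ", mg[[key]]))
    }
    if (!is.null(mg$ppi_edges) && !file.exists(mg$ppi_edges)) {
      abort(paste0("map_genes file not found: ", mg$ppi_edges))
    }
  }
  invisible(config)
}

merge_defaults <- function(config) {
  for (section in c("qc", "scan", "partition")) {
    merged <- pipeline_defaults[[section]]
    for (key in names(config[[section]])) merged[[key]] <- config[[section]][[key]]
    config[[section]] <- merged
  }
  config
}

#' Run the full analysis pipeline
#'
#' Orchestrates quality control, the pairwise interaction scan, variance
#' partitioning of the top pairs, and (optionally) gene mapping with PPI
#' overlap, from a single YAML configuration. Every stage's outputs are
#' written under `out_dir` and a machine-readable manifest
#' (`manifest.json`) records inputs, parameters, per-stage counts, seed and
#' package version, enough to re-run the analysis identically. The
#' configuration is validated before any computation; if a stage fails the
#' manifest still records the stages that completed.
#'
#' Input genotypes come either from a PLINK bed/bim/fam triple plus a
#' cohort TSV (`input: {bed:, cohort:}`) or from the synthetic generator
#' (`input: {simulate: {...}}` with [sim_config()] fields).
#'
#' @param config Path to a YAML file or an equivalent named list.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  config <- merge_defaults(config)
  validate_pipeline_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L

  manifest <- list(
    package = "epiqt",
    version = as.character(utils::packageVersion("epiqt")),
    seed = seed,
    parameters = config[c("qc", "scan", "partition", "map_genes")],
    stages = list()
  )
  record <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
    write_manifest(manifest, out_dir)
  }
  write_manifest <- function(man, dir) {
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      record(name, status = "failed", error = conditionMessage(e))
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  # --- input ------------------------------------------------------------
  inp <- config$input
  if (!is.null(inp$simulate)) {
    sim_args <- inp$simulate
    sim_args$seed <- sim_args$seed %||% seed
    if (!is.null(sim_args$planted_pairs)) {
      sim_args$planted_pairs <- purrr::map(sim_args$planted_pairs, as.list)
    }
    cfg <- do.call(sim_config, sim_args)
    study <- simulate_study(cfg)
    genotypes <- study$genotypes
    cohort <- study$cohort
    jsonlite::write_json(study$truth, file.path(out_dir, "truth.json"),
      auto_unbox = TRUE, digits = NA
    )
    record("input",
      status = "ok", source = "simulated",
      n_subjects = n_subjects(genotypes), n_snps = n_snps(genotypes)
    )
  } else {
    genotypes <- run_stage("input", function() read_plink(inp$bed))
    cohort <- run_stage("input", function() read_cohort(inp$cohort))
    record("input",
      status = "ok", source = inp$bed,
      n_subjects = n_subjects(genotypes), n_snps = n_snps(genotypes)
    )
  }

  # --- qc ---------------------------------------------------------------
  qc <- config$qc
  qc_out <- run_stage("qc", function() {
    check_baseline_unique(cohort)
    exclude <- if (!is.null(qc$exclude_subjects)) {
      read_gene_list(qc$exclude_subjects) # one id per line
    } else {
      character()
    }
    subj <- apply_subject_qc(genotypes, cohort,
      min_call_rate = qc$subject_call_rate, exclude = exclude
    )
    var <- apply_variant_qc(subj$genotypes,
      min_call_rate = qc$snp_call_rate, min_maf = qc$maf, min_hwe_p = qc$hwe_p
    )
    report <- dplyr::bind_rows(
      dplyr::mutate(subj$report, unit = "subjects"),
      dplyr::mutate(var$report, unit = "snps")
    )
    list(genotypes = var$genotypes, cohort = subj$cohort, report = report)
  })
  write_plink(qc_out$genotypes, file.path(out_dir, "qc_genotypes"))
  write_cohort(qc_out$cohort, file.path(out_dir, "qc_cohort.tsv"))
  readr::write_tsv(qc_out$report, file.path(out_dir, "qc_report.tsv"))
  record("qc",
    status = "ok",
    n_subjects = n_subjects(qc_out$genotypes), n_snps = n_snps(qc_out$genotypes),
    ptau_transform = qc$ptau_transform
  )

  # --- scan -------------------------------------------------------------
  y <- normalize_phenotype(qc_out$cohort$ptau, qc$ptau_transform)
  covariates <- build_design(qc_out$cohort)
  scan_cfg <- config$scan
  pairs <- run_stage("scan", function() {
    scan_all_pairs(qc_out$genotypes, y, covariates,
      p_threshold = scan_cfg$p_threshold, alpha = scan_cfg$alpha,
      block_size = scan_cfg$block_size
    )
  })
  write_pair_results(pairs, file.path(out_dir, "pairs.tsv"))
  record("scan",
    status = "ok", n_tests = attr(pairs, "n_tests"),
    p_threshold = attr(pairs, "p_threshold"),
    n_significant = nrow(pairs)
  )

  # --- partition --------------------------------------------------------
  partition <- run_stage("partition", function() {
    partition_top_pairs(pairs, qc_out$genotypes, y, covariates,
      top_n = config$partition$top_n
    )
  })
  readr::write_tsv(partition, file.path(out_dir, "partition.tsv"))
  record("partition", status = "ok", n_pairs = nrow(partition))

  # --- gene mapping (optional) -----------------------------------------
  if (!is.null(config$map_genes)) {
    mg <- config$map_genes
    gene_pairs <- run_stage("map_genes", function() {
      annotation <- read_gene_bed(mg$genes_bed)
      ad_genes <- read_gene_list(mg$ad_genes)
      gp <- pairs_to_gene_pairs(pairs, qc_out$genotypes$snps, annotation,
        window_bp = mg$window_bp %||% 100000,
        mode = mg$mode %||% "nearest"
      )
      gp <- categorize_pairs(gp, ad_genes)
      if (!is.null(mg$ppi_edges)) {
        gp <- overlap_with_ppi(gp, read_ppi_edges(mg$ppi_edges))
      }
      gp
    })
    flat <- dplyr::mutate(gene_pairs,
      supporting_pairs = purrr::map_chr(.data$supporting_pairs, paste, collapse = ",")
    )
    readr::write_tsv(flat, file.path(out_dir, "gene_pairs.tsv"))
    counts <- attr(gene_pairs, "category_counts")
    summary <- list(
      n_gene_pairs = nrow(gene_pairs),
      category_counts = as.list(setNames(as.integer(counts), names(counts))),
      n_ppi_overlap = attr(gene_pairs, "n_overlap"),
      n_intragenic_snp_pairs = length(attr(gene_pairs, "intragenic")),
      n_unmapped_snp_pairs = length(attr(gene_pairs, "unmapped"))
    )
    jsonlite::write_json(summary, file.path(out_dir, "gene_pairs_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
    record("map_genes",
      status = "ok", n_gene_pairs = nrow(gene_pairs),
      n_ppi_overlap = attr(gene_pairs, "n_overlap") %||% NA
    )
  }

  invisible(manifest)
}
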