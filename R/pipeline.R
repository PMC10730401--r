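# End-to-end orchestration: synthesize (optional) -> enrich -> annotate ->
# derive assays -> report, with a JSON run config, deterministic seeding and
# a run manifest. Outputs are plain-text TSV/CSV/JSON so runs diff cleanly.

#' Read and validate a pipeline run configuration
#'
#' The config is JSON with top-level fields:
#' * `seed` (integer, required) — every stage derives its randomness from it;
#' * `out_dir` (optional; may be overridden at run time);
#' * either `simulate` (configs for [simulate_de_table()] per contrast, plus
#'   optional decoy gene sets) or `de_tables` (named paths) + `gmt` (path);
#' * `enrichment` (optional overrides: `n_perm`, `convention`, `mode`,
#'   `min_size`, `alpha_nominal`, `fdr_cut`, `exhaustive_threshold`);
#' * `annotations` (optional: `table` path, `keywords`, `deg_threshold`,
#'   `deg_contrast`);
#' * `assays` (optional: `ocr_trace`+`ocr_schedule`, `crc_trace`+`crc_pulses`,
#'   `h2o2_trace` paths).
#'
#' @param path Path to a JSON config file.
#' @return The config as a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$seed)) {
    stop("config error: `seed` is required", call. = FALSE)
  }
  stop_unless_scalar_number(cfg$seed, "seed")
  has_sim <- !is.null(cfg$simulate)
  has_input <- !is.null(cfg$de_tables)
  if (!has_sim && !has_input) {
    stop("config error: need either `simulate` or `de_tables`",
         call. = FALSE)
  }
  if (has_input) {
    if (is.null(cfg$gmt)) {
      stop("config error: `gmt` is required with `de_tables`", call. = FALSE)
    }
    paths <- c(unlist(cfg$de_tables), cfg$gmt)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("config error: input path(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  structure(cfg, class = c("run_config", class(cfg)))
}

sim_stage <- function(cfg, out_dir) {
  sim <- cfg$simulate
  if (is.null(sim$contrasts) || length(sim$contrasts) == 0L) {
    stop("simulate stage: `contrasts` must be a non-empty named list",
         call. = FALSE)
  }
  de_tables <- list()
  truth_sets <- list()
  for (k in seq_along(sim$contrasts)) {
    nm <- names(sim$contrasts)[k]
    sc <- sim$contrasts[[k]]
    planted <- lapply(seq_len(NROW(sc$planted_sets)), function(i) {
      ps <- if (is.data.frame(sc$planted_sets)) {
        as.list(sc$planted_sets[i, ])
      } else {
        sc$planted_sets[[i]]
      }
      ps
    })
    dcfg <- de_sim_config(
      n_genes = sc$n_genes,
      null_sd = sc$null_sd %||% 0.5,
      planted_sets = planted,
      se_per_gene = sc$se_per_gene %||% 0.25,
      seed = cfg$seed + 100 * k
    )
    out <- simulate_de_table(dcfg)
    de_tables[[nm]] <- out$table
    for (s in names(out$truth$sets)) {
      truth_sets[[s]] <- out$truth$sets[[s]]$members
    }
    write_de_table(out$table, file.path(out_dir, paste0("de_", nm, ".tsv")))
  }
  # gene sets: planted sets plus seeded random decoys over the last universe
  genes <- de_tables[[length(de_tables)]]$gene
  n_decoys <- sim$n_decoy_sets %||% 10
  decoy_size <- sim$decoy_size %||% 40
  decoys <- with_seed(cfg$seed + 7, {
    stats::setNames(
      lapply(seq_len(n_decoys), function(i) sample(genes, decoy_size)),
      sprintf("decoy_%02d", seq_len(n_decoys)))
  })
  gene_sets <- c(truth_sets, decoys)
  gmt_path <- file.path(out_dir, "gene_sets.gmt")
  write_gmt(gene_sets, gmt_path)
  list(de_tables = de_tables, gene_sets = gene_sets)
}

enrich_stage <- function(cfg, de_tables, gene_sets, out_dir) {
  e <- cfg$enrichment
  results <- enrich_contrasts(
    de_tables, gene_sets,
    seed = cfg$seed + 1000,
    n_perm = e$n_perm %||% 1000,
    convention = e$convention %||% "balanced",
    mode = e$mode %||% "signed_extremum",
    min_size = e$min_size %||% 5,
    alpha_nominal = e$alpha_nominal %||% 0.05,
    fdr_cut = e$fdr_cut %||% 0.1,
    exhaustive_threshold = e$exhaustive_threshold %||% 10000
  )
  utils::write.table(results, file.path(out_dir, "enrichment_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  zm <- z_matrix(results, z_threshold = e$z_threshold %||% 1.96)
  utils::write.table(data.frame(pathway = rownames(zm$z), zm$z,
                                check.names = FALSE),
                     file.path(out_dir, "z_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(pathway = rownames(zm$mask), zm$mask,
                                check.names = FALSE),
                     file.path(out_dir, "z_mask.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(results = results, z = zm)
}

annot_stage <- function(cfg, de_tables, out_dir) {
  a <- cfg$annotations
  ann <- read_annotations(a$table)
  universe <- unique(ann$gene)
  contrast <- a$deg_contrast %||% names(de_tables)[1L]
  de <- de_tables[[contrast]]
  if (is.null(de)) {
    stop("annotations stage: unknown contrast '", contrast, "'",
         call. = FALSE)
  }
  degs <- identify_degs(de, threshold = a$deg_threshold %||% 0.1)
  deg_genes <- intersect(degs$gene[degs$is_deg], universe)
  keywords <- a$keywords %||% c("mitochondri", "inflamm", "autophag")
  kw_sets <- stats::setNames(
    lapply(keywords, function(kw) filter_genes_by_keyword(ann, kw)),
    keywords)
  fisher <- fisher_overrepresentation(deg_genes, kw_sets, universe)
  utils::write.table(fisher, file.path(out_dir, "keyword_enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(degs = degs, fisher = fisher)
}

assay_stage <- function(cfg, out_dir) {
  a <- cfg$assays
  out <- list()
  rows <- list()
  if (!is.null(a$ocr_trace)) {
    trace <- read_trace(a$ocr_trace)
    schedule <- read_schedule(a$ocr_schedule)
    ps <- segment_phases(trace, schedule,
                         discard_first = a$discard_first %||% 1)
    st <- derive_resp_states(ps)
    out$resp_states <- st
    rows <- c(rows, list(data.frame(
      assay = "ocr_coupling",
      quantity = c("state_II", "state_III", "state_IVo", "state_IIIu", "rcr"),
      value = c(st$state_II, st$state_III, st$state_IVo, st$state_IIIu,
                st$rcr))))
  }
  if (!is.null(a$crc_trace)) {
    trace <- read_trace(a$crc_trace)
    crc <- crc_retention(trace, unlist(a$crc_pulses),
                         mode = a$crc_mode %||% "uptake")
    out$crc <- crc
    rows <- c(rows, list(data.frame(assay = "crc", quantity = "retention",
                                    value = crc$retention)))
  }
  if (!is.null(a$h2o2_trace)) {
    trace <- read_trace(a$h2o2_trace)
    sl <- h2o2_slope(trace)
    out$h2o2 <- sl
    rows <- c(rows, list(data.frame(
      assay = "h2o2", quantity = c("slope_per_min", "slope_se"),
      value = c(sl$slope, sl$se))))
  }
  if (length(rows) > 0L) {
    utils::write.table(do.call(rbind, rows),
                       file.path(out_dir, "assay_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Run the full pipeline from a config
#'
#' Executes the requested stages (simulate, enrichment, annotations, assays)
#' and writes result tables, the Z matrix with its significance mask, and a
#' `manifest.json` recording the config hash, seed, package version and
#' per-stage counts. Identical config + seed produces byte-identical result
#' tables. Any stage failure aborts with a stage-labeled error.
#'
#' @param config A config list (from [read_run_config()]) or a path to a
#'   JSON config.
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `out_dir`.
#' @return Invisibly, a list with the stage outputs and the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else {
    validate_run_config(config)
  }
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) {
    stop("config error: no `out_dir` given", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if (!is.null(cfg$simulate)) {
    sim <- run_stage("simulate", sim_stage(cfg, out_dir))
    de_tables <- sim$de_tables
    gene_sets <- sim$gene_sets
  } else {
    de_tables <- run_stage("load", lapply(cfg$de_tables, read_de_table))
    gene_sets <- run_stage("load", read_gmt(cfg$gmt))
  }

  enr <- run_stage("enrichment",
                   enrich_stage(cfg, de_tables, gene_sets, out_dir))
  ann <- if (!is.null(cfg$annotations)) {
    run_stage("annotations", annot_stage(cfg, de_tables, out_dir))
  }
  assays <- if (!is.null(cfg$assays)) {
    run_stage("assays", assay_stage(cfg, out_dir))
  }

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "mespath",
    version = as.character(utils::packageVersion("mespath")),
    seed = cfg$seed,
    config_md5 = unname(tools::md5sum(tmp)),
    n_contrasts = length(de_tables),
    n_gene_sets = length(gene_sets),
    n_results = nrow(enr$results),
    n_significant = sum(enr$results$significant),
    stages = c("enrichment",
               if (!is.null(ann)) "annotations",
               if (!is.null(assays)) "assays")
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(results = enr$results, z = enr$z, annotations = ann,
                 assays = assays, manifest = manifest))
}
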