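#' Pipeline configuration
#'
#' Bundles every stage's parameters plus either a synthetic-cohort
#' configuration (`sim`) or a set of input paths (`inputs`: `vcf`, `msp`,
#' `map`, `annotations`, `metadata`, `ibd`).
#'
#' @param sim a `sim_config`, or NULL when `inputs` is given.
#' @param inputs named list of input file paths, or NULL to simulate.
#' @param thresholds a `classification_thresholds`.
#' @param flag_rules a `variant_flag_rules`.
#' @param geo a `geo_params`; the default here is scaled to desk-size
#'   cohorts (the published 100/500 thresholds assume a five-figure cohort).
#' @param merge_params an `ibd_merge_params`.
#' @param bins a `degree_bins`.
#' @param disease list with `targets`, `n_ref`, `min_cases`.
#' @param out_dir optional output directory for stage tables + manifest.
#' @param seed master seed; stage substreams are derived from it.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            thresholds = classification_thresholds(),
                            flag_rules = variant_flag_rules(),
                            geo = geo_params(min_zone_n = 20, min_category_n = 50),
                            merge_params = ibd_merge_params(),
                            bins = degree_bins(),
                            disease = list(targets = c("asthma", "obesity",
                                                       "diabetes", "hypertension"),
                                           n_ref = 200L, min_cases = 5L),
                            out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(inputs)) {
    stop_validation("pipeline needs either a sim config or input paths")
  }
  if (!is.null(inputs)) {
    need <- c("vcf", "msp", "annotations", "metadata")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop_validation("missing input paths: ", paste(miss, collapse = ", "))
    for (f in unlist(inputs)) {
      if (!file.exists(f)) stop_validation("input file does not exist: ", f)
    }
  }
  structure(list(sim = sim, inputs = inputs, thresholds = thresholds,
                 flag_rules = flag_rules, geo = geo,
                 merge_params = merge_params, bins = bins, disease = disease,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

run_stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  manifest$stages[[name]] <- list(
    status = "complete",
    rows = if (is.data.frame(res)) nrow(res) else NA_integer_,
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, result = res)
}

#' Run the full cohort-analysis pipeline
#'
#' Simulate (or load) a cohort, then: global ancestry and discrete
#' categories, allele-to-tract assignment, variant flags, burden by
#' ancestry, novelty and impact enrichment, zone composition and
#' dissimilarity, disease prevalence/odds ratios against the
#' Mantel-Haenszel random-condition reference, IBD merging, kinship,
#' degree classification and race concordance. A manifest records seed,
#' parameters and per-stage row counts.
#'
#' @param config a `pipeline_config`.
#' @return list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list(seed = config$seed, stages = list(),
                   parameters = list(
                     thresholds = unclass(config$thresholds),
                     flag_rules = unclass(config$flag_rules),
                     geo = unclass(config$geo),
                     merge = unclass(config$merge_params)))
  out <- list()

  if (!is.null(config$inputs)) {
    st <- run_stage(manifest, "load", {
      inp <- config$inputs
      list(geno = read_phased_vcf(inp$vcf), calls = read_msp(inp$msp),
           map = if (!is.null(inp$map)) read_genetic_map(inp$map) else
             constant_map(warn = TRUE),
           annotations = read_annotations(inp$annotations),
           metadata = read_metadata(inp$metadata),
           ibd = if (!is.null(inp$ibd)) read_ibd(inp$ibd) else NULL)
    })
    manifest <- st$manifest; data <- st$result
    ibd_in <- data$ibd
  } else {
    st <- run_stage(manifest, "simulate", {
      sim_cfg <- config$sim
      sim_cfg$seed <- stage_seed(config$seed, "simulate")
      simulate_cohort(sim_cfg)
    })
    manifest <- st$manifest
    sim <- st$result
    data <- list(geno = sim$geno, calls = sim$calls, map = sim$map,
                 annotations = sim$annotations, metadata = sim$metadata)
    ibd_in <- sim$ibd_truth
    out$sim <- sim
  }

  st <- run_stage(manifest, "classify", {
    props <- global_from_tracts(data$calls)
    data.frame(sample = rownames(props), props,
               category = classify_ancestry(props, config$thresholds),
               check.names = FALSE)
  })
  manifest <- st$manifest; classes <- st$result
  categories <- setNames(classes$category, classes$sample)

  st <- run_stage(manifest, "assign", assign_alleles(data$geno, data$calls))
  manifest <- st$manifest; assignment <- st$result

  flags <- variant_flags(data$geno, data$annotations, config$flag_rules)

  st <- run_stage(manifest, "burden",
                  burden_by_ancestry(assignment, flags, data$calls))
  manifest <- st$manifest; burden <- st$result

  st <- run_stage(manifest, "novelty", {
    props <- as.matrix(classes[, setdiff(names(classes), c("sample", "category"))])
    rownames(props) <- classes$sample
    list(by_individual = novelty_by_group(data$geno, flags, categories),
         per_tract = novelty_by_group(data$geno, flags, categories,
                                      per_tract = TRUE, assignment = assignment,
                                      proportions = props,
                                      component_min = config$thresholds$pair_component_min),
         private = private_to_ancestry(assignment, nrow(data$geno$variants)))
  })
  manifest <- st$manifest; novelty <- st$result

  st <- run_stage(manifest, "enrich",
                  impact_enrichment(flags, align_annotations(data$geno,
                                                             data$annotations)))
  manifest <- st$manifest; enrichment <- st$result

  st <- run_stage(manifest, "geo", {
    comp <- zone_composition(categories, data$metadata, config$geo)
    dis <- dissimilarity_matrix(categories, data$metadata, config$geo)
    list(composition = comp, dissimilarity = dis)
  })
  manifest <- st$manifest; geo <- st$result

  st <- run_stage(manifest, "disease", {
    rp <- reference_panel_or(data$metadata, config$disease$targets,
                             n_ref = config$disease$n_ref,
                             min_cases = config$disease$min_cases,
                             seed = stage_seed(config$seed, "disease"))
    counts <- case_counts_by_group(data$metadata, categories,
                                   config$disease$targets)
    list(reference_panel = rp, case_counts = counts)
  })
  manifest <- st$manifest; disease <- st$result

  st <- run_stage(manifest, "relate", {
    merged <- if (!is.null(ibd_in) && nrow(ibd_in) > 0) {
      merge_ibd(ibd_in, data$geno, data$map, config$merge_params)
    } else ibd_in
    tot <- if (!is.null(merged)) total_ibd(merged) else NULL
    kin <- king_matrix(data$geno)
    kin$degree <- classify_degree(phi = kin$phi, bins = config$bins)
    list(merged_ibd = merged, total_ibd = tot, kinship = kin)
  })
  manifest <- st$manifest; relate <- st$result

  st <- run_stage(manifest, "concordance", {
    l_tot <- total_map_cm(data$calls)
    if (!is.null(relate$total_ibd) && nrow(relate$total_ibd) > 0) {
      race_concordance(relate$total_ibd, data$metadata, categories, l_tot,
                       config$bins)
    } else {
      list(pairs = NULL, summary = list(n_related = 0L))
    }
  })
  manifest <- st$manifest; concordance <- st$result

  out <- c(out, list(classes = classes, assignment = assignment,
                     flags = flags, burden = burden, novelty = novelty,
                     enrichment = enrichment, geo = geo, disease = disease,
                     relate = relate, concordance = concordance,
                     manifest = manifest))
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

#' @rdname run_pipeline
#' @export
run_all <- run_pipeline

# total genetic length (cM) represented by the local-ancestry windows
total_map_cm <- function(calls) {
  sum(vapply(split(calls$windows, calls$windows$chrom),
             function(w) max(w$egpos) - min(w$sgpos), 0))
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fw <- function(x, f) data.table::fwrite(x, file.path(dir, f), sep = "\t")
  fw(out$classes, "ancestry_categories.tsv")
  fw(out$burden, "burden_by_ancestry.tsv")
  fw(out$novelty$by_individual, "novelty_by_individual.tsv")
  fw(out$novelty$per_tract, "novelty_per_tract.tsv")
  fw(out$enrichment, "impact_enrichment.tsv")
  fw(out$disease$reference_panel$targets, "disease_target_or.tsv")
  fw(out$disease$case_counts, "case_counts.tsv")
  fw(out$geo$dissimilarity, "dissimilarity.tsv")
  fw(out$relate$kinship, "kinship.tsv")
  if (!is.null(out$concordance$pairs)) fw(out$concordance$pairs, "pair_concordance.tsv")
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
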