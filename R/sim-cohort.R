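# build the pedigree data.frame realising the configured related-pair types;
# hidden individuals (ids starting "H") exist only to breed visible ones
relative_pedigree <- function(relatives) {
  rows <- list()
  pairs <- list()
  hid <- 0L
  new_h <- function() {
    hid <<- hid + 1L
    sprintf("H%03d", hid)
  }
  add <- function(id, fa = NA, mo = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(id = id, father = fa, mother = mo)
  }
  ridx <- 0L
  new_r <- function() {
    ridx <<- ridx + 1L
    sprintf("R%03d", ridx)
  }
  for (type in names(relatives)) {
    for (rep_i in seq_len(relatives[[type]])) {
      if (type == "po") {
        p <- new_r(); h <- new_h(); c1 <- new_r()
        add(p); add(h); add(c1, p, h)
        pairs[[length(pairs) + 1L]] <- data.frame(type = "po", id1 = p, id2 = c1)
      } else if (type == "fs") {
        f <- new_h(); m <- new_h(); c1 <- new_r(); c2 <- new_r()
        add(f); add(m); add(c1, f, m); add(c2, f, m)
        pairs[[length(pairs) + 1L]] <- data.frame(type = "fs", id1 = c1, id2 = c2)
      } else if (type == "hs") {
        f <- new_h(); m1 <- new_h(); m2 <- new_h(); c1 <- new_r(); c2 <- new_r()
        add(f); add(m1); add(m2); add(c1, f, m1); add(c2, f, m2)
        pairs[[length(pairs) + 1L]] <- data.frame(type = "hs", id1 = c1, id2 = c2)
      } else if (type == "c1") {
        g1 <- new_h(); g2 <- new_h(); s1 <- new_h(); s2 <- new_h()
        q1 <- new_h(); q2 <- new_h(); c1 <- new_r(); c2 <- new_r()
        add(g1); add(g2); add(s1, g1, g2); add(s2, g1, g2)
        add(q1); add(q2); add(c1, s1, q1); add(c2, s2, q2)
        pairs[[length(pairs) + 1L]] <- data.frame(type = "c1", id1 = c1, id2 = c2)
      } else if (type == "mz") {
        p <- new_r(); dup <- new_r()
        add(p) # the duplicate shares p's haplotypes; no pedigree edge
        pairs[[length(pairs) + 1L]] <- data.frame(type = "mz", id1 = p, id2 = dup)
      } else {
        stop_validation("unknown relative pair type: ", type)
      }
    }
  }
  list(pedigree = if (length(rows)) do.call(rbind, rows) else
         data.frame(id = character(), father = character(), mother = character()),
       pairs = if (length(pairs)) do.call(rbind, pairs) else
         data.frame(type = character(), id1 = character(), id2 = character()))
}

# union-breakpoint msp truth over all cohort haplotypes: the emitted windows
# cut every tract boundary, so the msp exactly represents the truth tracts
build_msp_truth <- function(tracts, config, variants) {
  samples <- unique(tracts$sample)
  hap_cols <- as.vector(rbind(paste0(samples, ".0"), paste0(samples, ".1")))
  win_l <- list()
  call_l <- list()
  for (ci in seq_len(nrow(config$chrom))) {
    cr <- config$chrom[ci, ]
    tc <- tracts[tracts$chrom == cr$chrom, , drop = FALSE]
    cuts <- sort(unique(c(0L, tc$start, tc$end, as.integer(cr$bp))))
    s <- cuts[-length(cuts)]
    e <- cuts[-1]
    nw <- length(s)
    calls <- matrix(NA_integer_, nw, length(hap_cols),
                    dimnames = list(NULL, hap_cols))
    for (sm in samples) {
      for (h in 0:1) {
        t0 <- tc[tc$sample == sm & tc$hap == h, , drop = FALSE]
        t0 <- t0[order(t0$start), , drop = FALSE]
        calls[, paste0(sm, ".", h)] <- t0$anc[findInterval(s, t0$start)]
      }
    }
    vp <- variants$pos[variants$chrom == cr$chrom] - 1L
    n_snps <- as.integer(table(factor(findInterval(vp, s), levels = seq_len(nw))))
    cm_per_bp <- cr$cM / cr$bp
    win_l[[ci]] <- data.frame(chrom = cr$chrom, spos = s, epos = e,
                              sgpos = s * cm_per_bp, egpos = e * cm_per_bp,
                              n_snps = n_snps)
    call_l[[ci]] <- calls
  }
  codes <- setNames(seq_along(config$labels) - 1L, config$labels)
  local_ancestry(codes, do.call(rbind, win_l), do.call(rbind, call_l))
}

#' Simulate a complete admixed cohort with ground truth
#'
#' Runs the full generative chain under one seed: admixture proportions and
#' ancestry tracts for every haplotype, pedigree relatives (with true IBD
#' segments), ancestry-specific allele frequencies and phased genotypes,
#' variant annotations with ancestry-biased catalog membership, and sample
#' metadata (race with configurable discordance, ancestry-stratified zones,
#' ancestry/zone-dependent phenotypes). The emitted local-ancestry calls are
#' the truth tracts, so the generator doubles as a perfect local-ancestry
#' oracle.
#'
#' @param config a `sim_config`.
#' @return object of class `sim_cohort`: list with `geno`, `calls`, `map`,
#'   `annotations`, `metadata`, `ibd_truth`, and `truth` (tracts,
#'   proportions, categories, variant origins/frequencies, pedigree pairs,
#'   metadata parameters, config).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  unrel <- sprintf("S%04d", seq_len(config$n_samples))
  relinfo <- relative_pedigree(as.list(config$relatives))
  ped <- rbind(data.frame(id = unrel, father = NA_character_,
                          mother = NA_character_),
               relinfo$pedigree)
  rel <- simulate_relatives(config, ped)
  # monozygotic duplicates share their source's haplotypes
  mz <- relinfo$pairs[relinfo$pairs$type == "mz", , drop = FALSE]
  for (r in seq_len(nrow(mz))) {
    rel$individuals[[mz$id2[r]]] <- rel$individuals[[mz$id1[r]]]
  }
  cohort_ids <- c(unrel, grep("^R", names(rel$individuals), value = TRUE),
                  mz$id2)
  cohort_ids <- unique(cohort_ids)

  variants <- simulate_variants(config)
  geno <- simulate_genotypes(rel, variants, cohort_ids)

  tracts <- do.call(rbind, lapply(cohort_ids, function(id) {
    ind <- rel$individuals[[id]]
    do.call(rbind, lapply(0:1, function(h) {
      segs <- ind[[h + 1L]]
      tr <- if (length(unique(segs$src)) == 1L) {
        rel$founder_tracts[[as.character(segs$src[1])]]
      } else {
        compose_tracts(segs, rel$founder_tracts)
      }
      data.frame(sample = id, hap = h, tr[, c("chrom", "start", "end", "anc")])
    }))
  }))
  rownames(tracts) <- NULL

  calls <- build_msp_truth(tracts, config, variants$variants)
  props <- global_from_tracts(calls)
  categories <- setNames(classify_ancestry(props), rownames(props))
  dominant <- colnames(props)[max.col(props, ties.method = "first")]

  md <- simulate_metadata(config, cohort_ids, unname(categories[cohort_ids]),
                          setNames(dominant, rownames(props))[cohort_ids])

  ibd_l <- lapply(seq_len(nrow(relinfo$pairs)), function(r) {
    p <- relinfo$pairs[r, ]
    true_ibd_segments(rel$individuals[[p$id1]], rel$individuals[[p$id2]],
                      p$id1, p$id2, config)
  })
  ibd_truth <- if (length(ibd_l)) {
    validate_ibd(do.call(rbind, ibd_l))
  } else {
    validate_ibd(data.frame(sample1 = character(), hap1 = integer(),
                            sample2 = character(), hap2 = integer(),
                            chrom = character(), start = integer(),
                            end = integer(), cM = numeric()))
  }

  map <- genetic_map(do.call(rbind, lapply(seq_len(nrow(config$chrom)),
    function(ci) {
      cr <- config$chrom[ci, ]
      data.frame(chrom = cr$chrom, pos = c(0, cr$bp), cM = c(0, cr$cM))
    })))

  structure(list(
    geno = geno, calls = calls, map = map,
    annotations = variants$annotations, metadata = md$metadata,
    ibd_truth = ibd_truth,
    truth = list(tracts = tracts, proportions = props,
                 categories = categories, origin = variants$origin,
                 freqs = variants$freqs,
                 deleterious = variants$deleterious,
                 pairs = relinfo$pairs, founder_m = rel$founder_m,
                 metadata_params = md$params, config = config)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", length(x$geno$samples), "samples,",
      nrow(x$geno$variants), "variants,", nrow(x$calls$windows),
      "ancestry windows,", nrow(x$truth$pairs), "related pairs\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Emits the consumable formats (phased VCF, msp.tsv, genetic map,
#' annotation/metadata/IBD TSVs) plus `truth/` tables and the configuration;
#' the same seed yields byte-identical files.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_phased_vcf(sim$geno, file.path(dir, "cohort.vcf"))
  write_msp(sim$calls, file.path(dir, "local_ancestry.msp.tsv"))
  write_genetic_map(sim$map, file.path(dir, "genetic_map.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_ibd(sim$ibd_truth, file.path(dir, "ibd_truth.tsv"))
  data.table::fwrite(sim$truth$tracts, file.path(dir, "truth", "tracts.tsv"),
                     sep = "\t")
  props <- data.frame(sample = rownames(sim$truth$proportions),
                      sim$truth$proportions,
                      category = unname(sim$truth$categories))
  data.table::fwrite(props, file.path(dir, "truth", "proportions.tsv"), sep = "\t")
  data.table::fwrite(sim$truth$pairs, file.path(dir, "truth", "pedigree_pairs.tsv"),
                     sep = "\t")
  cfg <- sim$truth$config
  cfg_out <- list(labels = cfg$labels, g = cfg$g,
                  chrom = as.list(cfg$chrom), n_variants = cfg$n_variants,
                  n_samples = cfg$n_samples, seed = cfg$seed,
                  race_discordance = cfg$race_discordance,
                  catalog_model = as.list(cfg$catalog_model),
                  relatives = as.list(cfg$relatives))
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  invisible(dir)
}
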