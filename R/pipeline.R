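#' Validate a pipeline configuration
#'
#' A pipeline run is driven by a flat named list (or a YAML file with the
#' same keys).  Unknown keys are rejected; all thresholds are checked before
#' any stage runs.
#'
#' Keys (defaults in parentheses): `genotypes`, `map`, `metadata` — input
#' paths (all optional when `simulate = TRUE`); `simulate` (FALSE),
#' `sim_preset` ("combined"), `sim_n_loci` (2000), `sim_n_samples` (preset
#' default); `max_missing` (0.25),
#' `min_maf` (0.05); `ld_window` (50), `ld_alpha` (0.001), `loess_span`
#' (0.5); `k_min` (1), `k_max` (10), `n_reps` (7), `burn_in` (10000),
#' `n_iter` (100000); `q_strong` (0.7), `q_moderate` (0.5); `seed` (1);
#' `out_dir` (required); `overwrite` (FALSE) — rerun stages whose outputs
#' already exist.
#'
#' @param config named list or path to a YAML file.
#' @return The completed configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- list(genotypes = NULL, map = NULL, metadata = NULL,
                   simulate = FALSE, sim_preset = "combined",
                   sim_n_loci = 2000, sim_n_samples = NULL,
                   max_missing = 0.25, min_maf = 0.05,
                   ld_window = 50, ld_alpha = 0.001, loess_span = 0.5,
                   k_min = 1, k_max = 10, n_reps = 7,
                   burn_in = 10000, n_iter = 100000,
                   q_strong = 0.7, q_moderate = 0.5,
                   seed = 1, out_dir = NULL, overwrite = FALSE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$out_dir)) stop("config needs an out_dir")
  if (!cfg$simulate && is.null(cfg$genotypes))
    stop("config needs input paths or simulate = TRUE")
  if (cfg$k_max < cfg$k_min) stop("k_max must be >= k_min")
  stopifnot(cfg$max_missing > 0, cfg$max_missing < 1,
            cfg$min_maf > 0, cfg$min_maf < 1,
            cfg$ld_window > 0, cfg$ld_alpha > 0, cfg$ld_alpha < 1,
            cfg$n_reps >= 1, cfg$burn_in >= 0, cfg$n_iter >= 1,
            cfg$q_strong > cfg$q_moderate)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full diversity-and-structure pipeline
#'
#' Executes, in order: input loading (or simulation), per-era marker QC,
#' polymorphism partition between eras, per-era diversity summaries by
#' chromosome and genome, per-era LD scans with per-genome critical
#' r-squared and per-chromosome LOESS decay distances, LD-decay thinning of
#' the common polymorphic markers followed by an admixture-model scan over
#' K on the thinned set (the joint era pre-pass) and per-era scans, Evanno
#' model choice and q-threshold membership, a Nei diversity partition over
#' the assigned subpopulations (structured samples only), and finally
#' simple-matching distances with a neighbour-joining tree and PCoA.
#'
#' Each stage writes its artifacts under `out_dir` and a stage is skipped
#' when its outputs already exist (unless `overwrite = TRUE`), making reruns
#' resumable.  A `pipeline_log.json` records seeds, thresholds and stage
#' status; a failing stage aborts with its name after writing the log.
#'
#' @param config a [pipeline_config()] list or YAML path.
#' @return Invisibly, a list with the principal in-memory results per stage.
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = unclass(cfg), stages = list())
  results <- list()
  stage_path <- function(f) file.path(cfg$out_dir, f)
  log_write <- function() {
    writeLines(as.character(yaml::as.yaml(log)),
               stage_path("pipeline_log.yaml"))
  }
  run_stage <- function(name, outputs, fun) {
    done <- all(file.exists(stage_path(outputs)))
    if (done && !cfg$overwrite) {
      log$stages[[name]] <<- "reused"
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) {
      log$stages[[name]] <<- paste("failed:", conditionMessage(e))
      log_write()
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log$stages[[name]] <<- "completed"
    res
  }

  ## stage: inputs
  if (cfg$simulate) {
    sim_args <- list(preset = cfg$sim_preset, n_loci = cfg$sim_n_loci,
                     seed = cfg$seed)
    if (!is.null(cfg$sim_n_samples)) sim_args$n_samples <- cfg$sim_n_samples
    panel <- do.call(simulate_panel, sim_args)
    gm <- panel$genotypes
    map <- panel$map
  } else {
    gm <- read_genotype_matrix(cfg$genotypes)
    map <- read_genetic_map(cfg$map)
    if (!is.null(cfg$metadata)) {
      md <- read_sample_metadata(cfg$metadata, gm)
      gm$era <- factor(md$era[match(sample_ids(gm), md$sample_id)])
    }
  }
  if (is.null(gm$era)) stop("era labels are required (metadata or preset)")
  log$stages$inputs <- "completed"
  eras <- levels(gm$era)

  ## stage: QC per era
  reports <- list()
  for (e in eras) {
    rep_e <- run_stage(paste0("qc_", e), paste0("filter_report_", e, ".tsv"),
                       function() {
      fr <- filter_markers(gm[gm$era == e, ], cfg$max_missing, cfg$min_maf)
      write_tsv(data.frame(era = e, n_input = fr$n_input,
                           n_removed_missing = fr$n_removed_missing,
                           n_removed_maf = fr$n_removed_maf,
                           n_retained = fr$n_retained),
                stage_path(paste0("filter_report_", e, ".tsv")))
      fr
    })
    if (!is.null(rep_e)) reports[[e]] <- rep_e
  }
  if (length(reports) < length(eras))  # resumed: recompute in memory
    reports <- lapply(stats::setNames(eras, eras), function(e)
      filter_markers(gm[gm$era == e, ], cfg$max_missing, cfg$min_maf))
  results$filter_reports <- reports

  ## stage: polymorphism partition
  part <- partition_polymorphism(gm, gm$era)
  write_tsv(data.frame(union = part$n_total_union, common = part$n_common,
                       only_group1 = part$n_only_group1,
                       only_group2 = part$n_only_group2),
            stage_path("polymorphism_partition.tsv"))
  log$stages$polymorphism <- "completed"
  results$partition <- part

  ## stage: diversity + LD per era
  decay_by_era <- list()
  for (e in eras) {
    gme <- reports[[e]]$genotypes
    div <- summarize_by_region(gme, map)
    ld <- ld_scan(gme, map, window_cM = cfg$ld_window, alpha = cfg$ld_alpha)
    crit <- critical_r2_per_genome(ld)
    summ <- attr(ld, "summary")
    decs <- numeric(0)
    for (ch in unique(summ$chromosome)) {
      g <- summ$genome[summ$chromosome == ch]
      fit <- suppressWarnings(
        fit_ld_decay(ld, ch, crit[[g]], span = cfg$loess_span))
      decs[ch] <- fit$decay_cM
    }
    tab1 <- merge(div, rbind(summ,
      data.frame(chromosome = "Total", genome = "-", n_pairs = nrow(ld),
                 mean_r2 = mean(ld$r2),
                 pct_significant = 100 * mean(ld$p_value < cfg$ld_alpha,
                                              na.rm = TRUE))),
      by.x = "region", by.y = "chromosome", all.x = TRUE)
    tab1$decay_cM <- decs[tab1$region]
    write_tsv(tab1[order(match(tab1$region,
                               c(wheat_chromosomes(), "A", "B", "D",
                                 "Total"))), ],
              stage_path(paste0("diversity_ld_", e, ".tsv")))
    log$stages[[paste0("diversity_ld_", e)]] <- "completed"
    decay_by_era[[e]] <- decs
    results$diversity[[e]] <- div
    results$ld_summary[[e]] <- summ
    results$critical_r2[[e]] <- crit
  }
  results$decay <- decay_by_era

  ## stage: thinning of common polymorphic markers
  common_ids <- locus_ids(gm)[part$polymorphic[, 1] & part$polymorphic[, 2]]
  common_ids <- intersect(common_ids,
                          Reduce(intersect,
                                 lapply(reports, function(r)
                                   locus_ids(r$genotypes))))
  decay_max <- do.call(pmax, c(lapply(decay_by_era, function(d)
    d[unique(map$chromosome)]), list(na.rm = TRUE)))
  decay_max[is.na(decay_max)] <- 0
  names(decay_max) <- unique(map$chromosome)
  thinned <- thin_by_decay(gm[, common_ids], map, decay_max)
  writeLines(thinned, stage_path("thinned_markers.txt"))
  log$stages$thinning <- "completed"
  results$thinned <- thinned

  ## stage: structure (joint pre-pass on thinned common set, then per era)
  gm_thin <- gm[, thinned]
  scan_joint <- structure_scan(gm_thin, k_range = cfg$k_min:cfg$k_max,
                               n_reps = cfg$n_reps, burn_in = cfg$burn_in,
                               n_iter = cfg$n_iter, seed = cfg$seed)
  ev_joint <- tryCatch(evanno_delta_k(scan_joint), error = function(e) NULL)
  results$structure_joint <- scan_joint
  results$evanno_joint <- ev_joint
  if (!is.null(ev_joint))
    write_tsv(as.data.frame(ev_joint), stage_path("evanno_joint.tsv"))

  memberships <- list()
  for (e in eras) {
    gme <- reports[[e]]$genotypes
    scan_e <- structure_scan(gme, k_range = cfg$k_min:cfg$k_max,
                             n_reps = cfg$n_reps, burn_in = cfg$burn_in,
                             n_iter = cfg$n_iter,
                             seed = cfg$seed + match(e, eras))
    ev <- tryCatch(evanno_delta_k(scan_e), error = function(e2) NULL)
    bestK <- if (!is.null(ev) && !is.na(attr(ev, "best_K")))
      attr(ev, "best_K") else max(2, cfg$k_min)
    qbar <- aggregate_runs(scan_e$fits[[paste0("K", bestK)]])
    mem <- assign_membership(qbar, cfg$q_strong, cfg$q_moderate)
    write_tsv(cbind(era = e, mem), stage_path(paste0("membership_", e,
                                                     ".tsv")))
    if (!is.null(ev))
      write_tsv(as.data.frame(ev), stage_path(paste0("evanno_", e, ".tsv")))
    memberships[[e]] <- list(best_K = bestK, Q = qbar, membership = mem,
                             evanno = ev)
    log$stages[[paste0("structure_", e)]] <- "completed"
  }
  results$structure <- memberships

  ## stage: diversity partition over assigned subpopulations
  sp <- rep(NA_character_, nrow(gm$dose))
  names(sp) <- sample_ids(gm)
  offset <- 0
  for (e in eras) {
    mem <- memberships[[e]]$membership
    ok <- mem$class != "admixed"
    sp[mem$sample_id[ok]] <- paste0("SP", offset +
      as.integer(sub("SP", "", mem$subpopulation[ok])))
    offset <- offset + memberships[[e]]$best_K
  }
  # subpopulations with fewer than 2 assigned members cannot enter a
  # diversity partition; drop them
  tab_sp <- table(sp[!is.na(sp)])
  sp[sp %in% names(tab_sp)[tab_sp < 2]] <- NA
  structured <- !is.na(sp)
  tab3 <- list()
  if (sum(structured) >= 4 && length(unique(sp[structured])) >= 2) {
    gms <- gm[structured, ]
    part_all <- diversity_partition(gms, factor(sp[structured]))
    tab3[["Total"]] <- part_all
    results$nei_total <- part_all
    sps <- sort(unique(sp[structured]))
    if (length(sps) > 2) {
      for (i in seq_along(sps)[-length(sps)]) for (j in (i + 1):length(sps)) {
        sel <- sp[structured] %in% c(sps[i], sps[j])
        if (min(table(sp[structured][sel])) >= 2)
          tab3[[paste0(sps[i], "-", sps[j])]] <-
            diversity_partition(gms[sel, ], factor(sp[structured][sel]))
      }
    }
    t3 <- do.call(rbind, lapply(names(tab3), function(nm) {
      x <- tab3[[nm]]
      data.frame(grouping = nm, N = x$n_samples, H_T = x$H_T, H_S = x$H_S,
                 D_ST = x$D_ST, G_ST = x$G_ST, Nm = x$Nm)
    }))
    write_tsv(t3, stage_path("nei_partition.tsv"))
    results$nei_table <- t3
  }
  log$stages$nei_partition <- "completed"

  ## stage: distance, tree, PCoA on the thinned common set
  dm <- simple_matching_distance(gm_thin)
  tree <- neighbor_joining(dm)
  write_newick(tree, stage_path("nj_tree.nwk"))
  pc <- pcoa(dm, n_axes = min(2, nrow(dm) - 1))
  write_tsv(data.frame(sample_id = rownames(pc$coordinates),
                       pc$coordinates, era = gm$era),
            stage_path("pcoa_coordinates.tsv"))
  write_tsv(data.frame(axis = seq_along(pc$eigenvalues),
                       eigenvalue = pc$eigenvalues),
            stage_path("pcoa_eigenvalues.tsv"))
  log$stages$distance_tree_pcoa <- "completed"
  results$distance <- dm
  results$tree <- tree
  results$pcoa <- pc

  log_write()
  invisible(results)
}
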