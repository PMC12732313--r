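# End-to-end orchestration: simulate -> classify -> ssn -> phylo ->
# conserve, with kinetics and melt as parallel tracks, a YAML config,
# and a JSON reproducibility manifest with checksum-gated idempotence.

#' Default pipeline configuration
#'
#' Stage toggles and per-stage parameter blocks for [run_pipeline()].
#' All stages run on synthetic data generated in the simulate stage;
#' every source of randomness derives from the single top-level `seed`.
#'
#' @return a nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    seed = 1L,
    outdir = "fkp_pipeline_out",
    stages = list(simulate = TRUE, classify = TRUE, ssn = TRUE,
                  phylo = TRUE, conserve = TRUE, kinetics = TRUE,
                  melt = TRUE),
    simulate = list(n_fuk = 4L, n_gfpp = 4L, n_fkp = 4L,
                    domain_len_fuk = 400L, domain_len_gfpp = 480L,
                    linker_len = 20L, substitution_rate = 0.05,
                    score_noise_sd = 0,
                    tree_n_tips = 16L, fusion_clade_size = 5L,
                    loss_count = 0L,
                    census_rows = 186L, census_gap_prefixed = 15L),
    classify = list(min_fuk_len = 333L, min_gfpp_len = 406L,
                    min_fkp_len = 739L, max_len = 1745L),
    # identity between a fused protein and either monofunctional family
    # is ~40-50% (a full domain aligns), so the family-resolution
    # network needs a threshold above that; 30% is the conventional
    # choice for a fused-proteins-only network
    ssn = list(threshold = 60, fkp_threshold = 30,
               min_cluster_size = 2L),
    conserve = list(positions = c("G75", "R79", "K88",
                                  "R597", "D606", "D767"),
                    boundary = 88L),
    kinetics = list(KM = 77, kcat = 0.90, E0 = 0.277, noise_cv = 0.05,
                    n_reps = 3L),
    melt = list(midpoints_apo = c(43.8, 52.5),
                midpoints_ligand = c(43.8, 54.3),
                steepness = 0.8, amplitudes = c(800, 1500),
                noise_sd = 5, n_reps = 3L)
  ), class = "pipeline_config")
}

# flatten nested config keys to "a.b" paths for unknown-key reporting
flat_keys <- function(x, prefix = "") {
  out <- character(0)
  for (k in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    out <- c(out, key)
    if (is.list(x[[k]]) && !is.null(names(x[[k]])))
      out <- c(out, flat_keys(x[[k]], key))
  }
  out
}

merge_config <- function(defaults, user, prefix = "", strict = TRUE) {
  known <- names(defaults)
  for (k in names(user)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% known) {
      hint <- agrep(k, known, max.distance = 0.3, value = TRUE)
      stop("unknown config key '", key, "'",
           if (length(hint)) paste0("; did you mean '", hint[1], "'?")
           else "")
    }
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      if (!is.list(user[[k]]))
        stop("config key '", key, "' must be a block")
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], key, strict)
    } else {
      v <- user[[k]]
      if (is.numeric(defaults[[k]]) && is.character(v)) {
        coerced <- suppressWarnings(as.numeric(v))
        if (anyNA(coerced))
          stop("config key '", key, "' must be numeric")
        if (strict)
          stop("config key '", key, "' must be numeric, got a string")
        warning("coercing config key '", key, "' from string to numeric")
        v <- coerced
      }
      if (is.logical(defaults[[k]]) && !is.logical(v))
        stop("config key '", key, "' must be TRUE/FALSE")
      defaults[[k]] <- v
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills defaults, rejects
#' unknown keys with a nearest-key suggestion, and type-checks values
#' against the defaults. An empty file yields the full default
#' configuration.
#'
#' @param config a YAML file path, a list, or `NULL` for pure defaults.
#' @param strict reject (TRUE, default) or coerce-with-warning (FALSE)
#'   numeric values supplied as strings.
#' @return a normalized `pipeline_config` list.
#' @export
validate_config <- function(config = NULL, strict = TRUE) {
  defaults <- default_pipeline_config()
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    yaml::read_yaml(config) %||% list()
  } else if (is.list(config)) {
    config
  } else stop("config must be a path, a list, or NULL")
  out <- merge_config(unclass(defaults), user, strict = strict)
  structure(out, class = "pipeline_config")
}

stage_seed <- function(config, offset) {
  (as.integer(config$seed) + offset) %% .Machine$integer.max
}

file_md5 <- function(paths) {
  stats::setNames(unname(tools::md5sum(paths)), basename(paths))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order on synthetic data:
#' simulate (families, hit table, fusion tree, census alignment, rate
#' data, melt curves), classify, ssn, phylo, conserve, kinetics and
#' melt. Outputs are plain-text tables under `config$outdir` and a JSON
#' manifest records the seed, a config checksum, per-stage outputs with
#' MD5 checksums, timings and (on failure) the failing stage. Rerunning
#' with an unchanged config and intact outputs skips all work
#' (checksum-gated idempotence). A stage failure still writes the
#' manifest, then aborts.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL) {
  config <- validate_config(config)
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # hash the normalized config without touching the output tree (the
  # idempotence check below must not disturb mtimes on a no-op rerun)
  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(unclass(config), cfg_tmp)
  cfg_md5 <- unname(tools::md5sum(cfg_tmp))
  unlink(cfg_tmp)
  cfg_path <- file.path(outdir, "config_normalized.yaml")
  manifest_path <- file.path(outdir, "manifest.json")

  # upstream-dependency validation before any execution: every enabled
  # downstream stage needs its inputs on disk or the simulate stage on
  needs_sim <- list(
    classify = c("hits.tsv", "proteins.fasta", "truth_families.tsv"),
    ssn = "proteins.fasta",
    phylo = c("fusion_tree.nwk", "tip_states.tsv"),
    conserve = c("census_alignment.fasta", "census_clades.tsv"),
    kinetics = "rates.csv",
    melt = "melt_curves.csv")
  if (!isTRUE(config$stages$simulate)) {
    for (st in names(needs_sim)) {
      if (!isTRUE(config$stages[[st]])) next
      missing <- needs_sim[[st]][!file.exists(file.path(outdir,
                                                        needs_sim[[st]]))]
      if (length(missing))
        stop("config validation error: stage '", st, "' needs ",
             paste(missing, collapse = ", "),
             " but the simulate stage is disabled")
    }
  }

  # idempotence: unchanged config + intact outputs -> skip
  if (file.exists(manifest_path)) {
    old <- tryCatch(jsonlite::read_json(manifest_path,
                                        simplifyVector = TRUE),
                    error = function(e) NULL)
    if (!is.null(old) && identical(old$config_md5, cfg_md5) &&
          identical(old$status, "ok")) {
      intact <- length(old$stages) > 0 &&
        all(vapply(old$stages, function(st) {
          paths <- file.path(outdir, st$outputs)
          length(paths) > 0 && all(file.exists(paths)) &&
            identical(unname(tools::md5sum(paths)),
                      unname(unlist(st$md5)))
        }, NA))
      if (intact) {
        message("pipeline outputs up to date; nothing to do")
        old$status <- "cached"
        return(invisible(old))
      }
    }
  }

  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(tool = "fkptools",
                   version = as.character(utils::packageVersion("fkptools")),
                   seed = config$seed, config_md5 = cfg_md5,
                   stages = list(), status = "ok", failed_stage = NULL)
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!isTRUE(config$stages[[name]])) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    outputs <- tryCatch(fun(), error = function(e) e)
    if (inherits(outputs, "error")) {
      manifest$status <<- "failed"
      manifest$failed_stage <<- name
      manifest$stages[[name]] <<- list(error = conditionMessage(outputs))
      jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                           null = "null")
      stop("pipeline stage '", name, "' failed: ",
           conditionMessage(outputs), call. = FALSE)
    }
    manifest$stages[[name]] <<- list(
      outputs = basename(outputs),
      md5 = file_md5(outputs),
      seconds = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(NULL)
  }

  run_stage("simulate", function() {
    sc <- config$simulate
    cfg <- sim_config(seed = stage_seed(config, 1L),
                      n_fuk = sc$n_fuk, n_gfpp = sc$n_gfpp,
                      n_fkp = sc$n_fkp,
                      domain_len_fuk = sc$domain_len_fuk,
                      domain_len_gfpp = sc$domain_len_gfpp,
                      linker_len = sc$linker_len,
                      substitution_rate = sc$substitution_rate,
                      score_noise_sd = sc$score_noise_sd,
                      tree_n_tips = sc$tree_n_tips,
                      fusion_clade_size = sc$fusion_clade_size,
                      loss_count = sc$loss_count)
    fam <- gen_domain_families(cfg)
    hits <- gen_hit_table(fam$proteins, fam$truth,
                          score_noise_sd = cfg$score_noise_sd,
                          seed = stage_seed(config, 2L))
    sim <- gen_fusion_tree(cfg$tree_n_tips, cfg$fusion_clade_size,
                           cfg$loss_count,
                           seed = stage_seed(config, 3L))
    cen <- gen_census_alignment(n_rows = sc$census_rows,
                                n_gap_prefixed = sc$census_gap_prefixed,
                                seed = stage_seed(config, 4L))
    kin <- config$kinetics
    rates <- gen_rate_data(
      kinetic_truth(KM = kin$KM, kcat = kin$kcat, E0 = kin$E0,
                    noise_cv = kin$noise_cv),
      substrate_concs = kin$KM * c(0.25, 0.5, 1, 2, 4, 10),
      n_reps = kin$n_reps, model = "mm",
      seed = stage_seed(config, 5L))
    mc <- config$melt
    melt_cond <- function(mids, cond, seed0) {
      do.call(rbind, lapply(seq_len(mc$n_reps), function(r)
        gen_melt_curve(
          melt_truth(data.frame(midpoint_C = mids,
                                steepness = mc$steepness,
                                amplitude = mc$amplitudes),
                     noise_sd = mc$noise_sd),
          seed = seed0 + r, replicate = r, condition = cond)))
    }
    melts <- rbind(
      melt_cond(mc$midpoints_apo, "apo", stage_seed(config, 6L)),
      melt_cond(mc$midpoints_ligand, "ligand", stage_seed(config, 60L)))
    paths <- c(
      write_protein_fasta(fam$proteins,
                          file.path(outdir, "proteins.fasta")),
      { p <- file.path(outdir, "truth_families.tsv")
        utils::write.table(fam$truth, p, sep = "\t", quote = FALSE,
                           row.names = FALSE); p },
      write_hit_table(hits, file.path(outdir, "hits.tsv")),
      write_newick(sim$tree, file.path(outdir, "fusion_tree.nwk")),
      write_tip_annotations(sim$tree, states = sim$states,
                            path = file.path(outdir, "tip_states.tsv")),
      write_protein_fasta(cen$alignment,
                          file.path(outdir, "census_alignment.fasta")),
      { p <- file.path(outdir, "census_clades.tsv")
        utils::write.table(
          data.frame(id = names(cen$clades), clade = unname(cen$clades)),
          p, sep = "\t", quote = FALSE, row.names = FALSE); p },
      { p <- file.path(outdir, "rates.csv")
        utils::write.csv(rates, p, row.names = FALSE); p },
      { p <- file.path(outdir, "melt_curves.csv")
        utils::write.csv(melts, p, row.names = FALSE); p }
    )
    state$fam <- fam; state$sim <- sim; state$cen <- cen
    state$rates <- rates; state$melts <- melts
    paths
  })

  run_stage("classify", function() {
    hits <- read_hit_table(file.path(outdir, "hits.tsv"))
    prot <- read_protein_fasta(file.path(outdir, "proteins.fasta"))
    lengths <- stats::setNames(nchar(prot), names(prot))
    cl <- config$classify
    calls <- classify_architecture(
      rank_models(hits), lengths,
      arch_thresholds(min_fuk = cl$min_fuk_len,
                      min_gfpp = cl$min_gfpp_len,
                      min_fkp = cl$min_fkp_len,
                      max_len = cl$max_len))
    truth <- utils::read.delim(file.path(outdir, "truth_families.tsv"),
                               stringsAsFactors = FALSE)
    pred <- predict_family(calls)
    acc <- 100 * mean(pred[truth$id] == truth$family)
    p <- file.path(outdir, "memberships.tsv")
    utils::write.table(as.data.frame(calls), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p2 <- file.path(outdir, "classification_accuracy.tsv")
    utils::write.table(data.frame(accuracy_pct = acc), p2, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    state$calls <- calls; state$accuracy <- acc
    c(p, p2)
  })

  run_stage("ssn", function() {
    prot <- read_protein_fasta(file.path(outdir, "proteins.fasta"))
    m <- identity_matrix(prot)
    state$identity <- m
    g <- build_ssn(m, config$ssn$threshold)
    clusters <- ssn_clusters(g, config$ssn$min_cluster_size)
    paths <- write_ssn_tables(g, file.path(outdir, "ssn_nodes.tsv"),
                              file.path(outdir, "ssn_edges.tsv"))
    p <- file.path(outdir, "ssn_clusters.tsv")
    utils::write.table(clusters, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- utils::read.delim(file.path(outdir, "truth_families.tsv"),
                               stringsAsFactors = FALSE)
    cong <- cluster_clade_congruence(
      clusters, stats::setNames(truth$family, truth$id))
    p2 <- file.path(outdir, "ssn_family_purity.tsv")
    utils::write.table(
      data.frame(cluster = names(cong$purity),
                 purity = unname(cong$purity),
                 overall = cong$overall_purity),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    state$clusters <- clusters; state$congruence <- cong
    c(paths$nodes, paths$edges, p, p2)
  })

  run_stage("phylo", function() {
    tree <- read_newick(file.path(outdir, "fusion_tree.nwk"))
    ann <- utils::read.delim(file.path(outdir, "tip_states.tsv"),
                             stringsAsFactors = FALSE)
    states <- stats::setNames(ann$state, ann$tip)
    fused <- ann$tip[ann$state == 1]
    mid <- midpoint_root(tree)
    roots <- monophyly_roots(tree, fused)
    summary <- data.frame(
      n_tips = ape::Ntip(tree),
      fused_tips = length(fused),
      fused_monophyletic = is_monophyletic(tree, fused),
      clade_cover = min_clade_cover(tree, fused),
      monophyly_root_edges = length(roots),
      fitch_events = fitch_fusion_events(tree, states, "unordered"),
      dollo_events = fitch_fusion_events(tree, states, "dollo"),
      midpoint_fused_cover = min_clade_cover(mid, fused))
    p <- file.path(outdir, "phylo_summary.tsv")
    utils::write.table(summary, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p2 <- write_newick(mid, file.path(outdir, "fusion_tree_midpoint.nwk"))
    state$phylo_summary <- summary
    c(p, p2)
  })

  run_stage("conserve", function() {
    aln <- read_alignment(file.path(outdir, "census_alignment.fasta"))
    clades <- utils::read.delim(file.path(outdir, "census_clades.tsv"),
                                stringsAsFactors = FALSE)
    clade_map <- stats::setNames(clades$clade, clades$id)
    cs <- config$conserve
    ref_id <- names(aln)[1]
    map <- map_ref_positions(aln, ref_id, cs$positions)
    retained <- apply_exclusion(aln, ref_id, cs$boundary)
    census <- conservation_fraction(aln, map, retained)
    rows <- conservation_by_row(aln, map, retained)
    nterm <- colnames(rows)[map$position <= cs$boundary]
    strat <- stratify_missing(rows, clade_map, positions = nterm)
    p <- write_census(census, file.path(outdir, "conservation.tsv"))
    p2 <- file.path(outdir, "missing_by_clade.tsv")
    utils::write.table(
      data.frame(clade = names(strat), fraction = unname(strat)),
      p2, sep = "\t", quote = FALSE, row.names = FALSE)
    state$census <- census; state$retained <- retained
    c(p, p2)
  })

  run_stage("kinetics", function() {
    rates <- utils::read.csv(file.path(outdir, "rates.csv"))
    fit <- fit_mm(rates, e0_uM = config$kinetics$E0)
    p <- file.path(outdir, "kinetic_fit.tsv")
    utils::write.table(summary(fit), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$kin_fit <- fit
    p
  })

  run_stage("melt", function() {
    melts <- utils::read.csv(file.path(outdir, "melt_curves.csv"))
    apo <- analyze_melt(melts[melts$condition == "apo", ])
    lig <- analyze_melt(melts[melts$condition == "ligand", ])
    dtm <- delta_tm(apo, lig)
    p <- file.path(outdir, "melt_summary.tsv")
    utils::write.table(
      cbind(condition = "apo", apo$summary), p, sep = "\t",
      quote = FALSE, row.names = FALSE)
    p2 <- file.path(outdir, "delta_tm.tsv")
    utils::write.table(dtm, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    state$dtm <- dtm
    c(p, p2)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       null = "null")
  invisible(manifest)
}
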