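# Pipeline orchestration: a config-driven driver chaining the stages in
# study order (simulate -> small-RNA filtering -> quantification -> DE ->
# target prediction -> degradome validation -> co-expression -> enrichment
# -> network assembly -> phenology), with per-stage output directories and
# a checksum manifest.

#' Default pipeline configuration
#'
#' Ships the study-default thresholds as the `"pmume2022"` profile: gene DE
#' at |log2FC| > 1.5 with adjusted P < 0.05, miRNA DE at log2FC >= 1 with
#' FDR < 0.05, soft powers 9 (genes) and 8 (miRNAs), minimum module size 50,
#' merge similarity 0.8, expression filters >= 2 across 70\% of samples with
#' SD > 0.25, degradome keep-category <= 2, duplex energy ratio >= 74\%, and
#' duplex score <= 4.
#'
#' @param seed RNG seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    profile = "pmume2022",
    sim = list(),
    thresholds = list(
      gene_lfc = 1.5, gene_alpha = 0.05,
      mirna_lfc = 1, mirna_alpha = 0.05,
      power_genes = 9, power_mirnas = 8,
      min_module_size = 50, merge_similarity = 0.8, cut_height = 0.99,
      expr_min_value = 2, expr_min_fraction = 0.7, expr_min_sd = 0.25,
      degradome_keep = 2, mfe_min = 74, max_score = 4, max_gaps = 0,
      trait_r_min = 0.8, k_neighbors = 10, hub_frac = 0.001)
  )
}

validate_config <- function(config) {
  th <- config$thresholds
  problems <- character()
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(is.numeric(config$seed), "seed: must be numeric")
  chk(th$power_genes >= 1, "thresholds.power_genes: must be >= 1")
  chk(th$power_mirnas >= 1, "thresholds.power_mirnas: must be >= 1")
  chk(th$merge_similarity > 0 && th$merge_similarity < 1,
      "thresholds.merge_similarity: must be in (0, 1)")
  chk(th$gene_alpha > 0 && th$gene_alpha < 1,
      "thresholds.gene_alpha: must be in (0, 1)")
  chk(th$mirna_alpha > 0 && th$mirna_alpha < 1,
      "thresholds.mirna_alpha: must be in (0, 1)")
  chk(th$expr_min_fraction > 0 && th$expr_min_fraction <= 1,
      "thresholds.expr_min_fraction: must be in (0, 1]")
  chk(th$degradome_keep %in% 0:4, "thresholds.degradome_keep: must be 0..4")
  chk(th$max_gaps %in% 0:1, "thresholds.max_gaps: must be 0 or 1")
  chk(th$min_module_size >= 2, "thresholds.min_module_size: must be >= 2")
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Fields missing from the file fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (k in names(user)) {
    if (k == "thresholds") {
      for (t in names(user$thresholds)) cfg$thresholds[[t]] <- user$thresholds[[t]]
    } else cfg[[k]] <- user[[k]]
  }
  cfg
}

PIPELINE_STAGES <- c("simulate", "filter-srna", "quantify", "de",
                     "predict-targets", "degradome-validate", "coexpr",
                     "enrich", "network", "phenology")

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

stage_dir <- function(outdir, stage) {
  d <- file.path(outdir, stage)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}

# Synthetic phenology inputs: a declining autumn-to-winter hourly
# temperature series and biweekly bud-break observations crossing 50%.
make_phenology_inputs <- function(seed) {
  set.seed(seed + 3L)
  t0 <- as.POSIXct("2020-10-12 00:00:00", tz = "UTC")
  hours <- 24 * 100
  ts <- t0 + (seq_len(hours) - 1) * 3600
  day <- (seq_len(hours) - 1) / 24
  temp <- 16 - 0.14 * day + 5 * sin(2 * pi * (seq_len(hours) %% 24) / 24) +
    stats::rnorm(hours, 0, 1.5)
  series <- data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S"),
                       temp_c = round(temp, 2))
  obs <- data.frame(
    date = as.Date("2020-10-26") + seq(0, by = 14, length.out = 6),
    flushed = c(1, 9, 42, 59, 74, 88), total = rep(100, 6))
  list(temperature = series, observations = obs)
}

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`, chaining every stage in study order) on a
#' synthetic bundle generated from the configuration. Each stage writes its
#' outputs to its own subdirectory of `outdir`; a manifest of output
#' checksums is written at the end.
#'
#' @param config configuration list (see [default_config()]) or a path to a
#'   YAML file.
#' @param subcommand one of `"simulate"`, `"filter-srna"`, `"quantify"`,
#'   `"de"`, `"predict-targets"`, `"degradome-validate"`, `"coexpr"`,
#'   `"enrich"`, `"network"`, `"phenology"`, `"all"`.
#' @param outdir output directory.
#' @param seed optional seed override.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest data.frame.
#' @export
run_pipeline <- function(config = default_config(), subcommand = "all",
                         outdir = tempfile("mirnet_run_"), seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
  subcommand <- match.arg(subcommand, c("all", PIPELINE_STAGES))
  stages <- if (subcommand == "all") PIPELINE_STAGES else subcommand
  say <- function(...) if (!quiet) message(...)
  th <- config$thresholds
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  sim_args <- config$sim
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  say("generating synthetic bundle (seed ", cfg$seed, ")")
  bundle <- simulate_bundle(cfg)
  res <- list(bundle = bundle)
  files <- character()

  if ("simulate" %in% stages) {
    d <- stage_dir(outdir, "simulate")
    write_bundle(bundle, d)
    phen <- make_phenology_inputs(cfg$seed)
    write_tsv(phen$temperature, file.path(d, "temperature.tsv"))
    write_tsv(phen$observations, file.path(d, "observations.tsv"))
    res$phenology_inputs <- phen
    files <- c(files, list.files(d, full.names = TRUE))
    say("simulate: bundle written to ", d)
  } else {
    res$phenology_inputs <- make_phenology_inputs(cfg$seed)
  }

  if ("filter-srna" %in% stages) {
    d <- stage_dir(outdir, "filter-srna")
    tags <- data.frame(sequence = unname(bundle$mirnas),
                       count = round(rowMeans(bundle$mirna_expr$values))[
                         seq_along(bundle$mirnas)],
                       stringsAsFactors = FALSE)
    junk <- data.frame(sequence = c("AAAAAAAAAAAAAAAAAAAA", "ACGUACGUACGU",
                                    paste(rep("ACGU", 10), collapse = "")),
                       count = c(5, 3, 2), stringsAsFactors = FALSE)
    junk$polya <- c(TRUE, FALSE, FALSE)
    tags$polya <- FALSE
    all_tags <- rbind(tags, junk)
    clean <- filter_tags(all_tags)
    known <- data.frame(id = names(bundle$mirnas),
                        family = sub("_.*", "", names(bundle$mirnas)),
                        sequence = unname(bundle$mirnas),
                        stringsAsFactors = FALSE)
    clean$family <- vapply(clean$sequence, assign_family, character(1),
                           known = known)
    files <- c(files, write_tsv(clean, file.path(d, "clean_tags.tsv")))
    res$clean_tags <- clean
    say("filter-srna: ", nrow(clean), " clean unique tags (log: length ",
        "window 18-30 nt, defect flags applied)")
  }

  if ("quantify" %in% stages) {
    d <- stage_dir(outdir, "quantify")
    mirna_tpm <- tpm_normalize(bundle$mirna_expr)
    res$mirna_tpm <- mirna_tpm
    df <- data.frame(id = rownames(mirna_tpm$values), mirna_tpm$values,
                     check.names = FALSE)
    files <- c(files, write_tsv(df, file.path(d, "mirna_tpm.tsv")))
    say("quantify: miRNA counts normalized to TPM (column sums 1e6)")
  }

  if ("de" %in% stages) {
    d <- stage_dir(outdir, "de")
    stages_lab <- cfg$stages
    samples <- bundle$expression$counts$samples
    de_g <- list(); de_m <- list()
    for (i in seq_len(length(stages_lab) - 1)) {
      ga <- samples$sample[samples$stage == stages_lab[i]]
      gb <- samples$sample[samples$stage == stages_lab[i + 1]]
      lab <- paste0(stages_lab[i], "_vs_", stages_lab[i + 1])
      de_g[[lab]] <- de_screen(bundle$expression$counts, ga, gb,
                               lfc_threshold = th$gene_lfc,
                               alpha = th$gene_alpha, strict_lfc = TRUE,
                               comparison = lab)
      de_m[[lab]] <- de_screen(bundle$mirna_expr, ga, gb,
                               lfc_threshold = th$mirna_lfc,
                               alpha = th$mirna_alpha, strict_lfc = FALSE,
                               comparison = lab)
    }
    res$de_genes <- do.call(rbind, de_g)
    res$de_mirnas <- do.call(rbind, de_m)
    rownames(res$de_genes) <- rownames(res$de_mirnas) <- NULL
    files <- c(files, write_tsv(res$de_genes, file.path(d, "de_genes.tsv")),
               write_tsv(res$de_mirnas, file.path(d, "de_mirnas.tsv")))
    say("de: genes |log2FC| > ", th$gene_lfc, ", adj P < ", th$gene_alpha,
        "; miRNAs log2FC >= ", th$mirna_lfc, ", FDR < ", th$mirna_alpha,
        " -> ", sum(res$de_genes$is_de), " gene and ",
        sum(res$de_mirnas$is_de), " miRNA DE calls")
  }

  if ("predict-targets" %in% stages) {
    d <- stage_dir(outdir, "predict-targets")
    preds <- predict_targets(bundle$mirnas, bundle$transcripts,
                             max_gaps = th$max_gaps, mfe_min = th$mfe_min,
                             max_score = th$max_score)
    res$predictions <- preds
    files <- c(files, write_tsv(preds, file.path(d, "predictions.tsv")))
    say("predict-targets: ", nrow(preds), " passing sites (energy ratio >= ",
        th$mfe_min, "%, score <= ", th$max_score, ", max_gaps = ",
        th$max_gaps, ")")
  }

  if ("degradome-validate" %in% stages) {
    d <- stage_dir(outdir, "degradome-validate")
    if (is.null(res$predictions)) {
      stop("degradome-validate requires predict-targets outputs; run 'all'",
           call. = FALSE)
    }
    profiles <- lapply(names(bundle$transcripts), function(tid) {
      build_profile(bundle$degradome, tid, nchar(bundle$transcripts[[tid]]))
    })
    names(profiles) <- names(bundle$transcripts)
    calls <- validate_targets(res$predictions, profiles,
                              keep_max_category = th$degradome_keep,
                              max_score = th$max_score)
    res$calls <- calls
    files <- c(files, write_tsv(calls, file.path(d, "calls.tsv")))
    say("degradome-validate: ", sum(calls$kept), " of ", nrow(calls),
        " predictions kept (category <= ", th$degradome_keep, ")")
  }

  if ("coexpr" %in% stages) {
    d <- stage_dir(outdir, "coexpr")
    filt <- filter_expressed(bundle$expression$fpkm, th$expr_min_value,
                             th$expr_min_fraction, th$expr_min_sd)
    mat <- log2(filt$values + 1)
    net <- coexpr_network(mat, trait = bundle$expression$trait,
                          beta = th$power_genes,
                          min_module_size = th$min_module_size,
                          cut_height = th$cut_height,
                          merge_similarity = th$merge_similarity)
    res$gene_coexpr <- net
    files <- c(files,
               write_tsv(data.frame(entity = names(net$labels),
                                    module = unname(net$labels),
                                    kme = unname(net$kme)),
                         file.path(d, "modules.tsv")),
               write_tsv(data.frame(sample = rownames(net$eigengenes),
                                    net$eigengenes, check.names = FALSE),
                         file.path(d, "eigengenes.tsv")))
    if (!is.null(net$trait_assoc)) {
      files <- c(files, write_tsv(net$trait_assoc,
                                  file.path(d, "trait_assoc.tsv")))
    }
    if (!is.null(net$dendro)) {
      write_dendrogram_newick(net$dendro, file.path(d, "dendrogram.nwk"))
      files <- c(files, file.path(d, "dendrogram.nwk"))
    }
    mirna_tpm <- if (!is.null(res$mirna_tpm)) res$mirna_tpm
                 else tpm_normalize(bundle$mirna_expr)
    mfilt <- filter_expressed(mirna_tpm, th$expr_min_value,
                              th$expr_min_fraction, th$expr_min_sd)
    if (nrow(mfilt$values) >= 2) {
      mnet <- coexpr_network(log2(mfilt$values + 1),
                             trait = bundle$expression$trait,
                             beta = th$power_mirnas,
                             min_module_size = th$min_module_size,
                             cut_height = th$cut_height,
                             merge_similarity = th$merge_similarity)
      res$mirna_coexpr <- mnet
      files <- c(files, write_tsv(
        data.frame(entity = names(mnet$labels), module = unname(mnet$labels)),
        file.path(d, "mirna_modules.tsv")))
    }
    say("coexpr: genes -> ",
        length(setdiff(unique(net$labels), "grey")), " modules (power ",
        th$power_genes, ", min size ", th$min_module_size, ", merge ",
        th$merge_similarity, ")")
  }

  if ("enrich" %in% stages) {
    d <- stage_dir(outdir, "enrich")
    if (is.null(res$de_genes)) {
      stop("enrich requires de outputs; run 'all'", call. = FALSE)
    }
    candidates <- unique(res$de_genes$id[res$de_genes$is_de])
    er <- if (length(candidates)) {
      enrich(candidates, bundle$annotations,
             background = rownames(bundle$expression$counts$values))
    } else NULL
    res$enrichment <- er
    if (!is.null(er)) {
      files <- c(files, write_tsv(er, file.path(d, "enrichment.tsv")))
    }
    say("enrich: ", if (is.null(er)) 0 else sum(er$significant),
        " significant terms at FDR <= 0.05")
  }

  if ("network" %in% stages) {
    d <- stage_dir(outdir, "network")
    if (is.null(res$calls) || is.null(res$de_mirnas) ||
        is.null(res$gene_coexpr)) {
      stop("network requires de, degradome-validate and coexpr outputs; ",
           "run 'all'", call. = FALSE)
    }
    demirs <- unique(res$de_mirnas$id[res$de_mirnas$is_de])
    pairs <- mirna_tf_pairs(res$calls, bundle$tf_annotation, demirs)
    assoc <- res$gene_coexpr$trait_assoc
    trait_mods <- assoc$module[abs(assoc$r) >= th$trait_r_min]
    filt <- filter_expressed(bundle$expression$fpkm, th$expr_min_value,
                             th$expr_min_fraction, th$expr_min_sd)
    mat <- log2(filt$values + 1)
    net <- assemble_network(pairs, mat, res$gene_coexpr$labels, trait_mods,
                            k_neighbors = th$k_neighbors,
                            de_genes = unique(
                              res$de_genes$id[res$de_genes$is_de]))
    res$network <- net
    res$targeting_pairs <- pairs
    paths <- write_network(net, file.path(d, "network"))
    files <- c(files, paths)
    say("network: ", nrow(net$nodes), " nodes / ", nrow(net$edges),
        " edges across trait modules [",
        paste(trait_mods, collapse = ", "), "]")
  }

  if ("phenology" %in% stages) {
    d <- stage_dir(outdir, "phenology")
    phen <- res$phenology_inputs
    ch <- chilling_hours(phen$temperature)
    rel <- endodormancy_release_date(phen$observations)
    res$chilling <- ch
    res$release_date <- rel
    files <- c(files,
               write_tsv(ch, file.path(d, "chilling_hours.tsv")),
               write_tsv(data.frame(release_date = as.character(rel),
                                    total_ch = max(ch$ch)),
                         file.path(d, "release.tsv")))
    say("phenology: ", max(ch$ch), " chilling hours (0-7.2 C band); ",
        "endodormancy release on ", as.character(rel))
  }

  cfg_file <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_file)
  manifest <- data.frame(
    file = sub(paste0("^", outdir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  attr(manifest, "config_md5") <- unname(tools::md5sum(cfg_file))
  attr(manifest, "seed") <- config$seed
  attr(manifest, "version") <- as.character(
    utils::packageVersion("mirnet"))
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  res$manifest <- manifest
  invisible(res)
}
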