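# Synthetic-data generator: emulates the statistical structure of a
# 4-stage x 3-replicate bud-break expression study with block-correlated
# planted co-expression modules, a trait-associated module, planted miRNA
# target sites of controlled mismatch/G:U/position patterns, and degradome
# 5'-end peaks at the planted cleavage sites over Poisson background noise.
# Every generator is deterministic given the config seed.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate the
#' study design the package targets: 4 stages x 3 replicates, three planted
#' co-expression modules at within-module correlation 0.8 with one
#' trait-associated module, negative-binomial counts, and planted duplex
#' sites with controlled defect patterns.
#'
#' @param seed integer RNG seed; the single source of randomness.
#' @param n_genes total genes (default 600).
#' @param n_mirnas background miRNAs in the expression matrix in addition to
#'   the planted-site miRNAs (default 20).
#' @param stages stage labels (default EndodorI, EndodorII, Ecodor, Bflush).
#' @param reps_per_stage biological replicates per stage (default 3).
#' @param n_modules planted modules (default 3).
#' @param within_module_cor target pairwise correlation of module members on
#'   the log2 scale (default 0.8).
#' @param trait_module_index which planted module drives the trait
#'   (1-based; default 1).
#' @param n_noise_genes genes with no module structure (default 150).
#' @param n_de_genes planted differentially expressed genes, drawn from the
#'   noise pool so the module structure is undisturbed (default 50).
#' @param de_effect_log2fc planted absolute log2 fold change (default 3;
#'   large single-stage bumps of the kind developmental transitions show,
#'   detectable at three replicates under a conservative small-sample test).
#'   Each planted DE gene carries one expression bump at a single stage
#'   (cycling over the non-initial stages with alternating sign), so planted
#'   effects spread over every adjacent-stage comparison without creating a
#'   shared expression pattern large enough to form a spurious module.
#' @param nb_dispersion negative-binomial dispersion (default 0.05).
#' @param transcript_length_range transcript length bounds in nt
#'   (default 300--600).
#' @param planted_site_spec list of site descriptors (see
#'   [default_site_specs()]); NULL uses the defaults.
#' @param degradome_peak_height 5'-end tag count planted at validated
#'   cleavage sites (default 50).
#' @param degradome_noise_rate per-position Poisson rate of background
#'   degradome tags (default 0.2).
#' @param latent_sd_log2 standard deviation of the latent log2 expression
#'   signal (default 1).
#' @param mirna_de_log2fc planted absolute log2 fold change of the
#'   planted-edge miRNAs (default 3; plant-miRNA stage swings are commonly
#'   larger than gene-level ones).
#' @param base_log2_mean range of baseline log2 FPKM means (default 5--9).
#' @param trait_noise_frac trait noise SD as a fraction of the latent factor
#'   SD (default 0.1).
#' @param mirna_length mature miRNA length (default 21).
#' @param n_tf_targets planted miRNA -> transcription-factor edges in the
#'   trait module (default 10).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 600L, n_mirnas = 20L,
                       stages = c("EndodorI", "EndodorII", "Ecodor",
                                  "Bflush"),
                       reps_per_stage = 3L, n_modules = 3L,
                       within_module_cor = 0.8, trait_module_index = 1L,
                       n_noise_genes = 150L, n_de_genes = 50L,
                       de_effect_log2fc = 3,
                       nb_dispersion = 0.05,
                       transcript_length_range = c(300L, 600L),
                       planted_site_spec = NULL,
                       degradome_peak_height = 50L,
                       degradome_noise_rate = 0.2,
                       latent_sd_log2 = 1, base_log2_mean = c(5, 9),
                       mirna_de_log2fc = 3,
                       trait_noise_frac = 0.1, mirna_length = 21L,
                       n_tf_targets = 10L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_mirnas = as.integer(n_mirnas), stages = stages,
              reps_per_stage = as.integer(reps_per_stage),
              n_modules = as.integer(n_modules),
              within_module_cor = within_module_cor,
              trait_module_index = as.integer(trait_module_index),
              n_noise_genes = as.integer(n_noise_genes),
              n_de_genes = as.integer(n_de_genes),
              de_effect_log2fc = de_effect_log2fc,
              nb_dispersion = nb_dispersion,
              transcript_length_range = as.integer(transcript_length_range),
              planted_site_spec = planted_site_spec,
              degradome_peak_height = as.integer(degradome_peak_height),
              degradome_noise_rate = degradome_noise_rate,
              latent_sd_log2 = latent_sd_log2,
              mirna_de_log2fc = mirna_de_log2fc,
              base_log2_mean = base_log2_mean,
              trait_noise_frac = trait_noise_frac,
              mirna_length = as.integer(mirna_length),
              n_tf_targets = as.integer(n_tf_targets))
  with(cfg, {
    if (n_genes <= 0 || reps_per_stage <= 0 || length(stages) == 0 ||
        n_modules <= 0) {
      stop("non-positive simulation dimensions", call. = FALSE)
    }
    if (within_module_cor < 0 || within_module_cor > 1) {
      stop("within_module_cor must be in [0, 1]", call. = FALSE)
    }
    if (trait_module_index < 1 || trait_module_index > n_modules) {
      stop("trait_module_index must index a planted module", call. = FALSE)
    }
    if (n_noise_genes >= n_genes) {
      stop("n_noise_genes must leave genes for the modules", call. = FALSE)
    }
    if (n_de_genes > n_noise_genes) {
      stop("planted DE genes are drawn from the noise pool", call. = FALSE)
    }
    if (nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
    if (degradome_noise_rate < 0) {
      stop("degradome_noise_rate must be >= 0", call. = FALSE)
    }
    if (length(stages) < 2) {
      stop("at least two stages are required", call. = FALSE)
    }
  })
  class(cfg) <- "sim_config"
  cfg
}

random_rna <- function(n, alphabet = RNA_BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

pad_id <- function(prefix, i, width = 4) sprintf("%s_%0*d", prefix, width, i)

# ---- expression -----------------------------------------------------------

sim_expression_impl <- function(config) {
  ns <- length(config$stages) * config$reps_per_stage
  stage <- rep(config$stages, each = config$reps_per_stage)
  repl <- rep(seq_len(config$reps_per_stage), length(config$stages))
  samples <- paste(stage, repl, sep = "_")
  genes <- pad_id("gene", seq_len(config$n_genes))

  n_mod_genes <- config$n_genes - config$n_noise_genes
  per_mod <- n_mod_genes %/% config$n_modules
  module <- integer(config$n_genes)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    module[idx:(idx + per_mod - 1L)] <- m
    idx <- idx + per_mod
  }
  names(module) <- genes

  # Stage-structured latent factor per module: a stage-level mean plus
  # within-stage jitter. Factors are orthogonalized across modules (QR) so
  # planted modules are mutually distinct -- with only a handful of stages,
  # independently drawn factors can correlate strongly by chance -- then
  # standardized to unit variance.
  raw <- vapply(seq_len(config$n_modules), function(m) {
    stage_base <- stats::rnorm(length(config$stages))
    rep(stage_base, each = config$reps_per_stage) + 0.5 * stats::rnorm(ns)
  }, numeric(ns))
  q <- qr.Q(qr(scale(raw, center = TRUE, scale = FALSE)))
  latent <- t(apply(q, 2, function(col) as.numeric(scale(col))))
  colnames(latent) <- samples

  mu_g <- stats::runif(config$n_genes, config$base_log2_mean[1],
                       config$base_log2_mean[2])
  lens <- as.integer(round(stats::runif(config$n_genes,
                                        config$transcript_length_range[1],
                                        config$transcript_length_range[2])))
  names(lens) <- genes
  lib_size <- round(stats::runif(ns, 1.5e6, 2.5e6))

  # Counting noise attenuates the log-scale correlation below the latent
  # value; compensate so the realized pairwise correlation of module
  # members matches within_module_cor.
  mu_count_bar <- 2^mu_g * (lens / 1000) * mean(lib_size) / 1e6
  noise_var <- (1 / mu_count_bar + config$nb_dispersion) / log(2)^2
  atten <- config$latent_sd_log2^2 /
    (config$latent_sd_log2^2 + noise_var)
  rho_eff <- pmin(config$within_module_cor / atten, 1)

  z <- matrix(stats::rnorm(config$n_genes * ns), config$n_genes, ns)
  x <- z
  for (m in seq_len(config$n_modules)) {
    sel <- module == m
    x[sel, ] <- sqrt(rho_eff[sel]) * matrix(latent[m, ], sum(sel), ns,
                                            byrow = TRUE) +
      sqrt(1 - rho_eff[sel]) * z[sel, ]
  }
  # The first member of each module is the planted hub: a noiseless
  # reporter of the latent factor (loading 1, high expression, negligible
  # overdispersion below), so the top-membership rule has an unambiguous
  # ground truth.
  hubs <- character(config$n_modules)
  for (m in seq_len(config$n_modules)) {
    first <- which(module == m)[1]
    x[first, ] <- latent[m, ]
    mu_g[first] <- config$base_log2_mean[2]
    hubs[m] <- genes[first]
  }

  log2_expr <- mu_g + config$latent_sd_log2 * x

  # Planted DE genes come from the noise pool (the tail of the gene list).
  # Their latent log2 noise is suppressed so the realized fold change
  # reflects the planted effect plus counting noise only. Each gene gets a
  # single-stage expression bump; bump stages cycle over the non-initial
  # stages and signs alternate, so no group of planted genes shares a
  # pattern in numbers that could form a module of its own.
  noise_ids <- genes[module == 0]
  de_ids <- utils::tail(noise_ids, config$n_de_genes)
  n_de <- length(de_ids)
  de_sign <- rep_len(c(1, -1), n_de)
  bump_idx <- rep_len(seq_along(config$stages)[-1], n_de)
  if (n_de) {
    rows <- match(de_ids, genes)
    log2_expr[rows, ] <- mu_g[rows]
    for (j in seq_len(n_de)) {
      sel_b <- stage == config$stages[bump_idx[j]]
      log2_expr[rows[j], sel_b] <- log2_expr[rows[j], sel_b] +
        de_sign[j] * config$de_effect_log2fc
    }
  }

  true_fpkm <- 2^log2_expr
  mu_count <- sweep(true_fpkm * (lens / 1000), 2, lib_size / 1e6, "*")
  disp_g <- rep(config$nb_dispersion, config$n_genes)
  disp_g[match(hubs, genes)] <- min(config$nb_dispersion, 1e-4)
  counts <- matrix(stats::rnbinom(length(mu_count), mu = mu_count,
                                  size = rep(1 / disp_g, ns)),
                   nrow = config$n_genes,
                   dimnames = list(genes, samples))
  fpkm <- sweep(counts / (lens / 1000), 2, lib_size / 1e6, "/")
  dimnames(fpkm) <- list(genes, samples)

  f_trait <- latent[config$trait_module_index, ]
  trait <- f_trait + stats::rnorm(ns, 0, config$trait_noise_frac *
                                    stats::sd(f_trait))
  names(trait) <- samples

  list(counts = expr_matrix(counts, stage, repl, "count"),
       fpkm = expr_matrix(fpkm, stage, repl, "FPKM"),
       trait = trait,
       truth = list(module = module, latent = latent, hubs = hubs,
                    de_genes = data.frame(
                      id = de_ids, sign = de_sign,
                      bump_stage = config$stages[bump_idx],
                      stringsAsFactors = FALSE),
                    lengths = lens, lib_size = lib_size))
}

#' Simulate a gene expression study with planted modules and a trait
#'
#' Module members share a latent per-sample factor giving pairwise log2
#' correlation close to `within_module_cor`; the trait equals the trait
#' module's latent factor plus small noise; counts are negative-binomial
#' around FPKM-derived means; FPKM is recomputed from the realized counts
#' using the true transcript lengths and nominal library sizes; a planted
#' subset of genes carries `de_effect_log2fc` between two chosen stages.
#'
#' @param config a [sim_config()].
#' @return list: `counts` and `fpkm` (`expr_matrix`), `trait` (named
#'   per-sample vector), `truth` (planted module labels, latent factors,
#'   DE genes, lengths, library sizes).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sim_expression_impl(config)
}

# ---- planted target sites -------------------------------------------------

# Literal, self-contained application of the six criteria to a defect
# pattern (used to label the truth table; intentionally independent of the
# alignment engine so the two act as mutual oracles).
literal_verdict <- function(mirna, mismatch, gu) {
  b <- strsplit(normalize_seq(mirna, "RNA"), "")[[1]]
  L <- length(b)
  eff <- rep("WC", L); eff[gu] <- "GU"; eff[mismatch] <- "MM"
  wc_e <- ifelse(b %in% c("G", "C"), -3, -2)
  e <- sum(ifelse(eff == "WC", wc_e, ifelse(eff == "GU", -1, 0)))
  seed <- 2:min(12L, L)
  mm <- eff == "MM"
  v <- list(
    c1 = 100 * e / sum(wc_e) >= 74,
    c2 = sum(mm) + 0.5 * sum(eff == "GU") <= 4,
    c3 = sum(mm[-1] & mm[-L]) <= 2,
    c4 = !any(mm[seed[-length(seed)]] & mm[seed[-length(seed)] + 1L]),
    c5 = !mm[10] && !mm[11],
    c6 = sum(mm[seed] + 0.5 * (eff[seed] == "GU")) <= 2.5)
  v$pass <- all(unlist(v))
  v
}

site_spec <- function(kind, mismatch = integer(), gu = integer(),
                      composition = "random", peak = "high",
                      violates = NA_character_, tf = FALSE) {
  list(kind = kind, mismatch = mismatch, gu = gu,
       composition = composition, peak = peak, violates = violates,
       tf = tf)
}

#' Default planted-site descriptors
#'
#' Builds `n_compliant` criterion-compliant site descriptors (a mix of
#' perfect duplexes and mild defect patterns) and `n_violators` descriptors
#' that each violate exactly one of the six criteria, with at least 8
#' violations per criterion across the set. The miRNA base composition of a
#' descriptor is constrained where the single-violation property requires it
#' (e.g. G/C-rich miRNAs keep the energy ratio above threshold while extra
#' mismatches break only the targeted rule).
#'
#' @param n_compliant compliant descriptors (default 50).
#' @param n_violators single-criterion violators (default 50).
#' @param n_tf among the compliant sites, how many are flagged as planted
#'   miRNA -> transcription-factor edges (default 10).
#' @param n_single_read among the compliant sites, how many receive a
#'   single-read degradome peak instead of a high peak (default 0).
#' @return list of site descriptors.
#' @export
default_site_specs <- function(n_compliant = 50L, n_violators = 50L,
                               n_tf = 10L, n_single_read = 0L) {
  compliant_kinds <- list(
    site_spec("perfect"),
    site_spec("one_gu_seed", gu = 5L, composition = "gu5"),
    site_spec("one_mm_tail", mismatch = 15L),
    site_spec("mm_plus_gu", mismatch = 16L, gu = 5L, composition = "gu5"))
  specs <- lapply(seq_len(n_compliant), function(i) {
    sp <- compliant_kinds[[(i - 1L) %% length(compliant_kinds) + 1L]]
    sp$tf <- i <= n_tf
    if (i > n_compliant - n_single_read) sp$peak <- "single"
    sp
  })
  violator_kinds <- list(
    # c1: eight G:U wobbles at G-bases outside positions 2-12 lose 2 energy
    # units each for only 0.5 score each; with A/U elsewhere the ratio drops
    # to 68% while the score stays at exactly 4 and every positional rule
    # holds.
    c1 = site_spec("v_c1", gu = c(1L, 13:19), composition = "c1_energy",
                   violates = "c1"),
    # c2: nine wobbles in the 3' tail score 4.5 (> 4) but cost little
    # energy and stay outside positions 2-12.
    c2 = site_spec("v_c2", gu = 13:21, composition = "u_tail",
                   violates = "c2"),
    # c3: a run of four mismatches in the tail gives three adjacent
    # mismatch pairs; A/U bases at those positions keep the energy ratio
    # high.
    c3 = site_spec("v_c3", mismatch = 14:17, composition = "au_at_mm",
                   violates = "c3"),
    c4 = site_spec("v_c4", mismatch = c(3L, 4L), violates = "c4"),
    c5 = site_spec("v_c5", mismatch = 10L, violates = "c5"),
    # c6: three spread mismatches inside positions 2-12 weigh 3 > 2.5 but
    # never sit adjacent and avoid 10-11.
    c6 = site_spec("v_c6", mismatch = c(2L, 5L, 8L),
                   composition = "au_at_mm", violates = "c6"))
  counts <- rep(8L, 6)
  extra <- n_violators - sum(counts)
  if (extra < 0) stop("need at least 48 violators", call. = FALSE)
  for (k in seq_len(extra)) {
    j <- (k - 1L) %% 6L + 1L
    counts[j] <- counts[j] + 1L
  }
  viol <- unlist(lapply(seq_along(violator_kinds), function(k) {
    rep(list(violator_kinds[[k]]), counts[k])
  }), recursive = FALSE)
  c(specs, viol)
}

# Generate a miRNA sequence for a site descriptor. Compositions are fully
# random over the four bases except for the minimal per-position forcing a
# descriptor's single-violation property needs; sequence complexity is kept
# high so planted miRNAs never cross-react with other planted sites.
spec_mirna <- function(spec, L) {
  b <- sample(RNA_BASES, L, replace = TRUE)
  comp <- spec$composition
  if (comp == "gu5") {
    b[5] <- "G"
  } else if (comp == "au_at_mm") {
    b[spec$mismatch] <- sample(c("A", "U"), length(spec$mismatch),
                               replace = TRUE)
  } else if (comp == "u_tail") {
    b[spec$gu] <- "U"
  } else if (comp == "c1_energy") {
    b <- sample(c("A", "U"), L, replace = TRUE)
    b[spec$gu] <- "G"
  } else if (comp != "random") {
    stop("unknown miRNA composition ", comp, call. = FALSE)
  }
  paste(b, collapse = "")
}

# Embed the modified reverse complement of a miRNA into a background
# transcript. Mismatches replace the target base with the miRNA base itself
# (never a pairing partner); G:U wobbles replace it so the pair becomes G:U.
plant_site <- function(mirna, tx_len, mismatch, gu) {
  b <- strsplit(mirna, "")[[1]]
  L <- length(b)
  if (any(c(mismatch, gu) < 1) || any(c(mismatch, gu) > L)) {
    stop("site pattern position exceeds miRNA length", call. = FALSE)
  }
  if (length(intersect(mismatch, gu))) {
    stop("a position cannot be both mismatch and wobble", call. = FALSE)
  }
  site <- strsplit(rev_comp_rna(mirna), "")[[1]]
  for (p in mismatch) site[L + 1L - p] <- b[p]
  for (p in gu) {
    site[L + 1L - p] <- switch(b[p], G = "U", U = "G",
      stop("G:U wobble requires a G or U miRNA base at position ", p,
           call. = FALSE))
  }
  start <- sample(seq_len(tx_len - L + 1L), 1)
  bg <- sample(RNA_BASES, tx_len, replace = TRUE)
  bg[start:(start + L - 1L)] <- site
  list(seq = paste(bg, collapse = ""), start = start, end = start + L - 1L)
}

sim_sites_impl <- function(config, specs, transcript_ids = NULL,
                           transcript_lengths = NULL) {
  L <- config$mirna_length
  n <- length(specs)
  if (is.null(transcript_ids)) transcript_ids <- pad_id("tx", seq_len(n))
  stopifnot(length(transcript_ids) == n)
  mirnas <- character(n); txs <- character(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    mid <- pad_id("mir", i, 3)
    mseq <- spec_mirna(sp, L)
    tx_len <- if (!is.null(transcript_lengths)) transcript_lengths[i]
      else as.integer(round(stats::runif(1, config$transcript_length_range[1],
                                         config$transcript_length_range[2])))
    planted <- plant_site(mseq, tx_len, sp$mismatch, sp$gu)
    v <- literal_verdict(mseq, sp$mismatch, sp$gu)
    mirnas[i] <- mseq; txs[i] <- planted$seq
    rows[[i]] <- data.frame(
      mirna_id = mid, transcript_id = transcript_ids[i],
      site_start = planted$start, site_end = planted$end,
      cleave_site = planted$start + L - 10L,
      mismatch = paste(sp$mismatch, collapse = ","),
      gu = paste(sp$gu, collapse = ","),
      c1 = v$c1, c2 = v$c2, c3 = v$c3, c4 = v$c4, c5 = v$c5, c6 = v$c6,
      compliant = v$pass, violates = sp$violates,
      peak = sp$peak, tf = sp$tf, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  names(mirnas) <- truth$mirna_id
  names(txs) <- transcript_ids
  list(mirnas = mirnas, transcripts = txs, truth = truth)
}

#' Simulate transcripts with planted miRNA target sites
#'
#' Each descriptor plants the (modified) reverse complement of a generated
#' miRNA into a random background transcript, introducing the requested
#' mismatches and G:U wobbles at the stated miRNA positions. The truth table
#' records, per site, the literal six-criterion verdict computed directly
#' from the defect pattern.
#'
#' @param config a [sim_config()].
#' @param specs site descriptors; defaults to `config$planted_site_spec` or
#'   [default_site_specs()].
#' @return list: `mirnas` (named RNA vector), `transcripts` (named RNA
#'   vector), `truth` (data.frame with per-site coordinates, patterns,
#'   criterion flags, compliance, peak plan).
#' @export
simulate_target_sites <- function(config, specs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(specs)) specs <- config$planted_site_spec
  if (is.null(specs)) specs <- default_site_specs()
  set.seed(config$seed + 1L)
  sim_sites_impl(config, specs)
}

# ---- degradome ------------------------------------------------------------

sim_degradome_impl <- function(truth, transcripts, config) {
  rows <- list()
  planted <- list()
  for (i in seq_len(nrow(truth))) {
    pk <- truth$peak[i]
    if (identical(pk, "none")) next
    count <- if (identical(pk, "high")) config$degradome_peak_height
             else if (identical(pk, "single")) 1L
             else as.integer(pk)
    tid <- truth$transcript_id[i]
    pos <- truth$cleave_site[i]
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tid, position = pos, count = count,
      stringsAsFactors = FALSE)
    planted[[tid]] <- c(planted[[tid]], pos)
  }
  if (config$degradome_noise_rate > 0) {
    for (tid in names(transcripts)) {
      len <- nchar(transcripts[[tid]])
      noise <- stats::rpois(len, config$degradome_noise_rate)
      noise[planted[[tid]]] <- 0L
      nz <- which(noise > 0)
      if (length(nz)) {
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = tid, position = nz, count = noise[nz],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(transcript_id = character(), position = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a degradome tag table for planted sites
#'
#' Places a 5'-end peak of `degradome_peak_height` tags at the cleavage
#' position (the transcript coordinate paired with miRNA position 10) of
#' every planted site whose `peak` plan is `"high"` (or a single tag for
#' `"single"`), and scatters Poisson background tags elsewhere. Background
#' noise never lands on a planted position, so the planted category is
#' controlled by the peak height alone.
#'
#' @param truth planted-site truth table from [simulate_target_sites()].
#' @param transcripts named transcript sequences.
#' @param config a [sim_config()].
#' @return data.frame: `transcript_id`, `position` (1-based), `count`.
#' @export
simulate_degradome <- function(truth, transcripts, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sim_degradome_impl(truth, transcripts, config)
}

# ---- miRNA expression and the full bundle ---------------------------------

sim_mirna_expression_impl <- function(config, site_mirna_ids, de_mirna_ids) {
  ns <- length(config$stages) * config$reps_per_stage
  stage <- rep(config$stages, each = config$reps_per_stage)
  repl <- rep(seq_len(config$reps_per_stage), length(config$stages))
  samples <- paste(stage, repl, sep = "_")
  ids <- c(site_mirna_ids, pad_id("bgmir", seq_len(config$n_mirnas), 3))
  mu <- 2^stats::runif(length(ids), 6, 10)
  log2_mu <- matrix(log2(mu), length(ids), ns,
                    dimnames = list(ids, samples))
  de_sign <- rep_len(c(-1, 1), length(de_mirna_ids))
  sel_b <- stage == config$stages[2]
  log2_mu[de_mirna_ids, sel_b] <- log2_mu[de_mirna_ids, sel_b] +
    de_sign * config$mirna_de_log2fc
  counts <- matrix(stats::rnbinom(length(log2_mu), mu = 2^log2_mu,
                                  size = 1 / config$nb_dispersion),
                   nrow = length(ids), dimnames = dimnames(log2_mu))
  list(counts = expr_matrix(counts, stage, repl, "count"),
       de_mirnas = data.frame(id = de_mirna_ids, sign = de_sign,
                              stringsAsFactors = FALSE))
}

make_annotations_impl <- function(genes, planted_genes, n_terms = 15L,
                                  term_size = c(20L, 60L)) {
  rows <- list(data.frame(entity = planted_genes, term = "TERM:0001",
                          name = "planted process", namespace = "BP",
                          stringsAsFactors = FALSE))
  for (k in 2:n_terms) {
    sz <- sample(seq(term_size[1], term_size[2]), 1)
    rows[[k]] <- data.frame(entity = sample(genes, sz),
                            term = sprintf("TERM:%04d", k),
                            name = sprintf("background process %d", k),
                            namespace = "BP", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

TF_FAMILIES <- c("MADS", "AP2/ERF", "HD-ZIP", "SBP", "GRAS", "TCP", "MYB",
                 "NAC", "ARF", "GRF")

#' Simulate the full synthetic study bundle
#'
#' Runs every generator off one seeded stream in a fixed order: gene
#' expression with planted modules and trait, planted miRNA target sites
#' (compliant sites attached to genes -- the trait-module sites annotated as
#' transcription factors -- and single-criterion violators), miRNA
#' expression with the planted-edge miRNAs differentially expressed,
#' degradome tags, term annotations, and the planted miRNA -> TF edge truth.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `config`, `expression`
#'   (counts/fpkm/trait/truth), `mirnas`, `transcripts`, `truth_sites`,
#'   `degradome`, `mirna_expr`, `de_mirnas`, `tf_annotation`, `annotations`,
#'   `truth_edges`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  expr <- sim_expression_impl(config)

  specs <- config$planted_site_spec
  if (is.null(specs)) specs <- default_site_specs(n_tf = config$n_tf_targets)
  n_sites <- length(specs)
  if (n_sites > config$n_genes) {
    stop("more planted sites than genes", call. = FALSE)
  }
  # Attach planted sites to genes: TF sites to trait-module members, the
  # rest to subsequent genes in id order.
  trait_members <- names(expr$truth$module)[
    expr$truth$module == config$trait_module_index]
  tf_idx <- which(vapply(specs, function(s) isTRUE(s$tf), logical(1)))
  other_idx <- setdiff(seq_len(n_sites), tf_idx)
  target_genes <- character(n_sites)
  if (length(tf_idx) > length(trait_members)) {
    stop("more TF sites than trait-module genes", call. = FALSE)
  }
  target_genes[tf_idx] <- trait_members[seq_along(tf_idx)]
  remaining <- setdiff(names(expr$truth$module), target_genes[tf_idx])
  target_genes[other_idx] <- remaining[seq_along(other_idx)]

  sites <- sim_sites_impl(config, specs, transcript_ids = target_genes,
                          transcript_lengths =
                            expr$truth$lengths[target_genes])

  tf_sites <- sites$truth[sites$truth$tf, , drop = FALSE]
  mir_expr <- sim_mirna_expression_impl(config, names(sites$mirnas),
                                        tf_sites$mirna_id)

  degradome <- sim_degradome_impl(sites$truth, sites$transcripts, config)

  annotations <- make_annotations_impl(rownames(expr$counts$values),
                                       trait_members)

  tf_annotation <- data.frame(
    gene_id = tf_sites$transcript_id,
    family = rep_len(TF_FAMILIES, nrow(tf_sites)),
    stringsAsFactors = FALSE)

  truth_edges <- data.frame(mirna_id = tf_sites$mirna_id,
                            target_id = tf_sites$transcript_id,
                            stringsAsFactors = FALSE)

  structure(list(config = config, expression = expr,
                 mirnas = sites$mirnas, transcripts = sites$transcripts,
                 truth_sites = sites$truth, degradome = degradome,
                 mirna_expr = mir_expr$counts,
                 de_mirnas = mir_expr$de_mirnas,
                 tf_annotation = tf_annotation,
                 annotations = annotations,
                 truth_edges = truth_edges),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("synthetic study bundle (seed ", x$config$seed, "): ",
      nrow(x$expression$counts$values), " genes x ",
      ncol(x$expression$counts$values), " samples, ",
      length(x$mirnas), " planted miRNAs, ",
      sum(x$truth_sites$compliant), " compliant / ",
      sum(!x$truth_sites$compliant), " violator sites, ",
      nrow(x$truth_edges), " planted miRNA->TF edges\n", sep = "")
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Writes the standard pipeline inputs: `transcripts.fasta`, `mirnas.fasta`,
#' `counts.tsv`, `fpkm.tsv`, `mirna_counts.tsv`, `samples.tsv`, `trait.tsv`,
#' `degradome.tsv`, `truth_sites.tsv`, `tf_annotation.tsv`,
#' `annotations.tsv`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(bundle$transcripts, p("transcripts.fasta"))
  write_fasta(bundle$mirnas, p("mirnas.fasta"))
  wt <- function(x, f) utils::write.table(x, p(f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  wm <- function(em, f) {
    df <- data.frame(id = rownames(em$values), em$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
    wt(df, f)
  }
  wm(bundle$expression$counts, "counts.tsv")
  wm(bundle$expression$fpkm, "fpkm.tsv")
  wm(bundle$mirna_expr, "mirna_counts.tsv")
  wt(bundle$expression$counts$samples, "samples.tsv")
  wt(data.frame(sample = names(bundle$expression$trait),
                trait = bundle$expression$trait), "trait.tsv")
  wt(bundle$degradome, "degradome.tsv")
  wt(bundle$truth_sites, "truth_sites.tsv")
  wt(bundle$tf_annotation, "tf_annotation.tsv")
  wt(bundle$annotations, "annotations.tsv")
  invisible(dir)
}
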