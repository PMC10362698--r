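# End-to-end driver: prep -> train -> embed -> fit-gp -> generate -> screen,
# with input-hash stage caching and a one-command synthetic demo.

#' Default pipeline configuration
#'
#' Returns the resolved configuration list for [run_pipeline()]. Either
#' `msa` (aligned FASTA path) and `fitness` (2-column TSV id/fitness) are
#' given, or `simulate` is a list passed to [simulate_family()] and the
#' pipeline starts from a synthetic family. Any element can be overridden
#' via `...` (nested lists are replaced wholesale).
#'
#' @param out Output directory.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param ... Overrides: `msa`, `fitness`, `simulate`, `max_gap_frac`,
#'   `train` (passed to [train_config()]), `tcn` (passed to [tcn_config()]),
#'   `gp` (list: `test_frac`), `generate` (list: `n`, `scale`,
#'   `window_width`), `verbose`.
#' @return A named configuration list.
#' @export
pipeline_config <- function(out, seed = 42L, ...) {
  cfg <- list(
    out = out, seed = as.integer(seed),
    msa = NULL, fitness = NULL,
    simulate = NULL,
    max_gap_frac = 0.2,
    train = list(epochs = 600L, dim_z = 2L, hidden_layer = 64L,
                 learning_rate = 2e-3, weight_decay = 1e-4, batch_size = 128L),
    tcn = list(n_blocks = 2L, hidden_channels = 24L, out_channels = 48L,
               dropout = 0.2),
    gp = list(test_frac = 0.2),
    generate = list(n = 600L, scale = 1, window_width = 2.3),
    verbose = FALSE
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  cfg
}

.stage_key <- function(...) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(list(...), f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

.stage_cached <- function(manifest, stage, key, outputs) {
  !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]]$key, key) &&
    all(file.exists(outputs))
}

.log_stage <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline
#'
#' Executes prep, train, embed, fit-gp, generate and screen in order,
#' skipping stages whose inputs (configuration plus input-file hashes) are
#' unchanged since the previous run in the same output directory. A
#' manifest with per-stage keys and output hashes, and a serialized copy of
#' the resolved configuration, are written next to the artifacts.
#'
#' @param cfg Configuration from [pipeline_config()].
#' @return The manifest list (stages, artifact hashes), invisibly; artifacts
#'   land under `cfg$out`.
#' @export
run_pipeline <- function(cfg) {
  out <- cfg$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  verbose <- isTRUE(cfg$verbose)

  if (is.null(cfg$simulate) && (is.null(cfg$msa) || !file.exists(cfg$msa)))
    stop("config error: either 'simulate' or an existing 'msa' path is required")
  if (!is.null(cfg$fitness) && !file.exists(cfg$fitness))
    stop("config error: fitness table not found: ", cfg$fitness)

  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  } else list(stages = list())
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))

  paths <- list(
    sim = file.path(out, "sim"),
    clean = file.path(out, "clean.fasta"),
    weights = file.path(out, "weights.tsv"),
    ckpt = file.path(out, "model.ckpt"),
    latent = file.path(out, "latent.tsv"),
    gp = file.path(out, "gp.rds"),
    gp_metrics = file.path(out, "gp_metrics.json"),
    var_fasta = file.path(out, "variants.fasta"),
    var_report = file.path(out, "variants.tsv"),
    screened = file.path(out, "screened.tsv"),
    summary = file.path(out, "summary.json")
  )

  # ---- stage: simulate (optional) ----
  fitness_tab <- NULL
  labels <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    key <- .stage_key("simulate", sim_args)
    sim_files <- file.path(paths$sim, c("family.fasta", "tree.nwk",
                                        "labels.tsv", "fitness.tsv"))
    if (!.stage_cached(manifest, "simulate", key, sim_files)) {
      .log_stage(verbose, "simulate", "generating synthetic family")
      sim <- do.call(simulate_family, sim_args)
      write_sim_family(sim, paths$sim)
      manifest$stages$simulate <- list(key = key)
    } else .log_stage(verbose, "simulate", "cached")
    msa_path <- sim_files[1]
    fitness_path <- sim_files[4]
    labels <- utils::read.delim(sim_files[3])
  } else {
    msa_path <- cfg$msa
    fitness_path <- cfg$fitness
  }
  if (!is.null(fitness_path) && file.exists(fitness_path))
    fitness_tab <- utils::read.delim(fitness_path)

  # ---- stage: prep ----
  key <- .stage_key("prep", tools::md5sum(msa_path), cfg$max_gap_frac)
  if (!.stage_cached(manifest, "prep", key, c(paths$clean, paths$weights))) {
    .log_stage(verbose, "prep", "cleaning and weighting")
    raw <- read_aligned_fasta(msa_path)
    fam <- as_aligned_family(clean_family(raw, cfg$max_gap_frac))
    write_aligned_fasta(fam, paths$clean)
    write_weights_tsv(fam, paths$weights)
    manifest$stages$prep <- list(key = key)
  } else .log_stage(verbose, "prep", "cached")
  fam <- as_aligned_family(read_aligned_fasta(paths$clean),
                           weights = utils::read.delim(paths$weights)$weight)

  # ---- stage: train ----
  tcn <- do.call(tcn_config, cfg$tcn)
  tr <- do.call(train_config, utils::modifyList(cfg$train,
                                                list(seed = cfg$seed)))
  key <- .stage_key("train", tools::md5sum(c(paths$clean, paths$weights)),
                    tr, tcn)
  if (!.stage_cached(manifest, "train", key, paths$ckpt)) {
    .log_stage(verbose, "train", sprintf("training %d epochs", tr$epochs))
    model <- vae_train(fam, tr, tcn, verbose = verbose)
    save_checkpoint(model, paths$ckpt)
    manifest$stages$train <- list(key = key)
  } else .log_stage(verbose, "train", "cached")
  model <- load_checkpoint(paths$ckpt)

  # ---- stage: embed ----
  key <- .stage_key("embed", tools::md5sum(c(paths$ckpt, paths$clean)))
  if (!.stage_cached(manifest, "embed", key, paths$latent)) {
    .log_stage(verbose, "embed", "embedding family")
    emb <- embed_family(fam, model)
    utils::write.table(data.frame(id = rownames(emb), emb), paths$latent,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$embed <- list(key = key)
  } else .log_stage(verbose, "embed", "cached")
  latent <- utils::read.delim(paths$latent)
  emb <- as.matrix(latent[, -1, drop = FALSE])
  rownames(emb) <- latent$id

  # ---- stage: fit-gp ----
  gp <- NULL
  gp_metrics <- NULL
  if (!is.null(fitness_tab)) {
    key <- .stage_key("fit_gp", tools::md5sum(paths$latent),
                      tools::md5sum(fitness_path), cfg$gp)
    if (!.stage_cached(manifest, "fit_gp", key, c(paths$gp, paths$gp_metrics))) {
      .log_stage(verbose, "fit_gp", "fitting Gaussian process")
      joined <- merge(latent, fitness_tab, by = "id")
      z <- as.matrix(joined[, grep("^z", names(joined)), drop = FALSE])
      y <- joined[[setdiff(names(fitness_tab), "id")[1]]]
      sp <- train_test_split(nrow(joined), cfg$gp$test_frac, seed = cfg$seed)
      gp <- fit_gp(z[sp$train, , drop = FALSE], y[sp$train], seed = cfg$seed)
      pr <- gp_predict(gp, z[sp$test, , drop = FALSE])
      met <- eval_metrics(pr$mean, y[sp$test])
      gp_metrics <- list(pearson = met$pearson, mad = met$mad,
                         n_train = length(sp$train), n_test = length(sp$test),
                         seed = cfg$seed)
      saveRDS(gp, paths$gp)
      jsonlite::write_json(gp_metrics, paths$gp_metrics, auto_unbox = TRUE,
                           digits = NA)
      manifest$stages$fit_gp <- list(key = key)
    } else .log_stage(verbose, "fit_gp", "cached")
    gp <- readRDS(paths$gp)
    gp_metrics <- jsonlite::read_json(paths$gp_metrics)
  }

  # ---- stage: generate + screen ----
  screen_summary <- NULL
  if (!is.null(gp)) {
    joined <- merge(latent, fitness_tab, by = "id")
    ycol <- setdiff(names(fitness_tab), "id")[1]
    ref_id <- joined$id[which.max(joined[[ycol]])]
    key <- .stage_key("generate", tools::md5sum(c(paths$ckpt, paths$gp)),
                      cfg$generate, ref_id)
    if (!.stage_cached(manifest, "generate", key,
                       c(paths$var_fasta, paths$var_report, paths$screened,
                         paths$summary))) {
      .log_stage(verbose, "generate",
                 sprintf("sampling %d variants around %s",
                         cfg$generate$n, ref_id))
      ref_row <- fam$matrix[match(ref_id, fam$ids), ]
      vars <- generate_variants(model, gp, ref_row, n = cfg$generate$n,
                                scale = cfg$generate$scale, seed = cfg$seed)
      write_variants(vars, paths$var_fasta, paths$var_report)
      lower <- max(joined[[ycol]])
      upper <- lower + cfg$generate$window_width
      kept <- screen_variants(vars, lower, upper)
      utils::write.table(
        kept[, c("id", "predicted_fitness", "global_identity",
                 "local_identity")],
        paths$screened, sep = "\t", quote = FALSE, row.names = FALSE)
      screen_summary <- list(
        reference = ref_id, lower = lower, upper = upper,
        n_generated = nrow(vars), n_screened = nrow(kept),
        mean_global_identity = mean(vars$global_identity),
        max_global_identity = max(vars$global_identity),
        mean_local_identity = mean(vars$local_identity))
      if (!is.null(labels)) {
        lab <- labels$clade[match(rownames(emb), labels$id)]
        screen_summary$silhouette <-
          latent_separation_score(emb, lab)
      }
      summary <- c(list(seed = cfg$seed, n_sequences = nrow(fam$matrix),
                        L = fam$L),
                   gp_metrics[setdiff(names(gp_metrics), "seed")],
                   screen_summary)
      jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                           digits = NA)
      manifest$stages$generate <- list(key = key)
    } else .log_stage(verbose, "generate", "cached")
  }

  # artifact manifest with content hashes
  arts <- unlist(paths)
  arts <- arts[file.exists(arts) & !dir.exists(arts)]
  manifest$artifacts <- as.list(tools::md5sum(arts))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  invisible(manifest)
}

#' One-command synthetic demo
#'
#' Simulates a 300-leaf, 4-ish-clade family (L = 60), trains a small
#' 2-dimensional T-VAE, fits the fitness GP, generates and screens variants,
#' and returns the summary (silhouette, GP Pearson/MAD, identity statistics,
#' screen counts). Desk-scale by construction: a few minutes on one CPU.
#'
#' @param seed Global seed.
#' @param out Output directory.
#' @param ... Configuration overrides forwarded to [pipeline_config()].
#' @return The summary list (also at `out/summary.json`).
#' @export
run_demo <- function(seed = 42L, out = tempfile("tvae_demo_"), ...) {
  cfg <- pipeline_config(
    out = out, seed = seed,
    simulate = list(n_leaves = 300L, L = 60L, rate = 0.3, n_clades = 4L,
                    noise_sd = 0.5),
    ...)
  run_pipeline(cfg)
  jsonlite::read_json(file.path(out, "summary.json"), simplifyVector = TRUE)
}
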