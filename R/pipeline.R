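# Config-driven orchestration: descriptors -> statistics -> interactions ->
# clustering -> per-cluster reports -> optional reweighting, with seeds and
# a machine-readable run manifest.

# Small deterministic config hash (FNV-1a over the deparsed config) so every
# output file can be traced to the configuration that produced it.
.config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "\n")
  h <- 216613626  # stays below 2^31 so bitwXor sees valid integers
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks plus dry-run file existence; all
#' violations are collected and returned (empty character vector when the
#' configuration is valid).
#'
#' @param config pipeline configuration list; see [run_pipeline()].
#' @return character vector of diagnostics.
#' @export
validate_config <- function(config) {
  diag <- character(0)
  if (is.null(config$ensembles) || !length(config$ensembles))
    diag <- c(diag, "no ensembles specified")
  labs <- names(config$ensembles)
  if (!is.null(labs) && anyDuplicated(labs))
    diag <- c(diag, "ensemble labels are not unique")
  for (nm in labs) {
    e <- config$ensembles[[nm]]
    if (!is.null(e$path)) {
      if (!file.exists(e$path))
        diag <- c(diag, paste0("ensemble '", nm, "': missing file ", e$path))
      if (is.null(e$topology))
        diag <- c(diag, paste0("ensemble '", nm, "': no topology given"))
      else if (is.character(e$topology) && !file.exists(e$topology))
        diag <- c(diag, paste0("ensemble '", nm, "': missing topology ",
                               e$topology))
    } else if (is.null(e$generator)) {
      diag <- c(diag, paste0("ensemble '", nm,
                             "': needs either a path or a generator config"))
    }
  }
  if (!is.null(config$cluster)) {
    if (!length(config$cluster$perplexities))
      diag <- c(diag, "cluster: empty perplexity grid")
    if (!length(config$cluster$n_values))
      diag <- c(diag, "cluster: empty N grid")
  }
  if (is.null(config$seed)) diag <- c(diag, "no global seed")
  diag
}

#' Run the full analysis pipeline
#'
#' Loads or generates the configured ensembles, then runs per-frame
#' descriptors, free-energy surfaces and subensemble statistics with
#' blocking errors, interaction profiles when a ligand is present, the
#' t-SNE clustering scan with per-cluster reports and cross-source profile
#' r-squared values, and optional maximum-entropy reweighting. All tables
#' are written under `out_dir` with the config hash and stage seeds; a
#' manifest records the run. Deterministic under the global seed: each
#' stage derives its own seed from it.
#'
#' @param config list with elements: `ensembles` (named list, each either
#'   `list(path=, topology=)` or `list(generator = generator_config(...),
#'   ligand_site =)`), `seed` (global integer seed), and optional `cluster`
#'   (`perplexities`, `n_values`, `downsample`), `reweight`
#'   (`observables` path or `ObservableTable`, and `target_kish` or
#'   `theta`), `fes` (`bins`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the computed objects (`ensembles`,
#'   `descriptors`, `summary`, `profiles`, `scan`, `report`, `reweight`).
#' @export
run_pipeline <- function(config, out_dir) {
  diag <- validate_config(config)
  if (length(diag)) stop("invalid pipeline config:\n  ",
                         paste(diag, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  seed <- as.integer(config$seed)
  meta <- function(stage, extra = list())
    c(list(config = hash, seed = seed, stage = stage), extra)
  stage_seed <- function(k) (seed * 13L + k * 7919L) %% 2147483647L

  enss <- list(); truths <- list()
  for (nm in names(config$ensembles)) {
    e <- config$ensembles[[nm]]
    if (!is.null(e$path)) {
      enss[[nm]] <- read_multimodel_pdb(e$path, e$topology)
    } else {
      gen <- e$generator
      out <- sample_ensemble(gen)
      if (!is.null(e$ligand_site)) {
        lig <- attach_pseudo_ligand(out$ensemble, e$ligand_site,
                                    seed = stage_seed(1L), truth = out$truth)
        out$ensemble <- lig$ensemble; out$truth <- lig$truth
      }
      enss[[nm]] <- out$ensemble
      truths[[nm]] <- out$truth
    }
  }

  desc <- list(); summaries <- list()
  bins <- if (is.null(config$fes$bins)) c(40, 40) else config$fes$bins
  for (nm in names(enss)) {
    d <- frame_descriptors(enss[[nm]])
    desc[[nm]] <- d
    write_report(d, file.path(out_dir, paste0("descriptors_", nm, ".tsv")),
                 meta("descriptors"))
    fes <- fes2d(d$salpha, d$rg, enss[[nm]]$weights, bins = bins)
    grid <- expand.grid(x_bin = seq_len(bins[1]), y_bin = seq_len(bins[2]))
    grid$free_energy <- as.vector(fes$free_energy)
    write_report(grid, file.path(out_dir, paste0("fes_", nm, ".tsv")),
                 meta("fes"))
    s <- subensemble_summary(enss[[nm]], seq_len(n_frames(enss[[nm]])), d)
    summaries[[nm]] <- cbind(data.frame(source = nm), s)
  }
  write_report(do.call(rbind, summaries),
               file.path(out_dir, "summary.tsv"), meta("summary"))

  profiles <- list()
  for (nm in names(enss)) {
    if (any(enss[[nm]]$topology$atoms$ligand)) {
      profiles[[nm]] <- interaction_profile(enss[[nm]])
      write_report(as.data.frame(profiles[[nm]]),
                   file.path(out_dir, paste0("interactions_", nm, ".tsv")),
                   meta("interactions"))
    }
  }

  scan <- NULL; report <- NULL
  if (!is.null(config$cluster)) {
    use <- enss
    if (!is.null(config$cluster$downsample))
      use <- lapply(enss, function(e)
        downsample(e, min(config$cluster$downsample, n_frames(e)),
                   mode = "stride")$ensemble)
    D <- rmsd_matrix(use)
    scan <- hyperparameter_scan(D, config$cluster$perplexities,
                                config$cluster$n_values,
                                seed = stage_seed(2L))
    write_report(scan$table, file.path(out_dir, "cluster_scores.tsv"),
                 meta("cluster"))
    lab_df <- cbind(scan$frame_labels, cluster = scan$best$labels)
    write_report(lab_df, file.path(out_dir, "cluster_labels.tsv"),
                 meta("cluster"))
    report <- cluster_report(use, scan$best$labels, scan$frame_labels)
    write_report(report, file.path(out_dir, "cluster_report.tsv"),
                 meta("cluster"))
  }

  rew <- NULL
  if (!is.null(config$reweight)) {
    obs <- config$reweight$observables
    if (is.character(obs)) obs <- read_observable_table(obs)
    ens1 <- names(enss)[1]
    if (is.null(config$reweight$theta)) {
      tuned <- tune_theta(obs, restraints = config$reweight$restraints,
                          target_kish = config$reweight$target_kish)
      rew <- tuned$result
    } else {
      rew <- maxent_fit(obs, restraints = config$reweight$restraints,
                        theta = config$reweight$theta)
    }
    write_report(data.frame(frame = seq_along(rew$weights),
                            weight = rew$weights),
                 file.path(out_dir, "reweight_weights.tsv"),
                 meta("reweight", list(kish = round(rew$kish, 6),
                                       theta = rew$theta)))
  }

  manifest <- list(config_hash = hash, seed = seed,
                   version = as.character(utils::packageVersion("idpensemble")),
                   ensembles = names(enss),
                   stages = c("descriptors", "fes", "summary",
                              if (length(profiles)) "interactions",
                              if (!is.null(scan)) "cluster",
                              if (!is.null(rew)) "reweight"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ensembles = enss, truths = truths, descriptors = desc,
                 summary = do.call(rbind, summaries), profiles = profiles,
                 scan = scan, report = report, reweight = rew))
}
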