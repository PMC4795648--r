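# Orchestration: one config drives stimulus generation, template
# learning and the three experiments, with a manifest for
# reproducibility.

#' Default pipeline configuration
#'
#' Three independent seed streams (stimuli, templates, experiments) so
#' each component can be varied on its own.  Training faces are the
#' odd-numbered identities, test faces the even-numbered ones.
#'
#' @param seed Base seed; the three streams are derived from it.
#' @param n_train,n_test Numbers of training and test identities.
#' @param per_image Templates learnt per training image.
#' @param n_resamples Bootstrap resamples for every experiment.
#' @param cfe_trials,wpe_trials Trial caps.
#' @param fie_faces Number of test faces used by the inversion analyses
#'   (at most `n_test`).
#' @param out_dir Output directory for [run_all()].
#' @return Nested configuration list.
#' @export
run_config <- function(seed = 1L, n_train = 50L, n_test = 20L,
                       per_image = 20L, n_resamples = 1000L,
                       cfe_trials = 60L, wpe_trials = 60L,
                       fie_faces = n_test, out_dir = "holoface-results") {
  list(seeds = list(stimuli = seed, templates = seed + 1000L,
                    experiments = seed + 2000L),
       stimuli = list(n_train = as.integer(n_train),
                      n_test = as.integer(n_test)),
       templates = list(per_image = as.integer(per_image)),
       experiments = list(n_resamples = as.integer(n_resamples),
                          cfe_trials = as.integer(cfe_trials),
                          wpe_trials = as.integer(wpe_trials),
                          fie_faces = as.integer(fie_faces)),
       out_dir = out_dir)
}

#' Run the whole pipeline: generate, learn, simulate
#'
#' Renders training and test faces, learns the template bank at all
#' three tuning sizes, runs the composite-face, inversion (behavioral
#' and neural) and whole-part simulations, writes each result plus a
#' manifest (file list, config hash, package version) to `out_dir`, and
#' returns everything invisibly.  Deterministic given the config.
#'
#' @param config A [run_config()]; may also be the path of a YAML file
#'   with the same structure.
#' @param stim_config A [stim_config()].
#' @param model_config An [hmax_config()].
#' @return Invisibly, a list with the bank, the four experiment results
#'   and the manifest.
#' @export
run_all <- function(config = run_config(),
                    stim_config = holoface::stim_config(),
                    model_config = hmax_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    message("[holoface] ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  n_ids <- 2L * max(config$stimuli$n_train, config$stimuli$n_test)
  train_ids <- seq(1L, by = 2L, length.out = config$stimuli$n_train)
  test_ids <- seq(2L, by = 2L, length.out = config$stimuli$n_test)
  train <- step("render training faces",
                render_identity_set(train_ids, config$seeds$stimuli, stim_config))
  test <- step("render test faces",
               render_identity_set(test_ids, config$seeds$stimuli, stim_config))

  bank <- step("learn template bank",
               learn_bank(train, per_image = config$templates$per_image,
                          seed = config$seeds$templates, config = model_config))

  es <- config$seeds$experiments
  ex <- config$experiments
  cfe <- step("composite face effect",
              run_cfe(bank, test, max_trials = ex$cfe_trials,
                      n_resamples = ex$n_resamples, seed = es,
                      stim_config = stim_config))
  fie_set <- test[seq_len(min(ex$fie_faces, length(test)))]
  c2fie <- step("inversion C2 extraction",
                fie_c2(bank, fie_set, c("large", "medium", "small"),
                       model_config))
  fie_b <- step("face inversion effect (behavioral)",
                run_fie_behavioral(bank, fie_set, n_resamples = ex$n_resamples,
                                   seed = es, c2 = c2fie))
  fie_n <- step("face inversion effect (neural)",
                run_fie_neural(bank, fie_set, band = NULL, seed = es,
                               c2 = c2fie))
  wpe <- step("whole-part effect",
              run_wpe(bank, test, max_trials = ex$wpe_trials,
                      n_resamples = ex$n_resamples, seed = es,
                      stim_config = stim_config))

  results <- list(cfe = cfe, fie_behavioral = fie_b, fie_neural = fie_n,
                  wpe = wpe)
  cfg_hash <- digest_config(config)
  files <- character()
  for (nm in names(results)) {
    path <- file.path(config$out_dir, paste0(nm, ".json"))
    out <- list(summary = results[[nm]]$summary,
                effects = results[[nm]]$effects,
                comparisons = results[[nm]]$comparisons,
                meta = results[[nm]]$meta[setdiff(names(results[[nm]]$meta),
                                                  "label")],
                config_hash = cfg_hash)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, path)
  }
  manifest <- list(files = basename(files), config = config,
                   config_hash = cfg_hash,
                   package_version = as.character(utils::packageVersion("holoface")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(list(bank = bank, manifest = manifest), results))
}

# stable hash of the configuration (order-normalized JSON)
digest_config <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small polynomial rolling hash over the serialized text
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
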