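#' Pipeline configuration
#'
#' Bundles every stage's settings: the cohort specification, the
#' analysis observer, which GLM variants to fit, the GCA settings, how
#' many subjects per group enter the imaging stages, and the master
#' seed from which all stage seeds are derived deterministically.
#'
#' @param cohort a [cohort_spec()].
#' @param observer analysis-observer parameters (defaults to the cohort
#'   observer).
#' @param glm_variants character vector among `"F1"`, `"F2"`, `"G"`.
#' @param n_imaging number of subjects per observed group entering the
#'   GLM and GCA stages (imaging is the expensive part; `Inf` takes
#'   everyone).
#' @param gca list with `p_max`, `n_perm`, `q`.
#' @param presets named list mapping group (`"SEQ"`, `"nSEQ"`) to a
#'   [neural_profile()].
#' @param seed master seed.
#' @return An object of class `sst_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            observer = NULL,
                            glm_variants = c("F1", "F2", "G"),
                            n_imaging = 12,
                            gca = list(p_max = 5, n_perm = 200, q = 0.05),
                            presets = list(SEQ = neural_profile("SEQ_fig4"),
                                           nSEQ = neural_profile("nSEQ_fig4")),
                            seed = 1L) {
  if (is.null(observer)) observer <- cohort$observer
  stopifnot(all(glm_variants %in% c("F1", "F2", "G")),
            all(c("p_max", "n_perm", "q") %in% names(gca)))
  structure(list(cohort = cohort, observer = observer,
                 glm_variants = glm_variants, n_imaging = n_imaging,
                 gca = gca, presets = presets, seed = as.integer(seed)),
            class = "sst_pipeline_config")
}

# Deterministic stage seeds below 2^31, derived from the master seed.
stage_seed <- function(master, stage) {
  (as.integer(master) * 7919L + stage * 104729L) %% 2147483587L
}

#' Run the full analysis pipeline
#'
#' simulate -> P(Stop) -> behavioural metrics and classification ->
#' ROI GLM contrasts -> group GCA -> group comparisons. All stages are
#' deterministic given the configuration and master seed.
#'
#' Subjects are grouped by their *observed* classification (significant
#' positive P(Stop)-goRT correlation) before the imaging stages, and
#' each observed group's BOLD data are generated under that group's
#' neural preset.
#'
#' @param config an [pipeline_config()].
#' @param verbose print stage progress to stderr.
#' @return An object of class `sst_report`: list with `metrics`,
#'   `summary` (group performance table), `glm` (per-subject contrast
#'   effects), `gca` (per-group `sst_gca`), `fisher` (connection count
#'   comparison), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "sst_pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("[simulate] generating cohort (%d + %d subjects)",
      config$cohort$n_seq, config$cohort$n_nseq)
  spec <- config$cohort
  spec$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(spec)

  say("[pstop] recomputing analysis P(Stop)")
  for (i in seq_along(cohort))
    cohort[[i]]$trials <- add_pstop(cohort[[i]]$trials, config$observer)

  say("[behavior] metrics and classification")
  metrics <- cohort_metrics(cohort)
  summary_tab <- group_summary(metrics, group_col = "group")

  # imaging subset: first n per observed group
  sel <- list(SEQ = which(metrics$group == "SEQ"),
              nSEQ = which(metrics$group == "nSEQ"))
  sel <- lapply(sel, function(idx) utils::head(idx, config$n_imaging))

  say("[bold] simulating ROI series (%d + %d subjects)",
      length(sel$SEQ), length(sel$nSEQ))
  bold <- list()
  for (g in names(sel)) {
    bold[[g]] <- lapply(seq_along(sel[[g]]), function(j) {
      i <- sel[[g]][j]
      simulate_roi_bold(cohort[[i]], config$presets[[g]],
                        seed = stage_seed(config$seed, 100L + i))
    })
  }

  say("[glm] fitting %s", paste(config$glm_variants, collapse = "/"))
  glm_rows <- list()
  for (g in names(sel)) {
    for (j in seq_along(sel[[g]])) {
      i <- sel[[g]][j]
      ev <- event_table(cohort[[i]])
      for (v in config$glm_variants) {
        des <- build_design(ev, v, cohort[[i]]$task)
        effects <- if (v == "G") {
          w_slow <- contrast_weights(des, c(GS_x_rt = 1))
          fit <- fit_glm_ar1(bold[[g]][[j]]$x[, "roi_slow"], des)
          fit2 <- fit_glm_ar1(bold[[g]][[j]]$x[, "roi_speed"], des)
          c(slowing = contrast_effect(fit, w_slow),
            speeding = contrast_effect(fit2, -w_slow))
        } else {
          w_p <- contrast_weights(des, c(GS_x_pstop = 1))
          w_f <- contrast_weights(des, c(GS_x_fp = 1))
          fit <- fit_glm_ar1(bold[[g]][[j]]$x[, "roi_pstop"], des)
          fit2 <- fit_glm_ar1(bold[[g]][[j]]$x[, "roi_fp"], des)
          c(pstop = contrast_effect(fit, w_p),
            fp = contrast_effect(fit2, w_f))
        }
        glm_rows[[length(glm_rows) + 1L]] <-
          data.frame(subject = i, group = g, variant = v,
                     contrast = names(effects), effect = unname(effects),
                     stringsAsFactors = FALSE)
      }
    }
  }
  glm_tab <- do.call(rbind, glm_rows)

  say("[gca] group Granger causality (n_perm = %d)", config$gca$n_perm)
  gca <- list()
  for (g in names(sel)) {
    gca[[g]] <- group_gca(bold[[g]], p_max = config$gca$p_max,
                          n_perm = config$gca$n_perm, q = config$gca$q,
                          seed = stage_seed(config$seed,
                                            200L + match(g, names(sel))))
  }
  fisher <- connection_count_comparison(gca$SEQ, gca$nSEQ)

  say("[done] %.1f s elapsed", as.numeric(Sys.time() - t0, units = "secs"))
  structure(list(metrics = metrics, summary = summary_tab,
                 glm = glm_tab, gca = gca, fisher = fisher,
                 config = config),
            class = "sst_report")
}

#' @export
print.sst_report <- function(x, ...) {
  cat("SST pipeline report\n\n")
  print(x$summary)
  cat("\nGCA, SEQ group:\n"); print(x$gca$SEQ)
  cat("\nGCA, nSEQ group:\n"); print(x$gca$nSEQ)
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes all stage tables as tab-delimited text, a machine-readable
#' JSON result file carrying every numeric field plus a provenance
#' block (master seed, configuration hash), and a short human-readable
#' summary.
#'
#' @param report an `sst_report`.
#' @param path output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "sst_report"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(path, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$metrics, "subject_metrics.tsv")
  wt(as.data.frame(unclass(report$summary)), "group_summary.tsv")
  wt(report$glm, "glm_contrasts.tsv")
  for (g in names(report$gca))
    wt(report$gca[[g]]$connections,
       sprintf("gca_connections_%s.tsv", g))
  wt(report$fisher, "fisher_comparisons.tsv")

  cfg_json <- jsonlite::serializeJSON(report$config)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  payload <- list(
    provenance = list(seed = report$config$seed, config_md5 = cfg_hash,
                      package_version =
                        as.character(utils::packageVersion("stopsignal"))),
    group_summary = as.data.frame(unclass(report$summary)),
    gca = lapply(report$gca, function(g) g$connections),
    fisher = report$fisher)
  jsonlite::write_json(payload, file.path(path, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  con <- file(file.path(path, "summary.txt"), "w")
  sink(con); on.exit({ sink(); close(con) }, add = TRUE)
  print(report)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Minimal schema: top-level keys `cohort` (`n_seq`, `n_nseq`, `seed`,
#' and any [task_config()] field under `task`), `observer`
#' ([observer_params()] fields), `glm_variants`, `n_imaging`, `gca`
#' (`p_max`, `n_perm`, `q`), `presets` (group -> preset name), `seed`.
#' Missing keys fall back to package defaults.
#'
#' @param path YAML file.
#' @return An `sst_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  task <- do.call(task_config, as.list(y$task %||% list()))
  obs <- do.call(observer_params, as.list(y$observer %||% list()))
  ch <- y$cohort %||% list()
  cohort <- cohort_spec(n_seq = ch$n_seq %||% 81L,
                        n_nseq = ch$n_nseq %||% 35L,
                        task = task, observer = obs,
                        seed = ch$seed %||% 1L)
  presets <- y$presets %||% list(SEQ = "SEQ_fig4", nSEQ = "nSEQ_fig4")
  presets <- lapply(presets, function(p)
    if (inherits(p, "sst_neural")) p else neural_profile(p))
  pipeline_config(
    cohort = cohort, observer = obs,
    glm_variants = y$glm_variants %||% c("F1", "F2", "G"),
    n_imaging = y$n_imaging %||% 12,
    gca = utils::modifyList(list(p_max = 5, n_perm = 200, q = 0.05),
                            as.list(y$gca %||% list())),
    presets = presets,
    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
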