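#' Default pipeline configuration
#'
#' @param out_dir artifact directory.
#' @param seed master seed; every randomized stage receives a derived,
#'   logged sub-seed.
#' @param sim named list of [sim_params()] overrides.
#' @param scoring named list: `max_edit_distance`, `semantic_possible`.
#' @param stats named list: `n_perm`, `alpha`.
#' @return config list, as read from / written to YAML.
#' @export
default_config <- function(out_dir = "recalldyn_run", seed = 1L,
                           sim = list(), scoring = list(),
                           stats = list()) {
  utils::modifyList(
    list(out_dir = out_dir, seed = as.integer(seed), sim = list(),
         scoring = list(max_edit_distance = 1L,
                        semantic_possible = "available"),
         stats = list(n_perm = 10000L, alpha = 0.05)),
    list(sim = sim, scoring = scoring, stats = stats)
  )
}

# deterministic per-stage sub-seed, kept below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full simulate-score-analyze pipeline
#'
#' Executes the three stages in order against a fresh artifact directory:
#' a synthetic study is simulated and written as CSV, read back and scored
#' (per-subject measures, lag-CRP and serial-position curves), and the
#' condition contrasts are computed. A manifest records package and R
#' versions, the derived per-stage seeds and the MD5 digest of every
#' artifact; re-running with the same config reproduces all CSVs.
#'
#' @param config a config list from [default_config()] or a path to a YAML
#'   file of the same shape.
#' @param stages which stages to run, in order (default all three); later
#'   stages read the artifacts earlier stages left in `out_dir`.
#' @return the artifact directory path, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "score", "analyze")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(default_config(), config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  seeds <- list(simulate = sub_seed(config$seed, 1L),
                analyze = sub_seed(config$seed, 3L))

  if ("simulate" %in% stages) run_stage("simulate", {
    stage_log("simulate", "seed %d", seeds$simulate)
    params <- do.call(sim_params, utils::modifyList(
      config$sim, list(seed = seeds$simulate)))
    cohort <- simulate_study(params)
    write_study_lists(cohort$study_lists, out("lists.csv"))
    write_similarity_matrix(cohort$sim, out("similarity.csv"))
    write_recalls(cohort$recalls, out("recalls.csv"))
    yaml::write_yaml(cohort$ground_truth, out("ground_truth.yaml"))
    stage_log("simulate", "%d transcripts written", length(cohort$recalls))
  })

  if ("score" %in% stages) run_stage("score", {
    lists <- read_study_lists(out("lists.csv"))
    sim <- read_similarity_matrix(
      out("similarity.csv"),
      vocabulary = unlist(lapply(lists, `[[`, "items")))
    recalls <- read_recalls(out("recalls.csv"))
    cohort <- score_cohort(
      recalls, lists, sim,
      max_edit_distance = config$scoring$max_edit_distance,
      semantic_possible = config$scoring$semantic_possible)
    utils::write.csv(cohort$measures, out("measures.csv"),
                     row.names = FALSE)
    crp_rows <- do.call(rbind, lapply(
      unique(cohort$measures$condition), function(cc) {
        av <- average_crp(cohort, cc)
        data.frame(condition = cc, lag = av$lag, crp = av$crp,
                   n_subjects = av$n)
      }))
    utils::write.csv(crp_rows, out("lagcrp.csv"), row.names = FALSE)
    spc_rows <- do.call(rbind, lapply(
      unique(cohort$measures$condition), function(cc) {
        sel <- cohort$measures$condition == cc
        sp <- serial_position_curve(cohort$spc[sel, , drop = FALSE])
        data.frame(condition = cc, serial_position = seq_len(cohort$L),
                   p_recall = sp$position_prob, bin = sp$bins)
      }))
    utils::write.csv(spc_rows, out("spc.csv"), row.names = FALSE)
    stage_log("score", "%d transcripts scored", nrow(cohort$measures))
  })

  if ("analyze" %in% stages) run_stage("analyze", {
    stage_log("analyze", "seed %d", seeds$analyze)
    measures <- utils::read.csv(out("measures.csv"),
                                stringsAsFactors = FALSE)
    contrasts <- analyze_measures(measures,
                                  n_perm = config$stats$n_perm,
                                  seed = seeds$analyze)
    utils::write.csv(contrasts, out("contrasts.csv"), row.names = FALSE)
    writeLines(format_report(contrasts, config$stats$alpha),
               out("report.txt"))
    stage_log("analyze", "%d contrasts written", nrow(contrasts))
  })

  manifest <- list(
    package = as.character(utils::packageVersion("recalldyn")),
    r_version = R.version.string,
    seed = config$seed, stage_seeds = seeds,
    config = config,
    files = as.list(tools::md5sum(list.files(config$out_dir,
                                             full.names = TRUE,
                                             pattern = "\\.(csv|yaml|txt)$")))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}

#' Compute the standard condition contrasts from a measures table
#'
#' For each of the semantic factor, temporal factor, correct recall and
#' ELI count: per-condition one-sample chance tests (factors only), the
#' 2x2 split-plot ANOVA (condition within, order between), a sign-flip
#' permutation companion, and the recall-by-organization Pearson
#' correlation per condition.
#'
#' @param measures data.frame as in `score_cohort()$measures`.
#' @param n_perm permutations for [paired_permutation()].
#' @param seed RNG seed for the permutation tests.
#' @return data.frame with one row per test: `measure`, `test`, `group`,
#'   `statistic`, `df1`, `df2`, `p`, `effect`, `effect_type`,
#'   `adjustment`.
#' @export
analyze_measures <- function(measures, n_perm = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  conds <- sort(unique(measures$condition))
  rows <- list()
  add <- function(measure, test, group, statistic, df1, df2, p,
                  effect = NA_real_, effect_type = NA_character_,
                  adjustment = "none") {
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, test = test, group = group,
      statistic = statistic, df1 = df1, df2 = df2, p = p, effect = effect,
      effect_type = effect_type, adjustment = adjustment,
      stringsAsFactors = FALSE)
  }
  add_cr <- function(measure, test, group, cr) {
    add(measure, test, group, cr$statistic, cr$df[1L],
        if (length(cr$df) > 1L) cr$df[2L] else NA_real_, cr$p, cr$effect,
        cr$effect_type, cr$adjustment)
  }

  for (v in c("semantic_factor", "temporal_factor")) {
    if (all(is.na(measures[[v]]))) next
    for (cc in conds) {
      x <- measures[[v]][measures$condition == cc]
      if (sum(!is.na(x)) >= 2L && stats::sd(x, na.rm = TRUE) > 0) {
        add_cr(v, "one_sample_vs_chance", cc,
               one_sample_vs_chance(x, measure = v))
      }
    }
  }
  for (v in c("semantic_factor", "temporal_factor", "n_correct", "n_ELI")) {
    if (all(is.na(measures[[v]]))) next
    df <- data.frame(subject_id = measures$subject_id,
                     condition = measures$condition,
                     condition_order = measures$condition_order,
                     score = measures[[v]])
    an <- tryCatch(mixed_anova_2x2(df), error = function(e) NULL)
    if (!is.null(an)) {
      for (k in seq_len(nrow(an))) {
        add(v, "mixed_anova_2x2", an$effect[k], an$F[k], an$df1[k],
            an$df2[k], an$p[k], an$pes[k], "partial_eta_sq")
      }
    }
    if (length(conds) == 2L) {
      wide <- merge(
        df[df$condition == conds[1L], c("subject_id", "score")],
        df[df$condition == conds[2L], c("subject_id", "score")],
        by = "subject_id")
      d <- wide$score.x - wide$score.y
      if (sum(!is.na(d)) >= 6L) {
        add_cr(v, "paired_permutation",
               paste(conds, collapse = "-"),
               paired_permutation(d, n_perm = n_perm))
      }
    }
  }
  for (cc in conds) {
    sel <- measures$condition == cc
    cr <- tryCatch(
      recall_organization_correlation(measures$n_correct[sel],
                                      measures$semantic_factor[sel]),
      error = function(e) NULL)
    if (!is.null(cr)) add_cr("recall_x_semantic", "pearson", cc, cr)
  }
  do.call(rbind, rows)
}

format_report <- function(contrasts, alpha = 0.05) {
  hdr <- sprintf("recalldyn condition contrasts (alpha = %.3g)", alpha)
  body <- sprintf(
    "%-18s %-22s %-30s stat=%8.4g df=(%s) p=%.4g%s",
    contrasts$measure, contrasts$test, contrasts$group,
    contrasts$statistic,
    ifelse(is.na(contrasts$df2), sprintf("%.4g", contrasts$df1),
           sprintf("%.4g, %.4g", contrasts$df1, contrasts$df2)),
    contrasts$p, ifelse(contrasts$p < alpha, " *", ""))
  c(hdr, strrep("-", nchar(hdr)), body)
}
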