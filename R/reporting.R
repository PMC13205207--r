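#' Export the base-case strategy table
#'
#' Writes the strategy table in the published shape — incremental cost in
#' million USD (2 decimals), incremental QALYs, ICUR versus the no-screening
#' reference — together with all pairwise ICURs among the screening
#' strategies. Report headers flag a synthetic prevalence profile.
#'
#' @param base_case A [run_base_case()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_base_case <- function(base_case, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- base_case$table
  tab$cost_million <- round(tab$cost_million, 2)
  tab$inc_qaly <- round(tab$inc_qaly, 1)
  tab$icur_vs_ref <- ifelse(tab$strategy == "S4", "Reference",
                            formatC(tab$icur_vs_ref, format = "f", digits = 1))
  p1 <- file.path(dir, "strategy_table.csv")
  utils::write.csv(tab, p1, row.names = FALSE)
  pairs <- list(c("S2", "S1"), c("S3", "S1"), c("S3", "S2"))
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    ic <- icur(base_case$results[[pr[1]]], base_case$results[[pr[2]]])
    data.frame(comparison = paste(pr[1], "vs", pr[2]),
               delta_cost_million = ic$delta_cost / 1e6,
               delta_qaly = ic$delta_qaly, icur = ic$icur, note = ic$note,
               stringsAsFactors = FALSE)
  }))
  p2 <- file.path(dir, "pairwise_icur.csv")
  utils::write.csv(pw, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Export a cascade result as a CSV row set
#'
#' One row per (strategy, age) with the six arm fractions and the per-child
#' one-off screening cost.
#'
#' @param cascades List of [run_cascade()] results.
#' @param path Output CSV path.
#' @return The data.frame written, invisibly.
#' @export
write_cascade_csv <- function(cascades, path) {
  tab <- do.call(rbind, lapply(cascades, function(cc) {
    cbind(data.frame(strategy = cc$strategy, age = cc$age,
                     prevalence = cc$prevalence, stringsAsFactors = FALSE),
          as.data.frame(as.list(cc$arms)),
          data.frame(responder_fraction = cc$responder_fraction,
                     one_off_cost_per_child = cc$one_off_cost_per_child))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Run manifest for a reproducible analysis
#'
#' Records the config hash, master seed, package version, scenario set and
#' output paths so every output file traces to exactly one manifest.
#'
#' @param config_path Path of the config used (`NULL` for built-in defaults).
#' @param seed Master seed.
#' @param outputs Character vector of output paths.
#' @param extra Named list of extra fields (e.g. scenario names).
#' @return A list (class `run_manifest`).
#' @export
run_manifest <- function(config_path = NULL, seed = NA_integer_,
                         outputs = character(), extra = list()) {
  hash <- if (!is.null(config_path) && file.exists(config_path)) {
    unname(tools::md5sum(config_path))
  } else "builtin-defaults"
  structure(c(list(config = config_path %||% "builtin-defaults",
                   config_hash = hash, seed = seed,
                   package_version = as.character(utils::packageVersion("masldcea")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   outputs = outputs), extra),
            class = "run_manifest")
}

write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Base-case command entry point
#'
#' Loads the config (built-in defaults when `config` is `NULL`), runs all
#' four strategies, and writes the strategy table, pairwise ICURs, frontier
#' decisions and a run manifest to `out_dir`.
#'
#' @param config Path to a YAML config, or `NULL` for defaults.
#' @param out_dir Output directory.
#' @return The [run_base_case()] result, invisibly.
#' @export
cli_base_case <- function(config = NULL, out_dir = "results") {
  params <- if (is.null(config)) default_parameters() else load_config(config)
  bc <- run_base_case(params)
  paths <- write_base_case(bc, out_dir)
  fr <- do.call(rbind, lapply(names(bc$frontier), function(nm) {
    data.frame(threshold = nm, wtp = bc$frontier[[nm]]$wtp,
               optimal = bc$frontier[[nm]]$optimal,
               dominated = paste(bc$frontier[[nm]]$dominated, collapse = ";"),
               ext_dominated = paste(bc$frontier[[nm]]$ext_dominated,
                                     collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  p3 <- file.path(out_dir, "frontier.csv")
  utils::write.csv(fr, p3, row.names = FALSE)
  write_manifest(run_manifest(config, outputs = c(paths, p3),
                              extra = list(analysis = "base_case",
                                           synthetic_prevalence = bc$synthetic_prevalence)),
                 out_dir)
  invisible(bc)
}

#' Sensitivity-analysis command entry point
#'
#' Dispatches to the requested analysis family and writes its CSV outputs
#' and a run manifest.
#'
#' @param kind `"oneway"`, `"twoway"`, `"scenario"` or `"psa"`.
#' @param config Path to a YAML config, or `NULL` for defaults.
#' @param out_dir Output directory.
#' @param seed Master seed (sub-streams are derived per analysis).
#' @param n_iter PSA iteration count.
#' @param cohort_size Optional cohort-size override.
#' @param test Second-stage test for the two-way analysis.
#' @param grid_points Grid resolution per axis for the two-way analysis.
#' @return The analysis result, invisibly.
#' @export
cli_sensitivity <- function(kind = c("oneway", "twoway", "scenario", "psa"),
                            config = NULL, out_dir = "results", seed = 1L,
                            n_iter = 1000L, cohort_size = NULL,
                            test = "fibroscan", grid_points = 5L) {
  kind <- match.arg(kind)
  params <- if (is.null(config)) default_parameters() else load_config(config)
  if (!is.null(cohort_size)) params$cohort_size <- cohort_size
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  res <- switch(kind,
    oneway = {
      tab <- one_way(params)
      paths <- file.path(out_dir, "tornado.csv")
      utils::write.csv(tab, paths, row.names = FALSE)
      tab
    },
    scenario = {
      tab <- run_scenarios(params)
      paths <- file.path(out_dir, "scenarios.csv")
      utils::write.csv(tab, paths, row.names = FALSE)
      tab
    },
    twoway = {
      uvse <- params$tests[[test]]$se
      uvsp <- params$tests[[test]]$sp
      tab <- two_way(params, test,
                     se_grid = seq(uvse$ci_low, uvse$ci_high,
                                   length.out = grid_points),
                     sp_grid = seq(uvsp$ci_low, uvsp$ci_high,
                                   length.out = grid_points))
      paths <- file.path(out_dir, "two_way.csv")
      utils::write.csv(tab, paths, row.names = FALSE)
      tab
    },
    psa = {
      psa <- run_psa(params, n_iter = n_iter,
                     seed = substream_seed(seed, "psa"))
      cc <- ceac(psa)
      p1 <- file.path(out_dir, "psa_draws.csv")
      p2 <- file.path(out_dir, "psa_results.csv")
      p3 <- file.path(out_dir, "ceac.csv")
      utils::write.csv(cbind(iteration = seq_len(psa$n_iter), psa$draws),
                       p1, row.names = FALSE)
      utils::write.csv(psa$results, p2, row.names = FALSE)
      utils::write.csv(as.data.frame(cc), p3, row.names = FALSE)
      paths <- c(p1, p2, p3)
      list(psa = psa, ceac = cc)
    })
  write_manifest(run_manifest(config, seed = seed, outputs = paths,
                              extra = list(analysis = kind)),
                 out_dir)
  invisible(res)
}
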