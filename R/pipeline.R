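#' Validate a run configuration
#'
#' Parses a YAML key-value configuration (per-module sections) and checks
#' it against the known schema. All problems are collected and returned
#' together, not just the first. Defaults are filled in so the validated
#' configuration is a complete record of the run.
#'
#' Recognised sections and keys:
#' \describe{
#'   \item{top level}{`output_dir` (required), `seed`, `log_level`}
#'   \item{kinetics}{`series` (list of `name:`, `file:`, optional
#'     `reaction:` primary/promiscuous), `reference`}
#'   \item{stability}{`curves` (list of `name:`, `file:`), `temperature`,
#'     `eps`}
#'   \item{compare}{`structure_a`, `structure_b`, `chain_a`, `chain_b`,
#'     `cap_range`, `dz_threshold`, `trim_after`}
#'   \item{tunnel}{`structure`, `path_file`, `step`, `length`,
#'     `min_prominence`}
#' }
#'
#' @param source path to a YAML file, or a YAML string.
#' @return a validated config (list, class `run_config`) if clean;
#'   otherwise an object of class `config_errors` holding a character
#'   vector of all problems.
#' @export
validate_config <- function(source) {
  raw <- tryCatch({
    if (length(source) == 1L && file.exists(source)) yaml::read_yaml(source)
    else yaml::yaml.load(paste(source, collapse = "\n"))
  }, error = function(e) e)
  if (inherits(raw, "error"))
    return(structure(list(errors = paste("YAML parse error:",
                                         conditionMessage(raw))),
                     class = "config_errors"))
  errors <- character(0)
  note <- function(msg) errors <<- c(errors, msg)
  known_top <- c("output_dir", "seed", "log_level", "kinetics", "stability",
                 "compare", "tunnel")
  for (k in setdiff(names(raw), known_top))
    note(paste0("unknown key: ", k))
  if (is.null(raw$output_dir)) note("missing required key: output_dir")
  cfg <- list(
    output_dir = raw$output_dir,
    seed = raw$seed %||% 1L,
    log_level = raw$log_level %||% "info"
  )
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    note("seed must be an integer")
  check_section <- function(name, known, required = character(0)) {
    sec <- raw[[name]]
    if (is.null(sec)) return(NULL)
    if (!is.list(sec)) { note(paste0(name, ": must be a mapping")); return(NULL) }
    for (k in setdiff(names(sec), known))
      note(paste0(name, ": unknown key: ", k))
    for (k in required)
      if (is.null(sec[[k]])) note(paste0(name, ": missing required key: ", k))
    sec
  }
  kin <- check_section("kinetics", c("series", "reference"), "series")
  if (!is.null(kin)) {
    for (s in kin$series %||% list()) {
      if (is.null(s$name) || is.null(s$file))
        note("kinetics: every series needs name and file")
    }
    cfg$kinetics <- list(series = kin$series %||% list(),
                         reference = kin$reference %||% NULL)
  }
  stab <- check_section("stability",
                        c("curves", "temperature", "eps", "native_window",
                          "unfolded_window"),
                        "curves")
  if (!is.null(stab)) {
    for (s in stab$curves %||% list()) {
      if (is.null(s$name) || is.null(s$file))
        note("stability: every curve needs name and file")
    }
    tmp <- stab$temperature %||% 295.15
    eps <- stab$eps %||% 0.05
    if (tmp <= 0) note("stability: temperature must be positive (K)")
    if (eps <= 0 || eps >= 0.5) note("stability: eps must be in (0, 0.5)")
    for (w in c("native_window", "unfolded_window")) {
      wv <- unlist(stab[[w]])
      if (!is.null(wv) && (length(wv) != 2L || wv[2] <= wv[1]))
        note(paste0("stability: ", w, " must be an increasing pair (M)"))
    }
    cfg$stability <- list(curves = stab$curves %||% list(),
                          temperature = tmp, eps = eps,
                          native_window = unlist(stab$native_window),
                          unfolded_window = unlist(stab$unfolded_window))
  }
  cmp <- check_section("compare",
                       c("structure_a", "structure_b", "chain_a", "chain_b",
                         "cap_range", "dz_threshold", "trim_after"),
                       c("structure_a", "structure_b"))
  if (!is.null(cmp)) {
    thr <- cmp$dz_threshold %||% 1
    if (thr < 0) note("compare: dz_threshold must be nonnegative")
    cfg$compare <- list(structure_a = cmp$structure_a,
                        structure_b = cmp$structure_b,
                        chain_a = cmp$chain_a %||% "A",
                        chain_b = cmp$chain_b %||% "A",
                        cap_range = unlist(cmp$cap_range %||% c(108, 179)),
                        dz_threshold = thr,
                        trim_after = cmp$trim_after %||% NULL)
  }
  tun <- check_section("tunnel",
                       c("structure", "path_file", "step", "length",
                         "min_prominence"),
                       c("structure", "path_file"))
  if (!is.null(tun)) {
    step <- tun$step %||% 0.5
    len <- tun$length %||% 10.5
    if (step <= 0) note("tunnel: step must be positive")
    if (len <= 0) note("tunnel: length must be positive")
    cfg$tunnel <- list(structure = tun$structure, path_file = tun$path_file,
                       step = step, length = len,
                       min_prominence = tun$min_prominence %||% 0.2)
  }
  if (length(errors))
    return(structure(list(errors = errors), class = "config_errors"))
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.config_errors <- function(x, ...) {
  cat("configuration errors:\n")
  for (e in x$errors) cat("  -", e, "\n")
  invisible(x)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the comparison pipeline from a configuration
#'
#' Executes each configured stage (kinetics, stability, compare, tunnel),
#' writing machine-readable CSV/JSON outputs, a run log, and a verbatim
#' echo of the validated configuration into `output_dir`. The run is
#' deterministic given the configuration. Stages are isolated: a failing
#' stage is recorded (status `"failed"`, its error message in the log)
#' without aborting the others.
#'
#' @param config a [validate_config()] result, or a path/string accepted
#'   by it.
#' @param base_dir directory against which relative input paths are
#'   resolved (defaults to the working directory).
#' @return object of class `comparison_report`: per-stage results and
#'   status, plus `output_dir` and `exit_status` (0 = all configured
#'   stages succeeded, 1 = at least one failed).
#' @export
run_pipeline <- function(config, base_dir = ".") {
  if (!inherits(config, "run_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_errors"))
      stop("invalid configuration:\n  ",
           paste(config$errors, collapse = "\n  "))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  logit <- function(...) {
    line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_echo.yaml"))
  logit("run started; seed = ", config$seed)
  logit("constants: R = ", R_KCAL, " kcal/(mol K); vdW radii: Bondi 1964; ",
        "max SASA reference: Gly-X-Gly (Tien 2013)")
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  stages <- list()
  run_stage <- function(name, fun) {
    res <- tryCatch(list(status = "ok", value = fun()),
                    error = function(e) list(status = "failed",
                                             error = conditionMessage(e)))
    if (res$status == "ok") logit("stage ", name, ": ok")
    else logit("stage ", name, ": FAILED: ", res$error)
    stages[[name]] <<- res
  }

  if (!is.null(config$kinetics)) run_stage("kinetics", function() {
    fits <- lapply(config$kinetics$series, function(s) {
      dat <- read.csv(resolve(s$file))
      fit <- fit_michaelis_menten(dat)
      data.frame(name = s$name, reaction = s$reaction %||% "primary",
                 kcat = fit$kcat, km = fit$km, efficiency = fit$efficiency,
                 se_kcat = fit$se_kcat, se_km = fit$se_km)
    })
    tab <- do.call(rbind, fits)
    write.csv(tab, file.path(out_dir, "kinetics_fits.csv"), row.names = FALSE)
    # promiscuity table when both reactions are present per variant
    prim <- tab[tab$reaction == "primary", ]
    prom <- tab[tab$reaction == "promiscuous", ]
    both <- intersect(prim$name, prom$name)
    if (length(both)) {
      entries <- data.frame(
        variant = both,
        eff_primary = prim$efficiency[match(both, prim$name)],
        eff_promiscuous = prom$efficiency[match(both, prom$name)]
      )
      ref <- config$kinetics$reference %||% both[1]
      ptab <- build_promiscuity_table(entries, reference = ref)
      write.csv(as.data.frame(ptab),
                file.path(out_dir, "promiscuity_table.csv"),
                row.names = FALSE)
      list(fits = tab, promiscuity = ptab)
    } else list(fits = tab)
  })

  if (!is.null(config$stability)) run_stage("stability", function() {
    fits <- lapply(config$stability$curves, function(s) {
      dat <- read.csv(resolve(s$file))
      fit <- fit_unfolding(dat,
                           native_window = config$stability$native_window,
                           unfolded_window = config$stability$unfolded_window,
                           temperature = config$stability$temperature,
                           eps = config$stability$eps)
      data.frame(name = s$name, m = fit$m, c_half = fit$c_half,
                 dg_h2o = fit$dg_h2o, se_m = fit$se_m)
    })
    tab <- do.call(rbind, fits)
    write.csv(tab, file.path(out_dir, "stability_fits.csv"),
              row.names = FALSE)
    if (nrow(tab) >= 2L) {
      cmps <- lapply(2:nrow(tab), function(i) {
        mk <- function(j) list(m = tab$m[j], c_half = tab$c_half[j],
                               converged = TRUE)
        d <- ddg_half_concentration(mk(1), mk(i))
        data.frame(reference = tab$name[1], protein = tab$name[i],
                   delta_c_half = d$delta_c_half, mean_m = d$mean_m,
                   ddg = d$ddg)
      })
      ddg_tab <- do.call(rbind, cmps)
      write.csv(ddg_tab, file.path(out_dir, "stability_ddg.csv"),
                row.names = FALSE)
      list(fits = tab, ddg = ddg_tab)
    } else list(fits = tab)
  })

  if (!is.null(config$compare)) run_stage("compare", function() {
    cc <- config$compare
    ma <- read_structure(resolve(cc$structure_a))
    mb <- read_structure(resolve(cc$structure_b))
    aln <- align_chains(ma, mb, cc$chain_a, cc$chain_b,
                        trim_after = cc$trim_after)
    za <- normalize_bfactors(ma, cc$chain_a)
    zb <- normalize_bfactors(mb, cc$chain_b)
    dz <- zscore_difference(za, zb, aln, threshold = cc$dz_threshold)
    sup <- superpose(ma, mb, aln, cc$chain_a, cc$chain_b)
    subs <- classify_substitutions(aln, ma, mb, cc$chain_a, cc$chain_b,
                                   cap_range = cc$cap_range)
    counts <- count_residue_types(ma, chain = cc$chain_a)
    write.csv(dz$points, file.path(out_dir, "compare_dz.csv"),
              row.names = FALSE)
    write.csv(dz$regions, file.path(out_dir, "compare_dz_regions.csv"),
              row.names = FALSE)
    write.csv(subs$records, file.path(out_dir, "compare_substitutions.csv"),
              row.names = FALSE)
    summary <- list(identity = aln$identity, n_aligned = aln$n_aligned,
                    rmsd = sup$rmsd, n_matched = sup$n_matched,
                    substitutions = subs$summary,
                    gly_pro = setNames(as.list(counts$count),
                                       tolower(counts$resid)))
    write_json_file(summary, file.path(out_dir, "compare_summary.json"))
    summary
  })

  if (!is.null(config$tunnel)) run_stage("tunnel", function() {
    tc <- config$tunnel
    model <- read_structure(resolve(tc$structure))
    path <- read.csv(resolve(tc$path_file))
    prof <- trace_profile(model, path, step = tc$step)
    seg <- active_site_volume(prof, length = tc$length,
                              min_prominence = tc$min_prominence)
    export_profile(prof, file.path(out_dir, "tunnel_profile.csv"))
    write_json_file(list(s_start = seg$s_start, s_end = seg$s_end,
                         volume_A3 = seg$volume,
                         pinch_points = seg$pinch_points),
                    file.path(out_dir, "tunnel_segment.json"))
    seg
  })

  status <- vapply(stages, function(s) s$status, character(1))
  logit("run finished: ", sum(status == "ok"), " ok / ",
        sum(status != "ok"), " failed")
  writeLines(log_lines, logfile)
  structure(list(stages = stages, output_dir = out_dir,
                 exit_status = if (all(status == "ok")) 0L else 1L),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("pipeline report (", x$output_dir, "):\n", sep = "")
  for (nm in names(x$stages))
    cat(sprintf("  %-10s %s\n", nm, x$stages[[nm]]$status))
  invisible(x)
}
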