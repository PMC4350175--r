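#' Read a pipeline configuration file
#'
#' YAML or JSON with optional sections `sim`, `seq`, `call`, `cohort`,
#' `sweep`; fields within each section override the package defaults.
#'
#' @param path config file (`.yaml`/`.yml`/`.json`).
#' @return nested list of raw settings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}

#' Validate raw settings into typed pipeline configuration
#'
#' Checks every invariant of the simulation, sequencing and calling
#' configurations, reporting all violations at once with field paths.
#'
#' @param raw nested list (from [read_config()]) or a path to a config file.
#' @return list of class `pipeline_config` with elements `sim`
#'   ([sim_config()]), `seq` ([seq_config()]), `call` ([call_policy()]),
#'   `trim` ([trim_policy()]), `cohort` (eps, min_peak), `sweep`
#'   (thresholds), `fastq_fixture` (n_fragments, dup_fraction or NULL).
#' @export
validate_config <- function(raw = list()) {
  if (is.character(raw) && length(raw) == 1) raw <- read_config(raw)
  errs <- character()
  grab <- function(section, fun, defaults = list()) {
    args <- utils::modifyList(defaults, if (is.null(raw[[section]]))
      list() else raw[[section]])
    known <- names(formals(fun))
    extra <- setdiff(names(args), known)
    if (length(extra))
      errs <<- c(errs, paste0(section, ": unknown field(s) ",
                              paste(extra, collapse = ", ")))
    tryCatch(do.call(fun, args[names(args) %in% known]),
             error = function(e) {
               errs <<- c(errs, paste0(section, ": ", conditionMessage(e)))
               NULL
             })
  }
  sim <- grab("sim", sim_config)
  seqc <- grab("seq", seq_config)
  callp <- grab("call", call_policy)
  trimp <- grab("trim", trim_policy)
  cohort <- utils::modifyList(list(eps = 0.05, min_peak = 0.05),
                              if (is.null(raw$cohort)) list() else raw$cohort)
  if (!(cohort$eps > 0)) errs <- c(errs, "cohort$eps: must be > 0")
  if (!(cohort$min_peak >= 0 && cohort$min_peak <= 1))
    errs <- c(errs, "cohort$min_peak: must be in [0, 1]")
  sweep <- utils::modifyList(list(hard_hi = 0.90, soft_min = 0.10,
                                  origin_max = 0.01),
                             if (is.null(raw$sweep)) list() else raw$sweep)
  if (!(sweep$soft_min < sweep$hard_hi))
    errs <- c(errs, "sweep: soft_min must be below hard_hi")
  fixture <- raw$fastq_fixture
  if (!is.null(fixture)) {
    fixture <- utils::modifyList(list(n_fragments = 200, dup_fraction = 0.1),
                                 fixture)
    if (!(fixture$dup_fraction >= 0 && fixture$dup_fraction < 1))
      errs <- c(errs, "fastq_fixture$dup_fraction: must be in [0, 1)")
  }
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  structure(list(sim = sim, seq = seqc, call = callp, trim = trimp,
                 cohort = cohort, sweep = sweep, fastq_fixture = fixture),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline: simulate, sequence, call, summarise, scan
#'
#' Executes simulate -> sequence -> (optional FASTQ fixture + preprocess)
#' -> call -> trajectories -> cohorts/sweeps with per-stage derived seeds,
#' writing every stage output as TSV/VCF/FASTQ under `outdir` and a
#' reproducibility manifest (config snapshot, seeds, file checksums, stage
#' timings) last. Re-running with the same config and seed reproduces
#' byte-identical tabular outputs.
#'
#' @param config a `pipeline_config` (see [validate_config()]), a raw
#'   settings list, or a config file path.
#' @param outdir output directory (created if needed).
#' @param seed root seed; defaults to the simulation config's seed.
#' @return the manifest, invisibly. Stage results are also returned in the
#'   `results` attribute (truth, table, cohorts, sweeps, ...).
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("poolsweep_run_"),
                         seed = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (!is.null(seed)) config$sim$seed <- as.integer(seed)
  seed <- config$sim$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  files <- character(0)
  stage_seeds <- list()
  stage <- function(name, code) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(code, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] done in %.2fs", name, timings[[name]]))
    res
  }

  truth <- stage("simulate", {
    stage_seeds$simulate <- derive_seed(seed, "simulate")
    tt <- run_simulation(config$sim)
    traj <- cbind(tt$mutations[, c("id", "position", "mut_class", "gene",
                                   "effect", "role")],
                  as.data.frame(tt$freq))
    files <- c(files, write_tsv(traj, file.path(outdir, "truth_trajectories.tsv")),
                write_tsv(tt$linkage, file.path(outdir, "truth_linkage.tsv")))
    tt
  })

  sites <- stage("sequence", {
    stage_seeds$sequence <- derive_seed(seed, "sequence")
    set.seed(stage_seeds$sequence)
    per_day <- lapply(seq_along(truth$sample_days), function(i)
      make_sample(data.frame(mutation_id = truth$mutations$id,
                             freq = truth$freq[, i],
                             stringsAsFactors = FALSE),
                  truth$sample_days[i], config$seq))
    sc <- do.call(rbind, per_day)
    files <- c(files, write_tsv(sc, file.path(outdir, "site_counts.tsv")))
    sc
  })

  if (!is.null(config$fastq_fixture)) {
    stage("preprocess", {
      stage_seeds$preprocess <- derive_seed(seed, "preprocess")
      set.seed(stage_seeds$preprocess)
      batch <- make_read_pairs(config$fastq_fixture$n_fragments,
                               config$fastq_fixture$dup_fraction, config$seq)
      f1 <- file.path(outdir, "fixture_R1.fastq")
      f2 <- file.path(outdir, "fixture_R2.fastq")
      write_fastq_pairs(batch, f1, f2)
      clean <- preprocess_pairs(batch, config$trim, verbose = FALSE)
      c1 <- file.path(outdir, "clean_R1.fastq")
      c2 <- file.path(outdir, "clean_R2.fastq")
      write_fastq_pairs(clean, c1, c2)
      files <- c(files, f1, f2, c1, c2)
      message(sprintf("[preprocess] %s",
                      paste(names(attr(clean, "summary")),
                            attr(clean, "summary"), sep = "=", collapse = " ")))
      clean
    })
  }

  calls <- stage("call", {
    res <- call_sample(sites, config$call)
    files <- c(files,
                write_tsv(res, file.path(outdir, "calls.tsv")),
                write_vcf(res, truth$mutations, sites,
                          file.path(outdir, "calls.vcf")))
    res
  })

  table <- stage("traj", {
    tb <- build_table(calls, truth$mutations, truth$sample_days)
    traj <- cbind(tb$meta[, c("id", "position", "mut_class", "gene",
                              "effect", "role")],
                  as.data.frame(tb$freq))
    spec <- occurrence_spectrum(tb)
    load <- do.call(rbind, lapply(tb$sample_days, function(d)
      c(day = d, mutational_load(tb, d))))
    files <- c(files,
                write_tsv(traj, file.path(outdir, "trajectories.tsv")),
                write_tsv(spec, file.path(outdir, "occurrence_spectrum.tsv")),
                write_tsv(as.data.frame(load),
                          file.path(outdir, "mutational_load.tsv")),
                write_tsv(gene_summary(tb),
                          file.path(outdir, "gene_summary.tsv")))
    tb
  })

  scan <- stage("sweeps", {
    co <- detect_cohorts(table, eps = config$cohort$eps,
                         min_peak = config$cohort$min_peak)
    sw <- classify_all_genes(table, hard_hi = config$sweep$hard_hi,
                             soft_min = config$sweep$soft_min,
                             origin_max = config$sweep$origin_max)
    hh <- detect_hitchhikers(co, table$meta)
    files <- c(files,
                write_tsv(co$membership, file.path(outdir, "cohorts.tsv")),
                write_tsv(sw, file.path(outdir, "sweep_calls.tsv")),
                write_tsv(hh, file.path(outdir, "hitchhikers.tsv")))
    list(cohorts = co, sweeps = sw, hitchhikers = hh)
  })

  manifest <- list(
    package = "poolsweep",
    version = as.character(utils::packageVersion("poolsweep")),
    root_seed = seed,
    stage_seeds = stage_seeds,
    config = serialize_config(config),
    files = as.list(tools::md5sum(files)),
    timings = timings
  )
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  attr(manifest, "results") <- list(truth = truth, sites = sites,
                                    calls = calls, table = table,
                                    cohorts = scan$cohorts,
                                    sweeps = scan$sweeps,
                                    hitchhikers = scan$hitchhikers,
                                    outdir = outdir)
  invisible(manifest)
}

serialize_config <- function(config) {
  sim <- unclass(config$sim)
  sim$gene_models <- NULL  # tabular; checksummed via outputs instead
  sim$init_lineages <- NULL
  list(sim = sim, seq = unclass(config$seq), call = unclass(config$call),
       trim = unclass(config$trim), cohort = config$cohort,
       sweep = config$sweep)
}
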