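# Orchestration: run configurations, one-command regeneration of each
# figure-level analysis, and the command-line entry point.

#' Run configuration
#'
#' A validated, serializable description of one analysis run.  The
#' organization label resolves to the published `gammaDNF_hat` values via
#' [organization_gamma()].
#'
#' @param experiment one of the known experiment ids (see
#'   [run_experiment()]).
#' @param organization organization label for toggle-switch experiments.
#' @param n_trains ensemble size for pulse-train experiments.
#' @param seed master seed.
#' @param units_per_min time-unit conversion factor recorded with the run.
#' @param extra named list of experiment-specific settings.
#' @return A `run_config` object.
#' @export
run_config <- function(experiment = c("fig1e", "fig3a", "fig3bc", "fig3e",
                                      "fig5c", "fig5d", "ev1"),
                       organization = "critical", n_trains = 1000,
                       seed = 1,
                       units_per_min = units_per_minute(),
                       extra = list()) {
  experiment <- match.arg(experiment)
  organization_gamma(organization) # validates the label
  structure(list(experiment = experiment, organization = organization,
                 n_trains = n_trains, seed = seed,
                 units_per_min = units_per_min, extra = extra),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  run_config(x$experiment, x$organization, x$n_trains, x$seed,
             x$units_per_min, as.list(x$extra))
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: experiment=%s organization=%s seed=%d\n",
              x$experiment, x$organization, x$seed))
  invisible(x)
}

all_organizations <- c("bistable", "critical", "reversible", "monostable")

#' Regenerate the data underlying one analysis
#'
#' Runs a configured analysis end to end and writes its results (delimited
#' text and JSON) into `out_dir`, together with a copy of the
#' configuration and a structured log.  Experiments: `fig1e` step
#' responses for the four organizations; `fig3a` two-pulse responses;
#' `fig3bc` pulse-train ensemble distributions; `fig3e` dynamic-range
#' scan; `fig5c` two-parameter fold curve with asymptote; `fig5d`
#' self-organized criticality run; `ev1` decay-baseline trade-off suite.
#' Reruns with the same configuration reproduce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the list of written files.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    log <<- c(log, msg)
  }
  emit <- function(name, writer, obj) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files <<- c(files, p)
  }
  write_config(config, file.path(out_dir, "config.json"))
  note("experiment %s started (seed %d)", config$experiment, config$seed)
  n_trains <- config$n_trains
  seed <- config$seed

  if (config$experiment == "fig1e") {
    for (org in all_organizations) {
      p <- toggle_params(gammaDNF_hat = organization_gamma(org))
      tr <- simulate_model("toggle", p, step_protocol(10, 15),
                           horizon = 120)
      emit(sprintf("step_response_%s.tsv", org), write_trajectory, tr)
    }
  } else if (config$experiment == "fig3a") {
    gap <- config$extra$gap %||% 15
    for (org in all_organizations) {
      p <- toggle_params(gammaDNF_hat = organization_gamma(org))
      tr <- simulate_model("toggle", p, two_pulse_protocol(5, gap),
                           horizon = 160)
      emit(sprintf("two_pulse_%s.tsv", org), write_trajectory, tr)
    }
  } else if (config$experiment == "fig3bc") {
    p <- toggle_params(
      gammaDNF_hat = organization_gamma(config$organization))
    ens <- ensemble_run(p, n_trains = n_trains, seed = seed)
    emit(sprintf("ensemble_%s.tsv", config$organization), write_branch,
         ens)
    summ <- list(organization = config$organization,
                 threshold = attr(ens, "threshold"),
                 fraction_mean = mean(ens$fraction),
                 fraction_sd = sd(ens$fraction),
                 intervals_min = min(ens$n_intervals),
                 intervals_max = max(ens$n_intervals))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "summary.json"))
  } else if (config$experiment == "fig3e") {
    scan <- dynamic_range_scan(toggle_params())
    emit("dynamic_range.tsv", write_branch, scan)
  } else if (config$experiment == "fig5c") {
    p <- compartment_params()
    emit("fold_curve.tsv", write_branch, compartment_fold_curve(p))
    asym <- compartment_rt_asymptote(p)
    jsonlite::write_json(asym, file.path(out_dir, "asymptote.json"),
                         auto_unbox = TRUE, digits = NA)
    files <- c(files, file.path(out_dir, "asymptote.json"))
  } else if (config$experiment == "fig5d") {
    runs <- self_organized_run(compartment_params())
    emit("selforg_dynamic.tsv", write_trajectory, runs$dynamic)
    emit("selforg_fixed.tsv", write_trajectory, runs$fixed)
  } else if (config$experiment == "ev1") {
    suites <- decay_tradeoff_suite(n_trains = n_trains, seed = seed)
    for (nm in names(suites))
      emit(paste0("decay_", gsub("[^0-9a-zA-Z.=-]", "_", nm), ".tsv"),
           write_branch, suites[[nm]])
  }
  note("experiment %s finished (%d files)", config$experiment,
       length(files))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(files)
}

#' Command-line entry point
#'
#' Minimal subcommand dispatcher (`simulate`, `bifurcate`, `protocol`,
#' `pulsetrain-ensemble`, `landscape`, `particles`, `sde`, `freqscan`,
#' `selforg`, `experiment`) used by the installed `exec/ghostmem`
#' script.  Arguments are `--key value` pairs.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the result of the dispatched command.
#' @export
ghostmem_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: ghostmem <simulate|bifurcate|protocol|",
        "pulsetrain-ensemble|landscape|particles|sde|freqscan|selforg|",
        "experiment> [--key value ...]\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- list()
  kv <- args[-1]
  i <- 1
  while (i <= length(kv)) {
    if (startsWith(kv[i], "--") && i < length(kv)) {
      opts[[substring(kv[i], 3)]] <- kv[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  num <- function(key, default) {
    if (!is.null(opts[[key]])) as.numeric(opts[[key]]) else default
  }
  chr <- function(key, default) opts[[key]] %||% default
  out <- chr("out", ".")
  res <- switch(
    cmd,
    simulate = {
      p <- toggle_params(gammaDNF_hat = organization_gamma(
        chr("organization", "critical")))
      tr <- simulate_model("toggle", p,
                           step_protocol(num("on", 10), num("off", 15)),
                           horizon = num("horizon", 120))
      write_trajectory(tr, file.path(out, "trajectory.tsv"))
    },
    bifurcate = {
      if (chr("model", "toggle") == "toggle") {
        br <- toggle_branch(toggle_params())
        write_branch(br, file.path(out, "branch.tsv"))
        write_branch(locate_folds(br, params = toggle_params()),
                     file.path(out, "folds.tsv"))
      } else {
        write_branch(compartment_fold_curve(compartment_params()),
                     file.path(out, "fold_curve.tsv"))
      }
    },
    protocol = {
      train <- random_pulse_train(num("n", 12), num("len", 5),
                                  num("horizon", 480),
                                  seed = num("seed", 1))
      write_pulse_train(train, file.path(out, "train.json"))
    },
    `pulsetrain-ensemble` = {
      cfg <- run_config("fig3bc",
                        organization = chr("organization", "critical"),
                        n_trains = num("reps", 1000),
                        seed = num("seed", 1))
      run_experiment(cfg, out)
    },
    landscape = {
      p <- toggle_params(gammaDNF_hat = organization_gamma(
        chr("organization", "bistable")))
      land <- assemble_landscape("toggle_input", p,
                                 n_grid = num("grid", 20))
      write_landscape(land, file.path(out, "landscape.tsv"))
    },
    particles = {
      mp <- micro_params(gamma_mult = num("gamma", 4.95),
                         side = num("area", 2.5))
      for (r in seq_len(num("reps", 1))) {
        sim <- simulate_particles(mp, horizon = num("horizon", 10),
                                  init = chr("init", "high"),
                                  seed = num("seed", 1) + r - 1)
        write_branch(sim$counts,
                     file.path(out, sprintf("particles_rep%d.tsv", r)))
      }
    },
    sde = {
      p <- toggle_params(gammaDNF_hat = organization_gamma(
        chr("organization", "critical")))
      tr <- sde_simulate("toggle", p,
                         noise_spec(sigma = num("sigma", 0.05),
                                    adaptive = FALSE),
                         step_protocol(num("on", 10), num("off", 15)),
                         horizon = num("horizon", 120),
                         seed = num("seed", 1))
      write_trajectory(tr, file.path(out, "sde_trajectory.tsv"))
    },
    freqscan = {
      rts <- seq(num("rt-min", 1.05), num("rt-max", 1.34),
                 length.out = num("rt-steps", 5))
      sc <- frequency_vs_RT_scan(rts, n_real = num("reps", 50),
                                 horizon = num("horizon", 200),
                                 seed = num("seed", 1))
      jsonlite::write_json(sc, file.path(out, "freqscan.json"),
                           digits = NA)
    },
    selforg = {
      runs <- self_organized_run(compartment_params())
      write_trajectory(runs$dynamic,
                       file.path(out, "selforg_dynamic.tsv"))
      write_trajectory(runs$fixed, file.path(out, "selforg_fixed.tsv"))
    },
    experiment = {
      cfg <- run_config(chr("experiment", "fig1e"),
                        organization = chr("organization", "critical"),
                        n_trains = num("reps", 1000),
                        seed = num("seed", 1))
      run_experiment(cfg, out)
    },
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
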