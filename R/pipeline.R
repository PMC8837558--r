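# End-to-end orchestration: synthetic data (or supplied traces) -> features
# -> densities -> surrogate -> adversarial population fit -> populations ->
# validation protocols -> sensitivity, with a JSON manifest recording seeds
# and file checksums for reproducibility.

#' Pipeline configuration
#'
#' @param out_dir run directory for artifacts and the manifest.
#' @param seed root seed; per-stage seeds are derived from it.
#' @param stages character vector of stages to execute, a subset of
#'   `c("synthetic", "features", "surrogate", "gan", "populations",
#'   "validate", "sensitivity")`. Later stages fail fast with an actionable
#'   error if an upstream artifact is missing.
#' @param synth a [synth_config()].
#' @param n_train prior samples for the surrogate training set.
#' @param surrogate_epochs,surrogate_hidden surrogate training options.
#' @param gan a [gan_config()].
#' @param n_pop virtual cells per group to sample after fitting.
#' @param sens_metric feature used as the sensitivity metric
#'   (`"dSL"`, `"sSL"` or `"TTP"`).
#' @param constants a [model_constants()].
#' @return List of class `"run_config"`.
#' @export
run_config <- function(out_dir = tempfile("sarcopop_run_"), seed = 1,
                       stages = c("synthetic", "features", "surrogate", "gan",
                                  "populations", "validate", "sensitivity"),
                       synth = synth_config(), n_train = 3000,
                       surrogate_epochs = 500, surrogate_hidden = c(128, 128, 128),
                       gan = gan_config(), n_pop = 2000,
                       sens_metric = "TTP", constants = model_constants()) {
  cfg <- list(out_dir = out_dir, seed = seed, stages = stages, synth = synth,
              n_train = n_train, surrogate_epochs = surrogate_epochs,
              surrogate_hidden = surrogate_hidden, gan = gan, n_pop = n_pop,
              sens_metric = sens_metric, constants = constants)
  known <- c("synthetic", "features", "surrogate", "gan", "populations",
             "validate", "sensitivity")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!sens_metric %in% c("dSL", "sSL", "TTP"))
    stop("sens_metric must be one of dSL, sSL, TTP")
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing artifacts and a
#' `manifest.json` (package version, seeds, stage timings and MD5 checksums
#' of every file written) to `cfg$out_dir`. Deterministic stages rerun with
#' the same configuration and seed produce identical checksums.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  manifest <- list(package = "sarcopop",
                   version = as.character(utils::packageVersion("sarcopop")),
                   seed = cfg$seed, stages = list())
  files <- character(0)
  t0_all <- Sys.time()
  stage <- function(name, code) {
    t0 <- Sys.time()
    out <- code()
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }
  need <- function(what, stage_name) {
    if (is.null(res[[what]]))
      stop(sprintf("stage '%s' requires the '%s' artifact; enable the upstream stage or supply it",
                   stage_name, what))
    res[[what]]
  }

  if ("synthetic" %in% cfg$stages) {
    res$ground_truth <- stage("synthetic", function() {
      gt <- make_ground_truth(cfg$synth, seed = cfg$seed)
      files <<- c(files, write_fixtures(gt, file.path(cfg$out_dir, "fixtures")))
      gt
    })
  }
  if ("features" %in% cfg$stages) {
    res$targets <- stage("features", function() {
      gt <- need("ground_truth", "features")
      list(c = gt$density_c, d = gt$density_d,
           slack = list(mean = mean(gt$params_c$SL_slack),
                        sd = stats::sd(gt$params_c$SL_slack)))
    })
  }
  if ("surrogate" %in% cfg$stages) {
    res$surrogate <- stage("surrogate", function() {
      ts <- build_training_set(cfg$synth$box, cfg$n_train,
                               seed = cfg$seed + 1, constants = cfg$constants)
      train_surrogate(ts$X, ts$Y, hidden = cfg$surrogate_hidden,
                      epochs = cfg$surrogate_epochs, seed = cfg$seed + 2)
    })
  }
  if ("gan" %in% cfg$stages) {
    res$vpop <- stage("gan", function() {
      targets <- need("targets", "gan")
      sur <- need("surrogate", "gan")
      gcfg <- cfg$gan
      gcfg$seed <- cfg$seed + 3
      fit_vpop(targets$c, targets$d, sur, prior = cfg$synth$box,
               slack = targets$slack, config = gcfg)
    })
  }
  if ("populations" %in% cfg$stages) {
    res$pops <- stage("populations", function() {
      vp <- need("vpop", "populations")
      pops <- simulate(vp, nsim = cfg$n_pop, seed = cfg$seed + 4)
      fc <- file.path(cfg$out_dir, "pop_control.csv")
      fd <- file.path(cfg$out_dir, "pop_drug.csv")
      write_population_csv(pops$control, "control", fc)
      write_population_csv(pops$drug, "drug", fd)
      files <<- c(files, fc, fd)
      pops
    })
  }
  if ("validate" %in% cfg$stages) {
    res$report <- stage("validate", function() {
      pops <- need("pops", "validate")
      validate_om_report(pops$control, pops$drug, cfg$constants)
    })
  }
  if ("sensitivity" %in% cfg$stages) {
    res$sensitivity <- stage("sensitivity", function() {
      sur <- need("surrogate", "sensitivity")
      X <- sample_prior(cfg$synth$box, max(1000, cfg$n_pop),
                        seed = cfg$seed + 5)
      y <- predict(sur, X)[, cfg$sens_metric]
      mda(X, y, regressor = "rf", seed = cfg$seed + 6, ntree = 200)
    })
  }

  manifest$elapsed_seconds <-
    as.numeric(difftime(Sys.time(), t0_all, units = "secs"))
  manifest$checksums <- as.list(tools::md5sum(files[file.exists(files)]))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(res, list(manifest = manifest)))
}

#' Counterfactual protocol comparison of two inferred populations
#'
#' Takes the mean parameter vector of each group and runs the three
#' validation protocols: the steady-state force-calcium sweep (Hill
#' coefficient and calcium sensitivity), unloaded shortening (diastolic
#' length, peak shortening velocity) including the zero-diastolic-calcium
#' counterfactual, and the isometric twitch (RT50). The drug signature
#' expected of a myosin-targeting inotrope is a lower Hill coefficient,
#' lower `Ca_50`, shorter diastolic length (an effect that disappears at
#' `Ca_diast = 0`), essentially unchanged peak shortening velocity and a
#' longer RT50.
#'
#' @param pop_c,pop_d non-empty data frames of parameter rows (columns
#'   [param_names()], optional `SL_slack`).
#' @param constants a [model_constants()].
#' @param t_grid simulation grid (ms) for the twitch protocols.
#' @return Object of class `"om_report"`: per-group `h`, `Ca_50`, `dSL`,
#'   `dSL_zero_ca`, `peak_velocity` (um/ms), `RT50`, plus drug-minus-control
#'   contrasts.
#' @export
validate_om_report <- function(pop_c, pop_d, constants = model_constants(),
                               t_grid = seq(0, 800, by = 1)) {
  if (!nrow(pop_c) || !nrow(pop_d)) stop("empty population")
  mean_params <- function(pop) {
    m <- colMeans(pop[param_names()])
    slack <- if ("SL_slack" %in% names(pop)) mean(pop$SL_slack) else 1.9
    row_params(m, SL_slack = slack)
  }
  group_stats <- function(p) {
    fca <- simulate_fca(p, constants)
    tr <- simulate_unloaded(p, constants, t_grid)
    p0 <- p; p0$Ca_diast <- 0
    tr0 <- simulate_unloaded(p0, constants, t_grid)
    vel <- max(-diff(tr$v) / diff(tr$t))
    iso <- simulate_isometric(p, constants, t_grid = t_grid)
    list(params = p, h = fca$fit$h, Ca_50 = fca$fit$Ca_50,
         dSL = tr$v[1], dSL_zero_ca = tr0$v[1], peak_velocity = vel,
         RT50 = iso$metrics$RT50)
  }
  ctl <- group_stats(mean_params(pop_c))
  drg <- group_stats(mean_params(pop_d))
  structure(list(
    control = ctl, drug = drg,
    delta = list(h = drg$h - ctl$h, Ca_50 = drg$Ca_50 - ctl$Ca_50,
                 dSL = drg$dSL - ctl$dSL,
                 dSL_zero_ca = drg$dSL_zero_ca - ctl$dSL_zero_ca,
                 velocity_ratio = drg$peak_velocity / ctl$peak_velocity,
                 RT50 = drg$RT50 - ctl$RT50)),
    class = "om_report")
}

#' @export
print.om_report <- function(x, ...) {
  cat("Validation protocols at group-mean parameters\n")
  cat(sprintf("  %-22s %12s %12s\n", "", "control", "drug"))
  row <- function(lab, a, b, fmt = "%12.4g")
    cat(sprintf("  %-22s %s %s\n", lab, sprintf(fmt, a), sprintf(fmt, b)))
  row("Hill h", x$control$h, x$drug$h)
  row("Ca_50 (uM)", x$control$Ca_50, x$drug$Ca_50)
  row("diastolic SL (um)", x$control$dSL, x$drug$dSL)
  row("  ... at Ca_diast=0", x$control$dSL_zero_ca, x$drug$dSL_zero_ca)
  row("peak velocity (um/ms)", x$control$peak_velocity, x$drug$peak_velocity)
  row("RT50 (ms)", x$control$RT50, x$drug$RT50)
  cat(sprintf("  velocity ratio drug/control: %.3f\n",
              x$delta$velocity_ratio))
  invisible(x)
}
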