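#' Default maternity schedule
#'
#' A simple pregnancy-rate schedule for a long-lived odontocete: zero until
#' the age at first reproduction, then a constant annual calf production per
#' female (a 4-year calving interval by default).
#'
#' @param max_age oldest age class.
#' @param age_first_repro first reproductive age (yr).
#' @param rate calves per mature female per year.
#' @return numeric vector of length `max_age + 1`.
#' @export
default_maternity <- function(max_age, age_first_repro = 8, rate = 0.25) {
  m <- rep(0, max_age + 1L)
  m[(0:max_age) >= age_first_repro] <- rate
  m
}

read_vector_csv <- function(path, col) {
  tab <- utils::read.csv(path)
  if (!col %in% names(tab)) stop("missing column: ", col)
  as.numeric(tab[[col]])
}

#' Run the stranding-analysis workflow
#'
#' Orchestrates the full analysis: simulate (or read) an age-structured
#' stranding record, build its life table, fit the Siler model, fit the
#' adapted Heligman-Pollard model by Bayesian melding with IMIS, and
#' project two Leslie matrices — one under natural-only mortality, one
#' under total (natural + bycatch) mortality — comparing their demographic
#' parameters.  All artefacts are written to `out_dir` together with a
#' run-metadata JSON recording the seed and full parameterisation.
#'
#' @param config a configuration list or the path to a YAML file with
#'   optional blocks `scenario` (arguments of [scenario_spec]), `input`
#'   (CSV of ages, used instead of simulation), `siler` (`rm`, `max_age`,
#'   `objective`), `hp` (`lower`, `upper`, `draws`, `n_imis`, `n_opt`,
#'   `n_resample`, `level`), `leslie` (`maternity` path or vector,
#'   `age_first_repro`, `rate`, `sex_ratio`, `years`) and `stages`
#'   (subset of `c("simulate", "lifetable", "siler", "hp", "leslie")`).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; overrides any seed in the config.
#' @param verbose print stage progress and timings.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = list(), out_dir = ".", seed = NULL,
                         verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(seed)) seed <- config$seed %||% 1
  stages <- config$stages %||%
    c("simulate", "lifetable", "siler", "hp", "leslie")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(seed = seed)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- list()

  # --- ages: simulate or read -----------------------------------------
  t0 <- tic()
  if (!is.null(config$input)) {
    sample <- read_age_table(config$input)
    say("read %d ages from %s", length(sample), config$input)
  } else {
    sc_args <- config$scenario %||% list()
    sc_args$seed <- seed
    spec <- do.call(scenario_spec, sc_args)
    sample <- simulate_strandings(spec)
    results$scenario <- spec
    results$truth <- scenario_truth(spec)
    if ("simulate" %in% stages) {
      write_age_table(sample, file.path(out_dir, "ages.csv"))
      say("simulated %d strandings -> ages.csv", length(sample))
    }
  }
  results$sample <- sample
  timings$ages <- tic() - t0
  max_age <- max(floor(as.numeric(sample)))

  # --- life table ------------------------------------------------------
  if ("lifetable" %in% stages) {
    t0 <- tic()
    lt <- life_table(sample)
    write_life_table(lt, file.path(out_dir, "life_table.csv"))
    results$life_table <- lt
    timings$lifetable <- tic() - t0
    say("life table over ages 0-%d -> life_table.csv", max_age)
  }

  # --- Siler fit -------------------------------------------------------
  if ("siler" %in% stages) {
    t0 <- tic()
    sa <- config$siler %||% list()
    fit <- fit_siler(sample, rm = sa$rm %||% 0,
                     max_age = sa$max_age %||% max_age,
                     objective = sa$objective %||% "multinomial",
                     seed = seed)
    sched <- predict(fit)
    names(sched) <- c("age", "mu_juvenile", "mu_constant", "mu_senescent",
                      "mu_total", "qx")
    utils::write.csv(sched, file.path(out_dir, "siler_schedule.csv"),
                     row.names = FALSE, quote = FALSE)
    results$siler <- fit
    timings$siler <- tic() - t0
    say("Siler fit (objective %.3f) -> siler_schedule.csv", fit$objective)
  }

  # --- aHP fit ---------------------------------------------------------
  if ("hp" %in% stages) {
    t0 <- tic()
    ha <- config$hp %||% list()
    pr_args <- list()
    if (!is.null(ha$lower)) pr_args$lower <- unlist(ha$lower)
    if (!is.null(ha$upper)) pr_args$upper <- unlist(ha$upper)
    if (!is.null(ha$draws)) pr_args$draws <- ha$draws
    priors <- do.call(ahp_priors, pr_args)
    post <- fit_ahp(sample, priors,
                    n_imis = ha$n_imis %||% 10,
                    n_opt = ha$n_opt %||% 10,
                    n_resample = ha$n_resample %||% 500,
                    seed = seed, verbose = verbose)
    utils::write.csv(as.data.frame(post$samples),
                     file.path(out_dir, "posterior.csv"),
                     row.names = FALSE, quote = FALSE)
    sched <- predict_ahp(post, 0:max_age, level = ha$level %||% 0.90)
    utils::write.csv(sched, file.path(out_dir, "hp_schedule.csv"),
                     row.names = FALSE, quote = FALSE)
    results$hp <- post
    timings$hp <- tic() - t0
    say("aHP fit: %d IMIS iterations, unique fraction %.3f -> posterior.csv",
        post$iterations, post$unique_fraction)
  }

  # --- Leslie projections ---------------------------------------------
  if ("leslie" %in% stages && !is.null(results$hp)) {
    t0 <- tic()
    la <- config$leslie %||% list()
    m <- if (is.character(la$maternity)) read_vector_csv(la$maternity, "m")
         else if (!is.null(la$maternity)) as.numeric(la$maternity)
         else default_maternity(max_age, la$age_first_repro %||% 8,
                                la$rate %||% 0.25)
    sched <- predict_ahp(results$hp, 0:max_age)
    med <- function(comp) sched[sched$component == comp, "median"]
    clamp_q <- function(q) pmin(pmax(q, 0), 1)
    q_nat <- clamp_q(med("natural")); q_tot <- clamp_q(med("total"))
    for (case in c("natural", "total")) {
      q <- if (case == "natural") q_nat else q_tot
      A <- leslie_matrix(q, m, sex_ratio = la$sex_ratio %||% 0.5)
      st <- eigen_analysis(A)
      n0 <- 1000 * st$stable_age
      traj <- leslie_project(A, n0, years = la$years %||% 100)
      utils::write.csv(data.frame(year = as.numeric(rownames(traj)),
                                  total = rowSums(traj)),
                       file.path(out_dir, paste0("projection_", case, ".csv")),
                       row.names = FALSE, quote = FALSE)
      jsonlite::write_json(
        list(lambda = st$lambda, r = st$r, R0 = st$R0,
             generation_time = st$generation_time,
             stable_age = st$stable_age, repro_value = st$repro_value),
        file.path(out_dir, paste0("stats_", case, ".json")),
        auto_unbox = TRUE, digits = NA)
      results[[paste0("leslie_", case)]] <- st
    }
    timings$leslie <- tic() - t0
    say("Leslie projections: lambda natural %.4f vs total %.4f",
        results$leslie_natural$lambda, results$leslie_total$lambda)
  }

  meta <- list(package = "strandmort",
               version = as.character(utils::packageVersion("strandmort")),
               seed = seed, stages = stages, config = config,
               timings = timings,
               imis_diagnostics = if (!is.null(results$hp))
                 results$hp$diagnostics)
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
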