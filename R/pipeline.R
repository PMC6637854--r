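# Pipeline orchestration: generate -> simulate -> targets -> waste/gap ->
# policies, with config validation and a deterministic run manifest.

#' Build a run configuration
#'
#' @param world A [world_config()] object (or arguments for one via
#'   `world_args`).
#' @param scenarios Scenario names to run (default: all in the world
#'   config).
#' @param waste_schemes List of [waste_scheme()] objects; at least one is
#'   required. Default: zero, FAO-style regional, uniform 15%, uniform
#'   33%.
#' @param minimum Flat minimum target (g/person/day).
#' @param snapshot_years Reporting years for the snapshot tables.
#' @param policy List with `n_records` and `fv_fraction` controlling the
#'   synthetic policy database stage.
#' @param seed Pipeline seed (world and policy seeds derive from it).
#' @return Object of class `fv_run_config`.
#' @export
run_config <- function(world = world_config(),
                       scenarios = NULL,
                       waste_schemes = NULL,
                       minimum = 400,
                       snapshot_years = c(1965, 1990, 2015, 2030, 2050),
                       policy = list(n_records = 200, fv_fraction = 0.22),
                       seed = 1L) {
  if (!inherits(world, "fv_world_config")) {
    stop("validation error: world must be a world_config()")
  }
  if (is.null(scenarios)) scenarios <- world$scenarios
  bad <- setdiff(scenarios, world$scenarios)
  if (length(bad) > 0) {
    stop("validation error: scenario(s) not in world config: ",
         paste(bad, collapse = ", "))
  }
  if (is.null(waste_schemes)) {
    waste_schemes <- list(
      waste_scheme("zero"),
      waste_scheme("regional", table = default_waste_table()),
      waste_scheme("uniform", share = 0.15),
      waste_scheme("uniform", share = 0.33))
  }
  if (length(waste_schemes) == 0) {
    stop("validation error: at least one waste scheme is required")
  }
  ok <- vapply(waste_schemes, inherits, logical(1), "fv_waste_scheme")
  if (!all(ok)) {
    stop("validation error: waste_schemes must be waste_scheme() objects")
  }
  if (!is.list(policy) || is.null(policy$n_records)) {
    stop("validation error: policy needs n_records")
  }
  structure(
    list(world = world, scenarios = scenarios,
         waste_schemes = waste_schemes, minimum = minimum,
         snapshot_years = snapshot_years, policy = policy,
         seed = as.integer(seed)),
    class = "fv_run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Expected top-level keys: `world` (fields of [world_config()]),
#' `scenarios`, `waste_schemes` (list of `{kind, share}` entries),
#' `minimum`, `snapshot_years`, `policy`, `seed`. Missing keys fall back
#' to defaults; malformed entries raise validation errors before any
#' computation.
#'
#' @param path Path to a YAML file.
#' @return `fv_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  wargs <- raw$world
  world <- if (is.null(wargs)) world_config() else {
    allowed <- setdiff(names(formals(world_config)), "presets")
    bad <- setdiff(names(wargs), allowed)
    if (length(bad) > 0) {
      stop("validation error: unknown world config field(s): ",
           paste(bad, collapse = ", "))
    }
    do.call(world_config, wargs)
  }
  schemes <- if (is.null(raw$waste_schemes)) NULL else {
    lapply(raw$waste_schemes, function(s) {
      if (is.null(s$kind)) stop("validation error: waste scheme needs a kind")
      if (identical(s$kind, "regional")) {
        waste_scheme("regional", table = default_waste_table())
      } else {
        waste_scheme(s$kind, share = s$share)
      }
    })
  }
  args <- list(world = world)
  if (!is.null(raw$scenarios)) args$scenarios <- unlist(raw$scenarios)
  if (!is.null(schemes)) args$waste_schemes <- schemes
  if (!is.null(raw$minimum)) args$minimum <- raw$minimum
  if (!is.null(raw$snapshot_years)) {
    args$snapshot_years <- unlist(raw$snapshot_years)
  }
  if (!is.null(raw$policy)) args$policy <- raw$policy
  if (!is.null(raw$seed)) args$seed <- raw$seed
  do.call(run_config, args)
}

# serialisable view of the config (for hashing and the manifest)
.config_digest <- function(config) {
  plain <- list(
    world = unclass(config$world),
    scenarios = config$scenarios,
    waste_schemes = lapply(config$waste_schemes,
                           function(s) s[c("kind", "share", "label")]),
    minimum = config$minimum,
    snapshot_years = config$snapshot_years,
    policy = config$policy,
    seed = config$seed)
  js <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(js, tf)
  unname(tools::md5sum(tf))
}

#' Run the full gap-analysis pipeline
#'
#' Executes every stage in order — world generation, market simulation per
#' scenario, target series, waste/gap tables per scheme, regional and
#' global summaries, policy review on a synthetic policy database — and
#' writes the declared CSV outputs plus a deterministic `manifest.json`
#' (config hash, seed, package version, solver diagnostics). Two runs with
#' identical config produce byte-identical outputs.
#'
#' @param config An [run_config()] (or path to a YAML file).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "fv_run_config")) {
    stop("validation error: config must be an fv_run_config")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  world <- stage("generate-world", {
    wc <- config$world
    wc$seed <- config$seed
    generate_world(wc)
  })
  write_world_panel(world, file.path(out_dir, "world"))

  sims <- stage("simulate", {
    setNames(lapply(config$scenarios,
                    function(sc) simulate_market(world, sc)),
             config$scenarios)
  })
  avail <- do.call(rbind, lapply(sims, function(s) s$availability))
  rownames(avail) <- NULL
  prices <- do.call(rbind, lapply(sims, function(s) s$prices))
  rownames(prices) <- NULL
  bal_out <- do.call(rbind, lapply(sims, function(s) s$balances))
  rownames(bal_out) <- NULL
  write.csv(avail, file.path(out_dir, "availability.csv"), row.names = FALSE)
  write.csv(prices, file.path(out_dir, "prices.csv"), row.names = FALSE)
  write.csv(bal_out, file.path(out_dir, "balances_out.csv"), row.names = FALSE)

  targets <- stage("targets", {
    do.call(rbind, lapply(config$scenarios, function(sc) {
      target_series(world, sc, minimum = config$minimum)
    }))
  })
  write.csv(targets, file.path(out_dir, "targets.csv"), row.names = FALSE)

  gaps <- stage("gap", {
    do.call(rbind, lapply(config$waste_schemes, function(sch) {
      as.data.frame(gap_table(avail, targets, sch, world$countries))
    }))
  })
  rownames(gaps) <- NULL
  write.csv(gaps, file.path(out_dir, "gap.csv"), row.names = FALSE)

  summaries <- stage("summarize", {
    reg <- summarize_gap(gaps, world, "region")
    glob <- summarize_gap(gaps, world, "global")
    rbind(reg, glob)
  })
  rownames(summaries) <- NULL
  write.csv(summaries, file.path(out_dir, "gap_summary.csv"),
            row.names = FALSE)
  write.csv(gap_snapshot(summaries, config$snapshot_years),
            file.path(out_dir, "table1_like.csv"), row.names = FALSE)

  policy <- stage("policies", {
    fvf <- if (is.null(config$policy$fv_fraction)) 0.22 else
      config$policy$fv_fraction
    db <- generate_policy_db(
      n_records = config$policy$n_records,
      seed = config$seed + 1L,
      fv_fraction = fvf,
      countries = world$countries$country)
    fv <- filter_fv_policies(db)
    membership <- default_region_membership()
    expanded <- expand_regions(fv, membership)
    region_map <- rbind(
      world$countries[, c("country", "region")],
      do.call(rbind, lapply(names(membership), function(b) {
        data.frame(country = membership[[b]], region = b,
                   stringsAsFactors = FALSE)
      })))
    tab <- tabulate_policies(expanded, region_map)
    list(db = db, expanded = expanded, counts = tab)
  })
  write.csv(policy$db, file.path(out_dir, "policies.csv"), row.names = FALSE)
  write.csv(policy$counts$by_region_rung,
            file.path(out_dir, "policy_counts.csv"), row.names = FALSE)

  manifest <- list(
    package = "fvgap",
    version = as.character(utils::packageVersion("fvgap")),
    seed = config$seed,
    config_hash = .config_digest(config),
    scenarios = config$scenarios,
    waste_schemes = vapply(config$waste_schemes, `[[`, "", "label"),
    solver = sims[[1]]$settings,
    diagnostics = list(
      max_abs_residual_rel = max(abs(prices$residual) /
                                   pmax(prices$supply_total, 1e-12))),
    files = c("world/", "availability.csv", "prices.csv", "balances_out.csv",
              "targets.csv", "gap.csv", "gap_summary.csv", "table1_like.csv",
              "policies.csv", "policy_counts.csv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, world = world, sims = sims,
                 targets = targets, gaps = gaps, summaries = summaries,
                 policy = policy))
}

#' Validate a set of pipeline output tables
#'
#' Re-reads the declared CSVs from a pipeline output directory and checks
#' column schemas and cross-table invariants: base-year trade closure,
#' age-band population conservation, gap-ratio/pass-flag coherence, and
#' region partition sums. Violations are collected and returned, not
#' raised one at a time.
#'
#' @param dir A directory written by [run_pipeline()].
#' @return data.frame with columns `check`, `table`, `detail`; zero rows
#'   means every check passed.
#' @export
validate_tables <- function(dir) {
  violations <- list()
  flag <- function(check, table, detail) {
    violations[[length(violations) + 1]] <<- data.frame(
      check = check, table = table, detail = detail, stringsAsFactors = FALSE)
  }
  need <- list(
    "world/balances.csv" = c("country", "commodity", "production",
                             "food_demand", "other_demand", "net_trade"),
    "world/population.csv" = c("country", "year", "scenario", "age_0_4",
                               "age_5_14", "age_15plus", "total"),
    "world/countries.csv" = c("country", "region", "income_group"),
    "gap.csv" = c("country", "year", "scenario", "scheme", "consumption",
                  "ratio_min", "pass_min", "pass_age"),
    "gap_summary.csv" = c("group", "year", "scenario", "scheme",
                          "population", "pop_pass_min"))
  tabs <- list()
  for (f in names(need)) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      flag("file-exists", f, "missing file")
      next
    }
    tb <- read.csv(p, stringsAsFactors = FALSE)
    missing <- setdiff(need[[f]], names(tb))
    if (length(missing) > 0) {
      flag("schema", f, paste("missing columns:",
                              paste(missing, collapse = ", ")))
    } else {
      tabs[[f]] <- tb
    }
  }

  bal <- tabs[["world/balances.csv"]]
  if (!is.null(bal)) {
    nt <- tapply(bal$net_trade, bal$commodity, sum)
    qs <- tapply(bal$production, bal$commodity, sum)
    bad <- abs(nt) > 1e-6 * pmax(qs, 1e-12)
    if (any(bad)) {
      flag("trade-closure", "world/balances.csv",
           paste("net trade does not sum to zero for:",
                 paste(names(nt)[bad], collapse = ", ")))
    }
  }
  pop <- tabs[["world/population.csv"]]
  if (!is.null(pop)) {
    dev <- abs(pop$age_0_4 + pop$age_5_14 + pop$age_15plus - pop$total)
    if (any(dev > 1e-6 * pmax(pop$total, 1))) {
      flag("age-band-sum", "world/population.csv",
           "age bands do not sum to the country total")
    }
  }
  ctry <- tabs[["world/countries.csv"]]
  if (!is.null(ctry) && any(is.na(ctry$region) | !nzchar(ctry$region))) {
    flag("grouping", "world/countries.csv", "country without region")
  }
  gap <- tabs[["gap.csv"]]
  if (!is.null(gap)) {
    if (any(gap$pass_min != (gap$ratio_min >= 1))) {
      flag("ratio-flag", "gap.csv", "pass_min inconsistent with ratio_min")
    }
  }
  gs <- tabs[["gap_summary.csv"]]
  if (!is.null(gs) && any(gs$group == "Global")) {
    glob <- gs[gs$group == "Global", ]
    regs <- gs[gs$group != "Global", ]
    regsum <- aggregate(list(population = regs$population),
                        by = list(year = regs$year, scenario = regs$scenario,
                                  scheme = regs$scheme), FUN = sum)
    mg <- merge(glob, regsum, by = c("year", "scenario", "scheme"),
                suffixes = c("", ".regions"))
    if (any(abs(mg$population - mg$population.regions) >
            1e-6 * pmax(mg$population, 1))) {
      flag("partition", "gap_summary.csv",
           "regional populations do not sum to the global row")
    }
  }
  if (length(violations) == 0) {
    data.frame(check = character(0), table = character(0),
               detail = character(0), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, violations)
  }
}
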