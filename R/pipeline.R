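## Config-driven analysis pipeline ----------------------------------------

.known_config_keys <- c("seed", "temperature", "output_dir", "stages",
                        "generate", "estimate", "restraints", "ledger", "fits")

#' Read and validate a pipeline configuration
#'
#' YAML configuration with units fixed package-wide (kcal, Angstrom, K, mM).
#' Unknown top-level keys are rejected rather than ignored.
#'
#' @param path YAML file, or a named list already in memory.
#' @return The validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), .known_config_keys)
  .assert(length(unknown) == 0, "bindfe_config_error",
          paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  .assert(!is.null(cfg$seed), "bindfe_config_error", "config needs a seed")
  if (is.null(cfg$temperature)) cfg$temperature <- 300
  if (is.null(cfg$stages)) cfg$stages <- c("generate", "estimate", "ledger", "fits")
  cfg
}

#' Run the analysis pipeline described by a configuration
#'
#' Executes the requested stages in dependency order -- `generate` (seeded
#' umbrella dataset on an analytic potential), `estimate` (WHAM PMF, overlap
#' QC, separation integral I* and surface term S*), `ledger` (Woo-Roux
#' assembly), `fits` (salt regression / interpolation) -- writing TSV/JSON
#' outputs plus the resolved configuration next to them.  Reruns with the
#' same seed produce identical numbers.
#'
#' @param config a YAML path or list accepted by [read_pipeline_config()].
#' @return A result bundle (named list per stage), invisibly also written to
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  out <- cfg$output_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  bundle <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      .bindfe_stop("bindfe_stage_error",
                   sprintf("stage '%s' failed: %s", name, conditionMessage(e))))
    message(sprintf("[bindfe] stage=%s seed=%s elapsed=%.2fs",
                    name, cfg$seed, proc.time()[["elapsed"]] - t0))
    res
  }

  if ("generate" %in% cfg$stages) {
    g <- cfg$generate
    .assert(!is.null(g), "bindfe_config_error", "generate stage needs a 'generate' block")
    bundle$dataset <- stage("generate", {
      pot <- do.call(analytic_potential,
                     c(list(form = g$potential$form), g$potential$params))
      generate_umbrella_dataset(pot, unlist(g$centers), g$k_bias,
                                convention = g$convention %||% "full",
                                n_per_window = g$n_per_window %||% 2000,
                                temperature = cfg$temperature,
                                seed = cfg$seed)
    })
  }

  if ("estimate" %in% cfg$stages) {
    e <- cfg$estimate %||% list()
    .assert(!is.null(bundle$dataset), "bindfe_stage_error",
            "estimate stage requires the generate stage")
    bundle$pmf <- stage("estimate",
      wham_1d(bundle$dataset$windows, bin_width = e$bin_width %||% 0.1,
              tol = e$tol %||% 1e-7))
    if (!is.null(e$site_range)) {
      bundle$I_star <- pmf_to_I_star(bundle$pmf, unlist(e$site_range), e$r_ref)
      if (!is.null(cfg$restraints)) {
        r <- cfg$restraints
        sch <- restraint_scheme(P0 = 0, P1 = 1, P2 = 2, Q0 = 3, Q1 = 4, Q2 = 5,
                                Theta0 = r$Theta0 %||% pi / 2,
                                Phi0 = r$Phi0 %||% 0, Psi0 = r$Psi0 %||% 0,
                                theta0 = r$theta0 %||% pi / 2,
                                phi0 = r$phi0 %||% 0,
                                k = r$k, convention = r$convention %||% "full")
        bundle$S_star <- axial_surface_term(sch, r$r_star, cfg$temperature)
        bundle$sep_term <- standard_state_term(bundle$I_star, bundle$S_star,
                                               cfg$temperature)
      }
    }
    if (!is.null(out)) write_pmf_tsv(bundle$pmf, file.path(out, "pmf.tsv"))
  }

  if ("ledger" %in% cfg$stages) {
    l <- cfg$ledger
    .assert(!is.null(l), "bindfe_config_error", "ledger stage needs a 'ledger' block")
    bundle$ledger <- stage("ledger", {
      led <- if (!is.null(l$from_table))
        ledger_from_table(l$from_table$water, l$from_table$salt_mM)
      else free_energy_ledger(unlist(l$values), unlist(l$stderrs),
                              temperature = cfg$temperature)
      list(ledger = led, dG_b = assemble_binding_free_energy(led),
           deltas = bulk_to_site_deltas(led))
    })
    if (!is.null(out)) {
      write_ledger_json(bundle$ledger$ledger, file.path(out, "ledger.json"))
      jsonlite::write_json(bundle$ledger$dG_b, file.path(out, "dG_b.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if ("fits" %in% cfg$stages) {
    f <- cfg$fits %||% list()
    bundle$fits <- stage("fits", {
      res <- list()
      if (!is.null(f$salt_regression)) {
        sr <- f$salt_regression
        ser <- table_salt_series(sr$water, sr$source %||% "restraint")
        reg <- salt_dependence_regression(ser)
        res$salt_slope <- reg$slope
        res$salt_slope_stderr <- reg$stderr
        if (!is.null(sr$target_dG))
          res$interpolated_mM <- interpolate_concentration(ser, sr$target_dG)
      }
      res
    })
    if (!is.null(out) && length(bundle$fits))
      jsonlite::write_json(bundle$fits, file.path(out, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
  }

  if (!is.null(out)) {
    resolved <- cfg
    resolved$package_version <- as.character(utils::packageVersion("bindfe"))
    jsonlite::write_json(resolved, file.path(out, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
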