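# Reproducible pipeline runs: each command validates its configuration,
# writes its artifacts into a run directory, and records a manifest
# (command, full configuration, seed, package version) from which the
# artifacts can be regenerated bit for bit.

pipeline_commands <- list(
  generate   = c("spec", "render_first"),
  simulate   = c("n_persons", "n_items", "dist", "params"),
  calibrate  = c("responses", "max_cycles", "a_prior_sd"),
  score      = c("responses", "parameters", "rescale"),
  evaluate   = c("responses", "method", "min_n", "n_factors", "item_types"),
  bestscales = c("data", "criterion", "k", "selection", "r_cut", "n_items")
)

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("`config` must be a list or a YAML path.", call. = FALSE)
  config
}

validate_config <- function(command, config) {
  if (!command %in% names(pipeline_commands)) {
    stop("unknown command `", command, "`; available: ",
         paste(names(pipeline_commands), collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(config), pipeline_commands[[command]])
  if (length(extra)) {
    stop("unknown config key(s) for `", command, "`: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  invisible(config)
}

write_manifest <- function(out_dir, command, config, seed, artifacts) {
  manifest <- list(
    tool = "hexrot",
    version = as.character(utils::packageVersion("hexrot")),
    command = command,
    seed = seed,
    config = config,
    config_hash = rlang::hash(list(command = command, config = config,
                                   seed = seed)),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

read_params_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("item_id", "a", "b") %in% names(p))) {
    stop("parameter table needs columns item_id, a, b: ", path, call. = FALSE)
  }
  tibble::as_tibble(p)
}

read_responses_csv <- function(path) {
  if (!file.exists(path)) stop("responses file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Run a pipeline command
#'
#' Thin, reproducible wrappers over the package's functions, mirroring the
#' stages of building and evaluating the measure: `generate` (item bank
#' JSON), `simulate` (planned-missingness design + responses),
#' `calibrate` (2PL parameters CSV), `score` (EAP abilities + reported
#' scores), `evaluate` (pairwise correlations, omega report, item-type
#' factor check) and `bestscales` (BISCUIT report). Every run writes
#' `manifest.json` with the command, configuration, seed and package
#' version.
#'
#' @param command One of `generate`, `simulate`, `calibrate`, `score`,
#'   `evaluate`, `bestscales`.
#' @param config Named list (or YAML file path) of command-specific keys;
#'   unknown keys are rejected before any work happens.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed recorded in the manifest and driving all
#'   randomness of the command.
#' @return The manifest, invisibly.
#' @export
run_command <- function(command, config = list(), out_dir, seed = 1L) {
  config <- load_config(config)
  validate_config(command, config)
  seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  path <- function(f) file.path(out_dir, f)

  if (command == "generate") {
    spec_name <- config$spec %||% "paper70"
    pool <- generate_pool(pool_spec(spec_name), seed = seed)
    serialize_pool(pool, path("bank.json"))
    artifacts <- "bank.json"
    if (isTRUE(config$render_first)) {
      render_item(pool$items[[1L]], path = path("item_001.svg"))
      artifacts <- c(artifacts, "item_001.svg")
    }
  } else if (command == "simulate") {
    params <- if (is.null(config$params)) surrogate_item_bank()
              else read_params_csv(config$params)
    n_items <- config$n_items %||% nrow(params)
    params <- params[seq_len(n_items), ]
    dist <- if (is.null(config$dist)) sapa_count_dist()
            else unlist(config$dist)
    des <- sapa_design(config$n_persons %||% 10000L, n_items, dist = dist,
                       seed = seed)
    resp <- simulate_responses(des, params, seed = seed + 1L)
    utils::write.csv(des$administrations, path("design.csv"), row.names = FALSE)
    utils::write.csv(resp, path("responses.csv"), row.names = FALSE)
    utils::write.csv(tibble::tibble(person_id = names(attr(resp, "thetas")),
                                    theta = unname(attr(resp, "thetas"))),
                     path("thetas.csv"), row.names = FALSE)
    artifacts <- c("design.csv", "responses.csv", "thetas.csv")
  } else if (command == "calibrate") {
    resp <- read_responses_csv(config$responses %||% path("responses.csv"))
    fit <- fit_2pl(resp, max_cycles = config$max_cycles %||% 500L,
                   a_prior_sd = config$a_prior_sd)
    utils::write.csv(tidy(fit), path("parameters.csv"), row.names = FALSE)
    artifacts <- "parameters.csv"
  } else if (command == "score") {
    resp <- read_responses_csv(config$responses %||% path("responses.csv"))
    params <- read_params_csv(config$parameters %||% path("parameters.csv"))
    sc <- score_eap(resp, params)
    if (!identical(config$rescale, FALSE)) {
      sc$score <- rescale_scores(sc$theta)
    }
    utils::write.csv(sc, path("scores.csv"), row.names = FALSE)
    artifacts <- "scores.csv"
  } else if (command == "evaluate") {
    resp <- read_responses_csv(config$responses %||% path("responses.csv"))
    Y <- as_response_matrix(resp)
    pc <- pairwise_correlation(Y, method = config$method %||% "pearson",
                               min_n = config$min_n %||% 500L)
    utils::write.csv(tidy(pc), path("correlations.csv"), row.names = FALSE)
    artifacts <- "correlations.csv"
    R <- pc$R
    complete <- !anyNA(R)
    if (complete) {
      om <- omega(R, n_factors = config$n_factors %||% 4L, seed = seed)
      jsonlite::write_json(
        list(omega_h = om$omega_h, omega_t = om$omega_t, alpha = om$alpha,
             n_factors = om$n_factors, n_items = om$n_items),
        path("omega.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
      artifacts <- c(artifacts, "omega.json")
      if (!is.null(config$item_types)) {
        types <- unlist(config$item_types)[colnames(R)]
        chk <- item_type_factor_check(R, unname(types),
                                      n_factors = length(unique(types)),
                                      seed = seed)
        utils::write.csv(chk$dominant, path("item_type_factors.csv"),
                         row.names = FALSE)
        artifacts <- c(artifacts, "item_type_factors.csv")
      }
    } else {
      warning("correlation matrix has missing entries; omega skipped.",
              call. = FALSE)
    }
  } else if (command == "bestscales") {
    d <- tibble::as_tibble(utils::read.csv(config$data, stringsAsFactors = FALSE))
    fit <- best_scales_cv(d, config$criterion, k = config$k %||% 10L,
                          selection = config$selection %||% "abs_r_cut",
                          r_cut = config$r_cut %||% 0.2,
                          n_items = config$n_items %||% 10L, seed = seed)
    jsonlite::write_json(
      list(report = tidy(fit), cv_r = fit$cv_r, in_sample_r = fit$in_sample_r,
           k = fit$k, n = fit$n),
      path("biscuit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(utils::capture.output(print(fit)), path("biscuit.txt"))
    artifacts <- c("biscuit.json", "biscuit.txt")
  }

  invisible(write_manifest(out_dir, command, config, seed, artifacts))
}
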