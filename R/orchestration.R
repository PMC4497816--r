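# ---------------------------------------------------------------------------
# Run management: genotype x model x repeats with split seeds, analysis
# summaries, and K sweeps.
# ---------------------------------------------------------------------------

#' Run configuration
#'
#' Defaults are the reference parameter set: 2,000 neurons per structure and
#' each model's published parameter values (which the model wrappers carry
#' as argument defaults); `model_args` overrides individual parameters.
#'
#' @param model `"gierer"`, `"koulakov"`, `"whitelaw"` or `"willshaw"`.
#' @param genotype a [genotype_spec()] or genotype name.
#' @param n_r,n_sc neuron counts.
#' @param repeats number of repeats with different initial conditions.
#' @param seed master seed; deterministically split per repeat.
#' @param model_args named list of overrides passed to the model runner
#'   (e.g. `n_epochs`, `n_steps`).
#' @param analyses character vector of analyses to run per repeat: any of
#'   `"lattice"`, `"collapse"`, `"coverage"`.
#' @param lattice_args,collapse_args extra arguments for the analyses.
#' @return an object of class `run_config`.
#' @export
run_config <- function(model, genotype = "wild_type", n_r = 2000,
                       n_sc = 2000, repeats = 10, seed = 1,
                       model_args = list(),
                       analyses = c("lattice", "collapse", "coverage"),
                       lattice_args = list(), collapse_args = list()) {
  model <- match.arg(model, c("gierer", "koulakov", "whitelaw", "willshaw"))
  if (is.character(genotype)) genotype <- genotype_spec(genotype)
  structure(list(model = model, genotype = genotype, n_r = n_r, n_sc = n_sc,
                 repeats = repeats, seed = seed, model_args = model_args,
                 analyses = analyses, lattice_args = lattice_args,
                 collapse_args = collapse_args),
            class = "run_config")
}

#' Run one model on one substrate
#'
#' Thin dispatcher over [run_gierer()], [run_koulakov()], [run_whitelaw()],
#' [run_willshaw()].
#'
#' @param model model name.
#' @param substrate the substrate.
#' @param seed RNG seed for the model.
#' @param ... passed to the model runner.
#' @return a `connection_state`.
#' @export
run_model <- function(model, substrate, seed = 1, ...) {
  fn <- switch(model,
               gierer = run_gierer, koulakov = run_koulakov,
               whitelaw = run_whitelaw, willshaw = run_willshaw,
               stop("unknown model: ", model))
  fn(substrate, seed = seed, ...)
}

#' Analyse one connection state
#'
#' @param state a `connection_state`.
#' @param substrate its substrate.
#' @param analyses which measures to compute (`"lattice"`, `"collapse"`,
#'   `"coverage"`).
#' @param lattice_args,collapse_args extra arguments.
#' @return one-row data frame of measures (NA where not computed), plus the
#'   full result objects as attribute `"details"`.
#' @export
analyze_state <- function(state, substrate,
                          analyses = c("lattice", "collapse", "coverage"),
                          lattice_args = list(), collapse_args = list()) {
  mp <- strongest_mapping(threshold_weights(state), substrate)
  out <- data.frame(nodes_pct = NA_real_, edges_pct = NA_real_,
                    ap_polarity = NA_real_, ml_polarity = NA_real_,
                    orientation_diff = NA_real_, collapse_pct = NA_real_,
                    collapse_status = NA_character_, coverage_pct = NA_real_)
  det <- list(mapping = mp)
  if ("lattice" %in% analyses) {
    la <- do.call(lattice_analysis, c(list(mp), lattice_args))
    out$nodes_pct <- la$nodes_pct
    out$edges_pct <- la$edges_pct
    out$ap_polarity <- la$ap_polarity
    out$ml_polarity <- la$ml_polarity
    out$orientation_diff <- la$orientation_diff
    det$lattice <- la
  }
  if ("collapse" %in% analyses) {
    cp <- do.call(collapse_point, c(list(mp), collapse_args))
    out$collapse_pct <- cp$collapse_pct
    out$collapse_status <- cp$status
    det$collapse <- cp
  }
  if ("coverage" %in% analyses) {
    cov <- sc_coverage(state, substrate)
    out$coverage_pct <- cov$area_pct
    det$coverage <- cov
  }
  attr(out, "details") <- det
  out
}

#' Run a full experiment (one model, one genotype, several repeats)
#'
#' Per repeat: build the substrate, run the model and analyse the final
#' map, each from seeds deterministically split from the master seed
#' ([seed_streams()]), so the whole experiment is reproducible bit for bit.
#'
#' @param config a [run_config()].
#' @param keep_states keep the per-repeat `connection_state`s (memory-heavy).
#' @param out_dir optional directory: per-repeat measures and the summary
#'   are written there as CSV.
#' @return an object of class `experiment_result`: list with `per_repeat`
#'   (data frame, one row per repeat) and `summary` (mean and SD of each
#'   numeric measure; SD over repeats with the n-1 denominator).
#' @export
run_experiment <- function(config, keep_states = FALSE, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seeds <- matrix(seed_streams(config$seed, 2 * config$repeats), ncol = 2)
  rows <- vector("list", config$repeats)
  states <- if (keep_states) vector("list", config$repeats) else NULL
  for (r in seq_len(config$repeats)) {
    sub <- build_substrate(config$genotype, n_r = config$n_r,
                           n_sc = config$n_sc, seed = seeds[r, 1])
    st <- do.call(run_model, c(list(config$model, sub, seed = seeds[r, 2]),
                               config$model_args))
    row <- analyze_state(st, sub, analyses = config$analyses,
                         lattice_args = config$lattice_args,
                         collapse_args = config$collapse_args)
    attr(row, "details") <- NULL
    row$repeat_id <- r
    rows[[r]] <- row
    if (keep_states) states[[r]] <- st
  }
  per_repeat <- do.call(rbind, rows)
  num <- vapply(per_repeat, is.numeric, logical(1)) &
    names(per_repeat) != "repeat_id"
  summary <- data.frame(
    measure = names(per_repeat)[num],
    mean = vapply(per_repeat[num], function(v) mean(v, na.rm = TRUE),
                  numeric(1)),
    sd = vapply(per_repeat[num], function(v) sd(v, na.rm = TRUE),
                numeric(1)),
    n = vapply(per_repeat[num], function(v) sum(!is.na(v)), numeric(1)),
    row.names = NULL)
  res <- structure(list(config = config, per_repeat = per_repeat,
                        summary = summary, states = states),
                   class = "experiment_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(per_repeat, file.path(out_dir, "per_repeat.csv"),
              row.names = FALSE)
    write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  }
  res
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %s / %s, %d repeats\n",
              x$config$model, x$config$genotype$name, x$config$repeats))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Weak-gradient (K) sweep for the ephrin-A triple knock-out
#'
#' Reruns the TKO genotype over a grid of weak-gradient strengths `K` and
#' reports lattice edge retention and AP polarity per K.
#'
#' @param model model name.
#' @param K_values weak gradient strengths.
#' @param repeats repeats per K.
#' @param n_r,n_sc neuron counts.
#' @param seed master seed.
#' @param model_args overrides for the model runner.
#' @return data frame with one row per K (means and SDs over repeats).
#' @export
sweep_tko_K <- function(model, K_values = c(1, 0.1, 0.01, 0.002),
                        repeats = 5, n_r = 2000, n_sc = 2000, seed = 1,
                        model_args = list()) {
  out <- lapply(seq_along(K_values), function(q) {
    cfg <- run_config(model, genotype_spec("tko", K = K_values[q]),
                      n_r = n_r, n_sc = n_sc, repeats = repeats,
                      seed = seed + q - 1, model_args = model_args,
                      analyses = "lattice")
    res <- run_experiment(cfg)
    s <- res$summary
    data.frame(K = K_values[q],
               edges_pct = s$mean[s$measure == "edges_pct"],
               edges_sd = s$sd[s$measure == "edges_pct"],
               ap_polarity = s$mean[s$measure == "ap_polarity"],
               ap_sd = s$sd[s$measure == "ap_polarity"])
  })
  do.call(rbind, out)
}
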