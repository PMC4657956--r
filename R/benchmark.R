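# One-command reproduction of the simulation experiments: simulate,
# analyze with each requested method, evaluate.

#' Run one simulation experiment grid
#'
#' For every grid cell (combination of sample size, effect size,
#' heritability and, for the confounded scenario, confounding strength),
#' simulates a dataset, analyzes it with each requested method, and
#' evaluates power, FDR detections, genomic control, AUC and calibration.
#'
#' Scenarios: \code{"power_no_structure"} (age-like predictor, h2 = 0
#' data), \code{"power_kinship"} (age-like predictor, kinship-structured
#' data), \code{"null_confounded"} (predictor confounded with population
#' structure, all effects null).
#'
#' @param scenario one of the three designs above.
#' @param n vector of sample sizes.
#' @param pve vector of effect sizes (ignored for the null scenario).
#' @param h2 vector of heritabilities.
#' @param target_r2 vector of predictor-PC1 squared correlations
#'   (confounded scenario).
#' @param methods subset of \code{c("bmm", "betabinom", "binomial",
#'   "linear", "lmm")}.
#' @param n_sites,n_true full-scale site counts before scaling.
#' @param scale site-count multiplier in (0, 1] for desk-scale runs.
#' @param replicates independent replicates per cell.
#' @param seed master seed.
#' @param bmm_iter,bmm_burnin MCMC budget per site for the BMM.
#' @param level FDR level for power summaries.
#' @param verbose print progress.
#' @return data.frame: one row per (cell, replicate, method) with the
#'   [evaluate_scan()] summary columns.
#' @export
run_experiment <- function(scenario = c("power_no_structure",
                                        "power_kinship",
                                        "null_confounded"),
                           n = 80, pve = 0.10, h2 = 0.6, target_r2 = 0.5,
                           methods = c("bmm", "betabinom", "binomial",
                                       "linear", "lmm"),
                           n_sites = 5000, n_true = 500, scale = 0.2,
                           replicates = 1, seed = 1,
                           bmm_iter = 2000, bmm_burnin = 200,
                           level = 0.10, verbose = FALSE) {
  scenario <- match.arg(scenario)
  stopifnot(scale > 0, scale <= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  m_sites <- max(20L, round(n_sites * scale))
  m_true <- if (scenario == "null_confounded") 0L
            else max(5L, round(n_true * scale))
  if (scenario == "null_confounded") pve <- 0
  grid <- expand.grid(n = n, pve = pve, h2 = h2,
                      target_r2 = if (scenario == "null_confounded")
                        target_r2 else NA,
                      rep = seq_len(replicates))
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    cell <- grid[gi, ]
    cell_seed <- (seed + 1299709 * gi) %% 2147483647
    sim <- simulate_dataset(
      n = cell$n, n_sites = m_sites, n_true = m_true,
      pve = if (scenario == "null_confounded") 0 else cell$pve,
      h2 = if (scenario == "power_no_structure") 0 else cell$h2,
      predictor_mode = if (scenario == "null_confounded") "confounded"
                       else "age_like",
      kinship_mode = if (scenario == "null_confounded") "two_pop"
                     else "baboon_like",
      target_r2 = if (scenario == "null_confounded") cell$target_r2
                  else 0.5,
      seed = cell_seed)
    for (meth in methods) {
      if (verbose)
        message(sprintf("cell %d/%d: %s", gi, nrow(grid), meth))
      res <- .run_method(meth, sim, bmm_iter, bmm_burnin, cell_seed)
      ev <- evaluate_scan(res, sim$truth, level = level)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(scenario = scenario, n = cell$n, pve = cell$pve,
                   h2 = cell$h2, target_r2 = cell$target_r2,
                   rep = cell$rep, method = meth,
                   n_sites = m_sites, n_true = m_true,
                   stringsAsFactors = FALSE),
        ev)
    }
  }
  do.call(rbind, rows)
}

.run_method <- function(method, sim, bmm_iter, bmm_burnin, seed) {
  switch(method,
    bmm = bmm_scan(sim$dataset, sim$x, K = sim$K,
                   control = bmm_control(n_iter = bmm_iter,
                                         n_burnin = bmm_burnin),
                   seed = seed),
    betabinom = betabinom_scan(sim$dataset, sim$x),
    binomial = binomial_scan(sim$dataset, sim$x),
    linear = {
      z <- transform_methylation(sim$dataset, "quantile_normal")
      z <- knn_impute(z)
      linear_scan(z, sim$x,
                  site_info = data.frame(site_id = sim$dataset$site_ids))
    },
    lmm = {
      z <- transform_methylation(sim$dataset, "quantile_normal")
      z <- knn_impute(z)
      lmm_scan(z, sim$x, K = sim$K,
               site_info = data.frame(site_id = sim$dataset$site_ids))
    },
    stop("unknown method: ", method))
}
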