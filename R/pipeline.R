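# End-to-end orchestration: filter -> diversity -> rate inference -> SBI ->
# null-ensemble trend tests -> homogenization classification -> per-OTU
# trends, writing one artifact per stage plus a manifest.

#' Assemble a pipeline run configuration
#'
#' @param counts_path,metadata_path input files (ignored when `scenario`
#'   is supplied: the synthetic dataset is generated in the run directory).
#' @param scenario optional [scenario_config()] for a synthetic run.
#' @param filter a [filter_config()].
#' @param sbi_n_sims SBI training-set size (full-scale 100000; the
#'   `desk_scale` preset uses 2000).
#' @param sbi_epochs maximum SBI training epochs.
#' @param n_null null-ensemble size (full-scale 1000).
#' @param metric beta metric.
#' @param otu_engine engine for [otu_occurrence_trend()].
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param outdir run directory.
#' @param desk_scale apply the reduced-size preset (2000 SBI simulations,
#'   null ensemble 200, fixed-intercept OTU-trend engine).
#' @return A list of class `run_config`.
#' @export
run_config <- function(counts_path = NULL, metadata_path = NULL,
                       scenario = NULL, filter = filter_config(),
                       sbi_n_sims = 100000L, sbi_epochs = 300L,
                       n_null = 1000L, metric = "jaccard",
                       otu_engine = "glmer",
                       seed = 1L, outdir = "etibdiv_run",
                       desk_scale = FALSE) {
  if (desk_scale) {
    sbi_n_sims <- 2000L; n_null <- 200L; otu_engine <- "glm"
  }
  structure(list(counts_path = counts_path, metadata_path = metadata_path,
                 scenario = scenario, filter = filter,
                 sbi_n_sims = as.integer(sbi_n_sims),
                 sbi_epochs = as.integer(sbi_epochs),
                 n_null = as.integer(n_null), metric = metric,
                 otu_engine = otu_engine, seed = as.integer(seed),
                 outdir = outdir, desk_scale = desk_scale),
            class = "run_config")
}

#' Run the full diversity-trend analysis pipeline
#'
#' Stages, in order: (0) load or generate the OTU table; (1) filter and
#' convert to occurrence; (2) diversity series; (3) ACE detection + HMM
#' immigration/extinction rates per site; (4) SBI estimation of S and
#' log(alpha); (5) null-ensemble simulation and trend tests per index;
#' (6) homogenization/differentiation classification; (7) per-OTU
#' occurrence trends. Each stage writes its artifact into `cfg$outdir`;
#' a failure aborts with the stage name while earlier artifacts remain.
#'
#' @param cfg a [run_config()].
#' @param through last stage to run: one of `"filter"`, `"diversity"`,
#'   `"rates"`, `"sbi"`, `"nulltest"`, `"blowes"`, `"otutrends"` (default:
#'   everything).
#' @return The run directory path, invisibly; the stage results are also
#'   returned in the `results` attribute.
#' @export
run_pipeline <- function(cfg, through = c("otutrends", "filter", "diversity",
                                          "rates", "sbi", "nulltest",
                                          "blowes")) {
  stopifnot(inherits(cfg, "run_config"))
  through <- match.arg(through)
  order_ <- c("filter", "diversity", "rates", "sbi", "nulltest", "blowes",
              "otutrends")
  wanted <- function(st) match(st, order_) <= match(through, order_)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    ed_log("stage ", name, " ...")
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(err)
      stop2("pipeline stage '", name, "' failed: ", conditionMessage(err)))
    ed_log("stage ", name, " done (",
           round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), "s)")
    out
  }
  res <- list()

  tbl <- stage("input", {
    if (!is.null(cfg$scenario)) {
      syn <- generate_scenario(cfg$scenario)
      write_scenario(syn, file.path(cfg$outdir, "synthetic"))
      syn$table
    } else {
      if (is.null(cfg$counts_path) || !file.exists(cfg$counts_path))
        stop2("input counts file missing: ", cfg$counts_path %||% "<NULL>")
      read_otu_table(cfg$counts_path, cfg$metadata_path)
    }
  })

  occ <- stage("filter", {
    ft <- filter_dataset(tbl, cfg$filter)
    oc <- to_occurrence(ft, cfg$filter$presence_threshold)
    write_occurrence(oc, file.path(cfg$outdir, "occurrence.tsv"),
                     filter_log = attr(ft, "filter_log"))
    res$table <- ft
    oc
  })

  if (!wanted("diversity")) return(finish(cfg, res, list(occ = occ)))
  div <- stage("diversity", {
    d <- compute_diversity(occ, cfg$metric)
    write_diversity(d, file.path(cfg$outdir, "diversity"))
    d
  })

  if (!wanted("rates"))
    return(finish(cfg, res, list(occ = occ, diversity = div)))
  rates_df <- stage("rates", {
    r <- infer_rates(res$table, occ)
    utils::write.table(r, file.path(cfg$outdir, "rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })
  rates <- lapply(seq_len(nrow(rates_df)), function(i)
    community_rates(rates_df$site[i], rates_df$m_hat[i],
                    rates_df$e_hat[i], rates_df$rho[i]))

  if (!wanted("sbi"))
    return(finish(cfg, res, list(occ = occ, diversity = div,
                                 rates = rates_df)))
  sbi_est <- stage("sbi", {
    s_obs <- sum(Reduce(`|`, lapply(occ$mats, function(m) colSums(m) > 0)))
    gmax <- max(div$gamma$gamma)
    training <- build_training_set(cfg$sbi_n_sims, rates, occ$scheme,
                                   prior_S = c(s_obs, 3 * gmax),
                                   prior_log_alpha = c(1, 5),
                                   seed = child_seed(cfg$seed, 41L),
                                   metric = cfg$metric)
    model <- train_sbi(training, epochs = cfg$sbi_epochs,
                       seed = child_seed(cfg$seed, 43L))
    est <- predict_params(model, featurize(div, occ$scheme), s_obs = s_obs)
    out <- list(S_hat = round(unname(est["S"])),
                log_alpha_hat = unname(est["log_alpha"]),
                s_obs = s_obs, gamma_max = gmax,
                r2_test = as.list(model$r2_test),
                n_sims = cfg$sbi_n_sims)
    jsonlite::write_json(out, file.path(cfg$outdir, "sbi_estimates.json"),
                         auto_unbox = TRUE, digits = NA)
    out
  })

  if (!wanted("nulltest"))
    return(finish(cfg, res, list(occ = occ, diversity = div,
                                 rates = rates_df, sbi = sbi_est)))
  tests <- stage("nulltest", {
    null <- simulate_null_ensemble(rates, sbi_est$S_hat,
                                   sbi_est$log_alpha_hat, occ$scheme,
                                   n = cfg$n_null,
                                   seed = child_seed(cfg$seed, 47L),
                                   metric = cfg$metric)
    res$null <- null
    kinds <- c("alpha", "temporal_beta", "spatial_beta", "gamma")
    rows <- lapply(kinds, function(k) {
      tr <- fit_trend(div, k)
      nt <- test_trend(tr, null[[k]])
      data.frame(index = k, slope = tr$slope, slope_se = tr$slope_se,
                 phi = tr$phi, n_obs = tr$n_obs, p_high = nt$p_high,
                 p_low = nt$p_low, significant = nt$significant)
    })
    out <- do.call(rbind, rows)
    utils::write.table(out, file.path(cfg$outdir, "trend_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  if (!wanted("blowes"))
    return(finish(cfg, res, list(occ = occ, diversity = div,
                                 rates = rates_df, sbi = sbi_est,
                                 tests = tests)))
  blowes <- stage("blowes", {
    b <- blowes_classify(div, res$null)
    jsonlite::write_json(unclass(b), file.path(cfg$outdir, "blowes.json"),
                         auto_unbox = TRUE, digits = NA)
    b
  })

  if (!wanted("otutrends"))
    return(finish(cfg, res, list(occ = occ, diversity = div,
                                 rates = rates_df, sbi = sbi_est,
                                 tests = tests, blowes = blowes)))
  otu_tr <- stage("otutrends", {
    ot <- otu_occurrence_trend(occ, engine = cfg$otu_engine)
    utils::write.table(ot, file.path(cfg$outdir, "otu_trends.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ot
  })

  finish(cfg, res, list(occ = occ, diversity = div, rates = rates_df,
                        sbi = sbi_est, tests = tests, blowes = blowes,
                        otu_trends = otu_tr))
}

# write the run manifest (artifacts actually present) and return the run
# directory with the stage results attached
finish <- function(cfg, res, results) {
  known <- c("occurrence.tsv", "diversity_alpha.tsv",
             "diversity_temporal_beta.tsv", "diversity_spatial_beta.tsv",
             "diversity_gamma.tsv", "rates.tsv", "sbi_estimates.json",
             "trend_tests.tsv", "blowes.json", "otu_trends.tsv")
  manifest <- list(
    package = "etibdiv",
    version = as.character(utils::packageVersion("etibdiv")),
    seed = cfg$seed,
    desk_scale = cfg$desk_scale,
    config = cfg[c("sbi_n_sims", "sbi_epochs", "n_null", "metric",
                   "otu_engine")],
    artifacts = known[file.exists(file.path(cfg$outdir, known))])
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- cfg$outdir
  attr(out, "results") <- results
  invisible(out)
}
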