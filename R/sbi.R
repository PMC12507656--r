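# Simulation-based inference of the metacommunity size S and the
# non-neutrality concentration log(alpha): simulate the occupancy model at
# parameters drawn from uniform priors, summarize every simulation by its
# diversity series, and train a neural regressor mapping summaries to
# (S, log alpha).

#' Flatten a diversity series into the fixed-length SBI feature vector
#'
#' Layout (versioned `"v1"`, recorded on the result): per-year mean alpha
#' richness, per-year bootstrap gamma, per-year mean spatial beta, per-lag
#' mean temporal beta for lags 1..L, where the years and L = max observable
#' lag come from the sampling scheme. Cells the scheme cannot produce
#' (years with < 2 sites, unobservable lags) are masked: the mask is
#' returned alongside and masked cells are excluded from scaling and
#' zeroed before prediction.
#'
#' @param div a `diversity_series` (see [compute_diversity()]).
#' @param scheme the sampling scheme data frame (`site`, `year`).
#' @return A list with `values` (named numeric vector), `mask` (logical,
#'   `TRUE` = observable) and `layout`.
#' @export
featurize <- function(div, scheme) {
  # two-stage temporal mean (per site-lag cell, then across sites) so that
  # ragged schemes featurize identically for empirical and simulated data
  cell <- tapply(div$temporal_beta$distance,
                 list(div$temporal_beta$site, div$temporal_beta$lag), mean)
  tb_lag <- colMeans(cell, na.rm = TRUE)
  ag <- list(
    alpha = list(site = div$alpha$site, year = div$alpha$year,
                 richness = div$alpha$richness),
    tbeta = list(lag = as.integer(colnames(cell))[!is.nan(tb_lag)],
                 distance = tb_lag[!is.nan(tb_lag)]),
    sbeta_year = div$spatial_beta$year,
    sbeta_dist = div$spatial_beta$distance,
    gamma = list(year = div$gamma$year, gamma = div$gamma$gamma))
  feature_vector(ag, scheme)
}

# shared layout builder; ag comes either from featurize() (above, tbeta
# pre-collapsed to one row per lag) or from diversity_aggregates() on a
# simulated run (tbeta rows are site-lag means); in both cases the final
# per-lag feature is the mean over site-lag cell means
feature_vector <- function(ag, scheme) {
  yrs <- sort(unique(scheme$year))
  lags <- seq_len(max(yrs) - min(yrs))
  a <- tapply(ag$alpha$richness, ag$alpha$year, mean)
  alpha_v <- as.numeric(a[as.character(yrs)])
  g <- ag$gamma$gamma[match(yrs, ag$gamma$year)]
  tb <- tapply(ag$tbeta$distance, ag$tbeta$lag, mean)
  tb_v <- as.numeric(tb[as.character(lags)])
  if (!is.null(ag$sbeta_year)) {
    sb <- tapply(ag$sbeta_dist, ag$sbeta_year, mean)
  } else {
    sb <- stats::setNames(ag$sbeta$distance, ag$sbeta$year)
  }
  sb_v <- as.numeric(sb[as.character(yrs)])
  values <- c(alpha_v, g, sb_v, tb_v)
  names(values) <- c(paste0("alpha_", yrs), paste0("gamma_", yrs),
                     paste0("sbeta_", yrs), paste0("tbeta_lag", lags))
  mask <- !is.na(values)
  values[!mask] <- 0
  list(values = values, mask = mask, layout = "v1")
}

#' Generate an SBI training set by simulating the occupancy model
#'
#' Draws `n_sims` parameter pairs from uniform priors — S from
#' `U(prior_S[1], prior_S[2])` (spanning observed richness to three times
#' the bootstrap gamma estimate when derived from data) and log(alpha) from
#' `U(prior_log_alpha[1], prior_log_alpha[2])`, default (1, 5) — simulates
#' the non-neutral model with detection thinning on the empirical scheme,
#' summarizes each run with [featurize()], and min-max scales features and
#' targets to [0, 1] with a 90/10 train/test split.
#'
#' @param n_sims number of simulations (>= 100; the full-scale analysis
#'   uses 100,000, the desk-scale profile 5,000).
#' @param rates list of per-site [community_rates()] (held fixed, from
#'   [infer_rates()]).
#' @param scheme sampling scheme data frame.
#' @param prior_S length-2 numeric, S prior bounds.
#' @param prior_log_alpha length-2 numeric, log(alpha) prior bounds.
#' @param seed RNG seed.
#' @param metric beta metric for the summaries.
#' @return A list of class `sbi_training_set`: `features`, `targets`
#'   (unscaled), `scaled` (features/targets in [0, 1]), `scaling`
#'   (per-column min/max), `mask`, `split` (`"train"`/`"test"`), `priors`.
#' @export
build_training_set <- function(n_sims, rates, scheme,
                               prior_S = c(100, 1500),
                               prior_log_alpha = c(1, 5),
                               seed = 1L,
                               metric = "jaccard") {
  if (n_sims < 100) stop2("n_sims < 100 gives a degenerate training set")
  stopifnot(prior_S[2] > prior_S[1], prior_log_alpha[2] >= prior_log_alpha[1])
  set.seed(seed)
  S_draw <- round(stats::runif(n_sims, prior_S[1], prior_S[2]))
  la_draw <- stats::runif(n_sims, prior_log_alpha[1], prior_log_alpha[2])
  feats <- NULL; mask_all <- NULL
  for (i in seq_len(n_sims)) {
    run <- simulate_etib(rates,
                         metacommunity_params(S_draw[i], la_draw[i],
                                              seed = child_seed(seed, 2L * i)),
                         scheme, seed = child_seed(seed, 2L * i + 1L),
                         init = "stationary")
    ag <- diversity_aggregates(run$observed, metric)
    fv <- feature_vector(ag, scheme)
    if (is.null(feats)) {
      feats <- matrix(0, n_sims, length(fv$values),
                      dimnames = list(NULL, names(fv$values)))
      mask_all <- matrix(FALSE, n_sims, length(fv$values))
    }
    feats[i, ] <- fv$values
    mask_all[i, ] <- fv$mask
  }
  mask <- apply(mask_all, 2, all)    # feature observable in every simulation
  targets <- cbind(S = S_draw, log_alpha = la_draw)
  scaling <- list(
    f_min = apply(feats, 2, min), f_max = apply(feats, 2, max),
    t_min = apply(targets, 2, min), t_max = apply(targets, 2, max))
  sf <- scale_minmax(feats, scaling$f_min, scaling$f_max)
  sf[, !mask] <- 0
  st <- scale_minmax(targets, scaling$t_min, scaling$t_max)
  split <- rep("train", n_sims)
  split[sample.int(n_sims, max(1L, round(0.1 * n_sims)))] <- "test"
  structure(list(features = feats, targets = targets,
                 scaled = list(features = sf, targets = st),
                 scaling = scaling, mask = mask, split = split,
                 priors = list(S = prior_S, log_alpha = prior_log_alpha),
                 metric = metric, seed = seed),
            class = "sbi_training_set")
}

scale_minmax <- function(x, mn, mx) {
  rng <- mx - mn
  rng[rng == 0] <- 1
  sweep(sweep(x, 2, mn), 2, rng, `/`)
}

unscale_minmax <- function(x, mn, mx) {
  sweep(sweep(x, 2, mx - mn, `*`), 2, mn, `+`)
}

#' Train the SBI neural regressor
#'
#' Multilayer perceptron with three hidden layers (132, 64, 32 units),
#' exponential-linear-unit activations and dropout 0.5 at every hidden
#' layer, trained with Adam on the mean-squared error of the min-max
#' scaled (S, log alpha) targets. The 10% held-out split drives early
#' stopping (patience `patience` epochs); the weights of the best held-out
#' epoch are kept.
#'
#' @param training an `sbi_training_set`.
#' @param epochs maximum training epochs.
#' @param seed RNG seed (fixes initialization, shuffling and dropout).
#' @param hidden hidden-layer sizes.
#' @param dropout dropout rate at each hidden layer.
#' @param lr,batch,patience Adam learning rate, minibatch size, early-
#'   stopping patience.
#' @return A list of class `sbi_model`: the fitted network, training
#'   history, scaling/mask/prior metadata and held-out R-squared per
#'   target (`r2_test`).
#' @export
train_sbi <- function(training, epochs = 300, seed = 1L,
                      hidden = c(132, 64, 32), dropout = 0.5,
                      lr = 1e-3, batch = 128, patience = 20) {
  stopifnot(inherits(training, "sbi_training_set"))
  tr <- training$split == "train"
  X <- training$scaled$features
  Y <- training$scaled$targets
  fit <- mlp_train(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                   hidden = hidden, dropout = dropout,
                   val = list(X = X[!tr, , drop = FALSE],
                              Y = Y[!tr, , drop = FALSE]),
                   epochs = epochs, batch = batch, lr = lr,
                   patience = patience, seed = seed)
  pred <- mlp_predict(fit, X[!tr, , drop = FALSE])
  r2 <- vapply(seq_len(ncol(Y)), function(j) {
    obs <- Y[!tr, j]
    1 - sum((pred[, j] - obs)^2) / sum((obs - mean(obs))^2)
  }, numeric(1))
  names(r2) <- colnames(training$targets)
  ed_log(sprintf("train_sbi: best epoch %d, held-out R2 S=%.3f log_alpha=%.3f",
                 fit$best_epoch, r2[1], r2[2]))
  structure(list(net = fit$net, history = fit$history,
                 best_epoch = fit$best_epoch,
                 scaling = training$scaling, mask = training$mask,
                 priors = training$priors, metric = training$metric,
                 r2_test = r2, hidden = hidden, dropout = dropout),
            class = "sbi_model")
}

#' @export
print.sbi_model <- function(x, ...) {
  cat(sprintf("sbi_model: %s net, best epoch %d, held-out R2 S=%.3f log_alpha=%.3f\n",
              paste(x$hidden, collapse = "-"), x$best_epoch,
              x$r2_test[1], x$r2_test[2]))
  invisible(x)
}

#' Predict (S, log alpha) from a diversity summary
#'
#' Applies the stored feature scaling and mask, runs the network with
#' dropout disabled and inverse-scales the outputs. The S estimate is
#' clamped from below at the observed regional richness when supplied.
#'
#' @param model an `sbi_model`.
#' @param features a feature list from [featurize()], or a numeric matrix
#'   of raw feature rows.
#' @param s_obs optional observed richness used as a lower clamp for S.
#' @return Named numeric vector `c(S, log_alpha)` (or a matrix for matrix
#'   input).
#' @export
predict_params <- function(model, features, s_obs = NULL) {
  stopifnot(inherits(model, "sbi_model"))
  X <- if (is.list(features) && !is.null(features$values))
    matrix(features$values, 1, dimnames = list(NULL, names(features$values)))
  else as.matrix(features)
  Xs <- scale_minmax(X, model$scaling$f_min, model$scaling$f_max)
  Xs[, !model$mask] <- 0
  pred <- unscale_minmax(mlp_predict(model, Xs),
                         model$scaling$t_min, model$scaling$t_max)
  colnames(pred) <- c("S", "log_alpha")
  pred[, "S"] <- pmax(pred[, "S"], if (is.null(s_obs)) model$priors$S[1] else s_obs)
  if (nrow(pred) == 1) pred[1, ] else pred
}
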