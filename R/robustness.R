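# Leave-one-site-in robustness protocol: train on one site's designated
# learning prototypes, test on the complement; compare against pooled
# (overall) training via relative performance variation.

#' Run one site-restricted or pooled training experiment
#'
#' In site mode the learning set consists of every prototype digitized at
#' the named site and the test set is the complement — all prototypes from
#' the other sites.  In `"OVERALL"` mode the learning set is a stratified
#' random draw of `split_cfg$overall_learning` (default 0.9) of all
#' prototypes and the test set the remaining ~10%.  The learning set is
#' further split 80/20 into train and validation; the ICA basis and the
#' classifier see only learning prototypes.
#'
#' @param protos A `prototype_set`.
#' @param site Site name, or `"OVERALL"` for pooled training.
#' @param split_cfg List: `overall_learning` (pooled learning fraction),
#'   `train_frac` (within-learning train share).
#' @param kind `"svm"` or `"mlp"`.
#' @param q Number of ICA components.
#' @param seed Integer seed.
#' @param svm_grid,mlp_opts Classifier search settings (see
#'   [optimize_extractor()]).
#' @return An object of class `site_experiment`: the trained `basis` and
#'   `model`, index sets, success `rates` (train, val, test, percent),
#'   test `roc` and `auc`.
#' @export
run_site_experiment <- function(protos, site = "OVERALL",
                                split_cfg = list(), kind = c("svm", "mlp"),
                                q = 10L, seed = 1L,
                                svm_grid = list(log2_gamma = seq(-9, 3, 2),
                                                log2_C = seq(-1, 7, 2)),
                                mlp_opts = list(H_grid = c(25L, 50L),
                                                restarts = 2L,
                                                cfg = rprop_config(
                                                  max_epochs = 200L,
                                                  patience = 30L))) {
  kind <- match.arg(kind)
  meta <- protos$meta
  cfg <- utils::modifyList(list(overall_learning = 0.9, train_frac = 0.8),
                           split_cfg)
  set.seed(seed)
  n <- nrow(meta)
  if (identical(site, "OVERALL")) {
    learn <- integer(0)
    for (st in split(seq_len(n), interaction(meta$pathology, meta$site))) {
      if (!length(st)) next
      learn <- c(learn, sample(st, round(cfg$overall_learning * length(st))))
    }
    learn <- sort(learn)
  } else {
    if (!site %in% meta$site) stop("unknown site '", site, "'")
    learn <- which(meta$site == site)
  }
  test <- setdiff(seq_len(n), learn)
  fit <- fit_fold(protos, learn, q, kind,
                  seed = (seed + 1L) %% .Machine$integer.max,
                  svm_grid = svm_grid, mlp_opts = mlp_opts,
                  train_frac = cfg$train_frac)
  sc_all <- predict(fit$model, fit$features$x)
  lab <- meta$label
  thr <- fit$model$threshold
  rates <- c(
    train = success_rate(decide(sc_all[fit$split$train], thr),
                         lab[fit$split$train]),
    val = success_rate(decide(sc_all[fit$split$val], thr),
                       lab[fit$split$val]),
    test = success_rate(decide(sc_all[test], thr), lab[test]))
  roc <- roc_auc(sc_all[test], lab[test])
  structure(list(site = site, kind = kind, q = q, basis = fit$basis,
                 model = fit$model,
                 idx = list(learn = learn, train = fit$split$train,
                            val = fit$split$val, test = test),
                 rates = rates, roc = roc, auc = roc$auc),
            class = "site_experiment")
}

#' @export
print.site_experiment <- function(x, ...) {
  cat(sprintf("site_experiment [%s, %s, q=%d]: train %.2f%% / val %.2f%% / test %.2f%%, AUC %.3f\n",
              x$site, x$kind, x$q, x$rates["train"], x$rates["val"],
              x$rates["test"], x$auc))
  invisible(x)
}

#' Relative-variation robustness report
#'
#' For each site-restricted result, computes the relative variation of the
#' test success rate against the pooled (overall) referent,
#' `100 * (overall_test - site_test) / overall_test`, rounded half-up to
#' `digits` decimals, together with AUC differences when available.
#'
#' @param site_results Named numeric vector of per-site test success rates,
#'   or a (named) list of `site_experiment` objects.
#' @param overall_result Overall test success rate (scalar) or a
#'   `site_experiment`.
#' @param digits Decimals for the reported variation (default 1; the
#'   two-decimal mode is available via `digits = 2`).
#' @return An object of class `robustness_report`: data frame with one row
#'   per site (`site`, `test_success`, `auc`, `relative_variation_pct`,
#'   `auc_difference`) plus attributes `overall_test` and `overall_auc`.
#' @export
robustness_report <- function(site_results, overall_result, digits = 1) {
  if (is.list(site_results) && all(vapply(site_results, inherits,
                                          logical(1), "site_experiment"))) {
    sites <- vapply(site_results, function(r) r$site, character(1))
    test <- vapply(site_results, function(r) unname(r$rates["test"]),
                   numeric(1))
    auc <- vapply(site_results, function(r) r$auc, numeric(1))
  } else {
    test <- as.numeric(site_results)
    sites <- if (!is.null(names(site_results))) names(site_results)
             else paste0("site", seq_along(test))
    auc <- rep(NA_real_, length(test))
  }
  if (inherits(overall_result, "site_experiment")) {
    overall_test <- unname(overall_result$rates["test"])
    overall_auc <- overall_result$auc
  } else {
    overall_test <- as.numeric(overall_result)
    overall_auc <- NA_real_
  }
  if (overall_test <= 0) stop("overall test rate must be positive")
  rel <- round_half_up(100 * (overall_test - test) / overall_test, digits)
  df <- data.frame(site = sites, test_success = test, auc = auc,
                   relative_variation_pct = rel,
                   auc_difference = overall_auc - auc)
  structure(df, overall_test = overall_test, overall_auc = overall_auc,
            class = c("robustness_report", "data.frame"))
}

# round-half-up (round() rounds half to even)
round_half_up <- function(x, digits = 0) {
  m <- 10 ^ digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report (overall test %.2f%%%s)\n",
              attr(x, "overall_test"),
              if (is.finite(attr(x, "overall_auc")))
                sprintf(", overall AUC %.3f", attr(x, "overall_auc"))
              else ""))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full leave-one-site-in robustness study
#'
#' Runs the pooled (`"OVERALL"`) experiment plus one site-restricted
#' experiment per site and assembles the [robustness_report()].
#'
#' @param protos A `prototype_set`.
#' @param kind,q,seed,svm_grid,mlp_opts As in [run_site_experiment()].
#' @param split_cfg Split settings shared by all experiments.
#' @param digits Decimals for the reported variation.
#' @return List with `overall`, `sites` (named list of `site_experiment`)
#'   and `report`.
#' @export
run_robustness_study <- function(protos, kind = c("svm", "mlp"),
                                 q = 10L, seed = 1L, split_cfg = list(),
                                 digits = 1, ...) {
  kind <- match.arg(kind)
  overall <- run_site_experiment(protos, "OVERALL", split_cfg, kind, q,
                                 seed = seed, ...)
  site_names <- unique(protos$meta$site)
  sites <- lapply(seq_along(site_names), function(i)
    run_site_experiment(protos, site_names[i], split_cfg, kind, q,
                        seed = (seed + 101L * i) %% .Machine$integer.max,
                        ...))
  names(sites) <- site_names
  list(overall = overall, sites = sites,
       report = robustness_report(sites, overall, digits = digits))
}
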