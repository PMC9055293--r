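## Approximate Bayesian computation -------------------------------------------

PARAM_NAMES <- c("NE1", "NE2", "T_div", "M12_old", "M21_old",
                 "T_old_12", "T_old_21", "M12_rec", "M21_rec",
                 "T_rec_12", "T_rec_21")

#' Build an ABC reference table
#'
#' For each scenario and each row: draw parameters from the priors,
#' simulate a dataset over `loci` (with the same diploid pairing,
#' inbreeding, missingness and one-SNP-per-locus thinning applied to the
#' observed data), and record the five summary statistics.  Rows with
#' undefined summaries (for instance no segregating site in one population)
#' are redrawn up to `retry_cap` times, then dropped with a message; more
#' than 1\% dropped rows is an error, signalling a degenerate configuration.
#'
#' @param models character vector of scenario ids.
#' @param prior_spec a [default_priors()] object.
#' @param n_sims_per_model rows per model.
#' @param loci list from [make_loci()].
#' @param inbreeding_f,missing_rate passed to [simulate_dataset()].
#' @param retry_cap redraw attempts per row.
#' @return data.frame of class `reference_table` with columns `model`, the
#'   11 scenario parameters (`NA` where not drawn), and the 5 statistics.
#' @export
build_reference_table <- function(models, prior_spec = default_priors(),
                                  n_sims_per_model, loci,
                                  inbreeding_f = c(0, 0), missing_rate = 0,
                                  retry_cap = 10) {
  stopifnot(n_sims_per_model >= 1, length(loci) >= 1)
  models <- match.arg(models, MODEL_IDS, several.ok = TRUE)
  total <- length(models) * n_sims_per_model
  param_mat <- matrix(NA_real_, total, length(PARAM_NAMES),
                      dimnames = list(NULL, PARAM_NAMES))
  stat_mat <- matrix(NA_real_, total, length(STAT_NAMES),
                     dimnames = list(NULL, STAT_NAMES))
  model_col <- character(total)
  dropped <- 0L
  row <- 0L
  for (m in models) {
    for (i in seq_len(n_sims_per_model)) {
      row <- row + 1L
      model_col[row] <- m
      for (attempt in seq_len(retry_cap + 1L)) {
        params <- draw_from_priors(m, prior_spec)
        scen <- build_scenario(m, params)
        ds <- simulate_dataset(scen, loci, inbreeding_f, missing_rate)
        ds <- one_random_snp_per_locus(ds)
        sv <- tryCatch(summary_vector(ds), error = function(e) rep(NA_real_, 5))
        if (!anyNA(sv)) break
      }
      if (anyNA(sv)) {
        dropped <- dropped + 1L
        next
      }
      drawn <- intersect(names(params), PARAM_NAMES)
      param_mat[row, drawn] <- unlist(params[drawn])
      stat_mat[row, ] <- as.numeric(sv)
    }
  }
  keep <- stats::complete.cases(stat_mat)
  if (dropped > 0)
    message(dropped, " row(s) dropped after ", retry_cap, " retries")
  if (dropped > 0.01 * total)
    stop("more than 1% of reference-table rows undefined; ",
         "the simulation configuration is degenerate")
  tab <- data.frame(model = model_col[keep], param_mat[keep, , drop = FALSE],
                    stat_mat[keep, , drop = FALSE])
  attr(tab, "n_per_model") <- n_sims_per_model
  class(tab) <- c("reference_table", "data.frame")
  tab
}

ref_stats <- function(table) as.matrix(table[, STAT_NAMES, drop = FALSE])

## accept observed summaries either named (any order) or unnamed in the
## canonical statistic order
as_stat_vector <- function(observed) {
  obs <- as.numeric(observed)
  if (!is.null(names(observed))) {
    if (!all(STAT_NAMES %in% names(observed)))
      stop("observed summary vector must carry the five statistic names")
    obs <- as.numeric(observed[STAT_NAMES])
  } else if (length(obs) != length(STAT_NAMES)) {
    stop("observed summary vector must have length 5")
  }
  names(obs) <- STAT_NAMES
  obs
}

#' Standardize and rotate summary statistics by PCA
#'
#' Columns are centred and scaled to unit variance before rotation; all
#' components are retained by default so the transform is an orthonormal
#' change of basis (total variance preserved).  Zero-variance columns are
#' dropped with a warning and recorded in the transform.
#'
#' @param stat_matrix numeric matrix (rows = simulations, 5 statistic
#'   columns).
#' @param n_components components to keep (default all).
#' @return list with `scores` and `transform` (apply to new rows with
#'   [predict_pca()]).
#' @export
pca_transform <- function(stat_matrix, n_components = NULL) {
  stat_matrix <- as.matrix(stat_matrix)
  if (nrow(stat_matrix) < 2) stop("need at least 2 rows")
  ctr <- colMeans(stat_matrix)
  scl <- apply(stat_matrix, 2, sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(stat_matrix)[zero], collapse = ", "))
  }
  keep <- !zero
  Z <- sweep(sweep(stat_matrix[, keep, drop = FALSE], 2, ctr[keep]), 2,
             scl[keep], "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  k <- n_components %||% ncol(Z)
  k <- min(k, ncol(Z))
  transform <- list(center = ctr[keep], scale = scl[keep],
                    rotation = pc$rotation[, seq_len(k), drop = FALSE],
                    kept_columns = colnames(stat_matrix)[keep])
  class(transform) <- "pca_stat_transform"
  list(scores = pc$x[, seq_len(k), drop = FALSE], transform = transform)
}

#' Apply a stored PCA transform to new summary rows
#'
#' @param transform the `transform` element of [pca_transform()].
#' @param newdata numeric vector (one summary vector) or matrix.
#' @return score matrix.
#' @export
predict_pca <- function(transform, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  nd <- newdata[, transform$kept_columns, drop = FALSE]
  Z <- sweep(sweep(nd, 2, transform$center), 2, transform$scale, "/")
  Z %*% transform$rotation
}

#' Rejection step: nearest simulations to the observed summaries
#'
#' Each statistic column is standardized by its standard deviation in the
#' simulated table, Euclidean distances to the observed vector are computed,
#' and the `ceiling(tolerance * n)` nearest rows are accepted (ties broken
#' by row order).
#'
#' @param observed numeric summary vector (raw or PCA space, matching
#'   `stat_matrix`).
#' @param stat_matrix simulated summaries, same space as `observed`.
#' @param tolerance accepted fraction in `(0, 1]`.
#' @return integer vector of accepted row indices sorted by distance, with
#'   attributes `dist` (their distances) and `dmax`.
#' @export
rejection_select <- function(observed, stat_matrix, tolerance) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must lie in (0, 1]")
  stat_matrix <- as.matrix(stat_matrix)
  obs <- as.numeric(observed)
  if (length(obs) != ncol(stat_matrix))
    stop("observed vector length does not match the table")
  scl <- apply(stat_matrix, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  D <- sweep(stat_matrix, 2, obs)
  D <- sweep(D, 2, scl, "/")
  d <- sqrt(rowSums(D^2))
  n_keep <- ceiling(tolerance * nrow(stat_matrix))
  ord <- order(d)[seq_len(n_keep)]
  structure(ord, dist = d[ord], dmax = max(d[ord]))
}

epanechnikov_weights <- function(d, dmax) {
  if (dmax <= 0) return(rep(1, length(d)))
  w <- 1 - (d / dmax)^2
  w[w < 0] <- 0
  ## the farthest accepted row would get weight 0; keep it infinitesimally in
  w + 1e-8
}

default_net_config <- function(net_config = list()) {
  utils::modifyList(list(size = 5L, n_nets = 10L, decay = 0.01,
                         maxit = 500L), net_config)
}

## ensemble of single-hidden-layer nets; returns averaged predictions at
## x_train and x_new (regression: linout, classification: softmax)
nnet_ensemble <- function(x, y, w, x_new, cfg, softmax = FALSE) {
  preds_new <- NULL
  preds_train <- NULL
  for (i in seq_len(cfg$n_nets)) {
    fit <- if (softmax) {
      nnet::nnet(x = x, y = y, weights = w, size = cfg$size,
                 decay = cfg$decay, maxit = cfg$maxit, softmax = TRUE,
                 trace = FALSE)
    } else {
      nnet::nnet(x = x, y = y, weights = w, size = cfg$size,
                 decay = cfg$decay, maxit = cfg$maxit, linout = TRUE,
                 trace = FALSE)
    }
    pn <- predict(fit, x_new)
    pt <- predict(fit, x)
    preds_new <- if (is.null(preds_new)) pn else preds_new + pn
    preds_train <- if (is.null(preds_train)) pt else preds_train + pt
  }
  list(new = preds_new / cfg$n_nets, train = preds_train / cfg$n_nets)
}

#' Neural-network ABC model choice
#'
#' Rejection on (optionally PCA-transformed) summaries followed by an
#' ensemble of single-hidden-layer feed-forward classifiers fitted to the
#' accepted rows with Epanechnikov distance weights.  Posterior model
#' probabilities are the ensemble-averaged class probabilities at the
#' observed point, renormalized.  `method = "rejection"` instead returns
#' the accepted-count fractions (the classical rejection estimate).
#'
#' @param observed named summary vector (raw statistic space).
#' @param table a [build_reference_table()] result.
#' @param tolerance accepted fraction (default 0.05).
#' @param transform `"pca"` (default) or `"raw"`.
#' @param method `"neuralnet"` (default) or `"rejection"`.
#' @param net_config list overriding `size` (5), `n_nets` (10), `decay`
#'   (0.01), `maxit` (500).
#' @return object of class `model_choice`: posterior probabilities per
#'   model, plus method/tolerance/transform metadata.
#' @export
nn_model_choice <- function(observed, table, tolerance = 0.05,
                            transform = c("pca", "raw"),
                            method = c("neuralnet", "rejection"),
                            net_config = list()) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  cfg <- default_net_config(net_config)
  stats <- ref_stats(table)
  obs <- as_stat_vector(observed)
  if (transform == "pca") {
    p <- pca_transform(stats)
    stats <- p$scores
    obs <- as.numeric(predict_pca(p$transform, obs))
  }
  acc <- rejection_select(obs, stats, tolerance)
  labels <- table$model[acc]
  all_models <- sort(unique(table$model))
  present <- sort(unique(labels))
  if (any(!(all_models %in% present)))
    warning("model(s) with zero accepted rows: ",
            paste(setdiff(all_models, present), collapse = ", "))
  post <- setNames(numeric(length(all_models)), all_models)
  if (length(present) == 1L || method == "rejection") {
    tab <- table(factor(labels, levels = all_models))
    post[] <- as.numeric(tab) / length(labels)
    used <- if (length(present) == 1L) "rejection" else method
  } else {
    w <- epanechnikov_weights(attr(acc, "dist"), attr(acc, "dmax"))
    X <- stats[acc, , drop = FALSE]
    ctr <- colMeans(X); scl <- apply(X, 2, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    obs_s <- (obs - ctr) / scl
    y <- nnet::class.ind(factor(labels, levels = present))
    ens <- nnet_ensemble(Xs, y, w, matrix(obs_s, nrow = 1), cfg,
                         softmax = TRUE)
    pr <- pmax(as.numeric(ens$new), 0)
    post[present] <- pr / sum(pr)
    used <- "neuralnet"
  }
  structure(list(posterior = post, method = used, tolerance = tolerance,
                 transform = transform, n_accepted = length(acc)),
            class = "model_choice")
}

#' @export
print.model_choice <- function(x, ...) {
  cat(sprintf("ABC model choice (%s, tolerance %.3g, %s summaries, %d accepted)\n",
              x$method, x$tolerance, x$transform, x$n_accepted))
  print(round(x$posterior, 4))
  invisible(x)
}

## parameter transforms for the regression scale
param_transforms <- function(param_names, prior_spec, model) {
  spec <- prior_spec$models[[model]]
  lapply(setNames(param_names, param_names), function(nm) {
    r <- spec[[nm]]
    if (is.null(r)) return(list(type = "identity"))
    if (identical(r$transform, "log10"))
      list(type = "log10")
    else
      list(type = "logit", lo = r$lo, hi = r$hi)
  })
}

apply_transform <- function(x, tr) {
  switch(tr$type,
    identity = x,
    log10 = log10(pmax(x, .Machine$double.xmin)),
    logit = {
      u <- (x - tr$lo) / (tr$hi - tr$lo)
      logit(pmin(pmax(u, 1e-8), 1 - 1e-8))
    })
}

invert_transform <- function(x, tr) {
  switch(tr$type,
    identity = x,
    log10 = 10^x,
    logit = tr$lo + (tr$hi - tr$lo) * inv_logit(x))
}

#' Neural-network regression-adjusted parameter posterior
#'
#' Nonlinear conditional-density adjustment of the accepted parameter
#' draws: each parameter is mapped to an unbounded regression scale (logit
#' of its prior range; log10 for migration rates), regressed on the
#' accepted summaries with an ensemble of single-hidden-layer networks
#' under Epanechnikov weights, and the draws are corrected to the observed
#' summary point (with a log-variance second regression for
#' heteroscedasticity when `hcorr = TRUE`).  Posterior means and
#' equal-tailed 95\% credible intervals are weighted by the rejection
#' kernel.
#'
#' @param observed summary vector in the same space as `accepted_stats`.
#' @param accepted_stats matrix of accepted summaries.
#' @param accepted_params data.frame/matrix of accepted parameter draws
#'   (natural scale).
#' @param weights Epanechnikov weights of the accepted rows.
#' @param transforms per-parameter transform list from the prior
#'   specification (see [abc_estimate()] for the user-facing wrapper).
#' @param net_config as in [nn_model_choice()].
#' @param adjust if `FALSE`, return the plain rejection posterior.
#' @param hcorr heteroscedastic correction (default `TRUE`).
#' @param level credible level (default 0.95).
#' @return object of class `param_posterior` with elements `draws`
#'   (accepted), `adjusted`, `weights`, `mean`, `ci`.
#' @export
nn_param_adjust <- function(observed, accepted_stats, accepted_params,
                            weights = NULL, transforms = NULL,
                            net_config = list(), adjust = TRUE,
                            hcorr = TRUE, level = 0.95) {
  cfg <- default_net_config(net_config)
  X <- as.matrix(accepted_stats)
  P <- as.matrix(accepted_params)
  obs <- as.numeric(observed)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  if (is.null(transforms))
    transforms <- lapply(setNames(colnames(P), colnames(P)),
                         function(nm) list(type = "identity"))
  ctr <- colMeans(X); scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  obs_s <- matrix((obs - ctr) / scl, nrow = 1)

  adjusted <- P
  did_adjust <- FALSE
  if (adjust) {
    degenerate <- all(apply(P, 2, function(p) length(unique(p)) == 1L))
    if (degenerate) {
      warning("accepted draws are degenerate; adjustment skipped")
    } else {
      for (j in seq_len(ncol(P))) {
        tr <- transforms[[colnames(P)[j]]] %||% list(type = "identity")
        y_raw <- apply_transform(P[, j], tr)
        if (length(unique(y_raw)) == 1L) { adjusted[, j] <- P[, j]; next }
        ## standardize the response so the weight decay regularizes on a
        ## comparable scale (prevents the nets from interpolating small
        ## accepted sets, which would collapse the posterior)
        y_ctr <- mean(y_raw); y_scl <- sd(y_raw)
        y <- (y_raw - y_ctr) / y_scl
        ens <- nnet_ensemble(Xs, matrix(y), weights, obs_s, cfg)
        m_obs <- as.numeric(ens$new)
        m_i <- as.numeric(ens$train)
        resid <- y - m_i
        if (hcorr && length(unique(resid)) > 1L) {
          ## the variance surface must be fitted much more stiffly than the
          ## mean: an interpolating fit would predict sigma_i ~ |resid_i|
          ## and collapse the adjusted draws onto two points
          cfg_var <- utils::modifyList(cfg, list(size = 2L, decay = 1))
          z <- log(resid^2 + .Machine$double.eps)
          ens2 <- nnet_ensemble(Xs, matrix(z), weights, obs_s, cfg_var)
          s_obs <- sqrt(exp(as.numeric(ens2$new)))
          s_i <- sqrt(exp(as.numeric(ens2$train)))
          ratio <- s_obs / pmax(s_i, .Machine$double.eps)
          ratio <- pmin(pmax(ratio, 0.1), 10)  # guard pathological fits
          ystar <- m_obs + ratio * resid
        } else {
          ystar <- m_obs + resid
        }
        adjusted[, j] <- invert_transform(ystar * y_scl + y_ctr, tr)
      }
      did_adjust <- TRUE
    }
  }
  a <- (1 - level) / 2
  post_mean <- vapply(seq_len(ncol(P)), function(j)
    sum(weights * adjusted[, j]) / sum(weights), numeric(1))
  ci <- vapply(seq_len(ncol(P)), function(j)
    weighted_quantile(adjusted[, j], weights, c(a, 1 - a)), numeric(2))
  names(post_mean) <- colnames(P)
  dimnames(ci) <- list(c("lower", "upper"), colnames(P))
  structure(list(draws = P, adjusted = adjusted, weights = weights,
                 mean = post_mean, ci = ci, adjusted_flag = did_adjust,
                 level = level),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat(sprintf("ABC parameter posterior (%s, %d draws)\n",
              if (x$adjusted_flag) "regression-adjusted" else "rejection only",
              nrow(x$adjusted)))
  out <- rbind(mean = x$mean, x$ci)
  print(signif(t(out), 4))
  invisible(x)
}

#' Estimate parameters under one scenario
#'
#' User-facing wrapper: restricts the reference table to `model`, runs the
#' rejection step at `tolerance` (optionally in PCA space), and calls
#' [nn_param_adjust()] with the prior-derived parameter transforms.
#'
#' @param observed named raw summary vector.
#' @param table a [build_reference_table()] result.
#' @param model scenario id whose parameters to estimate.
#' @param tolerance accepted fraction of the model's rows.
#' @param transform `"pca"` or `"raw"`.
#' @param prior_spec the prior specification used to build the table.
#' @param ... passed to [nn_param_adjust()].
#' @return a `param_posterior`.
#' @export
abc_estimate <- function(observed, table, model, tolerance = 0.05,
                         transform = c("pca", "raw"),
                         prior_spec = default_priors(), ...) {
  transform <- match.arg(transform)
  model <- match.arg(model, MODEL_IDS)
  sub <- table[table$model == model, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for model ", model)
  pn <- model_params(model)
  stats <- ref_stats(sub)
  obs <- as_stat_vector(observed)
  if (transform == "pca") {
    p <- pca_transform(stats)
    stats <- p$scores
    obs <- as.numeric(predict_pca(p$transform, obs))
  }
  acc <- rejection_select(obs, stats, tolerance)
  w <- epanechnikov_weights(attr(acc, "dist"), attr(acc, "dmax"))
  nn_param_adjust(obs, stats[acc, , drop = FALSE],
                  sub[acc, pn, drop = FALSE], weights = w,
                  transforms = param_transforms(pn, prior_spec, model), ...)
}

#' Cross-validation of ABC model choice
#'
#' Leave-one-out style: `n_eval_per_model` rows per model are treated in
#' turn as pseudo-observed, removed, and classified against the rest of the
#' table.  Returns the confusion matrix of classification proportions
#' (rows = true model, summing to 1) and the mean misclassification rate.
#'
#' @param table a [build_reference_table()] result.
#' @param n_eval_per_model evaluations per model.
#' @param tolerance rejection tolerance.
#' @param transform `"pca"` or `"raw"`.
#' @param method `"rejection"` (default, fast) or `"neuralnet"`.
#' @param net_config as in [nn_model_choice()].
#' @return list with `confusion` and `misclassification`.
#' @export
cross_validate_model_choice <- function(table, n_eval_per_model,
                                        tolerance = 0.05,
                                        transform = c("pca", "raw"),
                                        method = c("rejection", "neuralnet"),
                                        net_config = list()) {
  transform <- match.arg(transform)
  method <- match.arg(method)
  stopifnot(n_eval_per_model >= 1)
  models <- sort(unique(table$model))
  conf <- matrix(0, length(models), length(models),
                 dimnames = list(true = models, assigned = models))
  for (m in models) {
    rows <- which(table$model == m)
    eval_rows <- if (length(rows) <= n_eval_per_model) rows else
      sample(rows, n_eval_per_model)
    for (r in eval_rows) {
      obs <- ref_stats(table)[r, ]
      rest <- table[-r, , drop = FALSE]
      mc <- nn_model_choice(obs, rest, tolerance = tolerance,
                            transform = transform, method = method,
                            net_config = net_config)
      assigned <- names(which.max(mc$posterior))
      conf[m, assigned] <- conf[m, assigned] + 1
    }
    conf[m, ] <- conf[m, ] / sum(conf[m, ])
  }
  list(confusion = conf, misclassification = 1 - mean(diag(conf)))
}

#' Goodness-of-fit envelope of the observed summaries
#'
#' For each of the five statistics: the percentile of the observed value
#' within the simulated marginal and a flag for lying inside the simulated
#' range.
#'
#' @param observed named raw summary vector.
#' @param table a [build_reference_table()] result.
#' @return data.frame with `statistic`, `observed`, `percentile`,
#'   `in_range`.
#' @export
gof_envelope <- function(observed, table) {
  stats <- ref_stats(table)
  obs <- as_stat_vector(observed)
  data.frame(
    statistic = STAT_NAMES,
    observed = obs,
    percentile = vapply(seq_along(obs), function(j)
      mean(stats[, j] <= obs[j]), numeric(1)),
    in_range = vapply(seq_along(obs), function(j)
      obs[j] >= min(stats[, j]) & obs[j] <= max(stats[, j]), logical(1))
  )
}
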