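# build a reference-table-shaped data.frame directly from given stat clouds
fake_table <- function(model_stats, params = NULL) {
  rows <- do.call(rbind, lapply(names(model_stats), function(m) {
    s <- model_stats[[m]]
    colnames(s) <- c("tajd_pop1", "tajd_pop2", "fst", "prop_shared",
                     "prop_fixed")[seq_len(ncol(s))]
    data.frame(model = m, s)
  }))
  for (p in c("NE1", "NE2", "T_div")) if (!p %in% names(rows)) rows[[p]] <- NA
  if (!is.null(params)) for (p in names(params)) rows[[p]] <- params[[p]]
  class(rows) <- c("reference_table", "data.frame")
  rows
}

rand_stats <- function(n, centre) {
  matrix(rnorm(n * 5, rep(centre, each = n), 0.3), n, 5)
}

test_that("reference tables record one complete row per simulation", {
  loci <- make_loci(30, 500, 2e-8, 8, 8)
  set.seed(101)
  tab <- build_reference_table(c("I", "II"), n_sims_per_model = 10,
                               loci = loci)
  expect_s3_class(tab, "reference_table")
  expect_equal(nrow(tab), 20)
  expect_equal(as.vector(table(tab$model)), c(10, 10))
  expect_false(anyNA(tab[, c("tajd_pop1", "tajd_pop2", "fst")]))
  expect_true(all(is.na(tab$M12_old[tab$model == "I"])))
  expect_false(anyNA(tab$M12_old[tab$model == "II"]))
  set.seed(202)
  one_a <- build_reference_table("I", n_sims_per_model = 1, loci = loci)
  set.seed(202)
  one_b <- build_reference_table("I", n_sims_per_model = 1, loci = loci)
  expect_identical(one_a, one_b)
})

test_that("summary means separate strict isolation from strong migration", {
  loci <- make_loci(50, 500, 1e-8, 12, 12)
  pr <- default_priors()
  pr$models$II$M12_old <- list(lo = 9.99, hi = 10, sampling = "linear",
                               transform = "log10")
  pr$models$II$M21_old <- pr$models$II$M12_old
  set.seed(303)
  tab <- build_reference_table(c("I", "II"), pr, n_sims_per_model = 60,
                               loci = loci)
  m_iso <- mean(tab$fst[tab$model == "I"])
  m_mig <- mean(tab$fst[tab$model == "II"])
  expect_gt(m_iso, m_mig)
  expect_gt(mean(tab$prop_fixed[tab$model == "I"]),
            mean(tab$prop_fixed[tab$model == "II"]))
})

test_that("the PCA transform is an orthonormal variance-preserving rotation", {
  set.seed(1)
  X <- matrix(rnorm(200 * 5), 200, 5) %*% diag(c(3, 2, 1, 1, 0.5))
  colnames(X) <- c("tajd_pop1", "tajd_pop2", "fst", "prop_shared", "prop_fixed")
  p <- pca_transform(X)
  R <- p$transform$rotation
  expect_equal(R %*% t(R), diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(apply(p$scores, 2, stats::var)), 5, tolerance = 1e-10)
  held_out <- X[7, ]
  expect_equal(as.numeric(predict_pca(p$transform, held_out)),
               as.numeric(p$scores[7, ]), tolerance = 1e-10)
  # explicit projection oracle
  z <- (held_out - p$transform$center) / p$transform$scale
  expect_equal(as.numeric(predict_pca(p$transform, held_out)),
               as.numeric(z %*% R), tolerance = 1e-12)
})

test_that("zero-variance statistic columns are dropped with a warning", {
  X <- cbind(matrix(rnorm(40), 20, 2), 1, matrix(rnorm(40), 20, 2))
  colnames(X) <- c("tajd_pop1", "tajd_pop2", "fst", "prop_shared", "prop_fixed")
  expect_warning(p <- pca_transform(X), "zero-variance")
  expect_equal(ncol(p$scores), 4)
  expect_false("fst" %in% p$transform$kept_columns)
})

test_that("rejection keeps the tolerance fraction of nearest rows", {
  X <- matrix(c(1:10, rep(0, 10)), 10, 2)  # distances grow with row index
  obs <- c(0, 0)
  acc <- rejection_select(obs, X, 0.3)
  expect_equal(as.integer(acc), 1:3)
  expect_length(rejection_select(obs, X, 1), 10)
  # retention arithmetic at the conventional 5% tolerance
  set.seed(2)
  big <- matrix(rnorm(1e5 * 5), 1e5, 5)
  expect_length(rejection_select(rep(0, 5), big, 0.05), 5000)
  expect_error(rejection_select(obs, X, 0), "tolerance")
})

test_that("model choice is certain on a single-model table and sums to one", {
  set.seed(3)
  tab <- fake_table(list(V = rand_stats(200, rep(0, 5))))
  mc <- nn_model_choice(rep(0, 5), tab, tolerance = 0.5)
  expect_equal(unname(mc$posterior["V"]), 1)
  tab2 <- fake_table(list(A = rand_stats(300, rep(-1, 5)),
                          B = rand_stats(300, rep(1, 5))))
  obs <- setNames(rep(0.2, 5), c("tajd_pop1", "tajd_pop2", "fst",
                                 "prop_shared", "prop_fixed"))
  mc2 <- nn_model_choice(obs, tab2, tolerance = 0.3)
  expect_equal(sum(mc2$posterior), 1, tolerance = 1e-9)
  expect_true(all(mc2$posterior >= 0))
})

test_that("separable summary clouds give a near-certain neural-net choice", {
  set.seed(4)
  tab <- fake_table(list(A = rand_stats(600, rep(-3, 5)),
                         B = rand_stats(600, rep(3, 5))))
  obs <- setNames(rep(-3, 5), c("tajd_pop1", "tajd_pop2", "fst",
                                "prop_shared", "prop_fixed"))
  nn <- suppressWarnings(nn_model_choice(obs, tab, tolerance = 0.2))
  rj <- suppressWarnings(nn_model_choice(obs, tab, tolerance = 0.2,
                                         method = "rejection"))
  expect_gt(nn$posterior["A"], 0.99)
  expect_lt(abs(nn$posterior["A"] - rj$posterior["A"]), 0.05)
})

test_that("duplicate models receive the prior model probability", {
  set.seed(5)
  cloud <- rand_stats(3000, rep(0, 5))
  tab <- fake_table(list(A = cloud[1:1500, ], B = cloud[1501:3000, ]))
  obs <- setNames(rep(0, 5), c("tajd_pop1", "tajd_pop2", "fst",
                               "prop_shared", "prop_fixed"))
  # average a few ensemble runs to integrate out the net-initialization noise
  p_a <- mean(vapply(1:5, function(s) {
    set.seed(700 + s)
    nn_model_choice(obs, tab, tolerance = 0.3)$posterior[["A"]]
  }, numeric(1)))
  expect_lt(abs(p_a - 0.5), 0.05)
  rj <- nn_model_choice(obs, tab, tolerance = 0.3, method = "rejection")
  expect_lt(abs(rj$posterior[["A"]] - 0.5), 0.05)
})

test_that("rejection ABC recovers the conjugate-normal posterior", {
  # theta ~ N(0,1); one observation x | theta ~ N(theta, 1); summary = x.
  # Analytic posterior: N(x_obs/2, 1/2).
  set.seed(6)
  n <- 1e5
  theta <- rnorm(n)
  x <- rnorm(n, theta, 1)
  x_obs <- 0.8
  acc <- rejection_select(x_obs, matrix(x), 0.01)
  post <- nn_param_adjust(x_obs, matrix(x[acc]),
                          matrix(theta[acc], dimnames = list(NULL, "theta")),
                          adjust = FALSE)
  mc_se <- sqrt(1 / 2) / sqrt(length(acc))
  expect_lt(abs(post$mean["theta"] - x_obs / 2), 3 * mc_se + 0.02)
  post_var <- sum(post$weights * (post$adjusted[, 1] - post$mean)^2) /
    sum(post$weights)
  expect_lt(abs(post_var - 0.5), 0.1)
})

test_that("adjustment leaves an uninformative posterior at the prior", {
  set.seed(7)
  n <- 4000
  theta <- runif(n)                      # prior U(0,1), midpoint 0.5
  s <- matrix(rnorm(n * 5), n, 5)        # summaries carry no information
  acc <- rejection_select(rep(0, 5), s, 0.25)
  post <- nn_param_adjust(rep(0, 5), s[acc, ],
                          matrix(theta[acc], dimnames = list(NULL, "theta")),
                          transforms = list(theta = list(type = "logit",
                                                         lo = 0, hi = 1)))
  expect_lt(abs(post$mean["theta"] - 0.5), 0.025)  # within 5% of the midpoint
  expect_true(post$ci["lower", 1] <= post$mean[1])
  expect_true(post$ci["upper", 1] >= post$mean[1])
})

test_that("regression adjustment sharpens a linear-Gaussian posterior", {
  # theta ~ N(0,1), x = theta + noise; observed far from the prior mean so
  # plain rejection at a loose tolerance is biased toward 0, the adjusted
  # posterior is not
  set.seed(8)
  n <- 20000
  theta <- rnorm(n)
  x <- theta + rnorm(n)
  x_obs <- 1.6
  acc <- rejection_select(x_obs, matrix(x), 0.2)
  w <- divabc:::epanechnikov_weights(attr(acc, "dist"), attr(acc, "dmax"))
  raw <- nn_param_adjust(x_obs, matrix(x[acc]),
                         matrix(theta[acc], dimnames = list(NULL, "theta")),
                         weights = w, adjust = FALSE)
  adj <- nn_param_adjust(x_obs, matrix(x[acc]),
                         matrix(theta[acc], dimnames = list(NULL, "theta")),
                         weights = w)
  truth <- x_obs / 2
  expect_lt(abs(adj$mean["theta"] - truth), abs(raw$mean["theta"] - truth))
  expect_lt(abs(adj$mean["theta"] - truth), 0.1)
})

test_that("degenerate accepted draws skip adjustment with a warning", {
  expect_warning(
    post <- nn_param_adjust(0, matrix(rnorm(50)),
                            matrix(rep(2, 50), dimnames = list(NULL, "p"))),
    "degenerate")
  expect_equal(unname(post$mean["p"]), 2)
})

test_that("cross-validation separates well-separated models and not duplicates", {
  set.seed(9)
  tab <- fake_table(list(A = rand_stats(400, rep(-3, 5)),
                         B = rand_stats(400, rep(3, 5))))
  cv <- suppressWarnings(cross_validate_model_choice(tab, n_eval_per_model = 40,
                                                     tolerance = 0.1))
  expect_gt(cv$confusion["A", "A"], 0.9)
  expect_gt(cv$confusion["B", "B"], 0.9)
  expect_true(all(abs(rowSums(cv$confusion) - 1) < 1e-12))
  cloud <- rand_stats(800, rep(0, 5))
  dup <- fake_table(list(A = cloud[1:400, ], B = cloud[401:800, ]))
  cvd <- cross_validate_model_choice(dup, n_eval_per_model = 60,
                                     tolerance = 0.1)
  expect_gt(cvd$confusion["A", "A"], 0.3)
  expect_lt(cvd$confusion["A", "A"], 0.7)
  solo <- fake_table(list(A = rand_stats(50, rep(0, 5))))
  expect_equal(cross_validate_model_choice(solo, 10)$confusion["A", "A"], 1)
})

test_that("the goodness-of-fit envelope reports percentiles and range flags", {
  set.seed(10)
  tab <- fake_table(list(A = rand_stats(999, rep(0, 5))))
  obs_in <- unlist(tab[5, c("tajd_pop1", "tajd_pop2", "fst", "prop_shared",
                            "prop_fixed")])
  g <- gof_envelope(obs_in, tab)
  expect_true(all(g$in_range))
  obs_out <- obs_in
  obs_out[3] <- max(tab$fst) + 1
  g2 <- gof_envelope(obs_out, tab)
  expect_false(g2$in_range[3])
  med <- apply(divabc:::ref_stats(tab), 2, median)
  g3 <- gof_envelope(med, tab)
  expect_true(all(abs(g3$percentile - 0.5) <= 1 / sqrt(999)))
})

test_that("a full choice-and-estimation run is reproducible under one seed", {
  loci <- make_loci(25, 500, 2e-8, 8, 8)
  run <- function() {
    set.seed(1234)
    tab <- build_reference_table(c("I", "II"), n_sims_per_model = 30,
                                 loci = loci)
    obs <- summary_vector(one_random_snp_per_locus(
      quick_sim_dataset(25, "II", t_div = 2e6, theta_mu = 2e-8, M = 0.5,
                        n_dip = 4)))
    mc <- nn_model_choice(obs, tab, tolerance = 0.3)
    est <- abc_estimate(obs, tab, "II", tolerance = 0.5)
    list(mc$posterior, est$mean, est$ci)
  }
  expect_identical(run(), run())
})
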