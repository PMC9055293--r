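## Demographic scenarios ------------------------------------------------------
##
## Two demes (pop1, pop2) split from an ancestral population of diploid size
## N0 at T_div years before present.  Migration is piecewise constant in time.
## Rates are dimensionless ms-style scaled rates 4*N0*m, named by their
## forward-time direction: rate_1to2 is gene flow from pop1 (donor) into pop2
## (recipient); backward in time it moves pop2 lineages into pop1.

MODEL_IDS <- c("I", "II", "III", "IV", "V")

## parameter names drawn per model (times in years, sizes in diploids,
## migration as 4*N0*m)
model_params <- function(model_id) {
  base <- c("NE1", "NE2", "T_div")
  switch(model_id,
    I   = base,
    II  = c(base, "M12_old", "M21_old"),
    III = c(base, "M12_old", "M21_old", "T_old_12", "T_old_21"),
    IV  = c(base, "M12_rec", "M21_rec", "T_rec_12", "T_rec_21"),
    V   = c(base, "M12_old", "M21_old",
            "M12_rec", "M21_rec", "T_rec_12", "T_rec_21"),
    stop("unknown model_id: ", model_id)
  )
}

#' Default prior specification for the five divergence scenarios
#'
#' Uniform prior ranges for the scenario parameters: descendant effective
#' sizes 10--1e5 diploids, divergence time 0.5--10 Mya, "old" scaled
#' migration rates (4*N0*m) 1e-3--1, recent rates 1e-5--1e-2 for the
#' secondary-contact scenario and 1e-6--1e-3 for the decreasing-migration
#' scenario, old-migration change times 0.25--0.5 Mya and recent change
#' times 0--0.25 Mya.  The ancestral size (1e4 diploids), mutation rate
#' (1e-9 per site per generation) and generation time (5 years) are fixed.
#'
#' @param log_rates if `TRUE`, migration-rate priors are sampled
#'   log-uniformly over the same ranges (they span 3+ orders of magnitude);
#'   the default is linear-uniform.
#' @return an object of class `prior_spec`: per-model named lists of
#'   `c(lo, hi)` ranges with `sampling` and `transform` attributes, plus the
#'   fixed constants.
#' @export
default_priors <- function(log_rates = FALSE) {
  rng <- function(lo, hi, sampling = "linear", transform = "logit") {
    list(lo = lo, hi = hi, sampling = sampling, transform = transform)
  }
  rate_sampling <- if (log_rates) "log10" else "linear"
  common <- list(
    NE1   = rng(10, 1e5),
    NE2   = rng(10, 1e5),
    T_div = rng(0.5e6, 10e6)
  )
  old_mig <- list(
    M12_old = rng(1e-3, 1, rate_sampling, "log10"),
    M21_old = rng(1e-3, 1, rate_sampling, "log10")
  )
  old_t <- list(
    T_old_12 = rng(0.25e6, 0.5e6),
    T_old_21 = rng(0.25e6, 0.5e6)
  )
  rec_t <- list(
    T_rec_12 = rng(0, 0.25e6),
    T_rec_21 = rng(0, 0.25e6)
  )
  rec_mig_wide <- list(  # scenarios II/IV range
    M12_rec = rng(1e-5, 1e-2, rate_sampling, "log10"),
    M21_rec = rng(1e-5, 1e-2, rate_sampling, "log10")
  )
  rec_mig_narrow <- list(  # decreasing-migration scenario only
    M12_rec = rng(1e-6, 1e-3, rate_sampling, "log10"),
    M21_rec = rng(1e-6, 1e-3, rate_sampling, "log10")
  )
  out <- list(
    models = list(
      I   = common,
      II  = c(common, old_mig),
      III = c(common, old_mig, old_t),
      IV  = c(common, rec_mig_wide, rec_t),
      V   = c(common, old_mig, rec_mig_narrow, rec_t)
    ),
    fixed = list(N0 = 1e4, gen_time = 5, mu = 1e-9)
  )
  class(out) <- "prior_spec"
  out
}

#' Draw scenario parameters from their priors
#'
#' Samples every parameter relevant to `model_id` from the configured
#' uniform (or log-uniform) range.  Draws violating the ordering constraints
#' (change times must precede the divergence time; the recent change time
#' must not exceed the old one) are redrawn.
#'
#' @param model_id one of `"I"`..`"V"`.
#' @param prior_spec a [default_priors()]-style specification.
#' @return named list of parameter values (times in years), including the
#'   fixed constants `N0`, `gen_time` and `mu`.
#' @export
draw_from_priors <- function(model_id, prior_spec = default_priors()) {
  model_id <- match.arg(model_id, MODEL_IDS)
  spec <- prior_spec$models[[model_id]]
  for (nm in names(spec)) {
    r <- spec[[nm]]
    if (!is_scalar_number(r$lo) || !is_scalar_number(r$hi) || r$lo >= r$hi)
      stop("malformed prior range for ", nm)
  }
  draw1 <- function(r) {
    if (identical(r$sampling, "log10")) 10^runif(1, log10(r$lo), log10(r$hi))
    else runif(1, r$lo, r$hi)
  }
  repeat {
    params <- lapply(spec, draw1)
    ok <- TRUE
    tmax <- max(unlist(params[grep("^T_(old|rec)_", names(params))]), 0)
    if (tmax >= params$T_div) ok <- FALSE
    for (d in c("12", "21")) {
      to <- params[[paste0("T_old_", d)]]
      tr <- params[[paste0("T_rec_", d)]]
      if (!is.null(to) && !is.null(tr) && tr > to) ok <- FALSE
    }
    if (ok) break
  }
  c(params, prior_spec$fixed)
}

## piecewise forward-time rate profile for one direction:
## data.frame(t0, t1, rate) tiling [0, T_div]
direction_profile <- function(model_id, T_div, old_rate, t_old, rec_rate, t_rec) {
  seg <- function(t0, t1, rate) {
    if (t1 > t0) data.frame(t0 = t0, t1 = t1, rate = rate) else NULL
  }
  out <- switch(model_id,
    I   = seg(0, T_div, 0),
    II  = seg(0, T_div, old_rate),
    III = rbind(seg(0, t_old, 0), seg(t_old, T_div, old_rate)),
    IV  = rbind(seg(0, t_rec, rec_rate), seg(t_rec, T_div, 0)),
    V   = rbind(seg(0, t_rec, rec_rate), seg(t_rec, T_div, old_rate))
  )
  out
}

#' Build a demographic scenario
#'
#' Encodes one of the five divergence models as an explicit epoch table.
#' Model semantics (times run backwards from the present; rates are scaled
#' forward-time flows 4*N0*m):
#' \describe{
#'   \item{I}{strict isolation, no migration.}
#'   \item{II}{isolation with constant migration over the whole divergence.}
#'   \item{III}{old migration only: gene flow from the split until it ceases
#'     at `T_old_*`.}
#'   \item{IV}{secondary contact: gene flow only since `T_rec_*`.}
#'   \item{V}{decreasing migration: an old rate from the split, dropping to
#'     a (lower-prior) recent rate at `T_rec_*`.  Each direction has its own
#'     change time.}
#' }
#'
#' @param model_id one of `"I"`..`"V"`.
#' @param params named list with `N0`, `NE1`, `NE2`, `T_div`, `gen_time`
#'   (and `mu`, kept for locus simulation), plus the migration rates and
#'   change times the model requires (see [draw_from_priors()] for names).
#' @return object of class `dem_scenario` with an `epochs` data.frame
#'   (`t_start`, `t_end`, `rate_1to2`, `rate_2to1`; years, tiling
#'   `[0, T_div]`, adjacent epochs with identical rates merged).
#' @export
build_scenario <- function(model_id, params) {
  model_id <- match.arg(model_id, MODEL_IDS)
  need <- c("N0", "NE1", "NE2", "T_div", "gen_time")
  miss <- setdiff(need, names(params))
  if (length(miss)) stop("missing parameters: ", paste(miss, collapse = ", "))
  for (nm in need) {
    if (!is_scalar_number(params[[nm]]) || params[[nm]] <= 0)
      stop("parameter ", nm, " must be a positive number")
  }
  rates <- unlist(params[grep("^M", names(params))])
  if (any(rates < 0)) stop("negative migration rate")
  tchg <- unlist(params[grep("^T_(old|rec)_", names(params))])
  if (any(tchg < 0)) stop("negative change time")
  if (model_id %in% c("III", "IV", "V")) {
    used <- switch(model_id, III = "^T_old_", IV = "^T_rec_", V = "^T_rec_")
    tu <- unlist(params[grep(used, names(params))])
    if (length(tu) && max(tu) >= params$T_div)
      stop("migration change time must lie strictly inside (0, T_div)")
  }
  g <- function(nm) params[[nm]] %||% 0
  p12 <- direction_profile(model_id, params$T_div, g("M12_old"), g("T_old_12"),
                           g("M12_rec"), g("T_rec_12"))
  p21 <- direction_profile(model_id, params$T_div, g("M21_old"), g("T_old_21"),
                           g("M21_rec"), g("T_rec_21"))
  brk <- sort(unique(c(0, p12$t0, p12$t1, p21$t0, p21$t1, params$T_div)))
  brk <- brk[brk <= params$T_div]
  rate_at <- function(prof, t) {
    i <- which(prof$t0 <= t & t < prof$t1)
    if (length(i)) prof$rate[i[1]] else 0
  }
  ne <- length(brk) - 1L
  ep <- data.frame(
    t_start = brk[-length(brk)], t_end = brk[-1],
    rate_1to2 = vapply(brk[-length(brk)], rate_at, numeric(1), prof = p12),
    rate_2to1 = vapply(brk[-length(brk)], rate_at, numeric(1), prof = p21)
  )
  ## merge adjacent epochs with identical rates (canonical form, so a
  ## degenerate decreasing-migration draw collapses to constant migration)
  keep <- c(TRUE, ep$rate_1to2[-1] != ep$rate_1to2[-ne] |
                  ep$rate_2to1[-1] != ep$rate_2to1[-ne])
  grp <- cumsum(keep)
  ep <- do.call(rbind, lapply(split(ep, grp), function(b) {
    data.frame(t_start = min(b$t_start), t_end = max(b$t_end),
               rate_1to2 = b$rate_1to2[1], rate_2to1 = b$rate_2to1[1])
  }))
  rownames(ep) <- NULL

  out <- list(
    model_id = model_id,
    N0 = params$N0, NE1 = params$NE1, NE2 = params$NE2,
    T_div = params$T_div, gen_time = params$gen_time,
    mu = params$mu %||% 1e-9,
    epochs = ep,
    params = params
  )
  class(out) <- "dem_scenario"
  out
}

#' @export
print.dem_scenario <- function(x, ...) {
  cat("Two-deme divergence scenario", x$model_id, "\n")
  cat(sprintf("  N0 = %g, NE1 = %g, NE2 = %g diploids\n", x$N0, x$NE1, x$NE2))
  cat(sprintf("  T_div = %g years (%.3g coalescent units), generation time %g y\n",
              x$T_div, years_to_coalescent(x$T_div, x$N0, x$gen_time), x$gen_time))
  cat("  migration epochs (years; forward-time 4*N0*m):\n")
  print(x$epochs, row.names = FALSE)
  invisible(x)
}

#' Convert years before present to coalescent time
#'
#' Coalescent time is measured in units of 4*N0 generations:
#' `t_scaled = t_years / (gen_time * 4 * N0)`.
#'
#' @param t_years time in years (>= 0).
#' @param N0 ancestral diploid effective size.
#' @param gen_time generation time in years.
#' @export
years_to_coalescent <- function(t_years, N0, gen_time) {
  if (any(t_years < 0) || N0 <= 0 || gen_time <= 0)
    stop("years_to_coalescent needs non-negative time and positive N0, gen_time")
  t_years / (gen_time * 4 * N0)
}

#' @rdname years_to_coalescent
#' @param t_scaled time in units of 4*N0 generations.
#' @export
coalescent_to_years <- function(t_scaled, N0, gen_time) {
  if (any(t_scaled < 0) || N0 <= 0 || gen_time <= 0)
    stop("coalescent_to_years needs non-negative time and positive N0, gen_time")
  t_scaled * gen_time * 4 * N0
}
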