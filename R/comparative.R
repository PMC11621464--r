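# ---- linear mixed model: species cell means + colony random intercept ----
#
# y_ij = mu_{species(i)} + b_{colony(i)} + e_ij,  b ~ N(0, sb^2), e ~ N(0, se^2)
# Profiled REML over the variance ratio lambda = sb^2 / se^2: with V
# block-diagonal by colony (V_c = I + lambda J), the GLS species mean is a
# weighted mean of colony means with weights w_c = n_c / (1 + lambda n_c),
# and the whitened residual sum of squares is SSW + sum_c w_c (ybar_c - mu)^2.
# One-dimensional optimization over log(lambda) makes each fit cheap enough to
# sit inside bootstrap loops.

.lmm_stats <- function(y, colony, species_of_colony) {
  n_c <- tabulate(colony)
  sum_c <- unname(rowsum(y, colony)[, 1])
  ybar_c <- sum_c / n_c
  ssw <- sum((y - ybar_c[colony])^2)
  list(n_c = n_c, ybar_c = ybar_c, ssw = ssw, sp = species_of_colony,
       N = length(y), p = max(species_of_colony))
}

.lmm_profile <- function(st, lambda) {
  w <- st$n_c / (1 + lambda * st$n_c)
  sw <- unname(rowsum(w, st$sp)[, 1])
  mu <- unname(rowsum(w * st$ybar_c, st$sp)[, 1]) / sw
  d2 <- (st$ybar_c - mu[st$sp])^2
  rss <- st$ssw + sum(w * d2)
  sigma_e2 <- rss / (st$N - st$p)
  dev <- (st$N - st$p) * log(sigma_e2) + sum(log1p(lambda * st$n_c)) +
    sum(log(sw))
  list(dev = dev, mu = mu, sigma_e2 = sigma_e2, lambda = lambda)
}

# REML fit; returns species estimates and variance components
.lmm_reml <- function(y, colony, species_of_colony) {
  st <- .lmm_stats(y, colony, species_of_colony)
  zero <- .lmm_profile(st, 0)
  if (all(st$n_c == 1L) || st$N <= st$p + 1L ||
      zero$sigma_e2 <= 1e-12 * (1 + mean(y^2))) {
    # variance ratio unidentifiable (or residual variance degenerate);
    # estimates reduce to species means
    return(list(mu = zero$mu, sigma_e2 = max(zero$sigma_e2, 0),
                sigma_b2 = 0, lambda = 0))
  }
  obj <- function(ll) .lmm_profile(st, exp(ll))$dev
  opt <- stats::optimize(obj, c(-12, 12), tol = 1e-6)
  cand <- .lmm_profile(st, exp(opt$minimum))
  fit <- if (zero$dev <= cand$dev) zero else cand
  list(mu = fit$mu, sigma_e2 = fit$sigma_e2,
       sigma_b2 = fit$lambda * fit$sigma_e2, lambda = fit$lambda)
}

# tip values for one trait at one level; returns named vector over species
.tips_one_trait <- function(df, trait) {
  keep <- is.finite(df[[trait]])
  df <- df[keep, , drop = FALSE]
  species <- factor(df$species)
  colony <- factor(paste(df$species, df$colony_id, sep = "\r"))
  sp_of_col <- as.integer(species[match(levels(colony), as.character(colony))])
  fit <- .lmm_reml(df[[trait]], as.integer(colony), sp_of_col)
  stats::setNames(fit$mu, levels(species))
}

#' Species tip values from per-recording metrics
#'
#' Collapses the per-recording metric table into one value per species and
#' trait by fitting, for each trait, a linear mixed model with species as
#' cell-means fixed effects and colony of origin as a random intercept
#' (restricted maximum likelihood). The species coefficient is the tip value;
#' with one recording per colony the estimates reduce to species means. This
#' accounts for intraspecific variation and for colonies recorded twice.
#'
#' @param metrics data.frame with columns `species`, `colony_id`, `level`
#'   (`"colony"`/`"individual"`) and the trait columns `beta`,
#'   `dominant_period_min`, and optionally `walking_speed_bl_s` (individual
#'   rows only), as produced by [rhythm_metrics_table()].
#' @return data.frame with one row per species and columns
#'   `colony_rhythmicity`, `individual_rhythmicity`, `colony_period_min`,
#'   `individual_period_min`, `walking_speed_bl_s` (`NA` where a species has
#'   no data for a trait, with a warning).
#' @export
species_tip_values <- function(metrics) {
  stopifnot(all(c("species", "colony_id", "level") %in% names(metrics)))
  species <- sort(unique(metrics$species))
  out <- data.frame(species = species, stringsAsFactors = FALSE)
  grab <- function(level, trait) {
    df <- metrics[metrics$level == level, , drop = FALSE]
    if (!trait %in% names(df) || !nrow(df)) return(rep(NA_real_, length(species)))
    tv <- .tips_one_trait(df, trait)
    tv[match(species, names(tv))]
  }
  out$colony_rhythmicity <- grab("colony", "beta")
  out$individual_rhythmicity <- grab("individual", "beta")
  out$colony_period_min <- grab("colony", "dominant_period_min")
  out$individual_period_min <- grab("individual", "dominant_period_min")
  out$walking_speed_bl_s <- grab("individual", "walking_speed_bl_s")
  core <- c("colony_rhythmicity", "individual_rhythmicity",
            "colony_period_min", "individual_period_min")
  incomplete <- species[!stats::complete.cases(out[core])]
  if (length(incomplete))
    warning("species with missing tip values: ",
            paste(incomplete, collapse = ", "))
  out
}

#' Standardize species tip values by trait means
#'
#' Divides every species' tip value by the cross-species mean of that trait,
#' so each standardized trait has mean 1. Rates of evolution are compared on
#' this common scale.
#'
#' @param tips data.frame from [species_tip_values()], or any data.frame with
#'   a `species` column and numeric trait columns.
#' @return the data.frame with each numeric column divided by its mean.
#' @export
standardize_traits <- function(tips) {
  num <- vapply(tips, is.numeric, TRUE)
  for (j in which(num)) {
    if (all(is.na(tips[[j]]))) next  # trait absent from this dataset
    m <- mean(tips[[j]], na.rm = TRUE)
    if (!is.finite(m) || m == 0)
      stop("trait '", names(tips)[j], "' has zero or undefined mean",
           call. = FALSE)
    tips[[j]] <- tips[[j]] / m
  }
  tips
}

# ---- Brownian motion rate ----

.check_chronogram <- function(tree, tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"))
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  if (diff(range(depths)) > tol * max(depths))
    stop("tree is not ultrametric within tolerance", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels", call. = FALSE)
  invisible(tree)
}

# core ML fit given an inverse covariance (or its chol); x in C's tip order
.bm_fit_core <- function(x, Cinv, logdetC) {
  n <- length(x)
  one <- rep(1, n)
  Ci1 <- Cinv %*% one
  mu <- drop(crossprod(x, Ci1) / crossprod(one, Ci1))
  r <- x - mu
  sigma2 <- drop(crossprod(r, Cinv %*% r)) / n
  ll <- -0.5 * (n * log(2 * pi * sigma2) + logdetC + n)
  list(sigma2 = sigma2, root_state = mu, log_likelihood = ll)
}

#' Maximum-likelihood Brownian-motion rate of evolution
#'
#' Fits a single-rate Brownian motion model to species tip values on a
#' chronogram: `x ~ Normal(root_state * 1, sigma2 * C)` with `C` the shared
#' branch-length matrix. `sigma2` is the rate of evolution — phenotypic
#' variance accrued per unit of evolutionary time — estimated by maximum
#' likelihood (the `n` denominator, matching standard comparative-methods
#' software defaults). The tree is pruned to the tips with data.
#'
#' @param tree a rooted ultrametric [ape::phylo].
#' @param tips named numeric vector of at least 3 tip values (names = tip
#'   labels).
#' @return list of class `bm_fit`: `sigma2`, `root_state`, `log_likelihood`,
#'   `n`.
#' @export
fit_bm <- function(tree, tips) {
  .check_chronogram(tree)
  tips <- tips[is.finite(tips)]
  if (length(tips) < 2) stop("need >= 2 tips with data", call. = FALSE)
  if (!all(names(tips) %in% tree$tip.label))
    stop("tips absent from tree: ",
         paste(setdiff(names(tips), tree$tip.label), collapse = ", "),
         call. = FALSE)
  if (length(setdiff(tree$tip.label, names(tips))))
    tree <- ape::keep.tip(tree, names(tips))
  C <- ape::vcv(tree)
  x <- tips[rownames(C)]
  ch <- tryCatch(chol(C), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-length tips?)",
         call. = FALSE))
  fit <- .bm_fit_core(x, chol2inv(ch), 2 * sum(log(diag(ch))))
  structure(c(fit, list(n = length(x))), class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("<bm_fit> sigma2 = %.4g, root = %.4g, logLik = %.3f (n = %d)\n",
              x$sigma2, x$root_state, x$log_likelihood, x$n))
  invisible(x)
}

# ---- bootstrap rate comparison ----

# index structure for resampling: per species, the list of sampling units
# (colonies at colony level, individuals at individual level), each unit a
# vector of row indices into the metric table; species in sorted order
.resample_units <- function(df, level) {
  df <- df[df$level == level, , drop = FALSE]
  unit_col <- if (level == "colony") "colony_id" else "individual_id"
  split_units <- split(seq_len(nrow(df)),
                       paste(df$species, df[[unit_col]], sep = "\r"))
  unit_species <- vapply(split_units, function(i) df$species[i[1]], "")
  list(df = df, units = split_units,
       by_species = split(seq_along(split_units), unit_species))
}

# tip values for one resample: `sel` indexes units (with repetition);
# resampled copies of a unit get distinct group labels
.boot_tips <- function(rs, sel, trait) {
  rows <- unlist(rs$units[sel], use.names = FALSE)
  reps <- lengths(rs$units[sel])
  colony <- rep.int(seq_along(sel), reps)
  y <- rs$df[[trait]][rows]
  species <- factor(rs$df$species[rows])
  sp_of_col <- as.integer(species[match(seq_along(sel), colony)])
  fit <- .lmm_reml(y, colony, sp_of_col)
  stats::setNames(fit$mu, levels(species))
}

# one paired replicate: the same uniform draws drive the unit selection at
# both levels (common random numbers), so two literally identical input
# tables give a rate difference of exactly zero in every replicate
.boot_pair_sel <- function(rs_col, rs_ind, species) {
  sel_c <- vector("list", length(species))
  sel_i <- vector("list", length(species))
  for (k in seq_along(species)) {
    uc <- rs_col$by_species[[species[k]]]
    ui <- rs_ind$by_species[[species[k]]]
    u <- stats::runif(max(length(uc), length(ui)))
    sel_c[[k]] <- uc[ceiling(u[seq_along(uc)] * length(uc))]
    sel_i[[k]] <- ui[ceiling(u[seq_along(ui)] * length(ui))]
  }
  list(colony = unlist(sel_c), individual = unlist(sel_i))
}

#' Bootstrap comparison of colony-level vs individual-level evolutionary rates
#'
#' Tests whether a trait evolves faster at the colony level than at the
#' individual level. Within each species, sampling units (colonies with all
#' their recordings at the colony level; individuals at the individual level)
#' are resampled with replacement to the original counts, tip values are
#' recomputed with the mixed model, standardized by their cross-species mean,
#' and a Brownian-motion rate is fit per level. Replicates are paired: the
#' same uniform draws select units at both levels (common random numbers),
#' which sharpens the paired rate difference and makes two identical input
#' tables give a difference of exactly zero. The one-sided p-value is the
#' proportion of replicates whose rate difference (colony minus individual)
#' fails to exceed zero, floored at `1 / n_boot` — so 10,000 replicates with
#' no failures report p = 0.0001.
#'
#' @param metrics per-recording metric table (see [species_tip_values()])
#'   containing both levels for every species analyzed.
#' @param tree chronogram covering the species in `metrics`.
#' @param trait `"rhythmicity"` (the `beta` column) or `"period"`
#'   (`dominant_period_min`).
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param seed integer RNG seed.
#' @return list of class `rate_comparison`: observed rates and their
#'   difference, bootstrap draws per level, `p_value`, `n_boot`, `seed`, and
#'   a `summary` data.frame of rate medians with 2.5/97.5 percentiles.
#' @export
bootstrap_rate_comparison <- function(metrics, tree,
                                      trait = c("rhythmicity", "period"),
                                      n_boot = 10000L, seed = 1L) {
  trait <- match.arg(trait)
  column <- c(rhythmicity = "beta", period = "dominant_period_min")[[trait]]
  .check_chronogram(tree)
  if (n_boot < 100) warning("n_boot < 100 gives a very coarse p-value")
  species <- sort(unique(metrics$species))
  for (lv in c("colony", "individual")) {
    have <- unique(metrics$species[metrics$level == lv &
                                     is.finite(metrics[[column]])])
    if (length(setdiff(species, have)))
      stop("species without ", lv, "-level data: ",
           paste(setdiff(species, have), collapse = ", "), call. = FALSE)
  }
  if (!all(species %in% tree$tip.label))
    stop("species absent from tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "),
         call. = FALSE)
  if (length(setdiff(tree$tip.label, species)))
    tree <- ape::keep.tip(tree, species)
  C <- ape::vcv(tree)
  ch <- chol(C)
  Cinv <- chol2inv(ch)
  logdetC <- 2 * sum(log(diag(ch)))
  ord <- rownames(C)

  rate_of <- function(tips) {
    tips <- tips / mean(tips)  # divide-by-mean standardization
    .bm_fit_core(tips[ord], Cinv, logdetC)$sigma2
  }
  rs_col <- .resample_units(metrics, "colony")
  rs_ind <- .resample_units(metrics, "individual")
  obs_col <- rate_of(.tips_one_trait(rs_col$df, column))
  obs_ind <- rate_of(.tips_one_trait(rs_ind$df, column))

  set.seed(seed)
  draws_col <- numeric(n_boot)
  draws_ind <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    sel <- .boot_pair_sel(rs_col, rs_ind, species)
    draws_col[b] <- rate_of(.boot_tips(rs_col, sel$colony, column))
    draws_ind[b] <- rate_of(.boot_tips(rs_ind, sel$individual, column))
  }
  diffs <- draws_col - draws_ind
  p <- max(1L, sum(diffs <= 0)) / n_boot
  q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  structure(list(
    trait = trait,
    sigma2_colony = obs_col, sigma2_individual = obs_ind,
    observed_difference = obs_col - obs_ind,
    sigma2_colony_draws = draws_col, sigma2_individual_draws = draws_ind,
    p_value = p, n_boot = as.integer(n_boot), seed = as.integer(seed),
    summary = data.frame(level = c("colony", "individual"),
                         median = c(q(draws_col)[1], q(draws_ind)[1]),
                         ci_lo = c(q(draws_col)[2], q(draws_ind)[2]),
                         ci_hi = c(q(draws_col)[3], q(draws_ind)[3]))),
    class = "rate_comparison")
}

#' @export
print.rate_comparison <- function(x, ...) {
  cat(sprintf(
    "<rate_comparison> %s: sigma2 colony %.4g vs individual %.4g (p = %.4g, %d bootstraps)\n",
    x$trait, x$sigma2_colony, x$sigma2_individual, x$p_value, x$n_boot))
  invisible(x)
}

# ---- PGLS ----

#' Phylogenetic generalized least squares regression
#'
#' Regresses `y` on `x` across species with residual covariance proportional
#' to the Brownian-motion matrix `C` implied by the chronogram, testing
#' whether two traits are evolutionarily correlated. The slope t-statistic is
#' referred to a Student t distribution with `n - 2` degrees of freedom
#' (two-sided).
#'
#' @param tree chronogram.
#' @param x,y named numeric vectors of tip values on the same >= 3 tips.
#' @return list of class `pgls_fit`: `slope`, `intercept`, `t_statistic`,
#'   `p_value`, `df`, `slope_se`.
#' @export
pgls <- function(tree, x, y) {
  .check_chronogram(tree)
  common <- intersect(names(x), names(y))
  common <- common[is.finite(x[common]) & is.finite(y[common])]
  if (length(common) < 3) stop("need >= 3 shared tips", call. = FALSE)
  if (!all(common %in% tree$tip.label))
    stop("tips absent from tree", call. = FALSE)
  if (length(setdiff(tree$tip.label, common)))
    tree <- ape::keep.tip(tree, common)
  C <- ape::vcv(tree)
  xv <- x[rownames(C)]; yv <- y[rownames(C)]
  if (stats::sd(xv) == 0) stop("singular design: x is constant", call. = FALSE)
  n <- length(xv)
  X <- cbind(intercept = 1, slope = xv)
  Cinv <- chol2inv(chol(C))
  XtCi <- crossprod(X, Cinv)
  XtCiX_inv <- solve(XtCi %*% X)
  beta <- drop(XtCiX_inv %*% (XtCi %*% yv))
  r <- yv - drop(X %*% beta)
  df <- n - 2L
  s2 <- drop(crossprod(r, Cinv %*% r)) / df
  se <- sqrt(diag(XtCiX_inv) * s2)
  t_stat <- beta[["slope"]] / se[["slope"]]
  structure(list(slope = beta[["slope"]], intercept = beta[["intercept"]],
                 slope_se = se[["slope"]], t_statistic = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df), df = df),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("<pgls_fit> slope %.4g (t = %.3g, df = %d, p = %.3g)\n",
              x$slope, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Sensitivity analysis of PGLS to intraspecific variation
#'
#' Repeats the PGLS after perturbing each species' x and y values with
#' Gaussian noise at that species' intraspecific standard deviation,
#' `n_iter` times. The summary p-value is the median p across iterations;
#' the full distribution is returned.
#'
#' @inheritParams pgls
#' @param x_sd,y_sd named vectors of intraspecific SDs (>= 0) per species;
#'   scalars are recycled.
#' @param n_iter sampling iterations (default 10000).
#' @param seed integer RNG seed.
#' @return list of class `sensitivity_pgls`: `median_p`, `median_slope`,
#'   vectors `p_values` and `slopes`, `n_iter`, `seed`, and the unperturbed
#'   `base_fit`.
#' @export
sensitivity_pgls <- function(tree, x, y, x_sd = 0, y_sd = 0,
                             n_iter = 10000L, seed = 1L) {
  common <- intersect(names(x), names(y))
  x <- x[common]; y <- y[common]
  expand_sd <- function(s) {
    if (length(s) == 1L) return(stats::setNames(rep(s, length(common)), common))
    s[common]
  }
  x_sd <- expand_sd(x_sd); y_sd <- expand_sd(y_sd)
  stopifnot(all(x_sd >= 0), all(y_sd >= 0))
  base_fit <- pgls(tree, x, y)
  set.seed(seed)
  n <- length(common)
  p_values <- numeric(n_iter)
  slopes <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    xi <- x + stats::rnorm(n, 0, x_sd)
    yi <- y + stats::rnorm(n, 0, y_sd)
    f <- pgls(tree, xi, yi)
    p_values[i] <- f$p_value
    slopes[i] <- f$slope
  }
  structure(list(median_p = stats::median(p_values),
                 median_slope = stats::median(slopes),
                 p_values = p_values, slopes = slopes,
                 n_iter = as.integer(n_iter), seed = as.integer(seed),
                 base_fit = base_fit),
            class = "sensitivity_pgls")
}

#' @export
print.sensitivity_pgls <- function(x, ...) {
  cat(sprintf("<sensitivity_pgls> median p = %.3g over %d iterations\n",
              x$median_p, x$n_iter))
  invisible(x)
}

# ---- disparity ----

.sum_of_variances <- function(m) sum(apply(m, 2, stats::var))

#' Bootstrap comparison of colony vs individual phenotypic disparity
#'
#' Compares the total multivariate phenotypic space occupied by species at
#' the two levels. Both point clouds (species x traits, typically
#' rhythmicity and period) are jointly standardized per axis (pooled z-score
#' across the two levels, keeping the spaces comparable), and disparity is
#' the sum of per-axis variances across species. Species rows are resampled
#' with replacement within each level; the one-sided p-value is the
#' proportion of replicates where colony disparity fails to exceed individual
#' disparity, floored at `1 / n_boot`.
#'
#' @param colony_points,individual_points numeric matrices (species x traits)
#'   with matching row (species) sets and the same columns.
#' @param n_boot bootstrap replicates (default 10000).
#' @param seed integer RNG seed.
#' @return list of class `disparity_result`: observed
#'   `sum_of_variances_colony` / `sum_of_variances_individual`, bootstrap
#'   draw vectors, `p_value`, and a median/95% CI `summary`.
#' @export
disparity_comparison <- function(colony_points, individual_points,
                                 n_boot = 10000L, seed = 1L) {
  colony_points <- as.matrix(colony_points)
  individual_points <- as.matrix(individual_points)
  if (nrow(colony_points) < 3) stop("need >= 3 species", call. = FALSE)
  if (!identical(dim(colony_points), dim(individual_points)))
    stop("point matrices must have matching dimensions", call. = FALSE)
  if (!is.null(rownames(colony_points)) &&
      !setequal(rownames(colony_points), rownames(individual_points)))
    stop("point matrices must cover the same species", call. = FALSE)
  pooled <- rbind(colony_points, individual_points)
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, stats::sd)
  if (any(scl == 0)) stop("an axis is constant across all points", call. = FALSE)
  zc <- sweep(sweep(colony_points, 2, ctr), 2, scl, "/")
  zi <- sweep(sweep(individual_points, 2, ctr), 2, scl, "/")
  obs_c <- .sum_of_variances(zc)
  obs_i <- .sum_of_variances(zi)
  n <- nrow(zc)
  set.seed(seed)
  draws_c <- numeric(n_boot); draws_i <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    draws_c[b] <- .sum_of_variances(zc[sample.int(n, n, TRUE), , drop = FALSE])
    draws_i[b] <- .sum_of_variances(zi[sample.int(n, n, TRUE), , drop = FALSE])
  }
  p <- max(1L, sum(draws_c - draws_i <= 0)) / n_boot
  q <- function(x) stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  structure(list(sum_of_variances_colony = obs_c,
                 sum_of_variances_individual = obs_i,
                 colony_draws = draws_c, individual_draws = draws_i,
                 p_value = p, n_boot = as.integer(n_boot),
                 seed = as.integer(seed),
                 summary = data.frame(level = c("colony", "individual"),
                                      median = c(q(draws_c)[1], q(draws_i)[1]),
                                      ci_lo = c(q(draws_c)[2], q(draws_i)[2]),
                                      ci_hi = c(q(draws_c)[3], q(draws_i)[3]))),
            class = "disparity_result")
}

#' @export
print.disparity_result <- function(x, ...) {
  cat(sprintf(
    "<disparity_result> sum of variances: colony %.3g vs individual %.3g (p = %.4g)\n",
    x$sum_of_variances_colony, x$sum_of_variances_individual, x$p_value))
  invisible(x)
}

#' Likelihood-ratio test for interspecific differences in a trait
#'
#' Descriptive check that species differ in a per-recording metric after
#' accounting for colony structure: maximum-likelihood fits of the mixed
#' model with and without the species factor are compared by a chi-square
#' likelihood-ratio test.
#'
#' @param metrics per-recording metric table.
#' @param column metric column to test (e.g. `"beta"`).
#' @param level `"colony"` or `"individual"`.
#' @return data.frame with the LR statistic, df and p-value.
#' @export
species_effect_test <- function(metrics, column, level) {
  df <- metrics[metrics$level == level & is.finite(metrics[[column]]), ,
                drop = FALSE]
  species <- factor(df$species)
  colony <- factor(paste(df$species, df$colony_id, sep = "\r"))
  y <- df[[column]]
  ml_dev <- function(sp_idx, p) {
    st <- .lmm_stats(y, as.integer(colony),
                     sp_idx[match(levels(colony), as.character(colony))])
    dev_at <- function(lambda) {
      w <- st$n_c / (1 + lambda * st$n_c)
      sw <- unname(rowsum(w, st$sp)[, 1])
      mu <- unname(rowsum(w * st$ybar_c, st$sp)[, 1]) / sw
      rss <- st$ssw + sum(w * (st$ybar_c - mu[st$sp])^2)
      s2 <- rss / st$N
      st$N * log(s2) + sum(log1p(lambda * st$n_c))  # ML profile deviance
    }
    opt <- stats::optimize(function(ll) dev_at(exp(ll)), c(-12, 12))
    min(dev_at(0), dev_at(exp(opt$minimum)))
  }
  full <- ml_dev(as.integer(species), nlevels(species))
  null <- ml_dev(rep(1L, length(species)), 1L)
  lr <- null - full
  dfree <- nlevels(species) - 1L
  data.frame(column = column, level = level, lr_statistic = lr, df = dfree,
             p_value = stats::pchisq(lr, dfree, lower.tail = FALSE))
}
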