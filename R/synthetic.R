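# Synthetic cohorts with known ground truth.
#
# The generators invert the decomposition model: sparse super-Gaussian
# gene-weight sources S (components x genes), Gaussian activities A
# (components x samples), expression X = t(S) %*% A + noise, and a
# proportional-hazards survival layer driven by chosen source activities.

#' Generate sparse, heavy-tailed ground-truth sources
#'
#' Each component has `round(active_fraction * n_genes)` "active" genes with
#' one-sided exponential weights (scale 3; super-Gaussian, as ICA assumes,
#' and sign-coherent, as transcriptional programs predominantly induce
#' their targets) and near-zero Gaussian background elsewhere; rows are then
#' standardized to mean 0, SD 1 across genes. Active gene sets are disjoint
#' whenever `n_components * n_active <= n_genes`; otherwise genes are reused
#' as little as possible.
#'
#' @param n_genes number of genes.
#' @param n_components number of sources; must be < `n_genes`.
#' @param active_fraction fraction of genes active per component, in (0, 1).
#' @param seed integer seed.
#' @param active_scale scale of the exponential distribution of active
#'   weights.
#' @return a [tcset] whose `"active_genes"` attribute lists each component's
#'   planted active genes.
#' @export
generate_sources <- function(n_genes, n_components, active_fraction, seed,
                             active_scale = 3) {
  if (n_components >= n_genes) stop("n_components must be smaller than n_genes")
  if (active_fraction <= 0 || active_fraction >= 1)
    stop("active_fraction must lie in (0, 1)")
  set.seed(seed)
  n_active <- max(2L, round(active_fraction * n_genes))
  genes <- sprintf("g%05d", seq_len(n_genes))
  pool <- sample(genes)                       # randomized assignment order
  need <- n_components * n_active
  if (need > n_genes)                         # reuse genes only when forced to
    pool <- rep(pool, length.out = need)
  W <- matrix(rnorm(n_components * n_genes, sd = 0.01), n_components, n_genes,
              dimnames = list(paste0("S", seq_len(n_components)), genes))
  active <- vector("list", n_components)
  for (k in seq_len(n_components)) {
    idx <- pool[((k - 1) * n_active + 1):(k * n_active)]
    active[[k]] <- idx
    W[k, idx] <- active_scale * rexp(n_active)
  }
  names(active) <- rownames(W)
  out <- tcset(W, standardize = TRUE)
  attr(out, "active_genes") <- active
  attr(out, "seed") <- seed
  out
}

#' Mix sources into a synthetic expression matrix
#'
#' Activities are drawn i.i.d. normal(0, `activity_sd`^2); expression is the
#' inner product of activities and source weights plus i.i.d. Gaussian noise.
#'
#' @param truth a [tcset] of standardized sources.
#' @param n_samples number of samples; at least twice the component count.
#' @param activity_sd standard deviation of activities.
#' @param noise_sd standard deviation of additive noise (>= 0).
#' @param seed integer seed.
#' @return list with `expression` (genes x samples) and `mixing`
#'   (components x samples, the true activities).
#' @export
generate_expression <- function(truth, n_samples, activity_sd = 1,
                                noise_sd = 0.1, seed = 1) {
  stopifnot(inherits(truth, "tcset"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  k <- nrow(truth$weights)
  if (n_samples < 2 * k) stop("need n_samples >= 2 x number of components")
  set.seed(seed)
  samples <- sprintf("s%04d", seq_len(n_samples))
  A <- matrix(rnorm(k * n_samples, sd = activity_sd), k, n_samples,
              dimnames = list(rownames(truth$weights), samples))
  X <- crossprod(truth$weights, A)            # genes x samples
  if (noise_sd > 0)
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
  dimnames(X) <- list(colnames(truth$weights), samples)
  list(expression = X, mixing = A)
}

# default categorical covariate frequencies, mirroring a typical early-CRC
# cohort (male-skewed sex ratio, mostly stage 2/3, roughly half of molecular
# annotations unknown)
default_covariate_freqs <- function() {
  list(
    sex      = c(male = 0.53, female = 0.47),
    stage    = c("1" = 0.10, "2" = 0.55, "3" = 0.35),
    location = c(proximal = 0.36, distal = 0.51, unknown = 0.13),
    adjuvant = c(yes = 0.25, no = 0.47, unknown = 0.28),
    msi      = c("MSI-H" = 0.09, "MSS" = 0.43, unknown = 0.48),
    braf     = c(mutated = 0.04, wildtype = 0.43, unknown = 0.53),
    kras     = c(mutated = 0.19, wildtype = 0.32, unknown = 0.49)
  )
}

#' Generate proportional-hazards survival outcomes from component activities
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(sum_k beta_k * activity_k)`; censoring is an
#' independent exponential at `censor_rate` (0 disables censoring). The
#' observed time is the minimum, in months. Categorical clinical covariates
#' (sex, stage, location, adjuvant therapy, MSI, BRAF, KRAS) are sampled from
#' configurable frequencies including explicit "unknown" levels.
#'
#' @param mixing components x samples activity matrix.
#' @param hazard_betas log hazard ratio per unit activity, one per component.
#' @param baseline_rate baseline event rate per month (> 0).
#' @param censor_rate censoring rate per month (>= 0; 0 = no censoring).
#' @param seed integer seed.
#' @param covariate_freqs named list of level-frequency vectors.
#' @return a survival data.frame (see [validate_survival]).
#' @export
generate_survival <- function(mixing, hazard_betas, baseline_rate = 0.02,
                              censor_rate = 0.01, seed = 1,
                              covariate_freqs = default_covariate_freqs()) {
  if (baseline_rate <= 0) stop("baseline_rate must be positive")
  if (censor_rate < 0) stop("censor_rate must be non-negative")
  k <- nrow(mixing); n <- ncol(mixing)
  if (length(hazard_betas) != k)
    stop("hazard_betas must have one value per component")
  set.seed(seed)
  lp <- as.numeric(crossprod(mixing, hazard_betas))
  t_event <- rexp(n, rate = baseline_rate * exp(lp))
  t_cens <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
  surv <- data.frame(sample_id = colnames(mixing),
                     time = pmax(pmin(t_event, t_cens), .Machine$double.eps),
                     event = as.integer(t_event <= t_cens),
                     stringsAsFactors = FALSE)
  for (nm in names(covariate_freqs)) {
    f <- covariate_freqs[[nm]]
    surv[[nm]] <- sample(names(f), n, replace = TRUE, prob = f / sum(f))
  }
  validate_survival(surv)
  surv
}

#' Generate planted and null gene sets against known sources
#'
#' Planted sets are each component's active genes in descending weight
#' order, truncated at the maximum size and padded with random universe
#' genes up to the minimum; null sets are uniform draws from the gene
#' universe. The size range must respect the conventional 10-500 gene-set
#' filter.
#'
#' @param truth a [tcset] from [generate_sources].
#' @param n_null_sets number of null sets.
#' @param set_size_range integer c(min, max) within \[10, 500\].
#' @param planted_per_component planted sets per component.
#' @param seed integer seed.
#' @return a [gene_sets] collection; planted sets are named
#'   `planted_<component>_<j>`.
#' @export
generate_gene_sets <- function(truth, n_null_sets = 100,
                               set_size_range = c(10, 100),
                               planted_per_component = 1, seed = 1) {
  lo <- set_size_range[1]; hi <- set_size_range[2]
  if (lo < 10 || hi > 500 || lo > hi)
    stop("set_size_range must lie within [10, 500]")
  set.seed(seed)
  universe <- colnames(truth$weights)
  active <- attr(truth, "active_genes")
  if (is.null(active)) {
    active <- apply(truth$weights, 1, function(w)
      colnames(truth$weights)[abs(w) >= 2], simplify = FALSE)
  }
  sets <- list()
  for (k in seq_along(active)) {
    w <- truth$weights[k, active[[k]]]
    ordered_active <- names(w)[order(-w)]
    for (j in seq_len(planted_per_component)) {
      g <- ordered_active
      if (length(g) > hi) g <- g[seq_len(hi)]
      if (length(g) < lo)
        g <- c(g, sample(setdiff(universe, g), lo - length(g)))
      sets[[sprintf("planted_%s_%d", names(active)[k], j)]] <- g
    }
  }
  if (n_null_sets > 0) {
    null_sizes <- lo + sample.int(hi - lo + 1L, n_null_sets,
                                  replace = TRUE) - 1L
    for (i in seq_len(n_null_sets))
      sets[[sprintf("null_%04d", i)]] <- sample(universe, null_sizes[i])
  }
  gene_sets(sets, name = "synthetic")
}

#' Generate a spatial expression profile with a planted active region
#'
#' Every spot of a rows-by-cols grid is a sample. The boosted component's
#' activity equals `boost` inside the region mask and 0 outside; all other
#' activities are standard normal. Expression is mixed and noised as in
#' [generate_expression]; spot coordinates are attached as the
#' `"coordinates"` attribute (spot_id, row, col).
#'
#' @param truth a [tcset] of sources.
#' @param grid integer c(rows, cols).
#' @param region_mask logical matrix of the same dimensions.
#' @param boosted_component component id to boost.
#' @param boost activity level inside the mask.
#' @param noise_sd additive noise SD.
#' @param seed integer seed.
#' @return genes x spots expression matrix with a `"coordinates"` attribute
#'   and a `"true_mixing"` attribute.
#' @export
generate_spatial_profile <- function(truth, grid, region_mask,
                                     boosted_component, boost = 5,
                                     noise_sd = 0.1, seed = 1) {
  if (!all(dim(region_mask) == grid)) stop("region_mask must match grid dims")
  if (!any(region_mask)) stop("region mask must contain at least one spot")
  if (!boosted_component %in% rownames(truth$weights))
    stop("unknown boosted_component")
  set.seed(seed)
  n_spots <- prod(grid)
  coords <- expand.grid(row = seq_len(grid[1]), col = seq_len(grid[2]))
  coords <- data.frame(spot_id = sprintf("spot_%04d", seq_len(n_spots)),
                       coords, stringsAsFactors = FALSE)
  k <- nrow(truth$weights)
  A <- matrix(rnorm(k * n_spots), k, n_spots,
              dimnames = list(rownames(truth$weights), coords$spot_id))
  A[boosted_component, ] <- ifelse(region_mask[cbind(coords$row, coords$col)],
                                   boost, 0)
  X <- crossprod(truth$weights, A)
  if (noise_sd > 0)
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
  dimnames(X) <- list(colnames(truth$weights), coords$spot_id)
  attr(X, "coordinates") <- coords
  attr(X, "true_mixing") <- A
  X
}

#' Simulate a full synthetic cohort with ground truth
#'
#' Convenience wrapper chaining [generate_sources], [generate_expression],
#' [generate_survival] and [generate_gene_sets] with seeds derived from one
#' master seed, and attaching planted subgroup labels (median split on the
#' first hazard-driving component's activity).
#'
#' @param n_genes,n_components,n_samples cohort dimensions.
#' @param active_fraction fraction of active genes per source.
#' @param noise_sd expression noise SD; the default 0.7 gives a
#'   signal-to-noise ratio of about 10 at the default five components.
#' @param hazard_betas per-component log hazard ratios (default: first
#'   component at 1, rest 0).
#' @param baseline_rate,censor_rate survival rates per month.
#' @param n_null_sets null gene sets to plant alongside one planted set per
#'   component.
#' @param seed master seed.
#' @return list with `truth`, `expression`, `mixing`, `survival`,
#'   `gene_sets`, `hazard_betas`, `subgroups`, `seed`.
#' @export
simulate_cohort <- function(n_genes = 1000, n_components = 5, n_samples = 300,
                            active_fraction = 0.1, noise_sd = 0.7,
                            hazard_betas = NULL, baseline_rate = 0.02,
                            censor_rate = 0.01, n_null_sets = 50, seed = 1) {
  truth <- generate_sources(n_genes, n_components, active_fraction, seed = seed)
  mix <- generate_expression(truth, n_samples, activity_sd = 1,
                             noise_sd = noise_sd, seed = seed + 1L)
  if (is.null(hazard_betas))
    hazard_betas <- c(1, rep(0, n_components - 1))
  surv <- generate_survival(mix$mixing, hazard_betas,
                            baseline_rate = baseline_rate,
                            censor_rate = censor_rate, seed = seed + 2L)
  gs <- generate_gene_sets(truth, n_null_sets = n_null_sets, seed = seed + 3L)
  driver <- which(hazard_betas != 0)[1]
  if (is.na(driver)) driver <- 1L
  subgroups <- as.integer(mix$mixing[driver, ] > median(mix$mixing[driver, ])) + 1L
  list(truth = truth, expression = mix$expression, mixing = mix$mixing,
       survival = surv, gene_sets = gs, hazard_betas = hazard_betas,
       subgroups = setNames(subgroups, colnames(mix$mixing)), seed = seed)
}
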